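# Simulation against analytic oracles, steady-state finding, and metabolic
# control analysis.

test_that("a single Michaelis-Menten drain matches its Lambert-W solution", {
  A0 <- 10; vmax <- 0.05; km <- 2
  m <- mm_drain_model(A0, vmax, km)
  tr <- simulate_timecourse(m, duration = 400, n_out = 41,
                            reltol = 1e-10, abstol = 1e-12)
  # implicit solution Km log(A0/A) + (A0 - A) = Vmax t, solved explicitly
  # with the principal Lambert W branch
  analytic <- km * pracma::lambertWp(
    (A0 / km) * exp((A0 - vmax * tr$time) / km))
  expect_lt(max(abs(tr$conc[, "A"] - analytic)) / A0, 1e-6)
})

test_that("simulation is insensitive to halving the integrator tolerances", {
  m <- producing_model("Glu-Mcoa-AA")
  t1 <- simulate_timecourse(m, duration = 3600, n_out = 5,
                            reltol = 1e-8, abstol = 1e-10)
  t2 <- simulate_timecourse(m, duration = 3600, n_out = 5,
                            reltol = 5e-9, abstol = 5e-11)
  i <- nrow(t1$conc)
  rel <- abs(t1$conc[i, ] - t2$conc[i, ]) / pmax(abs(t1$conc[i, ]), 1e-4)
  expect_lt(max(rel), 1e-6)
})

test_that("the linear-chain steady state matches its closed form", {
  k0 <- 0.02; k1 <- 0.1; k2 <- 0.05
  m <- linear_chain_model(k0, k1, k2)
  ss <- find_steady_state(m)
  expect_lt(ss$residual, 1e-10)
  expect_true(ss$stable)
  expect_equal(unname(ss$concentrations["A"]), k0 / k1, tolerance = 1e-8)
  expect_equal(unname(ss$concentrations["B"]), k0 / k2, tolerance = 1e-8)
})

test_that("a batch model settles in the carbon-exhausted state or reports failure", {
  ch <- default_chassis()
  res <- tryCatch(find_steady_state(ch$kinetic), error = function(e) e)
  if (inherits(res, "error")) {
    expect_match(conditionMessage(res), "no steady state")
  } else {
    # essentially all of the 55.5 mM of glucose is gone
    expect_lt(unname(res$concentrations["GLCx"]), 0.05)
  }
})

test_that("the continuous chassis has a stable steady state at tight residual", {
  cont <- make_continuous(default_chassis()$kinetic)
  ss <- find_steady_state(cont)
  expect_lt(ss$residual, 1e-10)
  expect_true(ss$stable)
  expect_lt(ss$eig_max, 0)
  # all concentrations non-negative and the pools conserved
  expect_true(all(ss$concentrations >= -1e-12))
  tot <- function(ids) sum(ss$concentrations[ids])
  expect_equal(tot(c("NAD", "NADH")), 1.65, tolerance = 1e-6)
  expect_equal(tot(c("NADP", "NADPH")), 0.2, tolerance = 1e-6)
  expect_equal(tot(c("ATP", "ADP", "AMP")), 3.4, tolerance = 1e-6)
})

test_that("the isolated MM elasticity is Km/(Km+S)", {
  m <- mm_drain_model(A0 = 1.7, vmax = 0.3, km = 2.2)
  sys <- assemble_odes(m)
  y <- c(A = 1.7)
  dv <- aakin:::flux_jacobian(sys$fluxes, y)
  eps <- dv["drain", "A"] * y[["A"]] / sys$fluxes(y)[["drain"]]
  expect_equal(unname(eps), 2.2 / (2.2 + 1.7), tolerance = 1e-6)
})

test_that("a single controlling step carries all flux control", {
  # saturating supply (zero elasticity downstream of X) means the supply
  # step holds the whole summation-theorem budget
  m <- kinetic_model(
    rbind(species("X", 5, fixed = TRUE), species("A", 0.1)),
    list(reaction("supply", c(A = 1), rate_law("michaelis_menten_1s"),
                  roles = c(A = "X"), params = c(Vmax = 0.1, Km = 1)),
         reaction("use", c(A = -1), rate_law("michaelis_menten_1s"),
                  roles = c(A = "A"), params = c(Vmax = 0.3, Km = 1))))
  ss <- find_steady_state(m)
  fcc <- flux_control_coefficients(m, ss, "use")
  expect_equal(fcc$fcc_structural[fcc$reaction == "supply"], 1,
               tolerance = 1e-6)
  expect_equal(fcc$fcc_structural[fcc$reaction == "use"], 0,
               tolerance = 1e-6)
  expect_equal(attr(fcc, "sums")[["structural"]], 1, tolerance = 1e-9)
})

test_that("two-enzyme chain control matches the elasticity closed form", {
  V1 <- 0.1; K1 <- 0.5; Ki <- 0.8; V2 <- 0.15; K2 <- 0.6; X <- 1
  m <- two_enzyme_chain(V1, K1, Ki, V2, K2, X)
  ss <- find_steady_state(m)
  S <- unname(ss$concentrations["S"])
  # scaled elasticities of the two rates with respect to S:
  #   e1 = -K1 S / (Ki D) with D = K1 (1 + S/Ki) + X   (product inhibition)
  #   e2 = K2/(K2 + S)
  D <- K1 * (1 + S / Ki) + X
  e1 <- -K1 * S / (Ki * D)
  e2 <- K2 / (K2 + S)
  want <- c(e1 = e2 / (e2 - e1), e2 = -e1 / (e2 - e1))
  fcc <- flux_control_coefficients(m, ss, "e2", fd = TRUE)
  got_struct <- stats::setNames(fcc$fcc_structural, fcc$reaction)
  got_fd <- stats::setNames(fcc$fcc_fd, fcc$reaction)
  expect_equal(got_struct[["e1"]], want[["e1"]], tolerance = 1e-5)
  expect_equal(got_struct[["e2"]], want[["e2"]], tolerance = 1e-5)
  # the finite-difference oracle agrees with both
  expect_equal(got_fd[["e1"]], want[["e1"]], tolerance = 1e-3)
  expect_equal(got_fd[["e2"]], want[["e2"]], tolerance = 1e-3)
  expect_equal(attr(fcc, "sums")[["structural"]], 1, tolerance = 1e-9)
})

test_that("summation theorem and structural/FD agreement hold on the chassis", {
  cont <- make_continuous(default_chassis()$kinetic)
  ss <- find_steady_state(cont)
  fcc <- flux_control_coefficients(cont, ss, "oaa_sink", fd = TRUE)
  expect_lt(abs(attr(fcc, "sums")[["structural"]] - 1), 1e-3)
  big <- !is.na(fcc$fcc_fd) & abs(fcc$fcc_structural) > 0.05
  expect_true(any(big))
  rel <- abs(fcc$fcc_fd[big] - fcc$fcc_structural[big]) /
    abs(fcc$fcc_structural[big])
  expect_lt(max(rel), 0.01)
  # near-zero coefficients agree absolutely (finite differences carry a
  # noise floor there)
  small <- !is.na(fcc$fcc_fd) & !big
  expect_lt(max(abs(fcc$fcc_fd[small] - fcc$fcc_structural[small])), 0.01)
})

test_that("control analysis refuses unstable steady states", {
  cont <- make_continuous(default_chassis()$kinetic)
  ss <- find_steady_state(cont)
  ss$stable <- FALSE
  expect_error(flux_control_coefficients(cont, ss, "pts"),
               "unstable.*refusing")
})

test_that("MCA runs on the producing variants with unit summation", {
  for (nm in c("Glu-Gly-AA", "Glu-Mcoa-AA", "Glu-Ba-AA")) {
    cont <- make_continuous(producing_model(nm))
    ss <- find_steady_state(cont)
    expect_true(ss$stable, info = nm)
    fcc <- flux_control_coefficients(cont, ss, "AcoaTioE", fd = FALSE)
    expect_lt(abs(attr(fcc, "sums")[["structural"]] - 1), 1e-3)
    expect_true(all(is.finite(fcc$fcc_structural)), info = nm)
  }
})
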