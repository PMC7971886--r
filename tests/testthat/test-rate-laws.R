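# Rate-law library: printed-constant identities, frozen oracle values, and
# the structural properties every mechanism must satisfy.

# parameter sets giving every mechanism a valid, generic configuration
generic_params <- list(
  michaelis_menten_1s = c(Vmax = 2, Km = 0.5),
  mm_2s_multiplicative = c(Vmax = 2, Km_a = 0.5, Km_b = 0.8),
  mm_2s_random_bibi_denominator = c(Vmax = 2, Km_a = 0.5, Km_b = 0.8,
                                    Kd_a = 0.3),
  mm_competitive_product_inhibition_2s =
    c(Vmax = 2, Km_a = 0.5, Km_b = 0.8, Ki_p = 0.4),
  mm_3s_multiplicative = c(Vmax = 2, Km_a = 0.5, Km_b = 0.8, Km_c = 0.2),
  rapid_equilibrium_random_bibi_reversible =
    c(Vmax = 2, Km_a = 0.5, Km_b = 0.8, Km_p = 0.3, Km_q = 0.6, Keq = 9),
  ordered_bibi_product_inhibition =
    c(Vmax = 2, Km_a = 0.5, Km_b = 0.8, Ki_p = 0.4),
  ping_pong_bibi_reversible =
    c(Vmax = 2, Km_a = 0.5, Km_b = 0.8, Km_p = 0.3, Km_q = 0.6, Keq = 9),
  ping_pong_bibi_substrate_inhibition =
    c(Vmax = 2, Km_a = 0.5, Km_b = 0.8, Ki_b = 4),
  hill_2s = c(Vmax = 2, Km_a = 0.5, Km_b = 0.8, n = 1.7),
  specific_activation = c(Vmax = 2, Km_a = 0.5, Ka = 0.05),
  mass_action = c(k = 2),
  mass_action_reversible = c(k = 2, Keq = 9))

generic_conc <- function(law) {
  cc <- c(A = 0.7, B = 1.2, C = 0.9, P = 0.2, Q = 0.15, Activator = 0.5)
  roles <- if (law$mechanism %in% c("mass_action")) c("A", "B")
           else law$roles
  cc[roles]
}

test_that("printed-constant identities hold at characteristic points", {
  # half saturation of the glycerol-3-phosphatase law at its printed Km
  expect_equal(evaluate_rate(rate_law("michaelis_menten_1s"),
                             c(Vmax = 1, Km = 2.9), c(A = 2.9)), 0.5)
  # G3pD at the mass-action ratio equal to Keq = 900: net rate is zero
  g3pd <- c(Vmax = 1, Km_a = 0.175, Km_b = 0.0037, Km_p = 0.12,
            Km_q = 0.165, Keq = 900)
  expect_equal(evaluate_rate(rate_law("rapid_equilibrium_random_bibi_reversible"),
                             g3pd, c(A = 0.3, B = 0.5, P = 900 * 0.3,
                                     Q = 0.5)), 0)
  # elementary mass action is the product of its substrates
  expect_equal(evaluate_rate(rate_law("mass_action"), c(k = 1),
                             c(A = 2, B = 3)), 6)
})

test_that("ping-pong substrate-inhibition law matches the independent substitution oracle", {
  # expected values frozen from symbolic substitution of the canonical
  # closed form at the printed BaTA constants (E = 100 mM, A = Km_a,
  # B = Km_b)
  law <- rate_law("ping_pong_bibi_substrate_inhibition")
  p <- c(Kcat = 47.4, E_total = 100, Km_a = 5.8, Km_b = 1.07, Ki_b = 10.2)
  cc <- c(A = 5.8, B = 1.07)
  expect_equal(evaluate_rate(law, p, cc), 1526.6182507104513,
               tolerance = 1e-12)
  expect_equal(saturation_factor(law, p, cc), 0.32207136090937794,
               tolerance = 1e-12)
})

test_that("rapid-equilibrium random bi-bi matches the substitution oracle at a generic point", {
  law <- rate_law("rapid_equilibrium_random_bibi_reversible")
  p <- c(Vmax = 2.5, Km_a = 0.175, Km_b = 0.0037, Km_p = 0.12,
         Km_q = 0.165, Keq = 900)
  expect_equal(evaluate_rate(law, p, c(A = 0.7, B = 0.02, P = 0.3, Q = 0.5)),
               1.1834012741330258, tolerance = 1e-12)
})

test_that("every law is homogeneous of degree 1 in its maximal-rate parameter", {
  set.seed(42)
  for (mech in list_mechanisms()) {
    law <- rate_law(mech)
    p <- generic_params[[mech]]
    for (rep in 1:5) {
      cc <- generic_conc(law) * stats::runif(length(generic_conc(law)),
                                             0.2, 3)
      v1 <- evaluate_rate(law, p, cc)
      p2 <- p
      scale_slot <- if ("Vmax" %in% names(p)) "Vmax"
                    else if ("Kcat" %in% names(p)) "Kcat" else "k"
      p2[scale_slot] <- 2 * p[scale_slot]
      expect_equal(evaluate_rate(law, p2, cc), 2 * v1, tolerance = 1e-12,
                   info = mech)
    }
  }
  # Kcat/E_total parameterisation scales identically through either factor
  p <- c(Kcat = 47.4, E_total = 100, Km_a = 5.8, Km_b = 1.07, Ki_b = 10.2)
  law <- rate_law("ping_pong_bibi_substrate_inhibition")
  p2 <- p; p2["E_total"] <- 200
  expect_equal(evaluate_rate(law, p2, c(A = 1, B = 1)),
               2 * evaluate_rate(law, p, c(A = 1, B = 1)))
})

test_that("irreversible laws are monotone in substrates; BaTA has an interior optimum in B", {
  mono <- c("michaelis_menten_1s", "mm_2s_multiplicative",
            "mm_2s_random_bibi_denominator",
            "mm_competitive_product_inhibition_2s", "mm_3s_multiplicative",
            "ordered_bibi_product_inhibition", "hill_2s",
            "specific_activation", "mass_action")
  for (mech in mono) {
    law <- rate_law(mech)
    p <- generic_params[[mech]]
    roles <- if (mech == "mass_action") c("A", "B") else law$roles
    subs <- setdiff(roles, c("P", "Q"))
    for (role in subs) {
      grid <- seq(0, 5, length.out = 30)
      vals <- vapply(grid, function(x) {
        cc <- generic_conc(law); cc[role] <- x
        evaluate_rate(law, p, cc)
      }, numeric(1))
      expect_true(all(diff(vals) > -1e-12), info = paste(mech, role))
    }
  }
  # substrate inhibition: rate in B rises then falls, with an interior max
  law <- rate_law("ping_pong_bibi_substrate_inhibition")
  p <- generic_params$ping_pong_bibi_substrate_inhibition
  grid <- seq(0.01, 60, length.out = 400)
  vals <- vapply(grid, function(b)
    evaluate_rate(law, p, c(A = 0.7, B = b)), numeric(1))
  i <- which.max(vals)
  expect_gt(i, 1)
  expect_lt(i, length(grid))
})

test_that("reversible laws change sign exactly on the equilibrium manifold", {
  set.seed(7)
  for (mech in c("rapid_equilibrium_random_bibi_reversible",
                 "ping_pong_bibi_reversible")) {
    law <- rate_law(mech)
    p <- generic_params[[mech]]
    for (rep in 1:10) {
      A <- runif(1, 0.1, 2); B <- runif(1, 0.1, 2); Q <- runif(1, 0.1, 2)
      Peq <- A * B * p[["Keq"]] / Q
      expect_equal(evaluate_rate(law, p, c(A = A, B = B, P = Peq, Q = Q)),
                   0, tolerance = 1e-12)
      expect_gt(evaluate_rate(law, p, c(A = A, B = B, P = 0.9 * Peq, Q = Q)), 0)
      expect_lt(evaluate_rate(law, p, c(A = A, B = B, P = 1.1 * Peq, Q = Q)), 0)
    }
  }
})

test_that("Hill law with n = 1 reduces to multiplicative Michaelis-Menten", {
  set.seed(11)
  hill <- rate_law("hill_2s"); mm <- rate_law("mm_2s_multiplicative")
  for (rep in 1:20) {
    cc <- c(A = runif(1, 0.01, 5), B = runif(1, 0.01, 5))
    p <- c(Vmax = runif(1, 0.1, 10), Km_a = runif(1, 0.05, 2),
           Km_b = runif(1, 0.05, 2))
    v_h <- evaluate_rate(hill, c(p, n = 1), cc)
    v_m <- evaluate_rate(mm, p, cc)
    expect_equal(v_h, v_m, tolerance = 1e-12)
  }
})

test_that("saturation factor satisfies rate = Vmax * F and the saturation limits", {
  for (mech in setdiff(list_mechanisms(),
                       c("mass_action", "mass_action_reversible"))) {
    law <- rate_law(mech)
    p <- generic_params[[mech]]
    cc <- generic_conc(law)
    FF <- saturation_factor(law, p, cc)
    expect_equal(p[["Vmax"]] * FF, evaluate_rate(law, p, cc),
                 tolerance = 1e-12, info = mech)
  }
  # half saturation
  expect_equal(saturation_factor(rate_law("michaelis_menten_1s"),
                                 c(Vmax = 7, Km = 1.3), c(A = 1.3)), 0.5)
  # saturating limit -> 1 for the saturating irreversible mechanisms
  for (mech in c("michaelis_menten_1s", "mm_2s_multiplicative",
                 "mm_3s_multiplicative", "hill_2s", "specific_activation")) {
    law <- rate_law(mech)
    cc <- generic_conc(law); cc[] <- 1e9
    expect_equal(saturation_factor(law, generic_params[[mech]], cc), 1,
                 tolerance = 1e-6, info = mech)
  }
})

test_that("denominators are strictly positive away from the origin guard", {
  # every canonical form with a constant denominator term evaluates finite
  # at zero concentrations
  for (mech in setdiff(list_mechanisms(),
                       c("ping_pong_bibi_substrate_inhibition",
                         "mass_action", "mass_action_reversible"))) {
    law <- rate_law(mech)
    cc <- generic_conc(law); cc[] <- 0
    expect_true(is.finite(evaluate_rate(law, generic_params[[mech]], cc)),
                info = mech)
  }
  # the substrate-inhibition form's denominator vanishes at the origin;
  # the implementation returns the (zero) limit
  expect_identical(
    evaluate_rate(rate_law("ping_pong_bibi_substrate_inhibition"),
                  generic_params$ping_pong_bibi_substrate_inhibition,
                  c(A = 0, B = 0)), 0)
})

test_that("binding errors name the missing slot and reject negative concentrations", {
  law <- rate_law("mm_2s_multiplicative")
  expect_error(evaluate_rate(law, c(Vmax = 1, Km_a = 1, Km_b = 1),
                             c(A = 1)), "incomplete binding.*B")
  expect_error(evaluate_rate(law, c(Vmax = 1, Km_a = 1),
                             c(A = 1, B = 1)), "incomplete binding.*Km_b")
  expect_error(evaluate_rate(law, c(Km_a = 1, Km_b = 1), c(A = 1, B = 1)),
               "incomplete binding.*Vmax")
  expect_error(evaluate_rate(law, c(Vmax = 1, Km_a = 1, Km_b = 1),
                             c(A = -0.1, B = 1)), "negative concentration")
})
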