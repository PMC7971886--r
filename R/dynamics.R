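#' Time-course simulation, steady states and metabolic control analysis
#'
#' Batch time courses are integrated with the stiff-capable LSODA switching
#' integrator. Steady states are located by integrating towards equilibrium
#' and polishing with a damped Newton iteration on the conservation-reduced
#' system (cofactor pools are conserved moieties, so the full Jacobian is
#' singular; the link-matrix reduction removes the redundancy). Flux
#' control coefficients for a target flux are computed two ways — from the
#' elasticity/link-matrix algebra and by finite-difference re-solution of
#' the steady state — and both are reported.
#'
#' @name dynamics
NULL

#' Simulate a batch time course
#'
#' @param model an `aakin_model`.
#' @param duration simulated time, s (10800 = 3 h, 21600 = 6 h).
#' @param reltol,abstol integrator tolerances.
#' @param n_out number of output time points.
#' @param y0 optional named initial state overriding the model's initial
#'   concentrations (dynamic species only).
#' @return an `aakin_trajectory`: list with `time` (s), `conc` (mM,
#'   clamped at 0 for reporting), `flux` (mM/s), `model`.
#' @export
simulate_timecourse <- function(model, duration = 10800, reltol = 1e-8,
                                abstol = 1e-10, n_out = 241, y0 = NULL) {
  sys <- assemble_odes(model)
  start <- sys$y0
  if (!is.null(y0)) start[names(y0)] <- y0
  times <- seq(0, duration, length.out = n_out)
  out <- deSolve::lsoda(start, times, sys$rhs, parms = NULL,
                        rtol = reltol, atol = abstol, maxsteps = 50000)
  if (attr(out, "istate")[1] < 0)
    stop("integration failure after t = ", max(out[, "time"]), " s",
         call. = FALSE)
  conc <- out[, sys$state_ids, drop = FALSE]
  flux <- t(apply(conc, 1, sys$fluxes))
  conc[conc < 0] <- 0
  structure(list(time = out[, "time"], conc = conc, flux = flux,
                 model = model),
            class = "aakin_trajectory")
}

#' @export
print.aakin_trajectory <- function(x, ...) {
  cat("<trajectory>", length(x$time), "points over",
      max(x$time), "s,", ncol(x$conc), "species\n")
  invisible(x)
}

.titer_compound <- c(GLCx = "glucose", GLYx = "glycerol",
                     HPx = "3-HP", HP = "3-HP", AAx = "AA", AA = "AA")

#' Final-time titer of a species in g/L
#'
#' @param traj an `aakin_trajectory`.
#' @param species_id one of GLCx, GLYx, HP, HPx, AA, AAx.
#' @param time time point, s; defaults to the trajectory end.
#' @export
titer_gL <- function(traj, species_id, time = NULL) {
  if (!species_id %in% names(.titer_compound))
    stop("no molar mass known for ", species_id, call. = FALSE)
  i <- if (is.null(time)) length(traj$time)
       else which.min(abs(traj$time - time))
  convert_concentration(traj$conc[i, species_id], "mM_to_gL",
                        .titer_compound[[species_id]])
}

#' Write a trajectory as CSV
#'
#' RFC-4180 CSV with header `time_s,<species>...`, concentrations in mM.
#' @param traj an `aakin_trajectory`.
#' @param path output path.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- data.frame(time_s = traj$time, traj$conc, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- continuous variant ----------------------------------------------------

#' Continuous (feed-and-drain) variant of a batch model
#'
#' Adds a constant-rate feed for the carbon source and first-order drains
#' for glycerol, malonyl-CoA, beta-alanine and the end product, so the
#' model admits the steady state required for control analysis. The feed
#' default is the uptake flux of the batch model evaluated mid-exponential
#' (carbon source at half its initial concentration), scaled by a safety
#' margin so the continuous operating point sits strictly inside the
#' uptake capacity — a feed at the measured flux itself can be
#' unsustainable once pathway edits shift the balance, leaving the
#' carbon source drifting without bound.
#'
#' @param model batch `aakin_model`.
#' @param feed_rate constant carbon-source feed, mM/s; `NULL` = default.
#' @param feed_frac safety factor applied to the default feed.
#' @param drain_k first-order drain constant, 1/s.
#' @param drain_species intracellular species to drain (those present are
#'   used); extracellular product pools (HPx/AAx) are always drained so
#'   they do not accumulate without bound.
#' @param uptake_reaction id of the carbon-uptake reaction; autodetected
#'   from the chassis annotation when `NULL`.
#' @return an `aakin_model` with `feed_carbon` and `drain_*` reactions.
#' @export
make_continuous <- function(model, feed_rate = NULL, drain_k = 0.01,
                            drain_species = c("GLY", "MCOA", "BA", "AA"),
                            uptake_reaction = NULL, feed_frac = 0.9) {
  sp <- model$species
  carbon_sp <- if (isTRUE(model$annotations$carbon_source == "glycerol"))
    "GLYx" else "GLCx"
  if (is.null(uptake_reaction))
    uptake_reaction <- if (carbon_sp == "GLYx") "glyt" else "pts"
  if (is.null(feed_rate)) {
    # mid-exponential uptake flux of the batch model: first time point at
    # which half the carbon source is consumed
    tr <- simulate_timecourse(model, duration = 21600, n_out = 121)
    half <- tr$conc[1, carbon_sp] / 2
    i <- which(tr$conc[, carbon_sp] <= half)
    i <- if (length(i)) i[1] else nrow(tr$conc)
    feed_rate <- feed_frac * unname(tr$flux[i, uptake_reaction])
    if (!is.finite(feed_rate) || feed_rate <= 0)
      stop("cannot derive a default feed rate from ", uptake_reaction,
           call. = FALSE)
  }
  if (!"FEED" %in% sp$id)
    sp <- rbind(sp, species("FEED", 1, fixed = TRUE,
                            name = "constant feed driver"))
  rxns <- model$reactions
  rxns$feed_carbon <- reaction(
    "feed_carbon", stats::setNames(1, carbon_sp), rate_law("mass_action"),
    roles = c(A = "FEED"), params = c(k = feed_rate))
  targets <- intersect(c(drain_species, "HPx", "AAx"), sp$id)
  for (s in targets) {
    sto <- stats::setNames(-1, s)
    # draining a CoA thioester must hand the carrier back to the pool
    if (s %in% c("ACCOA", "MCOA", "HPCOA", "AACOA") && "COA" %in% sp$id)
      sto <- c(sto, COA = 1)
    rxns[[paste0("drain_", s)]] <- reaction(
      paste0("drain_", s), sto, rate_law("mass_action"),
      roles = c(A = s), params = c(k = drain_k))
  }
  kinetic_model(sp, rxns, compartments = model$compartments,
                annotations = utils::modifyList(
                  model$annotations,
                  list(continuous = "yes", feed_rate = feed_rate,
                       drain_k = drain_k)))
}

# ---- steady state ----------------------------------------------------------

# Conservation-aware reduction: independent species (rows of the free
# stoichiometric matrix spanning its row space) and the link matrix L with
# N = L %*% N[indep, ].
reduce_network <- function(S) {
  qrt <- qr(t(S))
  rank <- qrt$rank
  indep <- sort(qrt$pivot[seq_len(rank)])
  NR <- S[indep, , drop = FALSE]
  # L: rows l_i solving n_i = l_i NR  =>  L = S %*% NR^+ (pseudo-inverse)
  L <- t(qr.solve(tcrossprod(NR), NR %*% t(S)))
  list(indep = indep, NR = NR, L = L)
}

# numerical reaction-rate Jacobian dv/ds at full-state y (free species)
flux_jacobian <- function(fluxes, y) {
  v0 <- fluxes(y)
  J <- matrix(0, length(v0), length(y),
              dimnames = list(names(v0), names(y)))
  for (j in seq_along(y)) {
    h <- max(1e-7 * abs(y[j]), 1e-9)
    yp <- y; yp[j] <- y[j] + h
    ym <- y; ym[j] <- max(y[j] - h, 0)
    J[, j] <- (fluxes(yp) - fluxes(ym)) / (yp[j] - ym[j])
  }
  J
}

#' Find a steady state of a kinetic model
#'
#' Integrates towards equilibrium and polishes the root of the reduced
#' right-hand side with a damped Newton iteration under non-negativity.
#' Models without a feasible steady state (e.g. batch models that simply
#' exhaust their carbon) report `"no steady state"`.
#'
#' @param model an `aakin_model` (normally a [make_continuous()] variant).
#' @param guess optional named initial state.
#' @param tol residual tolerance on `max |d[S]/dt|`, mM/s.
#' @param t_settle integration horizons tried before/between Newton
#'   polishing.
#' @return an `aakin_steady_state`: `concentrations`, `fluxes`, `residual`,
#'   `stable` (max real part of the reduced Jacobian spectrum < 0),
#'   `eig_max`.
#' @export
find_steady_state <- function(model, guess = NULL, tol = 1e-8,
                              t_settle = c(1e3, 1e4, 1e5, 1e6)) {
  sys <- assemble_odes(model)
  y <- sys$y0
  if (!is.null(guess)) y[names(guess)] <- guess
  red <- reduce_network(sys$S)
  rhs_full <- function(y) as.vector(sys$S %*% sys$fluxes(y))

  newton_polish <- function(y, iters = 30) {
    for (it in seq_len(iters)) {
      g <- (red$NR %*% sys$fluxes(y))[, 1]
      if (max(abs(rhs_full(y))) < tol) return(y)
      dv <- flux_jacobian(sys$fluxes, y)
      M <- red$NR %*% dv %*% red$L
      step <- tryCatch(-solve(M, g), error = function(e) NULL)
      if (is.null(step)) return(y)
      full_step <- as.vector(red$L %*% step)
      lam <- 1
      repeat {
        cand <- y + lam * full_step
        if (all(cand > -1e-12)) {
          cand[cand < 0] <- 0
          gc2 <- (red$NR %*% sys$fluxes(cand))[, 1]
          if (sum(gc2^2) < sum(g^2) || lam < 1e-6) { y <- cand; break }
        }
        lam <- lam / 2
        if (lam < 1e-10) return(y)
      }
    }
    y
  }

  best <- y
  for (tt in t_settle) {
    out <- tryCatch(
      deSolve::lsoda(best, c(0, tt), sys$rhs, parms = NULL,
                     rtol = 1e-8, atol = 1e-10, maxsteps = 500000),
      error = function(e) NULL)
    if (!is.null(out) && attr(out, "istate")[1] >= 0)
      best <- pmax(out[nrow(out), sys$state_ids], 0)
    best <- newton_polish(best)
    if (max(abs(rhs_full(best))) < tol) break
  }
  res <- max(abs(rhs_full(best)))
  if (res >= tol * 100)
    stop("no steady state (residual ", signif(res, 3), " mM/s)",
         call. = FALSE)
  dv <- flux_jacobian(sys$fluxes, best)
  M <- red$NR %*% dv %*% red$L
  eig <- eigen(M, only.values = TRUE)$values
  structure(list(concentrations = best, fluxes = sys$fluxes(best),
                 residual = res, eig_max = max(Re(eig)),
                 stable = max(Re(eig)) < 1e-9),
            class = "aakin_steady_state")
}

#' @export
print.aakin_steady_state <- function(x, ...) {
  cat(sprintf("<steady state> residual %.3g mM/s, %s (max Re eig %.3g)\n",
              x$residual, if (x$stable) "stable" else "UNSTABLE",
              x$eig_max))
  invisible(x)
}

# ---- metabolic control analysis -------------------------------------------

#' Flux control coefficients for a target flux
#'
#' Scaled flux control coefficients `C^J_i` of every reaction over the
#' steady flux through `target`, computed two interchangeable ways:
#' structurally, from the elasticity matrix and the conservation link
#' matrix (`C = I - (dv/ds) L M^{-1} N_R`, scaled by `v_j / J`), and by
#' central finite differences on the enzyme activity (1% Vmax
#' perturbations with the steady state re-solved). The summation theorem
#' (`sum_i C^J_i = 1`) is a built-in diagnostic.
#'
#' @param model continuous `aakin_model`.
#' @param steady a stable [find_steady_state()] result.
#' @param target reaction id of the target flux (for acrylic-acid models,
#'   the AA-forming AcoaTioE step).
#' @param fd logical; also compute the finite-difference column.
#' @param delta relative Vmax perturbation for the finite-difference route.
#' @return an `aakin_fcc_table`: data frame with `reaction`,
#'   `fcc_structural`, `fcc_fd`, plus attributes `target` and `sums`.
#' @export
flux_control_coefficients <- function(model, steady, target, fd = TRUE,
                                      delta = 0.01) {
  if (!target %in% names(model$reactions))
    stop("unknown target reaction: ", target, call. = FALSE)
  if (!isTRUE(steady$stable))
    stop("steady state is unstable; refusing control analysis ",
         "(no valid steady state for MCA)", call. = FALSE)
  sys <- assemble_odes(model)
  y <- steady$concentrations
  v0 <- steady$fluxes
  J0 <- v0[[target]]
  if (abs(J0) < 1e-15)
    stop("target flux is zero at steady state", call. = FALSE)
  red <- reduce_network(sys$S)
  dv <- flux_jacobian(sys$fluxes, y)
  M <- red$NR %*% dv %*% red$L
  Cun <- diag(length(v0)) - dv %*% red$L %*% solve(M, red$NR)
  ti <- match(target, names(v0))
  fcc_struct <- Cun[ti, ] * v0 / J0

  fcc_fd <- rep(NA_real_, length(v0))
  if (fd) {
    for (j in seq_along(model$reactions)) {
      rid <- names(model$reactions)[j]
      p0 <- reaction_vmax(model, rid)
      if (!is.finite(p0) || p0 == 0) { fcc_fd[j] <- 0; next }
      Jpm <- vapply(c(1 + delta, 1 - delta), function(f) {
        m2 <- modify_vmax(model, rid, p0 * f)
        ss2 <- tryCatch(
          find_steady_state(m2, guess = y, t_settle = c(1e3, 1e5)),
          error = function(e) NULL)
        if (is.null(ss2)) return(NA_real_)
        ss2$fluxes[[target]]
      }, numeric(1))
      fcc_fd[j] <- (Jpm[1] - Jpm[2]) / (2 * delta * J0)
    }
  }
  out <- data.frame(reaction = names(v0), fcc_structural = unname(fcc_struct),
                    fcc_fd = fcc_fd, stringsAsFactors = FALSE)
  structure(out, class = c("aakin_fcc_table", "data.frame"),
            target = target,
            sums = c(structural = sum(fcc_struct),
                     fd = sum(fcc_fd)))
}

#' @export
print.aakin_fcc_table <- function(x, ...) {
  cat("<FCC table> target:", attr(x, "target"),
      sprintf("(sum structural %.4f)\n", attr(x, "sums")[["structural"]]))
  print.data.frame(x[order(-abs(x$fcc_structural)), ][1:min(8, nrow(x)), ],
                   row.names = FALSE, digits = 4)
  invisible(x)
}
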