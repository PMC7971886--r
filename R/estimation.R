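#' Vmax estimation
#'
#' Two estimation routes for maximal rates that the literature does not
#' report directly. Method 1 (native-metabolism reactions): determine the
#' chassis steady-state flux distribution, pin the shared reactions of a
#' stoichiometric model to those fluxes (within a small tolerance), run a
#' flux variability analysis to get the maximum feasible flux `v` of the
#' new reaction, and divide by the rate law's saturation factor at the
#' reference state (`Vmax = v / F`), with newly added metabolites assumed
#' at 1 mM. Method 2 (heterologous enzymes): `Vmax = Kcat * E_total` with
#' the enzyme deliberately in surplus (100 mM).
#'
#' @name vmax-estimation
NULL

#' Construct a stoichiometric model
#'
#' @param S species x reactions stoichiometric matrix (with dimnames).
#' @param lb,ub named (or positional) flux bounds; defaults 0/1000 for all
#'   reactions (set `lb < 0` for reversible ones).
#' @param objective optional objective reaction id.
#' @param mapping optional two-column data frame (`kinetic`, `stoich`)
#'   translating kinetic-model reaction ids to stoichiometric ids; identity
#'   on shared names when omitted.
#' @return an `aakin_stoich_model`.
#' @export
stoich_model <- function(S, lb = NULL, ub = NULL, objective = NULL,
                         mapping = NULL) {
  n <- ncol(S)
  if (is.null(lb)) lb <- rep(0, n)
  if (is.null(ub)) ub <- rep(1000, n)
  if (!is.null(names(lb))) lb <- lb[colnames(S)]
  if (!is.null(names(ub))) ub <- ub[colnames(S)]
  lb <- unname(lb); ub <- unname(ub)
  if (any(lb > ub)) stop("lb > ub", call. = FALSE)
  if (!is.null(mapping) && anyDuplicated(mapping$stoich))
    stop("mapping not injective", call. = FALSE)
  structure(list(S = S, lb = lb, ub = ub, objective = objective,
                 mapping = mapping),
            class = "aakin_stoich_model")
}

#' @export
print.aakin_stoich_model <- function(x, ...) {
  cat("<stoichiometric model>", nrow(x$S), "metabolites,",
      ncol(x$S), "reactions\n")
  invisible(x)
}

# Dense two-phase simplex with Bland's anti-cycling rule, for the small
# (tens of variables) highly degenerate flux LPs of this module. Standard
# form: minimise cost'x subject to A x = b, x >= 0, b >= 0.
simplex_bland <- function(cost, A, b) {
  m <- nrow(A); n <- ncol(A)
  flip <- b < 0
  A[flip, ] <- -A[flip, , drop = FALSE]
  b[flip] <- -b[flip]
  tab <- cbind(A, diag(m), b)
  basis <- n + seq_len(m)
  ncols <- n + m
  run_phase <- function(cvec, enterable) {
    repeat {
      red <- cvec - as.vector(cvec[basis] %*%
                                tab[, seq_len(ncols), drop = FALSE])
      ent <- which(red < -1e-9 & enterable)
      if (!length(ent)) return("optimal")
      ent <- ent[1]                         # Bland: lowest index enters
      col <- tab[, ent]
      pos <- which(col > 1e-11)
      if (!length(pos)) return("unbounded")
      ratios <- tab[pos, ncols + 1] / col[pos]
      cand <- pos[ratios <= min(ratios) + 1e-12]
      leave <- cand[which.min(basis[cand])]  # Bland: lowest index leaves
      tab[leave, ] <<- tab[leave, ] / tab[leave, ent]
      for (r in seq_len(m))
        if (r != leave && tab[r, ent] != 0)
          tab[r, ] <<- tab[r, ] - tab[r, ent] * tab[leave, ]
      basis[leave] <<- ent
    }
  }
  # phase 1: drive the artificial variables to zero
  st <- run_phase(c(rep(0, n), rep(1, m)), rep(TRUE, ncols))
  if (st != "optimal" || sum(tab[basis > n, ncols + 1]) > 1e-7)
    return(list(status = "infeasible"))
  # phase 2: artificials may linger in the basis at zero level but must
  # never re-enter
  st <- run_phase(c(cost, rep(0, m)),
                  c(rep(TRUE, n), rep(FALSE, m)))
  if (st != "optimal") return(list(status = st))
  x <- numeric(n)
  keep <- basis <= n
  x[basis[keep]] <- tab[keep, ncols + 1]
  list(status = "optimal", x = x, value = sum(cost * x))
}

# Bounded LP: optimise obj'v subject to S v = 0, lb <= v <= ub.
# Variables are shifted to y = v - lb >= 0 and capped with slack rows.
solve_lp <- function(obj, S, lb, ub, maximize = FALSE) {
  n <- length(obj)
  # conservation relations make rows of S linearly dependent; the simplex
  # needs an independent equality system
  S <- S[rowSums(abs(S)) > 0, , drop = FALSE]
  qrt <- qr(t(S))
  S <- S[sort(qrt$pivot[seq_len(qrt$rank)]), , drop = FALSE]
  span <- pmin(ub - lb, 1e6)
  m <- nrow(S)
  # [ S 0 ] y = -S lb ;  [ I I ] (y, s) = span
  A <- rbind(cbind(S, matrix(0, m, n)), cbind(diag(n), diag(n)))
  b <- c(as.vector(-S %*% lb), span)
  cost <- c(if (maximize) -obj else obj, rep(0, n))
  res <- simplex_bland(cost, A, b)
  if (!identical(res$status, "optimal")) return(list(feasible = FALSE))
  x <- res$x[seq_len(n)] + lb
  list(feasible = TRUE, x = x, value = sum(obj * x))
}

#' Maximum flux of a reaction under pinned-flux constraints
#'
#' Flux variability analysis step of Method 1: every reaction shared with
#' the kinetic model is constrained to its kinetic steady-state flux within
#' `+/- tol`, the original bounds are kept, and the target's flux is
#' maximised subject to `S v = 0`.
#'
#' @param stoich a [stoich_model()].
#' @param kinetic_fluxes named flux vector (mM/s) over shared reactions
#'   (stoichiometric-model ids, after mapping).
#' @param target reaction id whose maximum flux is sought.
#' @param tol pin half-width, mM/s.
#' @param direction `"max"` (default) or `"min"`.
#' @return optimal flux value (mM/s).
#' @export
constrained_fva_max <- function(stoich, kinetic_fluxes, target,
                                tol = 0.01, direction = c("max", "min")) {
  direction <- match.arg(direction)
  rxns <- colnames(stoich$S)
  if (!target %in% rxns)
    stop("target reaction not in stoichiometric model: ", target,
         call. = FALSE)
  if (any(!is.finite(kinetic_fluxes)))
    stop("non-finite kinetic flux", call. = FALSE)
  lb <- stoich$lb; ub <- stoich$ub
  shared <- intersect(names(kinetic_fluxes), rxns)
  i <- match(shared, rxns)
  lb[i] <- pmax(lb[i], kinetic_fluxes[shared] - tol)
  ub[i] <- pmin(ub[i], kinetic_fluxes[shared] + tol)
  bad <- which(lb > ub + 1e-12)
  if (length(bad))
    stop("infeasible pins (lb > ub) for: ",
         paste(rxns[bad], collapse = ", "), call. = FALSE)
  obj <- as.numeric(rxns == target)
  sol <- solve_lp(obj, stoich$S, lb, ub, maximize = direction == "max")
  if (!sol$feasible) {
    pins <- paste0(shared, "=", signif(kinetic_fluxes[shared], 6),
                   collapse = ", ")
    stop("infeasible LP under pinned fluxes (", pins, ")", call. = FALSE)
  }
  sol$value
}

#' Vmax by turnover number and enzyme surplus (Method 2)
#'
#' @param kcat turnover number, 1/s.
#' @param e_total total enzyme concentration, mM (100 by default: in
#'   surplus so the step is never artificially limiting).
#' @return Vmax in mM/s (`kcat * e_total`).
#' @examples
#' vmax_method2(0.55)   # AcoaTioE: 55 mM/s
#' @export
vmax_method2 <- function(kcat, e_total = 100) {
  if (any(kcat < 0) || any(e_total < 0))
    stop("kcat and e_total must be non-negative", call. = FALSE)
  kcat * e_total
}

#' Vmax by constrained FVA and saturation factor (Method 1)
#'
#' @param model chassis kinetic model (a continuous variant with a steady
#'   state; see [make_continuous()]).
#' @param stoich a [stoich_model()] containing the target reaction.
#' @param target the new [reaction()] whose Vmax is sought (its id must be
#'   a column of the stoichiometric model), or the id of a reaction already
#'   in `model`.
#' @param steady optional precomputed [find_steady_state()] result for
#'   `model` (computed when omitted).
#' @param tol FVA pin half-width, mM/s.
#' @param reference_conc concentration assumed for newly added metabolites
#'   (species absent from the kinetic model), mM.
#' @param reference_species ids of species present in the kinetic model
#'   that should nevertheless be clamped at `reference_conc` (metabolites
#'   the chassis carries but does not itself metabolise, e.g. cytosolic
#'   glycerol in a glucose chassis).
#' @param flux_scale multiplicative bridge between kinetic-model flux units
#'   and stoichiometric-model units (1 = take them as the same scale).
#' @return an `aakin_vmax_estimate`: list with `reaction`, `method`, `v`
#'   (FVA flux), `F` (saturation factor), `Vmax = v / F`.
#' @export
vmax_method1 <- function(model, stoich, target, steady = NULL,
                         tol = 0.01, reference_conc = 1,
                         reference_species = NULL, flux_scale = 1) {
  if (is.character(target)) {
    target <- model$reactions[[target]]
    if (is.null(target)) stop("target reaction not found", call. = FALSE)
  }
  if (is.null(steady)) steady <- find_steady_state(model)
  kin <- steady$fluxes * flux_scale
  # translate kinetic ids into stoichiometric ids
  if (!is.null(stoich$mapping)) {
    m <- stoich$mapping
    keep <- intersect(names(kin), m$kinetic)
    kin <- stats::setNames(kin[keep], m$stoich[match(keep, m$kinetic)])
  } else {
    kin <- kin[intersect(names(kin), colnames(stoich$S))]
  }
  v <- constrained_fva_max(stoich, kin, target$id, tol = tol)

  conc <- steady$concentrations
  full <- stats::setNames(model$species$initial, model$species$id)
  full[names(conc)] <- conc
  full[intersect(reference_species, names(full))] <- reference_conc
  cc <- lapply(unname(target$roles), function(sid)
    if (sid %in% names(full)) full[[sid]] else reference_conc)
  names(cc) <- names(target$roles)
  p1 <- as.list(target$params)
  p1[[if (target$law$scale == "k") "k" else "Vmax"]] <- 1
  FF <- evaluate_rate(target$law, p1, cc)
  if (!is.finite(FF) || FF == 0)
    stop("undefined Vmax at reference state (saturation factor ",
         FF, ") for ", target$id, call. = FALSE)
  structure(list(reaction = target$id, method = 1L, v = v, F = FF,
                 Vmax = v / FF,
                 notes = sprintf("FVA max with pins +/-%g mM/s", tol)),
            class = "aakin_vmax_estimate")
}

#' @export
print.aakin_vmax_estimate <- function(x, ...) {
  cat(sprintf("<Vmax estimate> %s (method %d): v = %.6g mM/s, F = %.6g, Vmax = %.6g mM/s\n",
              x$reaction, x$method, x$v, x$F, x$Vmax))
  invisible(x)
}

#' Method-1 estimates for the whole native extension
#'
#' Runs [vmax_method1()] for each native-extension reaction against the
#' chassis steady state, returning the Vmax vector (and the DhaPT
#' mass-action `k`) used to parameterise model variants.
#'
#' @param model continuous chassis model with a steady state.
#' @param stoich stoichiometric twin containing the extension reactions.
#' @param reactions reactions to estimate; defaults to the nine
#'   native-extension reactions.
#' @param ... passed to [vmax_method1()].
#' @return named numeric vector reaction id -> Vmax (mM/s); for DhaPT the
#'   value is the mass-action constant.
#' @export
estimate_native_vmax <- function(model, stoich,
                                 reactions = native_extension_reactions(),
                                 ...) {
  steady <- find_steady_state(model)
  ref_sp <- c("GLY", "G3P", "DHA", "MCOA", "LGLU", "ASP", "BA")
  out <- vapply(reactions, function(r) {
    est <- vmax_method1(model, stoich, r, steady = steady,
                        reference_species = ref_sp, ...)
    est$Vmax
  }, numeric(1))
  names(out) <- names(reactions)
  out
}
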