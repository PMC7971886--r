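#' FCC-guided in-silico strain design
#'
#' Iterative optimisation: run control analysis on a continuous variant of
#' the producing model, pick the reaction with the largest
#' absolute flux control coefficient, and search its Vmax within a bounded
#' fold-change window (50x by default) to maximise end-time acrylic-acid
#' titer in the batch model. The loop stops when the carbon feed becomes
#' the limiting factor, when the selected bottleneck was already optimised,
#' or when the mutant no longer reaches a stable steady state during
#' control analysis — whichever comes first.
#'
#' @name strain-design
NULL

#' Select the optimisation target from an FCC table
#'
#' @param fcc an `aakin_fcc_table`.
#' @param exclude reaction ids not eligible (e.g. feed/drain/export
#'   plumbing, or the target flux itself).
#' @return list with `reaction`, `fcc`, and `direction`
#'   (`"over_expression"` for positive coefficients,
#'   `"under_expression"` for negative ones).
#' @export
select_target <- function(fcc, exclude = character(0)) {
  tab <- fcc[!fcc$reaction %in% exclude, , drop = FALSE]
  if (!nrow(tab)) stop("empty FCC table", call. = FALSE)
  i <- which.max(abs(tab$fcc_structural))
  list(reaction = tab$reaction[i], fcc = tab$fcc_structural[i],
       direction = if (tab$fcc_structural[i] >= 0) "over_expression"
                   else "under_expression")
}

#' Bounded Vmax search maximising end-time product titer
#'
#' Deterministic golden-section/Brent search over log10(Vmax) within
#' `[Vmax/bound_fold, Vmax*bound_fold]`; the objective is the acrylic-acid
#' (or 3-HP) titer in g/L at the simulation horizon of the batch model.
#'
#' @param model batch producing model (e.g. 10 g/L glucose, no
#'   end-metabolite drains).
#' @param reaction_id reaction whose Vmax is searched.
#' @param horizon batch horizon, s.
#' @param bound_fold maximum fold change in either direction.
#' @param objective_species species reporting the objective; default
#'   `"AAx"` falling back to `"HPx"`.
#' @param rel_tol relative search tolerance on Vmax.
#' @return an `aakin_mutant_spec`: `reaction`, `vmax_original`, `vmax_new`,
#'   `fold_change`, `objective` (g/L), `objective_original`,
#'   `bound_active`.
#' @export
optimise_vmax <- function(model, reaction_id, horizon = 10800,
                          bound_fold = 50, objective_species = NULL,
                          rel_tol = 1e-3) {
  v0 <- reaction_vmax(model, reaction_id)
  if (!is.finite(v0) || v0 <= 0)
    stop("reaction ", reaction_id, " has no positive Vmax to scale",
         call. = FALSE)
  if (is.null(objective_species))
    objective_species <- if ("AAx" %in% model$species$id) "AAx" else "HPx"
  obj <- function(lv) {
    m <- modify_vmax(model, reaction_id, 10^lv)
    tr <- tryCatch(
      simulate_timecourse(m, duration = horizon, n_out = 25),
      error = function(e) NULL)
    if (is.null(tr)) return(NA_real_)  # rejected candidate
    titer_gL(tr, objective_species)
  }
  base_obj <- obj(log10(v0))
  if (bound_fold <= 1)
    return(structure(list(reaction = reaction_id, vmax_original = v0,
                          vmax_new = v0, fold_change = 1,
                          objective = base_obj,
                          objective_original = base_obj,
                          bound_active = FALSE),
                     class = "aakin_mutant_spec"))
  lo <- log10(v0 / bound_fold); hi <- log10(v0 * bound_fold)
  opt <- stats::optimize(function(lv) {
    val <- obj(lv)
    if (is.na(val)) -Inf else val
  }, c(lo, hi), maximum = TRUE,
  tol = rel_tol * (hi - lo) / log(10))
  # the interior optimiser never lands exactly on a bound: probe both
  cand_v <- c(min(max(10^opt$maximum, v0 / bound_fold), v0 * bound_fold),
              v0 / bound_fold, v0 * bound_fold, v0)
  vals <- c(opt$objective, obj(lo), obj(hi), base_obj)
  best <- which.max(vals)
  vnew <- cand_v[best]
  structure(list(reaction = reaction_id, vmax_original = v0,
                 vmax_new = vnew, fold_change = vnew / v0,
                 objective = vals[best], objective_original = base_obj,
                 bound_active = best %in% c(2, 3) ||
                   abs(log10(vnew / v0)) > log10(bound_fold) - 1e-6),
            class = "aakin_mutant_spec")
}

#' @export
print.aakin_mutant_spec <- function(x, ...) {
  cat(sprintf("<mutant> %s: Vmax %.6g -> %.6g mM/s (%.3g-fold)%s, objective %.4g g/L\n",
              x$reaction, x$vmax_original, x$vmax_new, x$fold_change,
              if (isTRUE(x$bound_active)) " [bound]" else "",
              x$objective))
  invisible(x)
}

#' FCC-guided design loop
#'
#' Alternates control analysis on the continuous variant with bounded Vmax
#' optimisation on the batch variant, applying each accepted edit before
#' the next iteration.
#'
#' @param model batch producing model.
#' @param max_iter maximum iterations.
#' @param horizon batch horizon, s.
#' @param bound_fold per-edit Vmax fold bound.
#' @param exclude reaction ids never selected as targets (plumbing:
#'   feeds, drains, export and the heterologous steps already saturated by
#'   construction are eligible unless listed here); defaults to the
#'   feed/drain/export reactions plus the target flux itself.
#' @param target_flux reaction reporting production; default AcoaTioE for
#'   AA models.
#' @param feed_exhaustion_frac carbon-source fraction below which the
#'   batch is considered feed-limited.
#' @return list of `aakin_mutant_spec` entries, with attributes
#'   `stop_reason` (`"feed_limited"`, `"already_optimised"`,
#'   `"no_steady_state"` or `"max_iterations"`) and `final_model`.
#' @export
design_loop <- function(model, max_iter = 5, horizon = 10800,
                        bound_fold = 50, exclude = NULL,
                        target_flux = NULL,
                        feed_exhaustion_frac = 0.01) {
  if (is.null(target_flux))
    target_flux <- if ("AcoaTioE" %in% names(model$reactions)) "AcoaTioE"
                   else "export_product"
  carbon_sp <- if (isTRUE(model$annotations$carbon_source == "glycerol"))
    "GLYx" else "GLCx"
  carbon0 <- model$species$initial[model$species$id == carbon_sp]
  history <- list()
  optimised <- character(0)
  stop_reason <- "max_iterations"
  for (it in seq_len(max_iter)) {
    cont <- make_continuous(model)
    if (is.null(exclude)) {
      plumbing <- grep("^(drain_|feed_|export_|synth_)",
                       names(cont$reactions), value = TRUE)
      excl <- c(plumbing, target_flux)
    } else excl <- exclude
    ss <- tryCatch(find_steady_state(cont), error = function(e) NULL)
    if (is.null(ss) || !isTRUE(ss$stable)) {
      stop_reason <- "no_steady_state"; break
    }
    fcc <- tryCatch(
      flux_control_coefficients(cont, ss, target_flux, fd = FALSE),
      error = function(e) NULL)
    if (is.null(fcc)) { stop_reason <- "no_steady_state"; break }
    sel <- select_target(fcc, exclude = excl)
    if (sel$reaction %in% optimised) {
      stop_reason <- "already_optimised"; break
    }
    mut <- optimise_vmax(model, sel$reaction, horizon = horizon,
                         bound_fold = bound_fold)
    mut$iteration <- it
    mut$fcc <- sel$fcc
    mut$direction <- sel$direction
    history[[length(history) + 1]] <- mut
    optimised <- c(optimised, sel$reaction)
    model <- modify_vmax(model, sel$reaction, mut$vmax_new)
    # feed-limited? carbon exhausted before the horizon and pushing the
    # bound further would not raise the objective
    tr <- simulate_timecourse(model, duration = horizon, n_out = 25)
    carbon_left <- tr$conc[nrow(tr$conc), carbon_sp] / carbon0
    gain <- (mut$objective - mut$objective_original) /
      max(mut$objective_original, 1e-12)
    if (carbon_left < feed_exhaustion_frac &&
        (!isTRUE(mut$bound_active) || gain < 1e-4)) {
      stop_reason <- "feed_limited"; break
    }
  }
  structure(history, stop_reason = stop_reason, final_model = model,
            class = "aakin_design_history")
}

#' @export
print.aakin_design_history <- function(x, ...) {
  cat("<design history>", length(x), "iteration(s), stop:",
      attr(x, "stop_reason"), "\n")
  for (m in x) print(m)
  invisible(x)
}

#' Mutant history as a data frame (Table-4-style summary)
#' @param history an `aakin_design_history`.
#' @export
mutants_table <- function(history) {
  if (!length(history))
    return(data.frame(iteration = integer(0), reaction = character(0),
                      vmax_original = numeric(0), vmax_new = numeric(0),
                      fold_change = numeric(0), titer_gL = numeric(0),
                      stop_reason = character(0)))
  data.frame(
    iteration = vapply(history, `[[`, 0, "iteration"),
    reaction = vapply(history, `[[`, "", "reaction"),
    vmax_original = vapply(history, `[[`, 0, "vmax_original"),
    vmax_new = vapply(history, `[[`, 0, "vmax_new"),
    fold_change = vapply(history, `[[`, 0, "fold_change"),
    titer_gL = vapply(history, `[[`, 0, "objective"),
    stop_reason = attr(history, "stop_reason"),
    stringsAsFactors = FALSE)
}
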