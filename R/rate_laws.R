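#' Enzyme rate-law library
#'
#' Closed-form kinetic mechanisms used throughout the extended
#' central-carbon-metabolism models: Michaelis-Menten (one to three
#' substrates), random and ordered bi-bi forms, reversible rapid-equilibrium
#' and ping-pong mechanisms, ping-pong with substrate inhibition, Hill
#' cooperativity, specific activation, and elementary mass action.
#'
#' Substrates and products are bound by *role* (A, B, C, P, Q, Activator);
#' parameters are bound by *slot* (Vmax, Kcat, E_total, Km, Km_a, ..., Keq,
#' n, k). Concentrations are mM, rates mM/s, Kcat 1/s, Keq dimensionless.
#' For heterologous enzymes the maximal rate is supplied as `Kcat` plus
#' `E_total` (mM) and the effective Vmax is their product; native laws carry
#' `Vmax` directly. Either spelling is accepted by every enzymatic mechanism.
#'
#' @name rate-laws
NULL

# Each registry entry: required roles, required parameter slots (excluding
# the scale), scale slot class ("Vmax" or "k"), reversible flag, the rate
# function fn(conc, p, V), and a printf template for a symbolic expression
# (used for SBML kinetic-law export). All denominators are strictly positive
# for non-negative concentrations and positive constants.
.law_registry <- list(

  michaelis_menten_1s = list(
    roles = "A", slots = "Km", scale = "Vmax", reversible = FALSE,
    fn = function(cc, p, V) V * cc[1] / (p[["Km"]] + cc[1]),
    template = "%V% * %A% / (Km + %A%)"),

  mm_2s_multiplicative = list(
    roles = c("A", "B"), slots = c("Km_a", "Km_b"), scale = "Vmax",
    reversible = FALSE,
    fn = function(cc, p, V)
      V * cc[1] / (p[["Km_a"]] + cc[1]) * cc[2] / (p[["Km_b"]] + cc[2]),
    template = "%V% * %A% / (Km_a + %A%) * %B% / (Km_b + %B%)"),

  mm_2s_random_bibi_denominator = list(
    roles = c("A", "B"), slots = c("Km_a", "Km_b", "Kd_a"), scale = "Vmax",
    reversible = FALSE,
    fn = function(cc, p, V) {
      A <- cc[1]; B <- cc[2]
      V * A * B / (p[["Kd_a"]] * p[["Km_b"]] + p[["Km_b"]] * A +
                     p[["Km_a"]] * B + A * B)
    },
    template = "%V% * %A% * %B% / (Kd_a * Km_b + Km_b * %A% + Km_a * %B% + %A% * %B%)"),

  mm_competitive_product_inhibition_2s = list(
    roles = c("A", "B", "P"), slots = c("Km_a", "Km_b", "Ki_p"),
    scale = "Vmax", reversible = FALSE,
    fn = function(cc, p, V)
      V * cc[1] / (p[["Km_a"]] * (1 + cc[3] / p[["Ki_p"]]) + cc[1]) *
        cc[2] / (p[["Km_b"]] + cc[2]),
    template = "%V% * %A% / (Km_a * (1 + %P% / Ki_p) + %A%) * %B% / (Km_b + %B%)"),

  mm_3s_multiplicative = list(
    roles = c("A", "B", "C"), slots = c("Km_a", "Km_b", "Km_c"),
    scale = "Vmax", reversible = FALSE,
    fn = function(cc, p, V)
      V * cc[1] / (p[["Km_a"]] + cc[1]) * cc[2] / (p[["Km_b"]] + cc[2]) *
        cc[3] / (p[["Km_c"]] + cc[3]),
    template = "%V% * %A% / (Km_a + %A%) * %B% / (Km_b + %B%) * %C% / (Km_c + %C%)"),

  rapid_equilibrium_random_bibi_reversible = list(
    roles = c("A", "B", "P", "Q"),
    slots = c("Km_a", "Km_b", "Km_p", "Km_q", "Keq"),
    scale = "Vmax", reversible = TRUE,
    fn = function(cc, p, V) {
      A <- cc[1]; B <- cc[2]; P <- cc[3]; Q <- cc[4]
      num <- (A * B - P * Q / p[["Keq"]]) / (p[["Km_a"]] * p[["Km_b"]])
      den <- (1 + A / p[["Km_a"]]) * (1 + B / p[["Km_b"]]) +
        (1 + P / p[["Km_p"]]) * (1 + Q / p[["Km_q"]]) - 1
      V * num / den
    },
    template = paste0(
      "%V% * ((%A% * %B% - %P% * %Q% / Keq) / (Km_a * Km_b)) / ",
      "((1 + %A% / Km_a) * (1 + %B% / Km_b) + ",
      "(1 + %P% / Km_p) * (1 + %Q% / Km_q) - 1)")),

  ordered_bibi_product_inhibition = list(
    roles = c("A", "B", "P"), slots = c("Km_a", "Km_b", "Ki_p"),
    scale = "Vmax", reversible = FALSE,
    fn = function(cc, p, V)
      V * cc[1] / (p[["Km_a"]] * (1 + cc[3] / p[["Ki_p"]]) + cc[1]) *
        cc[2] / (p[["Km_b"]] + cc[2]),
    template = "%V% * %A% / (Km_a * (1 + %P% / Ki_p) + %A%) * %B% / (Km_b + %B%)"),

  ping_pong_bibi_reversible = list(
    roles = c("A", "B", "P", "Q"),
    slots = c("Km_a", "Km_b", "Km_p", "Km_q", "Keq"),
    scale = "Vmax", reversible = TRUE,
    fn = function(cc, p, V) {
      A <- cc[1]; B <- cc[2]; P <- cc[3]; Q <- cc[4]
      num <- (A * B - P * Q / p[["Keq"]]) / (p[["Km_a"]] * p[["Km_b"]])
      den <- (1 + A / p[["Km_a"]] + Q / p[["Km_q"]]) *
        (1 + B / p[["Km_b"]] + P / p[["Km_p"]])
      V * num / den
    },
    template = paste0(
      "%V% * ((%A% * %B% - %P% * %Q% / Keq) / (Km_a * Km_b)) / ",
      "((1 + %A% / Km_a + %Q% / Km_q) * (1 + %B% / Km_b + %P% / Km_p))")),

  ping_pong_bibi_substrate_inhibition = list(
    roles = c("A", "B"), slots = c("Km_a", "Km_b", "Ki_b"),
    scale = "Vmax", reversible = FALSE,
    fn = function(cc, p, V) {
      A <- cc[1]; B <- cc[2]
      if (A <= 0 || B <= 0) return(0)  # denominator vanishes at the origin
      V * A * B / (p[["Km_b"]] * A +
                     p[["Km_a"]] * B * (1 + B / p[["Ki_b"]]) + A * B)
    },
    template = paste0("%V% * %A% * %B% / (Km_b * %A% + ",
                      "Km_a * %B% * (1 + %B% / Ki_b) + %A% * %B%)")),

  hill_2s = list(
    roles = c("A", "B"), slots = c("Km_a", "Km_b", "n"), scale = "Vmax",
    reversible = FALSE,
    fn = function(cc, p, V) {
      An <- max(cc[1], 0)^p[["n"]]; Bn <- max(cc[2], 0)^p[["n"]]
      V * An / (p[["Km_a"]]^p[["n"]] + An) * Bn / (p[["Km_b"]]^p[["n"]] + Bn)
    },
    template = paste0("%V% * %A%^n / (Km_a^n + %A%^n) * ",
                      "%B%^n / (Km_b^n + %B%^n)")),

  specific_activation = list(
    roles = c("A", "Activator"), slots = c("Km_a", "Ka"), scale = "Vmax",
    reversible = FALSE,
    fn = function(cc, p, V) {
      A <- cc[1]; Act <- cc[2]
      V * A * Act / (p[["Km_a"]] * p[["Ka"]] + (p[["Km_a"]] + A) * Act)
    },
    template = paste0("%V% * %A% * %Activator% / ",
                      "(Km_a * Ka + (Km_a + %A%) * %Activator%)")),

  mass_action = list(
    roles = character(0), slots = character(0), scale = "k",
    reversible = FALSE,
    fn = function(cc, p, V) V * prod(cc),
    template = NULL),

  mass_action_reversible = list(
    roles = c("A", "B", "P", "Q"), slots = "Keq", scale = "k",
    reversible = TRUE,
    fn = function(cc, p, V)
      V * (cc[1] * cc[2] - cc[3] * cc[4] / p[["Keq"]]),
    template = "k * (%A% * %B% - %P% * %Q% / Keq)")
)

#' List available kinetic mechanisms
#' @return character vector of mechanism identifiers.
#' @export
list_mechanisms <- function() names(.law_registry)

#' Construct a rate law
#'
#' @param mechanism one of [list_mechanisms()].
#' @return an object of class `aakin_rate_law` describing the mechanism's
#'   substrate roles and parameter slots.
#' @examples
#' rate_law("michaelis_menten_1s")
#' @export
rate_law <- function(mechanism) {
  if (!mechanism %in% names(.law_registry))
    stop("unknown mechanism: ", mechanism, call. = FALSE)
  entry <- .law_registry[[mechanism]]
  structure(
    list(mechanism = mechanism, roles = entry$roles, slots = entry$slots,
         scale = entry$scale, reversible = entry$reversible),
    class = "aakin_rate_law")
}

#' @export
print.aakin_rate_law <- function(x, ...) {
  cat("<rate law>", x$mechanism, "\n",
      " roles:", paste(x$roles, collapse = ", "), "\n",
      " slots:", paste(c(x$scale, x$slots), collapse = ", "),
      if (x$reversible) " (reversible)", "\n")
  invisible(x)
}

# Effective scale parameter: Vmax (mM/s), Kcat*E_total, or mass-action k.
law_scale_value <- function(law, params) {
  if (identical(law$scale, "none")) return(1)
  if (law$scale == "k") {
    if (is.na(params["k"]) || !"k" %in% names(params))
      stop("incomplete binding: parameter slot 'k'", call. = FALSE)
    return(params[["k"]])
  }
  if ("Vmax" %in% names(params) && !is.na(params["Vmax"]))
    return(params[["Vmax"]])
  if (all(c("Kcat", "E_total") %in% names(params)))
    return(params[["Kcat"]] * params[["E_total"]])
  stop("incomplete binding: parameter slot 'Vmax' (or 'Kcat' + 'E_total')",
       call. = FALSE)
}

check_law_inputs <- function(law, params, conc) {
  roles <- law$roles
  if (law$mechanism == "mass_action") {
    if (length(conc) < 1)
      stop("incomplete binding: mass_action needs at least one substrate role",
           call. = FALSE)
    roles <- names(conc)
  }
  missing_roles <- setdiff(roles, names(conc))
  if (length(missing_roles))
    stop("incomplete binding: role ", paste(missing_roles, collapse = ", "),
         call. = FALSE)
  cv <- unlist(conc[roles])
  if (any(!is.finite(cv)))
    stop("non-finite concentration for role ",
         paste(roles[!is.finite(cv)], collapse = ", "), call. = FALSE)
  if (any(cv < 0))
    stop("negative concentration for role ",
         paste(roles[cv < 0], collapse = ", "), call. = FALSE)
  missing_slots <- setdiff(law$slots, names(params))
  if (length(missing_slots))
    stop("incomplete binding: parameter slot ",
         paste(missing_slots, collapse = ", "), call. = FALSE)
  pv <- unlist(params[law$slots])
  if (length(pv) && any(!is.finite(pv)))
    stop("non-finite parameter: ",
         paste(law$slots[!is.finite(pv)], collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Evaluate a rate law
#'
#' @param law a [rate_law()].
#' @param params named numeric vector (or list) of parameter values; enzymatic
#'   mechanisms take either `Vmax` or both `Kcat` and `E_total`.
#' @param conc named numeric vector (or list) of concentrations keyed by role
#'   (`A`, `B`, `C`, `P`, `Q`, `Activator`), in mM.
#' @return reaction rate in mM/s (signed for reversible mechanisms).
#' @examples
#' evaluate_rate(rate_law("michaelis_menten_1s"),
#'               c(Vmax = 1, Km = 2.9), c(A = 2.9))
#' @export
evaluate_rate <- function(law, params, conc) {
  params <- as.list(params); conc <- as.list(conc)
  check_law_inputs(law, params, conc)
  V <- law_scale_value(law, params)
  fn <- if (!is.null(law$fn)) law$fn
        else .law_registry[[law$mechanism]]$fn
  cc <- if (law$mechanism %in% c("mass_action", "foreign")) unlist(conc)
        else unlist(conc[law$roles])
  unname(fn(cc, params, V))
}

#' Saturation factor of a rate law
#'
#' The dimensionless factor `F` such that `rate = Vmax * F` (with
#' `Vmax = Kcat * E_total` where the law is parameterised by turnover number,
#' and the elementary constant `k` for mass action, where `F` is the
#' concentration product and therefore not bounded by 1). Used by the
#' FVA-based Vmax estimation: `Vmax = v / F` at the reference state.
#'
#' @inheritParams evaluate_rate
#' @return dimensionless saturation factor; in `[0, 1]` for irreversible
#'   saturating mechanisms.
#' @export
saturation_factor <- function(law, params, conc) {
  params <- as.list(params)
  V <- law_scale_value(law, params)
  evaluate_rate(law, params, conc) / V
}

# Symbolic expression of a law with roles bound to species ids, for SBML
# kinetic-law export. `scale_expr` is the printed form of the maximal-rate
# factor ("Vmax", "(Kcat * E_total)" or "k").
law_expression <- function(law, roles, scale_expr = NULL) {
  if (is.null(scale_expr))
    scale_expr <- if (law$scale == "k") "k" else "Vmax"
  if (law$mechanism == "mass_action")
    return(paste(c(scale_expr, unname(roles)), collapse = " * "))
  tpl <- .law_registry[[law$mechanism]]$template
  tpl <- gsub("%V%", scale_expr, tpl, fixed = TRUE)
  for (r in names(roles))
    tpl <- gsub(paste0("%", r, "%"), roles[[r]], tpl, fixed = TRUE)
  tpl
}
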