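#' Reaction-network data model
#'
#' A kinetic model is a list of species (with compartments, initial
#' concentrations in mM, optional boundary-condition flag and carbon count)
#' and reactions (signed stoichiometry over species, a bound rate law, and
#' its parameter values). Fixed (boundary) species keep their initial
#' concentration during simulation; the ODE state is the set of non-fixed
#' species.
#'
#' @name network-model
NULL

#' Declare a species
#'
#' @param id short unique code (e.g. `"GLCx"`, `"DAP"`, `"AAx"`).
#' @param initial initial concentration, mM.
#' @param compartment `"cytosol"` or `"extracellular"`.
#' @param fixed boundary-condition flag: fixed species never change.
#' @param carbon number of carbon atoms counted in carbon-balance audits;
#'   use `NA` for cofactors/carriers excluded from the carbon sum.
#' @param name human-readable name.
#' @return one-row data frame.
#' @export
species <- function(id, initial, compartment = "cytosol", fixed = FALSE,
                    carbon = NA_real_, name = id) {
  stopifnot(initial >= 0, compartment %in% c("cytosol", "extracellular"))
  data.frame(id = id, name = name, compartment = compartment,
             initial = initial, fixed = fixed, carbon = carbon,
             stringsAsFactors = FALSE)
}

#' Declare a reaction
#'
#' @param id unique reaction id.
#' @param stoich named numeric vector, species id -> signed coefficient.
#' @param law a [rate_law()].
#' @param roles named character vector binding rate-law roles to species ids
#'   (e.g. `c(A = "DAP", B = "NADPH", P = "G3P", Q = "NADP")`).
#' @param params named numeric vector of parameter slot values.
#' @param reversible logical; reversible laws may carry negative rates.
#' @return an `aakin_reaction` object.
#' @export
reaction <- function(id, stoich, law, roles, params,
                     reversible = law$reversible) {
  if (!length(stoich) || all(stoich == 0))
    stop("reaction ", id, ": needs at least one non-zero coefficient",
         call. = FALSE)
  need <- if (law$mechanism == "mass_action") names(roles) else law$roles
  miss <- setdiff(need, names(roles))
  if (length(miss))
    stop("reaction ", id, ": unbound rate-law role ",
         paste(miss, collapse = ", "), call. = FALSE)
  structure(list(id = id, stoich = stoich, law = law,
                 roles = roles, params = params, reversible = reversible),
            class = "aakin_reaction")
}

#' Assemble a kinetic model
#'
#' @param species_df data frame of species rows (rbind of [species()] calls).
#' @param reactions list of [reaction()] objects.
#' @param compartments named numeric vector of compartment volumes
#'   (relative); defaults to 1:1 cytosol/extracellular.
#' @param annotations free-form provenance list (variant, carbon source, ...).
#' @return an `aakin_model` object.
#' @export
kinetic_model <- function(species_df, reactions,
                          compartments = c(cytosol = 1, extracellular = 1),
                          annotations = list()) {
  if (anyDuplicated(species_df$id))
    stop("duplicate species ids: ",
         paste(unique(species_df$id[duplicated(species_df$id)]),
               collapse = ", "), call. = FALSE)
  rids <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(rids))
    stop("duplicate reaction ids: ",
         paste(unique(rids[duplicated(rids)]), collapse = ", "),
         call. = FALSE)
  names(reactions) <- rids
  for (r in reactions) {
    unknown <- setdiff(unique(c(names(r$stoich), unname(r$roles))),
                       species_df$id)
    if (length(unknown))
      stop("reaction ", r$id, ": references undeclared species ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(list(species = species_df, reactions = reactions,
                 compartments = compartments, annotations = annotations),
            class = "aakin_model")
}

#' @export
print.aakin_model <- function(x, ...) {
  cat("<aakin kinetic model>",
      length(x$reactions), "reactions,", nrow(x$species), "species (",
      sum(!x$species$fixed), "dynamic )\n")
  if (length(x$annotations))
    cat("  annotations:",
        paste(names(x$annotations),
              vapply(x$annotations, function(a) paste(format(a), collapse = "/"), ""),
              sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Stoichiometric matrix of a kinetic model
#'
#' @param model an `aakin_model`.
#' @param free_only keep only non-fixed species rows.
#' @return species x reactions matrix.
#' @export
stoichiometry_matrix <- function(model, free_only = FALSE) {
  sp <- model$species
  if (free_only) sp <- sp[!sp$fixed, , drop = FALSE]
  S <- matrix(0, nrow(sp), length(model$reactions),
              dimnames = list(sp$id, names(model$reactions)))
  for (r in model$reactions) {
    keep <- intersect(names(r$stoich), rownames(S))
    S[keep, r$id] <- r$stoich[keep]
  }
  S
}

# Per-species volume factor: reaction rates are referenced to the cytosolic
# volume, so d[S]/dt picks up V_cyt / V(compartment of S).
volume_factors <- function(model, ids) {
  comp <- model$species$compartment[match(ids, model$species$id)]
  unname(model$compartments["cytosol"] / model$compartments[comp])
}

#' Assemble the ODE right-hand side of a model
#'
#' Mass-balance assembly: `d[S]/dt = sum_r nu_{S,r} v_r` for every non-fixed
#' species; fixed species are held at their initial concentration.
#'
#' @param model an `aakin_model`.
#' @return a list with `rhs(t, y, parms)` in the form [deSolve::lsoda()]
#'   expects, `fluxes(y)` returning the named reaction-rate vector at state
#'   `y`, `state_ids` (the dynamic species) and `y0` (initial state).
#' @export
assemble_odes <- function(model) {
  sp <- model$species
  free <- !sp$fixed
  state_ids <- sp$id[free]
  full0 <- stats::setNames(sp$initial, sp$id)
  Sfree <- stoichiometry_matrix(model, free_only = TRUE)
  Sfree <- Sfree * volume_factors(model, rownames(Sfree))
  rxns <- model$reactions

  # pre-resolve role -> index in the full concentration vector
  role_idx <- lapply(rxns, function(r) match(unname(r$roles), sp$id))
  role_names <- lapply(rxns, function(r) names(r$roles))
  plist <- lapply(rxns, function(r) as.list(r$params))
  fns <- lapply(rxns, function(r)
    if (!is.null(r$law$fn)) r$law$fn
    else .law_registry[[r$law$mechanism]]$fn)
  Vs <- vapply(rxns, function(r) law_scale_value(r$law, as.list(r$params)),
               numeric(1))

  # tiny negative excursions (within integrator tolerance) are passed
  # through un-clamped: the rational rate laws continue smoothly there and
  # a hard clamp at zero would put derivative kinks exactly where stiff
  # steps need a consistent Jacobian
  fluxes <- function(y) {
    full <- full0
    full[state_ids] <- y
    v <- numeric(length(rxns))
    for (i in seq_along(rxns))
      v[i] <- fns[[i]](full[role_idx[[i]]], plist[[i]], Vs[i])
    names(v) <- names(rxns)
    v
  }

  rhs <- function(t, y, parms) {
    list(as.vector(Sfree %*% fluxes(y)))
  }

  list(rhs = rhs, fluxes = fluxes, state_ids = state_ids,
       y0 = full0[state_ids], S = Sfree)
}

# -- unit conversion ---------------------------------------------------------

.molar_mass <- c(glucose = 180.16, glycerol = 92.09, `3-HP` = 90.08,
                 AA = 72.06)

#' Convert between g/L and mM for the headline compounds
#'
#' @param value non-negative concentration value(s).
#' @param direction `"gL_to_mM"` or `"mM_to_gL"`.
#' @param compound one of `"glucose"`, `"glycerol"`, `"3-HP"`, `"AA"`.
#' @return converted value; round-trips are exact to floating point.
#' @examples
#' convert_concentration(10, "gL_to_mM", "glucose")   # 55.5 mM
#' convert_concentration(20, "gL_to_mM", "glycerol")  # 217.2 mM
#' @export
convert_concentration <- function(value,
                                  direction = c("gL_to_mM", "mM_to_gL"),
                                  compound) {
  direction <- match.arg(direction)
  if (!compound %in% names(.molar_mass))
    stop("unknown compound: ", compound, call. = FALSE)
  if (any(value < 0)) stop("negative concentration", call. = FALSE)
  mm <- .molar_mass[[compound]]
  if (direction == "gL_to_mM") value / mm * 1000 else value * mm / 1000
}

#' Total carbon of a model state
#'
#' Sum of carbon atoms times concentration over the species whose `carbon`
#' field is set (cofactors carry `NA` and are excluded). Used by the
#' carbon-conservation audits on closed models.
#'
#' @param model an `aakin_model`.
#' @param conc named concentration vector; defaults to the initial state.
#' @return total carbon in mM-atoms.
#' @export
total_carbon <- function(model, conc = NULL) {
  sp <- model$species
  full <- stats::setNames(sp$initial, sp$id)
  if (!is.null(conc)) full[names(conc)] <- conc
  keep <- !is.na(sp$carbon)
  # weight by compartment volume so transport does not change the total
  vols <- unname(model$compartments[sp$compartment[keep]])
  sum(sp$carbon[keep] * full[sp$id[keep]] * vols)
}

#' Set or read a reaction's effective maximal rate
#'
#' `modify_vmax()` rewrites the scale parameter of a reaction (its `Vmax`,
#' its mass-action `k`, or — for turnover-parameterised laws — its `Kcat`
#' holding `E_total` fixed), returning the edited model; `reaction_vmax()`
#' reads the current effective value. These are the primitives behind
#' in-silico over-/under-expression edits.
#'
#' @param model an `aakin_model`.
#' @param reaction_id reaction to edit.
#' @param vmax new effective maximal rate (mM/s; 1/(mM s) for mass action).
#' @return the edited model, or the current value for `reaction_vmax()`.
#' @export
modify_vmax <- function(model, reaction_id, vmax) {
  r <- model$reactions[[reaction_id]]
  if (is.null(r)) stop("no reaction ", reaction_id, call. = FALSE)
  if (r$law$scale == "k") {
    r$params["k"] <- vmax
  } else if ("Vmax" %in% names(r$params) && !is.na(r$params["Vmax"])) {
    r$params["Vmax"] <- vmax
  } else {
    # Kcat * E_total parameterisation: rescale Kcat, keep E_total
    r$params["Kcat"] <- vmax / r$params[["E_total"]]
  }
  model$reactions[[reaction_id]] <- r
  model
}

#' @rdname modify_vmax
#' @export
reaction_vmax <- function(model, reaction_id) {
  r <- model$reactions[[reaction_id]]
  if (is.null(r)) stop("no reaction ", reaction_id, call. = FALSE)
  law_scale_value(r$law, as.list(r$params))
}

# set an initial concentration
set_initial <- function(model, species_id, value) {
  i <- match(species_id, model$species$id)
  if (is.na(i)) stop("no species ", species_id, call. = FALSE)
  model$species$initial[i] <- value
  model
}
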