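#' Pathway definitions: CCM extension and heterologous 3-HP/AA routes
#'
#' Encodes the nine reactions that extend the central carbon metabolism with
#' glycerol, malonyl-CoA and beta-alanine production (G3pD, G3pP, GlyK,
#' GlyD, DhaPT, AccC, GluD, AspAT, AspC), the three heterologous
#' 3-hydroxypropionate routes and the shared 3-HP to acrylic-acid trio
#' (3hpcoaS, 3hpcoaDH, AcoaTioE), the mass-action "synth" drains for newly
#' added metabolites, and the assembly of the twelve model variants
#' ({glucose, glycerol} x {glycerol, malonyl_coa, beta_alanine} x
#' {3-HP, AA}).
#'
#' @name pathways
NULL

.pathway_names <- c("glycerol", "malonyl_coa", "beta_alanine")
.synth_targets <- c("DAP", "ACCOA", "MCOA", "LGLU", "ASP", "BA")

# Species introduced by the extension/heterologous reactions, with carbon
# counts (CoA-thioester carbons count the acyl moiety only; the CoA carrier
# itself is treated as a cofactor). Newly added internal metabolites start
# at the 1 mM reference concentration used for Vmax estimation.
.added_species <- function() {
  rbind(
    species("G3P",   1, carbon = 3,  name = "glycerol-3-phosphate"),
    species("DHA",   1, carbon = 3,  name = "dihydroxyacetone"),
    species("MCOA",  1, carbon = 3,  name = "malonyl-CoA"),
    species("LGLU",  1, carbon = 5,  name = "L-glutamate"),
    species("ASP",   1, carbon = 4,  name = "L-aspartate"),
    species("BA",    1, carbon = 3,  name = "beta-alanine"),
    species("HPA",   0, carbon = 3,  name = "3-hydroxypropionaldehyde"),
    species("HP",    0, carbon = 3,  name = "3-hydroxypropionate"),
    species("MSA",   0, carbon = 3,  name = "malonic semialdehyde"),
    species("HPCOA", 0, carbon = 3,  name = "3-hydroxypropionyl-CoA"),
    species("AACOA", 0, carbon = 3,  name = "acrylyl-CoA"),
    species("AA",    0, carbon = 3,  name = "acrylic acid"),
    species("B12",   1, fixed = TRUE, name = "vitamin-B12 coenzyme"),
    species("HPx",   0, carbon = 3, compartment = "extracellular",
            name = "extracellular 3-HP"),
    species("AAx",   0, carbon = 3, compartment = "extracellular",
            name = "extracellular acrylic acid"))
}

#' Native-extension reactions of the central carbon metabolism
#'
#' The nine reactions adding glycerol, malonyl-CoA and beta-alanine
#' production (and glycerol catabolism) to the chassis, with their table
#' mechanisms and constants. `Vmax` values are not part of the printed
#' parameter set: they are estimated from a stoichiometric model (Method 1,
#' see [vmax_method1()]) or must be supplied here.
#'
#' @param vmax named numeric vector of Vmax values (mM/s) keyed by reaction
#'   id; missing entries stay `NA` and must be filled before simulation.
#' @param k_dhapt mass-action constant for DhaPT (1/(mM s)). No literature
#'   value exists for it, so there is no default: it is explicit
#'   configuration (`NA` until set).
#' @return named list of [reaction()] objects
#'   (G3pD, G3pP, GlyK, GlyD, DhaPT, AccC, GluD, AspAT, AspC).
#' @export
native_extension_reactions <- function(vmax = NULL, k_dhapt = NULL) {
  v <- stats::setNames(rep(NA_real_, 9),
                       c("G3pD", "G3pP", "GlyK", "GlyD", "DhaPT",
                         "AccC", "GluD", "AspAT", "AspC"))
  if (!is.null(vmax)) v[names(vmax)] <- vmax
  if (is.null(k_dhapt)) k_dhapt <- NA_real_
  rl <- list(
    # dihydroxyacetone phosphate + NADPH <=> glycerol-3-phosphate + NADP+
    reaction("G3pD", c(DAP = -1, NADPH = -1, G3P = 1, NADP = 1),
             rate_law("rapid_equilibrium_random_bibi_reversible"),
             roles = c(A = "DAP", B = "NADPH", P = "G3P", Q = "NADP"),
             params = c(Vmax = unname(v["G3pD"]), Km_a = 0.175,
                        Km_b = 0.0037, Km_p = 0.12, Km_q = 0.165,
                        Keq = 900)),
    reaction("G3pP", c(G3P = -1, GLY = 1, Pi = 1),
             rate_law("michaelis_menten_1s"), roles = c(A = "G3P"),
             params = c(Vmax = unname(v["G3pP"]), Km = 2.9)),
    reaction("GlyK", c(GLY = -1, ATP = -1, G3P = 1, ADP = 1),
             rate_law("mm_2s_random_bibi_denominator"),
             roles = c(A = "GLY", B = "ATP"),
             params = c(Vmax = unname(v["GlyK"]), Km_a = 0.0084,
                        Km_b = 0.0049, Kd_a = 0.086)),
    # forward (dihydroxyacetone-forming) direction only
    reaction("GlyD", c(GLY = -1, NAD = -1, DHA = 1, NADH = 1),
             rate_law("hill_2s"), roles = c(A = "GLY", B = "NAD"),
             params = c(Vmax = unname(v["GlyD"]), Km_a = 47.83,
                        Km_b = 1.385, n = 0.98)),
    reaction("DhaPT", c(DHA = -1, PEP = -1, DAP = 1, PYR = 1),
             rate_law("mass_action"), roles = c(A = "DHA", B = "PEP"),
             params = c(k = k_dhapt)),
    reaction("AccC", c(ACCOA = -1, ATP = -1, HCO3 = -1,
                       MCOA = 1, ADP = 1, Pi = 1),
             rate_law("ordered_bibi_product_inhibition"),
             roles = c(A = "ACCOA", B = "ATP", P = "MCOA"),
             params = c(Vmax = unname(v["AccC"]), Km_a = 0.018,
                        Km_b = 0.06, Ki_p = 0.07)),
    reaction("GluD", c(AKG = -1, NADPH = -1, NH4 = -1,
                       LGLU = 1, NADP = 1),
             rate_law("mm_2s_multiplicative"),
             roles = c(A = "AKG", B = "NADPH"),
             params = c(Vmax = unname(v["GluD"]), Km_a = 0.495,
                        Km_b = 0.037)),
    reaction("AspAT", c(OAA = -1, LGLU = -1, ASP = 1, AKG = 1),
             rate_law("ping_pong_bibi_reversible"),
             roles = c(A = "OAA", B = "LGLU", P = "ASP", Q = "AKG"),
             params = c(Vmax = unname(v["AspAT"]), Km_a = 19.07,
                        Km_b = 0.19, Km_p = 0.437, Km_q = 2.94,
                        Keq = 3.2)),
    reaction("AspC", c(ASP = -1, BA = 1, CO2 = 1),
             rate_law("michaelis_menten_1s"), roles = c(A = "ASP"),
             params = c(Vmax = unname(v["AspC"]), Km = 0.155)))
  stats::setNames(rl, vapply(rl, `[[`, "", "id"))
}

#' Heterologous pathway reactions
#'
#' Phase 1 converts central metabolites to 3-HP (two enzymes per pathway);
#' phase 2, shared by the three pathways, converts 3-HP to acrylic acid
#' (3hpcoaS, 3hpcoaDH, AcoaTioE). Maximal rates follow the turnover-number
#' method: `Vmax = Kcat * E_total`.
#'
#' @param pathway `"glycerol"`, `"malonyl_coa"` or `"beta_alanine"`.
#' @param end_product `"AA"` (adds phase 2) or `"3-HP"` (phase 1 only).
#' @param e_total total enzyme concentration (mM) shared by all
#'   heterologous laws; 100 mM by default (deliberately in surplus so no
#'   heterologous step is artificially limiting), 1/10 mM for sensitivity
#'   reruns.
#' @return named list of [reaction()] objects.
#' @export
heterologous_reactions <- function(pathway,
                                   end_product = c("AA", "3-HP"),
                                   e_total = 100) {
  end_product <- match.arg(end_product)
  if (!pathway %in% .pathway_names)
    stop("unknown pathway: ", pathway, " (expected ",
         paste(.pathway_names, collapse = ", "), ")", call. = FALSE)
  phase1 <- switch(
    pathway,
    glycerol = list(
      # B12-dependent glycerol dehydratase
      reaction("GlyDH", c(GLY = -1, HPA = 1),
               rate_law("specific_activation"),
               roles = c(A = "GLY", Activator = "B12"),
               params = c(Kcat = 0.0621, E_total = e_total,
                          Km_a = 6.15, Ka = 0.008)),
      reaction("3hpaD", c(HPA = -1, NAD = -1, HP = 1, NADH = 1),
               rate_law("mm_competitive_product_inhibition_2s"),
               roles = c(A = "HPA", B = "NAD", P = "HP"),
               params = c(Kcat = 16.73, E_total = e_total, Km_a = 0.39,
                          Km_b = 1.3, Ki_p = 0.12))),
    malonyl_coa = list(
      reaction("McoaR", c(MCOA = -1, NADPH = -1, MSA = 1, COA = 1,
                          NADP = 1),
               rate_law("mm_2s_random_bibi_denominator"),
               roles = c(A = "MCOA", B = "NADPH"),
               params = c(Kcat = 50, E_total = e_total, Km_a = 0.3,
                          Km_b = 0.03, Kd_a = 0.3)),
      .msar_reaction(e_total)),
    beta_alanine = list(
      reaction("BaTA", c(BA = -1, AKG = -1, MSA = 1, LGLU = 1),
               rate_law("ping_pong_bibi_substrate_inhibition"),
               roles = c(A = "BA", B = "AKG"),
               params = c(Kcat = 47.4, E_total = e_total, Km_a = 5.8,
                          Km_b = 1.07, Ki_b = 10.2)),
      .msar_reaction(e_total)))
  phase2 <- list(
    reaction("3hpcoaS", c(HP = -1, COA = -1, ATP = -1,
                          HPCOA = 1, Pi = 2, AMP = 1),
             rate_law("mm_3s_multiplicative"),
             roles = c(A = "HP", B = "COA", C = "ATP"),
             params = c(Kcat = 36, E_total = e_total, Km_a = 0.015,
                        Km_b = 0.01, Km_c = 0.05)),
    reaction("3hpcoaDH", c(HPCOA = -1, AACOA = 1),
             rate_law("michaelis_menten_1s"), roles = c(A = "HPCOA"),
             params = c(Kcat = 96, E_total = e_total, Km = 0.06)),
    reaction("AcoaTioE", c(AACOA = -1, AA = 1, COA = 1),
             rate_law("michaelis_menten_1s"), roles = c(A = "AACOA"),
             params = c(Kcat = 0.55, E_total = e_total, Km = 0.167)))
  rl <- if (end_product == "AA") c(phase1, phase2) else phase1
  stats::setNames(rl, vapply(rl, `[[`, "", "id"))
}

.msar_reaction <- function(e_total) {
  reaction("MsaR", c(MSA = -1, NADPH = -1, HP = 1, NADP = 1),
           rate_law("mm_2s_random_bibi_denominator"),
           roles = c(A = "MSA", B = "NADPH"),
           params = c(Kcat = 115, E_total = e_total, Km_a = 0.07,
                      Km_b = 0.07, Kd_a = 0.07))
}

#' Mass-action synth drains for newly added metabolites
#'
#' Pseudo-reactions representing the unmodelled pathways that consume
#' dihydroxyacetone phosphate (DAP), acetyl-CoA (ACCOA), malonyl-CoA
#' (MCOA), L-glutamate (LGLU), L-aspartate (ASP) and beta-alanine (BA).
#' Thioester drains release the CoA carrier back to the pool when the model
#' tracks free CoA.
#'
#' @param k named numeric vector of first-order constants (1/s) keyed by
#'   target metabolite; targets absent from `k` get `k = 0` (inert drain).
#' @param release_coa logical; have ACCOA/MCOA drains return `COA`.
#' @param release_pi logical; have the DAP drain return its phosphate as
#'   `Pi` (the carrier/phosphate moieties stay in the model; only carbon
#'   leaves through a synth drain).
#' @return named list of [reaction()] objects `synth_<target>`.
#' @export
synth_reactions <- function(k = numeric(0), release_coa = TRUE,
                            release_pi = TRUE) {
  kk <- stats::setNames(rep(0, length(.synth_targets)), .synth_targets)
  kk[names(k)] <- k
  rl <- lapply(.synth_targets, function(m) {
    sto <- stats::setNames(-1, m)
    if (release_coa && m %in% c("ACCOA", "MCOA")) sto <- c(sto, COA = 1)
    if (release_pi && m == "DAP") sto <- c(sto, Pi = 1)
    reaction(paste0("synth_", m), sto, rate_law("mass_action"),
             roles = c(A = m), params = c(k = kk[[m]]))
  })
  stats::setNames(rl, vapply(rl, `[[`, "", "id"))
}

#' Determine synth-drain constants from a stoichiometric flux distribution
#'
#' For each target metabolite, the first-order constant is the summed flux
#' of all reactions consuming it in the stoichiometric model, divided by
#' the 1 mM reference concentration assumed for newly added metabolites, so
#' that the synth rate at the reference state equals the summed consumption
#' flux.
#'
#' @param stoich a [stoich_model()].
#' @param fluxes named flux vector over the stoichiometric reactions
#'   (mM/s), e.g. from [constrained_fva_max()]/pinned FBA. Reactions absent
#'   from `fluxes` count as zero.
#' @param metabolites targets; defaults to the six synth targets.
#' @param reference_conc reference concentration, mM.
#' @return named numeric vector metabolite -> k (1/s).
#' @export
synth_constants <- function(stoich, fluxes,
                            metabolites = .synth_targets,
                            reference_conc = 1) {
  miss <- setdiff(metabolites, rownames(stoich$S))
  if (length(miss))
    stop("metabolite(s) absent from stoichiometric model: ",
         paste(miss, collapse = ", "), call. = FALSE)
  v <- stats::setNames(rep(0, ncol(stoich$S)), colnames(stoich$S))
  v[names(fluxes)] <- fluxes
  out <- vapply(metabolites, function(m) {
    coef <- stoich$S[m, ]
    cons <- -coef * v          # positive where the reaction consumes m
    sum(cons[coef < 0 & cons > 0]) / reference_conc
  }, numeric(1))
  out
}

# ---- variants --------------------------------------------------------------

#' Specify a model variant
#'
#' @param carbon_source `"glucose"` or `"glycerol"`.
#' @param pathway `"glycerol"`, `"malonyl_coa"` or `"beta_alanine"`.
#' @param end_product `"3-HP"` or `"AA"`.
#' @return an `aakin_variant_spec`.
#' @export
variant_spec <- function(carbon_source = c("glucose", "glycerol"),
                         pathway = .pathway_names,
                         end_product = c("AA", "3-HP")) {
  structure(list(carbon_source = match.arg(carbon_source),
                 pathway = match.arg(pathway),
                 end_product = match.arg(end_product)),
            class = "aakin_variant_spec")
}

#' All twelve variant specifications
#' @return list of 12 [variant_spec()] objects named like `"Glu-Mcoa-AA"`.
#' @export
variant_specs <- function() {
  grid <- expand.grid(carbon_source = c("glucose", "glycerol"),
                      pathway = .pathway_names,
                      end_product = c("3-HP", "AA"),
                      stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(i)
    variant_spec(grid$carbon_source[i], grid$pathway[i],
                 grid$end_product[i]))
  names(out) <- vapply(out, variant_name, "")
  out
}

#' @export
print.aakin_variant_spec <- function(x, ...) {
  cat("<variant>", variant_name(x), "\n"); invisible(x)
}

#' Short display name of a variant (e.g. "Glu-Mcoa-AA")
#' @param spec an `aakin_variant_spec`.
#' @export
variant_name <- function(spec) {
  paste(c(glucose = "Glu", glycerol = "Gly")[[spec$carbon_source]],
        c(glycerol = "Gly", malonyl_coa = "Mcoa",
          beta_alanine = "Ba")[[spec$pathway]],
        sub("3-", "", spec$end_product, fixed = TRUE), sep = "-")
}

#' Build a producing model variant on a chassis
#'
#' Inserts the native extension, the synth drains, the requested
#' heterologous pathway and a first-order export step for the end product
#' into a chassis model, and sets the carbon-source initial condition
#' (glucose 55.5 mM / glycerol 217.2 mM unless overridden).
#'
#' Glucose variants omit GlyD and DhaPT: with only the
#' dihydroxyacetone-forming direction of GlyD parameterised, those steps
#' would deflect freshly made glycerol back into central metabolism instead
#' of supplying the heterologous route.
#'
#' @param chassis an `aakin_model` exposing the attachment species
#'   (DAP, PEP, PYR, ACCOA, OAA, AKG, NAD(P)(H), ATP/ADP/AMP, Pi, NH4,
#'   HCO3, COA, GLY and the carbon-source exchange species).
#' @param spec a [variant_spec()].
#' @param vmax_native named Vmax vector for the native-extension reactions
#'   (from [vmax_method1()] estimates or explicit configuration).
#' @param synth_k named synth constants (from [synth_constants()]).
#' @param k_dhapt DhaPT mass-action constant (required for glycerol
#'   variants; no default exists).
#' @param e_total heterologous enzyme concentration, mM.
#' @param initial_carbon initial carbon-source concentration, mM;
#'   `NULL` uses 55.5 (glucose) / 217.2 (glycerol).
#' @param k_export first-order export constant (1/s) for the end product.
#' @param b12 vitamin-B12 coenzyme concentration, mM (fixed species;
#'   saturating by default).
#' @return an `aakin_model` with provenance annotations.
#' @export
build_variant <- function(chassis, spec, vmax_native = NULL,
                          synth_k = NULL, k_dhapt = NULL, e_total = 100,
                          initial_carbon = NULL, k_export = 1e-3,
                          b12 = 1) {
  required <- c("DAP", "PEP", "PYR", "ACCOA", "OAA", "AKG", "NAD", "NADH",
                "NADP", "NADPH", "ATP", "ADP", "AMP", "Pi", "NH4", "HCO3",
                "COA", "GLY",
                if (spec$carbon_source == "glucose") "GLCx" else "GLYx")
  miss <- setdiff(required, chassis$species$id)
  if (length(miss))
    stop("chassis lacks attachment species: ",
         paste(miss, collapse = ", "), call. = FALSE)

  sp <- chassis$species
  add <- .added_species()
  add <- add[!add$id %in% sp$id, , drop = FALSE]
  sp <- rbind(sp, add)
  sp$initial[sp$id == "B12"] <- b12

  native <- native_extension_reactions(vmax = vmax_native,
                                       k_dhapt = k_dhapt)
  if (spec$carbon_source == "glucose")
    native <- native[setdiff(names(native), c("GlyD", "DhaPT"))]
  synth <- synth_reactions(k = if (is.null(synth_k)) numeric(0) else synth_k,
                           release_coa = "COA" %in% sp$id,
                           release_pi = "Pi" %in% sp$id)
  hetero <- heterologous_reactions(spec$pathway, spec$end_product,
                                   e_total = e_total)
  target <- if (spec$end_product == "AA") c(AA = -1, AAx = 1)
            else c(HP = -1, HPx = 1)
  export <- list(export_product = reaction(
    "export_product", target, rate_law("mass_action"),
    roles = c(A = names(target)[1]), params = c(k = k_export)))

  rxns <- c(chassis$reactions, native, synth, hetero, export)
  model <- kinetic_model(sp, rxns, compartments = chassis$compartments,
                         annotations = utils::modifyList(
                           chassis$annotations,
                           list(variant = variant_name(spec),
                                carbon_source = spec$carbon_source,
                                pathway = spec$pathway,
                                end_product = spec$end_product)))
  init <- if (!is.null(initial_carbon)) initial_carbon
          else if (spec$carbon_source == "glucose") 55.5 else 217.2
  carbon_sp <- if (spec$carbon_source == "glucose") "GLCx" else "GLYx"
  model <- set_initial(model, carbon_sp, init)
  other <- setdiff(c("GLCx", "GLYx"), carbon_sp)
  if (other %in% model$species$id) model <- set_initial(model, other, 0)
  na_par <- vapply(model$reactions, function(r) anyNA(r$params), TRUE)
  if (any(na_par))
    model$annotations$unparameterised <-
      paste(names(model$reactions)[na_par], collapse = ",")
  model
}
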