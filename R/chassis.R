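#' Synthetic central-carbon-metabolism chassis
#'
#' Generates a small, well-conditioned kinetic chassis emulating the
#' central carbon metabolism — glucose (phosphotransferase) and glycerol
#' uptake, a lumped glycolytic backbone, TCA nodes, anaplerosis, oxidative
#' phosphorylation and conserved cofactor pools (NAD(H), NADP(H),
#' ATP/ADP/AMP, CoA, phosphate) — exposing every attachment species the
#' pathway extension needs, together with a stoichiometric twin whose
#' feasible flux cone contains the kinetic steady state by construction.
#' Kinetics are deliberately simple (irreversible Michaelis-Menten and
#' mass action) so closed-loop oracles stay tractable; realism beyond that
#' is not the goal of the synthetic stage.
#'
#' @name synthetic-chassis
NULL

#' Chassis specification
#'
#' @param carbon_source `"glucose"`, `"glycerol"` or `"both"` (both uptake
#'   routes present; initial conditions decide which is active).
#' @param seed optional integer seed for parameter jitter; `NULL` =
#'   unjittered reference chassis.
#' @param jitter relative half-width of the uniform log-jitter applied to
#'   Vmax/k constants when `seed` is set.
#' @param demands upper bounds (mM/s) of the biosynthetic demand reactions
#'   in the stoichiometric twin for the synth-target metabolites.
#' @param k_glyt first-order glycerol uptake constant, 1/s.
#' @param glucose_init,glycerol_init initial carbon, mM.
#' @return an `aakin_chassis_spec`.
#' @export
chassis_spec <- function(carbon_source = c("both", "glucose", "glycerol"),
                         seed = NULL, jitter = 0.1,
                         demands = c(MCOA = 0.002, LGLU = 0.01,
                                     ASP = 0.004, BA = 5e-4),
                         k_glyt = 2e-4,
                         glucose_init = 55.5, glycerol_init = 0) {
  structure(list(carbon_source = match.arg(carbon_source), seed = seed,
                 jitter = jitter, demands = demands, k_glyt = k_glyt,
                 glucose_init = glucose_init,
                 glycerol_init = glycerol_init),
            class = "aakin_chassis_spec")
}

.chassis_species <- function(spec) {
  rbind(
    species("GLCx", spec$glucose_init, compartment = "extracellular",
            carbon = 6, name = "extracellular glucose"),
    species("GLYx", spec$glycerol_init, compartment = "extracellular",
            carbon = 3, name = "extracellular glycerol"),
    species("G6P", 0.5, carbon = 6, name = "glucose-6-phosphate (lumped hexose-P)"),
    species("DAP", 0.5, carbon = 3, name = "dihydroxyacetone phosphate (lumped triose-P)"),
    species("PEP", 0.3, carbon = 3, name = "phosphoenolpyruvate"),
    species("PYR", 0.5, carbon = 3, name = "pyruvate"),
    species("ACCOA", 0.5, carbon = 2, name = "acetyl-CoA"),
    species("OAA", 0.3, carbon = 4, name = "oxaloacetate"),
    species("AKG", 0.5, carbon = 5, name = "alpha-ketoglutarate"),
    species("GLY", 0.1, carbon = 3, name = "glycerol (cytosolic)"),
    species("COA", 1.0, name = "free coenzyme A"),
    species("NAD", 1.5, name = "NAD+"),
    species("NADH", 0.15, name = "NADH"),
    species("NADP", 0.1, name = "NADP+"),
    species("NADPH", 0.1, name = "NADPH"),
    species("ATP", 2.5, name = "ATP"),
    species("ADP", 0.6, name = "ADP"),
    species("AMP", 0.3, name = "AMP"),
    species("Pi", 30, name = "inorganic phosphate"),
    species("NH4", 10, fixed = TRUE, name = "ammonium"),
    species("HCO3", 10, fixed = TRUE, carbon = 1, name = "bicarbonate"),
    species("CO2", 0, fixed = TRUE, carbon = 1, name = "carbon dioxide (sink)"))
}

# lumped chassis reactions; vm = named Vmax/k constants (jitterable)
.chassis_reactions <- function(vm, spec) {
  list(
    pts = reaction("pts", c(GLCx = -1, PEP = -1, G6P = 1, PYR = 1),
                   rate_law("mm_2s_multiplicative"),
                   roles = c(A = "GLCx", B = "PEP"),
                   params = c(Vmax = vm[["pts"]], Km_a = 0.2, Km_b = 0.05)),
    glyt = reaction("glyt", c(GLYx = -1, GLY = 1),
                    rate_law("mass_action"), roles = c(A = "GLYx"),
                    params = c(k = vm[["glyt"]])),
    pfk = reaction("pfk", c(G6P = -1, ATP = -1, DAP = 2, ADP = 1),
                   rate_law("mm_2s_multiplicative"),
                   roles = c(A = "G6P", B = "ATP"),
                   params = c(Vmax = vm[["pfk"]], Km_a = 0.3, Km_b = 0.3)),
    gapdh = reaction("gapdh", c(DAP = -1, NAD = -1, ADP = -1, Pi = -1,
                                PEP = 1, NADH = 1, ATP = 1),
                     rate_law("mm_3s_multiplicative"),
                     roles = c(A = "DAP", B = "NAD", C = "ADP"),
                     params = c(Vmax = vm[["gapdh"]], Km_a = 0.3,
                                Km_b = 0.3, Km_c = 0.1)),
    pyk = reaction("pyk", c(PEP = -1, ADP = -1, PYR = 1, ATP = 1),
                   rate_law("mm_2s_multiplicative"),
                   roles = c(A = "PEP", B = "ADP"),
                   params = c(Vmax = vm[["pyk"]], Km_a = 0.3, Km_b = 0.3)),
    pdh = reaction("pdh", c(PYR = -1, COA = -1, NAD = -1,
                            ACCOA = 1, NADH = 1, CO2 = 1),
                   rate_law("mm_3s_multiplicative"),
                   roles = c(A = "PYR", B = "COA", C = "NAD"),
                   params = c(Vmax = vm[["pdh"]], Km_a = 0.5, Km_b = 0.05,
                              Km_c = 0.3)),
    cs_icd = reaction("cs_icd", c(ACCOA = -1, OAA = -1, NADP = -1,
                                  AKG = 1, COA = 1, NADPH = 1, CO2 = 1),
                      rate_law("mm_3s_multiplicative"),
                      roles = c(A = "ACCOA", B = "OAA", C = "NADP"),
                      params = c(Vmax = vm[["cs_icd"]], Km_a = 0.1,
                                 Km_b = 0.1, Km_c = 0.05)),
    akgdh = reaction("akgdh", c(AKG = -1, NAD = -2, ADP = -1, Pi = -1,
                                OAA = 1, NADH = 2, CO2 = 1, ATP = 1),
                     rate_law("mm_3s_multiplicative"),
                     roles = c(A = "AKG", B = "NAD", C = "ADP"),
                     params = c(Vmax = vm[["akgdh"]], Km_a = 0.3,
                                Km_b = 0.3, Km_c = 0.1)),
    ppc = reaction("ppc", c(PEP = -1, HCO3 = -1, OAA = 1, Pi = 1),
                   rate_law("mm_2s_multiplicative"),
                   roles = c(A = "PEP", B = "HCO3"),
                   params = c(Vmax = vm[["ppc"]], Km_a = 0.4, Km_b = 5)),
    oxphos = reaction("oxphos", c(NADH = -1, ADP = -1, Pi = -1,
                                  NAD = 1, ATP = 1),
                      rate_law("mm_2s_multiplicative"),
                      roles = c(A = "NADH", B = "ADP"),
                      params = c(Vmax = vm[["oxphos"]], Km_a = 0.1,
                                 Km_b = 0.3)),
    pnt = reaction("pnt", c(NADPH = -1, NAD = -1, NADP = 1, NADH = 1),
                   rate_law("mass_action"), roles = c(A = "NADPH", B = "NAD"),
                   params = c(k = vm[["pnt"]])),
    oaa_sink = reaction("oaa_sink", c(OAA = -1, CO2 = 4),
                        rate_law("mass_action"), roles = c(A = "OAA"),
                        params = c(k = vm[["oaa_sink"]])),
    atpm = reaction("atpm", c(ATP = -1, ADP = 1, Pi = 1),
                    rate_law("michaelis_menten_1s"), roles = c(A = "ATP"),
                    params = c(Vmax = vm[["atpm"]], Km = 2)),
    # adenylate kinase kept reversible so the AMP produced by CoA-ligase
    # steps can re-enter the ATP/ADP cycle
    ak = reaction("ak", c(ATP = -1, AMP = -1, ADP = 2),
                  rate_law("mass_action_reversible"),
                  roles = c(A = "ATP", B = "AMP", P = "ADP", Q = "ADP"),
                  params = c(k = vm[["ak"]], Keq = 1)))
}

.chassis_base_constants <- function(spec) {
  c(pts = 0.02, glyt = spec$k_glyt, pfk = 0.05, gapdh = 0.12,
    pyk = 0.06, pdh = 0.15, cs_icd = 0.15, akgdh = 0.15, ppc = 0.0015,
    oxphos = 0.5, pnt = 2, oaa_sink = 1e-3, atpm = 0.5, ak = 0.5)
}

#' Generate the synthetic chassis and its stoichiometric twin
#'
#' @param spec a [chassis_spec()].
#' @return list with `kinetic` (an `aakin_model`) and `stoich` (an
#'   `aakin_stoich_model` containing the chassis reactions, the native
#'   extension, biosynthetic demand reactions for the synth-target
#'   metabolites, and exchange reactions for the boundary species).
#' @export
make_chassis <- function(spec = chassis_spec()) {
  vm <- .chassis_base_constants(spec)
  if (!is.null(spec$seed)) {
    set.seed(spec$seed)
    vm <- vm * exp(stats::runif(length(vm), -spec$jitter, spec$jitter))
  }
  sp <- .chassis_species(spec)
  rx <- .chassis_reactions(vm, spec)
  if (spec$carbon_source == "glucose") rx$glyt <- NULL
  if (spec$carbon_source == "glycerol") {
    rx$pts <- NULL
    if (spec$glycerol_init == 0 && spec$glucose_init > 0)
      stop("glycerol-only chassis needs a glycerol initial concentration",
           call. = FALSE)
  }
  kin <- kinetic_model(
    sp, rx,
    annotations = list(id = "aakin_synthetic_chassis",
                       chassis = "synthetic",
                       carbon_source = spec$carbon_source,
                       seed = if (is.null(spec$seed)) "none" else spec$seed))
  list(kinetic = kin, stoich = chassis_stoich_twin(kin, spec))
}

# stoichiometric twin: chassis + native extension + demands + exchanges
chassis_stoich_twin <- function(kin, spec) {
  ext <- native_extension_reactions()      # stoichiometry only
  add <- .added_species()
  all_sp <- unique(c(kin$species$id, add$id))
  cols <- list()
  for (r in c(kin$reactions, ext)) cols[[r$id]] <- r$stoich
  cols$dem_MCOA <- c(MCOA = -1, COA = 1)
  cols$dem_LGLU <- c(LGLU = -1)
  cols$dem_ASP <- c(ASP = -1)
  cols$dem_BA <- c(BA = -1)
  for (b in c("GLCx", "GLYx", "NH4", "HCO3"))
    cols[[paste0("src_", b)]] <- stats::setNames(1, b)
  cols$snk_CO2 <- c(CO2 = -1)
  S <- matrix(0, length(all_sp), length(cols),
              dimnames = list(all_sp, names(cols)))
  for (j in names(cols)) S[names(cols[[j]]), j] <- cols[[j]]
  # bounds an order of magnitude above any realistic chassis flux keep the
  # LP well conditioned
  lb <- stats::setNames(rep(0, ncol(S)), colnames(S))
  ub <- stats::setNames(rep(10, ncol(S)), colnames(S))
  rev_ids <- names(which(vapply(c(kin$reactions, ext),
                                function(r) isTRUE(r$reversible), TRUE)))
  lb[intersect(rev_ids, colnames(S))] <- -10
  dem <- spec$demands
  ub[paste0("dem_", names(dem))] <- dem
  stoich_model(S, lb = lb, ub = ub)
}

#' Reference results for the default chassis
#'
#' Recomputes the frozen steady-state and control-coefficient fixture
#' shipped with the package (computed once from the default unjittered
#' chassis with the finite-difference oracle) so tests can verify that
#' regeneration reproduces it.
#'
#' @param spec a default [chassis_spec()].
#' @return list with `steady` (data frame species/concentration and
#'   reaction/flux) and `fcc` (structural and finite-difference table for
#'   the glucose-uptake flux of the continuous chassis).
#' @export
reference_results <- function(spec = chassis_spec()) {
  ch <- make_chassis(spec)
  cont <- make_continuous(ch$kinetic)
  ss <- find_steady_state(cont)
  fcc <- flux_control_coefficients(cont, ss, target_flux_chassis(cont))
  list(steady = list(
         concentrations = data.frame(species = names(ss$concentrations),
                                     mM = unname(ss$concentrations)),
         fluxes = data.frame(reaction = names(ss$fluxes),
                             mM_per_s = unname(ss$fluxes))),
       fcc = as.data.frame(fcc))
}

# default MCA target on a bare chassis: the anabolic drain, whose control
# is distributed across several enzymes (the uptake flux is trivially
# feed-controlled in a continuous culture)
target_flux_chassis <- function(model) {
  if ("oaa_sink" %in% names(model$reactions)) "oaa_sink" else "pts"
}
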