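#' End-to-end workflows
#'
#' Convenience layer running the full analysis on a chassis: estimate the
#' native-extension Vmax values (constrained FVA + saturation factor),
#' derive the synth-drain constants from the stoichiometric twin, build
#' producing variants, simulate batch time courses, run control analysis
#' and the design loop. [run_workflow()] exposes the stages as named
#' commands with file artefacts and a JSON run manifest, so scripted
#' analyses stay reproducible.
#'
#' @name workflows
NULL

#' Flux distribution used for synth-constant derivation
#'
#' Pins the shared reactions of the stoichiometric model to the kinetic
#' steady-state fluxes (within `tol`) and maximises the summed flux of the
#' biosynthetic demand reactions, giving the consumption pattern of the
#' newly added metabolites at the reference state.
#'
#' @param stoich a [stoich_model()] with `dem_*` demand columns.
#' @param kinetic_fluxes named steady-state flux vector of the kinetic
#'   chassis.
#' @param tol pin half-width, mM/s.
#' @return named flux vector over all stoichiometric reactions.
#' @export
synth_flux_distribution <- function(stoich, kinetic_fluxes, tol = 0.01) {
  rx <- colnames(stoich$S)
  lb <- stoich$lb; ub <- stoich$ub
  shared <- intersect(names(kinetic_fluxes), rx)
  i <- match(shared, rx)
  lb[i] <- pmax(lb[i], kinetic_fluxes[shared] - tol)
  ub[i] <- pmin(ub[i], kinetic_fluxes[shared] + tol)
  obj <- as.numeric(grepl("^dem_", rx))
  if (!any(obj > 0))
    stop("stoichiometric model has no demand (dem_*) reactions",
         call. = FALSE)
  sol <- solve_lp(obj, stoich$S, lb, ub, maximize = TRUE)
  if (!sol$feasible)
    stop("infeasible LP while deriving synth constants", call. = FALSE)
  stats::setNames(sol$x, rx)
}

#' Default parameterisation of the pathway extension on a chassis
#'
#' Runs the estimation stage once: chassis steady state (continuous
#' variant), Method-1 Vmax for the nine native-extension reactions
#' (including the DhaPT mass-action constant), synth-drain constants from
#' the stoichiometric twin. The aspartate-carboxylase Vmax is replaced by
#' its turnover-number value (`vmax_method2(0.57)` = 57 mM/s): the
#' demand-limited Method-1 estimate throttles the whole beta-alanine route
#' to negligible flux, so the route is parameterised like the heterologous
#' enzymes instead.
#'
#' @param chassis result of [make_chassis()] (list with `kinetic`,
#'   `stoich`).
#' @param aspc_kcat turnover number used for the AspC override (1/s);
#'   set `NULL` to keep the Method-1 estimate.
#' @param e_total enzyme concentration for the override, mM.
#' @return list with `vmax_native`, `k_dhapt`, `synth_k` and the
#'   intermediate `steady`/`fluxes` records.
#' @export
pipeline_defaults <- function(chassis, aspc_kcat = 0.57, e_total = 100) {
  cont <- make_continuous(chassis$kinetic)
  steady <- find_steady_state(cont)
  vn <- estimate_native_vmax(cont, chassis$stoich)
  if (!is.null(aspc_kcat))
    vn["AspC"] <- vmax_method2(aspc_kcat, e_total)
  dist <- synth_flux_distribution(chassis$stoich, steady$fluxes)
  sk <- synth_constants(chassis$stoich, dist)
  list(vmax_native = vn[setdiff(names(vn), "DhaPT")],
       k_dhapt = unname(vn["DhaPT"]),
       synth_k = sk, steady = steady, flux_distribution = dist)
}

#' Build a fully parameterised producing model on the synthetic chassis
#'
#' @param spec a [variant_spec()].
#' @param chassis optional [make_chassis()] result; generated with default
#'   settings when omitted.
#' @param defaults optional [pipeline_defaults()] result (recomputed when
#'   omitted).
#' @param ... passed to [build_variant()].
#' @return an `aakin_model` ready for simulation.
#' @export
build_producing_model <- function(spec, chassis = NULL, defaults = NULL,
                                  ...) {
  if (is.null(chassis)) chassis <- make_chassis()
  if (is.null(defaults)) defaults <- pipeline_defaults(chassis)
  build_variant(chassis$kinetic, spec,
                vmax_native = defaults$vmax_native,
                synth_k = defaults$synth_k,
                k_dhapt = defaults$k_dhapt, ...)
}

#' Run a workflow command
#'
#' Dispatches one analysis stage and writes its artefacts (SBML, CSV) plus
#' a JSON manifest recording inputs, tolerances and outcomes. Fully
#' offline: the chassis is either generated synthetically or read from a
#' local SBML file.
#'
#' @param config list (or path to a YAML file) with fields:
#'   `chassis` (`"synthetic"` or a path to an SBML file), `carbon_source`,
#'   `pathway`, `end_product`, `initial_gL` (optional), `hours`
#'   (default 3), `e_total` (default 100), `out_dir` (default `"."`).
#' @param command one of `"chassis"`, `"build"`, `"simulate"`, `"steady"`,
#'   `"mca"`, `"estimate"`, `"design"`.
#' @return invisibly, a list with the computed objects and the manifest.
#' @export
run_workflow <- function(config, command = c("simulate", "build", "chassis",
                                             "steady", "mca", "estimate",
                                             "design")) {
  command <- match.arg(command)
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(
    list(chassis = "synthetic", carbon_source = "glucose",
         pathway = "malonyl_coa", end_product = "AA", hours = 3,
         e_total = 100, out_dir = ".", max_iter = 5, initial_gL = NULL),
    config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- list()
  manifest <- list(command = command, config = cfg[setdiff(names(cfg), "")])

  chassis <- if (identical(cfg$chassis, "synthetic")) make_chassis()
             else list(kinetic = read_sbml(cfg$chassis), stoich = NULL)

  if (command == "chassis") {
    p <- file.path(cfg$out_dir, "chassis.sbml")
    write_sbml(chassis$kinetic, p)
    art$chassis_sbml <- p
  } else if (command == "estimate") {
    if (is.null(chassis$stoich))
      stop("estimation needs the synthetic chassis (stoichiometric twin)",
           call. = FALSE)
    d <- pipeline_defaults(chassis)
    df <- data.frame(reaction = c(names(d$vmax_native), "DhaPT"),
                     vmax = c(unname(d$vmax_native), d$k_dhapt))
    p <- file.path(cfg$out_dir, "vmax_estimates.csv")
    utils::write.csv(df, p, row.names = FALSE)
    art$estimates_csv <- p
    art$estimates <- d
  } else {
    spec <- variant_spec(cfg$carbon_source, cfg$pathway, cfg$end_product)
    init <- if (!is.null(cfg$initial_gL))
      convert_concentration(cfg$initial_gL, "gL_to_mM",
                            if (cfg$carbon_source == "glucose") "glucose"
                            else "glycerol")
    model <- build_producing_model(spec, chassis = chassis,
                                   e_total = cfg$e_total,
                                   initial_carbon = init)
    if (command == "build") {
      p <- file.path(cfg$out_dir, paste0(variant_name(spec), ".sbml"))
      write_sbml(model, p)
      art$model_sbml <- p
    } else if (command == "simulate") {
      tr <- simulate_timecourse(model, duration = cfg$hours * 3600)
      p <- file.path(cfg$out_dir, paste0(variant_name(spec), "_traj.csv"))
      write_trajectory_csv(tr, p)
      art$trajectory_csv <- p
      prod <- if (spec$end_product == "AA") "AAx" else "HPx"
      manifest$final_titer_gL <- titer_gL(tr, prod)
    } else if (command %in% c("steady", "mca")) {
      cont <- make_continuous(model)
      ss <- find_steady_state(cont)
      manifest$residual <- ss$residual
      manifest$stable <- ss$stable
      if (command == "mca") {
        fcc <- flux_control_coefficients(cont, ss, "AcoaTioE", fd = FALSE)
        p <- file.path(cfg$out_dir, paste0(variant_name(spec), "_fcc.csv"))
        utils::write.csv(as.data.frame(fcc), p, row.names = FALSE)
        art$fcc_csv <- p
        art$fcc <- fcc
      } else art$steady <- ss
    } else if (command == "design") {
      h <- design_loop(model, max_iter = cfg$max_iter,
                       horizon = cfg$hours * 3600)
      tab <- mutants_table(h)
      p <- file.path(cfg$out_dir, paste0(variant_name(spec), "_mutants.csv"))
      utils::write.csv(tab, p, row.names = FALSE)
      art$mutants_csv <- p
      art$history <- h
      manifest$stop_reason <- attr(h, "stop_reason")
    }
  }
  manifest$artefacts <- names(art)[vapply(art, is.character, TRUE)]
  mp <- file.path(cfg$out_dir, paste0("manifest_", command, ".json"))
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(art, list(manifest = manifest, manifest_path = mp)))
}
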