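# Pathway encoding: the nine-reaction extension, the heterologous routes,
# synth drains, the twelve variants, and the transcription-fixture census.

test_that("the native extension has exactly nine reactions with the printed laws", {
  ext <- native_extension_reactions()
  expect_length(ext, 9)
  expect_setequal(names(ext), c("G3pD", "G3pP", "GlyK", "GlyD", "DhaPT",
                                "AccC", "GluD", "AspAT", "AspC"))
  expect_identical(ext$AspC$law$mechanism, "michaelis_menten_1s")
  expect_identical(unname(ext$AspC$params["Km"]), 0.155)
  # reversible equilibria as stated
  expect_true(ext$G3pD$reversible)
  expect_identical(unname(ext$G3pD$params["Keq"]), 900)
  expect_true(ext$AspAT$reversible)
  expect_identical(unname(ext$AspAT$params["Keq"]), 3.2)
  # glycerol dehydrogenase carries only the dihydroxyacetone-forming
  # direction
  expect_false(ext$GlyD$reversible)
  expect_identical(ext$GlyD$stoich[c("GLY", "DHA")], c(GLY = -1, DHA = 1))
})

test_that("heterologous routes assemble the documented reaction sets", {
  mcoa <- heterologous_reactions("malonyl_coa", "AA")
  expect_setequal(names(mcoa),
                  c("McoaR", "MsaR", "3hpcoaS", "3hpcoaDH", "AcoaTioE"))
  ba3 <- heterologous_reactions("beta_alanine", "3-HP")
  expect_setequal(names(ba3), c("BaTA", "MsaR"))
  gly <- heterologous_reactions("glycerol", "AA")
  expect_setequal(names(gly),
                  c("GlyDH", "3hpaD", "3hpcoaS", "3hpcoaDH", "AcoaTioE"))
  # the B12-dependent activation of the dehydratase
  expect_identical(gly$GlyDH$law$mechanism, "specific_activation")
  expect_identical(unname(gly$GlyDH$params["Ka"]), 0.008)
  expect_identical(unname(gly$GlyDH$roles["Activator"]), "B12")
  # phase 2 is shared verbatim across pathways
  for (r in c("3hpcoaS", "3hpcoaDH", "AcoaTioE"))
    expect_identical(heterologous_reactions("beta_alanine", "AA")[[r]],
                     mcoa[[r]])
  expect_error(heterologous_reactions("shikimate"), "unknown pathway")
})

test_that("turnover-number Vmax of the thioesterase is Kcat x enzyme surplus", {
  r <- heterologous_reactions("malonyl_coa", "AA")$AcoaTioE
  expect_equal(aakin:::law_scale_value(r$law, as.list(r$params)), 55)
  expect_equal(vmax_method2(0.55, 100), 55)
  r10 <- heterologous_reactions("malonyl_coa", "AA",
                                e_total = 10)$AcoaTioE
  expect_equal(aakin:::law_scale_value(r10$law, as.list(r10$params)), 5.5)
})

test_that("every printed table constant appears exactly once in the assembled reactions", {
  census <- utils::read.csv(system.file("extdata",
                                        "rate_law_parameters.csv",
                                        package = "aakin"))
  ext <- native_extension_reactions()
  het <- c(heterologous_reactions("glycerol", "AA"),
           heterologous_reactions("malonyl_coa", "AA"),
           heterologous_reactions("beta_alanine", "AA"))
  het <- het[!duplicated(names(het))]
  all_rx <- c(ext, het)
  for (i in seq_len(nrow(census))) {
    row <- census[i, ]
    r <- all_rx[[row$reaction]]
    expect_false(is.null(r), info = row$reaction)
    expect_identical(r$law$mechanism, row$mechanism, info = row$reaction)
    if (is.na(row$value)) {
      # the DhaPT elementary constant has no literature value: it must be
      # explicit configuration, not a silent default
      expect_true(is.na(r$params[[row$slot]]))
    } else {
      expect_identical(unname(r$params[[row$slot]]), row$value,
                       info = paste(row$reaction, row$slot))
    }
  }
  # census coverage: every non-scale constant of every reaction is audited
  audited <- split(census$slot, census$reaction)
  for (id in names(all_rx)) {
    slots <- setdiff(names(all_rx[[id]]$params), c("Vmax", "E_total"))
    # McoaR/MsaR print a random bi-bi denominator whose constant term is
    # Km_a * Km_b: their Kd_a binding is derived, not an extra constant
    if (id %in% c("McoaR", "MsaR")) slots <- setdiff(slots, "Kd_a")
    expect_setequal(slots, audited[[id]])
  }
})

test_that("synth constants sum consuming fluxes at the 1 mM reference", {
  S <- matrix(c(-1, 0, 1,
                -1, 0, 0,
                0, -1, 0), nrow = 3,
              dimnames = list(c("MCOA", "LGLU", "ASP"),
                              c("use1", "use2", "make1")))
  S["MCOA", ] <- c(-1, -1, 1)
  S["LGLU", ] <- c(0, 0, 0)
  S["ASP", ] <- c(0, 0, -1)
  st <- stoich_model(S)
  k <- synth_constants(st, c(use1 = 0.2, use2 = 0.3, make1 = 0.1),
                       metabolites = c("MCOA", "LGLU", "ASP"))
  expect_equal(unname(k["MCOA"]), 0.5)     # 0.2 + 0.3 consumed, at 1 mM
  expect_equal(unname(k["LGLU"]), 0)       # nothing consumes it
  expect_equal(unname(k["ASP"]), 0.1)
  expect_error(synth_constants(st, numeric(0), metabolites = "BA"),
               "absent from stoichiometric model")
  expect_length(synth_reactions(), 6)
  expect_setequal(names(synth_reactions()),
                  paste0("synth_", c("DAP", "ACCOA", "MCOA", "LGLU",
                                     "ASP", "BA")))
})

test_that("all twelve variants build deterministically on the synthetic chassis", {
  specs <- variant_specs()
  expect_length(specs, 12)
  expect_identical(anyDuplicated(names(specs)), 0L)
  ch <- default_chassis()
  d <- default_defaults()
  for (nm in names(specs)) {
    m <- build_variant(ch$kinetic, specs[[nm]],
                       vmax_native = d$vmax_native, synth_k = d$synth_k,
                       k_dhapt = d$k_dhapt)
    expect_s3_class(m, "aakin_model")
    expect_identical(m$annotations$variant, nm)
    if (specs[[nm]]$carbon_source == "glucose") {
      # parameterising GlyD only towards dihydroxyacetone would deflect
      # fresh glycerol back to central metabolism, so glucose variants
      # omit GlyD/DhaPT
      expect_false(any(c("GlyD", "DhaPT") %in% names(m$reactions)))
      expect_equal(m$species$initial[m$species$id == "GLCx"], 55.5)
    } else {
      expect_true(all(c("GlyD", "DhaPT") %in% names(m$reactions)))
      expect_equal(m$species$initial[m$species$id == "GLYx"], 217.2)
    }
    m2 <- build_variant(ch$kinetic, specs[[nm]],
                        vmax_native = d$vmax_native, synth_k = d$synth_k,
                        k_dhapt = d$k_dhapt)
    expect_identical(m2, m)
  }
})

test_that("removing phase-1 reactions starves acrylic-acid formation", {
  m <- producing_model("Glu-Mcoa-AA")
  keep <- setdiff(names(m$reactions), c("McoaR", "MsaR"))
  crippled <- kinetic_model(m$species, m$reactions[keep],
                            compartments = m$compartments,
                            annotations = m$annotations)
  tr <- simulate_timecourse(crippled, duration = 10800, n_out = 13)
  expect_lt(titer_gL(tr, "AAx"), 1e-6)
})

test_that("a chassis without the attachment species is rejected with the missing list", {
  tiny <- kinetic_model(
    rbind(species("GLCx", 10, compartment = "extracellular"),
          species("PYR", 1)),
    list(reaction("r", c(GLCx = -1, PYR = 1), rate_law("mass_action"),
                  roles = c(A = "GLCx"), params = c(k = 1e-3))))
  expect_error(build_variant(tiny, variant_spec("glucose", "malonyl_coa",
                                                "AA")),
               "attachment species.*DAP")
})
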