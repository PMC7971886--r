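# Shared fixtures, built in code. The default chassis and its estimation
# stage are computed once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

default_chassis <- function() {
  if (is.null(.fixtures$chassis)) .fixtures$chassis <- make_chassis()
  .fixtures$chassis
}

default_defaults <- function() {
  if (is.null(.fixtures$defaults))
    .fixtures$defaults <- pipeline_defaults(default_chassis())
  .fixtures$defaults
}

producing_model <- function(name) {
  key <- paste0("variant_", name)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- build_producing_model(
      variant_specs()[[name]], chassis = default_chassis(),
      defaults = default_defaults())
  .fixtures[[key]]
}

# Minimal one-substrate Michaelis-Menten drain: dA/dt = -Vmax A/(Km+A)
mm_drain_model <- function(A0 = 10, vmax = 0.05, km = 2) {
  kinetic_model(
    species("A", A0, carbon = 1),
    list(reaction("drain", c(A = -1), rate_law("michaelis_menten_1s"),
                  roles = c(A = "A"), params = c(Vmax = vmax, Km = km))))
}

# Linear mass-action chain with constant feed: FEED -> A -> B -> out
linear_chain_model <- function(k0 = 0.02, k1 = 0.1, k2 = 0.05) {
  sp <- rbind(species("FEED", 1, fixed = TRUE),
              species("A", 0.01), species("B", 0.01))
  kinetic_model(sp, list(
    reaction("feed", c(A = 1), rate_law("mass_action"),
             roles = c(A = "FEED"), params = c(k = k0)),
    reaction("r1", c(A = -1, B = 1), rate_law("mass_action"),
             roles = c(A = "A"), params = c(k = k1)),
    reaction("r2", c(B = -1), rate_law("mass_action"),
             roles = c(A = "B"), params = c(k = k2))))
}

# Two irreversible MM enzymes around one intermediate S; the first step is
# product-inhibited so both enzymes share control:
#   v1 = V1 * X/(K1+X) / (1 + S/Ki),  v2 = V2 * S/(K2+S)
two_enzyme_chain <- function(V1 = 0.1, K1 = 0.5, Ki = 0.8,
                             V2 = 0.15, K2 = 0.6, X = 1) {
  law1 <- rate_law("mm_competitive_product_inhibition_2s")
  sp <- rbind(species("X", X, fixed = TRUE),
              species("DUMMY", 10, fixed = TRUE),
              species("S", 0.1))
  kinetic_model(sp, list(
    # bind B to a saturating fixed dummy so the law reduces to
    # V1 * X/(K1 (1+S/Ki) + X) * ~1; Km_b chosen negligible
    reaction("e1", c(S = 1), law1,
             roles = c(A = "X", B = "DUMMY", P = "S"),
             params = c(Vmax = V1, Km_a = K1, Km_b = 1e-9, Ki_p = Ki)),
    reaction("e2", c(S = -1), rate_law("michaelis_menten_1s"),
             roles = c(A = "S"), params = c(Vmax = V2, Km = K2))))
}

# A closed (no boundary species) copy of a model: unfix everything and
# drop pure feed/exchange reactions so total carbon must be conserved.
close_model <- function(model, drop = character(0)) {
  sp <- model$species
  sp$fixed <- FALSE
  rx <- model$reactions[setdiff(names(model$reactions), drop)]
  kinetic_model(sp, rx, compartments = model$compartments,
                annotations = model$annotations)
}

# brute-force LP oracle for tiny networks: enumerate candidate vertices by
# fixing (n - rank(S)) variables at a bound and solving the equalities
vertex_enumeration_max <- function(S, lb, ub, target) {
  n <- ncol(S)
  qrS <- qr(S)
  r <- qrS$rank
  free <- n - r
  idx <- seq_len(n)
  best <- -Inf
  for (fix in utils::combn(n, free, simplify = FALSE)) {
    rest <- setdiff(idx, fix)
    grid <- expand.grid(rep(list(c(1, 2)), length(fix)))
    for (g in seq_len(nrow(grid))) {
      x <- numeric(n)
      x[fix] <- ifelse(grid[g, ] == 1, lb[fix], ub[fix])
      rhs <- -S[, fix, drop = FALSE] %*% x[fix]
      sol <- tryCatch(qr.solve(S[, rest, drop = FALSE], rhs),
                      error = function(e) NULL)
      if (is.null(sol)) next
      x[rest] <- sol
      ok <- all(x >= lb - 1e-9) && all(x <= ub + 1e-9) &&
        max(abs(S %*% x)) < 1e-9
      if (ok) best <- max(best, x[match(target, colnames(S))])
    }
  }
  best
}
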