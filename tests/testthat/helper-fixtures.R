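# Shared in-code fixtures: a small map, a BC1-derived panel with two
# environments and a purely programmatic tiny dataset for IO round-trips.

tiny_map <- function(seed = 1) simulate_map(2, 12, 100, 10000, seed = seed)

tiny_panel <- function(n_rils = 60, seed = 2,
                       scheme = "backcross_then_self") {
  simulate_ril_population(tiny_map(),
                          cross_design(scheme, 4, "W22", "TIL", n_rils),
                          seed = seed, population_id = "popA")
}

tiny_architecture <- function(map = tiny_map(), h2a = 0.5, h2e = 0.1,
                              envs = c(e1 = 0, e2 = 2), seed = 3) {
  random_architecture(map, n_qtl = 8, n_pairs = 2, trait = "DTA",
                      h2_additive = h2a, h2_epistatic = h2e,
                      env_effects = envs, trait_mean = 70, seed = seed)
}

# deterministic linear toy-regression data for model oracles
toy_regression <- function(n = 30, p = 20, h2 = 0.8, seed = 11,
                           beta = NULL) {
  set.seed(seed)
  X <- matrix(rbinom(n * p, 2, 0.5), n, p,
              dimnames = list(NULL, paste0("m", seq_len(p))))
  beta <- beta %||% rnorm(p)
  g <- as.numeric(X %*% beta)
  e_sd <- if (h2 >= 1) 0 else sd(g) * sqrt((1 - h2) / h2)
  y <- g + rnorm(n, 0, e_sd)
  list(X = X, y = y, beta = beta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
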