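# Marker-effect inference: linear effects, impurity importance, Shapley
# attribution (closed form, exact enumeration oracle, efficiency), pairwise
# interactions, normalisation, ensembles and quantile tracks.

# a deterministic linear "model" exposing the package's predict contract
lin_toy_model <- function(beta, markers = names(beta)) {
  structure(list(model_id = "SVR", markers = markers, beta = beta,
                 Ftrain = matrix(numeric(0), 0, 0)),
            class = c("lin_toy", "gp_model"))
}
registerS3method("predict", "lin_toy",
                 function(object, X, F = NULL, ...)
                   as.numeric(X %*% object$beta))

test_that("allele-substitution and impurity effects come from the right fits", {
  toy <- toy_regression(60, 10, h2 = 0.9, seed = 81, beta = c(4, rep(0, 9)))
  fr <- fit_rrblup(toy$X, toy$y, n_iter = 1200, burn_in = 300, seed = 82)
  ef <- effects_linear(fr)
  expect_equal(ef$marker, colnames(toy$X))
  expect_equal(which.max(abs(ef$raw)), 1)
  expect_equal(max(ef$normalized), 1)
  cst <- fit_rrblup(toy$X, rep(1, 60), n_iter = 800, burn_in = 200, seed = 83)
  expect_lt(max(abs(effects_linear(cst)$raw)), 1e-3)

  # impurity importance: only informative features are split on
  set.seed(84)
  X2 <- matrix(rbinom(400, 2, 0.5), 200, 2,
               dimnames = list(NULL, c("f1", "f2")))
  y2 <- as.numeric(X2[, 1] * 3) + rnorm(200, 0, 0.3)
  frf <- fit_rf(X2, y2, n_trees = 60, seed = 85)
  imp <- effects_impurity(frf)
  expect_gt(imp$raw[1], 10 * max(imp$raw[2], 1e-9))
  expect_true(all(imp$raw >= 0))
  expect_error(effects_linear(frf), "rrBLUP or BayesB")
  expect_error(effects_impurity(fr), "random-forest")
})

test_that("Shapley values obey the linear closed form and the efficiency identity", {
  set.seed(86)
  p <- 6
  beta <- setNames(c(2, -1, 0.5, 0, 0, 1), paste0("m", 1:p))
  mdl <- lin_toy_model(beta)
  Xe <- matrix(rbinom(5 * p, 2, 0.5), 5, p,
               dimnames = list(NULL, names(beta)))
  Xb <- matrix(rbinom(40 * p, 2, 0.5), 40, p,
               dimnames = list(NULL, names(beta)))
  prof <- shapley_effects(mdl, Xe, Xb, n_permutations = 150, seed = 87)
  phi <- attr(prof, "phi")
  # additive model, independent features: phi_j = beta_j (x_j - mean bg_j)
  closed <- sweep(Xe, 2, colMeans(Xb)) %*% diag(beta)
  expect_lt(max(abs(phi - closed)), 0.05 * max(abs(closed)))
  # markers the model ignores get ~0 attribution
  expect_lt(max(abs(phi[, 4:5])), 0.05)
  # efficiency: sum phi = f(x) - baseline, per explained sample, exactly
  gap <- abs(rowSums(phi) - (attr(prof, "fx") - attr(prof, "baseline")))
  expect_lt(max(gap), 1e-10)
})

test_that("sampled Shapley matches exact subset enumeration on 4 markers", {
  set.seed(88)
  p <- 4
  mk <- paste0("m", 1:p)
  # a nonlinear model so the check is not trivially additive
  beta <- setNames(c(1.5, -2, 0.8, 0.3), mk)
  nl <- structure(list(model_id = "SVR", markers = mk, beta = beta,
                       Ftrain = matrix(numeric(0), 0, 0)),
                  class = c("nl_toy", "gp_model"))
  registerS3method("predict", "nl_toy",
                   function(object, X, F = NULL, ...)
                     as.numeric(X %*% object$beta) + 0.8 * X[, 1] * X[, 2])
  Xe <- matrix(rbinom(3 * p, 2, 0.5), 3, p, dimnames = list(NULL, mk))
  Xb <- matrix(rbinom(12 * p, 2, 0.5), 12, p, dimnames = list(NULL, mk))
  # exact enumeration oracle over all 2^4 subsets with interventional values
  exact_phi <- function(x) {
    subsets <- expand.grid(rep(list(c(FALSE, TRUE)), p))
    v <- function(S) {
      Z <- Xb
      Z[, S] <- matrix(x[S], nrow(Xb), sum(S), byrow = TRUE)
      mean(predict(nl, Z))
    }
    vals <- apply(subsets, 1, function(S) v(as.logical(S)))
    phi <- numeric(p)
    for (j in 1:p) {
      for (r in seq_len(nrow(subsets))) {
        S <- as.logical(subsets[r, ])
        if (S[j]) next
        s <- sum(S)
        w <- factorial(s) * factorial(p - s - 1) / factorial(p)
        Sj <- S; Sj[j] <- TRUE
        vS <- vals[r]
        rj <- which(apply(subsets, 1, function(q) all(as.logical(q) == Sj)))
        phi[j] <- phi[j] + w * (vals[rj] - vS)
      }
    }
    phi
  }
  oracle <- t(apply(Xe, 1, exact_phi))
  prof <- shapley_effects(nl, Xe, Xb, n_permutations = 480, seed = 89)
  expect_lt(max(abs(attr(prof, "phi") - oracle)), 1e-2 * max(1, max(abs(oracle))))
  # exact mode reproduces the enumeration to numerical precision
  prof_ex <- shapley_effects(nl, Xe, Xb, exact = TRUE)
  expect_lt(max(abs(attr(prof_ex, "phi") - oracle)), 1e-10)
  expect_error(shapley_effects(nl, Xe, Xb[0, , drop = FALSE]), "non-empty")
})

test_that("pairwise interaction scores are symmetric and recover an epistatic pair", {
  set.seed(90)
  p <- 8
  X <- matrix(rbinom(150 * p, 2, 0.5), 150, p,
              dimnames = list(NULL, paste0("m", 1:p)))
  y_epi <- 3 * (X[, 2] * X[, 5]) + rnorm(150, 0, 0.4)
  frf <- fit_rf(X, y_epi, n_trees = 150, seed = 91)
  iset <- pairwise_shapley_rf(frf, X[1:25, ], n_draws = 12,
                              top_fraction = 0.2, seed = 92)
  sm <- attr(iset, "score_matrix")
  expect_equal(sm, t(sm))                         # symmetry by construction
  expect_setequal(c(iset$marker_i[1], iset$marker_j[1]), c("m2", "m5"))
  expect_equal(nrow(iset), ceiling(0.2 * choose(p, 2)))

  # additive trait: no pair dominates the way the true epistatic pair does
  y_add <- as.numeric(X %*% c(2, 2, 0, 0, 2, 0, 0, 0)) + rnorm(150, 0, 0.4)
  fadd <- fit_rf(X, y_add, n_trees = 150, seed = 93)
  iadd <- pairwise_shapley_rf(fadd, X[1:25, ], n_draws = 12,
                              top_fraction = 1, seed = 94)
  ratio_epi <- iset$score[1] / median(attr(iset, "score_matrix")[upper.tri(sm)])
  sm_add <- attr(iadd, "score_matrix")
  ratio_add <- max(sm_add) / median(sm_add[upper.tri(sm_add)])
  expect_gt(ratio_epi, 3 * ratio_add)
  expect_error(pairwise_shapley_rf(frf, X[1:4, 1, drop = FALSE]), "2 markers")

  # default selection quantile keeps ceiling(1e-4 * n_pairs) pairs
  expect_equal(nrow(pairwise_shapley_rf(fadd, X[1:5, ], n_draws = 2,
                                        seed = 95)), 1)
})

test_that("normalisation, ensembles and decile tracks follow their definitions", {
  prof <- gpensemble:::new_effects(c("a", "b", "c"), c(2, -1, 0), "rrBLUP",
                                   "allele_substitution")
  expect_equal(prof$normalized, c(1, 0.5, 0))
  z <- gpensemble:::new_effects(c("a", "b"), c(0, 0), "SVR", "shapley")
  expect_equal(z$normalized, c(0, 0))             # no division error
  scaled <- prof; scaled$raw <- prof$raw * -7.3
  expect_equal(normalize_effects(scaled)$normalized, prof$normalized)

  p2 <- gpensemble:::new_effects(c("a", "b", "c"), c(0, 1, 1), "RF", "impurity")
  ens <- ensemble_effects(list(prof, p2))
  expect_equal(ens$normalized, c(0.5, 0.75, 0.5))
  expect_equal(attr(ens, "model_id"), "ensemble")
  same <- ensemble_effects(list(prof, prof, prof))
  expect_equal(same$normalized, prof$normalized)  # idempotent on identical
  expect_true(all(ens$normalized <= pmax(prof$normalized, p2$normalized) &
                    ens$normalized >= pmin(prof$normalized, p2$normalized)))
  bad <- gpensemble:::new_effects(c("a", "x", "c"), 1:3, "RF", "impurity")
  expect_error(ensemble_effects(list(prof, bad)), "marker sets differ")

  map <- data.frame(marker = paste0("m", 1:10), chrom = "chr1",
                    cM = 1:10, bp = (1:10) * 1e4)
  class(map) <- c("gp_map", "data.frame")
  pr10 <- gpensemble:::new_effects(paste0("m", 1:10), seq(0.1, 1, 0.1),
                                   "MLP", "shapley")
  trk <- quantile_bin_track(pr10, map)
  expect_equal(sort(trk$level), 1:10)             # 10 distinct -> one per level
  expect_equal(trk$level[which.max(trk$normalized)], 10)
  cst <- gpensemble:::new_effects(paste0("m", 1:10), rep(0.4, 10), "RF",
                                  "impurity")
  cst$normalized <- rep(0.4, 10)
  expect_true(all(quantile_bin_track(cst, map)$level == 1))  # ties share low
  # sort-based decile oracle
  set.seed(96)
  vr <- runif(50)
  prr <- gpensemble:::new_effects(paste0("m", 1:50), vr, "RF", "impurity")
  map50 <- data.frame(marker = paste0("m", 1:50), chrom = "chr1",
                      cM = 1:50, bp = (1:50) * 1e4)
  class(map50) <- c("gp_map", "data.frame")
  lv <- quantile_bin_track(prr, map50)$level
  oracle <- ceiling(10 * match(prr$normalized, sort(prr$normalized)) / 50)
  expect_equal(lv, as.integer(oracle))
})
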