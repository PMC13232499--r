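# Per-model marker-effect inference, Shapley attribution, pairwise
# interaction scores, normalisation, ensemble combination and genome tracks.

new_effects <- function(marker, raw, model_id, method) {
  out <- data.frame(marker = marker, raw = as.numeric(raw),
                    stringsAsFactors = FALSE)
  out$normalized <- if (max(abs(out$raw)) > 0)
    abs(out$raw) / max(abs(out$raw)) else rep(0, nrow(out))
  attr(out, "model_id") <- model_id
  attr(out, "method") <- method
  class(out) <- c("gp_effects", "data.frame")
  out
}

#' Allele substitution effects from a linear fit (rrBLUP / BayesB)
#'
#' The raw effect is the posterior-mean regression coefficient of each
#' marker; fixed-effect (environment) columns are not marker effects and are
#' excluded.
#'
#' @param model a fitted `gp_rrblup` or `gp_bayesb`.
#' @return a `gp_effects` profile (marker, raw, normalized).
#' @export
effects_linear <- function(model) {
  if (!inherits(model, "gp_linear")) stopf("needs an rrBLUP or BayesB fit")
  new_effects(model$markers, model$beta[model$markers], model$model_id,
              "allele_substitution")
}

#' Impurity-based feature importance from a random forest
#'
#' Per-marker sum of weighted impurity (variance) decreases over all nodes
#' splitting on that marker, averaged over trees; features never split on
#' score zero.
#'
#' @param model a fitted `gp_rf`.
#' @return a `gp_effects` profile.
#' @export
effects_impurity <- function(model) {
  if (!inherits(model, "gp_rf")) stopf("needs a random-forest fit")
  new_effects(model$markers, model$importance[model$markers],
              model$model_id, "impurity")
}

# Build the batched state matrix for one explained sample and return the
# per-permutation telescoping contributions.
shapley_one_sample <- function(predict_fun, x, F_row, X_bg, orders, bg_rows) {
  p <- length(x)
  n_perm <- nrow(orders)
  states <- matrix(0, n_perm * (p + 1), p)
  row <- 1L
  for (k in seq_len(n_perm)) {
    z <- X_bg[bg_rows[k], ]
    states[row, ] <- z; row <- row + 1L
    for (j in orders[k, ]) {
      z[j] <- x[j]
      states[row, ] <- z; row <- row + 1L
    }
  }
  colnames(states) <- names(x)
  preds <- predict_fun(states, F_row)
  phi <- numeric(p)
  base <- numeric(n_perm)
  idx <- 0L
  for (k in seq_len(n_perm)) {
    seg <- preds[(idx + 1):(idx + p + 1)]
    phi[orders[k, ]] <- phi[orders[k, ]] + diff(seg)
    base[k] <- seg[1]
    idx <- idx + p + 1L
  }
  list(phi = phi / n_perm, fx = preds[idx], baseline = mean(base))
}

#' Shapley marker effects by seeded permutation sampling
#'
#' Interventional Shapley values: absent markers take values from a
#' background set; contributions are accumulated along sampled marker
#' orderings (telescoping, so the efficiency identity
#' `sum(phi) = f(x) - mean f(background)` holds exactly for the background
#' rows used).  The per-marker effect is the mean absolute Shapley value over
#' the explanation set.  Any fitted model with a `predict` method can be
#' explained; environment columns are held fixed at each explained sample's
#' own values.
#'
#' @param model a fitted `gp_model` (intended for RKHS / SVR / MLP).
#' @param X_explain matrix of samples to explain.
#' @param X_background background genotype matrix (non-empty).
#' @param F_explain optional fixed-effect rows aligned to `X_explain`.
#' @param n_permutations sampled orderings per explained sample (with
#'   `exact = TRUE`, all `p!` orderings are enumerated instead).
#' @param seed integer seed.
#' @param exact enumerate all orderings x all background rows (small p only).
#' @return a `gp_effects` profile; attributes `phi` (sample x marker Shapley
#'   matrix), `fx`, `baseline` per sample.
#' @export
shapley_effects <- function(model, X_explain, X_background, F_explain = NULL,
                            n_permutations = 20, seed = 1, exact = FALSE) {
  if (is.null(X_background) || nrow(X_background) == 0)
    stopf("background set must be non-empty")
  p <- ncol(X_explain)
  markers <- colnames(X_explain)
  predict_fun <- function(states, F_row) {
    Fm <- if (is.null(F_row)) NULL else
      matrix(rep(F_row, each = nrow(states)), nrow(states),
             dimnames = list(NULL, names(F_row)))
    predict(model, states, Fm)
  }
  orders_list <- NULL
  if (exact) {
    if (p > 7) stopf("exact enumeration only for p <= 7")
    perms <- all_permutations(p)
    orders_list <- perms[rep(seq_len(nrow(perms)), each = nrow(X_background)), ,
                         drop = FALSE]
    bg_rows <- rep(seq_len(nrow(X_background)), times = nrow(perms))
  }
  phi <- matrix(0, nrow(X_explain), p, dimnames = list(NULL, markers))
  fx <- numeric(nrow(X_explain)); baseline <- numeric(nrow(X_explain))
  with_seed(seed, {
    for (s in seq_len(nrow(X_explain))) {
      if (exact) {
        orders <- orders_list
        bgr <- bg_rows
      } else {
        orders <- t(vapply(seq_len(n_permutations), function(k) sample.int(p),
                           integer(p)))
        bgr <- rep_len(seq_len(nrow(X_background)), n_permutations)
      }
      F_row <- if (is.null(F_explain)) NULL else F_explain[s, ]
      res <- shapley_one_sample(predict_fun, X_explain[s, ], F_row,
                                X_background, orders, bgr)
      phi[s, ] <- res$phi
      fx[s] <- res$fx
      baseline[s] <- res$baseline
    }
  })
  out <- new_effects(markers, colMeans(abs(phi)), model$model_id, "shapley")
  attr(out, "phi") <- phi
  attr(out, "fx") <- fx
  attr(out, "baseline") <- baseline
  out
}

all_permutations <- function(p) {
  if (p == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(p - 1)
  out <- matrix(0L, 0, p)
  for (pos in seq_len(p)) {
    block <- cbind(sub[, seq_len(pos - 1), drop = FALSE], p,
                   sub[, seq(pos, p - 1)[seq_len(p - pos)], drop = FALSE])
    out <- rbind(out, block)
  }
  out
}

#' Pairwise Shapley interaction scores from a random forest
#'
#' Shapley interaction index estimated by its exact sampling scheme: for a
#' pair (i, j) the conditioning set size is uniform on 0..p-2 and the set is
#' drawn uniformly at that size, with absent markers taking background
#' values; the sampled quantity is the second difference
#' `f(S+ij) - f(S+i) - f(S+j) + f(S)`.  The per-pair score is the mean
#' absolute interaction value over the explanation set; scores are symmetric
#' by construction.  The selected set is the top `top_fraction` of all
#' `p(p-1)/2` pairs by |score| (`ceiling(top_fraction * n_pairs)` pairs).
#'
#' @param model a fitted `gp_rf` (any `gp_model` works).
#' @param X_explain explanation samples (also used as background).
#' @param F_explain optional fixed-effect rows aligned to `X_explain`, held
#'   fixed at each explained sample's own values.
#' @param map optional `gp_map` to flag within/between-chromosome pairs.
#' @param n_draws sampled conditioning sets per (sample, pair).
#' @param top_fraction selection quantile (default 1e-4, the top 0.01%).
#' @param seed integer seed.
#' @return data.frame (marker_i, marker_j, score, within_chromosome) of the
#'   selected pairs, ordered by decreasing score; the full symmetric score
#'   matrix is in attribute `score_matrix`.
#' @export
pairwise_shapley_rf <- function(model, X_explain, F_explain = NULL,
                                map = NULL, n_draws = 10,
                                top_fraction = 1e-4, seed = 1) {
  p <- ncol(X_explain)
  if (p < 2) stopf("need at least 2 markers")
  markers <- colnames(X_explain)
  n_ex <- nrow(X_explain)
  pairs <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  acc <- matrix(0, n_ex, nrow(pairs))
  with_seed(seed, {
    for (s in seq_len(n_ex)) {
      x <- X_explain[s, ]
      states <- matrix(0, nrow(pairs) * n_draws * 4, p,
                       dimnames = list(NULL, markers))
      row <- 1L
      for (d in seq_len(n_draws)) {
        bg <- X_explain[sample.int(n_ex, 1), ]
        for (q in seq_len(nrow(pairs))) {
          i <- pairs[q, 1]; j <- pairs[q, 2]
          others <- setdiff(seq_len(p), c(i, j))
          ssize <- sample.int(p - 1, 1) - 1L   # uniform on 0..p-2
          S <- if (ssize > 0) others[sample.int(length(others), ssize)]
               else integer(0)
          z <- bg
          z[S] <- x[S]
          z00 <- z
          z10 <- z; z10[i] <- x[i]
          z01 <- z; z01[j] <- x[j]
          z11 <- z10; z11[j] <- x[j]
          states[row, ] <- z00; states[row + 1L, ] <- z10
          states[row + 2L, ] <- z01; states[row + 3L, ] <- z11
          row <- row + 4L
        }
      }
      Fm <- if (is.null(F_explain)) NULL else
        matrix(rep(F_explain[s, ], each = nrow(states)), nrow(states),
               dimnames = list(NULL, colnames(F_explain)))
      preds <- predict(model, states, Fm)
      k <- seq(1, length(preds), by = 4)
      delta <- preds[k + 3] - preds[k + 1] - preds[k + 2] + preds[k]
      acc[s, ] <- rowMeans(matrix(delta, nrow(pairs), n_draws))
    }
  })
  score <- colMeans(abs(acc))
  smat <- matrix(0, p, p, dimnames = list(markers, markers))
  smat[pairs] <- score
  smat <- smat + t(smat)
  n_top <- max(1L, ceiling(top_fraction * nrow(pairs)))
  ord <- order(score, decreasing = TRUE)[seq_len(n_top)]
  out <- data.frame(marker_i = markers[pairs[ord, 1]],
                    marker_j = markers[pairs[ord, 2]],
                    score = score[ord], stringsAsFactors = FALSE)
  out$within_chromosome <- if (!is.null(map)) {
    chr <- setNames(map$chrom, map$marker)
    chr[out$marker_i] == chr[out$marker_j]
  } else NA
  rownames(out) <- NULL
  attr(out, "score_matrix") <- smat
  out
}

#' Re-normalise a marker-effect profile
#'
#' `normalized = |raw| / max |raw|` (all-zero input stays all zero);
#' `method = "zscore"` offers |raw - mean| / sd as an alternative scaling.
#'
#' @param profile a `gp_effects`.
#' @param method `"max_abs"` (default) or `"zscore"`.
#' @export
normalize_effects <- function(profile, method = c("max_abs", "zscore")) {
  method <- match.arg(method)
  raw <- profile$raw
  profile$normalized <- if (method == "max_abs") {
    if (max(abs(raw)) > 0) abs(raw) / max(abs(raw)) else rep(0, length(raw))
  } else {
    if (sd(raw) > 0) abs(raw - mean(raw)) / sd(raw) else rep(0, length(raw))
  }
  profile
}

#' Equal-weight ensemble of normalized marker effects
#'
#' Per-marker arithmetic mean of the member profiles' normalized effects;
#' all profiles must cover the same marker set.
#'
#' @param profiles list of `gp_effects` (one per model).
#' @return a `gp_effects` with `model_id = "ensemble"`.
#' @export
ensemble_effects <- function(profiles) {
  mk <- profiles[[1]]$marker
  for (pr in profiles)
    if (!identical(pr$marker, mk)) stopf("marker sets differ across profiles")
  M <- vapply(profiles, function(pr) pr$normalized, numeric(length(mk)))
  out <- data.frame(marker = mk, raw = rowMeans(M),
                    normalized = rowMeans(M), stringsAsFactors = FALSE)
  attr(out, "model_id") <- "ensemble"
  attr(out, "method") <- "mean_normalized"
  class(out) <- c("gp_effects", "data.frame")
  out
}

#' Quantile-binned genome track of marker effects
#'
#' Markers are assigned to `n_levels` intensity levels by the empirical-CDF
#' quantile of their normalized effect (level `n_levels` = strongest); tied
#' values share the lower level, so a constant profile sits entirely in
#' level 1.
#'
#' @param profile a `gp_effects`.
#' @param map a `gp_map` covering the profile's markers.
#' @param n_levels number of levels (default 10, decile binning).
#' @return data.frame (marker, chrom, cM, model_id, normalized, level).
#' @export
quantile_bin_track <- function(profile, map, n_levels = 10) {
  pos <- match(profile$marker, map$marker)
  if (anyNA(pos)) stopf("profile markers missing from map")
  n <- nrow(profile)
  lvl <- ceiling(n_levels * rank(profile$normalized, ties.method = "min") / n)
  lvl <- pmin(pmax(lvl, 1L), n_levels)
  data.frame(marker = profile$marker, chrom = map$chrom[pos],
             cM = map$cM[pos],
             model_id = attr(profile, "model_id") %||% "model",
             normalized = profile$normalized, level = as.integer(lvl),
             stringsAsFactors = FALSE)
}
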