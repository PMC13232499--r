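# Equal-weight ensemble averaging and the Diversity Prediction Theorem
# decomposition: (Mbar - V)^2 = sum_i (Mi - V)^2 / N - sum_i (Mi - Mbar)^2 / N
# (ensemble error = mean member error - prediction diversity).

#' Equal-weight ensemble of member predictions
#'
#' @param predictions numeric matrix (test samples x models) or named list of
#'   aligned prediction vectors.
#' @return per-sample arithmetic mean of member predictions.
#' @export
ensemble_average <- function(predictions) {
  M <- as_prediction_matrix(predictions)
  rowMeans(M)
}

as_prediction_matrix <- function(predictions) {
  if (is.list(predictions) && !is.matrix(predictions)) {
    lens <- vapply(predictions, length, integer(1))
    if (length(unique(lens)) != 1)
      stopf("member predictions are not aligned to the same test set")
    predictions <- do.call(cbind, predictions)
  }
  if (!is.matrix(predictions) || ncol(predictions) < 1)
    stopf("need at least 1 model's predictions")
  predictions
}

#' Diversity Prediction Theorem decomposition for one scenario
#'
#' Computes, per test sample and as scenario means over the test set, the
#' three theorem terms: ensemble (Many-Model) error `(Mbar - V)^2`, mean
#' member error `sum (Mi - V)^2 / N`, and prediction diversity
#' `sum (Mi - Mbar)^2 / N`.  The identity term1 = term2 - term3 is asserted
#' to 1e-10 relative tolerance; the scenario-mean ensemble error equals the
#' ensemble's MSE by construction.
#'
#' @param predictions test-sample x model matrix (or aligned list) of member
#'   predictions.
#' @param observed the observed phenotypes V of the test samples.
#' @param scenario_id optional label.
#' @return list of class `gp_diversity` with `per_sample` terms, scenario
#'   `terms` (means), `n_models`, `scenario_id`.
#' @export
decompose_diversity <- function(predictions, observed, scenario_id = NA) {
  M <- as_prediction_matrix(predictions)
  if (nrow(M) != length(observed)) stopf("observed values missing for some samples")
  if (anyNA(observed)) stopf("observed values missing for some samples")
  N <- ncol(M)
  mbar <- rowMeans(M)
  term1 <- (mbar - observed)^2
  term2 <- rowMeans((M - observed)^2)
  term3 <- rowMeans((M - mbar)^2)
  scale <- pmax(abs(term2), 1e-12)
  if (any(abs(term1 - (term2 - term3)) > 1e-10 * pmax(scale, 1)))
    stopf("diversity identity violated (numerical fault)")
  structure(list(
    per_sample = data.frame(ensemble_error = term1, mean_error = term2,
                            prediction_diversity = term3),
    terms = c(ensemble_error = mean(term1), mean_error = mean(term2),
              prediction_diversity = mean(term3)),
    n_models = N, scenario_id = scenario_id), class = "gp_diversity")
}

#' Summarise theorem terms over scenarios
#'
#' For each group (e.g. trait x dataset), the scenario-level term values are
#' reduced to mean, standard error of the mean, and CV = sample sd / mean.
#' With a single scenario the CV and SE are flagged unavailable (NA); a zero
#' mean flags the CV undefined.
#'
#' @param decomps data.frame with columns `group`, `ensemble_error`,
#'   `mean_error`, `prediction_diversity` (one row per scenario), or a list
#'   of `gp_diversity` plus a `groups` vector.
#' @param groups optional grouping vector when `decomps` is a list.
#' @return data.frame (group, term, mean, se, cv, n_scenarios).
#' @export
summarize_terms <- function(decomps, groups = NULL) {
  if (is.list(decomps) && !is.data.frame(decomps)) {
    tab <- do.call(rbind, lapply(decomps, function(d)
      as.data.frame(as.list(d$terms))))
    tab$group <- groups %||% "all"
  } else tab <- decomps
  terms <- c("ensemble_error", "mean_error", "prediction_diversity")
  out <- list()
  for (g in unique(tab$group)) {
    sub <- tab[tab$group == g, , drop = FALSE]
    for (tm in terms) {
      v <- sub[[tm]]
      k <- length(v)
      m <- mean(v)
      s <- if (k >= 2) sd(v) else NA_real_
      out[[paste(g, tm)]] <- data.frame(
        group = g, term = tm, mean = m,
        se = if (k >= 2) s / sqrt(k) else NA_real_,
        cv = if (k >= 2 && m != 0) s / m else NA_real_,
        n_scenarios = k, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
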