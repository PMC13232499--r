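# Scenario grid construction, the end-to-end experiment, and performance
# summaries (medians, top-3 shares, model-group correlations).

#' Pearson correlation and mean squared error
#'
#' `pearson()` returns NA when either vector is degenerate (zero variance);
#' `mse()` is always defined.
#'
#' @param observed,predicted equal-length numeric vectors (length >= 2).
#' @export
pearson <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stopf("length mismatch")
  if (length(observed) < 2) stopf("need at least 2 values")
  if (sd(observed) == 0 || sd(predicted) == 0) return(NA_real_)
  cor(observed, predicted)
}

#' @rdname pearson
#' @export
mse <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stopf("length mismatch")
  mean((observed - predicted)^2)
}

#' Build the (population x ratio x replicate) scenario grid
#'
#' Each scenario splits a population's RILs into train/test without
#' replacement under its own derived seed (all environment records of a RIL
#' stay on one side of the split).  Scenarios whose test set would hold
#' fewer than 2 RILs are skipped with a log entry.
#'
#' @param populations named list: population id -> character vector of RIL ids.
#' @param ratios list of c(train, test) fractions.
#' @param replicates replicates per (population, ratio).
#' @param seed global seed.
#' @return list with `scenarios` (each: id, population_id, ratio, replicate,
#'   train/test RIL ids, seed) and `skipped` log.
#' @export
build_scenarios <- function(populations, ratios, replicates, seed = 1) {
  scenarios <- list(); skipped <- list()
  for (pop in names(populations)) {
    rils <- populations[[pop]]
    if (length(rils) < 10) stopf("population %s has fewer than 10 RILs", pop)
    for (ri in seq_along(ratios)) {
      ratio <- ratios[[ri]]
      n_train <- round(ratio[1] * length(rils))
      n_test <- length(rils) - n_train
      for (rep in seq_len(replicates)) {
        sid <- sprintf("%s_r%d_rep%03d", pop, ri, rep)
        if (n_test < 2) {
          skipped[[sid]] <- sprintf("test set < 2 RILs (%d)", n_test)
          next
        }
        sseed <- derive_seed(seed, pop, ri, rep, "split")
        train <- with_seed(sseed, sample(rils, n_train))
        scenarios[[sid]] <- list(id = sid, population_id = pop,
                                 ratio = ratio, ratio_index = ri,
                                 replicate = rep, train = train,
                                 test = setdiff(rils, train), seed = sseed)
      }
    }
  }
  list(scenarios = scenarios, skipped = skipped)
}

subset_design <- function(design, rils) {
  keep <- design$ril_id %in% rils
  list(X = design$X[keep, , drop = FALSE],
       F = design$F[keep, , drop = FALSE],
       y = design$y[keep], ril_id = design$ril_id[keep],
       environment = design$environment[keep])
}

#' Run the full scenario-grid experiment on one or more populations
#'
#' For every scenario: fit the requested models on the training RILs,
#' predict the test RILs, ensemble-average, score (Pearson r, MSE), and
#' decompose the ensemble error by the Diversity Prediction Theorem.
#' Marker-effect extraction (allele substitution, impurity, Shapley) is
#' optional.  A model failure marks the scenario's ensemble as failed but
#' keeps the surviving members' metrics.  With `out_dir` set, per-scenario
#' metric files make the run resumable by scenario id.
#'
#' @param designs named list: population id -> `gp_design` (from
#'   [concat_environments()]).
#' @param config a [run_config()].
#' @param profile hyperparameter profile, `"full"` or `"test"`.
#' @param dataset_preset `"teonam"` or `"maizenam"` (MLP preset).
#' @param effects also extract per-model marker effects per scenario.
#' @param shapley_config list(n_explain, n_background, n_permutations) for
#'   the Shapley-based extractions.
#' @param out_dir optional directory for incremental per-scenario caches;
#'   on a rerun, scenarios whose cache file exists are loaded instead of
#'   recomputed (resume by scenario id).
#' @return list with `predictions` (long ledger), `metrics`, `decompositions`
#'   (one row per scenario), `effects` (list by scenario), `failures`.
#' @export
run_experiment <- function(designs, config, profile = c("full", "test"),
                           dataset_preset = c("teonam", "maizenam"),
                           effects = FALSE,
                           shapley_config = list(n_explain = 20,
                                                 n_background = 20,
                                                 n_permutations = 10),
                           out_dir = NULL) {
  profile <- match.arg(profile)
  dataset_preset <- match.arg(dataset_preset)
  hp <- default_hyperparameters(dataset_preset, profile)
  for (m in names(config$hyperparameters))
    hp[[m]][names(config$hyperparameters[[m]])] <- config$hyperparameters[[m]]
  pops <- lapply(designs, function(d) unique(d$ril_id))
  grid <- build_scenarios(pops, config$ratios, config$replicates, config$seed)

  preds <- list(); metrics <- list(); decomps <- list()
  eff_out <- list(); failures <- list()
  for (sc in grid$scenarios) {
    cache <- if (!is.null(out_dir))
      file.path(out_dir, paste0(sc$id, ".rds")) else NULL
    if (!is.null(cache) && file.exists(cache)) {
      hit <- readRDS(cache)
      metrics[names(hit$metrics)] <- hit$metrics
      preds[names(hit$preds)] <- hit$preds
      decomps[names(hit$decomps)] <- hit$decomps
      eff_out[names(hit$effects)] <- hit$effects
      failures[names(hit$failures)] <- hit$failures
      next
    }
    n_before <- c(m = length(metrics), p = length(preds),
                  d = length(decomps), e = length(eff_out),
                  f = length(failures))
    design <- designs[[sc$population_id]]
    tr <- subset_design(design, sc$train)
    te <- subset_design(design, sc$test)
    member_pred <- list(); fits <- list()
    for (m in config$models) {
      mseed <- derive_seed(config$seed, sc$population_id, sc$ratio_index,
                           sc$replicate, paste0("fit_", m))
      res <- tryCatch({
        fit <- fit_model(m, tr$X, tr$y, if (ncol(tr$F)) tr$F else NULL,
                         hyper = hp[[m]], seed = mseed)
        list(fit = fit,
             pred = predict(fit, te$X, if (ncol(te$F)) te$F else NULL))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[paste(sc$id, m)]] <- conditionMessage(res)
        next
      }
      fits[[m]] <- res$fit
      member_pred[[m]] <- res$pred
      metrics[[paste(sc$id, m)]] <- data.frame(
        scenario_id = sc$id, population_id = sc$population_id,
        ratio = paste(sc$ratio, collapse = "-"), replicate = sc$replicate,
        model_id = m, pearson_r = pearson(te$y, res$pred),
        mse = mse(te$y, res$pred), stringsAsFactors = FALSE)
      preds[[paste(sc$id, m)]] <- data.frame(
        scenario_id = sc$id, model_id = m, ril_id = te$ril_id,
        environment = te$environment, observed = te$y, predicted = res$pred,
        stringsAsFactors = FALSE)
    }
    if (length(member_pred) == length(config$models)) {
      M <- do.call(cbind, member_pred)
      ens <- ensemble_average(M)
      metrics[[paste(sc$id, "ensemble")]] <- data.frame(
        scenario_id = sc$id, population_id = sc$population_id,
        ratio = paste(sc$ratio, collapse = "-"), replicate = sc$replicate,
        model_id = "ensemble", pearson_r = pearson(te$y, ens),
        mse = mse(te$y, ens), stringsAsFactors = FALSE)
      preds[[paste(sc$id, "ensemble")]] <- data.frame(
        scenario_id = sc$id, model_id = "ensemble", ril_id = te$ril_id,
        environment = te$environment, observed = te$y, predicted = ens,
        stringsAsFactors = FALSE)
      dec <- decompose_diversity(M, te$y, sc$id)
      decomps[[sc$id]] <- data.frame(
        scenario_id = sc$id, population_id = sc$population_id,
        ratio = paste(sc$ratio, collapse = "-"), replicate = sc$replicate,
        t(dec$terms), stringsAsFactors = FALSE)
    }
    if (effects && length(fits) == length(config$models)) {
      eff_out[[sc$id]] <- extract_all_effects(
        fits, tr, shapley_config,
        seed = derive_seed(config$seed, sc$population_id, sc$ratio_index,
                           sc$replicate, "shapley"))
    }
    if (!is.null(cache)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      tail_of <- function(lst, n0) lst[seq_len(length(lst)) > n0]
      saveRDS(list(metrics = tail_of(metrics, n_before["m"]),
                   preds = tail_of(preds, n_before["p"]),
                   decomps = tail_of(decomps, n_before["d"]),
                   effects = tail_of(eff_out, n_before["e"]),
                   failures = tail_of(failures, n_before["f"])),
              cache)
    }
  }
  rb <- function(lst) if (length(lst))
    do.call(rbind, c(lst, list(make.row.names = FALSE))) else NULL
  list(predictions = rb(preds), metrics = rb(metrics),
       decompositions = rb(decomps), effects = eff_out,
       failures = failures, skipped = grid$skipped)
}

# Per-scenario marker-effect profiles for all six models plus the ensemble.
extract_all_effects <- function(fits, tr, shapley_config, seed = 1) {
  n_ex <- min(shapley_config$n_explain %||% 20, nrow(tr$X))
  n_bg <- min(shapley_config$n_background %||% 20, nrow(tr$X))
  ex_ix <- with_seed(derive_seed(seed, "explain"),
                     sample(nrow(tr$X), n_ex))
  bg_ix <- with_seed(derive_seed(seed, "background"),
                     sample(nrow(tr$X), n_bg))
  Xe <- tr$X[ex_ix, , drop = FALSE]
  Fe <- if (ncol(tr$F)) tr$F[ex_ix, , drop = FALSE] else NULL
  Xb <- tr$X[bg_ix, , drop = FALSE]
  profiles <- list()
  for (m in names(fits)) {
    fit <- fits[[m]]
    profiles[[m]] <- if (inherits(fit, "gp_linear")) effects_linear(fit)
      else if (inherits(fit, "gp_rf")) effects_impurity(fit)
      else shapley_effects(fit, Xe, Xb, F_explain = Fe,
                           n_permutations = shapley_config$n_permutations %||% 10,
                           seed = derive_seed(seed, "phi", m))
  }
  profiles$ensemble <- ensemble_effects(profiles)
  profiles
}

#' Group medians of the performance metrics
#'
#' @param metrics the metric table from [run_experiment()].
#' @param by grouping columns (default model within population).
#' @return data.frame of group medians for Pearson r (degenerate NA values
#'   excluded, with counts) and MSE.
#' @export
summarize_performance <- function(metrics, by = c("model_id", "population_id")) {
  groups <- split(metrics, metrics[by], drop = TRUE)
  out <- lapply(groups, function(g) {
    r <- g$pearson_r[!is.na(g$pearson_r)]
    cbind(g[1, by, drop = FALSE],
          data.frame(median_r = if (length(r)) median(r) else NA_real_,
                     median_mse = median(g$mse), n = nrow(g),
                     n_r_missing = sum(is.na(g$pearson_r))))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Share of groups in which each model ranks top-3
#'
#' Within each group (e.g. trait x population), models are ranked by median
#' Pearson r (descending) and by median MSE (ascending) with competition
#' ("1224") ranking, so all models tied at rank 3 count.  The share is the
#' percentage of groups in which the model's rank is <= 3.
#'
#' @param medians data.frame with columns `model_id`, `group`, `median_r`,
#'   `median_mse`.
#' @return data.frame (model_id, top3_pearson_pct, top3_mse_pct, n_groups).
#' @export
top3_share <- function(medians) {
  if (length(unique(medians$model_id)) < 2) stopf("need at least 2 models")
  comp_rank <- function(x) rank(x, ties.method = "min")
  groups <- split(medians, medians$group)
  models <- unique(medians$model_id)
  hit_r <- hit_m <- setNames(numeric(length(models)), models)
  for (g in groups) {
    rr <- comp_rank(-g$median_r)
    rm <- comp_rank(g$median_mse)
    hit_r[g$model_id[rr <= 3]] <- hit_r[g$model_id[rr <= 3]] + 1
    hit_m[g$model_id[rm <= 3]] <- hit_m[g$model_id[rm <= 3]] + 1
  }
  data.frame(model_id = models,
             top3_pearson_pct = 100 * hit_r[models] / length(groups),
             top3_mse_pct = 100 * hit_m[models] / length(groups),
             n_groups = length(groups), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Correlation between model groups at the phenotype and effect level
#'
#' Conventional (rrBLUP, BayesB, RKHS) vs machine-learning (RF, SVR, MLP)
#' groups: per test record the group's mean predicted phenotype, per marker
#' the group's mean normalized effect, then the Pearson correlation between
#' the two group means across records / markers.
#'
#' @param predictions prediction ledger from [run_experiment()].
#' @param effect_profiles optional list (by scenario) of per-model
#'   `gp_effects`, as produced with `effects = TRUE`.
#' @return list with `phenotype_r` and (if profiles given) `effect_r`.
#' @export
group_correlation <- function(predictions, effect_profiles = NULL) {
  predictions <- predictions[predictions$model_id %in% names(MODEL_GROUPS), ]
  predictions$group <- MODEL_GROUPS[predictions$model_id]
  key <- paste(predictions$scenario_id, predictions$ril_id,
               predictions$environment)
  mean_by <- function(sub) tapply(sub$predicted, key[as.numeric(rownames(sub))],
                                  mean)
  rownames(predictions) <- seq_len(nrow(predictions))
  conv <- predictions[predictions$group == "conventional", ]
  ml <- predictions[predictions$group == "machine_learning", ]
  mc <- mean_by(conv); mm <- mean_by(ml)
  common <- intersect(names(mc), names(mm))
  out <- list(phenotype_r = cor(mc[common], mm[common]))
  if (!is.null(effect_profiles)) {
    pull <- function(group) {
      vals <- lapply(effect_profiles, function(prof) {
        ms <- names(MODEL_GROUPS)[MODEL_GROUPS == group]
        ms <- intersect(ms, names(prof))
        rowMeans(vapply(prof[ms], function(p) p$normalized,
                        numeric(nrow(prof[[1]]))))
      })
      unlist(vals)
    }
    out$effect_r <- cor(pull("conventional"), pull("machine_learning"))
  }
  out
}
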