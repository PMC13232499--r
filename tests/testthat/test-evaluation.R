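# Scenario grid, metrics, grid-level summaries and the end-to-end runner.

test_that("scenario grids have the printed sizes and honour the split contract", {
  pops5 <- setNames(lapply(1:5, function(i) sprintf("p%d_r%03d", i, 1:500)),
                    paste0("p", 1:5))
  g <- build_scenarios(pops5, list(c(0.8, 0.2), c(0.65, 0.35), c(0.5, 0.5)),
                       replicates = 500, seed = 3)
  expect_length(g$scenarios, 7500)            # 5 populations x 3 ratios x 500

  pops25 <- setNames(lapply(1:25, function(i) sprintf("q%d_r%03d", i, 1:150)),
                     paste0("q", 1:25))
  g2 <- build_scenarios(pops25, list(c(0.8, 0.2), c(0.65, 0.35), c(0.5, 0.5)),
                        replicates = 50, seed = 3)
  expect_length(g2$scenarios, 3750)           # 25 populations x 3 ratios x 50

  one <- build_scenarios(pops5[1], list(c(0.5, 0.5)), 1, seed = 4)
  expect_length(one$scenarios, 1)
  sc <- one$scenarios[[1]]
  expect_length(intersect(sc$train, sc$test), 0)
  expect_setequal(c(sc$train, sc$test), pops5[[1]])
  expect_equal(length(sc$train), 250)

  # too-small test sets are skipped with a log entry
  tiny <- list(pp = sprintf("x%02d", 1:12))
  gs <- build_scenarios(tiny, list(c(0.95, 0.05)), 2, seed = 5)
  expect_length(gs$scenarios, 0)
  expect_length(gs$skipped, 2)
  expect_error(build_scenarios(list(p = letters[1:5]), list(c(0.5, 0.5)), 1),
               "fewer than 10")
  # same seed, same splits
  g3 <- build_scenarios(pops5[1:2], list(c(0.8, 0.2)), 3, seed = 6)
  g4 <- build_scenarios(pops5[1:2], list(c(0.8, 0.2)), 3, seed = 6)
  expect_identical(lapply(g3$scenarios, `[[`, "train"),
                   lapply(g4$scenarios, `[[`, "train"))
})

test_that("pearson and mse follow their definitions including degenerate input", {
  expect_equal(pearson(1:5, 1:5), 1)
  x <- c(-2, -1, 0, 1, 2)
  expect_equal(pearson(x, -x), -1)
  expect_equal(mse(c(1, 2, 3), c(2, 2, 2)), 2 / 3)
  expect_true(is.na(pearson(c(1, 2, 3), c(2, 2, 2))))   # zero-variance
  expect_equal(mse(1:4, 1:4), 0)
  expect_error(pearson(1:3, 1:4), "length mismatch")
  expect_error(mse(1:3, 1:4), "length mismatch")
})

test_that("performance medians and top-3 shares use competition ranking", {
  set.seed(7)
  met <- data.frame(model_id = rep(c("A", "B"), each = 5),
                    population_id = "p1",
                    pearson_r = c(0.2, 0.4, 0.9, NA, 0.3, rep(0.1, 5)),
                    mse = c(1:5, 6:10))
  s <- summarize_performance(met)
  expect_equal(s$median_r[s$model_id == "A"], 0.35)   # NA excluded
  expect_equal(s$n_r_missing[s$model_id == "A"], 1)
  expect_equal(s$median_mse[s$model_id == "B"], 8)
  # sort-based oracle on a random table
  r <- rnorm(11)
  met2 <- data.frame(model_id = "A", population_id = "p", pearson_r = r,
                     mse = abs(r))
  expect_equal(summarize_performance(met2)$median_r, sort(r)[6])

  # 7 models, 60 groups, model in top 3 of 47 -> 78.3%
  meds <- do.call(rbind, lapply(1:60, function(g) {
    base <- data.frame(model_id = paste0("M", 1:7), group = g,
                       median_r = 7:1 / 10, median_mse = 1:7)
    if (g <= 47) base$median_r[7] <- 0.65    # M7 into top 3
    else base$median_r[7] <- 0.05
    base
  }))
  t3 <- top3_share(meds)
  expect_equal(round(t3$top3_pearson_pct[t3$model_id == "M7"], 1), 78.3)
  best <- data.frame(model_id = rep(c("A", "B", "C", "D"), 5),
                     group = rep(1:5, each = 4),
                     median_r = rep(c(0.9, 0.5, 0.4, 0.3), 5),
                     median_mse = rep(1:4, 5))
  expect_equal(top3_share(best)$top3_pearson_pct[1], 100)   # best everywhere
  # three-way tie at rank 3 counts all tied models
  tie <- data.frame(model_id = c("A", "B", "C", "D", "E"), group = 1,
                    median_r = c(0.9, 0.8, 0.5, 0.5, 0.5),
                    median_mse = c(1, 2, 3, 3, 3))
  tt <- top3_share(tie)
  expect_equal(tt$top3_pearson_pct, rep(100, 5))
  expect_error(top3_share(tie[1, ]), "2 models")
})

test_that("run_experiment produces aligned ledgers, is deterministic, and flags failures", {
  dat <- simulate_nam_dataset("teonam", seed = 110, n_populations = 1,
                              n_rils_range = c(60, 60),
                              markers_per_chromosome = 6)
  fs <- filter_samples(dat$panels[[1]], dat$phenotypes, "DTA")
  pr <- ld_prune(impute_flanking(fs$panel))
  designs <- setNames(list(concat_environments(pr$panel, fs$phenotypes, "DTA")),
                      names(dat$panels))
  cfg <- run_config(ratios = list(c(0.8, 0.2)), replicates = 2, seed = 111,
                    hyperparameters = list(
                      rrBLUP = list(n_iter = 400, burn_in = 100),
                      BayesB = list(n_iter = 400, burn_in = 100),
                      RKHS = list(n_iter = 400, burn_in = 100),
                      RF = list(n_trees = 40), MLP = list(epochs = 20)))
  res <- run_experiment(designs, cfg, profile = "test",
                        dataset_preset = "teonam")
  # 2 scenarios x (6 members + ensemble)
  expect_equal(nrow(res$metrics), 14)
  expect_equal(nrow(res$decompositions), 2)
  expect_equal(sum(res$metrics$model_id == "ensemble"), 2)
  # per-scenario ensemble MSE equals term 1 of the decomposition
  ens <- res$metrics[res$metrics$model_id == "ensemble", ]
  expect_equal(ens$mse[order(ens$scenario_id)],
               res$decompositions$ensemble_error[
                 order(res$decompositions$scenario_id)],
               tolerance = 1e-12)
  # reruns with the same config are identical
  res2 <- run_experiment(designs, cfg, profile = "test",
                         dataset_preset = "teonam")
  expect_identical(res$predictions, res2$predictions)
  expect_identical(res$metrics, res2$metrics)

  # per-scenario caches make the run resumable by scenario id
  cdir <- tempfile("cache")
  r1 <- run_experiment(designs, cfg, profile = "test",
                       dataset_preset = "teonam", out_dir = cdir)
  expect_length(list.files(cdir, "\\.rds$"), 2)
  r2 <- run_experiment(designs, cfg, profile = "test",
                       dataset_preset = "teonam", out_dir = cdir)
  expect_identical(r1$metrics, r2$metrics)
  expect_identical(r1$predictions, r2$predictions)

  # a failing model downgrades the scenario but keeps surviving members
  cfg_bad <- cfg
  cfg_bad$models <- c("rrBLUP", "nosuch")
  res3 <- run_experiment(designs, cfg_bad, profile = "test",
                         dataset_preset = "teonam")
  expect_length(res3$failures, 2)
  expect_true(all(res3$metrics$model_id == "rrBLUP"))
  expect_equal(nrow(res3$decompositions %||% data.frame()), 0)
})

test_that("group correlations equal brute-force per-record averaging", {
  set.seed(112)
  led <- expand.grid(scenario_id = "s1", model_id = names(gpensemble:::MODEL_GROUPS),
                     ril_id = paste0("r", 1:30), stringsAsFactors = FALSE)
  led$environment <- "e1"
  led$observed <- rep(rnorm(30), each = 1)
  led$predicted <- rnorm(nrow(led))
  gc <- group_correlation(led)
  conv <- c("rrBLUP", "BayesB", "RKHS")
  mc <- tapply(led$predicted[led$model_id %in% conv],
               led$ril_id[led$model_id %in% conv], mean)
  mm <- tapply(led$predicted[!led$model_id %in% conv],
               led$ril_id[!led$model_id %in% conv], mean)
  expect_equal(gc$phenotype_r, cor(mc[names(mc)], mm[names(mc)]))
  # identical groups correlate exactly 1
  led2 <- led
  led2$predicted <- rep(rnorm(30), each = 6)   # model varies fastest per RIL
  expect_equal(group_correlation(led2)$phenotype_r, 1)
  # independent effect vectors of length 1000 are near-uncorrelated
  mk <- paste0("m", 1:1000)
  prof <- lapply(names(gpensemble:::MODEL_GROUPS), function(m)
    gpensemble:::new_effects(mk, abs(rnorm(1000)), m, "shapley"))
  names(prof) <- names(gpensemble:::MODEL_GROUPS)
  gc2 <- group_correlation(led, list(s1 = prof))
  expect_lt(abs(gc2$effect_r), 0.12)
})
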