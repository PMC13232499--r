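#!/usr/bin/env Rscript
# Genome-level view: fit all six models once per dataset on the largest
# population, extract normalized marker effects per model (allele
# substitution / impurity / Shapley), combine them into the ensemble
# profile, bin into decile tracks, and score pairwise RF interactions
# (top links exported for circos-style plotting).

library(gpensemble)

ind <- "results/preprocessed"
out <- "results/effects"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 2026

for (preset in c("teonam", "maizenam")) {
  pheno <- read_phenotypes(file.path(ind, sprintf("%s_phenotypes.tsv", preset)))
  maps <- list.files(ind, sprintf("^%s_.*_map.tsv$", preset), full.names = TRUE)
  sizes <- vapply(maps, function(mf) {
    nrow(read.table(sub("_map.tsv$", "_geno.tsv", mf), sep = "\t",
                    header = TRUE, nrows = 2000))
  }, numeric(1))
  mf <- maps[which.max(sizes)]
  pop <- sub("_map.tsv$", "", sub(sprintf("^%s_", preset), "", basename(mf)))
  pan <- read_genotypes(sub("_map.tsv$", "_geno.tsv", mf), mf,
                        population_id = pop)
  d <- concat_environments(pan, pheno, "DTA")
  hp <- default_hyperparameters(preset, "test")
  Fm <- if (ncol(d$F)) d$F else NULL
  fits <- list()
  for (m in c("rrBLUP", "BayesB", "RKHS", "RF", "SVR", "MLP"))
    fits[[m]] <- fit_model(m, d$X, d$y, Fm, hyper = hp[[m]],
                           seed = derive_seed(seed, preset, m, "effects"))
  prof <- gpensemble:::extract_all_effects(
    fits, list(X = d$X, F = d$F, y = d$y),
    shapley_config = list(n_explain = 25, n_background = 25,
                          n_permutations = 8),
    seed = derive_seed(seed, preset, "shapley"))
  tracks <- do.call(rbind, lapply(prof, quantile_bin_track, map = pan$map))
  rownames(tracks) <- NULL
  write.table(tracks, file.path(out, sprintf("%s_effect_tracks.tsv", preset)),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # interaction scan restricted to the strongest ensemble markers (the
  # quadratic pair cost makes a genome-wide scan a cluster job, and the
  # exported links highlight the strongest regions regardless)
  top_mk <- prof$ensemble$marker[order(-prof$ensemble$normalized)][1:60]
  top_mk <- top_mk[order(match(top_mk, pan$map$marker))]
  ex <- seq_len(min(15, nrow(d$X)))
  frf_top <- fit_rf(d$X[, top_mk], d$y,
                    if (ncol(d$F)) d$F else NULL,
                    n_trees = hp$RF$n_trees,
                    seed = derive_seed(seed, preset, "rf_top"))
  links <- pairwise_shapley_rf(frf_top, d$X[ex, top_mk],
                               F_explain = if (ncol(d$F))
                                 d$F[ex, , drop = FALSE] else NULL,
                               map = pan$map, n_draws = 6,
                               top_fraction = 0.005,
                               seed = derive_seed(seed, preset, "pairs"))
  i1 <- match(links$marker_i, pan$map$marker)
  i2 <- match(links$marker_j, pan$map$marker)
  link_tab <- data.frame(chrom_i = pan$map$chrom[i1], cM_i = pan$map$cM[i1],
                         chrom_j = pan$map$chrom[i2], cM_j = pan$map$cM[i2],
                         score = links$score,
                         within_chromosome = links$within_chromosome)
  write.table(link_tab, file.path(out, sprintf("%s_interaction_links.tsv",
                                               preset)),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # overlap of the ensemble's strongest decile with the true QTL regions
  qtl <- read_annotation(file.path("results/data",
                                   sprintf("%s_true_qtl.bed", preset)))
  top <- tracks[tracks$model_id == "ensemble" & tracks$level >= 9, ]
  hit <- mapply(function(cc, cm) any(qtl$chrom == cc & qtl$start_cM <= cm &
                                       qtl$end_cM >= cm),
                top$chrom, top$cM)
  message(sprintf("%s: %d/%d top-decile ensemble markers fall in true QTL windows",
                  preset, sum(hit), nrow(top)))
}
message("wrote ", out)
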