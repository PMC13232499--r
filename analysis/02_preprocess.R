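#!/usr/bin/env Rscript
# Preprocessing chain on the simulated panels: flanking-marker imputation,
# whole-chromosome / phenotype sample filters, windowed LD pruning.  Writes
# the processed panels, kept-marker lists and removal logs.

library(gpensemble)

ind <- "results/data"
out <- "results/preprocessed"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

for (preset in c("teonam", "maizenam")) {
  pheno <- read_phenotypes(file.path(ind, sprintf("%s_phenotypes.tsv", preset)))
  geno_files <- list.files(ind, sprintf("^%s_.*_geno.tsv$", preset),
                           full.names = TRUE)
  removed_all <- list(); kept_tab <- list()
  for (gf in geno_files) {
    pop <- sub("_geno.tsv$", "", sub(sprintf("^%s_", preset), "", basename(gf)))
    pan <- read_genotypes(gf, file.path(ind, sprintf("%s_map.tsv", preset)),
                          population_id = pop)
    fs <- filter_samples(pan, pheno)
    imp <- impute_flanking(fs$panel)
    pr <- ld_prune(imp)     # r2 >= 0.8, 30-kb window, 5-SNP step
    write_genotypes(pr$panel,
                    file.path(out, sprintf("%s_%s_geno.tsv", preset, pop)),
                    file.path(out, sprintf("%s_%s_map.tsv", preset, pop)))
    removed_all[[pop]] <- if (nrow(fs$removed))
      cbind(population_id = pop, fs$removed) else NULL
    kept_tab[[pop]] <- data.frame(population_id = pop, marker = pr$kept,
                                  stringsAsFactors = FALSE)
    message(sprintf("%s/%s: %d -> %d RILs, %d -> %d markers (%d monomorphic flagged)",
                    preset, pop, nrow(pan$geno), nrow(pr$panel$geno),
                    ncol(pan$geno), length(pr$kept), length(pr$monomorphic)))
  }
  write.table(do.call(rbind, removed_all),
              file.path(out, sprintf("%s_removed_samples.tsv", preset)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(do.call(rbind, kept_tab),
              file.path(out, sprintf("%s_kept_markers.tsv", preset)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_phenotypes(pheno, file.path(out, sprintf("%s_phenotypes.tsv", preset)))
}
message("wrote ", out)
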