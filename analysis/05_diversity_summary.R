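#!/usr/bin/env Rscript
# Aggregate the experiment: per-model performance medians, top-3 shares
# across trait-by-population groups, the three diversity terms with mean/SE/
# CV per trait x dataset, and the conventional-vs-ML group correlation of
# predicted phenotypes.

library(gpensemble)

ind <- "results/experiment"
out <- "results/summary"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

metric_files <- list.files(ind, "_metrics.tsv$", full.names = TRUE)
med_rows <- list(); term_rows <- list(); gc_rows <- list()
for (mf in metric_files) {
  tag <- sub("_metrics.tsv$", "", basename(mf))
  preset <- sub("_(DTA|ASI)$", "", tag)
  trait <- sub("^.*_", "", tag)
  met <- read.table(mf, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  med <- summarize_performance(met)
  med$group <- paste(trait, med$population_id)
  med$dataset <- preset; med$trait <- trait
  med_rows[[tag]] <- med
  div <- read.table(file.path(ind, paste0(tag, "_diversity_terms.tsv")),
                    sep = "\t", header = TRUE)
  div$group <- paste(preset, trait)
  term_rows[[tag]] <- summarize_terms(div)
  led <- read.table(file.path(ind, paste0(tag, "_predictions.tsv")),
                    sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  gc_rows[[tag]] <- data.frame(dataset = preset, trait = trait,
                               phenotype_r = group_correlation(led)$phenotype_r)
}
medians <- do.call(rbind, med_rows); rownames(medians) <- NULL
write.table(medians, file.path(out, "performance_medians.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

top3 <- top3_share(medians)
write.table(top3, file.path(out, "top3_share.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("top-3 share by Pearson accuracy (% of trait-by-population groups):")
print(top3[order(-top3$top3_pearson_pct), ], row.names = FALSE)

terms <- do.call(rbind, term_rows); rownames(terms) <- NULL
write.table(terms, file.path(out, "diversity_terms_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("diversity terms (mean +- SE, CV) per trait x dataset:")
print(terms, row.names = FALSE, digits = 3)

gc_tab <- do.call(rbind, gc_rows); rownames(gc_tab) <- NULL
write.table(gc_tab, file.path(out, "group_correlations.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("conventional vs machine-learning mean-prediction correlations:")
print(gc_tab, row.names = FALSE, digits = 3)
message("wrote ", out)
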