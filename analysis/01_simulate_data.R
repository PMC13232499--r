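#!/usr/bin/env Rscript
# Generate the two synthetic NAM worlds (teosinte-NAM-like and
# maize-NAM-like presets) at desk scale and write every table to disk in the
# pipeline's plain-text formats.  Downstream steps only read these files.

library(gpensemble)

seed <- 2026
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

for (preset in c("teonam", "maizenam")) {
  # desk scale: fewer/smaller populations than the full presets; structure
  # (cross scheme, environments, marker density, phenotype kind) unchanged
  dat <- simulate_nam_dataset(preset, seed = seed,
                              n_populations = if (preset == "teonam") 3 else 5,
                              n_rils_range = if (preset == "teonam")
                                c(240, 280) else NULL)
  for (pop in names(dat$panels)) {
    pan <- inject_missingness(dat$panels[[pop]], rate = 0.03,
                              block_rate = 0.01,
                              seed = derive_seed(seed, preset, pop, "miss"))
    write_genotypes(pan,
                    file.path(out, sprintf("%s_%s_geno.tsv", preset, pop)),
                    file.path(out, sprintf("%s_map.tsv", preset)))
  }
  write_phenotypes(dat$phenotypes,
                   file.path(out, sprintf("%s_phenotypes.tsv", preset)))
  arch <- lapply(dat$architectures, function(a)
    list(trait = a$trait, h2_additive = a$h2_additive,
         h2_epistatic = a$h2_epistatic, additive = a$additive,
         epistatic = a$epistatic, env_effects = as.list(a$env_effects)))
  jsonlite::write_json(arch, file.path(out, sprintf("%s_architecture.json",
                                                    preset)),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  # the true QTL regions double as an annotation track for step 06
  map <- dat$map
  qtl <- do.call(rbind, lapply(dat$architectures, function(a) {
    i <- match(a$additive$marker, map$marker)
    data.frame(chrom = map$chrom[i], start_cM = pmax(0, map$cM[i] - 2),
               end_cM = map$cM[i] + 2,
               label = paste0(a$trait, "_", a$additive$marker),
               category = "QTL_source1", stringsAsFactors = FALSE)
  }))
  write_annotation(qtl, file.path(out, sprintf("%s_true_qtl.bed", preset)))
  message(sprintf("%s: %d populations, %d markers, %d phenotype records",
                  preset, length(dat$panels), nrow(dat$map),
                  nrow(dat$phenotypes)))
}
message("wrote ", out)
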