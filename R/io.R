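# On-disk formats: genotype TSV + PLINK-MAP-style map, long phenotype TSV,
# BED-like annotation track (cM coordinates), JSON run configuration.

MISSING_TOKENS <- c("NA", "-", "", ".", "NaN")
ANNOTATION_CATEGORIES <- c("QTL_source1", "QTL_source2", "SAM", "leaf", "other")

#' Write / read a genotype panel
#'
#' Genotypes are a TSV with `ril_id` plus one column per marker (values 0/1/2,
#' missing written as `NA`); the map is 4-column PLINK-MAP-style text
#' (chromosome, marker id, cM, bp) without header.
#'
#' @param panel a `gp_panel`.
#' @param geno_path,map_path file paths.
#' @export
write_genotypes <- function(panel, geno_path, map_path) {
  tab <- data.frame(ril_id = panel$ril_ids, panel$geno, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(tab, geno_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(panel$map[, c("chrom", "marker", "cM", "bp")], map_path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(c(geno_path, map_path))
}

#' @rdname write_genotypes
#' @param population_id label for the panel read back.
#' @export
read_genotypes <- function(geno_path, map_path, population_id = "pop1") {
  for (f in c(geno_path, map_path))
    if (!file.exists(f)) stopf("file not found: %s", f)
  map <- read.table(map_path, sep = "\t", header = FALSE,
                    col.names = c("chrom", "marker", "cM", "bp"),
                    stringsAsFactors = FALSE)
  map <- map[, c("marker", "chrom", "cM", "bp")]
  class(map) <- c("gp_map", "data.frame")
  validate_map(map)
  tab <- read.table(geno_path, sep = "\t", header = TRUE, check.names = FALSE,
                    colClasses = "character")
  if (names(tab)[1] != "ril_id") stopf("genotype file must start with ril_id")
  mk <- names(tab)[-1]
  unknown <- setdiff(mk, map$marker)
  if (length(unknown))
    stopf("marker(s) absent from map: %s", paste(head(unknown, 3), collapse = ", "))
  if (length(mk) != nrow(map))
    stopf("genotype file has %d markers but map has %d", length(mk), nrow(map))
  raw <- as.matrix(tab[, -1, drop = FALSE])
  raw[raw %in% MISSING_TOKENS] <- NA_character_
  bad <- which(!is.na(raw) & !(raw %in% c("0", "1", "2")), arr.ind = TRUE)
  if (nrow(bad))
    stopf("invalid genotype code '%s' at row %d (%s), column %s",
          raw[bad[1, 1], bad[1, 2]], bad[1, 1], tab$ril_id[bad[1, 1]],
          mk[bad[1, 2]])
  geno <- matrix(as.integer(raw), nrow(raw), ncol(raw),
                 dimnames = list(tab$ril_id, mk))
  geno <- geno[, map$marker, drop = FALSE]
  new_panel(population_id, tab$ril_id, map, geno)
}

#' Write / read a long-format phenotype table
#' @param phenotypes long table (`ril_id`, `population_id`, `environment`,
#'   `trait`, `value`, `kind`).
#' @param path file path.
#' @export
write_phenotypes <- function(phenotypes, path) {
  write.table(phenotypes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  tab <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("ril_id", "population_id", "environment", "trait", "value", "kind")
  if (!all(need %in% names(tab)))
    stopf("phenotype file missing column(s): %s",
          paste(setdiff(need, names(tab)), collapse = ", "))
  if (!is.numeric(tab$value)) stopf("phenotype values must be numeric")
  dup <- duplicated(tab[, c("ril_id", "environment", "trait")])
  if (any(dup)) stopf("duplicate (ril, environment, trait) record: %s",
                      tab$ril_id[which(dup)[1]])
  tab
}

#' Write / read a BED-like annotation track in cM coordinates
#'
#' Columns: chromosome, start_cM, end_cM, label, category (one of
#' `QTL_source1`, `QTL_source2`, `SAM`, `leaf`, `other`).  Intervals are
#' closed.  An empty file is a valid empty track.
#' @param track annotation data.frame.
#' @param path file path.
#' @export
write_annotation <- function(track, path) {
  write.table(track, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  empty <- data.frame(chrom = character(), start_cM = numeric(),
                      end_cM = numeric(), label = character(),
                      category = character(), stringsAsFactors = FALSE)
  if (file.size(path) == 0) return(empty)
  tab <- read.table(path, sep = "\t", header = FALSE,
                    col.names = names(empty), stringsAsFactors = FALSE)
  if (nrow(tab) == 0) return(empty)
  if (any(tab$start_cM > tab$end_cM)) {
    i <- which(tab$start_cM > tab$end_cM)[1]
    stopf("annotation interval with start > end at line %d (%s)", i, tab$label[i])
  }
  bad <- setdiff(unique(tab$category), ANNOTATION_CATEGORIES)
  if (length(bad)) stopf("unknown annotation category: %s", bad[1])
  tab
}

#' Run configuration for the scenario-grid experiment
#'
#' @param dataset dataset label.
#' @param traits character vector of trait names.
#' @param ratios list of c(train, test) fractions, each summing to 1.
#' @param replicates resampling replicates per (population, ratio).
#' @param models model ids to fit.
#' @param hyperparameters named list of per-model hyperparameter overrides.
#' @param seed global seed.
#' @param out_dir optional output directory.
#' @export
run_config <- function(dataset = "synthetic",
                       traits = c("DTA", "ASI"),
                       ratios = list(c(0.8, 0.2), c(0.65, 0.35), c(0.5, 0.5)),
                       replicates = 10,
                       models = c("rrBLUP", "BayesB", "RKHS", "RF", "SVR", "MLP"),
                       hyperparameters = list(),
                       seed = 1, out_dir = NULL) {
  for (r in ratios)
    if (abs(sum(r) - 1) > 1e-8) stopf("train+test fractions must sum to 1")
  if (replicates < 1) stopf("replicates must be >= 1")
  if (!length(models)) stopf("model list must be non-empty")
  structure(list(dataset = dataset, traits = traits, ratios = ratios,
                 replicates = replicates, models = models,
                 hyperparameters = hyperparameters, seed = seed,
                 out_dir = out_dir),
            class = "gp_config")
}

#' @rdname run_config
#' @param config a `gp_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ratios <- if (is.matrix(x$ratios)) lapply(seq_len(nrow(x$ratios)),
                                            function(i) x$ratios[i, ])
            else if (is.list(x$ratios)) lapply(x$ratios, as.numeric)
            else list(as.numeric(x$ratios))
  run_config(dataset = x$dataset, traits = x$traits, ratios = ratios,
             replicates = x$replicates, models = x$models,
             hyperparameters = as.list(x$hyperparameters),
             seed = x$seed, out_dir = x$out_dir)
}
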