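# Dataset presets emulating the two NAM designs the analysis targets:
# a teosinte-NAM-like design (BC1-derived selfed populations, recurrent parent
# W22, two field environments, higher genetic diversity) and a maize-NAM-like
# design (F5 selfed populations on B73, phenotypes delivered as BLUEs,
# lower diversity).

#' Named simulation presets for NAM-style datasets
#'
#' `"teonam"`: 5 BC1-derived selfed populations (recurrent parent W22),
#' 450-620 RILs each, ~350 mapped SNPs, 2 environments with raw phenotypes;
#' flowering traits with a larger epistatic share (high-diversity world).
#' `"maizenam"`: 25 F5 selfed populations (common parent B73), 125-200 RILs,
#' ~220 SNPs, phenotypes reduced to BLUEs from 4 environments; mostly additive
#' architecture (low-diversity world).
#'
#' @param name `"teonam"` or `"maizenam"`.
#' @return a list of generator settings understood by [simulate_nam_dataset()].
#' @export
nam_preset <- function(name = c("teonam", "maizenam")) {
  name <- match.arg(name)
  if (name == "teonam") {
    list(
      name = "teonam",
      n_populations = 5,
      recurrent_parent = "W22",
      donor_prefix = "TIL",
      scheme = "backcross_then_self",
      n_self_generations = 4,
      n_rils_range = c(450, 620),
      n_chromosomes = 10, markers_per_chromosome = 35,
      chrom_length_cM = 150, bp_per_cM = 10000,
      environments = c(env2015 = 0, env2016 = 2),
      pheno_kind = "raw",
      traits = list(
        DTA = list(n_qtl = 30, n_pairs = 8, h2_additive = 0.45,
                   h2_epistatic = 0.15, trait_mean = 75),
        ASI = list(n_qtl = 25, n_pairs = 6, h2_additive = 0.40,
                   h2_epistatic = 0.12, trait_mean = 2.5)))
  } else {
    list(
      name = "maizenam",
      n_populations = 25,
      recurrent_parent = "B73",
      donor_prefix = "DON",
      scheme = "self_only",
      n_self_generations = 4,
      n_rils_range = c(125, 200),
      n_chromosomes = 10, markers_per_chromosome = 22,
      chrom_length_cM = 150, bp_per_cM = 10000,
      environments = c(NY = 0, NC = 1.2, MO = -0.8, IL = 0.5),
      pheno_kind = "BLUE",
      traits = list(
        DTA = list(n_qtl = 25, n_pairs = 3, h2_additive = 0.55,
                   h2_epistatic = 0.11, trait_mean = 70),
        ASI = list(n_qtl = 20, n_pairs = 2, h2_additive = 0.40,
                   h2_epistatic = 0.09, trait_mean = 1.5)))
  }
}

#' Simulate a complete NAM-style dataset from a preset
#'
#' Generates one shared genetic map, one QTL architecture per trait, and per
#' population a gamete-level RIL panel plus phenotypes.  For the
#' `"maizenam"` preset the per-environment raw records are reduced to BLUEs
#' through [fit_population_blups()] and [unshrink_to_blues()], mirroring how
#' that dataset ships its phenotypes; the `"teonam"` preset keeps raw
#' per-environment records (two environments to be concatenated downstream).
#'
#' @param preset a preset name or a list from [nam_preset()], possibly edited.
#' @param seed global seed; all internal streams derive from it.
#' @param n_populations,n_rils_range,markers_per_chromosome optional scale
#'   overrides (used to run the same world at desk scale).
#' @return list with `map`, `panels` (named list of `gp_panel`),
#'   `phenotypes` (long table over all populations/traits),
#'   `architectures` (per trait), `preset`.
#' @export
simulate_nam_dataset <- function(preset = "teonam", seed = 1,
                                 n_populations = NULL, n_rils_range = NULL,
                                 markers_per_chromosome = NULL) {
  ps <- if (is.character(preset)) nam_preset(preset) else preset
  if (!is.null(n_populations)) ps$n_populations <- n_populations
  if (!is.null(n_rils_range)) ps$n_rils_range <- n_rils_range
  if (!is.null(markers_per_chromosome))
    ps$markers_per_chromosome <- markers_per_chromosome

  map <- simulate_map(ps$n_chromosomes, ps$markers_per_chromosome,
                      ps$chrom_length_cM, ps$bp_per_cM,
                      seed = derive_seed(seed, ps$name, "map"))
  architectures <- lapply(names(ps$traits), function(tr) {
    cfg <- ps$traits[[tr]]
    random_architecture(map, n_qtl = cfg$n_qtl, n_pairs = cfg$n_pairs,
                        trait = tr, h2_additive = cfg$h2_additive,
                        h2_epistatic = cfg$h2_epistatic,
                        env_effects = ps$environments,
                        trait_mean = cfg$trait_mean,
                        seed = derive_seed(seed, ps$name, "arch", tr))
  })
  names(architectures) <- names(ps$traits)

  panels <- list(); phenos <- list()
  for (i in seq_len(ps$n_populations)) {
    pop <- sprintf("%s_%s%02d", ps$recurrent_parent, ps$donor_prefix, i)
    n_rils <- with_seed(derive_seed(seed, ps$name, "nril", i),
                        sample(seq(ps$n_rils_range[1], ps$n_rils_range[2]), 1))
    des <- cross_design(ps$scheme, ps$n_self_generations,
                        ps$recurrent_parent,
                        sprintf("%s%02d", ps$donor_prefix, i), n_rils)
    panel <- simulate_ril_population(map, des,
                                     seed = derive_seed(seed, ps$name, "pop", i),
                                     population_id = pop)
    panels[[pop]] <- panel
    for (tr in names(architectures)) {
      ph <- simulate_phenotypes(panel, architectures[[tr]],
                                seed = derive_seed(seed, ps$name, "pheno", i, tr))
      phenos[[paste(pop, tr)]] <- ph
    }
  }
  phenotypes <- do.call(rbind, phenos)
  rownames(phenotypes) <- NULL

  if (ps$pheno_kind == "BLUE") {
    phenotypes <- do.call(rbind, lapply(split(phenotypes,
        list(phenotypes$population_id, phenotypes$trait), drop = TRUE),
      function(tab) {
        bl <- fit_population_blups(tab)
        unshrink_to_blues(bl$blups, bl$H2)
      }))
    rownames(phenotypes) <- NULL
  }
  list(map = map, panels = panels, phenotypes = phenotypes,
       architectures = architectures, preset = ps)
}
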