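# Synthetic NAM RIL simulator: genetic maps, gamete-level line development,
# QTL architectures and multi-environment phenotypes.

#' Simulate a genetic map
#'
#' Markers are placed by jittered-uniform sampling along each chromosome, with
#' physical coordinates tied to the genetic ones through a constant bp/cM
#' expansion factor.  Positions are strictly increasing in both cM and bp
#' within a chromosome.
#'
#' @param n_chromosomes number of chromosomes.
#' @param markers_per_chromosome markers placed on each chromosome.
#' @param chrom_length_cM genetic length of every chromosome (cM).
#' @param bp_per_cM physical expansion factor (base pairs per cM).
#' @param seed integer seed.
#' @return a `data.frame` of class `gp_map` with columns `marker`, `chrom`,
#'   `cM`, `bp`.
#' @export
simulate_map <- function(n_chromosomes, markers_per_chromosome,
                         chrom_length_cM, bp_per_cM = 10000, seed = 1) {
  if (n_chromosomes < 1 || markers_per_chromosome < 1 ||
      chrom_length_cM <= 0 || bp_per_cM <= 0)
    stopf("all map dimensions must be positive")
  with_seed(seed, {
    rows <- lapply(seq_len(n_chromosomes), function(cc) {
      cm <- sort(runif(markers_per_chromosome, 0, chrom_length_cM))
      # enforce strict increase (ties have probability zero but be safe)
      cm <- cm + cumsum(c(0, as.numeric(diff(cm) == 0))) * 1e-6
      bp <- round(cm * bp_per_cM)
      for (i in seq_along(bp)[-1]) if (bp[i] <= bp[i - 1]) bp[i] <- bp[i - 1] + 1
      data.frame(
        marker = sprintf("chr%d_m%03d", cc, seq_len(markers_per_chromosome)),
        chrom = sprintf("chr%d", cc),
        cM = cm, bp = as.integer(bp),
        stringsAsFactors = FALSE)
    })
    map <- do.call(rbind, rows)
    rownames(map) <- NULL
    class(map) <- c("gp_map", "data.frame")
    map
  })
}

validate_map <- function(map) {
  stopifnot(all(c("marker", "chrom", "cM", "bp") %in% names(map)))
  if (anyDuplicated(map$marker)) stopf("duplicate marker ids in map")
  for (cc in unique(map$chrom)) {
    sub <- map[map$chrom == cc, ]
    if (any(diff(sub$cM) <= 0) || any(diff(sub$bp) <= 0))
      stopf("map positions not strictly increasing on %s", cc)
  }
  invisible(map)
}

#' Describe a line-development cross design
#'
#' @param scheme `"backcross_then_self"` (one backcross to the recurrent
#'   parent, then selfing) or `"self_only"` (selfing from the F1).
#' @param n_self_generations selfing generations by single-seed descent
#'   (4 gives F5-equivalent lines under `self_only`).
#' @param recurrent_parent,donor_parent parent labels.
#' @param n_rils number of lines to develop.
#' @export
cross_design <- function(scheme = c("backcross_then_self", "self_only"),
                         n_self_generations = 4,
                         recurrent_parent = "W22", donor_parent = "DONOR",
                         n_rils = 200) {
  scheme <- match.arg(scheme)
  if (n_self_generations < 1) stopf("n_self_generations must be >= 1")
  if (n_rils < 1) stopf("n_rils must be >= 1")
  structure(list(scheme = scheme, n_self_generations = n_self_generations,
                 recurrent_parent = recurrent_parent,
                 donor_parent = donor_parent, n_rils = n_rils),
            class = "gp_cross_design")
}

# One meiosis for a single chromosome: crossovers as a Poisson process at
# 1 event / 100 cM, no interference (Haldane model).
sim_gamete_chrom <- function(h1, h2, pos_cM, len_cM) {
  n_x <- rpois(1, len_cM / 100)
  start <- sample.int(2, 1) - 1L
  if (n_x == 0) {
    if (start == 0L) h1 else h2
  } else {
    breaks <- sort(runif(n_x, 0, len_cM))
    phase <- (findInterval(pos_cM, breaks) + start) %% 2L
    ifelse(phase == 0L, h1, h2)
  }
}

# Whole-genome gamete from a diploid individual given split map coordinates.
sim_gamete <- function(hap1, hap2, chrom_idx, chrom_pos, chrom_len) {
  g <- integer(length(hap1))
  for (k in seq_along(chrom_idx)) {
    ix <- chrom_idx[[k]]
    g[ix] <- sim_gamete_chrom(hap1[ix], hap2[ix], chrom_pos[[k]], chrom_len[k])
  }
  g
}

#' Simulate a RIL population by gamete-level line development
#'
#' Each line is produced independently: the F1 (one donor and one recurrent
#' haplotype) is optionally backcrossed once to the recurrent parent, then
#' advanced by single-seed descent for `n_self_generations` selfing
#' generations.  Recombination follows a Poisson crossover process (Haldane,
#' no interference).  Genotypes count donor-allele copies (0/1/2).
#'
#' @param map a `gp_map`.
#' @param design a [cross_design()].
#' @param seed integer seed.
#' @param population_id label stored on the panel.
#' @return a `gp_panel`: list with `population_id`, `ril_ids`, `map`, and
#'   `geno` (RIL x marker integer matrix, donor-allele dosage).
#' @export
simulate_ril_population <- function(map, design, seed = 1,
                                    population_id = NULL) {
  validate_map(map)
  if (!inherits(design, "gp_cross_design")) stopf("design must be a cross_design")
  chroms <- unique(map$chrom)
  chrom_idx <- lapply(chroms, function(cc) which(map$chrom == cc))
  chrom_pos <- lapply(chrom_idx, function(ix) map$cM[ix])
  chrom_len <- vapply(seq_along(chroms), function(k)
    max(chrom_pos[[k]]) + 1e-9, numeric(1))
  p <- nrow(map)
  donor <- rep(1L, p); recur <- rep(0L, p)
  population_id <- population_id %||%
    paste0(design$recurrent_parent, "x", design$donor_parent)

  with_seed(seed, {
    geno <- matrix(0L, design$n_rils, p)
    for (r in seq_len(design$n_rils)) {
      h1 <- donor; h2 <- recur            # the F1
      if (design$scheme == "backcross_then_self") {
        h1 <- sim_gamete(h1, h2, chrom_idx, chrom_pos, chrom_len)
        h2 <- recur                        # BC1 to the recurrent parent
      }
      for (g in seq_len(design$n_self_generations)) {
        new1 <- sim_gamete(h1, h2, chrom_idx, chrom_pos, chrom_len)
        new2 <- sim_gamete(h1, h2, chrom_idx, chrom_pos, chrom_len)
        h1 <- new1; h2 <- new2
      }
      geno[r, ] <- h1 + h2
    }
    ril_ids <- sprintf("%s_RIL%04d", population_id, seq_len(design$n_rils))
    dimnames(geno) <- list(ril_ids, map$marker)
    new_panel(population_id, ril_ids, map, geno)
  })
}

new_panel <- function(population_id, ril_ids, map, geno) {
  stopifnot(nrow(geno) == length(ril_ids), ncol(geno) == nrow(map))
  ok <- geno %in% c(0L, 1L, 2L) | is.na(geno)
  if (!all(ok)) stopf("genotype codes outside {0,1,2,NA}")
  dimnames(geno) <- list(ril_ids, map$marker)
  structure(list(population_id = population_id, ril_ids = ril_ids,
                 map = map, geno = geno),
            class = "gp_panel")
}

#' @export
print.gp_panel <- function(x, ...) {
  cat(sprintf("gp_panel '%s': %d RILs x %d markers (%d chromosomes), %.2f%% missing\n",
              x$population_id, nrow(x$geno), ncol(x$geno),
              length(unique(x$map$chrom)), 100 * mean(is.na(x$geno))))
  invisible(x)
}

#' Define a QTL architecture for phenotype simulation
#'
#' @param additive data.frame with columns `marker`, `effect` (trait units per
#'   donor-allele copy).
#' @param epistatic data.frame with columns `marker1`, `marker2`, `effect`
#'   (additive-by-additive interaction coefficients), or NULL.
#' @param trait trait name.
#' @param h2_additive,h2_epistatic target proportions of phenotypic variance.
#' @param env_effects named numeric vector of per-environment shifts.
#' @param trait_mean grand mean in trait units.
#' @export
qtl_architecture <- function(additive, epistatic = NULL, trait = "trait",
                             h2_additive = 0.5, h2_epistatic = 0,
                             env_effects = c(env1 = 0), trait_mean = 0) {
  if (h2_additive < 0 || h2_epistatic < 0 || h2_additive + h2_epistatic > 1)
    stopf("h2_additive + h2_epistatic must lie in [0,1]")
  if (!is.null(epistatic) && nrow(epistatic) &&
      any(epistatic$marker1 == epistatic$marker2))
    stopf("epistatic self-pairs are not allowed")
  structure(list(additive = additive, epistatic = epistatic, trait = trait,
                 h2_additive = h2_additive, h2_epistatic = h2_epistatic,
                 env_effects = env_effects, trait_mean = trait_mean),
            class = "gp_architecture")
}

#' Draw a random QTL architecture on a map
#'
#' Additive effects are drawn N(0,1) at randomly chosen markers; epistatic
#' pairs are sampled among the additive QTL with N(0,1) coefficients.  The
#' absolute scale is irrelevant: [simulate_phenotypes()] rescales components
#' to the target heritabilities.
#' @param map a `gp_map`.
#' @param n_qtl,n_pairs numbers of additive QTL and epistatic pairs.
#' @param seed integer seed.
#' @inheritParams qtl_architecture
#' @export
random_architecture <- function(map, n_qtl = 20, n_pairs = 0, trait = "trait",
                                h2_additive = 0.5, h2_epistatic = 0,
                                env_effects = c(env1 = 0), trait_mean = 0,
                                seed = 1) {
  with_seed(seed, {
    qtl <- sample(map$marker, min(n_qtl, nrow(map)))
    add <- data.frame(marker = qtl, effect = rnorm(length(qtl)),
                      stringsAsFactors = FALSE)
    epi <- NULL
    if (n_pairs > 0 && length(qtl) >= 2) {
      prs <- t(replicate(n_pairs, sample(qtl, 2)))
      epi <- data.frame(marker1 = prs[, 1], marker2 = prs[, 2],
                        effect = rnorm(n_pairs), stringsAsFactors = FALSE)
    }
    qtl_architecture(add, epi, trait, h2_additive, h2_epistatic,
                     env_effects, trait_mean)
  })
}

#' Simulate multi-environment phenotypes on a panel
#'
#' Genetic value = sum of additive dosage effects plus pairwise
#' dosage-product interaction effects.  The epistatic component and the
#' residual variance are rescaled so that the realized variance proportions
#' match the architecture's targets in expectation (the additive component is
#' the anchor when its target is positive).  Each environment receives its
#' stated shift and independent residual noise.
#'
#' @param panel a `gp_panel` (no missing genotypes at the QTL).
#' @param architecture a [qtl_architecture()].
#' @param seed integer seed.
#' @return a long-format `data.frame`: `ril_id`, `population_id`,
#'   `environment`, `trait`, `value`, `kind = "raw"`.
#' @export
simulate_phenotypes <- function(panel, architecture, seed = 1) {
  arc <- architecture
  miss <- setdiff(c(arc$additive$marker,
                    arc$epistatic$marker1, arc$epistatic$marker2),
                  colnames(panel$geno))
  if (length(miss)) stopf("architecture markers absent from panel: %s",
                          paste(head(miss, 3), collapse = ", "))
  X <- panel$geno
  if (anyNA(X[, unique(c(arc$additive$marker, arc$epistatic$marker1,
                         arc$epistatic$marker2)), drop = FALSE]))
    stopf("missing genotypes at QTL markers")
  g_add <- if (nrow(arc$additive))
    as.numeric(X[, arc$additive$marker, drop = FALSE] %*% arc$additive$effect)
  else numeric(nrow(X))
  g_epi <- numeric(nrow(X))
  if (!is.null(arc$epistatic) && nrow(arc$epistatic)) {
    for (i in seq_len(nrow(arc$epistatic)))
      g_epi <- g_epi + arc$epistatic$effect[i] *
        X[, arc$epistatic$marker1[i]] * X[, arc$epistatic$marker2[i]]
    g_epi <- g_epi - mean(g_epi)
  }
  g_add <- g_add - mean(g_add)
  # orthogonalise the interaction component against the additive one so the
  # two variance targets are realized jointly (dosage products correlate
  # with dosages otherwise)
  if (var(g_epi) > 0 && var(g_add) > 0)
    g_epi <- g_epi - g_add * (cov(g_add, g_epi) / var(g_add))
  va <- var(g_add); ve <- var(g_epi)
  h2a <- arc$h2_additive; h2e <- arc$h2_epistatic
  # anchor total phenotypic variance on the non-degenerate component
  vp <- if (h2a > 0 && va > 0) va / h2a
        else if (h2e > 0 && ve > 0) ve / h2e
        else 1
  if (h2e > 0 && ve > 0) g_epi <- g_epi * sqrt(h2e * vp / ve)
  else g_epi <- g_epi * 0
  if (h2a == 0) g_add <- g_add * 0
  res_var <- max(0, (1 - h2a - h2e) * vp)
  g <- g_add + g_epi
  envs <- names(arc$env_effects)
  with_seed(seed, {
    out <- lapply(envs, function(e) {
      data.frame(ril_id = panel$ril_ids,
                 population_id = panel$population_id,
                 environment = e, trait = arc$trait,
                 value = arc$trait_mean + g + arc$env_effects[[e]] +
                   rnorm(length(g), 0, sqrt(res_var)),
                 kind = "raw", stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, out)
    attr(res, "components") <- data.frame(ril_id = panel$ril_ids,
                                          additive = g_add, epistatic = g_epi)
    res
  })
}

#' Inject missing genotypes into a panel
#'
#' Marks cells missing completely at random at rate `rate`, and independently,
#' with probability `block_rate` per RIL, blanks one whole randomly chosen
#' chromosome (the failure mode the whole-chromosome sample filter targets).
#'
#' @param panel a `gp_panel`.
#' @param rate per-cell missingness probability.
#' @param block_rate per-RIL whole-chromosome dropout probability.
#' @param seed integer seed.
#' @export
inject_missingness <- function(panel, rate = 0.02, block_rate = 0, seed = 1) {
  if (rate < 0 || rate > 1 || block_rate < 0 || block_rate > 1)
    stopf("rates must lie in [0,1]")
  with_seed(seed, {
    geno <- panel$geno
    if (rate > 0) {
      mask <- matrix(runif(length(geno)) < rate, nrow(geno))
      geno[mask] <- NA_integer_
    }
    if (block_rate > 0) {
      chroms <- unique(panel$map$chrom)
      hit <- runif(nrow(geno)) < block_rate
      for (r in which(hit)) {
        cc <- sample(chroms, 1)
        geno[r, panel$map$chrom == cc] <- NA_integer_
      }
    }
    new_panel(panel$population_id, panel$ril_ids, panel$map, geno)
  })
}
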