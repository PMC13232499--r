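# Gamete-level NAM simulator: map geometry, Mendelian expectations under the
# two line-development schemes, Haldane recombination, phenotype variance
# targets and missingness injection.

test_that("simulated maps have the requested geometry and are reproducible", {
  map <- simulate_map(10, 50, 150, 10000, seed = 4)
  expect_equal(nrow(map), 500)
  expect_equal(length(unique(map$chrom)), 10)
  for (cc in unique(map$chrom)) {
    sub <- map[map$chrom == cc, ]
    expect_true(all(diff(sub$cM) > 0))
    expect_true(all(diff(sub$bp) > 0))
  }
  expect_false(anyDuplicated(map$marker) > 0)
  expect_identical(map, simulate_map(10, 50, 150, 10000, seed = 4))
  expect_error(simulate_map(0, 5, 100), "positive")
})

test_that("selfing and backcross schemes match single-locus Markov-chain expectations", {
  # independent oracle: exact single-locus chain under selfing.  From an F1
  # (het), one selfing generation maps (hom-donor, het, hom-rec) through
  # P = [[1,0,0],[1/4,1/2,1/4],[0,0,1]] applied to the genotype distribution.
  selfing_chain <- function(start, n_gen) {
    P <- matrix(c(1, 0, 0, 1 / 4, 1 / 2, 1 / 4, 0, 0, 1), 3, 3, byrow = TRUE)
    v <- start
    for (g in seq_len(n_gen)) v <- as.numeric(v %*% P)
    v
  }
  f5 <- selfing_chain(c(0, 1, 0), 4)           # F1 selfed 4x
  expect_equal(f5[2], 0.0625)                  # het probability
  bc1 <- selfing_chain(c(0, 0.5, 0.5), 4)      # BC1: het w.p. 1/2
  exp_donor_freq <- bc1[1] + bc1[2] / 2
  expect_equal(exp_donor_freq, 0.25)

  map <- simulate_map(2, 15, 100, 10000, seed = 5)
  pan_f5 <- simulate_ril_population(
    map, cross_design("self_only", 4, "B", "D", 1000), seed = 6)
  het <- mean(pan_f5$geno == 1)
  se_het <- sqrt(0.0625 * (1 - 0.0625) / length(pan_f5$geno))
  expect_lt(abs(het - 0.0625), 3 * se_het * sqrt(30))  # markers correlated within RIL

  pan_bc <- simulate_ril_population(
    map, cross_design("backcross_then_self", 4, "W", "T", 1000), seed = 7)
  freq <- mean(pan_bc$geno) / 2
  expect_lt(abs(freq - 0.25), 0.02)
  expect_true(all(pan_bc$geno %in% 0:2))
  expect_error(cross_design("weird"), "arg")
})

test_that("recombination follows the Haldane model", {
  # gamete-level oracle: direct recombination-fraction simulation
  for (d in c(10, 30, 60)) {
    pos <- c(0, d)
    set.seed(d)
    rec <- mean(replicate(20000, {
      g <- gpensemble:::sim_gamete_chrom(c(1L, 1L), c(0L, 0L), pos, d + 1e-9)
      g[1] != g[2]
    }))
    c_hald <- (1 - exp(-2 * d / 100)) / 2
    expect_lt(abs(rec - c_hald), 3.5 * sqrt(c_hald * (1 - c_hald) / 20000))
  }
  # RIL scale: after many selfing generations the observed recombinant
  # fraction between homozygous genotypes approaches 2c/(1+2c)
  map2 <- data.frame(marker = c("a", "b"), chrom = "chr1",
                     cM = c(0, 20), bp = c(1, 200000))
  class(map2) <- c("gp_map", "data.frame")
  pan <- simulate_ril_population(
    map2, cross_design("self_only", 8, "B", "D", 4000), seed = 8)
  hom <- pan$geno[, 1] %in% c(0, 2) & pan$geno[, 2] %in% c(0, 2)
  robs <- mean(pan$geno[hom, 1] != pan$geno[hom, 2])
  c20 <- (1 - exp(-0.4)) / 2
  expect_lt(abs(robs - 2 * c20 / (1 + 2 * c20)), 0.03)
})

test_that("phenotype simulation hits its variance targets and edge cases", {
  map <- tiny_map()
  pan <- simulate_ril_population(map, cross_design("self_only", 4, "B", "D", 500),
                                 seed = 9)
  arc <- random_architecture(map, n_qtl = 10, n_pairs = 3, trait = "DTA",
                             h2_additive = 0.5, h2_epistatic = 0.1,
                             env_effects = c(e1 = 0), trait_mean = 70, seed = 10)
  ph <- simulate_phenotypes(pan, arc, seed = 11)
  cmp <- attr(ph, "components")
  vp <- var(ph$value)
  expect_lt(abs(var(cmp$additive) / vp - 0.5), 0.08)
  expect_lt(abs(var(cmp$epistatic) / vp - 0.1), 0.08)
  # realized additive variance matches the sum over QTL of 2p(1-p)e^2 only
  # under linkage equilibrium; the direct component variance is the oracle
  expect_equal(var(cmp$additive) + var(cmp$epistatic) +
                 var(ph$value - 70 - cmp$additive - cmp$epistatic),
               vp, tolerance = 0.05)

  arc1 <- qtl_architecture(data.frame(marker = map$marker[1], effect = 2),
                           trait = "t", h2_additive = 1, h2_epistatic = 0,
                           env_effects = c(e1 = 0, e2 = 3))
  ph1 <- simulate_phenotypes(pan, arc1, seed = 12)
  g <- pan$geno[, 1] * 2
  g <- g - mean(g)
  expect_equal(ph1$value[ph1$environment == "e1"], unname(g), tolerance = 1e-12)
  expect_equal(ph1$value[ph1$environment == "e2"], unname(g) + 3,
               tolerance = 1e-12)

  arc0 <- qtl_architecture(data.frame(marker = character(), effect = numeric()),
                           trait = "t", h2_additive = 0, h2_epistatic = 0)
  ph0 <- simulate_phenotypes(pan, arc0, seed = 13)
  expect_equal(var(ph0$value), 1, tolerance = 0.2)   # unit residual anchor
  expect_error(qtl_architecture(data.frame(marker = "m", effect = 1),
                                h2_additive = 0.8, h2_epistatic = 0.3),
               "must lie")
  expect_error(
    qtl_architecture(data.frame(marker = "a", effect = 1),
                     epistatic = data.frame(marker1 = "a", marker2 = "a",
                                            effect = 1)),
    "self-pairs")
})

test_that("missingness injection is calibrated and seeds give identical panels", {
  pan <- tiny_panel(100, seed = 14)
  expect_identical(inject_missingness(pan, 0, 0, seed = 1)$geno, pan$geno)
  expect_true(all(is.na(inject_missingness(pan, 1, 0, seed = 1)$geno)))
  m <- inject_missingness(pan, 0.05, 0, seed = 15)
  n_cells <- length(pan$geno)
  n_na <- sum(is.na(m$geno))
  expect_lt(abs(n_na - 0.05 * n_cells), 4 * sqrt(n_cells * 0.05 * 0.95))
  b <- inject_missingness(pan, 0, 0.5, seed = 16)
  whole <- sapply(unique(pan$map$chrom), function(cc)
    rowSums(!is.na(b$geno[, pan$map$chrom == cc])) == 0)
  expect_gt(sum(whole), 0)
  expect_identical(inject_missingness(pan, 0.1, 0.1, seed = 17)$geno,
                   inject_missingness(pan, 0.1, 0.1, seed = 17)$geno)
  expect_error(inject_missingness(pan, 1.2, 0), "rates")
})

test_that("dataset presets produce the stated structure", {
  dat <- simulate_nam_dataset("maizenam", seed = 30, n_populations = 3,
                              n_rils_range = c(40, 50),
                              markers_per_chromosome = 5)
  expect_length(dat$panels, 3)
  expect_true(all(dat$phenotypes$kind == "BLUE"))
  expect_true(all(dat$phenotypes$environment == "combined"))
  expect_setequal(unique(dat$phenotypes$trait), c("DTA", "ASI"))
  dat2 <- simulate_nam_dataset("teonam", seed = 31, n_populations = 2,
                               n_rils_range = c(40, 50),
                               markers_per_chromosome = 5)
  expect_true(all(dat2$phenotypes$kind == "raw"))
  expect_equal(length(unique(dat2$phenotypes$environment)), 2)
  # same seed, same world
  dat3 <- simulate_nam_dataset("teonam", seed = 31, n_populations = 2,
                               n_rils_range = c(40, 50),
                               markers_per_chromosome = 5)
  expect_identical(dat2$phenotypes$value, dat3$phenotypes$value)
})
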