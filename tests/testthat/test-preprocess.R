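# Preprocessing chain: flanking imputation, sample filters, LD pruning,
# environment concatenation, BLUP/BLUE derivation.

test_that("flanking imputation fills from the nearest flank and never alters data", {
  pan <- inject_missingness(tiny_panel(40), 0.15, 0, seed = 5)
  imp <- impute_flanking(pan)
  obs <- !is.na(pan$geno)
  expect_identical(imp$geno[obs], pan$geno[obs])    # observed untouched
  expect_false(anyNA(imp$geno))
  # brute-force nearest-non-missing oracle (left flank on cM ties)
  for (r in 1:10) for (cc in unique(pan$map$chrom)) {
    ix <- which(pan$map$chrom == cc)
    v <- pan$geno[r, ix]; pos <- pan$map$cM[ix]
    for (i in which(is.na(v))) {
      o <- which(!is.na(v))
      d <- abs(pos[o] - pos[i])
      nearest <- o[order(d, pos[o])][1]
      expect_identical(unname(imp$geno[r, ix[i]]), unname(v[nearest]))
    }
  }
  # explicit decision cases on a hand-built panel
  map3 <- data.frame(marker = c("a", "b", "c"), chrom = "chr1",
                     cM = c(0, 5, 10), bp = c(1, 50, 100))
  class(map3) <- c("gp_map", "data.frame")
  g <- matrix(c(2L, NA, 2L,
                NA, 0L, 2L,
                0L, NA, 2L), 3, 3, byrow = TRUE,
              dimnames = list(paste0("r", 1:3), map3$marker))
  p3 <- gpensemble:::new_panel("p", rownames(g), map3, g)
  i3 <- impute_flanking(p3)
  expect_identical(i3$geno[1, 2], 2L)    # both flanks 2
  expect_identical(i3$geno[2, 1], 0L)    # chromosome end copies single flank
  expect_identical(i3$geno[3, 2], 0L)    # exact midpoint -> left flank
})

test_that("sample filter removes whole-missing chromosomes and phenotype-less RILs", {
  pan <- tiny_panel(30)
  ph <- simulate_phenotypes(pan, tiny_architecture(), seed = 6)
  clean <- filter_samples(pan, ph)
  expect_equal(nrow(clean$panel$geno), 30)
  expect_equal(nrow(clean$removed), 0)

  g <- pan$geno
  g[3, pan$map$chrom == "chr2"] <- NA
  pan2 <- gpensemble:::new_panel(pan$population_id, pan$ril_ids, pan$map, g)
  out <- filter_samples(pan2, ph)
  expect_equal(out$removed$ril_id, pan$ril_ids[3])
  expect_match(out$removed$reason, "missing_chromosome:chr2")

  ph3 <- ph[ph$ril_id != pan$ril_ids[5], ]
  out3 <- filter_samples(pan, ph3)
  expect_equal(out3$removed$reason, "no_phenotype")
  expect_false(pan$ril_ids[5] %in% out3$panel$ril_ids)

  # idempotent
  again <- filter_samples(out3$panel, out3$phenotypes)
  expect_identical(again$panel$geno, out3$panel$geno)
  expect_equal(nrow(again$removed), 0)
  expect_error(filter_samples(pan, ph[0, ]), "all samples removed")
})

test_that("LD pruning removes r2 >= 0.8 pairs and survives the all-pairs audit", {
  pan <- impute_flanking(tiny_panel(80, seed = 21))
  # duplicate a marker inside a 30-kb window: exactly one of the two survives
  mdup <- data.frame(marker = c("d1", "d2", "far"), chrom = "chr1",
                     cM = c(0, 1, 50), bp = c(1000, 11000, 500000))
  class(mdup) <- c("gp_map", "data.frame")
  gdup <- cbind(pan$geno[, 1], pan$geno[, 1], pan$geno[, 5])
  pdup <- gpensemble:::new_panel("p", pan$ril_ids, mdup, gdup)
  pr <- ld_prune(pdup)
  expect_equal(sum(c("d1", "d2") %in% pr$kept), 1)
  expect_true("far" %in% pr$kept)

  # orthogonal markers survive untouched
  set.seed(22)
  go <- matrix(0L, 64, 3)
  go[, 1] <- rep(c(0L, 2L), each = 32)
  go[, 2] <- rep(rep(c(0L, 2L), each = 16), 2)
  go[, 3] <- rep(rep(c(0L, 2L), each = 8), 4)
  mo <- data.frame(marker = c("x", "y", "z"), chrom = "chr1",
                   cM = c(0, 0.5, 1), bp = c(100, 600, 1100))
  class(mo) <- c("gp_map", "data.frame")
  po <- gpensemble:::new_panel("p", paste0("r", 1:64), mo, go)
  expect_equal(ld_prune(po)$kept, c("x", "y", "z"))

  # post-condition audit on a random panel: no surviving within-window pair
  # with r2 >= 0.8 (brute force over all pairs)
  pr2 <- ld_prune(pan)
  expect_equal(pr2$kept, pr2$panel$map$marker)   # map order preserved
  expect_true(all(pr2$kept %in% pan$map$marker))
  gm <- pr2$panel$geno; mp <- pr2$panel$map
  for (i in seq_len(ncol(gm) - 1)) for (j in (i + 1):ncol(gm)) {
    if (mp$chrom[i] == mp$chrom[j] && abs(mp$bp[j] - mp$bp[i]) <= 30000 &&
        var(gm[, i]) > 0 && var(gm[, j]) > 0)
      expect_lt(cor(gm[, i], gm[, j])^2, 0.8)
  }
  expect_error(ld_prune(inject_missingness(pan, 0.1, 0, 1)), "imputed")
})

test_that("environment concatenation stacks records with a factor encoding", {
  pan <- tiny_panel(60)
  ph <- simulate_phenotypes(pan, tiny_architecture(), seed = 7)
  d <- concat_environments(pan, ph, "DTA")
  expect_equal(length(d$y), 120)                 # 2 environments x n RILs
  expect_equal(ncol(d$F), 1)                     # one-hot minus reference
  expect_setequal(unique(d$F[, 1]), c(0, 1))
  # each RIL's genotype row is shared across its environments
  r <- d$ril_id[1]
  rows <- which(d$ril_id == r)
  expect_equal(d$X[rows[1], ], d$X[rows[2], ])

  ph1 <- ph[ph$environment == "e1", ]
  d1 <- concat_environments(pan, ph1, "DTA")
  expect_equal(length(d1$y), 60)
  expect_equal(ncol(d1$F), 0)                    # single environment

  # the simulated environment shift is recoverable from the stacked design
  delta <- mean(ph$value[ph$environment == "e2"]) -
    mean(ph$value[ph$environment == "e1"])
  fit <- fit_rrblup(d$X, d$y, d$F, n_iter = 1200, burn_in = 300, seed = 8)
  expect_lt(abs(fit$b["env_e2"] - delta), 2)
})

test_that("BLUP fitting recovers repeatability and BLUE unshrinking is its inverse", {
  pan <- tiny_panel(200, seed = 23)
  arc <- tiny_architecture(h2a = 0.6, h2e = 0, envs = c(e1 = 0, e2 = 1.5))
  ph <- simulate_phenotypes(pan, arc, seed = 24)
  fit <- fit_population_blups(ph)
  vg <- var(attr(ph, "components")$additive)
  # line-mean repeatability over 2 environments: vg / (vg + ve/2)
  expect_lt(abs(fit$H2$H2 - vg / (vg + fit$H2$sigma2_e / 2)), 0.1)
  expect_equal(mean(fit$blups$value), 0, tolerance = 1e-10)

  # zero residual variance: BLUP = centred line mean, H2 = 1
  ph0 <- ph
  g <- tapply(ph$value, ph$ril_id, mean)  # make records exactly repeatable
  ph0$value <- as.numeric(g[ph0$ril_id]) +
    ifelse(ph0$environment == "e2", 1.5, 0)
  fit0 <- fit_population_blups(ph0)
  expect_equal(fit0$H2$H2, 1, tolerance = 1e-8)
  m <- tapply(ph0$value[ph0$environment == "e1"],
              ph0$ril_id[ph0$environment == "e1"], mean)
  expect_equal(sort(fit0$blups$value), sort(as.numeric(m - mean(m))),
               tolerance = 1e-6)

  # zero genetic variance: BLUPs all ~0
  phn <- ph
  set.seed(25); phn$value <- rnorm(nrow(phn))
  fitn <- fit_population_blups(phn)
  expect_lt(sd(fitn$blups$value), 0.35 * sd(phn$value))

  blues <- unshrink_to_blues(fit$blups, fit$H2)
  expect_equal(blues$value, fit$blups$value / fit$H2$H2)
  expect_true(all(blues$kind == "BLUE"))
  expect_equal(var(blues$value), var(fit$blups$value) / fit$H2$H2^2,
               tolerance = 1e-10)
  expect_equal(unshrink_to_blues(fit$blups, 1)$value, fit$blups$value)
  expect_error(unshrink_to_blues(fit$blups, 0), "positive")
  expect_error(fit_population_blups(ph[ph$environment == "e1", ]),
               "single environment")
})
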