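# Preprocessing chain: flanking-marker imputation, sample filters, windowed
# LD pruning, multi-environment concatenation, BLUP fitting and BLUE
# derivation.

#' Impute missing genotypes from flanking markers
#'
#' Each missing genotype is filled with the value of the nearest non-missing
#' marker (in cM) on the same chromosome of the same RIL; exact midpoints take
#' the left flank; chromosome ends copy the single available flank.  Observed
#' genotypes are never altered.  Whole-missing chromosomes are left missing
#' (they are the business of [filter_samples()]).
#'
#' @param panel a `gp_panel`.
#' @return the imputed `gp_panel`.
#' @export
impute_flanking <- function(panel) {
  geno <- panel$geno
  chroms <- unique(panel$map$chrom)
  for (cc in chroms) {
    ix <- which(panel$map$chrom == cc)
    pos <- panel$map$cM[ix]
    sub <- geno[, ix, drop = FALSE]
    for (r in which(rowSums(is.na(sub)) > 0)) {
      v <- sub[r, ]
      obs <- which(!is.na(v))
      if (length(obs) == 0) next
      for (i in which(is.na(v))) {
        d <- abs(pos[obs] - pos[i])
        # nearest flank; on a tie the smaller position (left flank) wins
        best <- obs[order(d, pos[obs])][1]
        v[i] <- v[best]
      }
      sub[r, ] <- v
    }
    geno[, ix] <- sub
  }
  new_panel(panel$population_id, panel$ril_ids, panel$map, geno)
}

#' Remove RILs with whole-missing chromosomes or without phenotypes
#'
#' @param panel a `gp_panel`.
#' @param phenotypes long phenotype table (may span several traits).
#' @param traits traits that must be present; defaults to all traits in the
#'   table.
#' @return list with the filtered `panel`, `phenotypes`, and a `removed`
#'   data.frame logging each removal with its reason.
#' @export
filter_samples <- function(panel, phenotypes, traits = NULL) {
  traits <- traits %||% unique(phenotypes$trait)
  chroms <- unique(panel$map$chrom)
  removed <- data.frame(ril_id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  chrom_missing <- vapply(chroms, function(cc) {
    ix <- panel$map$chrom == cc
    rowSums(!is.na(panel$geno[, ix, drop = FALSE])) == 0
  }, logical(nrow(panel$geno)))
  if (is.null(dim(chrom_missing))) chrom_missing <- matrix(chrom_missing, nrow = 1)
  bad_chrom <- rowSums(chrom_missing) > 0
  for (r in which(bad_chrom))
    removed <- rbind(removed, data.frame(
      ril_id = panel$ril_ids[r],
      reason = paste0("missing_chromosome:",
                      paste(chroms[chrom_missing[r, ]], collapse = "+")),
      stringsAsFactors = FALSE))
  ph <- phenotypes[phenotypes$trait %in% traits &
                     !is.na(phenotypes$value), , drop = FALSE]
  has_pheno <- panel$ril_ids %in% ph$ril_id[ph$population_id == panel$population_id]
  for (r in which(!has_pheno & !bad_chrom))
    removed <- rbind(removed, data.frame(ril_id = panel$ril_ids[r],
                                         reason = "no_phenotype",
                                         stringsAsFactors = FALSE))
  keep <- !bad_chrom & has_pheno
  if (!any(keep)) stopf("all samples removed by filters")
  panel2 <- new_panel(panel$population_id, panel$ril_ids[keep], panel$map,
                      panel$geno[keep, , drop = FALSE])
  ph2 <- phenotypes[phenotypes$ril_id %in% panel2$ril_ids |
                      phenotypes$population_id != panel$population_id, ,
                    drop = FALSE]
  list(panel = panel2, phenotypes = ph2, removed = removed)
}

pair_r2 <- function(x, y) {
  if (var(x) == 0 || var(y) == 0) return(NA_real_)
  cor(x, y)^2
}

#' Windowed LD pruning (indep-pairwise style)
#'
#' Within a sliding window of `window_bp` base pairs (advanced by `step_snps`
#' markers), any marker pair with squared dosage correlation at or above
#' `r2_threshold` loses one member: the marker with the lower minor-allele
#' frequency, the later map position on ties.  A final audit pass over all
#' remaining pairs closer than `window_bp` guarantees the pruned panel
#' contains no violating pair.  Monomorphic markers have undefined r2; their
#' pairs are skipped and the markers flagged.
#'
#' @param panel an imputed `gp_panel` (no missing genotypes).
#' @param r2_threshold squared-correlation threshold (default 0.8).
#' @param window_bp window size in base pairs (default 30000).
#' @param step_snps window step in markers (default 5).
#' @return list with the pruned `panel`, `kept` marker ids in map order,
#'   `removed` marker ids, and `monomorphic` flagged marker ids.
#' @export
ld_prune <- function(panel, r2_threshold = 0.8, window_bp = 30000,
                     step_snps = 5) {
  if (anyNA(panel$geno)) stopf("ld_prune requires an imputed panel")
  map <- panel$map
  geno <- panel$geno
  maf <- pmin(colMeans(geno) / 2, 1 - colMeans(geno) / 2)
  mono <- colnames(geno)[apply(geno, 2, var) == 0]
  drop <- rep(FALSE, ncol(geno))
  names(drop) <- colnames(geno)

  prune_window <- function(ix) {
    ix <- ix[!drop[ix]]
    if (length(ix) < 2) return(invisible())
    repeat {
      live <- ix[!drop[ix]]
      if (length(live) < 2) break
      r2 <- suppressWarnings(cor(geno[, live, drop = FALSE])^2)
      r2[!is.finite(r2)] <- 0   # monomorphic pairs: undefined, skipped
      diag(r2) <- 0
      if (max(r2) < r2_threshold) break
      w <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
      a <- live[w[1]]; b <- live[w[2]]
      # drop the lower-MAF marker; later map position on ties
      victim <- if (maf[a] < maf[b]) a
                else if (maf[b] < maf[a]) b
                else max(a, b)            # later map position on ties
      drop[victim] <<- TRUE
    }
  }

  for (cc in unique(map$chrom)) {
    cix <- which(map$chrom == cc)
    starts <- cix[seq(1, length(cix), by = step_snps)]
    for (s in starts) {
      inwin <- cix[map$bp[cix] >= map$bp[s] &
                     map$bp[cix] <= map$bp[s] + window_bp]
      prune_window(inwin)
    }
    # audit pass: resolve any remaining pair within window_bp
    repeat {
      live <- cix[!drop[cix]]
      if (length(live) < 2) break
      viol <- FALSE
      for (i in seq_along(live)[-length(live)]) {
        js <- live[live > live[i] & map$bp[live] - map$bp[live[i]] <= window_bp]
        for (j in js) {
          r2 <- pair_r2(geno[, live[i]], geno[, j])
          if (!is.na(r2) && r2 >= r2_threshold) {
            a <- live[i]; b <- j
            victim <- if (maf[a] < maf[b]) a
                      else if (maf[b] < maf[a]) b
                      else max(a, b)
            drop[victim] <- TRUE
            viol <- TRUE
            break
          }
        }
        if (viol) break
      }
      if (!viol) break
    }
  }
  keep_ix <- which(!drop)
  kept <- colnames(geno)[keep_ix]
  map2 <- map[map$marker %in% kept, , drop = FALSE]
  rownames(map2) <- NULL
  class(map2) <- c("gp_map", "data.frame")
  list(panel = new_panel(panel$population_id, panel$ril_ids, map2,
                         geno[, kept, drop = FALSE]),
       kept = kept, removed = colnames(geno)[drop],
       monomorphic = mono)
}

#' Stack multi-environment records into one design
#'
#' Produces one record per (RIL, environment) with the RIL's genotype row
#' shared across its environments, plus the environment encoded as one-hot
#' columns minus the reference level (zero extra columns for a single
#' environment).
#'
#' @param panel a `gp_panel` (imputed).
#' @param phenotypes long phenotype table for one trait.
#' @param trait trait to extract (defaults to the only trait present).
#' @return a `gp_design`: list with `X` (marker matrix), `F` (environment
#'   factor columns), `y`, `ril_id`, `environment`, `map`.
#' @export
concat_environments <- function(panel, phenotypes, trait = NULL) {
  trait <- trait %||% unique(phenotypes$trait)
  if (length(trait) != 1) stopf("specify one trait")
  ph <- phenotypes[phenotypes$trait == trait &
                     phenotypes$population_id == panel$population_id &
                     phenotypes$ril_id %in% panel$ril_ids, , drop = FALSE]
  if (!nrow(ph)) stopf("no phenotype records for trait %s", trait)
  envs <- sort(unique(ph$environment))
  ph$environment <- factor(ph$environment, levels = envs)
  ph <- ph[order(ph$environment, match(ph$ril_id, panel$ril_ids)), , drop = FALSE]
  X <- panel$geno[ph$ril_id, , drop = FALSE]
  F <- if (length(envs) > 1) {
    m <- vapply(envs[-1], function(e) as.numeric(ph$environment == e),
                numeric(nrow(ph)))
    m <- matrix(m, nrow = nrow(ph),
                dimnames = list(NULL, paste0("env_", envs[-1])))
    m
  } else matrix(numeric(0), nrow(ph), 0)
  structure(list(X = X, F = F, y = ph$value, ril_id = ph$ril_id,
                 environment = as.character(ph$environment),
                 trait = trait, map = panel$map),
            class = "gp_design")
}

#' Fit per-population BLUPs and line-mean repeatability
#'
#' Two-stage fit of the one-way random-effects model with environment as a
#' fixed effect: records are adjusted by environment means, per-line means are
#' shrunken by the line-mean repeatability H2 estimated from the one-way
#' ANOVA mean squares.  BLUPs are centered at zero within each population.
#'
#' @param phenotypes long table of raw records with >= 2 environments/records
#'   per RIL.
#' @return list with `blups` (phenotype table, `kind = "BLUP"`,
#'   `environment = "combined"`) and `H2` (data.frame per population x trait).
#' @export
fit_population_blups <- function(phenotypes) {
  groups <- split(phenotypes,
                  list(phenotypes$population_id, phenotypes$trait), drop = TRUE)
  blups <- list(); h2s <- list()
  for (g in names(groups)) {
    tab <- groups[[g]]
    if (length(unique(tab$environment)) < 2)
      stopf("population %s has a single environment; use raw values",
            tab$population_id[1])
    cnt <- table(tab$ril_id)
    if (any(cnt < 2))
      stopf("every RIL needs >= 2 records for BLUP fitting (population %s)",
            tab$population_id[1])
    env_mean <- tapply(tab$value, tab$environment, mean)
    adj <- tab$value - env_mean[tab$environment]
    m <- tapply(adj, tab$ril_id, mean)
    r <- as.numeric(table(tab$ril_id)[names(m)])
    k <- length(m); N <- sum(r)
    msw <- sum((adj - m[tab$ril_id])^2) / max(1, N - k)
    r0 <- (N - sum(r^2) / N) / (k - 1)
    msb <- sum(r * (m - weighted.mean(m, r))^2) / (k - 1)
    sg2 <- max(0, (msb - msw) / r0)
    rbar <- mean(r)
    H2 <- if (sg2 + msw / rbar <= 0) 1 else sg2 / (sg2 + msw / rbar)
    blup <- H2 * (m - mean(m))
    blups[[g]] <- data.frame(ril_id = names(m),
                             population_id = tab$population_id[1],
                             environment = "combined",
                             trait = tab$trait[1], value = as.numeric(blup),
                             kind = "BLUP", stringsAsFactors = FALSE)
    h2s[[g]] <- data.frame(population_id = tab$population_id[1],
                           trait = tab$trait[1], H2 = H2,
                           sigma2_g = sg2, sigma2_e = msw,
                           stringsAsFactors = FALSE)
  }
  out_b <- do.call(rbind, blups); rownames(out_b) <- NULL
  out_h <- do.call(rbind, h2s); rownames(out_h) <- NULL
  list(blups = out_b, H2 = out_h)
}

#' Unshrink BLUPs to BLUEs using heritability
#'
#' On the centered scale, `BLUE = BLUP / H2` — the exact inverse of the BLUP
#' shrinkage factor.
#'
#' @param blups phenotype table with `kind = "BLUP"`.
#' @param H2 data.frame (population_id, trait, H2) or a single value in (0,1].
#' @export
unshrink_to_blues <- function(blups, H2) {
  if (is.numeric(H2))
    H2 <- data.frame(population_id = unique(blups$population_id),
                     trait = unique(blups$trait), H2 = H2)
  if (any(H2$H2 <= 0)) stopf("H2 must be positive to unshrink")
  key <- paste(blups$population_id, blups$trait)
  h <- setNames(H2$H2, paste(H2$population_id, H2$trait))[key]
  if (anyNA(h)) stopf("missing H2 for some population x trait")
  out <- blups
  out$value <- blups$value / h
  out$kind <- "BLUE"
  out
}
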