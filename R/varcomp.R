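# Genomic relationship matrices and the extended GBLUP variance partition:
# y = X beta + a + t + e with a ~ N(0, GA sA2), t ~ N(0, GAA sE2),
# e ~ N(0, I se2), fitted by REML (average information with EM fallback).

#' Additive genomic relationship matrix GA = W W' / n
#'
#' `W` is the column-mean-centred dosage matrix and `n` the number of
#' individuals (this /n scaling is used deliberately; it differs from the
#' 2*sum(pq) marker-count scaling of other conventions).
#'
#' @param panel a `gp_panel` (imputed) or a dosage matrix.
#' @return a symmetric n x n matrix of class `gp_kinship`, kind `"GA"`.
#' @export
compute_GA <- function(panel) {
  X <- if (inherits(panel, "gp_panel")) panel$geno else panel
  if (anyNA(X)) stopf("compute_GA requires an imputed panel")
  n <- nrow(X)
  if (n < 2) stopf("need at least 2 individuals")
  W <- sweep(X, 2, colMeans(X))
  GA <- tcrossprod(W) / n
  structure(GA, kind = "GA", class = c("gp_kinship", "matrix", "array"))
}

#' Additive-by-additive epistatic relationship matrix
#'
#' Hadamard square of GA normalised so its trace equals n:
#' `GAA = (GA * GA) / (tr(GA * GA) / n)`.
#'
#' @param GA a matrix from [compute_GA()].
#' @return a `gp_kinship` of kind `"GAA"` with trace exactly n.
#' @export
compute_GAA <- function(GA) {
  if (nrow(GA) != ncol(GA)) stopf("GA must be square")
  H <- unclass(GA) * unclass(GA)
  tr <- sum(diag(H))
  if (tr <= 0) stopf("tr(GA*GA) is zero: no additive variation")
  GAA <- H / (tr / nrow(GA))
  structure(GAA, kind = "GAA", class = c("gp_kinship", "matrix", "array"))
}

reml_loglik <- function(theta, y, X, Gs) {
  n <- length(y)
  V <- matrix(0, n, n)
  for (i in seq_along(Gs)) V <- V + theta[i] * Gs[[i]]
  V <- V + theta[length(theta)] * diag(n)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(list(ll = -Inf))
  Vi <- chol2inv(ch)
  XtVi <- crossprod(X, Vi)
  XtViX <- XtVi %*% X
  chx <- chol(XtViX)
  P <- Vi - t(XtVi) %*% chol2inv(chx) %*% XtVi
  Py <- P %*% y
  ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chx))) +
                  sum(y * Py))
  list(ll = as.numeric(ll), P = P, Py = Py, Vi = Vi, XtViX = XtViX)
}

#' Fit the extended GBLUP and partition phenotypic variance
#'
#' REML estimation of (sigma2_additive, sigma2_epistatic, sigma2_residual)
#' for the three-component Gaussian model with GA- and GAA-structured random
#' effects, by average-information updates with an EM fallback whenever an AI
#' step would leave the parameter space or decrease the restricted
#' likelihood.  Components are floored at 1e-8 (nonnegativity enforced);
#' convergence when the restricted log-likelihood changes by < 1e-6.
#'
#' @param y phenotype vector.
#' @param X fixed-effect design matrix (defaults to an intercept).
#' @param GA,GAA relationship matrices from [compute_GA()]/[compute_GAA()];
#'   `GAA = NULL` drops the epistatic term, reducing to standard GBLUP.
#' @param max_iter iteration cap.
#' @param verbose print the likelihood path.
#' @return a list of class `gp_varcomp`: `sigma2` (additive, epistatic,
#'   residual), `proportions`, `beta` (GLS fixed effects), `loglik`,
#'   `converged`, `iterations`.
#' @export
fit_extended_gblup <- function(y, X = NULL, GA, GAA = NULL, max_iter = 500,
                               verbose = FALSE) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  if (nrow(X) != n || nrow(GA) != n || (!is.null(GAA) && nrow(GAA) != n))
    stopf("dimension mismatch between y, X, GA, GAA")
  Gs <- if (is.null(GAA)) list(unclass(GA))
        else list(unclass(GA), unclass(GAA))
  comp_names <- if (is.null(GAA)) c("additive", "residual")
                else c("additive", "epistatic", "residual")
  k <- length(Gs) + 1L
  vy <- var(y)
  theta <- rep(vy / k, k)
  floor_v <- 1e-8 * max(vy, 1)
  st <- reml_loglik(theta, y, X, Gs)
  if (!is.finite(st$ll)) stopf("initial likelihood not finite")
  ll_old <- st$ll
  conv <- FALSE; it <- 0
  Glist <- c(Gs, list(diag(n)))
  for (it in seq_len(max_iter)) {
    P <- st$P; Py <- st$Py
    PG <- lapply(Glist, function(G) P %*% G)
    score <- vapply(seq_along(Glist), function(i) {
      -0.5 * (sum(diag(PG[[i]])) - sum(Py * (Glist[[i]] %*% Py)))
    }, numeric(1))
    # active-set: components pinned at the floor whose score pushes them
    # negative stay fixed this iteration (standard boundary handling)
    active <- !(theta <= 2 * floor_v & score < 0)
    if (max(abs(score[active])) < 1e-4) { conv <- TRUE; break }
    AI <- matrix(0, k, k)
    GPy <- lapply(Glist, function(G) G %*% Py)
    for (i in 1:k) for (j in i:k) {
      AI[i, j] <- AI[j, i] <- 0.5 * sum(GPy[[i]] * (P %*% GPy[[j]]))
    }
    step <- rep(0, k)
    st_try <- tryCatch(solve(AI[active, active, drop = FALSE], score[active]),
                       error = function(e) NULL)
    new_st <- NULL
    if (!is.null(st_try)) {
      # full AI step, then step-halving while it leaves the parameter space
      # or decreases the restricted likelihood
      step[active] <- st_try
      frac <- 1
      for (h in 1:8) {
        cand <- pmax(theta + frac * step, floor_v)
        try_st <- reml_loglik(cand, y, X, Gs)
        if (is.finite(try_st$ll) && try_st$ll >= ll_old - 1e-10) {
          new_st <- try_st
          theta <- cand
          break
        }
        frac <- frac / 2
      }
    }
    if (is.null(new_st)) {       # EM fallback, guaranteed ascent direction
      cand <- vapply(1:k, function(i) {
        if (!active[i]) return(theta[i])
        theta[i] + theta[i]^2 / n *
          (sum(Py * (Glist[[i]] %*% Py)) - sum(diag(P %*% Glist[[i]])))
      }, numeric(1))
      theta <- pmax(cand, floor_v)
      new_st <- reml_loglik(theta, y, X, Gs)
    }
    if (verbose) message(sprintf("iter %d logL %.6f theta %s", it, new_st$ll,
                                 paste(signif(theta, 4), collapse = " ")))
    if (!is.finite(new_st$ll))
      stopf("REML failed at iteration %d (non-finite likelihood)", it)
    done <- abs(new_st$ll - ll_old) < 1e-6
    ll_old <- new_st$ll
    st <- new_st
    if (done) { conv <- TRUE; break }
  }
  if (!conv)
    stopf("REML did not converge after %d iterations (|grad| last iterate: %s)",
          max_iter, paste(signif(theta, 4), collapse = " "))
  beta <- solve(st$XtViX, crossprod(X, st$Vi %*% y))
  sigma2 <- setNames(theta, comp_names)
  structure(list(sigma2 = sigma2, proportions = sigma2 / sum(sigma2),
                 beta = as.numeric(beta), loglik = ll_old,
                 converged = conv, iterations = it),
            class = "gp_varcomp")
}

#' Summarise variance components over populations
#'
#' In `"per_environment_then_average"` mode, per-environment proportions are
#' averaged within a population before summarising; in `"population_level"`
#' mode each population contributes one fit.  Dataset-level aggregation uses
#' the median (robust to the extreme per-population values the proportions
#' can take).
#'
#' @param fits data.frame with columns `population_id`, optional
#'   `environment`, `additive`, `epistatic`, `residual` (proportions).
#' @param mode aggregation mode.
#' @return list with `per_population` proportions and dataset `medians`.
#' @export
variance_summary <- function(fits,
                             mode = c("population_level",
                                      "per_environment_then_average")) {
  mode <- match.arg(mode)
  comp <- c("additive", "epistatic", "residual")
  per_pop <- if (mode == "per_environment_then_average") {
    agg <- aggregate(fits[comp], by = list(population_id = fits$population_id),
                     FUN = mean)
    agg
  } else fits[, c("population_id", comp)]
  medians <- vapply(comp, function(k) median(per_pop[[k]]), numeric(1))
  list(per_population = per_pop, medians = medians,
       genetic_median = median(per_pop$additive + per_pop$epistatic))
}
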