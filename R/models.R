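# The six genomic prediction models behind a uniform fit/predict contract.
# rrBLUP, BayesB and RKHS are MCMC fits (Gibbs, compiled samplers); RF, SVR
# and MLP are the machine-learning group.  Every fit is deterministic given
# (data, hyperparameters, seed).

MODEL_IDS <- c("rrBLUP", "BayesB", "RKHS", "RF", "SVR", "MLP")
MODEL_GROUPS <- c(rrBLUP = "conventional", BayesB = "conventional",
                  RKHS = "conventional", RF = "machine_learning",
                  SVR = "machine_learning", MLP = "machine_learning")

check_train <- function(X, y, F) {
  if (!is.matrix(X)) stopf("X must be a matrix")
  if (nrow(X) != length(y)) stopf("X and y dimensions differ")
  if (nrow(X) < 5) stopf("fewer than 5 training records")
  if (anyNA(X) || anyNA(y)) stopf("missing values in training data")
  if (!is.null(F) && ncol(F) > 0 && nrow(F) != nrow(X))
    stopf("F and X dimensions differ")
}

fixed_design <- function(F, n, intercept = TRUE) {
  Fd <- if (is.null(F) || ncol(F) == 0) matrix(numeric(0), n, 0) else as.matrix(F)
  if (intercept) Fd <- cbind(`(Intercept)` = rep(1, n), Fd)
  Fd
}

check_predict <- function(object, X, F) {
  if (length(object$markers) && !identical(colnames(X), object$markers))
    stopf("marker set/order of test genotypes differs from training")
  nf <- ncol(object$Ftrain %||% matrix(numeric(0), 0, 0))
  got <- if (is.null(F)) 0L else ncol(F)
  if (nf != got) stopf("fixed-effect columns differ from training (%d vs %d)",
                       nf, got)
}

#' Fit rrBLUP (Bayesian ridge regression over all markers)
#'
#' Gibbs sampler with a common normal prior on all marker effects and
#' scaled-inverse-chi-square hyperpriors on the two variances; fixed-effect
#' columns (intercept, environment factor) carry a flat prior.  Posterior-mean
#' effects are retained for prediction and allele-substitution-effect
#' extraction.  With `fix_variances = TRUE` the sampler runs at a fixed
#' variance ratio, which makes the posterior mean the closed-form ridge
#' solution (used as an oracle in the tests).
#'
#' @param X training genotype matrix (no missing values).
#' @param y training phenotypes.
#' @param F optional fixed-effect columns (e.g. environment one-hot).
#' @param n_iter,burn_in Gibbs chain length and burn-in (defaults 12000/2000).
#' @param seed integer seed.
#' @param intercept include an intercept column.
#' @param fix_variances,sigma_b2,sigma_e2 fix the variance components instead
#'   of sampling them.
#' @param df_prior,R2 hyperprior degrees of freedom and prior variance split.
#' @return a fitted model of class `gp_rrblup`.
#' @export
fit_rrblup <- function(X, y, F = NULL, n_iter = 12000, burn_in = 2000,
                       seed = 1, intercept = TRUE, fix_variances = FALSE,
                       sigma_b2 = 1, sigma_e2 = 1, df_prior = 5, R2 = 0.5) {
  check_train(X, y, F)
  Fd <- fixed_design(F, nrow(X), intercept)
  fit <- with_seed(seed, gibbs_rrblup_cpp(X, Fd, y, n_iter, burn_in,
                                          fix_variances, sigma_b2, sigma_e2,
                                          df_prior, R2))
  structure(list(model_id = "rrBLUP", beta = setNames(fit$beta, colnames(X)),
                 b = setNames(fit$b, colnames(Fd)),
                 sigma_e2 = fit$sigma_e2, sigma_b2 = fit$sigma_b2,
                 markers = colnames(X), intercept = intercept,
                 Ftrain = if (is.null(F)) matrix(numeric(0), 0, 0) else F),
            class = c("gp_rrblup", "gp_linear", "gp_model"))
}

#' Fit BayesB (point mass at zero + scaled-t slab per marker)
#'
#' Gibbs sampler where each marker is excluded with probability `pi`
#' (point mass at zero) or included with a per-marker variance drawn from a
#' scaled-inverse-chi-square (a scaled-t slab marginally).  The exclusion
#' probability carries a Beta hyperprior centred on `pi`.
#'
#' @inheritParams fit_rrblup
#' @param pi prior exclusion probability (point-mass weight), default 0.5.
#' @param beta_prior_weight prior weight (pseudo-counts) of the Beta
#'   hyperprior on the inclusion probability.
#' @param df_slab slab degrees of freedom.
#' @return a fitted model of class `gp_bayesb`.
#' @export
fit_bayesb <- function(X, y, F = NULL, n_iter = 12000, burn_in = 2000,
                       seed = 1, intercept = TRUE, pi = 0.5,
                       beta_prior_weight = 10, df_slab = 5, R2 = 0.5) {
  check_train(X, y, F)
  if (pi < 0 || pi >= 1) stopf("pi must lie in [0,1)")
  Fd <- fixed_design(F, nrow(X), intercept)
  prob_in <- min(max(1 - pi, 1e-3), 1 - 1e-4)
  fit <- with_seed(seed, gibbs_bayesb_cpp(X, Fd, y, n_iter, burn_in,
                                          prob_in, beta_prior_weight,
                                          df_slab, R2))
  structure(list(model_id = "BayesB", beta = setNames(fit$beta, colnames(X)),
                 b = setNames(fit$b, colnames(Fd)),
                 inclusion = setNames(fit$inclusion, colnames(X)),
                 markers = colnames(X), intercept = intercept,
                 Ftrain = if (is.null(F)) matrix(numeric(0), 0, 0) else F),
            class = c("gp_bayesb", "gp_linear", "gp_model"))
}

#' @export
predict.gp_linear <- function(object, X, F = NULL, ...) {
  if (nrow(X) == 0) return(numeric(0))
  check_predict(object, X, F)
  Fd <- fixed_design(F, nrow(X), object$intercept)
  as.numeric(Fd %*% object$b + X %*% object$beta)
}

cross_dist2 <- function(A, B) {
  # squared Euclidean distances between rows of A and rows of B
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

#' Fit RKHS regression (Gaussian kernel on genotype distances)
#'
#' Kernel `K_ij = exp(-d2_ij / (bandwidth * mean(d2)))` with `d2` the squared
#' Euclidean distance between genotype rows and `mean(d2)` the off-diagonal
#' mean.  The Bayesian fit runs the ridge-type Gibbs sampler on the kernel's
#' scaled eigenbasis, which makes the genetic values `u ~ N(0, sigma_u^2 K)`.
#'
#' @inheritParams fit_rrblup
#' @param bandwidth kernel bandwidth multiplier (default 1).
#' @return a fitted model of class `gp_rkhs`.
#' @export
fit_rkhs <- function(X, y, F = NULL, n_iter = 12000, burn_in = 2000,
                     bandwidth = 1, seed = 1, intercept = TRUE, R2 = 0.5) {
  check_train(X, y, F)
  D2 <- cross_dist2(X, X)
  md <- mean(D2[upper.tri(D2)])
  if (!is.finite(md) || md <= 0) stopf("degenerate kernel: all genotypes identical")
  K <- exp(-D2 / (bandwidth * md))
  eg <- eigen(K, symmetric = TRUE)
  keep <- eg$values > 1e-10
  U <- eg$vectors[, keep, drop = FALSE]
  lam <- eg$values[keep]
  B <- sweep(U, 2, sqrt(lam), "*")        # u = B alpha, alpha ~ N(0, s2 I)
  Fd <- fixed_design(F, nrow(X), intercept)
  fit <- with_seed(seed, gibbs_rrblup_cpp(B, Fd, y, n_iter, burn_in,
                                          FALSE, 1, 1, 5, R2))
  kinv_u <- U %*% (fit$beta / sqrt(lam))  # K^{-1} u, for kernel extrapolation
  structure(list(model_id = "RKHS", b = setNames(fit$b, colnames(Fd)),
                 kinv_u = kinv_u, Xtrain = X, mean_d2 = md,
                 bandwidth = bandwidth, markers = colnames(X),
                 intercept = intercept,
                 u_train = as.numeric(B %*% fit$beta),
                 Ftrain = if (is.null(F)) matrix(numeric(0), 0, 0) else F),
            class = c("gp_rkhs", "gp_model"))
}

#' @export
predict.gp_rkhs <- function(object, X, F = NULL, ...) {
  if (nrow(X) == 0) return(numeric(0))
  check_predict(object, X, F)
  D2 <- cross_dist2(X, object$Xtrain)
  Ks <- exp(-D2 / (object$bandwidth * object$mean_d2))
  Fd <- fixed_design(F, nrow(X), object$intercept)
  as.numeric(Fd %*% object$b + Ks %*% object$kinv_u)
}

#' Fit a random forest regressor
#'
#' Bagged CART regression trees grown to purity (variance-reduction splits,
#' unlimited depth) with `floor(p/3)` candidate features per split, recording
#' per-feature impurity decreases for importance and later Shapley-based
#' interaction scoring.
#'
#' @inheritParams fit_rrblup
#' @param n_trees number of trees (default 1000).
#' @param min_split minimum node size eligible for splitting.
#' @return a fitted model of class `gp_rf`.
#' @export
fit_rf <- function(X, y, F = NULL, n_trees = 1000, min_split = 5, seed = 1) {
  check_train(X, y, F)
  Z <- if (is.null(F) || ncol(F) == 0) X else cbind(X, F)
  mtry <- max(1L, floor(ncol(Z) / 3))
  fit <- build_forest_cpp(Z, y, n_trees, mtry, min_split, as.integer(seed))
  structure(list(model_id = "RF", trees = fit$trees,
                 importance = setNames(fit$importance, colnames(Z)),
                 markers = colnames(X), features = colnames(Z),
                 Ftrain = if (is.null(F)) matrix(numeric(0), 0, 0) else F),
            class = c("gp_rf", "gp_model"))
}

#' @export
predict.gp_rf <- function(object, X, F = NULL, ...) {
  if (nrow(X) == 0) return(numeric(0))
  check_predict(object, X, F)
  Z <- if (is.null(F) || ncol(F) == 0) X else cbind(X, F)
  as.numeric(predict_forest_cpp(object$trees, Z))
}

#' Fit epsilon-insensitive support vector regression (RBF kernel)
#'
#' Library-typical defaults: `C = 1`, `epsilon = 0.1`, RBF bandwidth
#' `gamma = 1 / (p * var(Z))`.  The dual is solved by cyclic coordinate
#' descent with the offset fixed at the training mean (no equality
#' constraint); a response entirely inside the epsilon tube therefore yields
#' the exactly flat predictor.
#'
#' @inheritParams fit_rrblup
#' @param C box constraint.
#' @param epsilon insensitivity-tube half width.
#' @param gamma RBF bandwidth; default `1/(p * var(Z))`.
#' @param max_passes,tol coordinate-descent control.
#' @return a fitted model of class `gp_svr`.
#' @export
fit_svr <- function(X, y, F = NULL, C = 1, epsilon = 0.1, gamma = NULL,
                    max_passes = 500, tol = 1e-6) {
  check_train(X, y, F)
  Z <- if (is.null(F) || ncol(F) == 0) X else cbind(X, F)
  vz <- var(as.numeric(Z))
  gamma <- gamma %||% (1 / (ncol(Z) * if (vz > 0) vz else 1))
  K <- exp(-gamma * cross_dist2(Z, Z))
  ym <- mean(y)
  beta <- svr_dual_cd_cpp(K, y - ym, C, epsilon, max_passes, tol)
  structure(list(model_id = "SVR", beta = as.numeric(beta), y_mean = ym,
                 Ztrain = Z, gamma = gamma, markers = colnames(X),
                 Ftrain = if (is.null(F)) matrix(numeric(0), 0, 0) else F),
            class = c("gp_svr", "gp_model"))
}

#' @export
predict.gp_svr <- function(object, X, F = NULL, ...) {
  if (nrow(X) == 0) return(numeric(0))
  check_predict(object, X, F)
  Z <- if (is.null(F) || ncol(F) == 0) X else cbind(X, F)
  Ks <- exp(-object$gamma * cross_dist2(Z, object$Ztrain))
  as.numeric(Ks %*% object$beta + object$y_mean)
}

#' Fit a single-hidden-layer ReLU multilayer perceptron
#'
#' Two dataset presets: `"teonam"` (50 hidden units, dropout 0, 200 epochs,
#' AdamW) and `"maizenam"` (10 hidden units, dropout 0.1, 2500 epochs,
#' RMSprop); both train with learning rate 0.005 and minibatches of 32.
#' Inputs are standardised to zero mean / unit variance using training-split
#' statistics only; the response is centred internally and the mean restored
#' at prediction.
#'
#' @inheritParams fit_rrblup
#' @param preset `"teonam"` or `"maizenam"`.
#' @param n_hidden,dropout,epochs,lr,optimizer,batch_size,weight_decay
#'   overrides of the preset values.
#' @return a fitted model of class `gp_mlp`.
#' @export
fit_mlp <- function(X, y, F = NULL, preset = c("teonam", "maizenam"),
                    seed = 1, n_hidden = NULL, dropout = NULL, epochs = NULL,
                    lr = 0.005, optimizer = NULL, batch_size = 32,
                    weight_decay = 0.01) {
  check_train(X, y, F)
  preset <- match.arg(preset)
  cfg <- if (preset == "teonam")
    list(n_hidden = 50, dropout = 0, epochs = 200, optimizer = "adamw")
  else list(n_hidden = 10, dropout = 0.1, epochs = 2500, optimizer = "rmsprop")
  n_hidden <- n_hidden %||% cfg$n_hidden
  dropout <- dropout %||% cfg$dropout
  epochs <- epochs %||% cfg$epochs
  optimizer <- optimizer %||% cfg$optimizer
  Z <- if (is.null(F) || ncol(F) == 0) X else cbind(X, F)
  ctr <- colMeans(Z)
  scl <- apply(Z, 2, sd); scl[scl == 0] <- 1
  Zs <- sweep(sweep(Z, 2, ctr), 2, scl, "/")
  ym <- mean(y)
  fit <- train_mlp_cpp(Zs, y - ym, n_hidden, dropout, epochs, lr, optimizer,
                       batch_size, weight_decay, as.integer(seed))
  structure(list(model_id = "MLP", W1 = fit$W1, b1 = as.numeric(fit$b1),
                 w2 = as.numeric(fit$w2), b2 = fit$b2, center = ctr,
                 scale = scl, y_mean = ym, preset = preset,
                 markers = colnames(X),
                 Ftrain = if (is.null(F)) matrix(numeric(0), 0, 0) else F),
            class = c("gp_mlp", "gp_model"))
}

#' @export
predict.gp_mlp <- function(object, X, F = NULL, ...) {
  if (nrow(X) == 0) return(numeric(0))
  check_predict(object, X, F)
  Z <- if (is.null(F) || ncol(F) == 0) X else cbind(X, F)
  Zs <- sweep(sweep(Z, 2, object$center), 2, object$scale, "/")
  as.numeric(predict_mlp_cpp(Zs, object$W1, object$b1, object$w2,
                             object$b2)) + object$y_mean
}

#' Default hyperparameters for the six models
#'
#' The `"full"` profile carries the published settings (12000/2000 MCMC,
#' 1000 trees, preset MLP epochs); the `"test"` profile shortens the MCMC to
#' 2000/500 and scales RF/MLP down for desk-scale runs.
#'
#' @param dataset `"teonam"` or `"maizenam"` (selects the MLP preset).
#' @param profile `"full"` or `"test"`.
#' @export
default_hyperparameters <- function(dataset = c("teonam", "maizenam"),
                                    profile = c("full", "test")) {
  dataset <- match.arg(dataset)
  profile <- match.arg(profile)
  mcmc <- if (profile == "full") list(n_iter = 12000, burn_in = 2000)
          else list(n_iter = 2000, burn_in = 500)
  list(
    rrBLUP = mcmc,
    BayesB = c(mcmc, list(pi = 0.5)),
    RKHS = c(mcmc, list(bandwidth = 1)),
    RF = list(n_trees = if (profile == "full") 1000 else 200),
    SVR = list(C = 1, epsilon = 0.1),
    MLP = list(preset = dataset,
               epochs = if (profile == "full") NULL
                        else if (dataset == "teonam") 100 else 150))
}

#' Fit one model by id on a training design
#'
#' @param model_id one of `rrBLUP`, `BayesB`, `RKHS`, `RF`, `SVR`, `MLP`.
#' @param X,y,F training data as in the individual `fit_*` functions.
#' @param hyper named list of hyperparameters for this model.
#' @param seed integer seed.
#' @export
fit_model <- function(model_id, X, y, F = NULL, hyper = list(), seed = 1) {
  hyper <- hyper[!vapply(hyper, is.null, logical(1))]
  args <- c(list(X = X, y = y, F = F), hyper)
  if (!model_id %in% c("SVR")) args$seed <- seed
  switch(model_id,
         rrBLUP = do.call(fit_rrblup, args),
         BayesB = do.call(fit_bayesb, args),
         RKHS = do.call(fit_rkhs, args),
         RF = do.call(fit_rf, args),
         SVR = do.call(fit_svr, args),
         MLP = do.call(fit_mlp, args),
         stopf("unknown model id: %s", model_id))
}
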