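# Bayesian Ridge Regression for whole-genome prediction:
#   y = 1 mu + X beta + e,   beta ~ N(0, sigma2_b I),   e ~ N(0, sigma2_e I)
# fitted by a Gibbs sampler with scaled-inverse-chi-square priors on both
# variance components. All marker effects share one shrinkage variance, so
# the model is the marker-effect formulation of GBLUP.

#' Sampler settings for the Bayesian Ridge Regression model
#'
#' Hyperpriors are scaled-inverse-chi-square with 5 degrees of freedom for
#' both variances; when the scales are left `NULL` they are solved at fit
#' time from a prior proportion of variance explained `R2`:
#' `scale_b = R2 * var(y) * (df_b + 2) / (df_b * sum_j var(x_j))` and
#' `scale_e = (1 - R2) * var(y) * (df_e + 2) / df_e`.
#'
#' @param n_iter total Gibbs iterations (default 45000).
#' @param burn_in discarded iterations (default 15000), so inference uses
#'   30000 post-burn-in samples; no thinning.
#' @param df_beta,df_e prior degrees of freedom.
#' @param scale_beta,scale_e prior scales; `NULL` solves them from `R2`.
#' @param R2 prior proportion of variance explained, in (0, 1).
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @return list of class `brr_model_spec`.
#' @export
brr_model_spec <- function(n_iter = 45000, burn_in = 15000,
                           df_beta = 5, scale_beta = NULL,
                           df_e = 5, scale_e = NULL,
                           R2 = 0.5, seed = NULL) {
  stopifnot(n_iter > burn_in, burn_in >= 0, R2 > 0, R2 < 1)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 df_beta = df_beta, scale_beta = scale_beta,
                 df_e = df_e, scale_e = scale_e, R2 = R2,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "brr_model_spec")
}

check_training_data <- function(y, X) {
  if (!is.matrix(X)) stop("X must be a matrix of allele dosages")
  if (length(y) != nrow(X))
    stop(sprintf("length(y) = %d does not match nrow(X) = %d",
                 length(y), nrow(X)))
  if (length(y) < 2) stop("at least two training observations are required")
  if (anyNA(X) || any(!is.finite(X)))
    stop("X contains missing or non-finite entries; impute before fitting")
  if (anyNA(y) || any(!is.finite(y)))
    stop("y contains missing or non-finite values")
  if (var(y) == 0) stop("y is constant; the model cannot be fitted")
  invisible(TRUE)
}

#' Fit the Bayesian Ridge Regression model by Gibbs sampling
#'
#' One sweep updates, in order: the intercept from its normal full
#' conditional; each marker effect from its normal full conditional with
#' single-site residual updating; `sigma2_b` from
#' scaled-inv-chisq(df_b + p, (sum(beta^2) + df_b scale_b)/(df_b + p)); and
#' `sigma2_e` likewise from the residuals. Marker columns are mean-centered
#' internally (the intercept absorbs the shift); raw 0-4 dosages are the
#' expected input. Posterior means over the post-burn-in samples are
#' returned. The same seed reproduces the fit bit-identically.
#'
#' @param y numeric phenotype vector (training individuals only).
#' @param X samples x markers dosage matrix aligned with `y`, no missing
#'   entries.
#' @param spec a [brr_model_spec()].
#' @param fixed_variances optional `c(sigma2_e =, sigma2_b =)`; when given,
#'   the variance components are held fixed and only `mu` and `beta` are
#'   sampled (used for oracle checks against closed-form ridge).
#' @param keep_beta_chain keep the post-burn-in marker-effect samples
#'   (`n_keep` x p matrix; memory-heavy for long chains).
#' @return object of class `brr_fit` with posterior means `mu_hat`,
#'   `beta_hat`, `sigma2_e`, `sigma2_b`, the variance/intercept `chains`,
#'   the training-column centers `x_center` and `marker_ids`.
#' @export
fit_brr <- function(y, X, spec = brr_model_spec(), fixed_variances = NULL,
                    keep_beta_chain = FALSE) {
  stopifnot(inherits(spec, "brr_model_spec"))
  y <- as.numeric(y)
  check_training_data(y, X)
  storage.mode(X) <- "double"
  p <- ncol(X)
  x_center <- colMeans(X)
  Xc <- sweep(X, 2, x_center)
  vy <- var(y)
  msx <- sum(colSums(Xc^2) / (nrow(X) - 1))
  if (msx == 0) msx <- 1  # all-constant X: prior scale is arbitrary
  Sb <- if (is.null(spec$scale_beta))
    spec$R2 * vy * (spec$df_beta + 2) / (spec$df_beta * msx) else spec$scale_beta
  Se <- if (is.null(spec$scale_e))
    (1 - spec$R2) * vy * (spec$df_e + 2) / spec$df_e else spec$scale_e
  fix_var <- !is.null(fixed_variances)
  if (fix_var) {
    stopifnot(all(c("sigma2_e", "sigma2_b") %in% names(fixed_variances)),
              all(fixed_variances > 0))
    s2e0 <- fixed_variances[["sigma2_e"]]
    s2b0 <- fixed_variances[["sigma2_b"]]
  } else {
    s2e0 <- (1 - spec$R2) * vy
    s2b0 <- spec$R2 * vy / msx
  }
  if (!is.null(spec$seed)) set.seed(spec$seed)
  res <- .brr_gibbs(y, Xc, spec$n_iter, spec$burn_in,
                    spec$df_beta, Sb, spec$df_e, Se,
                    mean(y), s2e0, s2b0, fix_var, keep_beta_chain)
  beta_hat <- setNames(as.numeric(res$beta_hat), colnames(X))
  structure(list(mu_hat = res$mu_hat, beta_hat = beta_hat,
                 sigma2_e = res$sigma2_e, sigma2_b = res$sigma2_b,
                 chains = data.frame(mu = res$mu_chain,
                                     sigma2_e = res$sigma2_e_chain,
                                     sigma2_b = res$sigma2_b_chain),
                 beta_chain = res$beta_chain,
                 x_center = x_center, marker_ids = colnames(X),
                 method = "gibbs", spec = spec),
            class = "brr_fit")
}

#' Closed-form marker-effect BLUP (ridge regression) at fixed variances
#'
#' The fixed-variance limit of the Bayesian Ridge model: with
#' `lambda = sigma2_e / sigma2_b`, the posterior mean of the marker effects
#' is the ridge solution
#' `beta = (Xc' Xc + lambda I)^-1 Xc' (y - ybar)` on centered markers.
#' For p > n the mathematically identical n x n form
#' `beta = Xc' (Xc Xc' + lambda I)^-1 (y - ybar)` is used. This is also the
#' marker-effect form of GBLUP with genomic relationship `Xc Xc' sigma2_b`.
#'
#' @inheritParams fit_brr
#' @param sigma2_e,sigma2_b fixed variance components (> 0).
#' @return a `brr_fit` (with `method = "blup"` and no chains).
#' @export
blup_marker_effects <- function(y, X, sigma2_e, sigma2_b) {
  y <- as.numeric(y)
  check_training_data(y, X)
  stopifnot(sigma2_e > 0, sigma2_b > 0)
  storage.mode(X) <- "double"
  x_center <- colMeans(X)
  Xc <- sweep(X, 2, x_center)
  lambda <- sigma2_e / sigma2_b
  yc <- y - mean(y)
  n <- nrow(X); p <- ncol(X)
  beta <- if (p <= n) {
    as.numeric(solve(crossprod(Xc) + diag(lambda, p), crossprod(Xc, yc)))
  } else {
    as.numeric(crossprod(Xc, solve(tcrossprod(Xc) + diag(lambda, n), yc)))
  }
  structure(list(mu_hat = mean(y), beta_hat = setNames(beta, colnames(X)),
                 sigma2_e = sigma2_e, sigma2_b = sigma2_b,
                 chains = NULL, beta_chain = NULL,
                 x_center = x_center, marker_ids = colnames(X),
                 method = "blup", spec = NULL),
            class = "brr_fit")
}

#' @export
print.brr_fit <- function(x, ...) {
  cat(sprintf("brr_fit (%s): %d markers\n", x$method, length(x$beta_hat)))
  cat(sprintf("  mu_hat = %.4f, sigma2_e = %.4f, sigma2_b = %.6g\n",
              x$mu_hat, x$sigma2_e, x$sigma2_b))
  invisible(x)
}

#' Genomic estimated breeding values for new individuals
#'
#' `gebv_i = sum_j (x_ij - center_j) * beta_hat_j (+ mu_hat)`. Columns of
#' `X_new` must match the training markers in order. Pearson prediction
#' accuracy is invariant to including the intercept.
#'
#' @param fit a `brr_fit`.
#' @param X_new samples x markers dosage matrix.
#' @param intercept add `mu_hat` to the predictions (default `TRUE`).
#' @return `data.frame` with `sample_id` and `gebv`.
#' @export
predict_gebv <- function(fit, X_new, intercept = TRUE) {
  stopifnot(inherits(fit, "brr_fit"), is.matrix(X_new))
  names_ok <- is.null(colnames(X_new)) || is.null(fit$marker_ids) ||
    identical(colnames(X_new), fit$marker_ids)
  if (ncol(X_new) != length(fit$beta_hat) || !names_ok) {
    tr <- fit$marker_ids
    nw <- colnames(X_new)
    first <- if (is.null(tr) || is.null(nw)) {
      sprintf("(unnamed; %d training vs %d new columns)",
              length(fit$beta_hat), ncol(X_new))
    } else {
      bad <- which(is.na(nw[seq_along(tr)]) | nw[seq_along(tr)] != tr)
      if (length(bad)) tr[bad[1]] else
        if (length(nw) > length(tr)) nw[length(tr) + 1] else "<missing>"
    }
    stop("marker columns of X_new do not match the training markers; ",
         "first divergence at marker ", first)
  }
  storage.mode(X_new) <- "double"
  g <- as.numeric(sweep(X_new, 2, fit$x_center) %*% fit$beta_hat)
  if (intercept) g <- g + fit$mu_hat
  data.frame(sample_id = if (is.null(rownames(X_new)))
    as.character(seq_len(nrow(X_new))) else rownames(X_new),
    gebv = g, stringsAsFactors = FALSE)
}
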