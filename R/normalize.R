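#' Build the technical covariate model matrix
#'
#' Covariates enter the NB mean model log-linearly: an intercept, log10 of the
#' per-seed total UMI count (sequencing depth), optionally the log1p-transformed
#' and standardized unspecific read count, and optionally one-hot batch
#' indicators (first level as reference).
#'
#' @param m a [seed_counts].
#' @param covariates subset of `c("depth", "unspecific", "batch")`.
#' @return Numeric model matrix, seeds x parameters.
#' @keywords internal
.covariate_matrix <- function(m, covariates) {
  n <- nrow(m$counts)
  X <- cbind(`(Intercept)` = rep(1, n))
  if ("depth" %in% covariates)
    X <- cbind(X, log10_umi = log10(m$meta$total_umis))
  if ("unspecific" %in% covariates) {
    u <- log1p(m$meta$unspecific_reads)
    s <- sd(u)
    X <- cbind(X, unspecific = if (is.na(s) || s == 0) rep(0, n) else (u - mean(u)) / s)
  }
  if ("batch" %in% covariates) {
    b <- factor(m$meta$batch)
    if (nlevels(b) < 2L) stop("batch covariate requested but <2 batches present")
    mm <- stats::model.matrix(~b)[, -1L, drop = FALSE]
    colnames(mm) <- paste0("batch_", levels(b)[-1L])
    # centered coding keeps the intercept at the average batch composition,
    # so intercepts stay comparable across genes during regularization
    mm <- scale(mm, center = TRUE, scale = FALSE)
    X <- cbind(X, mm)
  }
  X
}

# Poisson IRLS for all genes at once (shared model matrix X).
# Returns a genes x p coefficient matrix.
.poisson_irls <- function(Y, X, max_iter = 30L, tol = 1e-8) {
  n <- nrow(Y); G <- ncol(Y); p <- ncol(X)
  pairs <- which(upper.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)
  Xpair <- X[, pairs[, 1L], drop = FALSE] * X[, pairs[, 2L], drop = FALSE]
  # start from intercept-only fit at observed means, other coefficients 0
  beta <- matrix(0, p, G)
  beta[1L, ] <- log(pmax(colMeans(Y), 1e-8))
  eta <- X %*% beta
  dev_old <- rep(Inf, G)
  for (it in seq_len(max_iter)) {
    mu <- exp(eta)
    mu <- pmin(mu, 1e12)
    XtWX <- crossprod(Xpair, mu)                # p(p+1)/2 x G
    XtWz <- crossprod(X, mu * eta + Y - mu)     # p x G
    A <- matrix(0, p, p)
    for (g in seq_len(G)) {
      A[cbind(pairs[, 1L], pairs[, 2L])] <- XtWX[, g]
      A[cbind(pairs[, 2L], pairs[, 1L])] <- XtWX[, g]
      bg <- tryCatch(solve(A + diag(1e-10, p), XtWz[, g]),
                     error = function(e) beta[, g])
      beta[, g] <- bg
    }
    beta <- pmin(pmax(beta, -50), 50)
    eta <- X %*% beta
    mu <- exp(eta)
    dev <- 2 * colSums(ifelse(Y > 0, Y * log(Y / mu), 0) - (Y - mu))
    if (max(abs(dev - dev_old) / (abs(dev) + 0.1)) < tol) break
    dev_old <- dev
  }
  t(beta)
}

#' Fit per-gene negative-binomial regression models
#'
#' For each gene, counts are regressed on the technical covariates with a
#' log link: the mean model is fit by Poisson IRLS (shared across genes for
#' speed, a valid quasi-likelihood estimator of the NB mean), and the
#' dispersion theta is then estimated by maximum likelihood given the fitted
#' means ([MASS::theta.ml()]), with a method-of-moments fallback on
#' non-convergence. Near-Poisson genes get theta capped at `theta_max`.
#'
#' @param m a [seed_counts]; genes with all-zero counts must be pre-filtered.
#' @param covariates subset of `c("depth", "unspecific", "batch")`.
#' @param theta_max upper bound for the dispersion estimate.
#' @return A `gene_models` list: `beta` (genes x parameters), `theta`,
#'   `gene_mean`, the model matrix `X` and bookkeeping on fallbacks.
#' @export
fit_gene_models <- function(m, covariates = c("depth"), theta_max = 1e6) {
  stopifnot(inherits(m, "seed_counts"))
  Y <- m$counts
  if (any(colSums(Y) == 0)) stop("genes with all-zero counts must be filtered first")
  X <- .covariate_matrix(m, covariates)
  beta <- .poisson_irls(Y, X)
  dimnames(beta) <- list(colnames(Y), colnames(X))
  mu <- exp(X %*% t(beta))
  G <- ncol(Y)
  theta <- numeric(G)
  mom_fallback <- logical(G)
  # method-of-moments screen: excess Pearson variance over the Poisson part
  mom_denom <- colSums((Y - mu)^2 - mu)
  for (g in seq_len(G)) {
    if (mom_denom[g] <= 0) {
      # no excess variance: ML diverges, the gene is effectively Poisson
      theta[g] <- theta_max
      next
    }
    y <- Y[, g]; mug <- mu[, g]
    th <- tryCatch(
      suppressWarnings(as.numeric(MASS::theta.ml(y, mug, limit = 25))),
      error = function(e) NA_real_)
    if (!is.finite(th) || th <= 0) {
      th <- sum(mug^2) / mom_denom[g]
      mom_fallback[g] <- TRUE
    }
    theta[g] <- min(max(th, 1e-4), theta_max)
  }
  structure(list(beta = beta, theta = setNames(theta, colnames(Y)),
                 gene_mean = colMeans(Y), X = X,
                 covariates = covariates, mom_fallback = mom_fallback),
            class = "gene_models")
}

#' Regularize per-gene model parameters across the expression range
#'
#' Per-gene estimates are noisy at single-seed depths; each parameter
#' (coefficients and log10 dispersion) is smoothed as a function of log10
#' gene mean by local linear kernel regression (Gaussian kernel), so genes
#' borrow strength from genes of similar abundance. Local linear fitting
#' reproduces linear parameter trends exactly and avoids the boundary bias a
#' plain kernel average would impose on the most and least abundant genes.
#' Bandwidth defaults to a Sheather-Jones rule-of-thumb (times 3, so the
#' neighbourhood is dominated by well-behaved genes), falling back to
#' Silverman's rule if that fails.
#'
#' Genes whose raw dispersion deviates strongly from the local trend are
#' genuinely variable genes, not estimation noise; they are excluded as
#' *sources* of the smoothing (while still receiving regularized values), so
#' a cluster of biologically variable genes cannot drag the technical trend
#' toward itself and mask its own variability.
#'
#' @param models a [fit_gene_models()] result.
#' @param bandwidth kernel bandwidth on the log10 gene-mean axis; `NULL` for
#'   the rule-of-thumb. Values near 0 return the raw estimates.
#' @param outlier_mads how many median-absolute-deviations the log10
#'   dispersion may deviate from the first-pass trend before a gene is
#'   excluded from the second-pass fit.
#' @return A `gene_models` list with regularized `beta` and `theta`; raw
#'   values kept as `beta_raw`, `theta_raw`; excluded genes flagged in
#'   `regularization_outlier`.
#' @export
regularize_params <- function(models, bandwidth = NULL, outlier_mads = 4) {
  stopifnot(inherits(models, "gene_models"))
  G <- length(models$theta)
  if (G < 10L) stop("regularization needs at least 10 genes")
  x <- log10(models$gene_mean)
  if (is.null(bandwidth)) {
    bandwidth <- tryCatch(bw.SJ(x), error = function(e) bw.nrd0(x)) * 3
  }
  params <- cbind(models$beta, log10_theta = log10(models$theta))
  # intercept, depth slope and dispersion follow smooth trends in gene
  # abundance; batch and unspecific coefficients are gene-specific nuisance
  # parameters whose spread IS the technical effect, so they stay unsmoothed
  smooth_cols <- intersect(colnames(params),
                           c("(Intercept)", "log10_umi", "log10_theta"))
  outlier <- rep(FALSE, G)
  if (bandwidth <= 1e-8) {
    sm <- params
  } else {
    sm <- params
    fitted <- .local_linear(x, params[, smooth_cols, drop = FALSE], x, bandwidth)
    colnames(fitted) <- smooth_cols
    # second pass: drop dispersion outliers from the smoothing sources
    resid <- params[, "log10_theta"] - fitted[, "log10_theta"]
    s <- mad(resid)
    if (is.finite(s) && s > 0) {
      outlier <- abs(resid) > outlier_mads * s
      if (any(outlier) && sum(!outlier) >= 10L) {
        fitted <- .local_linear(x[!outlier],
                                params[!outlier, smooth_cols, drop = FALSE],
                                x, bandwidth)
        colnames(fitted) <- smooth_cols
      }
    }
    sm[, smooth_cols] <- fitted
  }
  dimnames(sm) <- dimnames(params)
  out <- models
  out$beta_raw <- models$beta
  out$theta_raw <- models$theta
  out$beta <- sm[, seq_len(ncol(models$beta)), drop = FALSE]
  out$theta <- setNames(10^sm[, "log10_theta"], names(models$theta))
  out$bandwidth <- bandwidth
  out$regularization_outlier <- outlier
  out
}

# local linear (degree-1) Gaussian-kernel regression of each column of
# `params` (observed at `x_src`) evaluated at `x_out`; exact for linear
# trends, so no boundary bias
.local_linear <- function(x_src, params, x_out, bandwidth, block = 1000L) {
  n_out <- length(x_out)
  sm <- matrix(0, n_out, ncol(params))
  for (i0 in seq(1L, n_out, by = block)) {
    ii <- i0:min(i0 + block - 1L, n_out)
    D <- outer(x_out[ii], x_src, "-")
    K <- exp(-0.5 * (D / bandwidth)^2)
    s0 <- rowSums(K); s1 <- rowSums(K * D); s2 <- rowSums(K * D^2)
    t0 <- K %*% params
    t1 <- (K * D) %*% params
    det <- s0 * s2 - s1^2
    est <- (s2 * t0 - s1 * t1) / det
    # degenerate neighbourhoods (det ~ 0) fall back to the kernel average
    bad <- !is.finite(det) | det < 1e-12
    if (any(bad)) est[bad, ] <- (t0 / s0)[bad, ]
    sm[ii, ] <- est
  }
  sm
}

#' Clipped Pearson residuals under the (regularized) NB models
#'
#' `r_gi = (x_gi - mu_gi) / sqrt(mu_gi + mu_gi^2 / theta_g)`, clipped to
#' `[-clip, clip]`; per-gene residual variance is the sample variance of the
#' clipped residuals. As theta grows the denominator tends to the Poisson
#' `sqrt(mu)`.
#'
#' @param m a [seed_counts].
#' @param models a `gene_models` object (typically after
#'   [regularize_params()]).
#' @param clip clipping bound; default `sqrt(n_seeds)`.
#' @return A `residual_matrix` list: `residuals` (seeds x genes),
#'   `residual_variance`, `clip`, `covariates`.
#' @export
pearson_residuals <- function(m, models, clip = NULL) {
  stopifnot(inherits(m, "seed_counts"), inherits(models, "gene_models"))
  n <- nrow(m$counts)
  if (is.null(clip)) clip <- sqrt(n)
  mu <- exp(models$X %*% t(models$beta))
  denom <- sqrt(mu + sweep(mu^2, 2L, models$theta, "/"))
  r <- (m$counts - mu) / denom
  r <- pmin(pmax(r, -clip), clip)
  dimnames(r) <- dimnames(m$counts)
  structure(list(residuals = r,
                 residual_variance = setNames(col_vars(r), colnames(r)),
                 clip = clip, covariates = models$covariates,
                 models = models),
            class = "residual_matrix")
}

#' @method print residual_matrix
#' @export
print.residual_matrix <- function(x, ...) {
  cat(sprintf("residual_matrix: %d seeds x %d genes (clip %.2f)\n",
              nrow(x$residuals), ncol(x$residuals), x$clip))
  cat(sprintf("median residual variance %.3f\n",
              median(x$residual_variance)))
  invisible(x)
}

#' One-call normalization: fit, regularize, residuals
#'
#' @param m a [seed_counts].
#' @param covariates subset of `c("depth", "unspecific", "batch")`.
#' @param bandwidth,clip passed to [regularize_params()] and
#'   [pearson_residuals()].
#' @return A `residual_matrix`.
#' @export
normalize_counts <- function(m, covariates = c("depth"), bandwidth = NULL,
                             clip = NULL) {
  models <- fit_gene_models(m, covariates)
  models <- regularize_params(models, bandwidth)
  pearson_residuals(m, models, clip)
}
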