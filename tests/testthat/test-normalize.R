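test_that("depth coefficient and dispersion are recovered for Poisson genes", {
  set.seed(4)
  n <- 400
  depth <- round(rlnorm(n, log(8000), 0.4))
  p <- runif(30, 1e-4, 2e-3)
  counts <- sapply(p, function(pg) rpois(n, pg * depth))
  colnames(counts) <- sprintf("g%02d", seq_along(p))
  rownames(counts) <- sprintf("s%03d", seq_len(n))
  m <- seed_counts(counts)
  fit <- fit_gene_models(m, covariates = "depth")
  # mu proportional to depth means a slope of ln(10) on log10(depth)
  expect_lt(median(abs(fit$beta[, "log10_umi"] - log(10))), 0.15)
  expect_gt(median(fit$theta), 1e3)  # effectively Poisson
})

test_that("constant counts at constant depth collapse to the intercept", {
  counts <- matrix(7L, 20, 12,
                   dimnames = list(sprintf("s%02d", 1:20), sprintf("g%02d", 1:12)))
  m <- seed_counts(counts)
  fit <- fit_gene_models(m, covariates = "depth")
  # identical depths leave log10(depth) constant; mu must equal the count
  mu <- exp(fit$X %*% t(fit$beta))
  expect_equal(unname(mu[1, ]), rep(7, 12), tolerance = 1e-6)
  expect_error(fit_gene_models(seed_counts(matrix(0L, 5, 2))), "all-zero")
})

test_that("NB dispersion is recovered within 20% at theta = 10", {
  set.seed(5)
  n <- 500
  depth <- round(rlnorm(n, log(10000), 0.3))
  p <- runif(150, 2e-4, 3e-3)
  counts <- sapply(p, function(pg) rnbinom(n, mu = pg * depth, size = 10))
  dimnames(counts) <- list(sprintf("s%03d", 1:n), sprintf("g%03d", seq_along(p)))
  fit <- fit_gene_models(seed_counts(counts), covariates = "depth")
  expect_lt(abs(median(fit$theta) - 10) / 10, 0.2)
})

test_that("regularization shrinks outliers and vanishes at zero bandwidth", {
  set.seed(6)
  n <- 300
  depth <- round(rlnorm(n, log(9000), 0.3))
  p <- rep(1e-3, 60)
  counts <- sapply(p, function(pg) rnbinom(n, mu = pg * depth, size = 10))
  dimnames(counts) <- list(sprintf("s%03d", 1:n), sprintf("g%03d", seq_along(p)))
  fit <- fit_gene_models(seed_counts(counts), covariates = "depth")

  reg <- regularize_params(fit, bandwidth = 0.3)
  # identical true parameters: regularized spread tightens around the truth
  expect_lt(sd(reg$beta[, "log10_umi"]), sd(fit$beta[, "log10_umi"]))

  raw <- regularize_params(fit, bandwidth = 1e-12)
  expect_equal(raw$beta, fit$beta, tolerance = 1e-10)

  # a single planted outlier coefficient is pulled toward its neighbours
  fit2 <- fit
  fit2$beta[1, "log10_umi"] <- fit$beta[1, "log10_umi"] + 5
  reg2 <- regularize_params(fit2, bandwidth = 0.3)
  expect_lt(abs(reg2$beta[1, "log10_umi"] - median(fit$beta[, "log10_umi"])),
            2.5)
  expect_error(regularize_params(fit_gene_models(
    seed_counts(matrix(rpois(40, 5), 10, 4)), covariates = "depth")),
    "at least 10")
})

test_that("Pearson residuals match the Poisson closed form as theta grows", {
  set.seed(7)
  counts <- matrix(rpois(200 * 20, 6), 200, 20,
                   dimnames = list(sprintf("s%03d", 1:200), sprintf("g%02d", 1:20)))
  m <- seed_counts(counts)
  fit <- fit_gene_models(m, covariates = "depth")
  fit$theta[] <- 1e12
  r <- pearson_residuals(m, fit)
  mu <- exp(fit$X %*% t(fit$beta))
  expect_lt(max(abs(r$residuals - (counts - mu) / sqrt(mu))), 1e-6)

  # x equal to mu gives residual zero
  fit$beta[, ] <- 0
  fit$beta[, 1] <- log(6)
  m2 <- seed_counts(matrix(6, 200, 20, dimnames = dimnames(counts)))
  r2 <- pearson_residuals(m2, fit)
  expect_equal(max(abs(r2$residuals)), 0)
})

test_that("null normalization stabilizes variance and decorrelates the mean", {
  cfg <- small_cfg(program_loading = 0, batch_effect_sd = 1e-8,
                   contaminated_gene_fraction = 0, rng_seed = 23)
  sim <- simulate_experiment(cfg)
  m <- filter_genes_mean(sim$counts, 1)
  r <- normalize_counts(m, covariates = c("depth", "unspecific"))
  rv <- r$residual_variance
  expect_gte(mean(rv > 0.5 & rv < 2), 0.95)
  expect_lt(abs(cor(r$models$gene_mean, rv, method = "spearman")), 0.1)
  expect_true(all(abs(r$residuals) <= r$clip + 1e-12))
})

test_that("the batch covariate absorbs a pure batch effect", {
  set.seed(8)
  n <- 240
  batch <- rep(c("b1", "b2"), each = n / 2)
  depth <- round(rlnorm(n, log(8000), 0.2))
  p <- runif(60, 3e-4, 3e-3)
  p[1] <- 8e-4
  counts <- sapply(seq_along(p), function(g) {
    mult <- if (g == 1) ifelse(batch == "b2", 3, 1) else 1
    rnbinom(n, mu = p[g] * depth * mult, size = 10)
  })
  dimnames(counts) <- list(sprintf("s%03d", 1:n), sprintf("g%02d", seq_along(p)))
  m <- seed_counts(counts, data.frame(batch = batch,
                                      row.names = rownames(counts)))
  with_batch <- normalize_counts(m, covariates = c("depth", "batch"))
  without <- normalize_counts(m, covariates = "depth")
  expect_lt(abs(with_batch$residual_variance["g01"] - 1), 0.35)
  expect_gt(without$residual_variance["g01"],
            with_batch$residual_variance["g01"] + 0.5)
  expect_error(normalize_counts(subset_counts(m, seeds = batch == "b1"),
                                covariates = c("depth", "batch")),
               "<2 batches")
})
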