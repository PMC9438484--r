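resmat <- function(x) {
  structure(list(residuals = x, residual_variance = col_vars_test(x),
                 clip = 99, covariates = "depth"),
            class = "residual_matrix")
}

test_that("module scores are means over present genes", {
  x <- cbind(g1 = c(1, 2, 3), g2 = c(0, 0, 0), g3 = c(-1, 1, 0))
  rownames(x) <- paste0("s", 1:3)
  r <- resmat(x)
  expect_equal(unname(module_score(r, "g1")), c(1, 2, 3), ignore_attr = TRUE)
  expect_equal(unname(module_score(r, c("g1", "g1", "g3"))),
               rowMeans(x[, c("g1", "g3")]), ignore_attr = TRUE)  # duplicates collapse
  s <- module_score(r, c("g1", "missing"))
  expect_equal(attr(s, "coverage"), 0.5)
  expect_equal(attr(s, "missing"), "missing")
  expect_error(module_score(r, "nope"), "none of the listed")
  expect_equal(unname(module_score(resmat(x * 0), c("g1", "g2", "g3"))),
               c(0, 0, 0), ignore_attr = TRUE)
})

test_that("composite signature min-max scales exactly to [-1, 1]", {
  x <- cbind(up = c(-2, 0, 2), dn = c(0, 0, 0))
  rownames(x) <- paste0("s", 1:3)
  s <- signed_gene_set("c", up = "up", down = "dn")
  sig <- composite_signature(resmat(x), s)
  expect_equal(unname(sig), c(-1, 0, 1), ignore_attr = TRUE)
  expect_equal(unname(attr(sig, "raw")), c(-2, 0, 2))

  # swapping up and down negates the raw scores
  sw <- composite_signature(resmat(x), signed_gene_set("c", up = "dn", down = "up"))
  expect_equal(attr(sw, "raw"), -attr(sig, "raw"))
  expect_equal(unname(sw), c(1, 0, -1), ignore_attr = TRUE)

  expect_warning(z <- composite_signature(resmat(x * 0), s), "degenerate")
  expect_equal(unname(z), c(0, 0, 0), ignore_attr = TRUE)
  expect_error(signed_gene_set("bad", up = "a", down = "a"), "disjoint")
  expect_error(signed_gene_set("bad", up = character(0)), "empty")
})

test_that("composite scaling anchors min and max on every non-degenerate run", {
  set.seed(14)
  for (i in 1:5) {
    x <- matrix(rnorm(40 * 10), 40, 10,
                dimnames = list(sprintf("s%02d", 1:40), sprintf("g%02d", 1:10)))
    s <- signed_gene_set("c", up = sprintf("g%02d", 1:5),
                         down = sprintf("g%02d", 6:10))
    sig <- composite_signature(resmat(x), s)
    expect_equal(min(sig), -1)
    expect_equal(max(sig), 1)
  }
})

test_that("DE tables convert to signed gene sets", {
  de <- data.frame(gene = paste0("g", 1:6),
                   log2fc = c(2, 1.5, -1, -2, 0.5, -0.5),
                   padj = c(0.01, 0.04, 0.01, 0.001, 0.5, 0.9))
  s <- signature_from_de(de)
  expect_setequal(s$up, c("g1", "g2"))
  expect_setequal(s$down, c("g3", "g4"))
  de$padj <- 1
  expect_error(signature_from_de(de), "no significant")
})

test_that("signature correlation behaves like Pearson with guards", {
  a <- c(s1 = 1, s2 = 2, s3 = 3)
  expect_equal(correlate_signatures(a, a), 1)
  expect_equal(correlate_signatures(a, -a), -1)
  expect_error(correlate_signatures(a, a[c(2, 1, 3)]), "seed sets differ")
  expect_error(correlate_signatures(a, c(s1 = 1, s2 = 1, s3 = 1)),
               "zero-variance")
})

test_that("temporal pattern clustering separates shapes and flags monotone groups", {
  set.seed(15)
  up <- matrix(rep(1:6, each = 10), 10) + rnorm(60, 0, 0.05)
  down <- -up
  flat_noise <- matrix(rnorm(60), 10, 6)
  x <- rbind(up, down, flat_noise)
  rownames(x) <- sprintf("g%02d", 1:30)
  ct <- cluster_temporal_patterns(x, k = 3)
  lab_up <- unique(ct$labels[1:10])
  lab_down <- unique(ct$labels[11:20])
  expect_length(lab_up, 1)
  expect_length(lab_down, 1)
  expect_false(lab_up == lab_down)  # mirrored shapes never share a group
  expect_equal(unname(ct$flags[lab_up]), "gradually-up")
  expect_equal(unname(ct$flags[lab_down]), "gradually-down")

  singl <- cluster_temporal_patterns(x[1:5, ], k = 5)
  expect_equal(as.integer(sort(table(singl$labels))), rep(1L, 5))
})

test_that("truth-set signatures track the latent competence", {
  sim <- simulate_experiment(small_cfg(rng_seed = 51))
  qc <- qc_filter(sim$counts)
  r <- normalize_counts(qc$counts, covariates = c("depth", "unspecific", "batch"))
  tr <- sim$truth$genes
  up <- intersect(tr$gene_id[tr$program == "group1"], colnames(r$residuals))
  dn <- intersect(tr$gene_id[tr$program == "group2"], colnames(r$residuals))
  cc <- sim$truth$seeds$latent_competence[
    match(rownames(r$residuals), sim$truth$seeds$seed_id)]
  ms <- module_score(r, up)
  expect_gte(cor(ms, cc, method = "spearman"), 0.8)
  sig <- composite_signature(r, signed_gene_set("comp", up = up, down = dn))
  expect_gte(cor(sig, cc, method = "spearman"), 0.9)
})

test_that("dog1-like contrast yields a program-polarized signed set", {
  cfg <- small_cfg(dog1_fraction = 0.5, timepoints = c("3d", "7d24h"),
                   competence_mean = c(0.3, 1.2), competence_sd = c(0.3, 0.7),
                   rng_seed = 52)
  sim <- simulate_experiment(cfg)
  qc <- qc_filter(sim$counts)
  r <- normalize_counts(qc$counts, covariates = c("depth", "unspecific", "batch"))
  geno <- factor(qc$counts$meta$genotype, levels = c("dog1", "Col0"))
  de <- wilcoxon_de(r, geno, counts = qc$counts, lfc = 0)
  s <- signature_from_de(data.frame(gene = de$gene, log2fc = de$log2fc,
                                    padj = de$padj))
  prog <- setNames(sim$truth$genes$program, sim$truth$genes$gene_id)
  genes <- colnames(r$residuals)
  in_de <- genes %in% c(s$up, s$down)
  is_g2 <- prog[genes] == "group2"
  ft <- fisher.test(table(is_g2, in_de))
  expect_lt(ft$p.value, 0.01)        # dry-seed genes enriched among DEGs
  expect_gt(sum(s$down %in% names(prog)[prog == "group2"]),
            sum(s$up %in% names(prog)[prog == "group2"]))

  # dog1 signature correlates strongly with the composite competence index
  tr <- sim$truth$genes
  comp <- composite_signature(r, signed_gene_set(
    "comp",
    up = intersect(tr$gene_id[tr$program == "group1"], genes),
    down = intersect(tr$gene_id[tr$program == "group2"], genes)))
  dog1_sig <- composite_signature(r, s)
  expect_gte(abs(correlate_signatures(dog1_sig, comp)), 0.8)
})

test_that("pool-split composite scores vary less than any biological time point", {
  cfg <- small_cfg(rng_seed = 53)
  sim <- simulate_experiment(cfg)
  qc <- qc_filter(sim$counts)
  r <- normalize_counts(qc$counts, covariates = c("depth", "unspecific", "batch"))
  tr <- sim$truth$genes
  set_ <- signed_gene_set(
    "comp",
    up = intersect(tr$gene_id[tr$program == "group1"], colnames(r$residuals)),
    down = intersect(tr$gene_id[tr$program == "group2"], colnames(r$residuals)))
  raw_bio <- attr(composite_signature(r, set_), "raw")
  tp <- qc$counts$meta$timepoint
  bio_vars <- tapply(raw_bio, tp, var)

  ps <- simulate_poolsplit(small_cfg(rng_seed = 54), n_aliquots = 48)
  rp <- normalize_counts(filter_genes_mean(ps, 1), covariates = "depth")
  set_ps <- signed_gene_set(
    "comp",
    up = intersect(set_$up, colnames(rp$residuals)),
    down = intersect(set_$down, colnames(rp$residuals)))
  raw_ps <- attr(composite_signature(rp, set_ps), "raw")
  expect_lt(var(raw_ps), min(bio_vars))
})
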