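#!/usr/bin/env Rscript
# Per-time-point variability: the HVG threshold is calibrated as the maximum
# pool-split residual variance plus one; each time point is re-normalized
# separately (gene re-selection, batch and unspecific covariates) and its
# HVGs counted. Expectation under the variance-contraction model: counts
# shrink through prolonged stress and rebound at recovery.

library(seedvar)

m <- read_counts("results/qc/filtered")
psrv <- read.delim("results/normalization/poolsplit_residual_variance.tsv")
thr <- hvg_threshold(psrv$residual_variance, margin = 1)
cat(sprintf("HVG threshold (pool-split max + 1): %.2f\n", thr))

tps <- unique(m$meta$timepoint)
hvg_table <- do.call(rbind, lapply(tps, function(tp) {
  pt <- per_timepoint_analysis(m, tp, thr)
  data.frame(timepoint = tp, n_seeds = pt$n_seeds, n_genes = pt$n_genes,
             n_hvgs = length(pt$hvgs),
             top_hvg = if (length(pt$hvgs)) pt$hvgs[1] else NA)
}))
print(hvg_table, row.names = FALSE)

# global embedding of the residuals
resid <- as.matrix(read.delim("results/normalization/residuals.tsv"))
rv <- read.delim("results/normalization/residual_variance.tsv")
r <- structure(list(residuals = resid,
                    residual_variance = setNames(rv$residual_variance, rv$gene),
                    clip = sqrt(nrow(resid)), covariates = "depth"),
               class = "residual_matrix")
emb <- pca_embed(r, n_pcs = 30)
cat(sprintf("variance explained by PC1/PC2: %.1f%% / %.1f%%\n",
            100 * emb$var_explained[1], 100 * emb$var_explained[2]))

dir.create("results/variability", showWarnings = FALSE, recursive = TRUE)
write.table(hvg_table, "results/variability/hvg_counts.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(seed_id = rownames(emb$coords), round(emb$coords, 4)),
            "results/variability/pca_coords.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote results/variability/\n")
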