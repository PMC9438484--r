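#!/usr/bin/env Rscript
# Global co-expression modules: pairwise correlations among residuals, edges
# at correlation > 0.5, highly-connected-subgraph clustering, modules with at
# least 10 genes labeled by decreasing size. Module purity against planted
# programs is reported when ground truth is available.

library(seedvar)

resid <- as.matrix(read.delim("results/normalization/residuals.tsv"))
rv <- read.delim("results/normalization/residual_variance.tsv")
r <- structure(list(residuals = resid,
                    residual_variance = setNames(rv$residual_variance, rv$gene),
                    clip = sqrt(nrow(resid)), covariates = "depth"),
               class = "residual_matrix")

mods <- find_coexpression_modules(r, threshold = 0.5, min_size = 10)
print(mods)

truth <- read.delim("results/simulation/truth_genes.tsv")
prog <- setNames(truth$program, truth$gene_id)
for (nm in names(mods$modules)) {
  tb <- sort(table(prog[mods$modules[[nm]]]), decreasing = TRUE)
  cat(sprintf("%s (n=%d, mean intra-cor %.2f): %s\n", nm,
              length(mods$modules[[nm]]), mods$mean_intra_cor[nm],
              paste(names(tb), tb, collapse = ", ")))
}

dir.create("results/modules", showWarnings = FALSE, recursive = TRUE)
membership <- do.call(rbind, lapply(names(mods$modules), function(nm)
  data.frame(module = nm, gene = mods$modules[[nm]])))
write.table(membership, "results/modules/membership.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(mods$edges, "results/modules/edges.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote results/modules/\n")
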