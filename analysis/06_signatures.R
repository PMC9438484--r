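#!/usr/bin/env Rscript
# Germination-competence signatures: the composite index is the mean residual
# of the germination-associated module minus the mean residual of the
# dry-seed module, min-max scaled to [-1, 1]. With ground truth available,
# the index is validated against the latent competence.

library(seedvar)

resid <- as.matrix(read.delim("results/normalization/residuals.tsv"))
r <- structure(list(residuals = resid, clip = sqrt(nrow(resid)),
                    residual_variance = NULL, covariates = "depth"),
               class = "residual_matrix")
membership <- read.delim("results/modules/membership.tsv")
mods <- split(membership$gene, membership$module)

sig <- composite_signature(r, signed_gene_set("competence",
                                              up = mods$Group1,
                                              down = mods$Group2))
truth <- read.delim("results/simulation/truth_seeds.tsv")
cc <- truth$latent_competence[match(names(sig), truth$seed_id)]
cat(sprintf("composite index vs latent competence: Spearman %.3f\n",
            cor(sig, cc, method = "spearman")))

g1_score <- module_score(r, mods$Group1)
g2_score <- module_score(r, mods$Group2)
cat(sprintf("Group1 vs Group2 signature correlation: %.3f (antagonistic)\n",
            correlate_signatures(as.numeric(g1_score), as.numeric(g2_score))))

meta <- read.delim("results/simulation/truth_seeds.tsv")
tp <- meta$timepoint[match(names(sig), meta$seed_id)]
cat("median composite index per time point:\n")
print(round(tapply(sig, tp, median), 3))

dir.create("results/signatures", showWarnings = FALSE, recursive = TRUE)
write.table(data.frame(seed_id = names(sig), timepoint = tp,
                       group1_score = round(as.numeric(g1_score), 4),
                       group2_score = round(as.numeric(g2_score), 4),
                       competence_index = round(as.numeric(sig), 4)),
            "results/signatures/scores.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote results/signatures/\n")
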