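#!/usr/bin/env Rscript
# Seed and gene quality filters: low-UMI seeds (<5,000), lowly expressed
# genes (<1 UMI per seed on average), and genes whose counts track the
# unspecific hotspot background (Pearson r > 0.3).

library(seedvar)

m <- read_counts("results/simulation/experiment")
qc <- qc_filter(m, min_umis = 5000, min_mean = 1, r_max = 0.3)
print(qc$report)

truth <- read.delim("results/simulation/truth_genes.tsv")
cont <- truth$gene_id[truth$program == "contaminated"]
at_stage <- setdiff(cont, qc$report$removed_genes_mean)
cat(sprintf("contaminated genes removed by the background filter: %.0f%%\n",
            100 * mean(at_stage %in% qc$report$removed_genes_background)))

dir.create("results/qc", showWarnings = FALSE, recursive = TRUE)
write_counts(qc$counts, "results/qc/filtered")
writeLines(qc$report$removed_genes_background, "results/qc/background_genes.txt")
cat("wrote results/qc/\n")
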