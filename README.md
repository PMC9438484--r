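# seedvar

Single-seed RNA-seq variability analysis for secondary-dormancy induction.

Seeds of one genotype respond non-uniformly to dormancy-inducing stress:
under identical conditions some seeds later germinate and some do not, which
population-based threshold models attribute to a normally distributed
per-seed sensitivity. `seedvar` analyses that heterogeneity at the
transcriptome level. It takes single-seed RNA-seq data — either bespoke
split-UMI paired FASTQ (21-nt R1 carrying a two-part UMI around a 6-nt seed
barcode, 55-nt R2 cDNA) or a ready seed × gene UMI count matrix — and runs
the full analysis chain:

1. **Read processing**: UMI recombination, poly(A) trimming
   (run ≥ 10 nt, post-trim length ≥ 30 nt), exact-match gene assignment with
   multimapper exclusion, per-(seed, gene) distinct-UMI counting.
2. **QC**: exclude seeds with < 5,000 UMIs and genes with < 1 UMI per seed
   on average; remove genes whose counts correlate (Pearson r > 0.3) with
   the per-seed unspecific (intergenic/organellar hotspot) read count.
3. **Normalization**: per-gene regularized negative-binomial regression on
   log10 depth, unspecific reads and batch, giving clipped Pearson residuals

   r(x) = (x − μ) / sqrt(μ + μ²/θ),  clipped to ±√n.

4. **Variability**: highly variable genes (HVGs) are genes with residual
   variance above the *maximum residual variance of any gene in a pool-split
   technical control, plus one* — the technical ceiling calibration.
5. **Co-expression modules**: gene pairs with correlation > 0.5 form a
   graph; highly connected subgraphs (min-cut > n/2, found by recursive
   minimum-cut splitting) with ≥ 10 genes become modules.
6. **Signatures**: the germination-competence index of a seed is
   mean(Group 1, germination/translation genes) − mean(Group 2, dry-seed
   storage genes) on normalized expression, min–max scaled to [−1, 1].
7. **Sub-pools & DE**: two sub-pools per time point (SNN + Louvain with a
   resolution scan), Wilcoxon rank-sum tests with BH correction
   (|log2FC| > 1 between time points, > log2(1.5) between sub-pools).

A synthetic-data generator (`simulate_experiment()`, `simulate_poolsplit()`,
`simulate_fastq()`) reproduces the study design — six time points
(1 h, 1 d, 3 d, 5 d, 7 d, 7 d + 24 h recovery) × 96 seeds in three batches,
two antagonistic gene programs driven by a latent competence whose spread
contracts under stress and expands at recovery, hotspot background
anti-correlated with genic yield, and a multinomial pool-split control —
with full ground truth, so the entire pipeline is testable offline.

## Worked example

```r
library(seedvar)

cfg <- sim_config(rng_seed = 1)          # the default study design
sim <- simulate_experiment(cfg)          # 576 seeds x 6000 genes + truth
qc  <- qc_filter(sim$counts)             # seed, gene and background filters
print(qc$report)

r <- normalize_counts(qc$counts, covariates = c("depth", "unspecific", "batch"))

# technical ceiling from an independent pool-split control
ps  <- simulate_poolsplit(sim_config(rng_seed = 99), n_aliquots = 96)
thr <- hvg_threshold(normalize_counts(filter_genes_mean(ps, 1),
                                      covariates = "depth")$residual_variance)

# co-expression modules and the competence index
mods <- find_coexpression_modules(r, threshold = 0.5, min_size = 10)
print(mods)
sig <- composite_signature(r, signed_gene_set("competence",
                                              up   = mods$modules$Group1,
                                              down = mods$modules$Group2))
cc <- sim$truth$seeds$latent_competence
cor(sig, cc[match(names(sig), sim$truth$seeds$seed_id)], method = "spearman")
```

Output from this exact script:

```
seeds: 576 -> 576 (min_umis 5000)
genes: 6000 -> 3554 (mean >= 1.00) -> 3442 (background r <= 0.30)
gene_modules: 2 modules (min size 10): 248, 99
[1] 0.9901036
```

All 576 synthetic seeds clear the 5,000-UMI cutoff at the default depth;
2,446 genes fall below 1 UMI/seed and 112 background-tracking genes are
removed by the r > 0.3 filter. The two recovered modules are the planted
germination program (248 of 250 genes) and the dry-seed program (99 of 120);
the composite index built from them ranks seeds almost exactly by their true
latent competence (Spearman 0.99). The HVG threshold calibrated on the
pool-split control lands near 2.6, and per-time-point HVG counts reproduce
the variance story: high at 1 h/1 d, near zero through late stress, maximal
at recovery.

The numbered scripts under `analysis/` run the same chain as a narrative
workflow (simulate → QC → normalize → variability → modules → signatures →
sub-pool DE), writing tables under `results/`.

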