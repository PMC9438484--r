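#' Configuration for the synthetic single-seed experiment
#'
#' Defines the study conditions the generator emulates: six time points of
#' secondary-dormancy induction (1 h imbibed control, 1/3/5/7 days of dark +
#' 30 C, and 7 days + 24 h recovery), 96 seeds per time point in three
#' technical batches, two antagonistic gene programs (Group 1,
#' germination/translation-associated; Group 2, dry-seed storage), a latent
#' per-seed germination competence whose population spread contracts under
#' prolonged stress and expands at recovery, per-seed unspecific background
#' accumulating at fixed hotspot positions and anti-correlated with genic
#' signal, and a small fraction of genes contaminated by that background.
#'
#' @param n_genes number of genes.
#' @param seeds_per_timepoint seeds per time point.
#' @param batches_per_timepoint technical batches per time point; batch labels
#'   (b1, b2, ...) are shared across time points, modelling processing runs.
#' @param timepoints time point labels, in experimental order.
#' @param program_sizes named counts for the two planted programs
#'   (`group1` germination-associated, `group2` dry-seed-associated).
#' @param competence_mean,competence_sd per-time-point mean and spread of the
#'   latent competence (variance contraction under stress, expansion at
#'   recovery).
#' @param program_loading log-scale effect of competence on Group 1 expression
#'   (Group 2 gets the negated loading).
#' @param nb_dispersion negative-binomial dispersion theta (scalar, shared
#'   across genes, or a per-gene vector of length `n_genes`).
#' @param lib_size_meanlog,lib_size_sdlog lognormal library-size parameters.
#' @param batch_effect_sd sd of gene-specific log-scale batch multipliers.
#' @param rt_shape1,rt_shape2 Beta parameters of the per-seed reverse
#'   transcription efficiency e in (0, 1]; `rt_shape2 = 0` fixes e = 1.
#' @param n_hotspots number of genomic hotspot positions collecting unspecific
#'   reads.
#' @param background_scale expected unspecific reads per seed at the mean RT
#'   efficiency; the per-seed mean is proportional to (1 - e).
#' @param contaminated_gene_fraction fraction of genes receiving additive
#'   hotspot-tied contamination.
#' @param contamination_rate expected contaminating counts per hotspot read at
#'   the gene's hotspot.
#' @param baseline_sdlog lognormal sd of baseline gene abundances.
#' @param program_baseline_quantiles baseline-abundance quantile ranges the
#'   program genes are drawn from: a list with `group1` and `group2` ranges
#'   (or one range applied to both). Translation-related mRNAs are abundant
#'   in seeds, and dry-seed storage transcripts (2S albumins, oleosins) are
#'   among the most abundant of all, hence the higher Group 2 range.
#' @param genotype_shift additive latent-competence shift of dog1-like seeds.
#' @param dog1_fraction fraction of seeds carrying the dog1-like genotype.
#' @param rng_seed integer seed; identical seeds give bit-identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 6000,
                       seeds_per_timepoint = 96,
                       batches_per_timepoint = 3,
                       timepoints = c("1h", "1d", "3d", "5d", "7d", "7d24h"),
                       program_sizes = c(group1 = 250, group2 = 120),
                       competence_mean = c(0, 0.6, 0.3, 0.2, 0.1, 1.2),
                       competence_sd = c(0.5, 0.5, 0.3, 0.2, 0.15, 0.7),
                       program_loading = 1,
                       nb_dispersion = 10,
                       lib_size_meanlog = log(20000),
                       lib_size_sdlog = 0.35,
                       batch_effect_sd = 0.1,
                       rt_shape1 = 8, rt_shape2 = 2,
                       n_hotspots = 50,
                       background_scale = 3000,
                       contaminated_gene_fraction = 0.02,
                       contamination_rate = 0.5,
                       baseline_sdlog = 1.2,
                       program_baseline_quantiles = list(
                         group1 = c(0.80, 0.999),
                         group2 = c(0.90, 0.9995)),
                       genotype_shift = 0.8,
                       dog1_fraction = 0,
                       rng_seed = NULL) {
  cfg <- as.list(environment())
  nt <- length(cfg$timepoints)
  stopifnot(cfg$n_genes >= 1, cfg$seeds_per_timepoint >= 1,
            cfg$batches_per_timepoint >= 1, nt >= 1)
  if (length(cfg$competence_mean) != nt || length(cfg$competence_sd) != nt)
    stop("competence_mean and competence_sd must match the number of time points")
  if (any(cfg$competence_sd <= 0)) stop("competence_sd must be strictly positive")
  if (any(cfg$nb_dispersion <= 0)) stop("nb_dispersion must be positive")
  if (!length(cfg$nb_dispersion) %in% c(1L, cfg$n_genes))
    stop("nb_dispersion must be scalar or per-gene")
  if (sum(cfg$program_sizes) > cfg$n_genes)
    stop("program sizes exceed n_genes")
  class(cfg) <- "sim_config"
  cfg
}

# shared gene-level setup: baseline proportions, program labels, hotspots
.sim_genes <- function(cfg) {
  G <- cfg$n_genes
  genes <- sprintf("gene%05d", seq_len(G))
  n1 <- cfg$program_sizes[["group1"]]
  n2 <- cfg$program_sizes[["group2"]]
  program <- rep("background", G)
  program[seq_len(n1)] <- "group1"
  program[n1 + seq_len(n2)] <- "group2"
  base <- rlnorm(G, 0, cfg$baseline_sdlog)
  pbq <- cfg$program_baseline_quantiles
  if (!is.list(pbq)) pbq <- list(group1 = pbq, group2 = pbq)
  for (pg in c("group1", "group2")) {
    idx <- which(program == pg)
    q <- runif(length(idx), pbq[[pg]][1], pbq[[pg]][2])
    base[idx] <- qlnorm(q, 0, cfg$baseline_sdlog)
  }
  n_cont <- floor(cfg$contaminated_gene_fraction * G)
  idx_bg <- which(program == "background")
  idx_cont <- sort(sample(idx_bg, min(n_cont, length(idx_bg))))
  program[idx_cont] <- "contaminated"
  hotspot_id <- rep(NA_integer_, G)
  if (length(idx_cont))
    hotspot_id[idx_cont] <- sample.int(cfg$n_hotspots, length(idx_cont),
                                       replace = TRUE)
  hot_w <- rgamma(cfg$n_hotspots, shape = 1)
  hot_w <- hot_w / sum(hot_w)
  list(genes = genes, program = program, base = base / sum(base),
       hotspot_id = hotspot_id, hot_w = hot_w,
       sgn = c(group1 = 1, group2 = -1, background = 0, contaminated = 0)[program])
}

# per-seed technical draws shared by generators
.sim_seed_tech <- function(cfg, n) {
  L <- rlnorm(n, cfg$lib_size_meanlog, cfg$lib_size_sdlog)
  e <- if (cfg$rt_shape2 <= 0) rep(1, n) else rbeta(n, cfg$rt_shape1, cfg$rt_shape2)
  list(L = L, e = e)
}

#' Simulate a single-seed UMI count experiment with ground truth
#'
#' Counts for seed i, gene g are negative binomial with mean
#' `mu_gi = L_i * e_i * p_g * exp(s_g * loading * c_i + b_{batch(i),g})`
#' where `p_g` are normalized baseline proportions, `s_g` is +1 for Group 1
#' genes, -1 for Group 2, 0 otherwise, `c_i` the latent competence, `L_i` the
#' library size and `e_i` the reverse-transcription efficiency. Unspecific
#' reads per seed are Poisson with mean proportional to `(1 - e_i)`, spread
#' over fixed hotspots; contaminated genes receive additional Poisson counts
#' proportional to the seed's signal at their hotspot, so genic and unspecific
#' totals are negatively related across seeds while contaminated genes track
#' the background.
#'
#' @param config a [sim_config()].
#' @return A list with class `sim_experiment`:
#'   `counts` -- a [seed_counts] whose metadata records time point, batch,
#'   genotype, total UMIs and unspecific reads;
#'   `truth` -- list with `seeds` (latent competence, RT efficiency, library
#'   size per seed) and `genes` (program label and hotspot id per gene).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ls_ <- local_seed(config$rng_seed); if (!is.null(ls_)) on.exit(ls_$restore())
  cfg <- config
  nt <- length(cfg$timepoints)
  n <- nt * cfg$seeds_per_timepoint
  G <- cfg$n_genes

  gene_info <- .sim_genes(cfg)
  tp <- rep(cfg$timepoints, each = cfg$seeds_per_timepoint)
  batch <- rep(rep(sprintf("b%d", seq_len(cfg$batches_per_timepoint)),
                   length.out = cfg$seeds_per_timepoint), nt)
  genotype <- ifelse(runif(n) < cfg$dog1_fraction, "dog1", "Col0")
  tpi <- match(tp, cfg$timepoints)
  cc <- rnorm(n, cfg$competence_mean[tpi] +
                 ifelse(genotype == "dog1", cfg$genotype_shift, 0),
              cfg$competence_sd[tpi])
  tech <- .sim_seed_tech(cfg, n)

  # gene-specific batch multipliers, shared across time points
  B <- matrix(rnorm(cfg$batches_per_timepoint * G, 0, cfg$batch_effect_sd),
              nrow = cfg$batches_per_timepoint)
  bi <- match(batch, sprintf("b%d", seq_len(cfg$batches_per_timepoint)))

  log_mu <- outer(cc * cfg$program_loading, gene_info$sgn) + B[bi, , drop = FALSE]
  log_mu <- log_mu + log(tech$L * tech$e) +
    matrix(log(gene_info$base), n, G, byrow = TRUE)
  theta <- if (length(cfg$nb_dispersion) == 1L) rep(cfg$nb_dispersion, G) else cfg$nb_dispersion
  counts <- matrix(rnbinom(n * G, mu = exp(log_mu),
                           size = rep(theta, each = n)), n, G)

  # unspecific hotspot background, anti-correlated with genic signal via e_i
  rt_mean <- if (cfg$rt_shape2 <= 0) 1 else cfg$rt_shape1 / (cfg$rt_shape1 + cfg$rt_shape2)
  u_mean <- if (rt_mean >= 1) rep(0, n) else
    cfg$background_scale * (1 - tech$e) / (1 - rt_mean)
  H <- matrix(rpois(n * cfg$n_hotspots, outer(u_mean, gene_info$hot_w)),
              n, cfg$n_hotspots)
  idx_cont <- which(gene_info$program == "contaminated")
  for (g in idx_cont) {
    counts[, g] <- counts[, g] +
      rpois(n, cfg$contamination_rate * H[, gene_info$hotspot_id[g]])
  }

  dimnames(counts) <- list(sprintf("seed%04d", seq_len(n)), gene_info$genes)
  meta <- data.frame(timepoint = tp, batch = batch, genotype = genotype,
                     unspecific_reads = rowSums(H),
                     row.names = rownames(counts))
  sc <- seed_counts(counts, meta)
  truth <- list(
    seeds = data.frame(seed_id = rownames(counts), timepoint = tp, batch = batch,
                       genotype = genotype, latent_competence = cc,
                       rt_efficiency = tech$e, lib_size = tech$L,
                       unspecific_reads = rowSums(H),
                       stringsAsFactors = FALSE),
    genes = data.frame(gene_id = gene_info$genes, program = gene_info$program,
                       hotspot_id = gene_info$hotspot_id,
                       baseline = gene_info$base, stringsAsFactors = FALSE)
  )
  structure(list(counts = sc, truth = truth, config = cfg),
            class = "sim_experiment")
}

#' Simulate a pool-split technical control
#'
#' Emulates mixing single-seed extracts of the 7-day time point and splitting
#' the pool into aliquots processed like seeds: every aliquot shares one
#' proportion vector (the mean of the simulated seed extracts) and its counts
#' are drawn multinomially at its own depth, so variation among aliquots is
#' purely technical.
#'
#' @param config a [sim_config()].
#' @param n_aliquots number of aliquots (>= 2).
#' @param timepoint which time point's competence distribution the pooled
#'   extracts are drawn from (default the second-to-last, i.e. late stress).
#' @return A [seed_counts] with `timepoint = "poolsplit"`. The shared
#'   proportion vector is attached as attribute `proportions`.
#' @export
simulate_poolsplit <- function(config, n_aliquots = 96,
                               timepoint = NULL) {
  stopifnot(inherits(config, "sim_config"), n_aliquots >= 2)
  ls_ <- local_seed(config$rng_seed); if (!is.null(ls_)) on.exit(ls_$restore())
  cfg <- config
  if (is.null(timepoint)) timepoint <- cfg$timepoints[max(1L, length(cfg$timepoints) - 1L)]
  tpi <- match(timepoint, cfg$timepoints)
  if (is.na(tpi)) stop("unknown timepoint")

  gene_info <- .sim_genes(cfg)
  # expected extract composition of the pooled seeds
  cc <- rnorm(cfg$seeds_per_timepoint, cfg$competence_mean[tpi], cfg$competence_sd[tpi])
  W <- exp(outer(cc * cfg$program_loading, gene_info$sgn))
  W <- W * matrix(gene_info$base, nrow(W), cfg$n_genes, byrow = TRUE)
  p <- colMeans(W / rowSums(W))
  p <- p / sum(p)

  tech <- .sim_seed_tech(cfg, n_aliquots)
  depth <- round(tech$L * tech$e)
  counts <- t(vapply(depth, function(d) rmultinom(1, d, p)[, 1],
                     numeric(cfg$n_genes)))
  dimnames(counts) <- list(sprintf("aliquot%03d", seq_len(n_aliquots)),
                           gene_info$genes)
  rt_mean <- if (cfg$rt_shape2 <= 0) 1 else cfg$rt_shape1 / (cfg$rt_shape1 + cfg$rt_shape2)
  u_mean <- if (rt_mean >= 1) rep(0, n_aliquots) else
    cfg$background_scale * (1 - tech$e) / (1 - rt_mean)
  meta <- data.frame(timepoint = "poolsplit", batch = "poolsplit",
                     genotype = "pool", unspecific_reads = rpois(n_aliquots, u_mean),
                     row.names = rownames(counts))
  out <- seed_counts(counts, meta)
  attr(out, "proportions") <- p
  out
}
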