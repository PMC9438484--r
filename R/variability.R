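#' Technical-control-calibrated HVG threshold
#'
#' The highly-variable-gene threshold is the maximum residual variance of any
#' gene from a pool-split technical control plus a margin (the margin-of-one
#' rule that realized a threshold of 4 on the original data).
#'
#' @param poolsplit_resvar per-gene residual variances from the pool-split
#'   control normalization.
#' @param margin added above the maximum.
#' @return The threshold (a single number).
#' @export
hvg_threshold <- function(poolsplit_resvar, margin = 1) {
  poolsplit_resvar <- poolsplit_resvar[is.finite(poolsplit_resvar)]
  if (!length(poolsplit_resvar)) stop("empty residual-variance vector")
  max(poolsplit_resvar) + margin
}

#' Call highly variable genes
#'
#' @param resvar named per-gene residual variances.
#' @param threshold genes with residual variance strictly greater than this
#'   are HVGs.
#' @return Character vector of gene ids, sorted by decreasing residual
#'   variance.
#' @export
call_hvgs <- function(resvar, threshold) {
  hv <- resvar[!is.na(resvar) & resvar > threshold]
  names(sort(hv, decreasing = TRUE))
}

#' Per-time-point variability analysis
#'
#' Subsets one time point, re-selects expressed genes (mean count across the
#' subset at least `min_mean`), normalizes with batch (and unspecific)
#' covariates removed, and calls HVGs against a pool-split-calibrated
#' threshold.
#'
#' @param m a [seed_counts] covering several time points.
#' @param timepoint the time point label to analyse.
#' @param threshold HVG threshold, usually [hvg_threshold()] on an
#'   independently normalized pool-split control.
#' @param min_mean gene re-selection cutoff (mean UMIs per seed).
#' @param covariates covariates for [normalize_counts()]; `"batch"` is dropped
#'   automatically when the subset has a single batch.
#' @return List with `residuals` (a `residual_matrix`), `hvgs`, `threshold`,
#'   `timepoint`, `n_seeds`, `n_genes`.
#' @export
per_timepoint_analysis <- function(m, timepoint, threshold,
                                   min_mean = 1,
                                   covariates = c("depth", "unspecific", "batch")) {
  stopifnot(inherits(m, "seed_counts"))
  sel <- which(m$meta$timepoint == timepoint)
  if (!length(sel)) stop("time point not present in metadata")
  if (length(sel) < 10L) stop("fewer than 10 seeds in time point")
  sub <- subset_counts(m, seeds = sel)
  if (length(unique(sub$meta$batch)) < 2L)
    covariates <- setdiff(covariates, "batch")
  if (all(sub$meta$unspecific_reads == 0))
    covariates <- setdiff(covariates, "unspecific")
  sub <- filter_genes_mean(sub, min_mean = min_mean)
  rm_ <- normalize_counts(sub, covariates = covariates)
  hv <- call_hvgs(rm_$residual_variance, threshold)
  list(residuals = rm_, hvgs = hv, threshold = threshold,
       timepoint = timepoint, n_seeds = nrow(sub$counts),
       n_genes = ncol(sub$counts))
}

#' PCA embedding of normalized residuals
#'
#' PCA on the clipped Pearson residuals, by default restricted to the 3000
#' most variable genes. Residuals are already centred by the model fit, so no
#' per-gene re-centring is applied.
#'
#' @param r a `residual_matrix`.
#' @param n_pcs number of components to return.
#' @param genes optional gene subset; default the top `max_genes` by residual
#'   variance.
#' @param max_genes size of the default feature set.
#' @return An `embedding` list: `coords` (seeds x n_pcs), `var_explained`
#'   (fraction of the total residual variance per PC, non-increasing),
#'   `genes`.
#' @export
pca_embed <- function(r, n_pcs = 30L, genes = NULL, max_genes = 3000L) {
  stopifnot(inherits(r, "residual_matrix"))
  if (is.null(genes)) {
    rv <- sort(r$residual_variance, decreasing = TRUE)
    genes <- names(rv)[seq_len(min(max_genes, length(rv)))]
  }
  x <- r$residuals[, genes, drop = FALSE]
  if (all(x == 0)) stop("degenerate all-zero residuals")
  n_pcs <- min(n_pcs, nrow(x) - 1L, ncol(x))
  pc <- prcomp(x, center = FALSE, rank. = n_pcs)
  total <- sum(x^2) / (nrow(x) - 1L)
  structure(list(coords = pc$x[, seq_len(n_pcs), drop = FALSE],
                 var_explained = pc$sdev[seq_len(n_pcs)]^2 / total,
                 genes = genes),
            class = "embedding")
}
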