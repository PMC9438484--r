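#' Remove low-quality seeds by total UMI count
#'
#' Seeds with fewer than `min_umis` total UMIs are excluded (strict `<`
#' exclusion, so a seed exactly at the cutoff is kept).
#'
#' @param m a [seed_counts].
#' @param min_umis minimum total UMIs.
#' @return Filtered [seed_counts]; removed seed ids in attribute `removed`.
#' @export
filter_seeds <- function(m, min_umis = 5000) {
  stopifnot(inherits(m, "seed_counts"))
  keep <- m$meta$total_umis >= min_umis
  if (!any(keep)) warning("no seeds pass the UMI filter")
  out <- subset_counts(m, seeds = which(keep))
  attr(out, "removed") <- rownames(m$counts)[!keep]
  out
}

#' Remove lowly expressed genes by mean count
#'
#' Genes averaging fewer than `min_mean` UMIs per retained seed are excluded
#' (strict `<` exclusion: a gene at exactly the cutoff is kept).
#'
#' @param m a [seed_counts] with at least one seed.
#' @param min_mean minimum mean UMIs per seed.
#' @return Filtered [seed_counts]; removed gene ids in attribute `removed`.
#' @export
filter_genes_mean <- function(m, min_mean = 1) {
  stopifnot(inherits(m, "seed_counts"), nrow(m$counts) >= 1L)
  keep <- colMeans(m$counts) >= min_mean
  out <- subset_counts(m, genes = which(keep))
  attr(out, "removed") <- colnames(m$counts)[!keep]
  out
}

#' Remove genes correlated with the unspecific background
#'
#' Computes, per gene, the Pearson correlation between its raw count vector
#' and the per-seed unspecific read counts, and removes genes with
#' correlation strictly above `r_max`. Unspecific reads accumulate at defined
#' hotspot positions, so genes tracking that signal are likely contaminated
#' by background rather than measuring transcription. Zero-variance genes (or
#' a zero-variance unspecific vector) get correlation 0 and are kept.
#'
#' @param m a [seed_counts] with at least 3 seeds and unspecific counts in
#'   its metadata.
#' @param r_max correlation cutoff.
#' @return List with `counts` (filtered [seed_counts]) and `report`
#'   (removed genes, correlations, threshold).
#' @export
filter_background_correlated <- function(m, r_max = 0.3) {
  stopifnot(inherits(m, "seed_counts"), nrow(m$counts) >= 3L)
  u <- m$meta$unspecific_reads
  if (sd(u) == 0) {
    rr <- setNames(rep(0, ncol(m$counts)), colnames(m$counts))
  } else {
    rr <- suppressWarnings(as.numeric(cor(m$counts, u)))
    rr[is.na(rr)] <- 0  # zero-variance genes
    rr <- setNames(rr, colnames(m$counts))
  }
  keep <- rr <= r_max
  out <- subset_counts(m, genes = which(keep))
  list(counts = out,
       report = list(removed = names(rr)[!keep], correlations = rr,
                     r_max = r_max))
}

#' Composed QC: seeds, then genes, then background correlation
#'
#' Applies the three filters in the pipeline's order -- low-UMI seeds, lowly
#' expressed genes (means computed on the retained seeds), genes correlated
#' with the unspecific background -- and reports counts in and out of every
#' stage.
#'
#' @param m a [seed_counts].
#' @param min_umis,min_mean,r_max stage cutoffs.
#' @return List with `counts` (filtered [seed_counts]) and `report`, a
#'   `filter_report` with per-stage in/out counts, removed identifiers and
#'   thresholds.
#' @export
qc_filter <- function(m, min_umis = 5000, min_mean = 1, r_max = 0.3) {
  stopifnot(inherits(m, "seed_counts"))
  st1 <- filter_seeds(m, min_umis)
  st2 <- filter_genes_mean(st1, min_mean)
  st3 <- filter_background_correlated(st2, r_max)
  report <- structure(list(
    seeds_in = nrow(m$counts), seeds_out = nrow(st1$counts),
    genes_in = ncol(m$counts),
    genes_after_mean = ncol(st2$counts),
    genes_out = ncol(st3$counts$counts),
    removed_seeds = attr(st1, "removed"),
    removed_genes_mean = attr(st2, "removed"),
    removed_genes_background = st3$report$removed,
    thresholds = list(min_umis = min_umis, min_mean = min_mean, r_max = r_max)
  ), class = "filter_report")
  list(counts = st3$counts, report = report)
}

#' @method print filter_report
#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("seeds: %d -> %d (min_umis %.0f)\n", x$seeds_in, x$seeds_out,
              x$thresholds$min_umis))
  cat(sprintf("genes: %d -> %d (mean >= %.2f) -> %d (background r <= %.2f)\n",
              x$genes_in, x$genes_after_mean, x$thresholds$min_mean,
              x$genes_out, x$thresholds$r_max))
  invisible(x)
}
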