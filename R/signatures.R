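#' Mean normalized expression of a gene set per seed
#'
#' The signature currency of the pipeline is the clipped Pearson residual;
#' the module score for a seed is the mean residual over the listed genes
#' that are present in the matrix. Duplicated gene ids are collapsed and
#' missing genes reported via attribute `missing`.
#'
#' @param expr a `residual_matrix`, or a seeds x genes numeric matrix.
#' @param genes character vector of gene ids.
#' @return Named per-seed numeric vector with attributes `coverage`
#'   (fraction of listed genes present) and `missing`.
#' @export
module_score <- function(expr, genes) {
  x <- if (inherits(expr, "residual_matrix")) expr$residuals else as.matrix(expr)
  genes <- unique(genes)
  present <- intersect(genes, colnames(x))
  if (!length(present)) stop("none of the listed genes present in the matrix")
  score <- rowMeans(x[, present, drop = FALSE])
  attr(score, "coverage") <- length(present) / length(genes)
  attr(score, "missing") <- setdiff(genes, present)
  score
}

#' A signed gene set (up-weighted and down-weighted genes)
#'
#' @param name set label.
#' @param up genes contributing with weight +1.
#' @param down genes contributing with weight -1.
#' @return A `signed_gene_set` list.
#' @export
signed_gene_set <- function(name, up, down = character(0)) {
  up <- unique(up); down <- unique(down)
  if (length(intersect(up, down))) stop("up and down sets must be disjoint")
  if (!length(c(up, down))) stop("gene set is empty")
  structure(list(name = name, up = up, down = down),
            class = "signed_gene_set")
}

#' Composite signed signature scaled to [-1, 1]
#'
#' Raw score per seed = mean normalized expression over the up set minus the
#' mean over the down set; the raw scores are then affinely min-max rescaled
#' across the scored seed set to exactly \[-1, 1\] (the germination-competence
#' index when up = germination-associated Group 1 and down =
#' dry-seed-associated Group 2). Degenerate all-equal raw scores map to 0
#' with a warning.
#'
#' @param expr a `residual_matrix` or seeds x genes matrix.
#' @param s a [signed_gene_set()].
#' @return Named per-seed numeric vector in `[-1, 1]`, with attribute `raw`
#'   (the unscaled scores).
#' @export
composite_signature <- function(expr, s) {
  stopifnot(inherits(s, "signed_gene_set"))
  up_score <- module_score(expr, s$up)
  raw <- setNames(as.numeric(up_score), names(up_score))
  if (length(s$down)) raw <- raw - as.numeric(module_score(expr, s$down))
  rng <- range(raw)
  if (diff(rng) == 0) {
    warning("degenerate raw scores (all equal); mapping to 0")
    out <- setNames(rep(0, length(raw)), names(raw))
  } else {
    out <- 2 * (raw - rng[1L]) / diff(rng) - 1
  }
  attr(out, "raw") <- raw
  out
}

#' Build a signed gene set from a differential-expression table
#'
#' Turns a DE contrast (e.g. wild type vs a dormancy mutant) into a signed
#' signature: significantly upregulated genes get weight +1, significantly
#' downregulated genes -1.
#'
#' @param de_table data.frame with columns `gene`, `log2fc` and `padj` (or
#'   column names given via arguments).
#' @param alpha FDR cutoff.
#' @param name set label.
#' @param gene_col,lfc_col,padj_col column names.
#' @return A [signed_gene_set()].
#' @export
signature_from_de <- function(de_table, alpha = 0.05, name = "de_signature",
                              gene_col = "gene", lfc_col = "log2fc",
                              padj_col = "padj") {
  sig <- de_table[[padj_col]] < alpha
  up <- de_table[[gene_col]][sig & de_table[[lfc_col]] > 0]
  down <- de_table[[gene_col]][sig & de_table[[lfc_col]] < 0]
  if (!length(up) && !length(down)) stop("no significant genes at alpha")
  signed_gene_set(name, up = up, down = down)
}

#' Pearson correlation between two per-seed signatures
#'
#' @param a,b per-seed numeric vectors over the same seed set.
#' @return The Pearson correlation coefficient.
#' @export
correlate_signatures <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3L)
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!identical(names(a), names(b))) stop("seed sets differ")
  }
  if (sd(a) == 0 || sd(b) == 0) stop("zero-variance signature")
  cor(a, b)
}

#' Cluster temporal expression patterns
#'
#' Rows (genes x time points mean profiles) are z-scaled per gene and grouped
#' by agglomerative hierarchical clustering (Euclidean distance, complete
#' linkage) cut to `k` groups. Each group is flagged `gradually-up` /
#' `gradually-down` when its mean profile is strictly monotone, `other`
#' otherwise. Constant profiles get zero z-scores and are assigned normally.
#'
#' @param mean_profiles numeric matrix, genes x time points.
#' @param k number of groups.
#' @return List with `labels` (named integer vector), `flags` (per group),
#'   `centers` (group mean scaled profiles).
#' @export
cluster_temporal_patterns <- function(mean_profiles, k = 10L) {
  x <- as.matrix(mean_profiles)
  stopifnot(nrow(x) >= k, ncol(x) >= 2L)
  z <- t(apply(x, 1L, function(v) {
    s <- sd(v)
    if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }))
  dimnames(z) <- dimnames(x)
  labels <- cutree(hclust(dist(z), method = "complete"), k = k)
  centers <- t(vapply(seq_len(k), function(g)
    colMeans(z[labels == g, , drop = FALSE]), numeric(ncol(z))))
  flags <- apply(centers, 1L, function(v) {
    d <- diff(v)
    if (all(d > 0)) "gradually-up" else if (all(d < 0)) "gradually-down" else "other"
  })
  list(labels = labels, flags = flags, centers = centers)
}
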