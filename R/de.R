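#' Split seeds of an embedding into two sub-pools
#'
#' Builds a shared-nearest-neighbour graph on the PC coordinates (Jaccard
#' weights over k-nearest-neighbour lists) and runs Louvain community
#' detection, scanning the resolution over a fixed grid until exactly two
#' communities result. If no resolution yields two communities the split
#' falls back to 2-means on the PCs (flagged in the result). Deterministic
#' given the input and `seed`.
#'
#' @param e an `embedding` from [pca_embed()], or a seeds x PCs matrix.
#' @param k_nn neighbours for the SNN graph.
#' @param n_pcs number of leading PCs used.
#' @param resolutions resolution grid scanned in order.
#' @param seed RNG seed for the community detection / fallback.
#' @return Named integer vector of labels (1/2) with attributes `method`
#'   (`"snn-louvain"` or `"kmeans"`), `resolution`, `separation` (mean
#'   silhouette width on the PCs) and `low_separation`.
#' @export
cluster_subpools <- function(e, k_nn = 20L, n_pcs = 10L,
                             resolutions = seq(0.05, 4, by = 0.05),
                             seed = 1L) {
  x <- if (inherits(e, "embedding")) e$coords else as.matrix(e)
  n <- nrow(x)
  stopifnot(n >= 4L)
  x <- x[, seq_len(min(n_pcs, ncol(x))), drop = FALSE]
  ls_ <- local_seed(seed); if (!is.null(ls_)) on.exit(ls_$restore())

  k_nn <- min(k_nn, n - 1L)
  d <- as.matrix(dist(x))
  nn <- apply(d, 1L, function(row) order(row)[2:(k_nn + 1L)])  # k_nn x n
  # SNN: Jaccard overlap of neighbour lists (self included, Seurat-style)
  inc <- matrix(0L, n, n)
  for (i in seq_len(n)) inc[i, c(i, nn[, i])] <- 1L
  shared <- tcrossprod(inc)
  jac <- shared / (2L * (k_nn + 1L) - shared)
  diag(jac) <- 0
  jac[jac < 1 / 15] <- 0  # prune weak links, standard SNN practice
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                           weighted = TRUE)
  labels <- NULL; used_res <- NA_real_; method <- "snn-louvain"
  for (res in resolutions) {
    cl <- igraph::cluster_louvain(g, resolution = res)
    memb <- igraph::membership(cl)
    if (max(memb) == 2L) { labels <- as.integer(memb); used_res <- res; break }
    if (max(memb) > 2L) break  # finer resolutions only add communities
  }
  if (is.null(labels)) {
    method <- "kmeans"
    labels <- kmeans(x, centers = 2L, nstart = 10L)$cluster
  }
  sil <- cluster::silhouette(labels, dist(x))
  sep <- mean(sil[, "sil_width"])
  structure(setNames(as.integer(labels), rownames(x)),
            method = method, resolution = used_res,
            separation = sep, low_separation = sep < 0.4)
}

#' Wilcoxon rank-sum differential expression between two groups
#'
#' Per gene, a two-sided Wilcoxon rank-sum test on normalized expression
#' (exact when both groups have at most `exact_max` seeds and no ties,
#' otherwise the normal approximation with continuity correction), with
#' Benjamini-Hochberg adjustment across tested genes. The log2 fold change
#' is computed on depth-normalized counts with a pseudo-count of 1:
#' `log2((mean_norm_A + 1) / (mean_norm_B + 1))`, where normalized counts are
#' counts per 10,000 total UMIs. A gene passes when `padj < alpha` and
#' `|log2fc| > lfc`.
#'
#' @param expr seeds x genes matrix of normalized expression (a
#'   `residual_matrix` is accepted), used for the rank-sum test.
#' @param labels two-level grouping over the seeds (first level = group A).
#' @param counts a [seed_counts] over the same seeds, used for fold changes;
#'   when `NULL` the `expr` matrix itself is used (not recommended).
#' @param alpha adjusted-p cutoff.
#' @param lfc absolute log2 fold-change cutoff (1 for time-point contrasts,
#'   `log2(1.5)` for sub-pool contrasts).
#' @param exact_max maximum per-group size for the exact test.
#' @return data.frame per gene: `log2fc`, `stat` (rank-sum W), `p`, `padj`,
#'   `pass`; group sizes and thresholds as attributes.
#' @export
wilcoxon_de <- function(expr, labels, counts = NULL, alpha = 0.05, lfc = 1,
                        exact_max = 8L) {
  x <- if (inherits(expr, "residual_matrix")) expr$residuals else as.matrix(expr)
  labels <- as.factor(labels)
  stopifnot(nlevels(labels) == 2L, length(labels) == nrow(x))
  ia <- labels == levels(labels)[1L]
  ib <- labels == levels(labels)[2L]
  if (sum(ia) < 3L || sum(ib) < 3L) stop("both groups need at least 3 seeds")

  exact <- sum(ia) <= exact_max && sum(ib) <= exact_max
  res <- apply(x, 2L, function(v) {
    wt <- suppressWarnings(wilcox.test(v[ia], v[ib], exact = exact,
                                       correct = TRUE))
    c(stat = unname(wt$statistic), p = wt$p.value)
  })
  p <- res["p", ]
  p[is.na(p)] <- 1  # constant genes: no evidence
  padj <- p.adjust(p, method = "BH")

  if (is.null(counts)) {
    cn <- x - min(x)  # shift so means are non-negative
    tot <- rowSums(cn); tot[tot == 0] <- 1
  } else {
    stopifnot(inherits(counts, "seed_counts"),
              nrow(counts$counts) == nrow(x))
    cn <- counts$counts[, colnames(x), drop = FALSE]
    tot <- counts$meta$total_umis
    tot[tot == 0] <- 1
  }
  norm <- cn / tot * 1e4
  l2fc <- log2((colMeans(norm[ia, , drop = FALSE]) + 1) /
                 (colMeans(norm[ib, , drop = FALSE]) + 1))

  out <- data.frame(gene = colnames(x), log2fc = l2fc, stat = res["stat", ],
                    p = p, padj = padj,
                    pass = padj < alpha & abs(l2fc) > lfc,
                    row.names = colnames(x), stringsAsFactors = FALSE)
  attr(out, "n_a") <- sum(ia); attr(out, "n_b") <- sum(ib)
  attr(out, "alpha") <- alpha; attr(out, "lfc") <- lfc
  attr(out, "exact") <- exact
  out
}

#' DEG counts between sequential time points
#'
#' Runs [wilcoxon_de()] between each consecutive pair of time points (on the
#' seeds of those two time points only) and counts passing genes split by
#' fold-change sign.
#'
#' @param m a [seed_counts] with `timepoint` metadata.
#' @param residuals a `residual_matrix` over the same seeds (normalized
#'   expression for the test).
#' @param order time points in experimental order (default: order of first
#'   appearance in the metadata).
#' @param alpha,lfc thresholds (the time-point preset is `lfc = 1`).
#' @return data.frame with one row per transition: `from`, `to`, `up`,
#'   `down`; the per-transition DE tables in attribute `tables`.
#' @export
sequential_timepoint_de <- function(m, residuals, order = NULL,
                                    alpha = 0.05, lfc = 1) {
  stopifnot(inherits(m, "seed_counts"))
  if (is.null(order)) order <- unique(m$meta$timepoint)
  stopifnot(length(order) >= 2L)
  x <- if (inherits(residuals, "residual_matrix")) residuals$residuals else as.matrix(residuals)
  tables <- list()
  rows <- lapply(seq_len(length(order) - 1L), function(i) {
    sel <- m$meta$timepoint %in% order[c(i, i + 1L)]
    sub <- subset_counts(m, seeds = which(sel))
    labels <- factor(sub$meta$timepoint, levels = order[c(i + 1L, i)])
    # group A = later time point, so log2fc > 0 means up during the transition
    de <- wilcoxon_de(x[sel, , drop = FALSE], labels, counts = sub,
                      alpha = alpha, lfc = lfc)
    tables[[i]] <<- de
    data.frame(from = order[i], to = order[i + 1L],
               up = sum(de$pass & de$log2fc > 0),
               down = sum(de$pass & de$log2fc < 0),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "tables") <- tables
  out
}
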