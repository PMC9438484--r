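#' Thresholded pairwise gene-gene correlations
#'
#' Pearson correlation (Spearman rank correlation by flag) for every gene pair across
#' seeds, returning the pairs whose correlation strictly exceeds the
#' threshold. Negative correlations never create edges (the threshold is
#' one-sided). Constant genes yield correlation 0 with all partners and are
#' reported.
#'
#' @param r a `residual_matrix`, or a seeds x genes numeric matrix.
#' @param genes optional gene subset.
#' @param threshold correlation cutoff (edges need cor > threshold).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return data.frame with columns `gene1`, `gene2`, `rho` (each unordered
#'   pair once); constant genes in attribute `constant_genes`.
#' @export
pairwise_correlations <- function(r, genes = NULL, threshold = 0.5,
                                  method = c("pearson", "spearman")) {
  method <- match.arg(method)
  x <- if (inherits(r, "residual_matrix")) r$residuals else as.matrix(r)
  if (!is.null(genes)) x <- x[, genes, drop = FALSE]
  stopifnot(nrow(x) >= 3L, ncol(x) >= 2L)
  const <- colnames(x)[apply(x, 2L, function(v) sd(v) == 0)]
  cc <- suppressWarnings(cor(x, method = method))
  cc[is.na(cc)] <- 0
  cc[lower.tri(cc, diag = TRUE)] <- -Inf
  hit <- which(cc > threshold, arr.ind = TRUE)
  out <- data.frame(gene1 = colnames(x)[hit[, 1L]],
                    gene2 = colnames(x)[hit[, 2L]],
                    rho = cc[hit], stringsAsFactors = FALSE)
  attr(out, "constant_genes") <- const
  attr(out, "threshold") <- threshold
  out
}

# edge list -> simple undirected igraph with lexicographically ordered vertices
.edge_graph <- function(edges) {
  verts <- sort(unique(c(edges$gene1, edges$gene2)))
  g <- igraph::graph_from_data_frame(edges[, c("gene1", "gene2")],
                                     directed = FALSE,
                                     vertices = data.frame(name = verts))
  igraph::simplify(g)
}

#' Highly-connected-subgraph clustering
#'
#' Recursive procedure per connected component: components with at most two
#' nodes are emitted as-is; otherwise the global minimum edge cut is computed
#' (unweighted edges) and, if the cut size exceeds half the node count, the
#' component is highly connected and emitted as one module; otherwise it is
#' split along the cut and both sides are processed recursively.
#'
#' @param g an `igraph` graph, or an edge data.frame as produced by
#'   [pairwise_correlations()].
#' @param method `"hcs"` (default) or `"components"` (plain connected
#'   components, for comparison).
#' @return List of character vectors (the modules, unfiltered -- including
#'   singletons and pairs).
#' @export
hcs_cluster <- function(g, method = c("hcs", "components")) {
  method <- match.arg(method)
  if (is.data.frame(g)) g <- .edge_graph(g)
  comps <- igraph::decompose(g)
  if (method == "components")
    return(lapply(comps, function(cg) sort(igraph::V(cg)$name)))
  out <- list()
  stack <- comps
  while (length(stack)) {
    cg <- stack[[1L]]
    stack <- stack[-1L]
    n <- igraph::vcount(cg)
    if (n <= 2L) {
      out[[length(out) + 1L]] <- sort(igraph::V(cg)$name)
      next
    }
    cut <- igraph::min_cut(cg, capacity = rep(1, igraph::ecount(cg)),
                           value.only = FALSE)
    if (cut$value > n / 2) {
      out[[length(out) + 1L]] <- sort(igraph::V(cg)$name)
    } else {
      p1 <- igraph::V(cg)$name[as.integer(cut$partition1)]
      p2 <- igraph::V(cg)$name[as.integer(cut$partition2)]
      sub1 <- igraph::induced_subgraph(cg, p1)
      sub2 <- igraph::induced_subgraph(cg, p2)
      # splitting can disconnect a side; recurse on its components
      stack <- c(stack, igraph::decompose(sub1), igraph::decompose(sub2))
    }
  }
  out
}

#' Filter and label gene modules by size
#'
#' Retains modules with at least `min_size` genes and relabels them by
#' decreasing size: Group1 is the largest.
#'
#' @param mods list of character vectors from [hcs_cluster()].
#' @param min_size minimum module size.
#' @return A `gene_modules` list: named `modules`, `sizes`, `min_size`.
#' @export
filter_modules <- function(mods, min_size = 10L) {
  sizes <- vapply(mods, length, integer(1))
  mods <- mods[sizes >= min_size]
  sizes <- sizes[sizes >= min_size]
  ord <- order(sizes, decreasing = TRUE)
  mods <- mods[ord]
  names(mods) <- if (length(mods)) paste0("Group", seq_along(mods)) else character(0)
  structure(list(modules = mods,
                 sizes = vapply(mods, length, integer(1)),
                 min_size = min_size),
            class = "gene_modules")
}

#' @method print gene_modules
#' @export
print.gene_modules <- function(x, ...) {
  if (!length(x$modules)) {
    cat("gene_modules: none of size >=", x$min_size, "\n")
  } else {
    cat(sprintf("gene_modules: %d modules (min size %d): %s\n",
                length(x$modules), x$min_size,
                paste(x$sizes, collapse = ", ")))
  }
  invisible(x)
}

#' Discover co-expression modules from residuals
#'
#' Convenience wrapper: thresholded pairwise correlations, HCS clustering of
#' the correlation graph, size filter, and per-module mean intra-module
#' correlation.
#'
#' @param r a `residual_matrix` (or seeds x genes matrix).
#' @param genes optional gene subset.
#' @param threshold correlation threshold for edges.
#' @param min_size minimum module size.
#' @param method clustering method, see [hcs_cluster()].
#' @param cor_method correlation flavor, see [pairwise_correlations()].
#' @return A `gene_modules` with an extra `mean_intra_cor` element.
#' @export
find_coexpression_modules <- function(r, genes = NULL, threshold = 0.5,
                                      min_size = 10L,
                                      method = c("hcs", "components"),
                                      cor_method = c("pearson", "spearman")) {
  edges <- pairwise_correlations(r, genes = genes, threshold = threshold,
                                 method = match.arg(cor_method))
  if (!nrow(edges)) {
    return(structure(list(modules = setNames(list(), character(0)),
                          sizes = integer(0), min_size = min_size,
                          mean_intra_cor = numeric(0)),
                     class = "gene_modules"))
  }
  mods <- filter_modules(hcs_cluster(edges, method = match.arg(method)),
                         min_size = min_size)
  mods$mean_intra_cor <- vapply(mods$modules, function(gs) {
    inside <- edges$gene1 %in% gs & edges$gene2 %in% gs
    if (any(inside)) mean(edges$rho[inside]) else NA_real_
  }, numeric(1))
  mods$edges <- edges
  mods
}
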