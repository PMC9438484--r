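#' Seed-by-gene UMI count matrix with per-seed metadata
#'
#' Lightweight container for deduplicated UMI counts. Rows are seeds, columns
#' are genes (the orientation used throughout the package). The metadata keeps
#' the technical covariates the normalization needs: total UMIs, unspecific
#' (intergenic/organellar hotspot) read counts, time point, batch and genotype.
#'
#' @param counts numeric matrix, seeds x genes, non-negative integers; row and
#'   column names are the seed and gene identifiers.
#' @param meta data.frame with one row per seed. Columns `total_umis` and
#'   `unspecific_reads` are filled in (recomputed / zero) when absent;
#'   `timepoint`, `batch`, `genotype` are optional labels.
#' @return An object of class `seed_counts`: a list with elements `counts` and
#'   `meta`.
#' @export
seed_counts <- function(counts, meta = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("seed%04d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("gene%05d", seq_len(ncol(counts)))
  if (anyDuplicated(rownames(counts))) stop("seed identifiers must be unique")
  if (anyDuplicated(colnames(counts))) stop("gene identifiers must be unique")
  if (is.null(meta)) meta <- data.frame(row.names = rownames(counts))
  if (!is.data.frame(meta) || nrow(meta) != nrow(counts))
    stop("meta must be a data.frame with one row per seed")
  rownames(meta) <- rownames(counts)
  meta$total_umis <- as.numeric(rowSums(counts))
  if (is.null(meta$unspecific_reads)) meta$unspecific_reads <- 0
  structure(list(counts = counts, meta = meta), class = "seed_counts")
}

#' @method print seed_counts
#' @export
print.seed_counts <- function(x, ...) {
  cat(sprintf("seed_counts: %d seeds x %d genes\n", nrow(x$counts), ncol(x$counts)))
  if (!is.null(x$meta$timepoint))
    cat("time points:", paste(names(table(x$meta$timepoint)), collapse = ", "), "\n")
  cat(sprintf("median total UMIs %.0f, median unspecific %.0f\n",
              median(x$meta$total_umis), median(x$meta$unspecific_reads)))
  invisible(x)
}

#' @export
dim.seed_counts <- function(x) dim(x$counts)

#' Subset a seed_counts object by seeds and/or genes
#'
#' @param x a [seed_counts] object.
#' @param seeds,genes character, logical or integer index into rows/columns.
#' @return A `seed_counts` with `total_umis` recomputed on the retained genes
#'   only when `genes` is given (so the depth covariate always reflects the
#'   matrix actually analysed).
#' @export
subset_counts <- function(x, seeds = NULL, genes = NULL) {
  stopifnot(inherits(x, "seed_counts"))
  counts <- x$counts
  meta <- x$meta
  if (!is.null(seeds)) {
    counts <- counts[seeds, , drop = FALSE]
    meta <- meta[seeds, , drop = FALSE]
  }
  if (!is.null(genes)) counts <- counts[, genes, drop = FALSE]
  out <- seed_counts(counts, meta)
  # seed_counts() recomputes total_umis from the retained genes
  out
}

#' Write / read a seed_counts object as MTX + TSV sidecars
#'
#' `write_counts()` writes `counts.mtx` (MatrixMarket, genes x seeds as is
#' conventional for expression matrices on disk), `genes.tsv`, `seeds.tsv`
#' (identifier per line) and `meta.tsv`. `read_counts()` reads them back.
#'
#' @param x a [seed_counts] object.
#' @param dir output / input directory.
#' @return `write_counts()` the directory, invisibly; `read_counts()` a
#'   [seed_counts] object.
#' @export
write_counts <- function(x, dir) {
  stopifnot(inherits(x, "seed_counts"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(t(x$counts), sparse = TRUE),
                  file.path(dir, "counts.mtx"))
  writeLines(colnames(x$counts), file.path(dir, "genes.tsv"))
  writeLines(rownames(x$counts), file.path(dir, "seeds.tsv"))
  write.table(data.frame(seed_id = rownames(x$meta), x$meta),
              file.path(dir, "meta.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_counts
#' @export
read_counts <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "counts.mtx")))
  genes <- readLines(file.path(dir, "genes.tsv"))
  seeds <- readLines(file.path(dir, "seeds.tsv"))
  counts <- t(m)
  dimnames(counts) <- list(seeds, genes)
  meta <- read.delim(file.path(dir, "meta.tsv"), stringsAsFactors = FALSE)
  rownames(meta) <- meta$seed_id
  meta$seed_id <- NULL
  seed_counts(counts, meta[seeds, , drop = FALSE])
}
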