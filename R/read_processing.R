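#' Recombine the split UMI from an R1 read
#'
#' The library's R1 carries the UMI in two segments flanking the 6-nt seed
#' barcode: positions 1-9 (first UMI part), 10-15 (barcode), 16-20 (second
#' UMI part); the 21st base is a filler and ignored. The canonical 14-nt UMI
#' is the second part followed by the first, i.e. the result of moving
#' `r1[16..20]` in front of `r1[1..15]` and reading 14 UMI bases then 6
#' barcode bases.
#'
#' @param r1 character vector of R1 sequences.
#' @return A data.frame with columns `barcode` (6 nt) and `umi` (14 nt), one
#'   row per read of length >= 20; shorter reads are dropped and their number
#'   recorded in attribute `n_discarded`.
#' @export
rearrange_r1 <- function(r1) {
  len <- nchar(r1)
  keep <- len >= 20L
  r1 <- r1[keep]
  out <- data.frame(barcode = substr(r1, 10L, 15L),
                    umi = paste0(substr(r1, 16L, 20L), substr(r1, 1L, 9L)),
                    stringsAsFactors = FALSE)
  attr(out, "n_discarded") <- sum(!keep)
  out
}

#' Trim terminal poly(A) runs from cDNA reads
#'
#' Removes the whole terminal run of 'A' when it is at least `min_run` long
#' (oligo-dT priming reads through into the poly(A) tail); reads whose trimmed
#' length falls below `min_len` are discarded (returned as `NA`). Reads with a
#' shorter terminal run are returned unchanged.
#'
#' @param r2 character vector of R2 sequences.
#' @param min_run minimum terminal A-run length that triggers trimming.
#' @param min_len minimum post-trim length to keep a read.
#' @return Character vector of the same length; `NA` marks discarded reads.
#' @export
trim_polya <- function(r2, min_run = 10L, min_len = 30L) {
  m <- regexpr("A+$", r2)
  run <- ifelse(m > 0L, attr(m, "match.length"), 0L)
  len <- nchar(r2)
  trim <- run >= min_run
  out <- ifelse(trim, substr(r2, 1L, len - run), r2)
  out[trim & (len - run) < min_len] <- NA_character_
  out
}

#' Build an exact-match transcript index for gene assignment
#'
#' Indexes every k-mer of the transcript 3'-end sequences. A k-mer present in
#' more than one gene is ambiguous and removed, so reads starting with it are
#' multimappers and stay unassigned (mirroring a unique-mapping-only aligner
#' setting). Assignment verifies the full read against the transcript at the
#' indexed position, so only exact substrings are assigned.
#'
#' @param transcripts named character vector of transcript sequences, a
#'   `DNAStringSet`, or the path to a FASTA file.
#' @param k k-mer length (reads shorter than `k` cannot be assigned).
#' @return A `transcript_index` list.
#' @export
build_transcript_index <- function(transcripts, k = 25L) {
  if (is.character(transcripts) && length(transcripts) == 1L &&
      file.exists(transcripts))
    transcripts <- Biostrings::readDNAStringSet(transcripts)
  if (methods::is(transcripts, "DNAStringSet"))
    transcripts <- setNames(as.character(transcripts), names(transcripts))
  if (is.null(names(transcripts))) stop("transcripts must be named")
  lens <- nchar(transcripts)
  if (any(lens < k)) stop("all transcripts must be at least k nt long")
  km <- lapply(seq_along(transcripts), function(i) {
    st <- seq_len(lens[i] - k + 1L)
    data.frame(kmer = substring(transcripts[i], st, st + k - 1L),
               gene = names(transcripts)[i], pos = st,
               stringsAsFactors = FALSE)
  })
  km <- do.call(rbind, km)
  # a k-mer seen in >1 gene is ambiguous; within-gene repeats keep the first hit
  first <- !duplicated(km$kmer)
  multi_gene <- names(which(table(unique(km[, c("kmer", "gene")])$kmer) > 1L))
  keep <- first & !(km$kmer %in% multi_gene)
  structure(list(kmers = km$kmer[keep], gene = km$gene[keep],
                 pos = km$pos[keep], seqs = transcripts, k = k),
            class = "transcript_index")
}

#' Assign reads to genes by exact transcript match
#'
#' @param r2 character vector of (trimmed) cDNA reads.
#' @param index a [build_transcript_index()] object.
#' @return Character vector of gene ids; `NA` for unassigned reads
#'   (no match, ambiguous/multimapping k-mer, or read shorter than `k`).
#' @export
assign_gene <- function(r2, index) {
  stopifnot(inherits(index, "transcript_index"))
  out <- rep(NA_character_, length(r2))
  ok <- !is.na(r2) & nchar(r2) >= index$k
  if (!any(ok)) return(out)
  i <- match(substr(r2[ok], 1L, index$k), index$kmers)
  hit <- !is.na(i)
  idx <- which(ok)[hit]
  gi <- index$gene[i[hit]]
  pos <- index$pos[i[hit]]
  full <- substr(index$seqs[gi], pos, pos + nchar(r2[idx]) - 1L)
  match_ok <- full == r2[idx]
  out[idx[match_ok]] <- gi[match_ok]
  out
}

#' Deduplicate UMIs into a seed-by-gene count matrix
#'
#' The count for a (seed, gene) pair is the number of distinct UMI sequences
#' observed for it (exact-match collapse; the dedup key is barcode + gene +
#' UMI, so the same UMI under two genes counts once for each). Reads whose
#' barcode is not in the whitelist are excluded and counted in attribute
#' `n_nonwhitelist`.
#'
#' @param records data.frame with columns `barcode`, `umi`, `gene` (rows with
#'   `NA` gene are ignored).
#' @param whitelist data.frame with columns `barcode`, `seed_id`, or a named
#'   character vector mapping barcode to seed id.
#' @param genes optional gene universe for the matrix columns (default: genes
#'   observed in `records`).
#' @return Integer matrix, whitelist seeds x genes, with attribute
#'   `n_nonwhitelist`.
#' @export
count_umis <- function(records, whitelist, genes = NULL) {
  wl <- .as_whitelist(whitelist)
  records <- records[!is.na(records$gene), , drop = FALSE]
  seed <- wl[records$barcode]
  n_nonwl <- sum(is.na(seed))
  records <- records[!is.na(seed), , drop = FALSE]
  seed <- seed[!is.na(seed)]
  if (is.null(genes)) genes <- sort(unique(records$gene))
  key <- paste(seed, records$gene, records$umi, sep = "\r")
  first <- !duplicated(key)
  seeds_all <- unname(wl)
  counts <- table(factor(seed[first], levels = seeds_all),
                  factor(records$gene[first], levels = genes))
  counts <- matrix(as.integer(counts), nrow = length(seeds_all),
                   dimnames = list(seeds_all, genes))
  attr(counts, "n_nonwhitelist") <- n_nonwl
  counts
}

.as_whitelist <- function(whitelist) {
  if (is.data.frame(whitelist)) {
    wl <- setNames(as.character(whitelist$seed_id), whitelist$barcode)
  } else wl <- whitelist
  if (anyDuplicated(names(wl))) stop("whitelist barcodes must be unique")
  if (any(nchar(names(wl)) != 6L)) stop("whitelist barcodes must be 6 nt")
  wl
}

#' Tally unspecific (non-genic) reads per seed
#'
#' @param records data.frame with columns `barcode` and `label` (`"genic"` or
#'   `"unspecific"`); in synthetic data the label travels in the read name,
#'   for real data it comes from a user-supplied read classification.
#' @param whitelist as in [count_umis()].
#' @return Named integer vector of unspecific read counts, one per whitelist
#'   seed.
#' @export
tally_unspecific <- function(records, whitelist) {
  wl <- .as_whitelist(whitelist)
  seed <- wl[records$barcode]
  keep <- !is.na(seed) & records$label == "unspecific"
  tab <- table(factor(seed[keep], levels = unname(wl)))
  setNames(as.integer(tab), names(tab))
}

#' Process paired split-UMI FASTQ files into a seed_counts matrix
#'
#' End-to-end demultiplexing: recombines the split UMI from R1, trims terminal
#' poly(A) from R2 (discarding reads shorter than `min_len` after trimming),
#' assigns genes by exact transcript match, deduplicates UMIs per (seed, gene)
#' and tallies unspecific reads (reads whose name carries the `:us` label, as
#' written by [simulate_fastq()], or classified via `classification`).
#'
#' @param r1_path,r2_path paths to the (optionally gzipped) FASTQ files.
#' @param whitelist barcode-to-seed mapping (data.frame, named vector, or path
#'   to a two-column TSV `barcode<TAB>seed_id`).
#' @param index a [build_transcript_index()] object or path to the transcript
#'   FASTA.
#' @param min_run,min_len poly(A) trimming parameters, see [trim_polya()].
#' @param classification optional data.frame (`read_id`, `gene_or_label`) used
#'   instead of the index for real data: values are gene ids or
#'   `"unspecific"`.
#' @return A [seed_counts] whose metadata records per-seed total UMIs and
#'   unspecific read counts; processing tallies (discarded, unassigned,
#'   non-whitelist reads) are attached as attribute `report`.
#' @export
process_fastq <- function(r1_path, r2_path, whitelist, index,
                          min_run = 10L, min_len = 30L,
                          classification = NULL) {
  if (is.character(whitelist) && length(whitelist) == 1L && file.exists(whitelist))
    whitelist <- read.delim(whitelist, stringsAsFactors = FALSE)
  wl <- .as_whitelist(whitelist)
  if (!inherits(index, "transcript_index")) index <- build_transcript_index(index)

  r1 <- Biostrings::readDNAStringSet(r1_path, format = "fastq")
  r2 <- Biostrings::readDNAStringSet(r2_path, format = "fastq")
  stopifnot(length(r1) == length(r2))
  ids <- sub(" .*", "", names(r1))
  r1 <- as.character(r1); r2 <- as.character(r2)

  short <- nchar(r1) < 20L
  bcumi <- rearrange_r1(r1[!short])
  r2 <- r2[!short]; ids <- ids[!short]

  label <- ifelse(grepl(":us$", ids), "unspecific", "genic")
  if (!is.null(classification)) {
    cl <- setNames(classification[[2L]], classification[[1L]])
    label <- ifelse(unname(cl[ids]) == "unspecific", "unspecific", "genic")
    label[is.na(label)] <- "genic"
  }
  unspec <- tally_unspecific(
    data.frame(barcode = bcumi$barcode, label = label), wl)

  trimmed <- trim_polya(r2, min_run = min_run, min_len = min_len)
  gene <- rep(NA_character_, length(trimmed))
  keep <- !is.na(trimmed) & label == "genic"
  if (!is.null(classification)) {
    cl <- setNames(classification[[2L]], classification[[1L]])
    g <- unname(cl[ids[keep]])
    g[g %in% "unspecific"] <- NA_character_
    gene[keep] <- g
    gene_universe <- sort(unique(gene[!is.na(gene)]))
  } else {
    gene[keep] <- assign_gene(trimmed[keep], index)
    gene_universe <- sort(unique(index$gene))
  }

  records <- data.frame(barcode = bcumi$barcode, umi = bcumi$umi, gene = gene,
                        stringsAsFactors = FALSE)
  counts <- count_umis(records, wl, genes = gene_universe)
  meta <- data.frame(unspecific_reads = unname(unspec[rownames(counts)]),
                     row.names = rownames(counts))
  out <- seed_counts(counts, meta)
  attr(out, "report") <- list(
    n_reads = length(short), n_short_r1 = sum(short),
    n_polya_discarded = sum(is.na(trimmed) & label == "genic"),
    n_unassigned = sum(keep & is.na(gene)),
    n_nonwhitelist = attr(counts, "n_nonwhitelist"))
  out
}
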