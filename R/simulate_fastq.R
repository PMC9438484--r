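# random DNA strings, vectorized
.rand_seq <- function(n, len, alphabet = c("A", "C", "G", "T")) {
  if (n == 0L) return(character(0))
  m <- matrix(alphabet[sample.int(length(alphabet), n * len, replace = TRUE)],
              nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Simulate paired split-UMI FASTQ files with a known expected count matrix
#'
#' Writes R1/R2 FASTQ for one 32-seed pool in the library's bespoke layout:
#' R1 = 9 nt UMI part A + 6 nt seed barcode + 5 nt UMI part B + 1 filler nt;
#' R2 = 55 nt of transcript 3'-end sequence, running into the poly(A) tail for
#' molecules primed close to it. Duplicate read pairs are injected per
#' molecule to exercise UMI collapse, some molecules are primed so deep into
#' the tail that the trimmed read falls below the length cutoff (exercising
#' the discard path), two transcripts share their entire sampled 3' region so
#' their reads are genuine multimappers, and unspecific hotspot reads (tagged
#' `:us` in the read name) plus non-whitelist barcodes exercise the remaining
#' filters. The returned expected matrix is what exact processing must
#' reproduce: one count per distinct UMI of each valid molecule.
#'
#' @param config a [sim_config()]; `n_genes` transcripts are generated and
#'   `rng_seed` drives all randomness.
#' @param out_dir directory to write `r1.fastq.gz`, `r2.fastq.gz`,
#'   `whitelist.tsv`, `transcripts.fa` and the expected counts (MTX + TSV).
#' @param whitelist optional character vector of unique 6-nt barcodes (one per
#'   seed); 32 random barcodes by default.
#' @param depth expected molecules per seed.
#' @param dup_rate expected extra PCR duplicate reads per molecule.
#' @param unspecific_rate unspecific molecules as a fraction of `depth`.
#' @param n_bad_barcode number of reads carrying non-whitelist barcodes.
#' @param transcript_len genic transcript length (nt) before the poly(A) tail.
#' @param polya_len poly(A) tail length appended to each transcript.
#' @return List with the written `paths`, the `whitelist` data.frame, the
#'   transcript sequences, and `expected`, a [seed_counts] over all whitelist
#'   seeds and all genes (unspecific read totals in its metadata).
#' @export
simulate_fastq <- function(config, out_dir,
                           whitelist = NULL,
                           depth = 1200, dup_rate = 0.3,
                           unspecific_rate = 0.05, n_bad_barcode = 200,
                           transcript_len = 150L, polya_len = 45L) {
  stopifnot(inherits(config, "sim_config"))
  ls_ <- local_seed(config$rng_seed); if (!is.null(ls_)) on.exit(ls_$restore())
  cfg <- config
  G <- cfg$n_genes
  stopifnot(G >= 3L, transcript_len >= 110L)

  if (is.null(whitelist)) {
    whitelist <- unique(.rand_seq(200L, 6L))[1:32]
  }
  if (anyDuplicated(whitelist) || any(nchar(whitelist) != 6L))
    stop("whitelist barcodes must be unique and 6 nt")
  n_seeds <- length(whitelist)
  seed_ids <- sprintf("s%02d", seq_len(n_seeds))
  wl <- data.frame(barcode = whitelist, seed_id = seed_ids,
                   stringsAsFactors = FALSE)

  genes <- sprintf("gene%05d", seq_len(G))
  tx <- .rand_seq(G, transcript_len)
  # the last two transcripts share the whole sampled 3' region -> multimappers
  shared_from <- transcript_len - 54L  # priming positions start here
  substr(tx[G], shared_from, transcript_len) <-
    substr(tx[G - 1L], shared_from, transcript_len)
  tx <- paste0(tx, strrep("A", polya_len))
  names(tx) <- genes
  multimap <- c(G - 1L, G)

  p <- rlnorm(G, 0, 1)
  p <- p / sum(p)

  # molecules: seed, gene, UMI, priming position
  n_mol <- rpois(n_seeds, depth)
  mol_seed <- rep(seed_ids, n_mol)
  mol_bc <- rep(whitelist, n_mol)
  M <- length(mol_seed)
  mol_gene_i <- sample.int(G, M, replace = TRUE, prob = p)
  mol_umi <- .rand_seq(M, 14L)
  # priming positions span untrimmed, trimmed-and-kept and discarded reads
  pos_lo <- transcript_len - 54L
  pos_hi <- transcript_len + polya_len - 54L
  mol_pos <- sample(pos_lo:pos_hi, M, replace = TRUE)
  mol_read <- substr(tx[mol_gene_i], mol_pos, mol_pos + 54L)

  # validity under the processing rules: poly(A) trim then length cutoff,
  # and no multimapping transcript
  m <- regexpr("A+$", mol_read)
  run <- ifelse(m > 0L, attr(m, "match.length"), 0L)
  trimmed_len <- ifelse(run >= 10L, 55L - run, 55L)
  valid <- trimmed_len >= 30L & !(mol_gene_i %in% multimap)

  expected <- count_umis(
    data.frame(barcode = mol_bc[valid], umi = mol_umi[valid],
               gene = genes[mol_gene_i[valid]], stringsAsFactors = FALSE),
    wl, genes = genes)

  # unspecific hotspot molecules (oligo-dT primed, proper R1, off-target R2)
  hs <- .rand_seq(cfg$n_hotspots, transcript_len)
  n_us <- rpois(n_seeds, depth * unspecific_rate)
  us_bc <- rep(whitelist, n_us)
  U <- length(us_bc)
  us_hs <- sample.int(cfg$n_hotspots, U, replace = TRUE)
  us_pos <- sample.int(transcript_len - 54L, U, replace = TRUE)
  us_read <- substr(hs[us_hs], us_pos, us_pos + 54L)
  us_umi <- .rand_seq(U, 14L)

  # reads with barcodes outside the whitelist
  bad_bc <- setdiff(unique(.rand_seq(n_bad_barcode * 2L, 6L)), whitelist)
  bad_bc <- sample(bad_bc, n_bad_barcode, replace = TRUE)
  bad_gene_i <- sample.int(G, n_bad_barcode, replace = TRUE)
  bad_read <- substr(tx[bad_gene_i], pos_lo, pos_lo + 54L)
  bad_umi <- .rand_seq(n_bad_barcode, 14L)

  all_bc <- c(mol_bc, us_bc, bad_bc)
  all_umi <- c(mol_umi, us_umi, bad_umi)
  all_r2 <- c(mol_read, us_read, bad_read)
  all_label <- c(rep("genic", M), rep("us", U), rep("genic", n_bad_barcode))

  reps <- 1L + rpois(length(all_bc), dup_rate)
  idx <- rep(seq_along(all_bc), reps)
  idx <- sample(idx)  # shuffle read order

  r1 <- paste0(substr(all_umi[idx], 6L, 14L), all_bc[idx],
               substr(all_umi[idx], 1L, 5L), "T")
  r2 <- all_r2[idx]
  ids <- sprintf("r%07d:%s", seq_along(idx), all_label[idx])

  # per-seed unspecific READ totals (duplicates included), as tallied
  us_reads <- rep(us_bc, reps[M + seq_len(U)])
  unspec <- table(factor(us_reads, levels = whitelist))
  meta <- data.frame(unspecific_reads = as.integer(unspec),
                     row.names = seed_ids)
  expected_sc <- seed_counts(expected, meta)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(r1 = file.path(out_dir, "r1.fastq.gz"),
                r2 = file.path(out_dir, "r2.fastq.gz"),
                whitelist = file.path(out_dir, "whitelist.tsv"),
                transcripts = file.path(out_dir, "transcripts.fa"))
  .write_fastq_gz(paths$r1, ids, r1)
  .write_fastq_gz(paths$r2, ids, r2)
  write.table(wl, paths$whitelist, sep = "\t", quote = FALSE, row.names = FALSE)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(tx), paths$transcripts)
  write_counts(expected_sc, file.path(out_dir, "expected_counts"))

  list(paths = paths, whitelist = wl, transcripts = tx,
       expected = expected_sc)
}

.write_fastq_gz <- function(path, ids, seqs) {
  con <- gzfile(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n",
                    strrep("I", nchar(seqs))), con)
}
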