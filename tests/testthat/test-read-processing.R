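test_that("rearrange_r1 recombines the split UMI around the barcode", {
  out <- rearrange_r1("AAAAAAAAACCCCCCGGGGGT")
  expect_equal(out$barcode, "CCCCCC")
  expect_equal(out$umi, "GGGGGAAAAAAAAA")

  out <- rearrange_r1(strrep("N", 20))
  expect_equal(out$barcode, "NNNNNN")
  expect_equal(out$umi, strrep("N", 14))

  out <- rearrange_r1("TTTTTTTTTGGGGGGAAAAAC")
  expect_equal(out$barcode, "GGGGGG")
  expect_equal(out$umi, "AAAAATTTTTTTTT")
})

test_that("rearrange_r1 drops and counts short reads", {
  out <- rearrange_r1(c("ACGTACGTACGTACGTACGT", "ACGT"))
  expect_equal(nrow(out), 1L)
  expect_equal(attr(out, "n_discarded"), 1L)
})

test_that("rearrange_r1 is lossless on the first 20 nt", {
  set.seed(1)
  for (i in 1:25) {
    r1 <- paste(sample(c("A", "C", "G", "T"), 21, replace = TRUE),
                collapse = "")
    out <- rearrange_r1(r1)
    rebuilt <- paste0(substr(out$umi, 6, 14), out$barcode, substr(out$umi, 1, 5))
    expect_equal(rebuilt, substr(r1, 1, 20))
  }
})

test_that("trim_polya removes terminal A runs and applies the length cutoff", {
  r <- paste0(strrep("C", 43), strrep("A", 12))   # 55 nt, 12-A tail
  expect_equal(trim_polya(r), strrep("C", 43))
  r <- paste0(strrep("C", 28), strrep("A", 10))   # 38 nt -> 28 < 30
  expect_true(is.na(trim_polya(r)))
  r <- paste0(strrep("C", 46), strrep("A", 9))    # run below min_run
  expect_equal(trim_polya(r), r)
  expect_equal(trim_polya("CGCGCGCG", min_len = 5), "CGCGCGCG")
})

test_that("gene assignment is exact and drops multimappers", {
  set.seed(2)
  t1 <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE), collapse = "")
  t2 <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE), collapse = "")
  shared <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE), collapse = "")
  idx <- build_transcript_index(
    c(geneA = t1, geneB = t2, geneC = shared, geneD = shared))
  expect_equal(assign_gene(substr(t1, 10, 50), idx), "geneA")
  expect_true(is.na(assign_gene(substr(shared, 5, 45), idx)))  # two transcripts
  expect_true(is.na(assign_gene(strrep("ACGT", 10), idx)))     # absent
  expect_true(is.na(assign_gene("ACGTACGT", idx)))             # shorter than k
})

test_that("count_umis counts distinct UMIs per seed and gene", {
  wl <- data.frame(barcode = c("AAAAAA", "CCCCCC"), seed_id = c("s1", "s2"))
  rec <- data.frame(barcode = rep("AAAAAA", 5), umi = c("u1", "u1", "u1", "u2", "u2"),
                    gene = "g1")
  counts <- count_umis(rec, wl)
  expect_equal(counts["s1", "g1"], 2L)
  expect_equal(counts["s2", "g1"], 0L)

  rec <- data.frame(barcode = "AAAAAA", umi = "u1", gene = c("g1", "g2"))
  counts <- count_umis(rec, wl)
  expect_equal(unname(counts["s1", ]), c(1L, 1L))  # dedup key includes gene

  counts <- count_umis(rec[0, ], wl, genes = c("g1", "g2"))
  expect_true(all(counts == 0L))

  rec <- data.frame(barcode = c("AAAAAA", "GGGGGG"), umi = "u1", gene = "g1")
  counts <- count_umis(rec, wl)
  expect_equal(attr(counts, "n_nonwhitelist"), 1L)
  expect_equal(counts["s1", "g1"], 1L)
})

test_that("unspecific tallies count labeled reads per seed", {
  wl <- data.frame(barcode = c("AAAAAA", "CCCCCC"), seed_id = c("s1", "s2"))
  rec <- data.frame(barcode = c("AAAAAA", "AAAAAA", "CCCCCC"),
                    label = c("unspecific", "unspecific", "genic"))
  expect_equal(tally_unspecific(rec, wl), c(s1 = 2L, s2 = 0L))
  expect_equal(tally_unspecific(rec[0, ], wl), c(s1 = 0L, s2 = 0L))
})

test_that("processing simulated FASTQ reproduces the expected matrix exactly", {
  fx <- simulate_fastq(fastq_cfg(), out_dir = withr::local_tempdir(),
                       depth = 250, n_bad_barcode = 40)
  idx <- build_transcript_index(fx$paths$transcripts)
  got <- process_fastq(fx$paths$r1, fx$paths$r2, fx$paths$whitelist, idx)
  expect_equal(unclass(got$counts)[, ], unclass(fx$expected$counts)[, ],
               ignore_attr = TRUE)
  expect_identical(dimnames(got$counts), dimnames(fx$expected$counts))
  expect_equal(got$meta$unspecific_reads, fx$expected$meta$unspecific_reads)
  rep <- attr(got, "report")
  expect_gt(rep$n_polya_discarded, 0)     # discard path exercised
  expect_gt(rep$n_nonwhitelist, 0)        # non-whitelist path exercised
})

test_that("UMI deduplication is idempotent", {
  wl <- data.frame(barcode = c("AAAAAA", "CCCCCC"), seed_id = c("s1", "s2"))
  set.seed(3)
  rec <- data.frame(barcode = sample(c("AAAAAA", "CCCCCC"), 200, replace = TRUE),
                    umi = sample(sprintf("u%02d", 1:20), 200, replace = TRUE),
                    gene = sample(c("g1", "g2", "g3"), 200, replace = TRUE))
  c1 <- count_umis(rec, wl)
  dedup <- unique(rec)
  c2 <- count_umis(dedup, wl, genes = colnames(c1))
  expect_equal(unclass(c1)[, ], unclass(c2)[, ], ignore_attr = TRUE)
})

test_that("seeds with zero molecules stay all-zero columns of the experiment", {
  fx <- simulate_fastq(fastq_cfg(rng_seed = 12), out_dir = withr::local_tempdir(),
                       depth = 30, unspecific_rate = 0)
  # with shallow depth some (seed, gene) pairs must be zero; totals still match
  expect_true(any(fx$expected$counts == 0))
  expect_equal(fx$expected$meta$total_umis, unname(rowSums(fx$expected$counts)))
})
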