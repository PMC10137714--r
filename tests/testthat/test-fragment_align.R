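test_that("collapsing preserves total reads and distinct sequences per sample", {
  seq_list <- list(
    s1 = c("ACGTACGTACGTACGT", "ACGTACGTACGTACGT", "TTTTGGGGCCCCAAAA"),
    s2 = c("TTTTGGGGCCCCAAAA")
  )
  reads <- collapse_sequences(seq_list)
  expect_s3_class(reads, "collapsed_reads")
  expect_equal(sum(reads$counts), 4)
  expect_equal(colSums(reads$counts), c(s1 = 3, s2 = 1))
  expect_equal(length(reads$sequence), 2L)
  i <- match("ACGTACGTACGTACGT", reads$sequence)
  expect_equal(unname(reads$counts[i, ]), c(2, 0))
  j <- match("TTTTGGGGCCCCAAAA", reads$sequence)
  expect_equal(unname(reads$counts[j, ]), c(1, 1))
})

test_that("collapsing is case-insensitive and FASTQ input round-trips", {
  reads <- collapse_sequences(list(a = c("acgtacgtacgtacgt", "ACGTACGTACGTACGT")))
  expect_equal(length(reads$sequence), 1L)
  expect_equal(sum(reads$counts), 2)

  fq <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGTACGTACGTACGT", "+", strrep("I", 16),
               "@r2", "ACGTACGTACGTACGT", "+", strrep("I", 16)), fq)
  from_file <- collapse_reads(c(a = fq))
  expect_equal(from_file$sequence, reads$sequence)
  expect_equal(from_file$counts, reads$counts)
  expect_error(collapse_reads(fq), "named")
  unlink(fq)
})

test_that("adapter trimming removes read suffixes matching an adapter prefix", {
  adapter <- "AGATCGGAAGAGC"
  insert <- "ACGTACGTACGTACGTACGT"  # 20 nt
  reads <- collapse_sequences(list(s = c(
    paste0(insert, adapter),                 # full adapter
    paste0(insert, substr(adapter, 1, 8)),   # min_overlap-length suffix
    paste0(insert, substr(adapter, 1, 5))    # too short an overlap to trim
  )))
  out <- filter_reads(reads, adapter3 = adapter, min_overlap = 8L)
  expect_equal(out$report$reads[out$report$rule == "adapter_trimmed"], 2)
  # the two trimmed reads collapse onto the bare insert
  i <- match(insert, out$reads$sequence)
  expect_equal(unname(out$reads$counts[i, "s"]), 2)
})

test_that("length window and N cap are applied with an accurate report", {
  reads <- collapse_sequences(list(s = c(
    strrep("A", 10),             # too short
    strrep("C", 50),             # too long
    "ACGTNCGTACGTACGT",          # one N
    "ACGTACGTACGTACGT"           # clean
  )))
  out <- filter_reads(reads, min_len = 15L, max_len = 45L, max_n = 0L)
  expect_equal(out$report$reads[out$report$rule == "too_short"], 1)
  expect_equal(out$report$reads[out$report$rule == "too_long"], 1)
  expect_equal(out$report$reads[out$report$rule == "too_many_N"], 1)
  expect_equal(length(out$reads$sequence), 1L)
  expect_equal(sum(out$reads$counts), 1)
})

test_that("exact placements match the brute-force oracle on all spaces", {
  models <- list(canonical_template(), shifted_template())
  names(models) <- vapply(models, `[[`, "", "gene_id")
  m <- models[[1]]
  pre <- precursor_seq(m)
  probe <- list(
    mature_5p = substr(m$mature_seq, 1, 20),
    trailer = substr(pre, 77, 92),
    junction = substr(pre, 70, 85),
    absent = strrep("ACGT", 5)
  )
  reads <- collapse_sequences(list(s = unlist(probe, use.names = FALSE)))
  res <- align_to_trna(reads, models, max_mismatch = 0L)
  for (i in seq_along(reads$sequence)) {
    oracle <- brute_align_one(reads$sequence[[i]], models, 0L)
    got <- res$alignments[res$alignments$read_id == names(reads$sequence)[i],
                          c("gene_id", "space", "start", "end", "mismatches")]
    got <- got[order(got$gene_id, got$space, got$start), , drop = FALSE]
    rownames(got) <- NULL
    if (is.null(oracle)) {
      expect_equal(nrow(got), 0L)
      expect_true(reads$sequence[[i]] %in% res$unaligned$sequence)
    } else {
      rownames(oracle) <- NULL
      expect_equal(got, oracle)
    }
  }
})

test_that("one-mismatch reads place only when no exact placement exists", {
  models <- list(canonical_template())
  names(models) <- vapply(models, `[[`, "", "gene_id")
  m <- models[[1]]
  exact <- substr(m$mature_seq, 5, 30)
  mutated <- paste0("T", substr(exact, 2, nchar(exact)))
  if (mutated == exact) mutated <- paste0("A", substr(exact, 2, nchar(exact)))
  reads <- collapse_sequences(list(s = c(exact, mutated)))

  strict <- align_to_trna(reads, models, max_mismatch = 0L)
  expect_true(mutated %in% strict$unaligned$sequence)

  lenient <- align_to_trna(reads, models, max_mismatch = 1L)
  expect_equal(nrow(lenient$unaligned), 0L)
  mm <- tapply(lenient$alignments$mismatches, lenient$alignments$read_id, max)
  id_exact <- names(reads$sequence)[match(exact, reads$sequence)]
  id_mut <- names(reads$sequence)[match(mutated, reads$sequence)]
  expect_equal(unname(mm[id_exact]), 0L)
  expect_equal(unname(mm[id_mut]), 1L)
})

test_that("per-read placement weights always sum to one", {
  # two genes sharing a 3' arm so some reads are multi-placed
  m1 <- canonical_template()
  s <- strsplit(m1$gene_seq, "")[[1]]
  s[2:10] <- rev(s[2:10])
  m2 <- trna_gene_model(
    gene_id = "tRNA-Gly-GCC-2-1", amino_acid = "Gly", anticodon = "GCC",
    origin = "cytosolic", gene_seq = paste(s, collapse = ""),
    trailer_seq = m1$trailer_seq, landmarks = m1$landmarks
  )
  models <- list(m1, m2)
  names(models) <- vapply(models, `[[`, "", "gene_id")
  shared <- substr(m1$mature_seq, 55, 76)  # identical in both genes
  unique5 <- substr(m1$mature_seq, 1, 18)
  reads <- collapse_sequences(list(s = c(shared, unique5)))
  res <- align_to_trna(reads, models)
  w <- tapply(res$alignments$weight, res$alignments$read_id, sum)
  expect_true(all(abs(w - 1) < 1e-12))
  id_shared <- names(reads$sequence)[match(shared, reads$sequence)]
  expect_gt(sum(res$alignments$read_id == id_shared), 1L)
})

test_that("precursor placements inside the mature region are suppressed", {
  models <- list(canonical_template())
  names(models) <- vapply(models, `[[`, "", "gene_id")
  inner <- substr(models[[1]]$mature_seq, 10, 30)
  reads <- collapse_sequences(list(s = inner))
  res <- align_to_trna(reads, models)
  expect_true(all(res$alignments$space == "mature"))
})
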