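test_that("landmark-anchored example fragments receive their textbook labels", {
  m <- canonical_template()
  expect_equal(classify_fragment(m, 1L, 18L), "tRF-5a")   # ends in the D loop
  expect_equal(classify_fragment(m, 1L, 25L), "tRF-5b")   # D loop .. anticodon loop
  expect_equal(classify_fragment(m, 1L, 38L), "tRF-5c")   # in-loop, too long for a half
  expect_equal(classify_fragment(m, 59L, 76L), "tRF-3a")  # 18 nt, CCA end
  expect_equal(classify_fragment(m, 55L, 76L), "tRF-3b")  # 22 nt, CCA end
  expect_equal(classify_fragment(m, 1L, 34L), "tiRNA-5")  # 5' half
  expect_equal(classify_fragment(m, 35L, 76L), "tiRNA-3") # 3' half
  expect_equal(classify_fragment(m, 10L, 40L), "i-tRF")   # internal
  expect_equal(classify_fragment(m, 77L, 92L, space = "precursor"), "tRF-1")
})

test_that("tRF-3 lengths 18 and 22 are the a/b archetypes and both end in CCA", {
  m <- canonical_template()
  f18 <- substr(m$mature_seq, 76L - 18L + 1L, 76L)
  f22 <- substr(m$mature_seq, 76L - 22L + 1L, 76L)
  expect_equal(substr(f18, 16L, 18L), "CCA")
  expect_equal(substr(f22, 20L, 22L), "CCA")
  expect_equal(classify_fragment(m, 59L, 76L), "tRF-3a")
  expect_equal(classify_fragment(m, 55L, 76L), "tRF-3b")
  # the a/b boundary sits at 20 nt
  expect_equal(classify_fragment(m, 57L, 76L), "tRF-3a")  # 20 nt
  expect_equal(classify_fragment(m, 56L, 76L), "tRF-3b")  # 21 nt
})

test_that("tRNA halves obey both the cleavage-site and the 30-36 nt rules", {
  m <- canonical_template()
  b <- tirna5_length_bounds(m)
  expect_equal(unname(b["min"]), 30)
  expect_equal(unname(b["max"]), 36)
  # 5'-anchored fragments ending in the loop but longer than 36 nt are tRF-5c
  expect_equal(classify_fragment(m, 1L, 37L), "tRF-5c")
  # 29-nt fragment ends before the cleavage window -> tRF-5b
  expect_equal(classify_fragment(m, 1L, 29L), "tRF-5b")
  # 3' halves start at or before the anticodon loop end
  expect_equal(classify_fragment(m, 38L, 76L), "tiRNA-3")
  expect_equal(classify_fragment(m, 39L, 76L), "tRF-3b")
})

test_that("every admissible 15-45 nt placement gets exactly one of nine labels", {
  for (m in list(canonical_template(), shifted_template())) {
    wins <- tsrnaflow:::admissible_windows(m)
    labels <- unlist(lapply(names(wins), function(t) rep(t, nrow(wins[[t]]))))
    expect_true(all(labels %in% tsrna_types()))
    n_mature <- sum(vapply(15:45, function(L) {
      max(0L, m$landmarks$mature_end - L + 1L)
    }, 0L))
    pre_len <- m$landmarks$mature_end + nchar(m$trailer_seq)
    n_pre <- sum(vapply(15:45, function(L) {
      sum((m$landmarks$mature_end + 1:2) + L - 1L <= pre_len)
    }, 0L))
    expect_equal(length(labels), n_mature + n_pre)
  }
})

test_that("classification errors on fragments that leave the reference", {
  m <- canonical_template()
  expect_error(classify_fragment(m, 1L, 77L), "past the mature")
  expect_error(classify_fragment(m, 80L, 99L, space = "precursor"),
               "past the precursor")
  expect_error(classify_fragment(m, 5L, 3L), "invalid fragment interval")
})

test_that("merged records carry majority types, sorted parents and family serials", {
  models <- list(canonical_template(), shifted_template())
  names(models) <- vapply(models, `[[`, "", "gene_id")
  m <- models[[1]]
  frags <- c(substr(m$mature_seq, 1, 18),   # tRF-5a on gene 1
             substr(m$mature_seq, 1, 34),   # tiRNA-5 on gene 1
             substr(m$mature_seq, 59, 76))  # tRF-3a on gene 1
  reads <- collapse_sequences(list(
    s1 = rep(frags, c(5, 3, 2)), s2 = rep(frags, c(1, 1, 1))
  ))
  aln <- align_to_trna(reads, models)
  rec <- merge_and_name(aln$alignments, reads, models)
  expect_s3_class(rec, "tsrna_records")
  expect_equal(nrow(rec$table), 3L)
  expect_setequal(rec$table$type, c("tRF-5a", "tiRNA-5", "tRF-3a"))
  expect_true(all(grepl("^(tRF|tiRNA)-[A-Za-z]+-[A-Z]{3}-\\d{3}$", rec$table$name)))
  # tiRNA records take the tiRNA name prefix, tRFs the tRF prefix
  expect_match(rec$table$name[rec$table$type == "tiRNA-5"], "^tiRNA-")
  # counts stay aligned with the table after ordering
  expect_equal(rownames(rec$counts), rec$table$name)
  expect_equal(sum(rec$counts), sum(reads$counts))
  # serials within the tRF-Gly-GCC family follow descending abundance
  fam <- rec$table[grepl("^tRF-Gly-GCC", rec$table$name), ]
  expect_equal(fam$name[order(-fam$total_count, fam$sequence)],
               sort(fam$name))
})

test_that("multi-parent records are flagged and mixed origin counts as cytosolic", {
  m1 <- canonical_template()
  m2 <- trna_gene_model(
    gene_id = "tRNA-Ala-AGC-1-1", amino_acid = "Ala", anticodon = "AGC",
    origin = "mitochondrial",
    gene_seq = sub("GCC", "AGC", m1$gene_seq),  # same gene, Ala anticodon
    trailer_seq = m1$trailer_seq, landmarks = m1$landmarks
  )
  models <- list(m1, m2)
  names(models) <- vapply(models, `[[`, "", "gene_id")
  # the first 18 nt are shared between the two genes
  shared <- substr(m1$mature_seq, 1, 18)
  reads <- collapse_sequences(list(s = shared))
  aln <- align_to_trna(reads, models)
  rec <- merge_and_name(aln$alignments, reads, models)
  expect_equal(nrow(rec$table), 1L)
  expect_true(rec$table$ambiguous_parents)
  expect_true(rec$table$mixed_origin)
  expect_equal(rec$table$origin, "cytosolic")
  expect_equal(rec$table$parents,
               "tRNA-Ala-AGC-1-1;tRNA-Gly-GCC-1-1")
  # lexicographically first parent provides the name family
  expect_match(rec$table$name, "^tRF-Ala-AGC-")
})

test_that("landscape percentages sum to 100 within every table", {
  models <- simulate_reference(12L, seed = 3L)
  cfg <- simulation_config(n_genes = 12L, n_fragments = 80L, error_rate = 0,
                           seed = 3L)
  sim <- simulate_fragmentome(models, cfg)
  aln <- align_to_trna(sim$reads, models)
  rec <- merge_and_name(aln$alignments, sim$reads, models)
  summ <- summarize_landscape(rec, sim$groups[colnames(rec$counts)])
  expect_equal(sum(summ$type_composition$distinct_pct), 100)
  expect_equal(sum(summ$type_composition$reads_pct), 100)
  expect_equal(sum(summ$type_composition$reads_pct_A), 100)
  expect_equal(sum(summ$origin_split$distinct_pct), 100)
  expect_equal(sum(summ$space_split$reads_pct), 100)
  expect_equal(sum(summ$parent_portions$reads_pct), 100)
  expect_equal(sum(summ$aa_portions$distinct_pct), 100)
  expect_equal(sum(summ$length_histogram$distinct), nrow(rec$table))
  expect_equal(sum(summ$length_histogram$reads), sum(rec$counts))
})
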