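#' Collapse small-RNA reads into distinct sequences with per-sample counts
#'
#' Each distinct sequence becomes one record; the total collapsed count per
#' sample equals the number of input reads for that sample.
#'
#' @param files Named character vector of FASTQ/FASTA paths; names are sample
#'   ids. Format is taken from the extension (`.fastq`/`.fq` vs anything else).
#' @return A `collapsed_reads` object: list with `sequence` (character, named
#'   by read id) and `counts` (matrix, reads x samples).
#' @export
collapse_reads <- function(files) {
  if (is.null(names(files)) || any(names(files) == "")) {
    stop("files must be a named vector (names are sample ids)")
  }
  seq_list <- lapply(files, function(path) {
    fmt <- if (grepl("\\.(fastq|fq)(\\.gz)?$", path)) "fastq" else "fasta"
    as.character(Biostrings::readDNAStringSet(path, format = fmt))
  })
  collapse_sequences(seq_list)
}

#' Collapse in-memory reads into distinct sequences with per-sample counts
#'
#' @param seq_list Named list of character vectors, one element per sample;
#'   each vector holds the (possibly repeated) read sequences of that sample.
#' @return A `collapsed_reads` object; see [collapse_reads()].
#' @export
collapse_sequences <- function(seq_list) {
  samples <- names(seq_list)
  seq_list <- lapply(seq_list, toupper)
  all_seqs <- sort(unique(unlist(seq_list, use.names = FALSE)))
  counts <- matrix(0, nrow = length(all_seqs), ncol = length(samples),
                   dimnames = list(NULL, samples))
  for (s in samples) {
    tab <- table(seq_list[[s]])
    counts[match(names(tab), all_seqs), s] <- as.integer(tab)
  }
  read_ids <- sprintf("read_%06d", seq_len(length(all_seqs)))
  rownames(counts) <- read_ids
  structure(list(sequence = stats::setNames(all_seqs, read_ids),
                 counts = counts),
            class = "collapsed_reads")
}

#' @export
print.collapsed_reads <- function(x, ...) {
  cat(sprintf("<collapsed_reads> %d distinct sequences, %d sample(s), %d reads total\n",
              length(x$sequence), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Filter and adapter-trim collapsed reads
#'
#' Applies, in order: 3' adapter trimming (a read suffix equal to a prefix of
#' the adapter, with at least `min_overlap` nt of overlap, is removed), an
#' ambiguous-base cap, and a length window. Trimming can merge previously
#' distinct sequences, so the result is re-collapsed.
#'
#' @param reads A `collapsed_reads` object.
#' @param min_len,max_len Length window (nt) applied after trimming.
#' @param max_n Maximum number of `N` bases tolerated.
#' @param adapter3 Optional 3' adapter sequence.
#' @param min_overlap Minimum read/adapter overlap for trimming (nt).
#' @return List with `reads` (filtered `collapsed_reads`) and `report`
#'   (data frame of reads removed per rule, in read counts).
#' @export
filter_reads <- function(reads, min_len = 15L, max_len = 45L, max_n = 0L,
                         adapter3 = NULL, min_overlap = 8L) {
  seqs <- reads$sequence
  counts <- reads$counts
  trimmed <- 0L
  if (!is.null(adapter3)) {
    adapter3 <- toupper(adapter3)
    new_seqs <- vapply(seqs, function(s) {
      L <- nchar(s)
      kmax <- min(L, nchar(adapter3))
      if (kmax >= min_overlap) {
        for (k in seq(kmax, min_overlap, by = -1L)) {
          if (substr(s, L - k + 1L, L) == substr(adapter3, 1L, k)) {
            return(substr(s, 1L, L - k))
          }
        }
      }
      s
    }, "", USE.NAMES = FALSE)
    trimmed <- sum(counts[new_seqs != unname(seqs), , drop = FALSE])
    seqs <- new_seqs
  }
  lens <- nchar(seqs)
  n_count <- nchar(gsub("[^N]", "", seqs))
  keep <- lens >= min_len & lens <= max_len & n_count <= max_n
  report <- data.frame(
    rule = c("adapter_trimmed", "too_short", "too_long", "too_many_N"),
    reads = c(trimmed,
              sum(counts[lens < min_len, , drop = FALSE]),
              sum(counts[lens > max_len, , drop = FALSE]),
              sum(counts[n_count > max_n & lens >= min_len & lens <= max_len,
                         , drop = FALSE]))
  )
  # re-collapse: trimming may have merged sequences
  kept_seqs <- seqs[keep]
  kept_counts <- counts[keep, , drop = FALSE]
  uniq <- sort(unique(kept_seqs))
  new_counts <- matrix(0, nrow = length(uniq), ncol = ncol(counts),
                       dimnames = list(sprintf("read_%06d", seq_along(uniq)),
                                       colnames(counts)))
  for (i in seq_along(kept_seqs)) {
    j <- match(kept_seqs[i], uniq)
    new_counts[j, ] <- new_counts[j, ] + kept_counts[i, ]
  }
  out <- structure(list(
    sequence = stats::setNames(uniq, rownames(new_counts)),
    counts = new_counts
  ), class = "collapsed_reads")
  list(reads = out, report = report)
}

# Substring index over all references: maps every substring of the relevant
# lengths to its placements. Precursor placements fully inside the mature
# region are excluded (the mature-space placement represents them).
build_alignment_index <- function(models, lengths) {
  index <- new.env(hash = TRUE, parent = emptyenv())
  add <- function(key, gene_id, space, start, end) {
    hit <- list(gene_id = gene_id, space = space, start = start, end = end)
    if (is.null(index[[key]])) {
      index[[key]] <- list(hit)
    } else {
      index[[key]] <- c(index[[key]], list(hit))
    }
  }
  for (m in models) {
    mat <- m$mature_seq
    pre <- precursor_seq(m)
    me <- m$landmarks$mature_end
    for (L in lengths) {
      n_mat <- nchar(mat) - L + 1L
      if (n_mat >= 1L) {
        for (st in seq_len(n_mat)) {
          add(substr(mat, st, st + L - 1L), m$gene_id, "mature", st, st + L - 1L)
        }
      }
      n_pre <- nchar(pre) - L + 1L
      if (n_pre >= 1L) {
        for (st in seq_len(n_pre)) {
          en <- st + L - 1L
          if (en > me) add(substr(pre, st, en), m$gene_id, "precursor", st, en)
        }
      }
    }
  }
  index
}

lookup_placements <- function(index, seq) {
  hits <- index[[seq]]
  if (is.null(hits)) NULL else hits
}

one_mismatch_variants <- function(seq) {
  bases <- c("A", "C", "G", "T")
  L <- nchar(seq)
  chars <- strsplit(seq, "")[[1]]
  out <- character(0)
  for (pos in seq_len(L)) {
    for (b in setdiff(bases, chars[pos])) {
      v <- chars
      v[pos] <- b
      out <- c(out, paste(v, collapse = ""))
    }
  }
  out
}

#' Place collapsed reads on mature and precursor tRNA references
#'
#' Gap-free, sense-strand placement with at most `max_mismatch` substitutions
#' (0 or 1). All placements at the optimal mismatch level across all genes and
#' both coordinate spaces are reported; precursor placements that fall entirely
#' inside the mature region are suppressed in favour of the mature-space
#' placement. Each read's retained placements share its count through equal
#' fractional weights summing to one.
#'
#' @param reads A `collapsed_reads` object.
#' @param models Named list of validated [trna_gene_model()]s.
#' @param max_mismatch Maximum substitutions (0, the default, or 1).
#' @return List with `alignments` (data frame: `read_id`, `gene_id`, `space`,
#'   `start`, `end`, `mismatches`, `weight`) and `unaligned` (data frame of
#'   read ids and sequences that found no placement).
#' @export
align_to_trna <- function(reads, models, max_mismatch = 0L) {
  stopifnot(max_mismatch %in% c(0L, 1L))
  lengths <- sort(unique(nchar(reads$sequence)))
  index <- build_alignment_index(models, lengths)
  rows <- list()
  unaligned <- logical(length(reads$sequence))
  for (i in seq_along(reads$sequence)) {
    s <- reads$sequence[[i]]
    hits <- lookup_placements(index, s)
    mm <- 0L
    if (is.null(hits) && max_mismatch >= 1L) {
      hits <- list()
      for (v in one_mismatch_variants(s)) {
        h <- lookup_placements(index, v)
        if (!is.null(h)) hits <- c(hits, h)
      }
      mm <- 1L
      if (length(hits) == 0L) hits <- NULL
    }
    if (is.null(hits)) {
      unaligned[i] <- TRUE
      next
    }
    w <- 1 / length(hits)
    for (h in hits) {
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = names(reads$sequence)[i], gene_id = h$gene_id,
        space = h$space, start = h$start, end = h$end,
        mismatches = mm, weight = w, stringsAsFactors = FALSE
      )
    }
  }
  alignments <- if (length(rows) > 0L) {
    do.call(rbind, rows)
  } else {
    data.frame(read_id = character(0), gene_id = character(0),
               space = character(0), start = integer(0), end = integer(0),
               mismatches = integer(0), weight = numeric(0))
  }
  list(
    alignments = alignments,
    unaligned = data.frame(
      read_id = names(reads$sequence)[unaligned],
      sequence = unname(reads$sequence[unaligned]),
      stringsAsFactors = FALSE
    )
  )
}

#' Write alignments to TSV
#'
#' @param alignments Alignment data frame from [align_to_trna()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_alignments <- function(alignments, path) {
  utils::write.table(alignments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
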