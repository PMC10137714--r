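#' The nine tsRNA type labels
#'
#' tRF-5a/b/c arise from 5'-anchored cleavage at increasing distance (within
#' the D loop, between D loop and anticodon loop, and into the anticodon
#' region); tRF-3a/b are CCA-terminated 3' fragments (up to 20 nt vs longer);
#' tRF-1 is the RNase Z trailer product of the precursor; i-tRF is internal;
#' tiRNA-5/tiRNA-3 are the 5' and 3' halves from anticodon-region cleavage.
#'
#' @return Character vector of the nine labels.
#' @export
tsrna_types <- function() {
  c("tRF-5a", "tRF-5b", "tRF-5c", "tRF-3a", "tRF-3b", "tRF-1",
    "i-tRF", "tiRNA-5", "tiRNA-3")
}

# The anticodon cleavage window: the loop plus the two 3'-side anticodon-stem
# positions adjacent to it. tRNA halves are defined both by length (30-36 nt)
# and by anticodon-region cleavage; on a canonically numbered tRNA a 30-nt 5'
# half ends two positions before the loop, so the admissible cut window
# extends that far into the stem.
anticodon_window <- function(model) {
  c(model$landmarks$anticodon_loop[1] - 2L, model$landmarks$anticodon_loop[2])
}

#' Classify one aligned fragment into a tsRNA type
#'
#' Deterministic decision table on the fragment's placement relative to the
#' cloverleaf landmarks (`L` is the fragment length, `me` the mature 3' end):
#'
#' 1. Precursor placements starting within 2 nt after `me` are `tRF-1`
#'    (RNase Z trailer products); precursor placements entirely inside the
#'    mature region fall through to the mature rules; other precursor
#'    placements (junction-spanning) are `i-tRF`.
#' 2. 5'-anchored (start <= 2): `tiRNA-5` when the 3' end falls in the
#'    anticodon cleavage window and `L` is 30-36 nt; else `tRF-5a` when the
#'    end is within the D loop, `tRF-5b` when between D loop and anticodon
#'    loop, `tRF-5c` when inside the anticodon loop with a length outside the
#'    tiRNA window, and `tiRNA-5` when past the anticodon loop.
#' 3. 3'-anchored (end >= me - 1, and not 5'-anchored): `tiRNA-3` when the
#'    start is at or before the anticodon loop end, else `tRF-3a` for
#'    `L` <= 20 nt and `tRF-3b` for longer fragments.
#' 4. Everything else is `i-tRF`.
#'
#' Rule 2 takes precedence over rule 3 for near-full-length fragments.
#'
#' @param model A [trna_gene_model()].
#' @param start,end 1-based closed placement (mature axis; the precursor axis
#'   continues past `mature_end`).
#' @param space `"mature"` or `"precursor"`.
#' @return One of [tsrna_types()].
#' @export
classify_fragment <- function(model, start, end, space = c("mature", "precursor")) {
  space <- match.arg(space)
  lm <- model$landmarks
  me <- lm$mature_end
  if (start < 1L || end < start) stop("invalid fragment interval")
  L <- end - start + 1L
  if (space == "precursor") {
    if (end > me + nchar(model$trailer_seq)) {
      stop("fragment extends past the precursor 3' end")
    }
    if (start >= me + 1L && start <= me + 2L) return("tRF-1")
    if (end > me) return("i-tRF")
    # fully inside the mature region: use mature rules
  } else if (end > me) {
    stop("mature-space fragment extends past the mature 3' end")
  }
  ac <- lm$anticodon_loop
  win <- anticodon_window(model)
  if (start <= 2L) {
    if (end >= win[1] && end <= win[2] && L >= 30L && L <= 36L) return("tiRNA-5")
    if (end <= lm$d_loop[2]) return("tRF-5a")
    if (end < ac[1]) return("tRF-5b")
    if (end <= ac[2]) return("tRF-5c")
    return("tiRNA-5")
  }
  if (end >= me - 1L) {
    if (start <= ac[2]) return("tiRNA-3")
    if (L <= 20L) return("tRF-3a")
    return("tRF-3b")
  }
  "i-tRF"
}

#' Classify every alignment row
#'
#' @param alignments Alignment data frame from [align_to_trna()].
#' @param models Named list of [trna_gene_model()]s.
#' @return Character vector of type labels, one per row.
#' @export
classify_alignments <- function(alignments, models) {
  vapply(seq_len(nrow(alignments)), function(i) {
    classify_fragment(models[[alignments$gene_id[i]]],
                      alignments$start[i], alignments$end[i],
                      alignments$space[i])
  }, "")
}

#' Length bounds of 5' tRNA halves on a model
#'
#' Enumerates 5'-anchored fragments (start = 1) whose 3' end falls at each
#' position of the anticodon cleavage window, classifies them, and returns the
#' minimum and maximum length among those labeled `tiRNA-5`.
#'
#' @param model A [trna_gene_model()].
#' @return Named numeric vector with `min`, `max` and `n_enumerated`.
#' @export
tirna5_length_bounds <- function(model) {
  win <- anticodon_window(model)
  ends <- seq(win[1], win[2])
  labels <- vapply(ends, function(e) classify_fragment(model, 1L, e), "")
  lens <- ends[labels == "tiRNA-5"]
  c(min = min(lens), max = max(lens), n_enumerated = length(ends))
}

#' Merge classified alignments into named tsRNA records
#'
#' Identical sequences collapse into one record whose parents are all genes
#' carrying an optimal placement. The type is the majority-weight label across
#' the read's placements (ties broken by the lexicographically first label and
#' flagged). Names follow `tRF-<AA>-<anticodon>-<serial>` /
#' `tiRNA-<AA>-<anticodon>-<serial>`; when parents disagree on amino
#' acid/anticodon the lexicographically first parent provides them and the
#' record is flagged. Serials are zero-padded and assigned within each
#' `<prefix>-<AA>-<anticodon>` family in descending total-count order, ties by
#' sequence. A record is mitochondrial only when all parents are; mixed
#' parentage counts as cytosolic and is flagged.
#'
#' @param alignments Alignment data frame from [align_to_trna()].
#' @param reads The `collapsed_reads` the alignments were computed from.
#' @param models Named list of [trna_gene_model()]s.
#' @return A `tsrna_records` object: list with `table` (one row per tsRNA) and
#'   `counts` (matrix, tsRNAs x samples, read-count weighted).
#' @export
merge_and_name <- function(alignments, reads, models) {
  if (nrow(alignments) == 0L) {
    stop("no alignments to merge")
  }
  alignments$type <- classify_alignments(alignments, models)
  rows <- list()
  counts <- list()
  for (rid in unique(alignments$read_id)) {
    al <- alignments[alignments$read_id == rid, , drop = FALSE]
    wsum <- tapply(al$weight, al$type, sum)
    best <- max(wsum)
    winners <- sort(names(wsum)[wsum >= best - 1e-12])
    type <- winners[1]
    ambiguous_type <- length(winners) > 1L
    parents <- sort(unique(al$gene_id))
    aa_ac <- unique(vapply(parents, function(g) {
      paste(models[[g]]$amino_acid, models[[g]]$anticodon, sep = "-")
    }, ""))
    ambiguous_parents <- length(aa_ac) > 1L
    first <- models[[parents[1]]]
    origins <- vapply(parents, function(g) models[[g]]$origin, "")
    mixed_origin <- length(unique(origins)) > 1L
    origin <- if (all(origins == "mitochondrial")) "mitochondrial" else "cytosolic"
    sp <- tapply(al$weight, al$space, sum)
    space <- names(sp)[which.max(sp)]
    cnt <- reads$counts[rid, ]
    rows[[length(rows) + 1L]] <- data.frame(
      read_id = rid, type = type, sequence = unname(reads$sequence[[rid]]),
      parents = paste(parents, collapse = ";"),
      amino_acid = first$amino_acid, anticodon = first$anticodon,
      origin = origin, source_space = space,
      ambiguous_type = ambiguous_type, ambiguous_parents = ambiguous_parents,
      mixed_origin = mixed_origin, total_count = sum(cnt),
      stringsAsFactors = FALSE
    )
    counts[[length(counts) + 1L]] <- cnt
  }
  tab <- do.call(rbind, rows)
  cmat <- do.call(rbind, counts)
  colnames(cmat) <- colnames(reads$counts)
  prefix <- ifelse(grepl("^tiRNA", tab$type), "tiRNA", "tRF")
  family <- paste(prefix, tab$amino_acid, tab$anticodon, sep = "-")
  ord <- order(family, -tab$total_count, tab$sequence)
  tab <- tab[ord, , drop = FALSE]
  cmat <- cmat[ord, , drop = FALSE]
  family <- family[ord]
  serial <- stats::ave(seq_along(family), family, FUN = seq_along)
  tab$name <- sprintf("%s-%03d", family, serial)
  tab$read_id <- NULL
  tab <- tab[, c("name", "type", "sequence", "parents", "amino_acid",
                 "anticodon", "origin", "source_space", "ambiguous_type",
                 "ambiguous_parents", "mixed_origin", "total_count")]
  # present records in descending overall abundance
  ord2 <- order(-tab$total_count, tab$sequence)
  tab <- tab[ord2, , drop = FALSE]
  cmat <- cmat[ord2, , drop = FALSE]
  rownames(tab) <- NULL
  rownames(cmat) <- tab$name
  structure(list(table = tab, counts = cmat), class = "tsrna_records")
}

#' @export
print.tsrna_records <- function(x, ...) {
  cat(sprintf("<tsrna_records> %d tsRNAs, %d sample(s), %.0f reads\n",
              nrow(x$table), ncol(x$counts), sum(x$counts)))
  print(utils::head(x$table[, c("name", "type", "sequence", "origin",
                                "total_count")]))
  invisible(x)
}

pct <- function(x) if (sum(x) > 0) 100 * x / sum(x) else x * 0

#' Landscape summary tables for a tsRNA record set
#'
#' Produces the standard descriptive tables: type composition (by distinct
#' tsRNA and by read count), the 15-45 nt length histogram, the
#' mitochondrial/cytosolic and mature/precursor splits, and per-parental-tRNA
#' and per-amino-acid portions. Distinct-count and read-count versions are both
#' reported because published percentages mix the two bases. All percentage
#' columns sum to 100 within a table.
#'
#' @param records A `tsrna_records` object.
#' @param groups Optional factor/character of group labels per sample; when
#'   given, read-count type compositions are also reported per group.
#' @return Named list of data frames: `type_composition`, `length_histogram`,
#'   `origin_split`, `space_split`, `parent_portions`, `aa_portions`.
#' @export
summarize_landscape <- function(records, groups = NULL) {
  tab <- records$table
  if (nrow(tab) == 0L) stop("no records to summarize")
  rc <- rowSums(records$counts)
  types <- tsrna_types()
  d_type <- vapply(types, function(t) sum(tab$type == t), 0)
  r_type <- vapply(types, function(t) sum(rc[tab$type == t]), 0)
  type_composition <- data.frame(
    type = types, distinct = d_type, distinct_pct = pct(d_type),
    reads = r_type, reads_pct = pct(r_type), row.names = NULL
  )
  if (!is.null(groups)) {
    groups <- as.character(groups)
    for (g in unique(groups)) {
      gc <- rowSums(records$counts[, groups == g, drop = FALSE])
      rg <- vapply(types, function(t) sum(gc[tab$type == t]), 0)
      type_composition[[paste0("reads_pct_", g)]] <- pct(rg)
    }
  }
  lens <- nchar(tab$sequence)
  bins <- 15:45
  length_histogram <- data.frame(
    length = bins,
    distinct = vapply(bins, function(b) sum(lens == b), 0),
    reads = vapply(bins, function(b) sum(rc[lens == b]), 0)
  )
  origin_split <- data.frame(
    origin = c("cytosolic", "mitochondrial"),
    distinct_pct = pct(c(sum(tab$origin == "cytosolic"),
                         sum(tab$origin == "mitochondrial"))),
    reads_pct = pct(c(sum(rc[tab$origin == "cytosolic"]),
                      sum(rc[tab$origin == "mitochondrial"])))
  )
  space_split <- data.frame(
    space = c("mature", "precursor"),
    distinct_pct = pct(c(sum(tab$source_space == "mature"),
                         sum(tab$source_space == "precursor"))),
    reads_pct = pct(c(sum(rc[tab$source_space == "mature"]),
                      sum(rc[tab$source_space == "precursor"])))
  )
  fam <- paste(tab$amino_acid, tab$anticodon, sep = "-")
  fams <- sort(unique(fam))
  parent_portions <- data.frame(
    parent_trna = fams,
    distinct_pct = pct(vapply(fams, function(f) sum(fam == f), 0)),
    reads_pct = pct(vapply(fams, function(f) sum(rc[fam == f]), 0))
  )
  aas <- sort(unique(tab$amino_acid))
  aa_portions <- data.frame(
    amino_acid = aas,
    distinct_pct = pct(vapply(aas, function(a) sum(tab$amino_acid == a), 0)),
    reads_pct = pct(vapply(aas, function(a) sum(rc[tab$amino_acid == a]), 0))
  )
  list(type_composition = type_composition,
       length_histogram = length_histogram,
       origin_split = origin_split, space_split = space_split,
       parent_portions = parent_portions, aa_portions = aa_portions)
}

#' Write tsRNA records (with per-sample counts) to TSV
#'
#' @param records A `tsrna_records` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tsrna_records <- function(records, path) {
  out <- cbind(records$table, as.data.frame(records$counts))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
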