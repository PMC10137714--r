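#' tRNA gene models with cloverleaf landmarks
#'
#' A `trna_gene_model` bundles the genomic sequence of a tRNA gene, its mature
#' (intron-spliced, CCA-terminated) sequence, the 3' trailer of the precursor
#' transcript, and the cloverleaf landmark coordinates used by the fragment
#' classifier. All coordinates are 1-based closed intervals on the mature
#' sequence; precursor coordinates extend the mature axis, so trailer position
#' one is `mature_end + 1`.
#'
#' @param gene_id Gene identifier, e.g. `"tRNA-Gly-GCC-2-1"`.
#' @param amino_acid Amino acid carried by the tRNA (one of the 22 labels used
#'   for tRNA genes, including `"Sec"` and `"iMet"`).
#' @param anticodon Three-letter anticodon (DNA alphabet).
#' @param origin `"cytosolic"` or `"mitochondrial"`.
#' @param gene_seq Genomic sequence of the gene (DNA alphabet).
#' @param intron_span Optional length-2 integer vector, the 1-based closed
#'   intron interval on `gene_seq`.
#' @param trailer_seq 3' trailer of the precursor transcript (may be `""`).
#' @param landmarks A list with elements `d_loop`, `anticodon_loop`,
#'   `anticodon`, `t_loop` (each a length-2 integer interval on the mature
#'   sequence) and `mature_end` (integer, the position of the 3' A of CCA).
#' @return An object of class `trna_gene_model`.
#' @seealso [validate_trna_gene_model()], [load_trna_references()],
#'   [canonical_template()]
#' @export
trna_gene_model <- function(gene_id, amino_acid, anticodon, origin, gene_seq,
                            intron_span = NULL, trailer_seq = "", landmarks) {
  origin <- match.arg(origin, c("cytosolic", "mitochondrial"))
  mat <- build_mature(gene_seq, intron_span)
  landmarks$mature_end <- as.integer(landmarks$mature_end)
  model <- structure(
    list(
      gene_id = as.character(gene_id),
      amino_acid = as.character(amino_acid),
      anticodon = toupper(as.character(anticodon)),
      origin = origin,
      gene_seq = toupper(gene_seq),
      intron_span = if (is.null(intron_span)) NULL else as.integer(intron_span),
      mature_seq = mat$mature_seq,
      cca_appended = mat$cca_appended,
      trailer_seq = toupper(trailer_seq),
      landmarks = landmarks
    ),
    class = "trna_gene_model"
  )
  model
}

#' Splice and CCA-terminate a tRNA gene sequence
#'
#' Removes the intron (if any) and appends a 3' CCA when the spliced sequence
#' does not already end in CCA, mirroring post-transcriptional CCA addition.
#'
#' @inheritParams trna_gene_model
#' @return A list with `mature_seq`, logical `cca_appended`, and `length`.
#' @export
build_mature <- function(gene_seq, intron_span = NULL) {
  gene_seq <- toupper(gene_seq)
  n <- nchar(gene_seq)
  if (!is.null(intron_span)) {
    intron_span <- as.integer(intron_span)
    if (length(intron_span) != 2L || intron_span[1] > intron_span[2] ||
        intron_span[1] <= 1L || intron_span[2] >= n) {
      stop("intron_span must lie strictly inside the gene sequence")
    }
    gene_seq <- paste0(
      substr(gene_seq, 1L, intron_span[1] - 1L),
      substr(gene_seq, intron_span[2] + 1L, n)
    )
  }
  cca_appended <- substr(gene_seq, nchar(gene_seq) - 2L, nchar(gene_seq)) != "CCA"
  if (cca_appended) gene_seq <- paste0(gene_seq, "CCA")
  list(mature_seq = gene_seq, cca_appended = cca_appended,
       length = nchar(gene_seq))
}

#' Validate a tRNA gene model
#'
#' Checks the structural invariants: the mature sequence ends in CCA, the
#' landmark intervals are ordered and non-overlapping within the mature
#' sequence, the anticodon landmark sits inside the anticodon loop, and the
#' sequence at the anticodon landmark equals the declared anticodon.
#'
#' @param model A [trna_gene_model()].
#' @return Character vector of problems; `character(0)` when the model is valid.
#' @export
validate_trna_gene_model <- function(model) {
  problems <- character(0)
  lm <- model$landmarks
  len <- nchar(model$mature_seq)
  if (substr(model$mature_seq, len - 2L, len) != "CCA") {
    problems <- c(problems, "mature sequence does not end in CCA")
  }
  if (!identical(as.integer(lm$mature_end), len)) {
    problems <- c(problems, sprintf(
      "mature_end landmark (%d) does not equal mature length (%d)",
      lm$mature_end, len))
  }
  iv <- function(x) length(x) == 2L && x[1] <= x[2] && x[1] >= 1L && x[2] <= len
  for (nm in c("d_loop", "anticodon_loop", "anticodon", "t_loop")) {
    if (!iv(lm[[nm]])) {
      problems <- c(problems, sprintf("landmark %s is not a valid interval", nm))
    }
  }
  if (length(problems) == 0L) {
    if (lm$d_loop[2] >= lm$anticodon_loop[1]) {
      problems <- c(problems, "D loop must end before the anticodon loop starts")
    }
    if (lm$anticodon[1] < lm$anticodon_loop[1] ||
        lm$anticodon[2] > lm$anticodon_loop[2]) {
      problems <- c(problems, "anticodon must lie inside the anticodon loop")
    }
    if (lm$anticodon_loop[2] >= lm$t_loop[1]) {
      problems <- c(problems, "anticodon loop must end before the T loop starts")
    }
    ac_seq <- substr(model$mature_seq, lm$anticodon[1], lm$anticodon[2])
    if (ac_seq != model$anticodon) {
      problems <- c(problems, sprintf(
        "declared anticodon %s does not match mature sequence %s at [%d,%d]",
        model$anticodon, ac_seq, lm$anticodon[1], lm$anticodon[2]))
    }
  }
  problems
}

#' @export
print.trna_gene_model <- function(x, ...) {
  cat(sprintf("<trna_gene_model> %s (%s-%s, %s)\n", x$gene_id, x$amino_acid,
              x$anticodon, x$origin))
  cat(sprintf("  mature %d nt%s, trailer %d nt\n", nchar(x$mature_seq),
              if (x$cca_appended) " (CCA appended)" else "",
              nchar(x$trailer_seq)))
  invisible(x)
}

#' Precursor sequence of a tRNA gene model
#'
#' Mature sequence followed by the 3' trailer; the coordinate axis continues
#' from the mature axis, so the trailer starts at `mature_end + 1`.
#'
#' @param model A [trna_gene_model()].
#' @return Character scalar.
#' @export
precursor_seq <- function(model) {
  paste0(model$mature_seq, model$trailer_seq)
}

#' Load tRNA gene models from FASTA plus a landmark table
#'
#' FASTA headers must follow `>gene_id|amino_acid|anticodon|origin`; the
#' landmark table (TSV) has one row per gene with columns `gene_id`,
#' `d_loop_start`, `d_loop_end`, `ac_loop_start`, `ac_loop_end`,
#' `anticodon_start`, `anticodon_end`, `t_loop_start`, `t_loop_end`,
#' `trailer_seq`. Genes that fail validation are returned in a problem report
#' rather than silently dropped; a gene without a landmark row is a hard error.
#'
#' @param fasta_path Path to the gene FASTA.
#' @param landmark_table_path Path to the landmark TSV.
#' @return A list with `models` (named list of valid [trna_gene_model()]s) and
#'   `problems` (data frame with columns `gene_id`, `problem`).
#' @export
load_trna_references <- function(fasta_path, landmark_table_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  lmt <- utils::read.delim(landmark_table_path, stringsAsFactors = FALSE)
  needed <- c("gene_id", "d_loop_start", "d_loop_end", "ac_loop_start",
              "ac_loop_end", "anticodon_start", "anticodon_end",
              "t_loop_start", "t_loop_end", "trailer_seq")
  missing_cols <- setdiff(needed, names(lmt))
  if (length(missing_cols) > 0L) {
    stop("landmark table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  models <- list()
  problems <- list()
  for (i in seq_along(seqs)) {
    header <- names(seqs)[i]
    fields <- strsplit(header, "|", fixed = TRUE)[[1]]
    if (length(fields) != 4L) {
      stop("unparseable FASTA header (expected gene_id|amino_acid|anticodon|origin): ",
           header)
    }
    gene_id <- fields[1]
    row <- lmt[lmt$gene_id == gene_id, , drop = FALSE]
    if (nrow(row) == 0L) stop("no landmark row for gene ", gene_id)
    gene_seq <- as.character(seqs[[i]])
    mature_len <- build_mature(gene_seq)$length
    landmarks <- list(
      d_loop = c(row$d_loop_start, row$d_loop_end),
      anticodon_loop = c(row$ac_loop_start, row$ac_loop_end),
      anticodon = c(row$anticodon_start, row$anticodon_end),
      t_loop = c(row$t_loop_start, row$t_loop_end),
      mature_end = mature_len
    )
    trailer <- row$trailer_seq
    if (is.na(trailer)) trailer <- ""
    model <- trna_gene_model(
      gene_id = gene_id, amino_acid = fields[2], anticodon = fields[3],
      origin = fields[4], gene_seq = gene_seq, trailer_seq = trailer,
      landmarks = landmarks
    )
    probs <- validate_trna_gene_model(model)
    if (length(probs) > 0L) {
      problems[[length(problems) + 1L]] <-
        data.frame(gene_id = gene_id, problem = probs,
                   stringsAsFactors = FALSE)
    } else {
      models[[gene_id]] <- model
    }
  }
  problems <- if (length(problems) > 0L) {
    do.call(rbind, problems)
  } else {
    data.frame(gene_id = character(0), problem = character(0))
  }
  list(models = models, problems = problems)
}

#' Write tRNA gene models to FASTA plus a landmark table
#'
#' Inverse of [load_trna_references()]: the gene sequences go to FASTA with
#' `>gene_id|amino_acid|anticodon|origin` headers and the landmarks to a TSV.
#'
#' @param models Named list of [trna_gene_model()]s.
#' @param fasta_path,landmark_table_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_trna_references <- function(models, fasta_path, landmark_table_path) {
  seqs <- Biostrings::DNAStringSet(vapply(models, `[[`, "", "gene_seq"))
  names(seqs) <- vapply(models, function(m) {
    paste(m$gene_id, m$amino_acid, m$anticodon, m$origin, sep = "|")
  }, "")
  Biostrings::writeXStringSet(seqs, fasta_path)
  lmt <- do.call(rbind, lapply(models, function(m) {
    lm <- m$landmarks
    data.frame(
      gene_id = m$gene_id,
      d_loop_start = lm$d_loop[1], d_loop_end = lm$d_loop[2],
      ac_loop_start = lm$anticodon_loop[1], ac_loop_end = lm$anticodon_loop[2],
      anticodon_start = lm$anticodon[1], anticodon_end = lm$anticodon[2],
      t_loop_start = lm$t_loop[1], t_loop_end = lm$t_loop[2],
      trailer_seq = m$trailer_seq,
      stringsAsFactors = FALSE
    )
  }))
  utils::write.table(lmt, landmark_table_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta_path, landmark_table_path))
}

#' Canonical 76-nt tRNA archetype
#'
#' A deterministic mature tRNA model on standard tRNA numbering, used by tests
#' and the simulator: D loop at positions 14-21, anticodon loop at 32-38 with
#' the anticodon at 34-36, T loop at 54-60, CCA ending at position 76, and a
#' 16-nt precursor trailer ending in TTTT. The sequence is fixed (a Gly-GCC
#' archetype), so repeated calls return byte-identical models.
#'
#' @return A [trna_gene_model()].
#' @export
canonical_template <- function() {
  seq76 <- paste0(
    "GCGGGAATAGCTC",  #  1-13 acceptor/D stem
    "AGTTGGTA",       # 14-21 D loop
    "GAGCGCACGC",     # 22-31
    "CTGCCAA",        # 32-38 anticodon loop (GCC at 34-36)
    "TCGGCAGGGTTCGAC",# 39-53
    "TCCCTGT",        # 54-60 T loop
    "GGGTCCGCCCTCACCA"# 61-76, ends CCA
  )
  stopifnot(nchar(seq76) == 76L)
  trna_gene_model(
    gene_id = "tRNA-Gly-GCC-1-1", amino_acid = "Gly", anticodon = "GCC",
    origin = "cytosolic", gene_seq = seq76,
    trailer_seq = "AGCTAGCTAGCCTTTT",
    landmarks = list(
      d_loop = c(14L, 21L), anticodon_loop = c(32L, 38L),
      anticodon = c(34L, 36L), t_loop = c(54L, 60L), mature_end = 76L
    )
  )
}
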