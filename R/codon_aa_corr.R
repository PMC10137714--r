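#' The 20-letter comparison amino-acid alphabet
#'
#' Parental tRNA labels span 22 values (the 20 standard amino acids plus
#' initiator Met and selenocysteine), but translation of coding sequences with
#' the standard genetic code can neither produce Sec nor distinguish iMet.
#' Comparisons therefore use the 20 standard three-letter codes, with parental
#' iMet folded into Met and Sec excluded (renormalized).
#'
#' @return Character vector of 20 three-letter codes.
#' @export
aa_alphabet <- function() {
  c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His", "Ile",
    "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp", "Tyr", "Val")
}

.aa1to3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
             Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
             L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
             S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val")

#' Amino-acid usage of coding sequences
#'
#' Translates each CDS with the standard genetic code, treating every codon
#' literally (alternative initiator codons such as CTG are not remapped to
#' Met; lengths not divisible by three are trimmed with a warning), pools
#' codons over the gene subset,
#' excludes stop codons, and returns proportions over [aa_alphabet()]. Each
#' gene contributes its codon counts once (no expression weighting).
#'
#' @param cds Named character vector of CDS sequences, or a FASTA path.
#' @param gene_subset Optional character vector of gene ids to pool (default
#'   all).
#' @return An `aa_usage` object: named numeric proportions (summing to 1)
#'   with attribute `n_codons`.
#' @export
aa_usage_from_cds <- function(cds, gene_subset = NULL) {
  if (is.character(cds) && length(cds) == 1L && file.exists(cds)) {
    cds <- as.character(Biostrings::readDNAStringSet(cds))
  }
  if (!is.null(gene_subset)) {
    missing <- setdiff(gene_subset, names(cds))
    if (length(missing) > 0L) {
      stop("genes absent from the CDS set: ", paste(missing, collapse = ", "))
    }
    cds <- cds[gene_subset]
  }
  if (length(cds) == 0L) stop("empty gene subset")
  counts <- stats::setNames(numeric(length(aa_alphabet())), aa_alphabet())
  for (s in cds) {
    s <- toupper(s)
    extra <- nchar(s) %% 3L
    if (extra != 0L) {
      warning("CDS length not divisible by 3; trailing ", extra,
              " nt trimmed")
      s <- substr(s, 1L, nchar(s) - extra)
    }
    aa <- strsplit(as.character(
      Biostrings::translate(Biostrings::DNAString(s),
                            no.init.codon = TRUE,
                            if.fuzzy.codon = "solve")), "")[[1]]
    aa <- aa[aa != "*"]
    tab <- table(.aa1to3[aa])
    counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
  }
  n_codons <- sum(counts)
  if (n_codons == 0) stop("no non-stop codons in the subset")
  structure(counts / n_codons, n_codons = n_codons, class = "aa_usage")
}

#' Parental amino-acid spectrum of a tsRNA record set
#'
#' Proportions of tsRNAs per parental amino acid, per distinct tsRNA (the
#' default, matching counts of identified tsRNAs) or weighted by reads.
#' Records with multiple parents that disagree on amino acid are split
#' fractionally across them. iMet is folded into Met; Sec-parented mass is
#' excluded and the proportions renormalized (the number of excluded units is
#' recorded in the `sec_excluded` attribute).
#'
#' @param records A `tsrna_records` object.
#' @param models Named list of [trna_gene_model()]s (for per-parent labels).
#' @param basis `"distinct"` (default) or `"reads"`.
#' @return An `aa_usage` object over [aa_alphabet()].
#' @export
tsrna_parental_aa <- function(records, models, basis = c("distinct", "reads")) {
  basis <- match.arg(basis)
  tab <- records$table
  rc <- rowSums(records$counts)
  counts <- stats::setNames(numeric(length(aa_alphabet())), aa_alphabet())
  sec_excluded <- 0
  for (i in seq_len(nrow(tab))) {
    parents <- strsplit(tab$parents[i], ";", fixed = TRUE)[[1]]
    aas <- unique(vapply(parents, function(g) models[[g]]$amino_acid, ""))
    aas[aas == "iMet"] <- "Met"
    aas <- unique(aas)
    unit <- if (basis == "distinct") 1 else rc[i]
    share <- unit / length(aas)
    for (a in aas) {
      if (a == "Sec") {
        sec_excluded <- sec_excluded + share
      } else {
        counts[a] <- counts[a] + share
      }
    }
  }
  tot <- sum(counts)
  if (tot == 0) stop("no non-Sec parental mass")
  structure(counts / tot, n_codons = NULL, basis = basis,
            sec_excluded = sec_excluded, class = "aa_usage")
}

#' Correlate two amino-acid usage vectors
#'
#' Pearson correlation (with a two-sided t-test) between two proportion
#' vectors over the shared amino-acid alphabet. The comparison is invariant
#' to rescaling either vector by a constant.
#'
#' @param v1,v2 `aa_usage` objects or named numeric vectors over the same
#'   alphabet.
#' @return List with `r` and `p`.
#' @export
aa_correlation <- function(v1, v2) {
  if (!setequal(names(v1), names(v2))) stop("alphabet mismatch")
  v2 <- v2[names(v1)]
  cc <- correlate(as.numeric(v1), as.numeric(v2))
  list(r = cc$r, p = cc$p)
}

#' @export
print.aa_usage <- function(x, ...) {
  cat(sprintf("<aa_usage> %d amino acids\n", length(x)))
  print(round(unclass(x), 4))
  invisible(x)
}
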