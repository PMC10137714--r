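#' Seed-region base-preference profile
#'
#' Position-wise base frequencies over the seed region (positions 2-7 of the
#' small RNA by default), optionally weighted by read counts. The consensus is
#' the argmax base per position, ties broken alphabetically.
#'
#' @param sequences Character vector of small-RNA sequences (DNA alphabet).
#' @param weights Optional non-negative weights (e.g. read counts); default
#'   equal weight per distinct sequence.
#' @param positions Integer positions profiled (default `2:7`).
#' @return A `seed_profile` object: list with `freq` (positions x ACGT matrix
#'   of frequencies), `consensus` (character scalar), `n_sequences`, and
#'   `positions`. Sequences shorter than `max(positions)` are excluded with a
#'   warning.
#' @export
seed_profile <- function(sequences, weights = NULL, positions = 2:7) {
  if (is.null(weights)) weights <- rep(1, length(sequences))
  stopifnot(length(weights) == length(sequences), all(weights >= 0))
  too_short <- nchar(sequences) < max(positions)
  if (any(too_short)) {
    warning(sum(too_short), " sequence(s) shorter than ", max(positions),
            " nt excluded from the seed profile")
    sequences <- sequences[!too_short]
    weights <- weights[!too_short]
  }
  bases <- c("A", "C", "G", "T")
  freq <- matrix(0, nrow = length(positions), ncol = 4,
                 dimnames = list(paste0("pos", positions), bases))
  if (length(sequences) > 0L && sum(weights) > 0) {
    for (i in seq_along(positions)) {
      ch <- substr(sequences, positions[i], positions[i])
      for (b in bases) freq[i, b] <- sum(weights[ch == b])
    }
    freq <- freq / rowSums(freq)
  }
  consensus <- paste(apply(freq, 1, function(row) {
    bases[which.max(row)]  # which.max takes the first (alphabetical) maximum
  }), collapse = "")
  structure(list(freq = freq, consensus = consensus,
                 n_sequences = length(sequences), positions = positions),
            class = "seed_profile")
}

#' @export
print.seed_profile <- function(x, ...) {
  cat(sprintf("<seed_profile> positions %d-%d over %d sequence(s), consensus %s\n",
              min(x$positions), max(x$positions), x$n_sequences, x$consensus))
  print(round(x$freq, 3))
  invisible(x)
}

#' Fragment length distribution
#'
#' Integer-binned histogram over the small-RNA length window, by distinct
#' sequence and by read count.
#'
#' @param sequences Character vector of sequences.
#' @param counts Optional read counts per sequence (default 1 each).
#' @param bins Integer bins (default `15:45`).
#' @return Data frame with `length`, `distinct`, `reads`.
#' @export
length_distribution <- function(sequences, counts = NULL, bins = 15:45) {
  if (is.null(counts)) counts <- rep(1, length(sequences))
  lens <- nchar(sequences)
  data.frame(
    length = bins,
    distinct = vapply(bins, function(b) sum(lens == b), 0),
    reads = vapply(bins, function(b) sum(counts[lens == b]), 0)
  )
}
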