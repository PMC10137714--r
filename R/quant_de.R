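#' Reads-per-million normalization
#'
#' @param counts Numeric matrix, features x samples; column sums must be > 0.
#' @return Matrix of the same shape whose columns each sum to one million.
#' @export
normalize_rpm <- function(counts) {
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("zero library size")
  sweep(counts, 2, lib, "/") * 1e6
}

#' Scale columns to the geometric mean library size
#'
#' Deterministic library-size equalization used before the conditional exact
#' test; scaled values are kept as reals.
#'
#' @param counts Numeric matrix, features x samples.
#' @param lib_sizes Optional per-sample library sizes; defaults to the column
#'   sums of `counts`.
#' @return Matrix with equal (geometric-mean) column sums.
#' @export
equalize_lib_sizes <- function(counts, lib_sizes = NULL) {
  lib <- if (is.null(lib_sizes)) colSums(counts) else lib_sizes
  if (any(lib <= 0)) stop("zero library size")
  target <- exp(mean(log(lib)))
  sweep(counts, 2, target / lib, "*")
}

#' Method-of-moments estimate of a common negative binomial dispersion
#'
#' On library-size-equalized counts, pools the per-feature, per-group excess
#' of the sample variance over the sample mean and divides by the pooled
#' squared mean: for NB counts `var = mu + phi * mu^2`, so the ratio estimates
#' `phi`. The estimate is floored at zero.
#'
#' @param counts Numeric matrix, features x samples.
#' @param group Factor/character of length `ncol(counts)` with two levels and
#'   at least two samples per level.
#' @param lib_sizes Optional known per-sample library sizes; defaults to the
#'   column sums of `counts`.
#' @return Non-negative scalar dispersion estimate.
#' @export
estimate_common_dispersion <- function(counts, group, lib_sizes = NULL) {
  group <- as.factor(group)
  if (nlevels(group) != 2L) stop("exactly two groups are required")
  if (any(table(group) < 2L)) stop("at least 2 replicates per group are required")
  eq <- equalize_lib_sizes(counts, lib_sizes)
  num <- 0
  den <- 0
  for (g in levels(group)) {
    sub <- eq[, group == g, drop = FALSE]
    mu <- rowMeans(sub)
    v <- apply(sub, 1, stats::var)
    num <- num + sum(v - mu)
    den <- den + sum(mu^2)
  }
  max(0, num / den)
}

# Two-sided conditional exact NB p-value for one feature.
# Given rounded group sums sa, sb (after library-size equalization), the null
# conditional distribution of SA given SA + SB = t is proportional to
# dnbinom(s, size = na/phi, mu) * dnbinom(t - s, size = nb/phi, mu'); for
# phi = 0 it is binomial(t, na/(na+nb)). Two-sided p sums all outcomes at
# least as unlikely as the observed one (minimum-likelihood rule).
nb_exact_pvalue_one <- function(sa, sb, na, nb, phi) {
  t <- as.integer(round(sa) + round(sb))
  if (t == 0L) return(1)
  s <- 0:t
  if (phi <= 0) {
    logp <- stats::dbinom(s, t, na / (na + nb), log = TRUE)
  } else {
    mu <- t / (na + nb)
    logp <- stats::dnbinom(s, size = na / phi, mu = na * mu, log = TRUE) +
      stats::dnbinom(t - s, size = nb / phi, mu = nb * mu, log = TRUE)
    logp <- logp - max(logp)
  }
  p <- exp(logp)
  p <- p / sum(p)
  obs <- p[as.integer(round(sa)) + 1L]
  min(1, sum(p[p <= obs * (1 + 1e-10)]))
}

#' Conditional exact negative binomial test between two groups
#'
#' Counts are library-size-equalized by scaling to the geometric mean library
#' size; per feature, the group sums are compared by a two-sided exact test
#' conditional on their total under a common-dispersion negative binomial
#' model (an exact binomial test when `dispersion = 0`). Log2 fold change is
#' computed from group mean equalized counts with a 0.5 pseudo-count (applied
#' to the fold change only, never to the test). Benjamini-Hochberg FDR is
#' reported alongside; significance follows the raw-p rule
#' `|log2FC| >= lfc_threshold` and `p <= p_threshold`.
#'
#' @param counts Numeric matrix, features x samples (rownames are feature ids).
#' @param group Factor/character of length `ncol(counts)` with two levels; the
#'   first level is group A (fold changes are A over B).
#' @param dispersion Common NB dispersion; `NULL` (default) estimates it with
#'   [estimate_common_dispersion()].
#' @param lfc_threshold,p_threshold Significance thresholds (defaults 1, 0.05).
#' @param lib_sizes Optional known per-sample library sizes (e.g. sequencing
#'   depths); defaults to the column sums of `counts`.
#' @return Data frame with `feature_id`, `log2fc`, `p_value`, `fdr`,
#'   `significant`, `direction` (`up_in_A`/`up_in_B`/`ns`).
#' @export
nb_exact_test <- function(counts, group, dispersion = NULL,
                          lfc_threshold = 1, p_threshold = 0.05,
                          lib_sizes = NULL) {
  group <- as.factor(group)
  if (nlevels(group) != 2L) stop("exactly two groups are required")
  if (is.null(dispersion)) {
    dispersion <- estimate_common_dispersion(counts, group, lib_sizes)
  }
  if (dispersion < 0) stop("dispersion must be >= 0")
  eq <- equalize_lib_sizes(counts, lib_sizes)
  a_idx <- group == levels(group)[1]
  na <- sum(a_idx)
  nb <- sum(!a_idx)
  sa <- rowSums(eq[, a_idx, drop = FALSE])
  sb <- rowSums(eq[, !a_idx, drop = FALSE])
  ma <- sa / na
  mb <- sb / nb
  log2fc <- log2((ma + 0.5) / (mb + 0.5))
  p <- vapply(seq_len(nrow(eq)), function(i) {
    nb_exact_pvalue_one(sa[i], sb[i], na, nb, dispersion)
  }, 0)
  all_zero <- sa + sb == 0
  p[all_zero] <- 1
  log2fc[all_zero] <- 0
  fdr <- stats::p.adjust(p, method = "BH")
  significant <- abs(log2fc) >= lfc_threshold & p <= p_threshold
  direction <- ifelse(!significant, "ns",
                      ifelse(log2fc > 0, "up_in_A", "up_in_B"))
  ids <- rownames(counts)
  if (is.null(ids)) ids <- sprintf("feature_%05d", seq_len(nrow(counts)))
  data.frame(feature_id = ids, log2fc = log2fc, p_value = p, fdr = fdr,
             significant = significant, direction = direction,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Tally differential features and build a clustering-ready table
#'
#' @param results Data frame from [nb_exact_test()].
#' @param counts Optional count matrix (same features) used to build a
#'   z-scored RPM table of the significant features for heatmaps/clustering.
#' @return List with `tally` (named vector `up_in_A`, `up_in_B`) and `zscore`
#'   (matrix or `NULL`).
#' @export
de_summary <- function(results, counts = NULL) {
  tally <- c(up_in_A = sum(results$direction == "up_in_A"),
             up_in_B = sum(results$direction == "up_in_B"))
  zscore <- NULL
  if (!is.null(counts)) {
    sig <- results$feature_id[results$significant]
    if (length(sig) > 0L) {
      rpm <- normalize_rpm(counts)[sig, , drop = FALSE]
      zscore <- t(scale(t(log2(rpm + 1))))
      zscore[is.nan(zscore)] <- 0
    }
  }
  list(tally = tally, zscore = zscore)
}

#' Read/write count matrices as TSV with a sidecar group map
#'
#' @param counts Numeric matrix, features x samples.
#' @param path Output path for the matrix TSV (header row = sample ids).
#' @param group Optional group labels written to `<path>.groups.tsv`.
#' @return Invisibly, `path`.
#' @export
write_count_matrix <- function(counts, path, group = NULL) {
  df <- data.frame(feature_id = rownames(counts), counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(group)) {
    utils::write.table(
      data.frame(sample_id = colnames(counts), group = as.character(group)),
      paste0(path, ".groups.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_count_matrix
#' @return For `read_count_matrix`: a list with `counts` and `group` (or
#'   `NULL` when no sidecar file exists).
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df[[1]]
  gpath <- paste0(path, ".groups.tsv")
  group <- NULL
  if (file.exists(gpath)) {
    g <- utils::read.delim(gpath, stringsAsFactors = FALSE)
    group <- stats::setNames(g$group, g$sample_id)[colnames(counts)]
  }
  list(counts = counts, group = group)
}
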