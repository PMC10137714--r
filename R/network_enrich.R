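#' Pearson correlation with a two-sided t-test
#'
#' Thin wrapper around [stats::cor.test()] that flags degenerate (constant)
#' inputs instead of erroring.
#'
#' @param x,y Equal-length numeric vectors (length >= 3, finite values).
#' @return List with `r`, `p`, and logical `degenerate` (`TRUE` with `r` and
#'   `p` set to `NA` when either vector is constant).
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3L) stop("at least 3 paired observations are required")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, degenerate = TRUE))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, degenerate = FALSE)
}

#' Assemble the regulator/mRNA anti-correlation network
#'
#' Candidate edges are duplex hits whose regulator and target are both
#' differentially expressed; an edge is retained when the two features move in
#' opposite directions between the groups and their expression Pearson
#' correlation across the common samples is negative. A correlation p-value
#' cut is available but off by default: at three replicates per group
#' correlation p-values carry little information, so the sign rule is the
#' honest default.
#'
#' @param de_regulators,de_targets DE result data frames (from
#'   [nb_exact_test()]) for the regulators (tsRNAs and/or miRNAs) and the
#'   mRNAs.
#' @param duplex_hits Data frame from [predict_targets()].
#' @param reg_expr,target_expr Expression matrices (features x samples) with
#'   identical, aligned sample columns (>= 3 shared samples).
#' @param corr_p_max Optional correlation p-value cut (e.g. 0.05); `NULL`
#'   (default) disables it.
#' @return Data frame of `NetworkEdge`s: `regulator_id`, `target_gene_id`,
#'   `mfe`, `pearson_r`, `corr_p`, `retained`.
#' @export
build_network <- function(de_regulators, de_targets, duplex_hits,
                          reg_expr, target_expr, corr_p_max = NULL) {
  stopifnot(identical(colnames(reg_expr), colnames(target_expr)),
            ncol(reg_expr) >= 3L)
  reg_dir <- stats::setNames(de_regulators$direction, de_regulators$feature_id)
  tgt_dir <- stats::setNames(de_targets$direction, de_targets$feature_id)
  rows <- list()
  for (i in seq_len(nrow(duplex_hits))) {
    rid <- duplex_hits$regulator_id[i]
    gid <- duplex_hits$gene_id[i]
    rd <- reg_dir[rid]
    td <- tgt_dir[gid]
    if (is.na(rd) || is.na(td) || rd == "ns" || td == "ns") next
    cc <- correlate(reg_expr[rid, ], target_expr[gid, ])
    retained <- !cc$degenerate && rd != td && cc$r < 0 &&
      (is.null(corr_p_max) || cc$p <= corr_p_max)
    rows[[length(rows) + 1L]] <- data.frame(
      regulator_id = rid, target_gene_id = gid, mfe = duplex_hits$mfe[i],
      pearson_r = cc$r, corr_p = cc$p, retained = retained,
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0L) {
    return(data.frame(regulator_id = character(0),
                      target_gene_id = character(0), mfe = numeric(0),
                      pearson_r = numeric(0), corr_p = numeric(0),
                      retained = logical(0)))
  }
  do.call(rbind, rows)
}

#' Top-k hub nodes by degree
#'
#' Degree is counted over retained edges; ties are broken by node id.
#'
#' @param edges Edge data frame from [build_network()].
#' @param k Number of hubs to return (default 10).
#' @return Data frame with `node` and `degree`, degree-sorted.
#' @export
hub_nodes <- function(edges, k = 10L) {
  edges <- edges[edges$retained, , drop = FALSE]
  if (nrow(edges) == 0L) {
    return(data.frame(node = character(0), degree = integer(0)))
  }
  deg <- table(c(edges$regulator_id, edges$target_gene_id))
  out <- data.frame(node = names(deg), degree = as.integer(deg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$node), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, k)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT path (term, description, then member genes, tab-separated).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, "", USE.NAMES = FALSE)
  sets
}

#' Over-representation analysis (hypergeometric)
#'
#' Per term, the upper-tail hypergeometric probability of observing at least
#' the overlap between the query and the term within the universe, with
#' Benjamini-Hochberg FDR across terms.
#'
#' @param query_genes Character vector of query genes (subset of universe).
#' @param universe Character vector, the gene universe.
#' @param gene_sets Named list of character vectors, or a GMT path.
#' @return Data frame with `term_id`, `term_size`, `overlap`, `p_value`,
#'   `fdr`.
#' @export
ora_hypergeometric <- function(query_genes, universe, gene_sets) {
  if (is.character(gene_sets) && length(gene_sets) == 1L) {
    gene_sets <- read_gmt(gene_sets)
  }
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  query_genes <- unique(query_genes)
  if (!all(query_genes %in% universe)) {
    stop("query genes must be a subset of the universe")
  }
  N <- length(universe)
  q <- length(query_genes)
  res <- lapply(names(gene_sets), function(term) {
    set <- intersect(unique(gene_sets[[term]]), universe)
    m <- length(set)
    k <- length(intersect(set, query_genes))
    p <- stats::phyper(k - 1L, m, N - m, q, lower.tail = FALSE)
    data.frame(term_id = term, term_size = m, overlap = k, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

# Classic GSEA running sum for one set on a decreasing-score ranking.
gsea_running_es <- function(ranked_genes, scores, set, weight_p = 1) {
  hit <- ranked_genes %in% set
  nh <- sum(hit)
  n <- length(ranked_genes)
  if (nh == 0L || nh == n) return(NA_real_)
  w <- abs(scores)^weight_p
  inc <- ifelse(hit, w / sum(w[hit]), -1 / (n - nh))
  run <- cumsum(inc)
  run[which.max(abs(run))]
}

#' Preranked gene set enrichment analysis
#'
#' Classic running-sum enrichment score: hits increment by their
#' `|score|^weight_p` share, misses decrement by `1/(N - Nh)`; the enrichment
#' score (ES) is the signed extremum of the running sum. Significance comes
#' from gene-label permutation with a fixed seed: the normalized ES (NES)
#' divides ES by the mean |permuted ES| of matching sign, and the permutation
#' p-value is the fraction of same-sign permuted ES at least as extreme.
#' Benjamini-Hochberg FDR is reported across terms.
#'
#' @param scores Named numeric vector (gene -> ranking score), any order;
#'   genes must be unique and scores finite.
#' @param gene_sets Named list of character vectors, or a GMT path.
#' @param n_perm Number of gene-label permutations (default 1000).
#' @param weight_p Score weighting exponent (default 1; 0 gives the
#'   unweighted Kolmogorov-Smirnov-style statistic).
#' @param seed Integer seed for the permutations.
#' @return Data frame with `term_id`, `term_size`, `es`, `nes`, `p_value`,
#'   `fdr`; sets with no gene in the ranking are skipped with a warning.
#' @export
gsea_preranked <- function(scores, gene_sets, n_perm = 1000L, weight_p = 1,
                           seed = 1L) {
  if (is.character(gene_sets) && length(gene_sets) == 1L) {
    gene_sets <- read_gmt(gene_sets)
  }
  stopifnot(all(is.finite(scores)), !is.null(names(scores)),
            !anyDuplicated(names(scores)))
  ord <- order(scores, decreasing = TRUE)
  ranked <- names(scores)[ord]
  sc <- unname(scores[ord])
  n <- length(ranked)
  rows <- list()
  for (term in names(gene_sets)) {
    set <- intersect(unique(gene_sets[[term]]), ranked)
    if (length(set) == 0L) {
      warning("gene set ", term, " has no genes in the ranking; skipped")
      next
    }
    es <- gsea_running_es(ranked, sc, set, weight_p)
    set.seed(seed)
    perm_es <- vapply(seq_len(n_perm), function(i) {
      gsea_running_es(ranked, sc, sample(ranked, length(set)), weight_p)
    }, 0)
    same_sign <- perm_es[sign(perm_es) == sign(es)]
    if (length(same_sign) == 0L) {
      p <- 1 / (n_perm + 1)
      nes <- NA_real_
    } else {
      p <- (sum(abs(same_sign) >= abs(es)) + 1) / (length(same_sign) + 1)
      nes <- es / mean(abs(same_sign))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      term_id = term, term_size = length(set), es = es, nes = nes,
      p_value = p, stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0L) {
    return(data.frame(term_id = character(0), term_size = integer(0),
                      es = numeric(0), nes = numeric(0), p_value = numeric(0),
                      fdr = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}
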