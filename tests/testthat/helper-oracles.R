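# Brute-force reference implementations used as oracles, plus tiny fixtures.
# These are deliberately naive (full scans, exhaustive recursion) so that
# agreement with the package implementations is evidence of correctness.

# Exhaustive gap-free placement of one read over all references, mirroring the
# aligner's conventions: sense strand only, precursor placements kept only when
# they extend past the mature 3' end, and only the optimal mismatch level
# reported.
brute_align_one <- function(seq, models, max_mismatch = 0L) {
  sv <- strsplit(seq, "")[[1]]
  L <- length(sv)
  by_mm <- list(`0` = list(), `1` = list())
  for (m in models) {
    me <- m$landmarks$mature_end
    for (space in c("mature", "precursor")) {
      src <- if (space == "mature") m$mature_seq else precursor_seq(m)
      if (nchar(src) < L) next
      for (st in seq_len(nchar(src) - L + 1L)) {
        en <- st + L - 1L
        if (space == "precursor" && en <= me) next
        d <- sum(strsplit(substr(src, st, en), "")[[1]] != sv)
        if (d <= 1L) {
          key <- as.character(d)
          by_mm[[key]][[length(by_mm[[key]]) + 1L]] <- data.frame(
            gene_id = m$gene_id, space = space, start = st, end = en,
            mismatches = d, stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  hits <- if (length(by_mm[["0"]]) > 0L) {
    by_mm[["0"]]
  } else if (max_mismatch >= 1L && length(by_mm[["1"]]) > 0L) {
    by_mm[["1"]]
  } else {
    return(NULL)
  }
  out <- do.call(rbind, hits)
  out[order(out$gene_id, out$space, out$start), , drop = FALSE]
}

# Exhaustive minimum free energy over all antiparallel base-pair chains,
# mirroring the DP's move set: consecutive pairs either stack or are separated
# by a bulge/internal loop of at most max_loop unpaired nucleotides per side.
brute_duplex_mfe <- function(regulator_seq, window_seq, model = energy_model()) {
  r <- strsplit(toupper(regulator_seq), "")[[1]]
  q <- rev(strsplit(toupper(window_seq), "")[[1]])
  n <- length(r)
  m <- length(q)
  pairable <- outer(r, q, tsrnaflow:::can_pair)
  if (!any(pairable)) return(NULL)
  ml <- model$max_loop
  best <- Inf
  extend <- function(i, j, e) {
    if (e < best) best <<- e
    imax <- min(n, i + 1L + ml)
    jmax <- min(m, j + 1L + ml)
    for (i2 in seq(i + 1L, imax)) {
      if (i2 > n) break
      for (j2 in seq(j + 1L, jmax)) {
        if (j2 > m) break
        if (!pairable[i2, j2]) next
        a <- i2 - i - 1L
        b <- j2 - j - 1L
        trans <- if (a == 0L && b == 0L) {
          model$stacks[[paste0(r[i], r[i2], "/", q[j], q[j2])]]
        } else if (a == 0L || b == 0L) {
          (a + b) * model$bulge_penalty
        } else {
          (a + b) * model$internal_loop_penalty
        }
        extend(i2, j2, e + trans)
      }
    }
  }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      if (pairable[i, j]) extend(i, j, 0)
    }
  }
  model$init_penalty + min(best, 0)
}

# Classic running-sum enrichment score computed independently of the package.
brute_gsea_es <- function(ranked_genes, scores, set, weight_p = 1) {
  hit <- ranked_genes %in% set
  w <- abs(scores)^weight_p
  run <- 0
  extremum <- 0
  for (i in seq_along(ranked_genes)) {
    run <- run + if (hit[i]) w[i] / sum(w[hit]) else -1 / sum(!hit)
    if (abs(run) > abs(extremum)) extremum <- run
  }
  extremum
}

# A second, structurally distinct gene model (90-nt mature, shifted loops)
# for tests that need heterogeneous geometry.
shifted_template <- function() {
  set.seed(404)
  s <- strsplit(tsrnaflow:::random_dna(90L), "")[[1]]
  s[40:42] <- c("T", "T", "C")
  s[88:90] <- c("C", "C", "A")
  trna_gene_model(
    gene_id = "tRNA-Glu-TTC-9-1", amino_acid = "Glu", anticodon = "TTC",
    origin = "cytosolic", gene_seq = paste(s, collapse = ""),
    trailer_seq = "GATTACAGATTACATTTT",
    landmarks = list(
      d_loop = c(16L, 25L), anticodon_loop = c(38L, 44L),
      anticodon = c(40L, 42L), t_loop = c(62L, 70L), mature_end = 90L
    )
  )
}
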