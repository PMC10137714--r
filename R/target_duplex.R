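#' Nearest-neighbor duplex energy model
#'
#' Stacking free energies for an intermolecular RNA duplex (DNA input letters
#' are treated as RNA, T = U). Keys follow the `5'XY3'/3'WZ5'` convention
#' (X pairs W, Y pairs Z). The 16 Watson-Crick stacks carry standard
#' nearest-neighbor values; wobble-containing stacks use a simplified flat
#' value (-1.3 kcal/mol with one wobble pair, -0.5 with two). Loops are
#' penalized per unpaired nucleotide. The table is bundled, versioned package
#' data, not a reproduction of any external tool's parameter set.
#'
#' @param init_penalty Duplex initiation penalty, kcal/mol (default 4.09).
#' @param bulge_penalty Penalty per unpaired nucleotide in a bulge (one-sided
#'   loop), kcal/mol (default 3.0).
#' @param internal_loop_penalty Penalty per unpaired nucleotide in an internal
#'   (two-sided) loop, kcal/mol (default 1.5).
#' @param max_loop Maximum unpaired nucleotides per side between consecutive
#'   base pairs (default 4).
#' @return An `energy_model` object.
#' @export
energy_model <- function(init_penalty = 4.09, bulge_penalty = 3.0,
                         internal_loop_penalty = 1.5, max_loop = 4L) {
  stopifnot(init_penalty >= 0, bulge_penalty >= 0, internal_loop_penalty >= 0,
            max_loop >= 1L)
  structure(list(
    stacks = build_stack_table(),
    init_penalty = init_penalty,
    bulge_penalty = bulge_penalty,
    internal_loop_penalty = internal_loop_penalty,
    max_loop = as.integer(max_loop)
  ), class = "energy_model")
}

# Canonical pairs in DNA letters (T stands for U).
.pairs <- list(c("A", "T"), c("T", "A"), c("G", "C"), c("C", "G"),
               c("G", "T"), c("T", "G"))
.wc <- c("A:T", "T:A", "G:C", "C:G")

can_pair <- function(a, b) {
  (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G") |
    (a == "G" & b == "T") | (a == "T" & b == "G")
}

# Watson-Crick nearest-neighbor stack table (kcal/mol), 5'XY3'/3'WZ5',
# plus the 180-degree symmetry partners ZW/YX, plus flat wobble values.
build_stack_table <- function() {
  base10 <- c(
    "AA/TT" = -0.93, "AT/TA" = -1.10, "TA/AT" = -1.33,
    "CT/GA" = -2.08, "CA/GT" = -2.11, "GT/CA" = -2.24,
    "GA/CT" = -2.35, "CG/GC" = -2.36, "GG/CC" = -3.26, "GC/CG" = -3.42
  )
  stacks <- numeric(0)
  for (k in names(base10)) {
    stacks[k] <- base10[[k]]
    x <- substr(k, 1, 1); y <- substr(k, 2, 2)
    w <- substr(k, 4, 4); z <- substr(k, 5, 5)
    stacks[paste0(z, w, "/", y, x)] <- base10[[k]]
  }
  for (p1 in .pairs) {
    for (p2 in .pairs) {
      key <- paste0(p1[1], p2[1], "/", p1[2], p2[2])
      if (!key %in% names(stacks)) {
        wob <- sum(!(paste(p1, collapse = ":") %in% .wc),
                   !(paste(p2, collapse = ":") %in% .wc))
        stacks[key] <- if (wob >= 2) -0.5 else -1.3
      }
    }
  }
  stacks
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Scan a 3'UTR for exact seed-complementary sites
#'
#' Finds every UTR window whose 6-mer is the exact reverse complement of
#' regulator positions 2-7 (Watson-Crick only; no G:U in the seed).
#'
#' @param regulator_seq Small-RNA sequence (>= 8 nt).
#' @param utr_seq 3'UTR sequence (>= 7 nt).
#' @return Data frame with `site_start`, `site_end` (1-based closed on the
#'   UTR) and `seed_class` (`"full_2_7"`); zero rows when no site exists.
#' @export
seed_scan <- function(regulator_seq, utr_seq) {
  regulator_seq <- toupper(regulator_seq)
  utr_seq <- toupper(utr_seq)
  stopifnot(nchar(regulator_seq) >= 8L, nchar(utr_seq) >= 7L)
  seed <- substr(regulator_seq, 2L, 7L)
  target <- revcomp(seed)
  m <- gregexpr(target, utr_seq, fixed = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(site_start = integer(0), site_end = integer(0),
                      seed_class = character(0)))
  }
  data.frame(site_start = as.integer(m), site_end = as.integer(m) + 5L,
             seed_class = "full_2_7", stringsAsFactors = FALSE)
}

#' Minimum free energy of an intermolecular duplex
#'
#' Dynamic program over gapped, antiparallel base-pair chains between the
#' regulator and a target window, allowing nearest-neighbor stacks, bulges and
#' internal loops with up to `max_loop` unpaired nucleotides per side, plus
#' the initiation penalty. No intramolecular structure is considered.
#'
#' @param regulator_seq,window_seq Sequences (DNA letters; T = U).
#' @param model An [energy_model()].
#' @return `NULL` when no base pair can form, otherwise a list with `mfe`
#'   (kcal/mol) and `trace` (data frame of paired positions: `reg_pos` on the
#'   regulator, `window_pos` on the window, both 1-based 5'->3').
#' @export
duplex_mfe <- function(regulator_seq, window_seq, model = energy_model()) {
  r <- strsplit(toupper(regulator_seq), "")[[1]]
  w <- strsplit(toupper(window_seq), "")[[1]]
  q <- rev(w)  # bottom strand, read 3'->5' left to right under the regulator
  n <- length(r)
  m <- length(q)
  pairable <- outer(r, q, can_pair)
  if (!any(pairable)) return(NULL)
  ml <- model$max_loop
  stacks <- model$stacks
  E <- matrix(Inf, n, m)
  bpi <- matrix(NA_integer_, n, m)
  bpj <- matrix(NA_integer_, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      if (!pairable[i, j]) next
      best <- 0  # chain may start at this pair
      bi <- NA_integer_; bj <- NA_integer_
      for (k in seq(i - 1L, max(1L, i - 1L - ml))) {
        if (k < 1L) break
        a <- i - k - 1L
        for (l in seq(j - 1L, max(1L, j - 1L - ml))) {
          if (l < 1L) break
          if (!is.finite(E[k, l])) next
          b <- j - l - 1L
          trans <- if (a == 0L && b == 0L) {
            stacks[[paste0(r[k], r[i], "/", q[l], q[j])]]
          } else if (a == 0L || b == 0L) {
            (a + b) * model$bulge_penalty
          } else {
            (a + b) * model$internal_loop_penalty
          }
          cand <- E[k, l] + trans
          if (cand < best) {
            best <- cand; bi <- k; bj <- l
          }
        }
      }
      E[i, j] <- best
      bpi[i, j] <- bi
      bpj[i, j] <- bj
    }
  }
  idx <- which(E == min(E), arr.ind = TRUE)[1, , drop = TRUE]
  mfe <- model$init_penalty + E[idx[1], idx[2]]
  # traceback
  reg_pos <- integer(0); q_pos <- integer(0)
  i <- idx[1]; j <- idx[2]
  while (!is.na(i)) {
    reg_pos <- c(i, reg_pos); q_pos <- c(j, q_pos)
    i2 <- bpi[i, j]; j2 <- bpj[i, j]
    i <- i2; j <- j2
  }
  list(mfe = unname(mfe),
       trace = data.frame(reg_pos = reg_pos, window_pos = m - q_pos + 1L))
}

#' Predict regulator targets on 3'UTRs with a duplex energy filter
#'
#' For every regulator/UTR pair: exact seed-complementary sites (positions
#' 2-7) are located, each site is extended 30 nt upstream on the UTR (clipped
#' at the 5' end), the duplex minimum free energy is computed, and hits with
#' `mfe <= energy_threshold` are retained. One best hit (lowest energy, ties
#' by leftmost site) is kept per regulator/gene pair.
#'
#' @param regulators Named character vector of small-RNA sequences.
#' @param utrs Named character vector of 3'UTR sequences (names are gene ids).
#' @param energy_threshold Retention threshold in kcal/mol (default -20; more
#'   negative duplexes are more stable).
#' @param model An [energy_model()].
#' @param upstream Upstream extension of the seed site on the UTR (nt).
#' @return Data frame of `DuplexHit`s: `regulator_id`, `gene_id`,
#'   `site_start`, `site_end`, `mfe`, `seed_class`.
#' @export
predict_targets <- function(regulators, utrs, energy_threshold = -20,
                            model = energy_model(), upstream = 30L) {
  rows <- list()
  for (rid in names(regulators)) {
    for (gid in names(utrs)) {
      sites <- seed_scan(regulators[[rid]], utrs[[gid]])
      if (nrow(sites) == 0L) next
      best <- NULL
      for (s in seq_len(nrow(sites))) {
        win_start <- max(1L, sites$site_start[s] - upstream)
        window <- substr(utrs[[gid]], win_start, sites$site_end[s])
        if (nchar(window) < 8L) next
        dp <- duplex_mfe(regulators[[rid]], window, model)
        if (is.null(dp) || dp$mfe > energy_threshold) next
        hit <- data.frame(
          regulator_id = rid, gene_id = gid,
          site_start = sites$site_start[s], site_end = sites$site_end[s],
          mfe = dp$mfe, seed_class = sites$seed_class[s],
          stringsAsFactors = FALSE
        )
        if (is.null(best) || hit$mfe < best$mfe ||
            (hit$mfe == best$mfe && hit$site_start < best$site_start)) {
          best <- hit
        }
      }
      if (!is.null(best)) rows[[length(rows) + 1L]] <- best
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(regulator_id = character(0), gene_id = character(0),
                      site_start = integer(0), site_end = integer(0),
                      mfe = numeric(0), seed_class = character(0)))
  }
  do.call(rbind, rows)
}
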