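#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. The defaults emulate
#' the study design the package targets: two tissue groups with three
#' replicates each, 44 tRNA genes across the 22 amino-acid labels with about
#' one gene in ten mitochondrial, a type mixture dominated by tRF-5c, a
#' lognormal abundance model (sdlog 1.5) that concentrates most reads in a few
#' tsRNAs, negative binomial counts with dispersion 0.1, and planted two-fold
#' (log2) expression differences.
#'
#' @param n_genes Number of simulated tRNA genes.
#' @param n_fragments Number of distinct tsRNA fragments to draw.
#' @param type_mixture Named proportions over [tsrna_types()] (must sum to 1).
#' @param error_rate Per-base substitution probability in `[0, 0.05]`.
#' @param n_samples_per_group Replicates per group (two groups).
#' @param dispersion Negative binomial dispersion of the counts.
#' @param planted_log2fc Numeric vector of log2 fold changes (group A over B)
#'   planted on randomly chosen fragments; others are null.
#' @param mean_log,sd_log Lognormal abundance parameters (meanlog, sdlog).
#' @param n_regulators,n_utr_targets,n_decoys Regulatory-system sizes.
#' @param target_site_kind `"perfect"` (full complementary site) or
#'   `"seed_only"`.
#' @param beta Regulator-target coupling strength of the expression model.
#' @param aa_target_r Planted parental-AA vs codon-usage Pearson correlation.
#' @param seed Integer RNG seed; a fixed seed makes every generator
#'   deterministic.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 44L, n_fragments = 300L,
                              type_mixture = c("tRF-5a" = 0.05, "tRF-5b" = 0.10,
                                               "tRF-5c" = 0.35, "tRF-3a" = 0.08,
                                               "tRF-3b" = 0.10, "tRF-1" = 0.05,
                                               "i-tRF" = 0.12, "tiRNA-5" = 0.10,
                                               "tiRNA-3" = 0.05),
                              error_rate = 0.001,
                              n_samples_per_group = 3L, dispersion = 0.1,
                              planted_log2fc = numeric(0),
                              mean_log = log(50), sd_log = 1.5,
                              n_regulators = 6L, n_utr_targets = 10L,
                              n_decoys = 20L,
                              target_site_kind = c("perfect", "seed_only"),
                              beta = 1, aa_target_r = 0.7, seed = 1L) {
  target_site_kind <- match.arg(target_site_kind)
  stopifnot(abs(sum(type_mixture) - 1) < 1e-8,
            all(names(type_mixture) %in% tsrna_types()),
            error_rate >= 0, error_rate <= 0.05, dispersion >= 0,
            n_samples_per_group >= 2L)
  structure(list(
    n_genes = as.integer(n_genes), n_fragments = as.integer(n_fragments),
    type_mixture = type_mixture, error_rate = error_rate,
    n_samples_per_group = as.integer(n_samples_per_group),
    dispersion = dispersion, planted_log2fc = planted_log2fc,
    mean_log = mean_log, sd_log = sd_log,
    n_regulators = as.integer(n_regulators),
    n_utr_targets = as.integer(n_utr_targets), n_decoys = as.integer(n_decoys),
    target_site_kind = target_site_kind, beta = beta,
    aa_target_r = aa_target_r, seed = as.integer(seed)
  ), class = "simulation_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# One representative anticodon per parental label (DNA letters).
.anticodon_map <- c(
  Ala = "AGC", Arg = "ACG", Asn = "GTT", Asp = "GTC", Cys = "GCA",
  Gln = "TTG", Glu = "TTC", Gly = "GCC", His = "GTG", Ile = "AAT",
  Leu = "CAA", Lys = "CTT", Met = "CAT", Phe = "GAA", Pro = "AGG",
  Ser = "AGA", Thr = "AGT", Trp = "CCA", Tyr = "GTA", Val = "AAC",
  iMet = "CAT", Sec = "TCA"
)

#' Simulate a tRNA reference set
#'
#' Genes are built on the canonical cloverleaf coordinates (see
#' [canonical_template()]) with randomized sequence content, the assigned
#' anticodon written at positions 34-36 and a genomic CCA at the 3' end.
#' Amino-acid labels cycle through the 22 parental labels and every tenth
#' gene is flagged mitochondrial. All models validate.
#'
#' @param n_genes Number of genes (>= 1).
#' @param seed Integer RNG seed.
#' @return Named list of [trna_gene_model()]s.
#' @export
simulate_reference <- function(n_genes = 44L, seed = 1L) {
  stopifnot(n_genes >= 1L)
  set.seed(seed)
  labels <- c(aa_alphabet(), "iMet", "Sec")
  tmpl <- canonical_template()
  models <- list()
  serial <- stats::setNames(integer(length(labels)), labels)
  for (i in seq_len(n_genes)) {
    aa <- labels[((i - 1L) %% length(labels)) + 1L]
    serial[aa] <- serial[aa] + 1L
    anticodon <- .anticodon_map[[aa]]
    repeat {
      s <- strsplit(random_dna(76L), "")[[1]]
      s[34:36] <- strsplit(anticodon, "")[[1]]
      s[74:76] <- c("C", "C", "A")
      seq76 <- paste(s, collapse = "")
      if (!seq76 %in% vapply(models, `[[`, "", "gene_seq")) break
    }
    gene_id <- sprintf("tRNA-%s-%s-%d-1", aa, anticodon, serial[aa])
    model <- trna_gene_model(
      gene_id = gene_id, amino_acid = aa, anticodon = anticodon,
      origin = if (i %% 10L == 0L) "mitochondrial" else "cytosolic",
      gene_seq = seq76,
      trailer_seq = paste0(random_dna(12L), "TTTT"),
      landmarks = tmpl$landmarks
    )
    probs <- validate_trna_gene_model(model)
    if (length(probs) > 0L) stop("simulated gene failed validation: ", probs[1])
    models[[gene_id]] <- model
  }
  models
}

# All (space, start, end) placements on a model that classify to each type,
# within the read-length window.
admissible_windows <- function(model, min_len = 15L, max_len = 45L) {
  me <- model$landmarks$mature_end
  g <- expand.grid(start = seq_len(me), len = min_len:max_len)
  g$end <- g$start + g$len - 1L
  mat <- g[g$end <= me, c("start", "end")]
  mat$space <- "mature"
  pre_len <- me + nchar(model$trailer_seq)
  g2 <- expand.grid(start = (me + 1L):(me + 2L), len = min_len:max_len)
  g2$end <- g2$start + g2$len - 1L
  pre <- g2[g2$end <= pre_len & g2$start <= pre_len, c("start", "end")]
  pre$space <- if (nrow(pre) > 0L) "precursor" else character(0)
  df <- rbind(mat, pre)
  df$type <- vapply(seq_len(nrow(df)), function(i) {
    classify_fragment(model, df$start[i], df$end[i], df$space[i])
  }, "")
  split(df[, c("space", "start", "end")], df$type)
}

mutate_one_base <- function(seq) {
  pos <- sample.int(nchar(seq), 1L)
  old <- substr(seq, pos, pos)
  new <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
  paste0(substr(seq, 1L, pos - 1L), new, substr(seq, pos + 1L, nchar(seq)))
}

#' Simulate a tsRNA fragmentome with full ground truth
#'
#' Draws distinct fragments according to the configured type mixture, with cut
#' coordinates sampled uniformly within each type's admissible window on a
#' randomly chosen gene; per-fragment abundance is lognormal, per-sample
#' counts are negative binomial, planted log2 fold changes lower the group-B
#' mean, and sequencing errors substitute single bases at the configured rate.
#'
#' @param models Named list of [trna_gene_model()]s.
#' @param config A [simulation_config()].
#' @return List with `reads` (a `collapsed_reads` object over all samples),
#'   `truth` (data frame: `fragment_id`, `gene_id`, `type`, `space`, `start`,
#'   `end`, `sequence`, `base_mean`, `log2fc`), `groups` (named group labels
#'   per sample), and `resampled` (count of candidates skipped because of
#'   sequence collisions plus type draws redirected because a type's
#'   admissible fragment space was exhausted). The realized type counts can
#'   therefore fall below the mixture for types with few admissible cuts.
#' @export
simulate_fragmentome <- function(models, config = simulation_config()) {
  set.seed(config$seed)
  nf <- config$n_fragments
  ns <- config$n_samples_per_group
  samples <- c(sprintf("A%d", seq_len(ns)), sprintf("B%d", seq_len(ns)))
  groups <- stats::setNames(rep(c("A", "B"), each = ns), samples)
  # windows depend only on the landmark geometry, so cache by signature
  win_cache <- list()
  get_windows <- function(gene_id) {
    m <- models[[gene_id]]
    key <- paste(unlist(m$landmarks), nchar(m$trailer_seq), collapse = "_")
    if (is.null(win_cache[[key]])) {
      win_cache[[key]] <<- admissible_windows(m)
    }
    win_cache[[key]]
  }
  types <- sample(names(config$type_mixture), nf, replace = TRUE,
                  prob = config$type_mixture)
  # per-type candidate pools over all genes, shuffled and drawn without
  # replacement: sampling always terminates even when a type's admissible
  # fragment space is smaller than its demand (tRF-5c, for instance, has few
  # admissible cuts per gene because in-loop 5' fragments of half length are
  # tiRNA-5 by definition)
  pools <- list()
  for (gid in names(models)) {
    wins <- get_windows(gid)
    for (t in names(wins)) {
      if (nrow(wins[[t]]) == 0L) next
      w <- wins[[t]]
      w$gene_id <- gid
      pools[[t]] <- if (is.null(pools[[t]])) w else rbind(pools[[t]], w)
    }
  }
  pools <- lapply(pools, function(p) p[sample.int(nrow(p)), , drop = FALSE])
  cursor <- stats::setNames(rep(1L, length(pools)), names(pools))
  seqs <- character(nf)
  truth <- vector("list", nf)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  resampled <- 0L
  pop_window <- function(type) {
    # next unseen candidate of this type, or NULL when the pool is exhausted
    p <- pools[[type]]
    while (!is.null(p) && cursor[[type]] <= nrow(p)) {
      w <- p[cursor[[type]], ]
      cursor[[type]] <<- cursor[[type]] + 1L
      src <- if (w$space == "mature") models[[w$gene_id]]$mature_seq
             else precursor_seq(models[[w$gene_id]])
      sq <- substr(src, w$start, w$end)
      if (is.null(seen[[sq]])) {
        seen[[sq]] <- TRUE
        return(list(w = w, sq = sq))
      }
      resampled <<- resampled + 1L
    }
    NULL
  }
  for (i in seq_len(nf)) {
    hit <- pop_window(types[i])
    while (is.null(hit)) {
      # this type's fragment space is used up: fall back to a type that still
      # has candidates, re-weighted by the configured mixture
      open <- names(pools)[cursor[names(pools)] <=
                             vapply(pools, nrow, 0L)]
      if (length(open) == 0L) {
        stop("the admissible fragment space is exhausted; ",
             "lower n_fragments or add genes")
      }
      resampled <- resampled + 1L
      types[i] <- sample(open, 1L, prob = config$type_mixture[open])
      hit <- pop_window(types[i])
    }
    w <- hit$w
    seqs[i] <- hit$sq
    truth[[i]] <- data.frame(
      fragment_id = sprintf("frag_%04d", i), gene_id = w$gene_id,
      type = types[i], space = w$space, start = w$start, end = w$end,
      sequence = hit$sq, stringsAsFactors = FALSE
    )
  }
  truth <- do.call(rbind, truth)
  truth$base_mean <- stats::rlnorm(nf, config$mean_log, config$sd_log)
  lfc <- numeric(nf)
  np <- length(config$planted_log2fc)
  if (np > 0L) {
    lfc[sample.int(nf, np)] <- config$planted_log2fc
  }
  truth$log2fc <- lfc
  phi <- config$dispersion
  draw <- function(mu) {
    if (phi <= 0) stats::rpois(length(mu), mu)
    else stats::rnbinom(length(mu), size = 1 / phi, mu = mu)
  }
  seq_list <- list()
  for (s in samples) {
    mu <- if (groups[[s]] == "A") truth$base_mean
          else truth$base_mean * 2^(-truth$log2fc)
    cnt <- draw(mu)
    clean <- cnt
    err_seqs <- character(0)
    if (config$error_rate > 0) {
      L <- nchar(truth$sequence)
      p_err <- 1 - (1 - config$error_rate)^L
      n_err <- stats::rbinom(nf, cnt, p_err)
      clean <- cnt - n_err
      for (i in which(n_err > 0L)) {
        err_seqs <- c(err_seqs, vapply(seq_len(n_err[i]), function(k) {
          mutate_one_base(truth$sequence[i])
        }, ""))
      }
    }
    seq_list[[s]] <- c(rep(truth$sequence, clean), err_seqs)
  }
  reads <- collapse_sequences(seq_list)
  list(reads = reads, truth = truth, groups = groups, resampled = resampled)
}

#' Write a simulated fragmentome as per-sample FASTQ files
#'
#' Expands the collapsed reads of [simulate_fragmentome()] into plain FASTQ
#' (constant quality `I`), one file per sample.
#'
#' @param sim Result of [simulate_fragmentome()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths.
#' @export
write_fragmentome_fastq <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (s in colnames(sim$reads$counts)) {
    cnt <- sim$reads$counts[, s]
    keep <- cnt > 0
    seqs <- rep(sim$reads$sequence[keep], cnt[keep])
    path <- file.path(dir, paste0(s, ".fastq"))
    con <- file(path, "w")
    for (i in seq_along(seqs)) {
      writeLines(c(sprintf("@%s_r%06d", s, i), seqs[i], "+",
                   strrep("I", nchar(seqs[i]))), con)
    }
    close(con)
    paths[s] <- path
  }
  paths
}

#' Simulate a regulator/target system with planted binding sites
#'
#' Each true target 3'UTR carries a planted site for its regulator (a perfect
#' reverse-complement site, or a seed-only site); decoy genes carry none.
#' Regulators are expressed higher in group B; each target's per-sample mean
#' is anti-coupled to its regulator's (standardized log) expression, so true
#' pairs are anti-correlated and differential in opposite directions.
#'
#' The simulated libraries are depth-matched: the per-sample sequencing depth
#' is known and equal by construction, so downstream tests should use the
#' returned `lib_sizes` rather than column sums of these small feature panels.
#'
#' @param config A [simulation_config()].
#' @return List with `regulators`, `utrs` (named sequences), `reg_counts`,
#'   `mrna_counts` (matrices, features x samples), `lib_sizes` (equal known
#'   depths), `groups`, and `truth` (data frame of true
#'   `regulator_id` / `gene_id` links).
#' @export
simulate_regulatory_system <- function(config = simulation_config()) {
  stopifnot(config$n_utr_targets >= 1L)
  set.seed(config$seed + 1L)
  ns <- config$n_samples_per_group
  samples <- c(sprintf("A%d", seq_len(ns)), sprintf("B%d", seq_len(ns)))
  groups <- stats::setNames(rep(c("A", "B"), each = ns), samples)
  nr <- config$n_regulators
  regulators <- stats::setNames(
    vapply(seq_len(nr), function(i) random_dna(22L), ""),
    sprintf("reg_%02d", seq_len(nr)))
  nt <- config$n_utr_targets
  reg_of_target <- rep(seq_len(nr), length.out = nt)
  utr_len <- 300L
  utrs <- character(0)
  for (t in seq_len(nt)) {
    utr <- random_dna(utr_len)
    site <- if (config$target_site_kind == "perfect") {
      revcomp(regulators[[reg_of_target[t]]])
    } else {
      revcomp(substr(regulators[[reg_of_target[t]]], 2L, 7L))
    }
    pos <- sample.int(utr_len - nchar(site) + 1L, 1L)
    utr <- paste0(substr(utr, 1L, pos - 1L), site,
                  substr(utr, pos + nchar(site), utr_len))
    utrs[sprintf("target_%02d", t)] <- utr
  }
  for (d in seq_len(config$n_decoys)) {
    utrs[sprintf("decoy_%02d", d)] <- random_dna(utr_len)
  }
  phi <- 0.05
  delta <- 2  # regulator log2 group effect (up in B)
  reg_counts <- matrix(0, nrow = nr, ncol = length(samples),
                       dimnames = list(names(regulators), samples))
  for (r in seq_len(nr)) {
    mu <- ifelse(groups == "A", 200, 200 * 2^delta)
    reg_counts[r, ] <- stats::rnbinom(length(samples), size = 1 / phi, mu = mu)
  }
  mrna_counts <- matrix(0, nrow = length(utrs), ncol = length(samples),
                        dimnames = list(names(utrs), samples))
  for (t in seq_len(nt)) {
    z <- scale(log2(reg_counts[reg_of_target[t], ] + 1))[, 1]
    mu <- 400 * 2^(-config$beta * z)
    mrna_counts[t, ] <- stats::rnbinom(length(samples), size = 1 / phi, mu = mu)
  }
  for (d in seq_len(config$n_decoys)) {
    mrna_counts[nt + d, ] <- stats::rnbinom(length(samples), size = 1 / phi,
                                            mu = 300)
  }
  truth <- data.frame(
    regulator_id = names(regulators)[reg_of_target],
    gene_id = sprintf("target_%02d", seq_len(nt)),
    stringsAsFactors = FALSE
  )
  list(regulators = regulators, utrs = utrs, reg_counts = reg_counts,
       mrna_counts = mrna_counts,
       lib_sizes = stats::setNames(rep(1e6, length(samples)), samples),
       groups = groups, truth = truth)
}

# Representative (stop-free) codon per standard amino acid.
.codon_map <- c(
  Ala = "GCT", Arg = "CGT", Asn = "AAT", Asp = "GAT", Cys = "TGT",
  Gln = "CAA", Glu = "GAA", Gly = "GGT", His = "CAT", Ile = "ATT",
  Leu = "CTG", Lys = "AAA", Met = "ATG", Phe = "TTT", Pro = "CCT",
  Ser = "TCT", Thr = "ACT", Trp = "TGG", Tyr = "TAT", Val = "GTT"
)

#' Simulate CDS sequences with a planted amino-acid usage correlation
#'
#' Takes a parental amino-acid vector (a lognormal draw by default, or a
#' supplied spectrum such as one measured from real records), then constructs the
#' codon-usage vector to have exactly the target Pearson correlation with it:
#' a second lognormal draw is orthogonalized against the (standardized)
#' parental vector and the two are mixed with weights `r` and `sqrt(1-r^2)`;
#' an affine shift keeps the usage positive without changing the correlation.
#' The only residual deviation from `r` comes from rounding the usage to
#' integer codon counts. Codon counts realizing the
#' usage are rounded to integers (large `total_codons` keeps rounding noise
#' small) and distributed over `n_genes` CDS sequences built from one
#' stop-free codon per amino acid, so translating the emitted CDS reproduces
#' the emitted codon-usage vector exactly.
#'
#' @param aa_target_r Target Pearson correlation in `[-1, 1]`.
#' @param n_genes Number of CDS sequences to emit.
#' @param total_codons Total codons across all CDS (>= 300).
#' @param seed Integer RNG seed.
#' @param parental_aa Optional parental amino-acid spectrum (named over
#'   [aa_alphabet()], non-constant) to plant the usage against; by default a
#'   fresh lognormal vector is drawn.
#' @return List with `cds` (named sequences), `parental_aa` and
#'   `codon_usage` (`aa_usage` vectors over [aa_alphabet()]), and `truth`.
#' @export
simulate_cds_with_aa_corr <- function(aa_target_r = 0.7, n_genes = 20L,
                                      total_codons = 3000L, seed = 1L,
                                      parental_aa = NULL) {
  stopifnot(aa_target_r >= -1, aa_target_r <= 1, total_codons >= 300L)
  set.seed(seed)
  k <- length(aa_alphabet())
  sigma <- 0.3
  if (is.null(parental_aa)) {
    x <- exp(sigma * stats::rnorm(k))
  } else {
    if (!setequal(names(parental_aa), aa_alphabet())) {
      stop("parental_aa must be named over the 20-letter alphabet")
    }
    x <- as.numeric(parental_aa[aa_alphabet()])
    if (stats::sd(x) == 0) stop("parental_aa is constant")
  }
  a <- as.numeric(scale(x))
  b <- exp(sigma * stats::rnorm(k))
  b <- as.numeric(scale(b - a * sum(a * b) / sum(a * a)))
  y_std <- aa_target_r * a + sqrt(1 - aa_target_r^2) * b
  y <- y_std - min(y_std) + 0.2
  parental <- structure(stats::setNames(x / sum(x), aa_alphabet()),
                        class = "aa_usage")
  counts <- round(total_codons * y / sum(y))
  counts[which.max(counts)] <- counts[which.max(counts)] +
    (total_codons - sum(counts))
  counts <- pmax(counts, 0)
  codon_usage <- structure(stats::setNames(counts / sum(counts), aa_alphabet()),
                           n_codons = sum(counts), class = "aa_usage")
  pool <- sample(rep(aa_alphabet(), counts))
  splits <- cut(seq_along(pool), breaks = n_genes, labels = FALSE)
  cds <- vapply(seq_len(n_genes), function(g) {
    paste(.codon_map[pool[splits == g]], collapse = "")
  }, "")
  names(cds) <- sprintf("gene_%03d", seq_len(n_genes))
  list(cds = cds, parental_aa = parental, codon_usage = codon_usage,
       truth = list(target_r = aa_target_r, counts = counts))
}
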