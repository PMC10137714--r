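#' Pipeline configuration
#'
#' The declarative configuration for an end-to-end run. Thresholds default to
#' the analysis' published decision rules: differential expression at
#' `|log2FC| >= 1` and `p <= 0.05`, duplex retention at `<= -20` kcal/mol,
#' seed positions 2-7. The configuration round-trips losslessly through YAML
#' via [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param outdir Run directory for stage artifacts.
#' @param seed Integer RNG seed used by every stochastic stage.
#' @param lfc_threshold,p_threshold Differential expression thresholds.
#' @param energy_threshold Duplex energy retention threshold (kcal/mol).
#' @param seed_start,seed_end Seed positions on the small RNA.
#' @param max_mismatch Aligner mismatch tolerance (0 or 1).
#' @param sim A [simulation_config()] driving the synthetic inputs.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(outdir = tempfile("tsrnaflow_run_"), seed = 1L,
                            lfc_threshold = 1, p_threshold = 0.05,
                            energy_threshold = -20, seed_start = 2L,
                            seed_end = 7L, max_mismatch = 0L,
                            sim = simulation_config(seed = seed)) {
  structure(list(
    outdir = outdir, seed = as.integer(seed),
    lfc_threshold = lfc_threshold, p_threshold = p_threshold,
    energy_threshold = energy_threshold,
    seed_start = as.integer(seed_start), seed_end = as.integer(seed_end),
    max_mismatch = as.integer(max_mismatch), sim = sim
  ), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass_deep(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim <- raw$sim
  sim$type_mixture <- unlist(sim$type_mixture)
  sim$planted_log2fc <- as.numeric(unlist(sim$planted_log2fc))
  cfg <- do.call(pipeline_config, c(
    raw[setdiff(names(raw), "sim")],
    list(sim = do.call(simulation_config, sim))
  ))
  cfg
}

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) return(lapply(x, unclass_deep))
  # named atomic vectors must become maps, or YAML drops the names
  if (!is.null(names(x)) && length(x) > 0L) return(as.list(x))
  x
}

pipeline_stages <- function() {
  c("simulate", "classify", "quantify", "de", "features", "targets",
    "network", "enrich", "aacorr", "all")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run one pipeline stage (or all of them)
#'
#' Stages operate on the run directory named in the configuration: `simulate`
#' generates the synthetic inputs; `classify` aligns and classifies reads into
#' named tsRNAs with landscape summaries; `quantify`/`de` build the count
#' matrix and test differential expression; `features` emits seed profiles and
#' length distributions; `targets`, `network`, `enrich` and `aacorr` run the
#' regulatory and usage analyses on the simulated system; `all` chains every
#' stage in dependency order and writes a manifest (parameters, seed,
#' parameter hash, artifact list). Identical configurations produce identical
#' artifacts and manifests.
#'
#' @param stage One of `simulate`, `classify`, `quantify`, `de`, `features`,
#'   `targets`, `network`, `enrich`, `aacorr`, `all`.
#' @param config A [pipeline_config()].
#' @return Invisibly, a character vector of artifact paths written by the
#'   stage(s).
#' @export
run_stage <- function(stage, config = pipeline_config()) {
  if (!is.character(stage) || length(stage) != 1L ||
      !stage %in% pipeline_stages()) {
    stop("unknown stage '", paste(stage, collapse = ","),
         "'; must be one of: ", paste(pipeline_stages(), collapse = ", "))
  }
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  od <- function(f) file.path(config$outdir, f)
  artifacts <- character(0)

  if (stage %in% c("simulate", "all")) {
    models <- simulate_reference(config$sim$n_genes, config$sim$seed)
    write_trna_references(models, od("trna.fasta"), od("trna_landmarks.tsv"))
    sim <- simulate_fragmentome(models, config$sim)
    fq <- write_fragmentome_fastq(sim, od("fastq"))
    write_tsv(sim$truth, od("fragment_truth.tsv"))
    write_tsv(data.frame(sample_id = names(sim$groups),
                         group = unname(sim$groups)), od("groups.tsv"))
    artifacts <- c(artifacts, od("trna.fasta"), od("trna_landmarks.tsv"),
                   unname(fq), od("fragment_truth.tsv"), od("groups.tsv"))
    if (stage == "simulate") return(invisible(artifacts))
  }

  for (f in c("trna.fasta", "trna_landmarks.tsv", "groups.tsv")) {
    if (!file.exists(od(f))) {
      stop("missing input: ", od(f), " (run the simulate stage first)")
    }
  }
  refs <- load_trna_references(od("trna.fasta"), od("trna_landmarks.tsv"))
  groups_df <- utils::read.delim(od("groups.tsv"), stringsAsFactors = FALSE)
  groups <- stats::setNames(groups_df$group, groups_df$sample_id)
  fq_files <- stats::setNames(
    file.path(od("fastq"), paste0(names(groups), ".fastq")), names(groups))
  reads <- collapse_reads(fq_files)
  filt <- filter_reads(reads)
  aln <- align_to_trna(filt$reads, refs$models, config$max_mismatch)
  records <- merge_and_name(aln$alignments, filt$reads, refs$models)

  if (stage %in% c("classify", "all")) {
    write_tsrna_records(records, od("tsrna_records.tsv"))
    summ <- summarize_landscape(records, groups[colnames(records$counts)])
    for (nm in names(summ)) {
      write_tsv(summ[[nm]], od(paste0("summary_", nm, ".tsv")))
    }
    artifacts <- c(artifacts, od("tsrna_records.tsv"),
                   od(paste0("summary_", names(summ), ".tsv")))
    if (stage == "classify") return(invisible(artifacts))
  }

  counts <- records$counts
  grp <- factor(groups[colnames(counts)], levels = c("A", "B"))
  if (stage %in% c("quantify", "all")) {
    write_count_matrix(counts, od("tsrna_counts.tsv"), grp)
    write_count_matrix(normalize_rpm(counts), od("tsrna_rpm.tsv"))
    artifacts <- c(artifacts, od("tsrna_counts.tsv"), od("tsrna_rpm.tsv"))
    if (stage == "quantify") return(invisible(artifacts))
  }

  de <- nb_exact_test(counts, grp, lfc_threshold = config$lfc_threshold,
                      p_threshold = config$p_threshold)
  if (stage %in% c("de", "all")) {
    write_tsv(de, od("tsrna_de.tsv"))
    tal <- de_summary(de, counts)
    write_tsv(data.frame(direction = names(tal$tally),
                         n = unname(tal$tally)), od("tsrna_de_tally.tsv"))
    artifacts <- c(artifacts, od("tsrna_de.tsv"), od("tsrna_de_tally.tsv"))
    if (stage == "de") return(invisible(artifacts))
  }

  if (stage %in% c("features", "all")) {
    rc <- rowSums(records$counts)
    prof_d <- seed_profile(records$table$sequence,
                           positions = config$seed_start:config$seed_end)
    prof_w <- seed_profile(records$table$sequence, weights = rc,
                           positions = config$seed_start:config$seed_end)
    write_tsv(data.frame(position = rownames(prof_d$freq), prof_d$freq),
              od("seed_profile_distinct.tsv"))
    write_tsv(data.frame(position = rownames(prof_w$freq), prof_w$freq),
              od("seed_profile_weighted.tsv"))
    write_tsv(length_distribution(records$table$sequence, rc),
              od("length_distribution.tsv"))
    artifacts <- c(artifacts, od("seed_profile_distinct.tsv"),
                   od("seed_profile_weighted.tsv"),
                   od("length_distribution.tsv"))
    if (stage == "features") return(invisible(artifacts))
  }

  reg <- simulate_regulatory_system(config$sim)
  hits <- predict_targets(reg$regulators, reg$utrs,
                          energy_threshold = config$energy_threshold)
  if (stage %in% c("targets", "all")) {
    write_tsv(hits, od("duplex_hits.tsv"))
    artifacts <- c(artifacts, od("duplex_hits.tsv"))
    if (stage == "targets") return(invisible(artifacts))
  }

  rgrp <- factor(reg$groups, levels = c("A", "B"))
  de_reg <- nb_exact_test(reg$reg_counts, rgrp, dispersion = 0.05,
                          lfc_threshold = config$lfc_threshold,
                          p_threshold = config$p_threshold,
                          lib_sizes = reg$lib_sizes)
  de_mrna <- nb_exact_test(reg$mrna_counts, rgrp, dispersion = 0.05,
                           lfc_threshold = config$lfc_threshold,
                           p_threshold = config$p_threshold,
                           lib_sizes = reg$lib_sizes)
  edges <- build_network(de_reg, de_mrna, hits, reg$reg_counts,
                         reg$mrna_counts)
  if (stage %in% c("network", "all")) {
    write_tsv(edges, od("network_edges.tsv"))
    write_tsv(hub_nodes(edges, k = 10L), od("network_hubs.tsv"))
    artifacts <- c(artifacts, od("network_edges.tsv"), od("network_hubs.tsv"))
    if (stage == "network") return(invisible(artifacts))
  }

  if (stage %in% c("enrich", "all")) {
    universe <- rownames(reg$mrna_counts)
    query <- unique(edges$target_gene_id[edges$retained])
    sets <- list(true_targets = rownames(reg$mrna_counts)[
      seq_len(config$sim$n_utr_targets)],
      decoys = grep("^decoy", universe, value = TRUE))
    if (length(query) > 0L) {
      write_tsv(ora_hypergeometric(query, universe, sets), od("ora.tsv"))
    }
    scores <- stats::setNames(de_mrna$log2fc, de_mrna$feature_id)
    write_tsv(gsea_preranked(scores, sets, n_perm = 200L,
                             seed = config$seed), od("gsea.tsv"))
    artifacts <- c(artifacts, od("ora.tsv"), od("gsea.tsv"))
    if (stage == "enrich") return(invisible(artifacts))
  }

  if (stage %in% c("aacorr", "all")) {
    parental <- tsrna_parental_aa(records, refs$models)
    cds <- simulate_cds_with_aa_corr(config$sim$aa_target_r, seed = config$seed,
                                     parental_aa = parental)
    usage <- aa_usage_from_cds(cds$cds)
    common <- aa_correlation(parental, usage)
    write_tsv(data.frame(amino_acid = names(parental),
                         tsrna_parental = as.numeric(parental),
                         cds_usage = as.numeric(usage[names(parental)])),
              od("aa_usage.tsv"))
    write_tsv(data.frame(r = common$r, p = common$p), od("aa_correlation.tsv"))
    artifacts <- c(artifacts, od("aa_usage.tsv"), od("aa_correlation.tsv"))
    if (stage == "aacorr") return(invisible(artifacts))
  }

  pars <- unclass_deep(config)
  pars$outdir <- NULL  # machine-local; must not affect the parameter hash
  manifest <- list(
    stages = "all",
    seed = config$seed,
    parameters = pars,
    parameter_hash = rlang::hash(pars),
    artifacts = sort(basename(unique(artifacts)))
  )
  jsonlite::write_json(manifest, od("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(c(artifacts, od("manifest.json")))
}

#' Run the full pipeline
#'
#' Equivalent to `run_stage("all", config)`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the artifact paths.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  run_stage("all", config)
}
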