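# End-to-end orchestration from a single declarative config.
#
# Stages run in the fixed order simulate -> normalize -> stats -> recon ->
# core -> enrich; a stage runs iff its section is present and not toggled
# off. Every run writes a manifest capturing the package version, the full
# config (seeds included) and checksums of all inputs and outputs, so a
# rerun of the same config on the same inputs is byte-identical and
# verifiably so.

#' Load a pipeline configuration
#'
#' @param path YAML file. Top-level keys: `output_dir`, optional `seed`,
#'   optional `stages` (named logical toggles), and one section per stage
#'   (`simulate`, `normalize`, `stats`, `recon`, `core`, `enrich`) holding
#'   that stage's parameters and input paths.
#' @return The config as a named list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$output_dir)) stopf("config must set output_dir")
  cfg
}

stage_enabled <- function(cfg, stage) {
  on <- cfg$stages[[stage]]
  if (!is.null(on)) isTRUE(on) else !is.null(cfg[[stage]])
}

#' Run the evaluation pipeline from a config
#'
#' Executes the configured stages in order and writes per-stage TSV/JSON
#' outputs plus `manifest.json` under `output_dir`. When a `simulate`
#' section is present, its outputs (reference, contigs, hit table, reads,
#' counts) become the defaults for the downstream stages, giving a fully
#' self-contained demonstration run with known ground truth.
#'
#' @param config A config list or a YAML path (see
#'   [read_pipeline_config()]).
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) read_pipeline_config(config) else config
  if (is.null(cfg$output_dir)) stopf("config must set output_dir")
  out_dir <- cfg$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- character(0)
  outputs <- character(0)
  note <- function(x) outputs <<- unique(c(outputs, x))
  run_stage <- function(stage, code) {
    tryCatch(code, error = function(e)
      stopf("stage '%s' failed: %s", stage, conditionMessage(e)))
  }

  if (stage_enabled(cfg, "simulate")) run_stage("simulate", {
    sc <- cfg$simulate
    seed <- sc$seed %||% cfg$seed %||% 1L
    ref <- simulate_reference(sc$n_genes %||% 50,
                              sc$isoforms_per_gene %||% c(1, 3),
                              sc$protein_length %||% c(150, 600),
                              seed = seed)
    sim_dir <- file.path(out_dir, "sim")
    note(write_reference(ref, sim_dir))
    plan <- unlist(sc$plan %||% list("0.99" = 10, "0.90" = 10, "0.80" = 10,
                                     "0.50" = 10, "sub" = 5))
    ctg <- simulate_contigs(ref, plan, sc$fragmentation %||% 0, seed = seed + 1L)
    p_ctg <- file.path(sim_dir, "contigs.fna")
    Biostrings::writeXStringSet(ctg$contigs, p_ctg); note(p_ctg)
    aln <- simulate_alignments(ctg$truth, ref,
                               spurious_rate = sc$spurious_rate %||% 0,
                               seed = seed + 2L)
    p_hits <- file.path(sim_dir, "hits.tsv")
    write_outfmt6(aln$hits, p_hits); note(p_hits)
    p_truth <- file.path(sim_dir, "truth_contigs.tsv")
    utils::write.table(ctg$truth$provenance, p_truth, sep = "\t",
                       quote = FALSE, row.names = FALSE); note(p_truth)
    if (!is.null(sc$reads)) {
      rd <- simulate_reads(ref, depth = sc$reads$depth %||% 20,
                           read_length = sc$reads$read_length %||% 101,
                           error_rate = sc$reads$error_rate %||% 0.01,
                           seed = seed + 3L)
      p_r1 <- file.path(sim_dir, "reads_1.fastq")
      p_r2 <- file.path(sim_dir, "reads_2.fastq")
      write_fastq(rd$r1, p_r1); write_fastq(rd$r2, p_r2)
      note(c(p_r1, p_r2))
      cfg$normalize$fastq1 <- cfg$normalize$fastq1 %||% p_r1
      cfg$normalize$fastq2 <- cfg$normalize$fastq2 %||% p_r2
    }
    n_core <- sc$n_core %||% max(1L, round(0.02 * length(ref$genes)))
    core <- with_seed(seed + 4L, resample(ref$genes, n_core))
    ex <- simulate_expression(ref, n_libraries = sc$n_libraries %||% 13,
                              core_genes = core,
                              core_multiplier = sc$core_multiplier %||% 10,
                              dispersion = sc$dispersion %||% 0.1,
                              seed = seed + 5L)
    note(write_expression(ex, file.path(sim_dir, "expression")))
    p_core <- file.path(sim_dir, "truth_core_genes.txt")
    writeLines(sort(core), p_core); note(p_core)
    cfg$stats$contigs <- cfg$stats$contigs %||% p_ctg
    cfg$recon$blast <- cfg$recon$blast %||% p_hits
    cfg$recon$proteins <- cfg$recon$proteins %||% file.path(sim_dir, "proteins.faa")
    cfg$recon$gene_map <- cfg$recon$gene_map %||% file.path(sim_dir, "gene_map.tsv")
    cfg$core$counts_dir <- cfg$core$counts_dir %||% file.path(sim_dir, "expression")
  })

  if (stage_enabled(cfg, "normalize")) run_stage("normalize", {
    nc <- cfg$normalize
    inputs <- c(inputs, nc$fastq1, nc$fastq2)
    params <- normalization_params(
      k = nc$k %||% 25, C = nc$C %||% 30, Q = nc$Q %||% 24,
      abund_cutoff = nc$abund_cutoff %||% 2,
      paired_policy = nc$paired_policy %||% "keep-if-either",
      min_read_length = nc$min_read_length %||% 25,
      shuffle_seed = nc$shuffle_seed)
    p1 <- file.path(out_dir, "normalized_1.fastq")
    p2 <- if (!is.null(nc$fastq2)) file.path(out_dir, "normalized_2.fastq")
    plog <- file.path(out_dir, "normalization_log.tsv")
    normalize_fastq(nc$fastq1, nc$fastq2, p1, p2, plog, params,
                    filter_abund = isTRUE(nc$filter_abund))
    note(c(p1, p2, plog))
  })

  if (stage_enabled(cfg, "stats")) run_stage("stats", {
    sc <- cfg$stats
    inputs <- c(inputs, sc$contigs)
    contigs <- Biostrings::readDNAStringSet(sc$contigs)
    st <- contig_stats(contigs, sc$min_length %||% 201)
    p_st <- file.path(out_dir, "contig_stats.tsv")
    utils::write.table(as.data.frame(unclass(st)), p_st, sep = "\t",
                       quote = FALSE, row.names = FALSE); note(p_st)
    hist <- length_histogram(contigs,
                             unlist(sc$bin_edges) %||% c(200, 400, 800, 1600, 3200, 6400, Inf))
    p_h <- file.path(out_dir, "length_histogram.tsv")
    utils::write.table(hist, p_h, sep = "\t", quote = FALSE, row.names = FALSE)
    note(p_h)
    iso <- suppressWarnings(isotig_mean(names(contigs)))
    p_i <- file.path(out_dir, "isotig_mean.tsv")
    utils::write.table(data.frame(isotig_mean = as.numeric(iso)), p_i,
                       sep = "\t", quote = FALSE, row.names = FALSE); note(p_i)
  })

  if (stage_enabled(cfg, "recon")) run_stage("recon", {
    rc <- cfg$recon
    blast_paths <- unlist(rc$blast)
    inputs <- c(inputs, blast_paths, rc$proteins, rc$gene_map)
    db <- protein_db(Biostrings::readAAStringSet(rc$proteins),
                     read_gene_map(rc$gene_map))
    evx <- rc$evalue %||% 1e-10
    levels <- unlist(rc$levels) %||% c(0.99, 0.90, 0.80, 0.50)
    if (length(blast_paths) == 1L) {
      hits <- parse_blast_table(blast_paths, evx)
      rep <- reconstruction_report(hits, db, levels)
    } else {
      tags <- names(blast_paths) %||% basename(blast_paths)
      hit_list <- lapply(seq_along(blast_paths), function(i)
        parse_blast_table(blast_paths[i], evx, library = tags[i]))
      names(hit_list) <- tags
      rep <- union_reports(hit_list, db, levels)
    }
    note(write_report(rep, tsv = file.path(out_dir, "reconstruction_report.tsv"),
                      json = file.path(out_dir, "reconstruction_report.json")))
    ch <- coverage_histogram(rep$gene_best, rc$bin_width %||% 0.01)
    p_ch <- file.path(out_dir, "coverage_histogram.tsv")
    utils::write.table(ch, p_ch, sep = "\t", quote = FALSE, row.names = FALSE)
    note(p_ch)
  })

  core_genes_out <- NULL
  if (stage_enabled(cfg, "core")) run_stage("core", {
    cc <- cfg$core
    count_paths <- unlist(cc[["counts"]]) %||%
      sort(list.files(cc$counts_dir, "^counts_.*\\.tsv$", full.names = TRUE))
    if (length(count_paths) == 0L) stopf("no count tables found")
    eff_path <- cc$eff_lengths %||% file.path(cc$counts_dir, "eff_lengths.tsv")
    inputs <- c(inputs, count_paths, eff_path)
    eff <- read_eff_lengths(eff_path)
    first <- read_counts_tsv(count_paths[1L])
    counts <- vapply(count_paths, function(p) read_counts_tsv(p)[names(first)],
                     numeric(length(first)))
    rownames(counts) <- names(first)
    colnames(counts) <- sub("^counts_(.*)\\.tsv$", "\\1", basename(count_paths))
    tpm_mat <- tpm(counts, eff)
    q <- cc$q %||% 0.05
    tops <- apply(tpm_mat, 2L, top_fraction, q = q, simplify = FALSE)
    core <- core_set(tops, tpm_mat, q = q)
    core_genes_out <- core$gene_id
    p_tpm <- file.path(out_dir, "tpm_matrix.tsv")
    utils::write.table(data.frame(gene_id = rownames(tpm_mat), tpm_mat),
                       p_tpm, sep = "\t", quote = FALSE, row.names = FALSE)
    p_core <- file.path(out_dir, "core_set.tsv")
    utils::write.table(core, p_core, sep = "\t", quote = FALSE, row.names = FALSE)
    note(c(p_tpm, p_core))
  })

  if (stage_enabled(cfg, "enrich")) run_stage("enrich", {
    ec <- cfg$enrich
    inputs <- c(inputs, ec$term_map, ec$background, ec$study)
    term_map <- read_term_map(ec$term_map)
    background <- readLines(ec$background)
    study <- if (!is.null(ec$study)) readLines(ec$study)
             else core_genes_out %||% stopf("no study set: run the core stage or set study")
    res <- enrich(term_map, study, background, ec$alpha %||% 0.05)
    p_e <- file.path(out_dir, "enrichment.tsv")
    utils::write.table(res, p_e, sep = "\t", quote = FALSE, row.names = FALSE)
    note(p_e)
  })

  manifest <- list(
    package = "txeval",
    version = as.character(utils::packageVersion("txeval")),
    config = cfg,
    inputs = as.list(tools::md5sum(sort(unique(inputs[file.exists(inputs)])))),
    outputs = as.list(tools::md5sum(sort(unique(outputs[file.exists(outputs)]))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
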