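# End-to-end run: parse -> annotate -> screen -> triage -> compare -> report.
# All outputs are deterministic given inputs and configuration; every
# threshold used is recorded in a provenance block.

#' Run the full curation pipeline
#'
#' Reads a genome FASTA and its predicted tRNA genes, curates every gene
#' ([curate_genes()]), compares raw and/or curated gene sets against the
#' standard set, and writes the report bundle: curation TSV + JSON, anomaly
#' TSVs, count-matrix TSV, score-histogram TSV, BED and GFF3 of the calls,
#' and a text summary. Re-running with identical inputs reproduces
#' byte-identical outputs.
#'
#' @param genome_path FASTA path.
#' @param predictions_path tRNAscan-SE tabular output path.
#' @param out_dir Output directory (created if needed).
#' @param genome_id Genome identifier (default: FASTA file stem).
#' @param standard_path Optional standard-set TSV (default: the packaged
#'   archaeal 46-type set).
#' @param mode `"raw"`, `"curated"` or `"both"` for the comparison step.
#' @param structure_cfg,screen_cfg,triage_cfg Module configurations.
#' @param tmrna_bed Optional BED of known tmRNA genes.
#' @return Invisibly, a list with `calls`, `anomalies_raw`,
#'   `anomalies_curated`, `matrix`, `histogram`, `summary_lines` and `paths`.
#' @export
run_pipeline <- function(genome_path, predictions_path, out_dir,
                         genome_id = NULL, standard_path = NULL,
                         mode = c("both", "raw", "curated"),
                         structure_cfg = structure_config(),
                         screen_cfg = screen_config(),
                         triage_cfg = triage_config(),
                         tmrna_bed = NULL) {
  mode <- match.arg(mode)
  for (p in c(genome_path, predictions_path)) {
    if (!file.exists(p)) abort(sprintf("input file not found: '%s'", p))
  }
  genome <- read_genome(genome_path)
  genome_id <- genome_id %||% sub("\\.[^.]*$", "", basename(genome_path))
  predictions <- read_trnascan(predictions_path, genome_id = genome_id)
  standard <- if (is.null(standard_path)) standard_archaea46() else
    read_standard_set(standard_path)
  tmrna <- if (is.null(tmrna_bed)) NULL else read_bed(tmrna_bed)
  if (nrow(predictions) > 0 && all(is.na(predictions$isotype_score))) {
    inform(paste("no isotype scores in input; was the detail output enabled",
                 "in the upstream gene finder?"))
  }
  if (nrow(predictions) > 0 && !any(predictions$pseudo_flag)) {
    inform(paste("no pseudogene flags present in input; if pseudogene",
                 "detection was deactivated upstream, fragment-like genes may",
                 "be listed as standard"))
  }

  calls <- curate_genes(predictions, genome, standard = standard,
                        structure_cfg = structure_cfg, screen_cfg = screen_cfg,
                        triage_cfg = triage_cfg, tmrna_track = tmrna)
  anomalies_raw <- if (mode %in% c("raw", "both")) {
    compare_to_standard(predictions, standard, mode = "raw")
  } else {
    NULL
  }
  anomalies_cur <- if (mode %in% c("curated", "both")) {
    compare_to_standard(calls, standard, mode = "curated")
  } else {
    NULL
  }
  mat <- build_matrix(if (mode == "raw") predictions else calls, standard,
                      mode = if (mode == "raw") "raw" else "curated")
  hist <- score_histogram(calls, low_flag = triage_cfg$low_flag)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  provenance <- c(
    sprintf("# trnacurate %s", as.character(utils::packageVersion("trnacurate"))),
    sprintf("# bands: low<%g uncertain<=%g low_flag<%g", triage_cfg$band_low,
            triage_cfg$band_high, triage_cfg$low_flag),
    sprintf("# screens: min_repeat=%d max_mismatch=%d max_separation=%d min_repeats=%d",
            screen_cfg$min_repeat_length, screen_cfg$max_mismatches,
            screen_cfg$max_separation, screen_cfg$min_repeats),
    sprintf("# structure: acceptor_tol=%d min_length=%d",
            structure_cfg$acceptor_tolerance, structure_cfg$min_length))
  write_tsv_prov <- function(df, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(provenance, con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  paths <- c(curation = file.path(out_dir, "curation.tsv"),
             curation_json = file.path(out_dir, "curation.json"),
             matrix = file.path(out_dir, "matrix.tsv"),
             histogram = file.path(out_dir, "histogram.tsv"),
             bed = file.path(out_dir, "calls.bed"),
             gff3 = file.path(out_dir, "calls.gff3"),
             summary = file.path(out_dir, "summary.txt"))
  write_tsv_prov(as_tibble(calls), paths["curation"])
  jsonlite::write_json(as_tibble(calls), paths["curation_json"],
                       auto_unbox = TRUE, digits = NA, na = "null")
  write_tsv_prov(unclass_keep_cols(mat), paths["matrix"])
  write_tsv_prov(unclass_keep_cols(hist), paths["histogram"])
  write_bed(as_tibble(calls), paths["bed"])
  write_gff3(as_tibble(calls), paths["gff3"])
  if (!is.null(anomalies_raw)) {
    paths["anomalies_raw"] <- file.path(out_dir, "anomalies_raw.tsv")
    write_tsv_prov(anomalies_raw, paths["anomalies_raw"])
  }
  if (!is.null(anomalies_cur)) {
    paths["anomalies_curated"] <- file.path(out_dir, "anomalies_curated.tsv")
    write_tsv_prov(anomalies_cur, paths["anomalies_curated"])
  }

  cat_counts <- as_tibble(calls) |> count(.data$category)
  low_genes <- as_tibble(calls) |> filter(.data$low_score_flag)
  summary_lines <- c(
    provenance,
    sprintf("genes: %d", nrow(calls)),
    sprintf("categories: %s",
            paste(sprintf("%s=%d", cat_counts$category, cat_counts$n),
                  collapse = " ")),
    sprintf("raw anomalies: %s",
            if (is.null(anomalies_raw)) "not computed" else nrow(anomalies_raw)),
    sprintf("curated anomalies: %s",
            if (is.null(anomalies_cur)) "not computed" else nrow(anomalies_cur)),
    sprintf("low-score genes (<%g): %s", triage_cfg$low_flag,
            if (nrow(low_genes) == 0) "none" else
              paste(low_genes$gene_name, collapse = " ")))
  writeLines(summary_lines, paths["summary"])
  invisible(list(calls = calls, anomalies_raw = anomalies_raw,
                 anomalies_curated = anomalies_cur, matrix = mat,
                 histogram = hist, summary_lines = summary_lines,
                 paths = paths))
}

#' Read pipeline configuration from a YAML file
#'
#' The YAML may contain `structure`, `screen` and `triage` sections whose
#' keys are the arguments of [structure_config()], [screen_config()] and
#' [triage_config()]; omitted sections and keys keep their defaults.
#'
#' @param path YAML file path.
#' @return List with elements `structure`, `screen`, `triage`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  build <- function(fn, section) {
    args <- y[[section]]
    if (is.null(args)) args <- list()
    do.call(fn, args)
  }
  list(structure = build(structure_config, "structure"),
       screen = build(screen_config, "screen"),
       triage = build(triage_config, "triage"))
}
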