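# Per-gene triage: combine isotype-score bands, structural defects,
# pseudogene flags and genomic-context evidence into a final curation call.
#
# Precedence (context evidence outranks scores, since every known fragment
# case carries both): CRISPR overlap > attR partial copy > ambiguous-isotype
# rescue > tmRNA overlap > score band / pseudogene+defects > canonical;
# a canonical call duplicating an already-satisfied standard type becomes a
# legitimate duplicate.

BANDS <- c("LIKELY_NONCANONICAL", "UNCERTAIN", "LIKELY_CANONICAL")
CATEGORIES <- c("CANONICAL", "FRAGMENT_ATTR", "FRAGMENT_CRISPR",
                "MISASSIGNED_AMBIGUOUS", "NONCANONICAL_OTHER",
                "LEGITIMATE_DUPLICATE", "UNCERTAIN")

#' Configuration for isotype-score triage
#'
#' Isotype scores below `band_low` mark likely non-canonical genes, scores
#' above `band_high` likely canonical genes, and the interval between them is
#' uncertain (either outcome possible). Separately, `low_flag` marks genes
#' whose score warrants manual scrutiny; it is a reporting flag, distinct
#' from the decision bands.
#'
#' @param band_low Lower decision threshold in bits (default 60).
#' @param band_high Upper decision threshold in bits (default 90).
#' @param low_flag Reporting threshold in bits (default 85).
#' @param honor_pseudo Honor upstream pseudogene flags when structural
#'   defects concur (default TRUE).
#' @return A list of class `triage_config`.
#' @export
triage_config <- function(band_low = 60, band_high = 90, low_flag = 85,
                          honor_pseudo = TRUE) {
  stopifnot(band_low < band_high)
  structure(list(band_low = band_low, band_high = band_high,
                 low_flag = low_flag, honor_pseudo = honor_pseudo),
            class = "triage_config")
}

#' Band an isotype score
#'
#' @param isotype_score Numeric vector of isotype scores (bits); NA scores
#'   are banded UNCERTAIN with a warning.
#' @param config A [triage_config()].
#' @return Character vector over `LIKELY_NONCANONICAL`, `UNCERTAIN`,
#'   `LIKELY_CANONICAL`.
#' @export
score_band <- function(isotype_score, config = triage_config()) {
  if (any(is.na(isotype_score))) {
    warn("isotype score absent for some gene(s); banded as UNCERTAIN")
  }
  case_when(
    is.na(isotype_score) ~ "UNCERTAIN",
    isotype_score < config$band_low ~ "LIKELY_NONCANONICAL",
    isotype_score > config$band_high ~ "LIKELY_CANONICAL",
    TRUE ~ "UNCERTAIN"
  )
}

#' Resolve an ambiguous isotype/anticodon against the missing standard types
#'
#' A prediction whose anticodon contains N (or whose isotype is undetermined
#' with Ns in the sequence) may actually be a standard type that appears
#' missing from the gene set. The rescue succeeds when exactly one missing
#' standard type matches the observed anticodon at every non-N position (and
#' matches the predicted isotype, when that is determined).
#'
#' @param isotype Predicted isotype (possibly `"Und"`).
#' @param anticodon Predicted anticodon (3 characters, may contain N).
#' @param deficit Tibble of missing standard types with columns `isotype`,
#'   `anticodon`.
#' @return A one-row tibble `(isotype, anticodon)` of the rescued type, or
#'   `NULL` when zero or multiple types match.
#' @export
resolve_ambiguous <- function(isotype, anticodon, deficit) {
  if (is.null(deficit) || nrow(deficit) == 0) return(NULL)
  ac_ok <- vapply(deficit$anticodon, function(d) {
    count_mismatches(anticodon, d) == 0
  }, logical(1))
  iso_ok <- if (identical(isotype, "Und")) rep(TRUE, nrow(deficit)) else
    deficit$isotype == isotype
  hit <- which(ac_ok & iso_ok)
  if (length(hit) != 1) return(NULL)
  deficit[hit, c("isotype", "anticodon")]
}

# evidence rows applying to one gene, in its role
evidence_for_gene <- function(evidence, gene_name) {
  if (nrow(evidence) == 0) return(evidence)
  evidence |> filter(.data$subject == gene_name | (!is.na(.data$partner) &
                                                     .data$partner == gene_name))
}

gene_is_partial_in <- function(ev, gene_name) {
  attr_ev <- ev |> filter(.data$kind == "ATTR_PAIR")
  if (nrow(attr_ev) == 0) return(FALSE)
  any((attr_ev$subject == gene_name & attr_ev$partial_copy == "subject") |
        (!is.na(attr_ev$partner) & attr_ev$partner == gene_name &
           attr_ev$partial_copy == "partner"))
}

#' Classify a single predicted tRNA gene
#'
#' Applies the triage precedence to one gene given its structural annotation,
#' the context evidence that names it, the score band configuration, the
#' per-genome deficit of missing standard types, and whether its type is
#' already satisfied by other confidently canonical genes.
#'
#' @param prediction One-row prediction tibble.
#' @param annotation `trna_annotation` for the gene (may be `NULL` when only
#'   tabular information is available, e.g. no genome sequence; treated as
#'   zero fatal defects).
#' @param evidence Evidence tibble (rows mentioning other genes are ignored).
#' @param config A [triage_config()].
#' @param deficit Missing-standard-type tibble for the genome (may be empty).
#' @param type_satisfied Is the gene's (possibly rescued) type already
#'   satisfied by other canonical calls?
#' @return One-row tibble: `band`, `low_score_flag`, `category`,
#'   `reassigned_isotype`, `reassigned_anticodon`, `n_fatal_defects`,
#'   `defect_codes`, `evidence_kinds`, `rationale`.
#' @export
classify <- function(prediction, annotation = NULL, evidence = empty_evidence(),
                     config = triage_config(), deficit = NULL,
                     type_satisfied = FALSE, .batch = FALSE) {
  stopifnot(nrow(prediction) == 1)
  ev <- evidence_for_gene(evidence, prediction$gene_name)
  # in single-gene use (the default), evidence naming only other genes is a
  # caller error; the orchestrator passes .batch = TRUE with the full table
  if (!isTRUE(.batch) && nrow(evidence) > 0 && nrow(ev) < nrow(evidence)) {
    other <- setdiff(evidence$subject, prediction$gene_name)
    abort(sprintf("evidence references gene(s) %s, not '%s'",
                  paste(sQuote(other), collapse = ", "), prediction$gene_name))
  }
  fatal <- if (is.null(annotation)) 0L else count_fatal(annotation)
  defect_codes <- if (is.null(annotation)) "" else
    paste(annotation$defects$code, collapse = ",")
  band <- suppressWarnings(score_band(prediction$isotype_score, config))
  low_flag <- !is.na(prediction$isotype_score) &&
    prediction$isotype_score < config$low_flag

  category <- NULL
  reassigned <- NULL
  rationale <- ""

  if (any(ev$kind == "CRISPR_OVERLAP")) {
    category <- "FRAGMENT_CRISPR"
    rationale <- "prediction lies within a CRISPR repeat-spacer array"
  } else if (gene_is_partial_in(ev, prediction$gene_name)) {
    category <- "FRAGMENT_ATTR"
    rationale <- "partial copy of an attR direct-repeat pair flanking an integrated element"
  } else {
    ambiguous <- grepl("N", prediction$anticodon, fixed = TRUE) ||
      (prediction$isotype == "Und" && any(ev$kind == "AMBIGUOUS_N"))
    if (ambiguous && fatal == 0) {
      reassigned <- resolve_ambiguous(prediction$isotype, prediction$anticodon,
                                      deficit)
      if (!is.null(reassigned)) {
        category <- "MISASSIGNED_AMBIGUOUS"
        rationale <- sprintf(
          "ambiguous bases; uniquely matches missing standard type %s-%s",
          reassigned$isotype, reassigned$anticodon)
      }
    }
    if (is.null(category)) {
      if (any(ev$kind == "TMRNA_OVERLAP")) {
        category <- "NONCANONICAL_OTHER"
        rationale <- "overlaps a tmRNA gene track interval"
      } else if (band == "LIKELY_NONCANONICAL" ||
                 (config$honor_pseudo && isTRUE(prediction$pseudo_flag) &&
                    fatal > 0)) {
        category <- "NONCANONICAL_OTHER"
        rationale <- if (band == "LIKELY_NONCANONICAL") {
          "isotype score in the likely-non-canonical band"
        } else {
          "pseudogene flag with concurring fatal structural defects"
        }
      } else if (band == "UNCERTAIN") {
        if (fatal > 0) {
          category <- "NONCANONICAL_OTHER"
          rationale <- "uncertain score band with fatal structural defects"
        } else {
          category <- "CANONICAL"
          rationale <- "uncertain score band, structure intact; manual review recommended"
        }
      } else if (fatal > 0) {
        category <- "NONCANONICAL_OTHER"
        rationale <- "fatal structural defects"
      } else {
        category <- "CANONICAL"
        rationale <- "intact structure, likely-canonical score band"
      }
    }
  }
  if (category == "CANONICAL" && isTRUE(type_satisfied)) {
    category <- "LEGITIMATE_DUPLICATE"
    rationale <- "structurally intact extra copy of an already-satisfied standard type"
  }
  tibble(
    band = band, low_score_flag = low_flag, category = category,
    reassigned_isotype = if (is.null(reassigned)) NA_character_ else reassigned$isotype,
    reassigned_anticodon = if (is.null(reassigned)) NA_character_ else reassigned$anticodon,
    n_fatal_defects = as.integer(fatal),
    defect_codes = defect_codes,
    evidence_kinds = paste(unique(ev$kind), collapse = ","),
    rationale = rationale
  )
}

# deficit of a genome: standard types with fewer confidently canonical calls
# than expected
compute_deficit <- function(counts, standard) {
  standard |>
    left_join(counts, by = c("isotype", "anticodon")) |>
    mutate(n = replace_na(.data$n, 0L)) |>
    filter(.data$n < .data$expected_copies) |>
    select("isotype", "anticodon")
}

#' Curate a predicted tRNA gene set
#'
#' End-to-end per-gene triage for one or more genomes: annotates every
#' predicted gene's cloverleaf structure, runs the genomic-context screens
#' (CRISPR arrays, attR pairs, N-ambiguity, optional tmRNA track), computes
#' the per-genome deficit of missing standard types from the confidently
#' canonical calls, rescues ambiguous isotype assignments against that
#' deficit in a second pass, and marks structurally intact extra copies of
#' already-satisfied types as legitimate duplicates. Deterministic given its
#' inputs and configurations.
#'
#' @param predictions Prediction tibble (possibly multiple genomes; each
#'   `genome_id` must map to contigs present in `genome`).
#' @param genome Named [Biostrings::DNAStringSet] with all referenced contigs.
#' @param standard Standard-set tibble (default [standard_archaea46()]).
#' @param structure_cfg A [structure_config()].
#' @param screen_cfg A [screen_config()].
#' @param triage_cfg A [triage_config()].
#' @param tmrna_track Optional tmRNA interval tibble (see [read_bed()]).
#' @param crispr_arrays Optional pre-computed array tibble (see
#'   [detect_crispr_arrays()]); detected from `genome` when omitted.
#' @return A tibble of class `trna_curation`: the prediction columns plus
#'   `band`, `low_score_flag`, `category`, reassignment columns, defect and
#'   evidence summaries, and `rationale`. Configurations are attached as
#'   attributes.
#' @export
curate_genes <- function(predictions, genome,
                         standard = standard_archaea46(),
                         structure_cfg = structure_config(),
                         screen_cfg = screen_config(),
                         triage_cfg = triage_config(),
                         tmrna_track = NULL,
                         crispr_arrays = NULL) {
  validate_predictions(predictions)
  if (nrow(predictions) == 0) {
    out <- bind_cols(empty_predictions(),
                     classify(tibble(gene_name = "x", anticodon = "AAA",
                                     isotype = "Ala", isotype_score = 100,
                                     pseudo_flag = FALSE))[c(), ])
    return(new_curation(out, standard, structure_cfg, screen_cfg, triage_cfg))
  }
  annotations <- annotate_predictions(predictions, genome, structure_cfg)
  arrays <- crispr_arrays %||% detect_crispr_arrays(genome, screen_cfg)
  evidence <- bind_rows(
    crispr_overlap(predictions, arrays),
    find_attr_pairs(predictions, genome, screen_cfg, annotations, structure_cfg),
    ambiguity_check(predictions, genome, annotations),
    tmrna_overlap(predictions, tmrna_track)
  )
  curate_with_evidence(predictions, annotations, evidence, standard,
                       structure_cfg, screen_cfg, triage_cfg)
}

# triage given precomputed annotations/evidence (also used for tabular-only
# listings where annotations are NULL)
curate_with_evidence <- function(predictions, annotations, evidence,
                                 standard = standard_archaea46(),
                                 structure_cfg = structure_config(),
                                 screen_cfg = screen_config(),
                                 triage_cfg = triage_config()) {
  n <- nrow(predictions)
  ann_of <- function(i) if (is.null(annotations)) NULL else annotations[[i]]
  # pass 1: no deficit, no duplicate marking
  pass1 <- map(seq_len(n), function(i) {
    classify(predictions[i, ], ann_of(i), evidence, triage_cfg,
             deficit = NULL, type_satisfied = FALSE, .batch = TRUE)
  }) |> list_rbind()
  calls <- bind_cols(predictions, pass1)

  # per-genome deficit from confidently canonical pass-1 calls
  canon_counts <- calls |>
    filter(.data$category == "CANONICAL") |>
    count(.data$genome_id, .data$isotype, .data$anticodon)
  out <- vector("list", n)
  for (gid in unique(predictions$genome_id)) {
    idx <- which(predictions$genome_id == gid)
    deficit <- compute_deficit(
      canon_counts |> filter(.data$genome_id == gid) |>
        select("isotype", "anticodon", "n"),
      standard)
    # pass 2: rescue + duplicate marking, processing genes in genomic order
    # and tracking how many copies of each type are already accepted
    key <- function(iso, ac) paste(iso, ac, sep = "-")
    seen <- integer(0)
    ord <- idx[order(predictions$seq_id[idx], predictions$start[idx])]
    for (i in ord) {
      p <- predictions[i, ]
      provisional <- classify(p, ann_of(i), evidence, triage_cfg,
                              deficit = deficit, type_satisfied = FALSE,
                              .batch = TRUE)
      type_satisfied <- FALSE
      if (provisional$category == "CANONICAL") {
        k <- key(p$isotype, p$anticodon)
        expected <- standard$expected_copies[standard$isotype == p$isotype &
                                               standard$anticodon == p$anticodon]
        expected <- if (length(expected) == 1) expected else 0L
        seen[k] <- (if (k %in% names(seen)) seen[[k]] else 0L) + 1L
        if (seen[[k]] > expected) type_satisfied <- TRUE
      }
      out[[i]] <- classify(p, ann_of(i), evidence, triage_cfg,
                           deficit = deficit, type_satisfied = type_satisfied,
                           .batch = TRUE)
    }
  }
  calls <- bind_cols(predictions, list_rbind(out[seq_len(n)]))
  new_curation(calls, standard, structure_cfg, screen_cfg, triage_cfg,
               evidence = evidence)
}

new_curation <- function(calls, standard, structure_cfg, screen_cfg,
                         triage_cfg, evidence = empty_evidence()) {
  structure(calls,
            standard = standard,
            structure_config = structure_cfg,
            screen_config = screen_cfg,
            triage_config = triage_cfg,
            evidence = evidence,
            class = c("trna_curation", class(tibble())))
}

#' Tidy a curation result
#'
#' @param x A `trna_curation` from [curate_genes()].
#' @param ... Unused.
#' @return A plain tibble of per-gene calls.
#' @export
#' @exportS3Method generics::tidy
tidy.trna_curation <- function(x, ...) {
  as_tibble(unclass(x)[!names(unclass(x)) %in% character(0)])
}

#' One-row-per-genome summary of a curation result
#'
#' @param x A `trna_curation`.
#' @param ... Unused.
#' @return Tibble with per-genome gene counts by category and the number of
#'   low-score and pseudogene-flagged genes.
#' @export
#' @exportS3Method generics::glance
glance.trna_curation <- function(x, ...) {
  tb <- as_tibble(x)
  tb |>
    group_by(.data$genome_id) |>
    summarise(
      n_genes = n(),
      n_canonical = sum(.data$category %in% c("CANONICAL", "LEGITIMATE_DUPLICATE")),
      n_fragment_attr = sum(.data$category == "FRAGMENT_ATTR"),
      n_fragment_crispr = sum(.data$category == "FRAGMENT_CRISPR"),
      n_misassigned = sum(.data$category == "MISASSIGNED_AMBIGUOUS"),
      n_noncanonical_other = sum(.data$category == "NONCANONICAL_OTHER"),
      n_low_score = sum(.data$low_score_flag),
      n_pseudo_flagged = sum(.data$pseudo_flag),
      .groups = "drop")
}
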