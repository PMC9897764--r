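# Comparison of tRNA gene listings against a standard set: per-unit anomaly
# records, genomes-by-types count matrices, and score-distribution summaries.

#' Count tRNA types per genome
#'
#' In raw mode every record is counted under its predicted type. In curated
#' mode (requires curation columns) fragment and other non-canonical calls
#' are excluded and ambiguous misassignments are counted under their rescued
#' type; legitimate duplicates count under their own type.
#'
#' @param x Listing or curation tibble with `genome_id`, `isotype`,
#'   `anticodon` (and curation columns for curated mode).
#' @param mode `"raw"` or `"curated"`.
#' @return Tibble `genome_id`, `isotype`, `anticodon`, `n`.
#' @export
count_gene_types <- function(x, mode = c("raw", "curated")) {
  mode <- match.arg(mode)
  tb <- as_tibble(x)
  if (mode == "curated") {
    if (!"category" %in% names(tb)) {
      abort("curated mode requires curation calls (run curate_genes() first)")
    }
    tb <- tb |>
      filter(!.data$category %in% c("FRAGMENT_ATTR", "FRAGMENT_CRISPR",
                                    "NONCANONICAL_OTHER")) |>
      mutate(
        isotype = ifelse(.data$category == "MISASSIGNED_AMBIGUOUS",
                         .data$reassigned_isotype, .data$isotype),
        anticodon = ifelse(.data$category == "MISASSIGNED_AMBIGUOUS",
                           .data$reassigned_anticodon, .data$anticodon))
  }
  tb |> count(.data$genome_id, .data$isotype, .data$anticodon)
}

#' Compare gene listings against a standard set
#'
#' Emits one anomaly record per unit of deviation: a type observed three
#' times against an expectation of one yields two `ADDITIONAL` records; a
#' type never observed yields one `MISSING` record per expected copy. Types
#' observed but absent from the standard set are `ADDITIONAL` with
#' `expected = 0`.
#'
#' @inheritParams count_gene_types
#' @param standard Standard-set tibble (see [read_standard_set()]).
#' @return Tibble of anomalies: `genome_id`, `isotype`, `anticodon`,
#'   `direction` (`ADDITIONAL`/`MISSING`), `observed`, `expected`; zero rows
#'   when every genome carries exactly the standard set.
#' @export
compare_to_standard <- function(x, standard, mode = c("raw", "curated")) {
  counts <- count_gene_types(x, mode)
  genomes <- unique(as_tibble(x)$genome_id)
  rows <- list()
  for (gid in genomes) {
    cg <- counts |> filter(.data$genome_id == gid)
    full <- standard |>
      full_join(cg |> select(-"genome_id"), by = c("isotype", "anticodon")) |>
      mutate(n = replace_na(.data$n, 0L),
             expected_copies = replace_na(.data$expected_copies, 0L))
    dev <- full |> filter(.data$n != .data$expected_copies)
    if (nrow(dev) == 0) next
    for (i in seq_len(nrow(dev))) {
      delta <- dev$n[i] - dev$expected_copies[i]
      dir <- if (delta > 0) "ADDITIONAL" else "MISSING"
      rows[[length(rows) + 1]] <- tibble(
        genome_id = gid, isotype = dev$isotype[i], anticodon = dev$anticodon[i],
        direction = rep(dir, abs(delta)),
        observed = dev$n[i], expected = dev$expected_copies[i])
    }
  }
  if (length(rows) == 0) {
    return(tibble(genome_id = character(), isotype = character(),
                  anticodon = character(), direction = character(),
                  observed = integer(), expected = integer()))
  }
  bind_rows(rows) |> arrange(.data$genome_id, .data$isotype, .data$anticodon)
}

#' Build a genomes-by-types count matrix
#'
#' Counts are taken over the union of the standard types and every observed
#' type, in standard-set order followed by extra observed types; genomes
#' deviating from the standard expectation are flagged.
#'
#' @inheritParams compare_to_standard
#' @return A tibble of class `trna_geneset_matrix`: `genome_id`, `deviant`,
#'   then one integer column per tRNA type (named `isotype-anticodon`).
#' @export
build_matrix <- function(x, standard, mode = c("raw", "curated")) {
  counts <- count_gene_types(x, mode) |>
    mutate(type = paste(.data$isotype, .data$anticodon, sep = "-"))
  std_types <- paste(standard$isotype, standard$anticodon, sep = "-")
  extra <- setdiff(unique(counts$type), std_types)
  all_types <- c(std_types, sort(extra))
  wide <- counts |>
    select("genome_id", "type", "n") |>
    pivot_wider(names_from = "type", values_from = "n", values_fill = 0L)
  for (t in setdiff(all_types, names(wide))) wide[[t]] <- 0L
  wide <- wide[c("genome_id", all_types)]
  anomalies <- compare_to_standard(x, standard, mode)
  wide <- wide |>
    mutate(deviant = .data$genome_id %in% unique(anomalies$genome_id),
           .after = "genome_id") |>
    arrange(.data$genome_id)
  structure(wide, standard = standard,
            class = c("trna_geneset_matrix", class(tibble())))
}

#' Summarize an isotype-score distribution
#'
#' Bins isotype scores at a fixed width (bins anchored at 0) and computes the
#' exact minimum, maximum and median. When a `category` column is present the
#' per-bin counts are also broken down by category.
#'
#' @param records Tibble with an `isotype_score` column (NA scores dropped),
#'   optionally `category`.
#' @param bin_width Bin width in bits (default 5).
#' @param low_flag Reporting threshold; the summary counts genes below it
#'   (default 85).
#' @return A tibble of class `trna_score_histogram` (`bin_start`, `bin_end`,
#'   `count`, and per-category counts when available), with the distribution
#'   summary retrievable via [glance()].
#' @export
score_histogram <- function(records, bin_width = 5, low_flag = 85) {
  scores <- as_tibble(records)
  scores <- scores[!is.na(scores$isotype_score), , drop = FALSE]
  if (nrow(scores) == 0) {
    out <- tibble(bin_start = double(), bin_end = double(), count = integer())
    return(structure(out, summary = tibble(n = 0L, min = NA_real_,
                                           max = NA_real_, median = NA_real_,
                                           n_below_flag = 0L,
                                           low_flag = low_flag),
                     class = c("trna_score_histogram", class(tibble()))))
  }
  bin <- floor(scores$isotype_score / bin_width) * bin_width
  tab <- tibble(bin_start = bin) |>
    count(.data$bin_start, name = "count")
  if ("category" %in% names(scores)) {
    bycat <- tibble(bin_start = bin, category = scores$category) |>
      count(.data$bin_start, .data$category) |>
      pivot_wider(names_from = "category", values_from = "n",
                  values_fill = 0L, names_prefix = "n_")
    tab <- left_join(tab, bycat, by = "bin_start")
  }
  tab <- tab |>
    mutate(bin_end = .data$bin_start + bin_width, .after = "bin_start") |>
    arrange(.data$bin_start)
  structure(tab,
            summary = tibble(n = nrow(scores),
                             min = min(scores$isotype_score),
                             max = max(scores$isotype_score),
                             median = median(scores$isotype_score),
                             n_below_flag = sum(scores$isotype_score < low_flag),
                             low_flag = low_flag),
            class = c("trna_score_histogram", class(tibble())))
}

#' @export
#' @rdname score_histogram
#' @param x A `trna_score_histogram`.
#' @param ... Unused.
glance.trna_score_histogram <- function(x, ...) attr(x, "summary")

#' @export
#' @rdname score_histogram
tidy.trna_score_histogram <- function(x, ...) as_tibble(unclass_keep_cols(x))

unclass_keep_cols <- function(x) {
  as_tibble(setNames(lapply(names(x), function(nm) x[[nm]]), names(x)))
}

#' @export
#' @exportS3Method generics::tidy
tidy.trna_geneset_matrix <- function(x, ...) {
  unclass_keep_cols(x) |>
    tidyr::pivot_longer(cols = -c("genome_id", "deviant"),
                        names_to = "type", values_to = "n")
}

#' @export
#' @exportS3Method generics::glance
glance.trna_geneset_matrix <- function(x, ...) {
  tibble(n_genomes = nrow(x),
         n_types = ncol(x) - 2L,
         n_deviant = sum(x$deviant),
         n_standard = sum(!x$deviant))
}
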