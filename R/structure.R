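# Rule-based cloverleaf annotation of a tRNA gene sequence.
#
# The annotator applies six anchoring steps in a fixed 3'-to-5' order, each
# relative to the previously located element:
#   (i)   the genomically encoded 3' CCA (when present), the discriminator
#         base, and the 7-bp acceptor stem (positions 1-7 paired with 72-66);
#   (ii)  the T-arm immediately 5' of the acceptor 3' side: a 17-nt stem-loop
#         whose 7-nt loop matches T-T-C-R-A-N-N;
#   (iii) the variable region between T-arm and anticodon arm (4-5 nt, or a
#         longer extra arm in Leu/Ser-type genes);
#   (iv)  the anticodon arm: 5-bp stem with a 7-nt loop, anticodon at loop
#         positions 3-5 (Sprinzl 34-36), loop typically starting C-T;
#   (v)   the D-arm: 3-4-bp stem with a flexible 4-12-nt loop;
#   (vi)  the single-stranded connectors (positions 8-9, and 26).
# Every element that cannot be located adds a defect; fatal defects mark the
# sequence as non-canonical. All pairing uses Watson-Crick plus G:T wobble,
# with N treated as a wildcard (tallied separately for the ambiguity screen).

FATAL_CODES <- c("NO_ACCEPTOR_STEM", "NO_T_ARM", "NO_ANTICODON_ARM",
                 "LOOP_NOT_7", "NO_D_ARM", "TRUNCATED")
WARN_CODES <- c("NO_CCA", "ACCEPTOR_MISPAIR", "BAD_CONNECTOR", "NON_CU_LOOP_START")

#' Configuration for the cloverleaf structure annotator
#'
#' @param acceptor_tolerance Mispairs tolerated in the 7-bp acceptor stem
#'   before the stem is called absent (default 1: a single mispair is reported
#'   as a warning, consistent with known canonical genes carrying one
#'   acceptor-stem point defect).
#' @param t_stem_tolerance Mispairs tolerated in the 5-bp T-arm stem (default 0).
#' @param anticodon_stem_tolerance Mispairs tolerated in the 5-bp anticodon
#'   stem (default 0).
#' @param d_stem_lengths Admissible D-arm stem lengths in bp (default 4:3,
#'   longer stem preferred).
#' @param d_loop_range Admissible D-loop length range in nt (default c(4, 12)).
#' @param variable_lengths Preferred short variable-region lengths in nt
#'   (default c(5, 4)).
#' @param extra_arm_range Length range of a long variable (extra) arm in nt
#'   (default c(10, 24)).
#' @param min_length Minimum gene length in nt below which a TRUNCATED fatal
#'   defect is recorded (default 50).
#' @return A list of class `structure_config`.
#' @export
structure_config <- function(acceptor_tolerance = 1,
                             t_stem_tolerance = 0,
                             anticodon_stem_tolerance = 0,
                             d_stem_lengths = c(4, 3),
                             d_loop_range = c(4, 12),
                             variable_lengths = c(5, 4),
                             extra_arm_range = c(10, 24),
                             min_length = 50) {
  structure(list(acceptor_tolerance = acceptor_tolerance,
                 t_stem_tolerance = t_stem_tolerance,
                 anticodon_stem_tolerance = anticodon_stem_tolerance,
                 d_stem_lengths = d_stem_lengths,
                 d_loop_range = d_loop_range,
                 variable_lengths = variable_lengths,
                 extra_arm_range = extra_arm_range,
                 min_length = min_length),
            class = "structure_config")
}

#' Locate the T-arm motif in a sequence
#'
#' Scans for a 17-nt stem-loop whose loop (window positions 6-12) matches
#' T-T-C-\{A,G\}-A-N-N and whose 5-bp stem sides pair under Watson-Crick/G:T
#' rules. The match nearest the 3' end of the searched region is returned,
#' reflecting that the T-arm directly precedes the acceptor 3' side.
#'
#' @param seq Nucleotide sequence (character string).
#' @param before Last position the window may end at (default: sequence end).
#' @param tolerance Stem mispairs tolerated (default 0).
#' @return Integer `c(start, end)` of the 17-nt window, or `NULL`.
#' @export
find_t_arm <- function(seq, before = nchar(seq), tolerance = 0) {
  n <- as.integer(min(nchar(seq), before))
  if (n < 17) return(NULL)
  chars <- seq_chars(seq)
  for (end in seq(n, 17L)) {
    s <- end - 16L
    loop <- chars[(s + 5):(s + 11)]
    motif_ok <- bases_match(loop[1], "T") && bases_match(loop[2], "T") &&
      bases_match(loop[3], "C") &&
      (loop[4] %in% c("A", "G", "N")) && bases_match(loop[5], "A")
    if (!motif_ok) next
    if (stem_mismatches(chars, s, s + 12, 5) <= tolerance) {
      return(c(s, end))
    }
  }
  NULL
}

add_defect <- function(defects, code, detail = "") {
  severity <- if (code %in% FATAL_CODES) "fatal" else "warning"
  c(defects, list(tibble(code = code, severity = severity, detail = detail)))
}

#' Annotate the cloverleaf structure of a tRNA gene sequence
#'
#' Applies the six-step rule set described in the package vignette to locate
#' the canonical structural elements (acceptor stem, discriminator, CCA,
#' T-arm, variable region, anticodon arm, D-arm, connectors) and to collect a
#' defect list. A genomically encoded CCA is optional (its absence is a
#' warning); the unlocatable core arms are fatal defects.
#'
#' @param seq Gene sequence, 5' to 3', introns already spliced out. N bases
#'   are allowed and counted toward an ambiguity tally.
#' @param config A [structure_config()].
#' @return An object of class `trna_annotation`: list with `elements`
#'   (tibble of located spans, in gene-local 1-based coordinates), `defects`
#'   (tibble of code/severity/detail), `anticodon`, `anticodon_span`,
#'   `cca_present`, `n_count`, and `seq`.
#' @export
annotate_structure <- function(seq, config = structure_config()) {
  seq <- normalize_seq(seq)
  L <- nchar(seq)
  chars <- seq_chars(seq)
  defects <- list()
  elements <- list()
  add_el <- function(name, start, end, note = "") {
    elements[[length(elements) + 1]] <<- tibble(element = name,
                                                start = as.integer(start),
                                                end = as.integer(end),
                                                note = note)
  }

  if (L < config$min_length) {
    defects <- add_defect(defects, "TRUNCATED",
                          sprintf("length %d < %d nt", L, config$min_length))
  }

  # (i) CCA / discriminator / acceptor stem
  cca_present <- L >= 3 && count_mismatches(substr(seq, L - 2, L), "CCA") == 0
  if (cca_present) {
    disc <- L - 3L
    add_el("cca", L - 2L, L)
  } else {
    defects <- add_defect(defects, "NO_CCA", "no genomically encoded 3' CCA")
    disc <- L
  }
  acc3 <- c(disc - 7L, disc - 1L)
  acceptor_ok <- FALSE
  if (acc3[1] >= 8) {
    mm <- stem_mismatches(chars, 1L, acc3[1], 7L)
    if (mm <= config$acceptor_tolerance) {
      acceptor_ok <- TRUE
      add_el("acceptor_5p", 1L, 7L)
      if (mm > 0) {
        defects <- add_defect(defects, "ACCEPTOR_MISPAIR",
                              sprintf("%d mispair(s) in acceptor stem", mm))
      }
    } else {
      defects <- add_defect(defects, "NO_ACCEPTOR_STEM",
                            sprintf("%d mispairs exceed tolerance %d", mm,
                                    config$acceptor_tolerance))
    }
  } else {
    defects <- add_defect(defects, "NO_ACCEPTOR_STEM",
                          "sequence too short to host both acceptor sides")
  }

  # (ii) T-arm 5' of the acceptor 3' side
  t_before <- if (acc3[1] >= 8) acc3[1] - 1L else L
  t_span <- find_t_arm(seq, before = t_before, tolerance = config$t_stem_tolerance)
  if (is.null(t_span)) {
    defects <- add_defect(defects, "NO_T_ARM", "no T-loop stem-loop motif found")
  } else {
    add_el("t_arm", t_span[1], t_span[2],
           note = paste0("loop=", substr(seq, t_span[1] + 5, t_span[1] + 11)))
  }

  # (iii)+(iv) variable region, then anticodon arm 5' of it
  ac_span <- NULL
  var_span <- NULL
  anticodon <- NA_character_
  anticodon_span <- NULL
  if (!is.null(t_span)) {
    var_try <- c(config$variable_lengths,
                 seq(config$extra_arm_range[1], config$extra_arm_range[2]))
    for (v in var_try) {
      ac_end <- t_span[1] - 1L - v
      ac_start <- ac_end - 16L
      if (ac_start < 1) next
      if (stem_mismatches(chars, ac_start, ac_end - 4L, 5L) <=
          config$anticodon_stem_tolerance) {
        ac_span <- c(ac_start, ac_end)
        var_span <- c(ac_end + 1L, t_span[1] - 1L)
        break
      }
    }
    if (is.null(ac_span)) {
      defects <- add_defect(defects, "NO_ANTICODON_ARM",
                            "no paired 17-nt anticodon stem-loop 5' of the T-arm")
    } else {
      loop_start <- ac_span[1] + 5L
      anticodon_span <- c(loop_start + 2L, loop_start + 4L)
      anticodon <- substr(seq, anticodon_span[1], anticodon_span[2])
      add_el("anticodon_arm", ac_span[1], ac_span[2],
             note = paste0("anticodon=", anticodon))
      add_el("variable_region", var_span[1], var_span[2],
             note = if (var_span[2] - var_span[1] + 1 > 5) "extra_arm" else "")
      if (!(bases_match(chars[loop_start], "C") &&
            bases_match(chars[loop_start + 1L], "T"))) {
        defects <- add_defect(defects, "NON_CU_LOOP_START",
                              "anticodon loop does not begin with C-T")
      }
    }
  } else {
    defects <- add_defect(defects, "NO_ANTICODON_ARM", "no T-arm anchor")
  }

  # (v) D-arm 5' of the anticodon arm (one connector base at position 26)
  d_span <- NULL
  d_stem <- NA_integer_
  if (!is.null(ac_span)) {
    for (conn26 in c(1L, 2L)) {
      d_end <- ac_span[1] - 1L - conn26
      for (s in config$d_stem_lengths) {
        for (l in seq(config$d_loop_range[1], config$d_loop_range[2])) {
          d_start <- d_end - (2L * s + l) + 1L
          if (d_start < 9) next
          if (stem_mismatches(chars, d_start, d_end - s + 1L, s) == 0) {
            d_span <- c(d_start, d_end)
            d_stem <- s
            break
          }
        }
        if (!is.null(d_span)) break
      }
      if (!is.null(d_span)) break
    }
  }
  if (is.null(d_span)) {
    defects <- add_defect(defects, "NO_D_ARM", "no D-arm stem-loop found")
  } else {
    add_el("d_arm", d_span[1], d_span[2], note = sprintf("stem=%dbp", d_stem))
  }

  # (vi) connectors
  if (acceptor_ok && !is.null(d_span)) {
    conn_len <- d_span[1] - 8L
    add_el("connector_8_9", 8L, d_span[1] - 1L)
    if (conn_len < 1 || conn_len > 3) {
      defects <- add_defect(defects, "BAD_CONNECTOR",
                            sprintf("acceptor/D-arm connector of %d nt", conn_len))
    }
  }
  if (!is.null(d_span) && !is.null(ac_span) && ac_span[1] - d_span[2] >= 2) {
    add_el("connector_26", d_span[2] + 1L, ac_span[1] - 1L)
  }
  if (acceptor_ok) add_el("acceptor_3p", acc3[1], acc3[2])
  if (acceptor_ok || cca_present) add_el("discriminator", disc, disc)

  elements <- if (length(elements)) {
    list_rbind(elements) |> arrange(.data$start, .data$end)
  } else {
    tibble(element = character(), start = integer(), end = integer(),
           note = character())
  }
  defects <- if (length(defects)) list_rbind(defects) else
    tibble(code = character(), severity = character(), detail = character())

  structure(list(seq = seq, elements = elements, defects = defects,
                 anticodon = anticodon,
                 anticodon_span = anticodon_span,
                 cca_present = cca_present,
                 n_count = sum(chars == "N")),
            class = "trna_annotation")
}

#' Is an annotated structure canonical?
#'
#' A structure is canonical when its annotation carries no fatal defects;
#' warnings (missing genomic CCA, a tolerated acceptor mispair, an unusual
#' loop start, odd connector lengths) do not disqualify it.
#'
#' @param ann A `trna_annotation` from [annotate_structure()].
#' @return Logical.
#' @export
is_canonical_structure <- function(ann) {
  stopifnot(inherits(ann, "trna_annotation"))
  !any(ann$defects$severity == "fatal")
}

#' @export
print.trna_annotation <- function(x, ...) {
  cat(sprintf("<trna_annotation> %d nt, %d element(s), %d defect(s) (%d fatal)\n",
              nchar(x$seq), nrow(x$elements), nrow(x$defects),
              sum(x$defects$severity == "fatal")))
  if (!is.na(x$anticodon)) cat("  anticodon:", x$anticodon, "\n")
  invisible(x)
}

#' Tidy a structure annotation into its element table
#'
#' @param x A `trna_annotation`.
#' @param ... Unused.
#' @return Tibble of located elements with gene-local 1-based spans.
#' @export
#' @exportS3Method generics::tidy
tidy.trna_annotation <- function(x, ...) x$elements

#' One-row summary of a structure annotation
#'
#' @param x A `trna_annotation`.
#' @param ... Unused.
#' @return One-row tibble: length, element/defect counts, canonical flag,
#'   anticodon, CCA presence, N count.
#' @export
#' @exportS3Method generics::glance
glance.trna_annotation <- function(x, ...) {
  tibble(length_nt = nchar(x$seq),
         n_elements = nrow(x$elements),
         n_defects = nrow(x$defects),
         n_fatal = sum(x$defects$severity == "fatal"),
         canonical = is_canonical_structure(x),
         anticodon = x$anticodon,
         cca_present = x$cca_present,
         n_count = x$n_count)
}

# annotate every prediction of a table; returns a list of trna_annotation
annotate_predictions <- function(predictions, genome, config = structure_config()) {
  seqs <- prediction_sequences(predictions, genome)
  map(seqs, annotate_structure, config = config)
}
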