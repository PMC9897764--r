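# Genomic-context evidence generators. Each screen returns rows of a shared
# evidence tibble: kind (ATTR_PAIR / CRISPR_OVERLAP / AMBIGUOUS_N /
# TMRNA_OVERLAP), the subject gene, an optional partner, and kind-specific
# payload columns (NA elsewhere).

#' Configuration for the genomic-context screens
#'
#' @param min_repeat_length Minimum shared terminal repeat (bp) for calling an
#'   attR pair (default 20; the integration events that motivated the screen
#'   carry 44-bp repeats, well above it).
#' @param max_mismatches Maximum mismatches within an attR repeat (default 1).
#' @param max_separation Maximum distance (bp) between the two copies of an
#'   attR pair (default 250000, accommodating elements relocated ~179 kb away
#'   by post-integration rearrangement).
#' @param terminal_scan_length Length (bp) of the gene-terminal segment
#'   scanned genome-wide for unpredicted partial copies (default 100).
#' @param crispr_k Seed k-mer length for the CRISPR repeat finder (default 13).
#' @param repeat_length_range Admissible CRISPR repeat lengths, bp (default
#'   c(20, 50)).
#' @param spacer_length_range Admissible CRISPR spacer lengths, bp (default
#'   c(20, 60)).
#' @param min_repeats Minimum repeat copies for calling an array (default 3).
#' @param max_repeat_mismatches Maximum mismatches between repeat copies
#'   (default 1).
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(min_repeat_length = 20,
                          max_mismatches = 1,
                          max_separation = 250000,
                          terminal_scan_length = 100,
                          crispr_k = 13,
                          repeat_length_range = c(20, 50),
                          spacer_length_range = c(20, 60),
                          min_repeats = 3,
                          max_repeat_mismatches = 1) {
  structure(list(min_repeat_length = as.integer(min_repeat_length),
                 max_mismatches = as.integer(max_mismatches),
                 max_separation = as.integer(max_separation),
                 terminal_scan_length = as.integer(terminal_scan_length),
                 crispr_k = as.integer(crispr_k),
                 repeat_length_range = as.integer(repeat_length_range),
                 spacer_length_range = as.integer(spacer_length_range),
                 min_repeats = as.integer(min_repeats),
                 max_repeat_mismatches = as.integer(max_repeat_mismatches)),
            class = "screen_config")
}

empty_evidence <- function() {
  tibble(kind = character(), genome_id = character(), seq_id = character(),
         subject = character(), partner = character(),
         repeat_length = integer(), mismatches = integer(),
         element_start = integer(), element_end = integer(),
         element_length = integer(), same_strand = logical(),
         partial_copy = character(),
         array_id = integer(), n_repeats_covered = integer(),
         n_spacers_covered = integer(),
         n_count = integer(), n_in_anticodon = logical(),
         overlap_bp = integer(), detail = character())
}

as_evidence <- function(...) bind_rows(empty_evidence(), tibble(...))

# maximal shared terminal segment of two oriented sequences.
# side = "3p" compares suffixes, "5p" compares prefixes.
# Returns list(length, mismatches) of the longest terminal run whose total
# mismatch count stays <= max_mm (N is a wildcard).
max_terminal_match <- function(a, b, side = c("3p", "5p"), max_mm = 1) {
  side <- match.arg(side)
  ca <- seq_chars(a)
  cb <- seq_chars(b)
  if (side == "3p") {
    ca <- rev(ca)
    cb <- rev(cb)
  }
  n <- min(length(ca), length(cb))
  if (n == 0) return(list(length = 0L, mismatches = 0L))
  mm <- cumsum(!bases_match(ca[seq_len(n)], cb[seq_len(n)]))
  ok <- which(mm <= max_mm)
  if (length(ok) == 0) return(list(length = 0L, mismatches = 0L))
  len <- max(ok)
  list(length = as.integer(len), mismatches = as.integer(mm[len]))
}

# genomic span of the terminal `len` bases of an oriented gene
terminal_span <- function(start, end, strand, len, side) {
  if ((side == "3p") == (strand == "+")) {
    c(end - len + 1L, end)   # 3' on plus, or 5' on minus
  } else {
    c(start, start + len - 1L)
  }
}

count_fatal <- function(ann) sum(ann$defects$severity == "fatal")

#' Detect attR-style partial/full tRNA gene pairs
#'
#' Integration of a mobile genetic element into a tRNA gene leaves one
#' complete and one partial copy of the target gene at opposing ends of the
#' integrated element, sharing a direct repeat (the attachment site). This
#' screen (a) compares the terminal segments of every pair of same-isotype
#' (or undetermined-isotype) predictions on a contig within
#' `max_separation`, in both orientations, and (b) scans each prediction's
#' 3'-terminal segment against the whole contig to catch partial copies that
#' the gene finder did not call. For each pair the maximal shared terminal
#' repeat meeting the thresholds is reported, together with which copy is the
#' partial one (fewer located structural elements; ties broken by lower
#' isotype score; remaining ties flagged uncertain).
#'
#' @param predictions Prediction tibble (see [read_trnascan()]).
#' @param genome Named [Biostrings::DNAStringSet].
#' @param config A [screen_config()].
#' @param annotations Optional pre-computed list of `trna_annotation` objects
#'   parallel to `predictions` (recomputed if omitted).
#' @param structure_cfg [structure_config()] used when annotating.
#' @return Evidence tibble with one `ATTR_PAIR` row per detected pair.
#' @export
find_attr_pairs <- function(predictions, genome, config = screen_config(),
                            annotations = NULL,
                            structure_cfg = structure_config()) {
  if (nrow(predictions) == 0) return(empty_evidence())
  missing_ctg <- setdiff(unique(predictions$seq_id), names(genome))
  if (length(missing_ctg) > 0) {
    abort(sprintf("prediction references missing contig(s): %s",
                  paste(missing_ctg, collapse = ", ")))
  }
  seqs <- prediction_sequences(predictions, genome)
  if (is.null(annotations)) {
    annotations <- map(seqs, annotate_structure, config = structure_cfg)
  }
  n_fatal <- map_int(annotations, count_fatal)
  n_el <- map_int(annotations, ~ nrow(.x$elements))
  out <- list()

  pair_row <- function(i, j) {
    # element span between inner repeat edges; repeats mapped to the genome
    best <- NULL
    for (side in c("3p", "5p")) {
      m <- max_terminal_match(seqs[i], seqs[j], side, config$max_mismatches)
      if (m$length >= config$min_repeat_length &&
          (is.null(best) || m$length > best$m$length)) {
        best <- list(side = side, m = m)
      }
    }
    if (is.null(best)) return(NULL)
    sp_i <- terminal_span(predictions$start[i], predictions$end[i],
                          predictions$strand[i], best$m$length, best$side)
    sp_j <- terminal_span(predictions$start[j], predictions$end[j],
                          predictions$strand[j], best$m$length, best$side)
    inner <- sort(c(sp_i, sp_j))[2:3]
    partial <- if (n_el[i] != n_el[j]) {
      if (n_el[i] < n_el[j]) "subject" else "partner"
    } else {
      si <- predictions$isotype_score[i]
      sj <- predictions$isotype_score[j]
      if (!is.na(si) && !is.na(sj) && si != sj) {
        if (si < sj) "subject" else "partner"
      } else {
        "uncertain"
      }
    }
    as_evidence(
      kind = "ATTR_PAIR", genome_id = predictions$genome_id[i],
      seq_id = predictions$seq_id[i],
      subject = predictions$gene_name[i], partner = predictions$gene_name[j],
      repeat_length = best$m$length, mismatches = best$m$mismatches,
      element_start = inner[1] + 1L, element_end = inner[2] - 1L,
      element_length = max(0L, inner[2] - inner[1] - 1L),
      same_strand = predictions$strand[i] == predictions$strand[j],
      partial_copy = partial,
      detail = sprintf("terminal=%s", best$side))
  }

  for (ctg in unique(predictions$seq_id)) {
    idx <- which(predictions$seq_id == ctg)
    if (length(idx) >= 2) {
      for (a in seq_along(idx)[-length(idx)]) {
        for (b in seq((a + 1), length(idx))) {
          i <- idx[a]; j <- idx[b]
          compatible <- predictions$isotype[i] == predictions$isotype[j] ||
            "Und" %in% predictions$isotype[c(i, j)]
          gap <- max(predictions$start[i], predictions$start[j]) -
            min(predictions$end[i], predictions$end[j])
          if (!compatible || gap > config$max_separation) next
          r <- pair_row(i, j)
          if (!is.null(r)) out[[length(out) + 1]] <- r
        }
      }
    }
    # de novo scan: 3'-terminal seed of each structurally intact (full-length)
    # prediction against the contig; fragment-like predictions are not
    # anchors (their termini are element sequence, not tRNA sequence)
    for (i in idx) {
      if (n_fatal[i] > 0) next
      r <- denovo_partial_scan(i, predictions, seqs, genome, config)
      if (!is.null(r)) out[[length(out) + 1]] <- bind_rows(r)
    }
  }
  if (length(out) == 0) return(empty_evidence())
  bind_rows(out) |> distinct()
}

# scan the 3'-terminal segment of prediction i against its contig for
# unpredicted partial copies (both strands); hits overlapping any prediction
# are skipped (those surface through the pairwise route).
denovo_partial_scan <- function(i, predictions, seqs, genome, config) {
  seed_len <- config$min_repeat_length
  gene_seq <- seqs[i]
  if (nchar(gene_seq) < seed_len) return(NULL)
  seed <- substr(gene_seq, nchar(gene_seq) - seed_len + 1L, nchar(gene_seq))
  if (grepl("N", seed)) return(NULL)
  ctg <- predictions$seq_id[i]
  subject <- genome[[ctg]]
  ctg_len <- length(subject)
  rows <- list()
  for (hit_strand in c("+", "-")) {
    pat <- if (hit_strand == "+") seed else revcomp(seed)
    hits <- Biostrings::matchPattern(pat, subject,
                                     max.mismatch = config$max_mismatches,
                                     fixed = FALSE)
    for (h in seq_along(hits)) {
      hs <- Biostrings::start(hits)[h]
      he <- Biostrings::end(hits)[h]
      # skip the gene's own terminus and anything overlapping a prediction
      ov <- predictions$seq_id == ctg & predictions$start <= he &
        predictions$end >= hs
      if (any(ov)) next
      if (max(predictions$start[i], hs) - min(predictions$end[i], he) >
          config$max_separation) next
      # extend towards the gene 5' end while mismatch budget allows
      ext <- extend_terminal_hit(gene_seq, subject, hs, he, hit_strand,
                                 seed_len, config)
      if (ext$length < config$min_repeat_length) next
      sp_full <- terminal_span(predictions$start[i], predictions$end[i],
                               predictions$strand[i], ext$length, "3p")
      inner <- sort(c(ext$span, sp_full))[2:3]
      rows[[length(rows) + 1]] <- as_evidence(
        kind = "ATTR_PAIR", genome_id = predictions$genome_id[i],
        seq_id = ctg,
        subject = sprintf("%s:%d-%d(%s)", ctg, ext$span[1], ext$span[2], hit_strand),
        partner = predictions$gene_name[i],
        repeat_length = ext$length, mismatches = ext$mismatches,
        element_start = inner[1] + 1L, element_end = inner[2] - 1L,
        element_length = max(0L, inner[2] - inner[1] - 1L),
        same_strand = hit_strand == predictions$strand[i],
        partial_copy = "subject",
        detail = "terminal=3p;unpredicted_partial")
    }
  }
  if (length(rows)) rows else NULL
}

extend_terminal_hit <- function(gene_seq, subject, hs, he, hit_strand,
                                seed_len, config) {
  ctg_len <- length(subject)
  gl <- nchar(gene_seq)
  max_ext <- min(config$terminal_scan_length, gl) - seed_len
  # oriented hit sequence extended on its 5' side
  lo <- if (hit_strand == "+") max(1L, hs - max_ext) else hs
  hi <- if (hit_strand == "+") he else min(ctg_len, he + max_ext)
  window <- as.character(Biostrings::subseq(subject, lo, hi))
  if (hit_strand == "-") window <- revcomp(window)
  tail_gene <- substr(gene_seq, gl - (nchar(window) - 1L), gl)
  m <- max_terminal_match(tail_gene, window, "3p", config$max_mismatches)
  len <- m$length
  span <- if (hit_strand == "+") {
    c(he - len + 1L, he)
  } else {
    c(hs, hs + len - 1L)
  }
  list(length = len, mismatches = m$mismatches, span = as.integer(span))
}

#' Detect CRISPR repeat-spacer arrays
#'
#' A minimal periodic direct-repeat finder: exact seed k-mers occurring at
#' admissible periods (repeat + spacer) are chained into candidate arrays,
#' anchored repeats are extended to their maximal common length, and
#' overlapping candidates are merged. It is intended for flagging predicted
#' tRNA genes that fall inside arrays, not as a general-purpose CRISPR
#' annotator; externally detected arrays can be supplied as a BED track
#' instead.
#'
#' @param genome Named [Biostrings::DNAStringSet].
#' @param config A [screen_config()].
#' @return Tibble of arrays: `seq_id`, `array_id`, `array_start`, `array_end`,
#'   `repeat_length`, `n_repeats`, `repeat_consensus`, plus nested
#'   `repeat_spans` and `spacer_spans` list-columns of two-column matrices.
#' @export
detect_crispr_arrays <- function(genome, config = screen_config()) {
  out <- list()
  next_id <- 1L
  for (ctg in names(genome)) {
    seq <- as.character(genome[[ctg]])
    arrays <- detect_arrays_one(seq, config)
    for (a in arrays) {
      out[[length(out) + 1]] <- tibble(
        seq_id = ctg, array_id = next_id,
        array_start = a$repeat_spans[1, 1],
        array_end = a$repeat_spans[nrow(a$repeat_spans), 2],
        repeat_length = a$repeat_length,
        n_repeats = nrow(a$repeat_spans),
        repeat_consensus = a$consensus,
        repeat_spans = list(a$repeat_spans),
        spacer_spans = list(a$spacer_spans))
      next_id <- next_id + 1L
    }
  }
  if (length(out) == 0) {
    return(tibble(seq_id = character(), array_id = integer(),
                  array_start = integer(), array_end = integer(),
                  repeat_length = integer(), n_repeats = integer(),
                  repeat_consensus = character(),
                  repeat_spans = list(), spacer_spans = list()))
  }
  bind_rows(out)
}

detect_arrays_one <- function(seq, config) {
  n <- nchar(seq)
  k <- config$crispr_k
  if (n < 2 * k) return(list())
  rmin <- config$repeat_length_range[1]; rmax <- config$repeat_length_range[2]
  smin <- config$spacer_length_range[1]; smax <- config$spacer_length_range[2]
  pmin <- rmin + smin; pmax <- rmax + smax
  starts <- seq_len(n - k + 1L)
  kmers <- substring(seq, starts, starts + k - 1L)
  keep <- !grepl("N", kmers, fixed = TRUE)
  occ <- split(starts[keep], kmers[keep])
  occ <- occ[lengths(occ) >= config$min_repeats]
  chains <- list()
  for (p in occ) {
    p <- sort(p)
    gaps_ok <- diff(p) >= pmin & diff(p) <= pmax
    r <- rle(gaps_ok)
    ends <- cumsum(r$lengths)
    starts_r <- ends - r$lengths + 1L
    for (q in which(r$values & r$lengths >= config$min_repeats - 1L)) {
      anchor <- p[starts_r[q]:(ends[q] + 1L)]
      chains[[length(chains) + 1]] <- anchor
    }
  }
  if (length(chains) == 0) return(list())
  # merge chains whose anchor spans overlap; keep the longest chain, then the
  # 5'-most anchor, as the representative
  spans <- t(vapply(chains, function(a) c(min(a), max(a) + k - 1L), integer(2)))
  ord <- order(spans[, 1], spans[, 2])
  groups <- integer(length(chains))
  g <- 0L; cur_end <- -1L
  for (i in ord) {
    if (spans[i, 1] > cur_end) {
      g <- g + 1L
      cur_end <- spans[i, 2]
    } else {
      cur_end <- max(cur_end, spans[i, 2])
    }
    groups[i] <- g
  }
  arrays <- list()
  for (gi in seq_len(g)) {
    members <- which(groups == gi)
    best <- members[order(-lengths(chains[members]),
                          vapply(chains[members], min, integer(1)))][1]
    a <- build_array(seq, chains[[best]], k, config)
    if (!is.null(a)) arrays[[length(arrays) + 1]] <- a
  }
  arrays
}

# extend anchored k-mer occurrences to the maximal common repeat and derive
# repeat/spacer spans
build_array <- function(seq, anchors, k, config) {
  n <- nchar(seq)
  m <- length(anchors)
  rmax <- config$repeat_length_range[2]
  chars <- seq_chars(seq)
  all_eq <- function(off) {
    pos <- anchors + off
    if (any(pos < 1 | pos > n)) return(FALSE)
    b <- chars[pos]
    all(bases_match(b, b[1]))
  }
  left <- 0L
  gap_floor <- min(diff(anchors))
  while (k + left < rmax && left < gap_floor && all_eq(-(left + 1L))) left <- left + 1L
  right <- 0L
  while (k + left + right < rmax && (left + k + right) < gap_floor &&
         all_eq(k + right)) right <- right + 1L
  rep_len <- k + left + right
  if (rep_len < config$repeat_length_range[1]) return(NULL)
  rs <- cbind(anchors - left, anchors - left + rep_len - 1L)
  sp_start <- rs[-m, 2] + 1L
  sp_end <- rs[-1, 1] - 1L
  sp_len <- sp_end - sp_start + 1L
  if (any(sp_len < config$spacer_length_range[1] |
          sp_len > config$spacer_length_range[2])) {
    return(NULL)
  }
  copies <- substring(seq, rs[, 1], rs[, 2])
  mm <- vapply(copies, count_mismatches, integer(1), b = copies[1])
  if (any(mm > config$max_repeat_mismatches)) return(NULL)
  list(repeat_spans = rs, spacer_spans = cbind(sp_start, sp_end),
       repeat_length = as.integer(rep_len), consensus = copies[1])
}

#' Overlap predicted genes with CRISPR arrays
#'
#' @param predictions Prediction tibble.
#' @param arrays Array tibble from [detect_crispr_arrays()] (or built from an
#'   external BED via [read_bed()] plus manual construction).
#' @return Evidence tibble with one `CRISPR_OVERLAP` row per prediction whose
#'   span intersects an array span by at least 1 bp, recording how many
#'   repeats and spacers the gene covers.
#' @export
crispr_overlap <- function(predictions, arrays) {
  if (nrow(predictions) == 0 || nrow(arrays) == 0) return(empty_evidence())
  rows <- list()
  for (i in seq_len(nrow(predictions))) {
    for (j in seq_len(nrow(arrays))) {
      if (predictions$seq_id[i] != arrays$seq_id[j]) next
      ov <- min(predictions$end[i], arrays$array_end[j]) -
        max(predictions$start[i], arrays$array_start[j]) + 1L
      if (ov < 1) next
      covers <- function(spans) {
        sum(pmin(predictions$end[i], spans[, 2]) >=
              pmax(predictions$start[i], spans[, 1]))
      }
      nr <- if (is.null(arrays$repeat_spans[[j]])) NA_integer_ else
        covers(arrays$repeat_spans[[j]])
      ns <- if (is.null(arrays$spacer_spans[[j]])) NA_integer_ else
        covers(arrays$spacer_spans[[j]])
      rows[[length(rows) + 1]] <- as_evidence(
        kind = "CRISPR_OVERLAP", genome_id = predictions$genome_id[i],
        seq_id = predictions$seq_id[i], subject = predictions$gene_name[i],
        array_id = arrays$array_id[j],
        n_repeats_covered = nr, n_spacers_covered = ns,
        overlap_bp = ov,
        detail = sprintf("array=%d-%d", arrays$array_start[j], arrays$array_end[j]))
    }
  }
  if (length(rows) == 0) return(empty_evidence())
  bind_rows(rows)
}

#' Flag predictions containing ambiguous (N) bases
#'
#' @param predictions Prediction tibble.
#' @param genome Named [Biostrings::DNAStringSet].
#' @param annotations Optional list of `trna_annotation` objects parallel to
#'   `predictions`; used to test whether an N falls in the anticodon.
#' @return Evidence tibble with one `AMBIGUOUS_N` row per prediction whose
#'   sequence (or reported anticodon) contains at least one N.
#' @export
ambiguity_check <- function(predictions, genome, annotations = NULL) {
  if (nrow(predictions) == 0) return(empty_evidence())
  seqs <- prediction_sequences(predictions, genome)
  rows <- list()
  for (i in seq_len(nrow(predictions))) {
    n_count <- sum(seq_chars(seqs[i]) == "N")
    in_ac <- grepl("N", predictions$anticodon[i], fixed = TRUE)
    if (!in_ac && !is.null(annotations) && n_count > 0) {
      sp <- annotations[[i]]$anticodon_span
      if (!is.null(sp)) {
        in_ac <- grepl("N", substr(seqs[i], sp[1], sp[2]), fixed = TRUE)
      }
    }
    if (n_count == 0 && !in_ac) next
    rows[[length(rows) + 1]] <- as_evidence(
      kind = "AMBIGUOUS_N", genome_id = predictions$genome_id[i],
      seq_id = predictions$seq_id[i], subject = predictions$gene_name[i],
      n_count = as.integer(n_count), n_in_anticodon = in_ac,
      detail = "")
  }
  if (length(rows) == 0) return(empty_evidence())
  bind_rows(rows)
}

#' Intersect predictions with a tmRNA gene track
#'
#' tmRNA genes carry tRNA-like features and are a known source of spurious
#' tRNA calls; predictions overlapping a user-supplied tmRNA track are
#' flagged.
#'
#' @param predictions Prediction tibble.
#' @param track Interval tibble with `seq_id`, `start`, `end` (1-based
#'   inclusive; see [read_bed()]). May be empty.
#' @return Evidence tibble with one `TMRNA_OVERLAP` row per intersecting
#'   prediction, recording the overlap length in bp.
#' @export
tmrna_overlap <- function(predictions, track) {
  if (nrow(predictions) == 0 || is.null(track) || nrow(track) == 0) {
    return(empty_evidence())
  }
  rows <- list()
  for (i in seq_len(nrow(predictions))) {
    for (j in seq_len(nrow(track))) {
      if (predictions$seq_id[i] != track$seq_id[j]) next
      ov <- min(predictions$end[i], track$end[j]) -
        max(predictions$start[i], track$start[j]) + 1L
      if (ov < 1) next
      rows[[length(rows) + 1]] <- as_evidence(
        kind = "TMRNA_OVERLAP", genome_id = predictions$genome_id[i],
        seq_id = predictions$seq_id[i], subject = predictions$gene_name[i],
        partner = if ("name" %in% names(track)) track$name[j] else NA_character_,
        overlap_bp = ov, detail = "")
    }
  }
  if (length(rows) == 0) return(empty_evidence())
  bind_rows(rows)
}
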