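# Seeded synthetic-genome generator with planted ground truth: canonical
# tRNA genes built from the same cloverleaf rules the annotator checks,
# integration events leaving attR-style partial/full gene pairs, CRISPR
# repeat-spacer arrays (optionally with a tRNA-fragment spacer), and
# N-masked genes emulating ambiguous assembly regions.

#' Specification for a synthetic fixture genome
#'
#' @param seed Integer seed; the same spec generates byte-identical output.
#' @param genome_length Background genome length in bp (default 50000).
#' @param n_canonical Number of planted canonical genes, drawn in order from
#'   `standard` (default 46, the full archaeal complement).
#' @param gc Background GC content (default 0.5, the middle of the 0.40-0.56
#'   range typical of the archaeal genomes this emulates).
#' @param integrations List of integration events, each a list with `target`
#'   (index of the planted gene that donated the full copy),
#'   `repeat_length` (bp of duplicated terminal segment, default 44),
#'   `mismatches` (planted mismatches in the partial copy, default 1),
#'   `element_length` (bp between the inner edges of the two repeat copies,
#'   default 21400), `invert` (place the partial copy reverse-complemented,
#'   default FALSE), and `predict_partial` (emit a prediction record for the
#'   partial copy, default TRUE).
#' @param arrays List of CRISPR arrays, each a list with `n_repeats`
#'   (default 5), `repeat_length` (default 30), `spacer_length` (default 36),
#'   `embed_fragment` (plant a tRNA-fragment spacer, default FALSE) and
#'   `fragment_target` (gene index donating the fragment, default 1).
#' @param maskings List of N-maskings, each a list with `gene` (index) and
#'   `positions` (`"anticodon"` to mask the first anticodon base, or a vector
#'   of gene-local positions).
#' @param standard Standard set supplying the planted gene types.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed, genome_length = 50000, n_canonical = 46,
                         gc = 0.5, integrations = list(), arrays = list(),
                         maskings = list(), standard = standard_archaea46()) {
  stopifnot(genome_length > 0, n_canonical >= 0,
            n_canonical <= nrow(standard))
  fill <- function(x, defaults) {
    for (nm in names(defaults)) x[[nm]] <- x[[nm]] %||% defaults[[nm]]
    x
  }
  integrations <- map(integrations, function(x) {
    x <- fill(x, list(target = 1L, repeat_length = 44L, mismatches = 1L,
                      element_length = 21400L, invert = FALSE,
                      predict_partial = TRUE))
    for (nm in c("target", "repeat_length", "mismatches", "element_length")) {
      x[[nm]] <- as.integer(x[[nm]])
    }
    x
  })
  arrays <- map(arrays, function(x) {
    x <- fill(x, list(n_repeats = 5L, repeat_length = 30L, spacer_length = 36L,
                      embed_fragment = FALSE, fragment_target = 1L))
    for (nm in c("n_repeats", "repeat_length", "spacer_length", "fragment_target")) {
      x[[nm]] <- as.integer(x[[nm]])
    }
    x
  })
  structure(list(seed = as.integer(seed), genome_length = as.integer(genome_length),
                 n_canonical = as.integer(n_canonical), gc = gc,
                 integrations = integrations, arrays = arrays,
                 maskings = maskings, standard = standard),
            class = "fixture_spec")
}

sample_stem <- function(n) {
  s5 <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  list(s5 = paste(s5, collapse = ""),
       s3 = paste(rev(wc_complement(s5)), collapse = ""))
}

#' Generate a canonical tRNA gene sequence
#'
#' Samples a gene that satisfies every rule the structure annotator checks:
#' Watson-Crick-paired stems, the T-T-C-R-A loop motif, a C-T anticodon loop
#' start with the requested anticodon at loop positions 3-5, a genomic CCA,
#' and (for Leu/Ser-type genes) a long variable arm. Candidates are validated
#' with [annotate_structure()] and resampled until the annotation is clean,
#' so every emitted gene is canonical by construction. Uses the current RNG
#' stream; seed outside for reproducibility.
#'
#' @param isotype Isotype label (determines extra-arm usage by default).
#' @param anticodon 3-character N-free anticodon (DNA alphabet).
#' @param extra_arm Plant a long variable arm (default for Leu and Ser).
#' @param config [structure_config()] used for validation.
#' @param max_tries Resampling cap (default 50).
#' @return Gene sequence (character string, 76 nt, or longer with an extra arm).
#' @export
make_canonical_gene <- function(isotype, anticodon,
                                extra_arm = isotype %in% c("Leu", "Ser"),
                                config = structure_config(),
                                max_tries = 50) {
  stopifnot(grepl("^[ACGT]{3}$", anticodon))
  for (try in seq_len(max_tries)) {
    acc <- sample_stem(7)
    conn89 <- random_dna(2)
    d <- sample_stem(4)
    d_loop <- random_dna(8)
    conn26 <- random_dna(1)
    ac <- sample_stem(5)
    ac_loop <- paste0("CT", anticodon, sample(c("A", "G"), 1), random_dna(1))
    var <- if (extra_arm) {
      e <- sample_stem(4)
      paste0(random_dna(1), e$s5, random_dna(4), e$s3, random_dna(1))
    } else {
      random_dna(5)
    }
    t <- sample_stem(5)
    t_loop <- paste0("TTC", sample(c("A", "G"), 1), "A", random_dna(2))
    seq <- paste0(acc$s5, conn89, d$s5, d_loop, d$s3, conn26,
                  ac$s5, ac_loop, ac$s3, var, t$s5, t_loop, t$s3,
                  acc$s3, random_dna(1), "CCA")
    ann <- annotate_structure(seq, config)
    if (is_canonical_structure(ann) && identical(ann$anticodon, anticodon)) {
      return(seq)
    }
  }
  abort("failed to sample a clean canonical gene (raise max_tries)")
}

# T-arm plus 3' acceptor side of a gene: the geometry of integration
# remnants and of the known tRNA-fragment CRISPR spacer
make_fragment <- function(gene_seq, pad5 = 8) {
  core <- substr(gene_seq, nchar(gene_seq) - 27, nchar(gene_seq))
  paste0(random_dna(pad5), core)
}

plant_mismatches <- function(seq, n_mm) {
  if (n_mm == 0) return(seq)
  chars <- seq_chars(seq)
  L <- length(chars)
  pos <- sample(seq(5, L - 5), n_mm)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

# a base guaranteed to differ from (and not pair ambiguously with) `b`
differing_base <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1)

#' Generate a synthetic fixture genome with planted ground truth
#'
#' Builds a uniform-random background genome and plants the features of a
#' [fixture_spec()] at non-overlapping positions (rejection sampling with a
#' retry cap): canonical genes, integration events (partial copy, element
#' interior, full copy; the partial copy duplicates the chosen terminal
#' segment of the target gene with the requested mismatch count, and inverted
#' events place it reverse-complemented), CRISPR arrays (optionally carrying
#' a T-arm/acceptor-side fragment of a planted gene in one spacer), and
#' N-maskings. Emits the prediction table a gene finder would produce
#' (fragments carry low synthetic isotype scores and pseudogene flags;
#' canonical and masked genes carry high scores) alongside machine-readable
#' truth.
#'
#' @param spec A [fixture_spec()].
#' @return List of class `trna_fixture`: `genome` (DNAStringSet, one contig
#'   `ctg1`), `predictions` (prediction tibble), `truth` (list with `genes`,
#'   `attr_pairs`, `arrays`, `maskings` tibbles), and `spec`.
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  std <- spec$standard[seq_len(spec$n_canonical), , drop = FALSE]
  genes <- map2(std$isotype, std$anticodon, function(iso, ac) {
    list(isotype = iso, anticodon = ac, seq = make_canonical_gene(iso, ac))
  })

  blocks <- list()
  add_block <- function(seq, features) {
    blocks[[length(blocks) + 1]] <<- list(seq = seq, features = features)
  }
  integrated <- vapply(spec$integrations, function(ev) ev$target, integer(1))
  crispr_targets <- vapply(spec$arrays, function(a)
    if (isTRUE(a$embed_fragment)) as.integer(a$fragment_target) else NA_integer_,
    integer(1))

  # stand-alone canonical genes (integration targets are embedded in their
  # event blocks instead)
  for (i in seq_along(genes)) {
    if (i %in% integrated) next
    g <- genes[[i]]
    add_block(g$seq, tibble(feature = "canonical", gene_index = i,
                            rel_start = 1L, rel_end = nchar(g$seq),
                            strand = "+", predict = TRUE))
  }

  # integration events: [partial copy][element interior][full copy]
  for (ev in spec$integrations) {
    g <- genes[[ev$target]]
    Lg <- nchar(g$seq)
    rl <- ev$repeat_length
    stopifnot(rl < Lg, ev$element_length >= Lg - rl)
    rep_seq <- plant_mismatches(substr(g$seq, Lg - rl + 1L, Lg), ev$mismatches)
    pe <- sample(20:40, 1)
    # element_length is measured between the inner repeat edges; on inversion
    # the partial copy's 5' extension flips onto the element side
    interior_len <- ev$element_length - (Lg - rl) - (if (ev$invert) pe else 0L)
    stopifnot(interior_len >= 0)
    ext5 <- random_dna(pe)
    # force the base just 5' of the repeat to differ from the target gene's,
    # so the maximal shared terminal segment is exactly the planted repeat
    ext5 <- paste0(substr(ext5, 1, pe - 1),
                   differing_base(substr(g$seq, Lg - rl, Lg - rl)))
    partial <- paste0(ext5, rep_seq)
    interior <- random_dna(interior_len, spec$gc)
    if (ev$invert) {
      block_seq <- paste0(revcomp(partial), interior, g$seq)
      partial_strand <- "-"
    } else {
      block_seq <- paste0(partial, interior, g$seq)
      partial_strand <- "+"
    }
    feats <- bind_rows(
      tibble(feature = "partial_copy", gene_index = ev$target,
             rel_start = 1L, rel_end = nchar(partial),
             strand = partial_strand, predict = isTRUE(ev$predict_partial)),
      tibble(feature = "canonical", gene_index = ev$target,
             rel_start = nchar(partial) + interior_len + 1L,
             rel_end = nchar(block_seq), strand = "+", predict = TRUE))
    add_block(block_seq, feats |> mutate(repeat_length = rl,
                                         mismatches = ev$mismatches,
                                         element_length = ev$element_length))
  }

  # CRISPR arrays: R (S R) x (n-1)
  for (ai in seq_along(spec$arrays)) {
    a <- spec$arrays[[ai]]
    rep_unit <- random_dna(a$repeat_length, spec$gc)
    frag_idx <- if (isTRUE(a$embed_fragment)) ceiling((a$n_repeats - 1) / 2) else -1L
    pieces <- rep_unit
    feats <- tibble(feature = "crispr_repeat", gene_index = NA_integer_,
                    rel_start = 1L, rel_end = a$repeat_length, strand = "+",
                    predict = FALSE, array_index = ai)
    pos <- a$repeat_length
    for (si in seq_len(a$n_repeats - 1L)) {
      spacer <- if (si == frag_idx) {
        frag <- make_fragment(genes[[a$fragment_target]]$seq,
                              pad5 = max(0L, a$spacer_length - 28L))
        substr(frag, 1, a$spacer_length)
      } else {
        s <- random_dna(a$spacer_length, spec$gc)
        # cycle the spacer edge bases so the flanks of the repeat copies can
        # never all agree, which would extend the repeats past their planted
        # length
        substr(s, 1, 1) <- c("G", "T", "C")[si %% 3 + 1]
        substr(s, nchar(s), nchar(s)) <- c("A", "C", "G")[si %% 3 + 1]
        s
      }
      feats <- bind_rows(
        feats,
        tibble(feature = if (si == frag_idx) "crispr_fragment_spacer" else "crispr_spacer",
               gene_index = if (si == frag_idx) a$fragment_target else NA_integer_,
               rel_start = pos + 1L, rel_end = pos + nchar(spacer), strand = "+",
               predict = si == frag_idx, array_index = ai),
        tibble(feature = "crispr_repeat", gene_index = NA_integer_,
               rel_start = pos + nchar(spacer) + 1L,
               rel_end = pos + nchar(spacer) + a$repeat_length, strand = "+",
               predict = FALSE, array_index = ai))
      pieces <- c(pieces, spacer, rep_unit)
      pos <- pos + nchar(spacer) + a$repeat_length
    }
    add_block(paste(pieces, collapse = ""), feats)
  }

  # place blocks without overlap (10 bp margin)
  background <- random_dna(spec$genome_length, spec$gc)
  placed <- list()
  occupied <- matrix(integer(0), ncol = 2)
  # largest blocks first: long elements only fit in a narrow start window
  blocks <- blocks[order(-vapply(blocks, function(b) nchar(b$seq), integer(1)))]
  for (b in blocks) {
    blen <- nchar(b$seq)
    if (blen + 2 > spec$genome_length) {
      abort("fixture feature longer than the genome")
    }
    ok <- FALSE
    for (try in seq_len(500)) {
      s <- sample.int(spec$genome_length - blen + 1L, 1)
      e <- s + blen - 1L
      if (nrow(occupied) == 0 ||
          all(s > occupied[, 2] + 10L | e < occupied[, 1] - 10L)) {
        occupied <- rbind(occupied, c(s, e))
        placed[[length(placed) + 1]] <- list(start = s, block = b)
        ok <- TRUE
        break
      }
    }
    if (!ok) abort("features cannot be placed without overlap")
  }
  chars <- seq_chars(background)
  for (p in placed) {
    s <- p$start
    chars[s:(s + nchar(p$block$seq) - 1L)] <- seq_chars(p$block$seq)
  }

  # absolute feature table
  feats <- map(placed, function(p) {
    p$block$features |> mutate(start = p$start + .data$rel_start - 1L,
                               end = p$start + .data$rel_end - 1L)
  }) |> list_rbind()

  # N-maskings (applied to the assembled genome)
  mask_rows <- list()
  for (mk in spec$maskings) {
    gi <- mk$gene
    grow <- feats |> filter(.data$feature == "canonical", .data$gene_index == gi)
    stopifnot(nrow(grow) == 1)
    gene_seq <- genes[[gi]]$seq
    ann <- annotate_structure(gene_seq)
    rel_pos <- if (identical(mk$positions, "anticodon")) {
      ann$anticodon_span[1]
    } else {
      as.integer(mk$positions)
    }
    abs_pos <- grow$start + rel_pos - 1L
    chars[abs_pos] <- "N"
    masked_ac <- genes[[gi]]$anticodon
    ac_rel <- rel_pos - ann$anticodon_span[1] + 1L
    in_ac <- ac_rel >= 1 & ac_rel <= 3
    for (k in which(in_ac)) {
      substr(masked_ac, ac_rel[k], ac_rel[k]) <- "N"
    }
    mask_rows[[length(mask_rows) + 1]] <- tibble(
      gene_index = gi, positions = list(abs_pos),
      original_isotype = genes[[gi]]$isotype,
      original_anticodon = genes[[gi]]$anticodon,
      masked_anticodon = masked_ac)
  }
  maskings <- if (length(mask_rows)) list_rbind(mask_rows) else
    tibble(gene_index = integer(), positions = list(),
           original_isotype = character(), original_anticodon = character(),
           masked_anticodon = character())
  masked_idx <- maskings$gene_index

  genome <- Biostrings::DNAStringSet(setNames(paste(chars, collapse = ""), "ctg1"))

  # prediction table (what a gene finder would report)
  pred_rows <- list()
  feats_pred <- feats |> filter(.data$predict)
  counter <- 0L
  for (i in seq_len(nrow(feats_pred))) {
    f <- feats_pred[i, ]
    counter <- counter + 1L
    if (f$feature == "canonical") {
      gi <- f$gene_index
      iso <- genes[[gi]]$isotype
      ac <- if (gi %in% masked_idx) {
        maskings$masked_anticodon[match(gi, masked_idx)]
      } else {
        genes[[gi]]$anticodon
      }
      score <- round(runif(1, 95, 135), 1)
      role <- if (gi %in% masked_idx) "masked" else "canonical"
      pseudo <- FALSE
    } else if (f$feature == "partial_copy") {
      gi <- f$gene_index
      iso <- genes[[gi]]$isotype
      ac <- genes[[gi]]$anticodon
      score <- round(runif(1, 2, 40), 1)
      role <- "fragment_attr"
      pseudo <- TRUE
    } else { # crispr_fragment_spacer: prediction spans flanking repeats too
      gi <- f$gene_index
      iso <- genes[[gi]]$isotype
      ac <- genes[[gi]]$anticodon
      score <- round(runif(1, 2, 40), 1)
      role <- "fragment_crispr"
      pseudo <- TRUE
      arr <- feats |> filter(.data$feature == "crispr_repeat",
                             .data$array_index == f$array_index)
      before <- arr |> filter(.data$end < f$start) |> slice_max(.data$end, n = 1)
      after <- arr |> filter(.data$start > f$end) |> slice_min(.data$start, n = 1)
      if (nrow(before) == 1) f$start <- before$start
      if (nrow(after) == 1) f$end <- after$end
    }
    pred_rows[[counter]] <- tibble(
      genome_id = "fixture", seq_id = "ctg1", trna_no = counter,
      gene_name = sprintf("tRNA-%s-%s-%d-1", iso, ac, counter),
      start = f$start, end = f$end, strand = f$strand,
      isotype = iso, anticodon = ac, length_bp = f$end - f$start + 1L,
      general_score = score, isotype_score = score,
      hmm_score = NA_real_, ss_score = NA_real_, pseudo_flag = pseudo,
      intron_start = NA_integer_, intron_end = NA_integer_,
      note = if (pseudo) "pseudo" else "", role = role)
  }
  predictions <- if (length(pred_rows)) list_rbind(pred_rows) else
    bind_cols(empty_predictions(), tibble(role = character()))
  roles <- predictions$role
  predictions$role <- NULL

  # truth tables
  truth_genes <- feats |>
    filter(.data$feature %in% c("canonical", "partial_copy",
                                "crispr_fragment_spacer")) |>
    mutate(role = case_when(
      .data$feature == "canonical" & .data$gene_index %in% masked_idx ~ "masked",
      .data$feature == "canonical" ~ "canonical",
      .data$feature == "partial_copy" ~ "fragment_attr",
      TRUE ~ "fragment_crispr")) |>
    select("role", "gene_index", "start", "end", "strand", "predict")
  attr_truth <- if ("repeat_length" %in% names(feats)) {
    feats |>
      filter(.data$feature == "partial_copy") |>
      select("gene_index", partial_start = "start", partial_end = "end",
             partial_strand = "strand", "repeat_length", "mismatches",
             "element_length")
  } else {
    tibble(gene_index = integer(), partial_start = integer(),
           partial_end = integer(), partial_strand = character(),
           repeat_length = integer(), mismatches = integer(),
           element_length = integer())
  }
  array_truth <- if ("array_index" %in% names(feats)) {
    feats |>
      filter(.data$feature == "crispr_repeat") |>
      group_by(.data$array_index) |>
      summarise(n_repeats = n(),
                repeat_length = .data$end[1] - .data$start[1] + 1L,
                array_start = min(.data$start), array_end = max(.data$end),
                .groups = "drop")
  } else {
    tibble(array_index = integer(), n_repeats = integer(),
           repeat_length = integer(), array_start = integer(),
           array_end = integer())
  }

  structure(list(genome = genome, predictions = predictions,
                 prediction_roles = roles,
                 truth = list(genes = truth_genes, attr_pairs = attr_truth,
                              arrays = array_truth, maskings = maskings),
                 spec = spec),
            class = "trna_fixture")
}

#' Write a fixture to disk
#'
#' Emits the genome FASTA, the prediction table in tRNAscan-SE layout, the
#' ground truth as JSON, and a truth BED (0-based half-open, like all BED
#' output).
#'
#' @param fixture A `trna_fixture` from [generate_fixture()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(fasta = file.path(dir, "genome.fa"),
             predictions = file.path(dir, "predictions.tsv"),
             truth_json = file.path(dir, "truth.json"),
             truth_bed = file.path(dir, "truth.bed"))
  Biostrings::writeXStringSet(fixture$genome, paths["fasta"])
  write_trnascan(fixture$predictions, paths["predictions"])
  truth <- fixture$truth
  truth$maskings$positions <- map(truth$maskings$positions, as.integer)
  jsonlite::write_json(truth, paths["truth_json"], auto_unbox = TRUE, digits = NA)
  bed <- fixture$truth$genes |>
    mutate(seq_id = "ctg1",
           gene_name = sprintf("%s_%d", .data$role, .data$gene_index))
  write_bed(bed, paths["truth_bed"])
  invisible(paths)
}
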