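test_that("planted integration events are recovered with exact geometry", {
  fx <- make_screen_fixture(seed = 301, crispr = FALSE)
  ev <- find_attr_pairs(fx$predictions, fx$genome)
  ev <- ev[ev$kind == "ATTR_PAIR", ]
  expect_equal(nrow(ev), 1)
  expect_equal(ev$repeat_length, 44L)
  expect_equal(ev$mismatches, 1L)
  expect_equal(ev$element_length, 2000L)
  expect_true(ev$same_strand)
  # the partial copy is named as such
  partial_gene <- if (ev$partial_copy == "subject") ev$subject else ev$partner
  truth <- fx$truth$attr_pairs
  partial_pred <- fx$predictions[fx$predictions$start == truth$partial_start, ]
  expect_equal(partial_gene, partial_pred$gene_name)
})

test_that("a genome without duplication yields no attR pairs", {
  spec <- fixture_spec(seed = 302, genome_length = 8000, n_canonical = 8)
  fx <- generate_fixture(spec)
  ev <- find_attr_pairs(fx$predictions, fx$genome)
  expect_equal(nrow(ev), 0)
})

test_that("inverted partial copies are found on the opposite strand", {
  fx <- make_screen_fixture(seed = 303, crispr = FALSE, invert = TRUE)
  ev <- find_attr_pairs(fx$predictions, fx$genome)
  expect_equal(nrow(ev), 1)
  expect_false(ev$same_strand)
  expect_equal(ev$repeat_length, 44L)
  expect_equal(ev$element_length, 2000L)
})

test_that("unpredicted partial copies are caught by the genome-wide terminal scan", {
  spec <- fixture_spec(seed = 304, genome_length = 8000, n_canonical = 5,
                       integrations = list(list(target = 1, repeat_length = 44,
                                                mismatches = 1,
                                                element_length = 2000,
                                                predict_partial = FALSE)))
  fx <- generate_fixture(spec)
  ev <- find_attr_pairs(fx$predictions, fx$genome)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$repeat_length, 44L)
  expect_equal(ev$partial_copy, "subject")
  expect_match(ev$subject, "^ctg1:")
  # the reported span is the planted partial copy's repeat
  truth <- fx$truth$attr_pairs
  expect_match(ev$subject, sprintf("-%d\\(", truth$partial_end))
})

test_that("pairwise terminal repeats agree with a brute-force loop oracle", {
  for (seed in 311:316) {
    fx <- make_screen_fixture(seed = seed, crispr = FALSE)
    preds <- fx$predictions
    genome <- fx$genome
    seqs <- vapply(seq_len(nrow(preds)), function(i) {
      extract_span(genome, preds$seq_id[i], preds$start[i], preds$end[i],
                   preds$strand[i])
    }, character(1))
    ev <- find_attr_pairs(preds, genome)
    ev_pairs <- ev[!grepl("^ctg1:", ev$subject), ]
    for (i in seq_len(nrow(preds) - 1)) {
      for (j in seq(i + 1, nrow(preds))) {
        best <- 0L
        best_mm <- 0L
        for (side in c("3p", "5p")) {
          m <- oracle_terminal_match(seqs[i], seqs[j], side, max_mm = 1)
          if (m$length > best) {
            best <- m$length
            best_mm <- m$mismatches
          }
        }
        hit <- ev_pairs$subject == preds$gene_name[i] &
          ev_pairs$partner == preds$gene_name[j]
        if (best >= 20 && preds$isotype[i] == preds$isotype[j]) {
          expect_true(any(hit))
          expect_equal(ev_pairs$repeat_length[hit], best)
          expect_equal(ev_pairs$mismatches[hit], best_mm)
        } else {
          expect_false(any(hit))
        }
      }
    }
  }
})

test_that("the terminal genome scan agrees with a quadratic position-by-position oracle", {
  for (seed in 321:324) {
    spec <- fixture_spec(seed = seed, genome_length = 6000, n_canonical = 3,
                         integrations = list(list(target = 1, repeat_length = 44,
                                                  mismatches = 1,
                                                  element_length = 1500,
                                                  predict_partial = FALSE)))
    fx <- generate_fixture(spec)
    preds <- fx$predictions
    genome_seq <- as.character(fx$genome[["ctg1"]])
    ev <- find_attr_pairs(preds, fx$genome)
    denovo <- ev[grepl("^ctg1:", ev$subject), ]
    # oracle hits outside predicted genes, maximal per 3'-end position
    all_hits <- list()
    for (i in seq_len(nrow(preds))) {
      g <- extract_span(fx$genome, "ctg1", preds$start[i], preds$end[i],
                        preds$strand[i])
      hits <- oracle_denovo_hits(g, genome_seq)
      for (h in hits) {
        ov <- any(preds$start <= h$end & preds$end >= h$start)
        if (!ov) all_hits[[length(all_hits) + 1]] <- h
      }
    }
    expect_equal(nrow(denovo), length(all_hits))
    if (length(all_hits) == 1) {
      h <- all_hits[[1]]
      expect_equal(denovo$repeat_length, h$length)
      expect_equal(denovo$subject,
                   sprintf("ctg1:%d-%d(%s)", h$start, h$end, h$strand))
    }
  }
})

test_that("planted CRISPR arrays are recovered exactly", {
  fx <- make_screen_fixture(seed = 331)
  arr <- detect_crispr_arrays(fx$genome)
  truth <- fx$truth$arrays
  expect_equal(nrow(arr), 1)
  expect_equal(arr$n_repeats, truth$n_repeats)
  expect_equal(arr$repeat_length, truth$repeat_length)
  expect_equal(arr$array_start, truth$array_start)
  expect_equal(arr$array_end, truth$array_end)
  # repeats and spacers alternate: one more repeat than spacers
  expect_equal(nrow(arr$repeat_spans[[1]]), nrow(arr$spacer_spans[[1]]) + 1L)
})

test_that("uniform random sequence yields no arrays across 20 seeds", {
  for (seed in 341:360) {
    set.seed(seed)
    g <- Biostrings::DNAStringSet(setNames(paste(
      sample(c("A", "C", "G", "T"), 10000, replace = TRUE), collapse = ""), "c1"))
    expect_equal(nrow(detect_crispr_arrays(g)), 0, info = seed)
  }
})

test_that("two repeat copies stay below the array threshold", {
  set.seed(361)
  rep_unit <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE), collapse = "")
  spacer <- paste(sample(c("A", "C", "G", "T"), 36, replace = TRUE), collapse = "")
  bg <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  g <- Biostrings::DNAStringSet(setNames(
    paste0(bg(500), rep_unit, spacer, rep_unit, bg(500)), "c1"))
  expect_equal(nrow(detect_crispr_arrays(g)), 0)
})

test_that("array detection is certified by the all-shift repeat oracle", {
  for (seed in c(331, 371, 372)) {
    fx <- make_screen_fixture(seed = seed)
    seq <- as.character(fx$genome[["ctg1"]])
    arr <- detect_crispr_arrays(fx$genome)
    chains <- oracle_crispr_chains(seq)
    expect_equal(nrow(arr), length(chains))
    for (k in seq_len(nrow(arr))) {
      expect_array_certified(arr$repeat_spans[[k]], chains[[k]])
    }
  }
  # and the oracle agrees nothing is there in clean sequence
  set.seed(373)
  clean <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
                 collapse = "")
  expect_length(oracle_crispr_chains(clean), 0)
})

test_that("gene/array overlap is reported with covered repeat and spacer counts", {
  fx <- make_screen_fixture(seed = 381)
  arr <- detect_crispr_arrays(fx$genome)
  ov <- crispr_overlap(fx$predictions, arr)
  expect_equal(nrow(ov), 1)
  expect_equal(ov$n_repeats_covered, 2L)
  expect_equal(ov$n_spacers_covered, 1L)

  # a prediction 1 bp outside the array is not flagged
  outside <- fx$predictions[1, ]
  outside$start <- arr$array_end + 2L
  outside$end <- outside$start + 75L
  outside$length_bp <- 76L
  expect_equal(nrow(crispr_overlap(outside, arr)), 0)
  edge <- fx$predictions[1, ]
  edge$start <- arr$array_end
  edge$end <- arr$array_end + 75L
  edge$length_bp <- 76L
  expect_equal(nrow(crispr_overlap(edge, arr)), 1)
})

test_that("ambiguity evidence records N counts and anticodon involvement", {
  set.seed(391)
  g <- make_canonical_gene("Leu", "CAG", extra_arm = TRUE)
  chars <- strsplit(g, "")[[1]]
  chars[34] <- "N"
  masked <- paste(chars, collapse = "")
  genome <- Biostrings::DNAStringSet(setNames(
    paste0(strrep("A", 100), masked, strrep("A", 100)), "c1"))
  pred <- tibble::tibble(
    genome_id = "g", seq_id = "c1", trna_no = 1L,
    gene_name = "tRNA-Leu-NAG-1-1", start = 101L,
    end = 100L + nchar(masked), strand = "+", isotype = "Leu",
    anticodon = "NAG", length_bp = nchar(masked), general_score = 50,
    isotype_score = 135.1, hmm_score = NA_real_, ss_score = NA_real_,
    pseudo_flag = FALSE, intron_start = NA_integer_, intron_end = NA_integer_,
    note = "")
  ev <- ambiguity_check(pred, genome)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$n_count, 1L)
  expect_true(ev$n_in_anticodon)

  # N-free gene: no evidence
  clean_pred <- pred
  clean_pred$anticodon <- "CAG"
  clean_genome <- Biostrings::DNAStringSet(setNames(
    paste0(strrep("A", 100), g, strrep("A", 100)), "c1"))
  expect_equal(nrow(ambiguity_check(clean_pred, clean_genome)), 0)

  # Ns outside the anticodon
  chars2 <- strsplit(g, "")[[1]]
  chars2[c(9, 45)] <- "N"
  genome2 <- Biostrings::DNAStringSet(setNames(
    paste0(strrep("A", 100), paste(chars2, collapse = ""), strrep("A", 100)), "c1"))
  anns <- list(annotate_structure(paste(chars2, collapse = "")))
  ev2 <- ambiguity_check(clean_pred, genome2, annotations = anns)
  expect_equal(ev2$n_count, 2L)
  expect_false(ev2$n_in_anticodon)
})

test_that("tmRNA track intersection records the overlap length", {
  pred <- tibble::tibble(
    genome_id = "g", seq_id = "c1", trna_no = 1L, gene_name = "tRNA-Und-NNN-3-1",
    start = 500L, end = 590L, strand = "+", isotype = "Und", anticodon = "NNN",
    length_bp = 91L, general_score = 30, isotype_score = 23.7,
    hmm_score = NA_real_, ss_score = NA_real_, pseudo_flag = FALSE,
    intron_start = NA_integer_, intron_end = NA_integer_, note = "")
  track <- tibble::tibble(seq_id = "c1", start = 200L, end = 620L,
                          name = "tmRNA", strand = "+")
  ev <- tmrna_overlap(pred, track)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$overlap_bp, 91L)

  expect_equal(nrow(tmrna_overlap(pred, track[c(), ])), 0)

  partial_track <- tibble::tibble(seq_id = "c1", start = 100L, end = 509L,
                                  name = "tmRNA", strand = "+")
  ev2 <- tmrna_overlap(pred, partial_track)
  expect_equal(ev2$overlap_bp, 10L)
})

test_that("screens are strand-symmetric up to mirrored coordinates", {
  fx <- make_screen_fixture(seed = 401)
  n <- length(fx$genome[["ctg1"]])
  rc <- Biostrings::DNAStringSet(setNames(
    revcomp(as.character(fx$genome[["ctg1"]])), "ctg1"))
  flip <- function(p) {
    tibble::tibble(p, start2 = n - p$end + 1L, end2 = n - p$start + 1L) |>
      dplyr::mutate(start = start2, end = end2,
                    strand = ifelse(strand == "+", "-", "+")) |>
      dplyr::select(-start2, -end2)
  }
  preds_rc <- flip(fx$predictions)
  ev <- find_attr_pairs(fx$predictions, fx$genome)
  ev_rc <- find_attr_pairs(preds_rc, rc)
  expect_equal(nrow(ev), nrow(ev_rc))
  expect_equal(sort(ev$repeat_length), sort(ev_rc$repeat_length))
  expect_equal(sort(ev$element_length), sort(ev_rc$element_length))
  arr <- detect_crispr_arrays(fx$genome)
  arr_rc <- detect_crispr_arrays(rc)
  expect_equal(nrow(arr), nrow(arr_rc))
  expect_equal(arr_rc$array_start, n - arr$array_end + 1L)
  expect_equal(arr_rc$array_end, n - arr$array_start + 1L)
  expect_equal(arr_rc$repeat_length, arr$repeat_length)
  expect_equal(arr_rc$n_repeats, arr$n_repeats)
})

test_that("predictions referencing missing contigs raise an error", {
  fx <- make_screen_fixture(seed = 402, crispr = FALSE)
  bad <- fx$predictions
  bad$seq_id[1] <- "nope"
  expect_error(find_attr_pairs(bad, fx$genome), "missing contig")
})
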