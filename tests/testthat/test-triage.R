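pred_row <- function(gene_name = "tRNA-Ala-TGC-1-1", isotype = "Ala",
                     anticodon = "TGC", isotype_score = 120,
                     pseudo_flag = FALSE) {
  tibble::tibble(
    genome_id = "g", seq_id = "c1", trna_no = 1L, gene_name = gene_name,
    start = 100L, end = 175L, strand = "+", isotype = isotype,
    anticodon = anticodon, length_bp = 76L, general_score = 70,
    isotype_score = isotype_score, hmm_score = NA_real_, ss_score = NA_real_,
    pseudo_flag = pseudo_flag, intron_start = NA_integer_,
    intron_end = NA_integer_, note = "")
}

test_that("score banding follows the published thresholds", {
  cfg <- triage_config()
  expect_equal(score_band(83.4, cfg), "UNCERTAIN")
  expect_equal(score_band(2.3, cfg), "LIKELY_NONCANONICAL")
  expect_equal(score_band(135.1, cfg), "LIKELY_CANONICAL")
  expect_equal(score_band(c(59.9, 60, 90, 90.1), cfg),
               c("LIKELY_NONCANONICAL", "UNCERTAIN", "UNCERTAIN",
                 "LIKELY_CANONICAL"))
  expect_warning(b <- score_band(NA_real_, cfg), "absent")
  expect_equal(b, "UNCERTAIN")
})

test_that("ambiguous anticodons are rescued only against a unique missing type", {
  deficit <- tibble::tibble(isotype = c("Leu", "Pro", "Gln"),
                            anticodon = c("CAG", "GGG", "CTG"))
  expect_equal(resolve_ambiguous("Leu", "NAG", deficit)$anticodon, "CAG")
  expect_equal(resolve_ambiguous("Pro", "NGG", deficit)$anticodon, "GGG")
  r <- resolve_ambiguous("Und", "NTG", deficit)
  expect_equal(r$isotype, "Gln")
  expect_equal(r$anticodon, "CTG")
  # multiple matches: no rescue
  two <- tibble::tibble(isotype = c("Leu", "Leu"), anticodon = c("CAG", "TAG"))
  expect_null(resolve_ambiguous("Leu", "NNN", two))
  expect_null(resolve_ambiguous("Leu", "NAG", two))
  # no matches
  expect_null(resolve_ambiguous("Ala", "NGC", deficit))
  expect_null(resolve_ambiguous("Leu", "NAG", deficit[c(), ]))
})

test_that("uncertain-band genes are classified by structural integrity", {
  set.seed(501)
  g <- make_canonical_gene("Val", "CAC", extra_arm = FALSE)
  # break acceptor stem (three mispairs) and D-arm
  chars <- strsplit(g, "")[[1]]
  chars[2:4] <- "A"; chars[69:71] <- "A"; chars[10:13] <- "A"; chars[22:25] <- "A"
  broken <- annotate_structure(paste(chars, collapse = ""))
  expect_false(is_canonical_structure(broken))
  call <- classify(pred_row("tRNA-Val-CAC-1-1", "Val", "CAC", 83.4), broken)
  expect_equal(call$band, "UNCERTAIN")
  expect_equal(call$category, "NONCANONICAL_OTHER")

  # a single tolerated acceptor mispair stays canonical (manual review advised)
  ok <- annotate_structure(g)
  call2 <- classify(pred_row("tRNA-Arg-GCG-1-1", "Arg", "GCG", 88.1), ok)
  expect_equal(call2$band, "UNCERTAIN")
  expect_equal(call2$category, "CANONICAL")
  expect_match(call2$rationale, "manual review")
})

test_that("context evidence outranks scores in the precedence order", {
  set.seed(502)
  ann <- annotate_structure(make_canonical_gene("Gln", "TTG"))
  p <- pred_row("tRNA-Gln-TTG-9-1", "Gln", "TTG", 120)
  ev_crispr <- trnacurate:::as_evidence(kind = "CRISPR_OVERLAP", genome_id = "g",
                                        seq_id = "c1", subject = p$gene_name)
  expect_equal(classify(p, ann, ev_crispr)$category, "FRAGMENT_CRISPR")
  ev_attr <- trnacurate:::as_evidence(kind = "ATTR_PAIR", genome_id = "g",
                                      seq_id = "c1", subject = p$gene_name,
                                      partner = "tRNA-Gln-TTG-2-1",
                                      partial_copy = "subject")
  expect_equal(classify(p, ann, ev_attr)$category, "FRAGMENT_ATTR")
  # the full-copy partner of an attR pair is not a fragment
  ev_attr2 <- ev_attr
  ev_attr2$partial_copy <- "partner"
  expect_equal(classify(p, ann, ev_attr2)$category, "CANONICAL")
  ev_tmrna <- trnacurate:::as_evidence(kind = "TMRNA_OVERLAP", genome_id = "g",
                                       seq_id = "c1", subject = p$gene_name)
  expect_equal(classify(p, ann, ev_tmrna)$category, "NONCANONICAL_OTHER")
})

test_that("pseudogene flags are advisory unless defects concur", {
  set.seed(503)
  ann <- annotate_structure(make_canonical_gene("Thr", "TGT"))
  flagged <- pred_row("tRNA-Thr-TGT-1-1", "Thr", "TGT", 110, pseudo_flag = TRUE)
  expect_equal(classify(flagged, ann)$category, "CANONICAL")
  broken <- annotate_structure("ACGTACGTACGTACGTACGTACGT")
  low <- pred_row("tRNA-Thr-TGT-1-1", "Thr", "TGT", 70, pseudo_flag = TRUE)
  expect_equal(classify(low, broken)$category, "NONCANONICAL_OTHER")
})

test_that("already-satisfied types become legitimate duplicates", {
  set.seed(504)
  ann <- annotate_structure(make_canonical_gene("Ala", "TGC", extra_arm = FALSE))
  p <- pred_row("tRNA-Ala-TGC-2-1", "Ala", "TGC", 122.6)
  expect_equal(classify(p, ann, type_satisfied = TRUE)$category,
               "LEGITIMATE_DUPLICATE")
  expect_equal(classify(p, ann, type_satisfied = FALSE)$category, "CANONICAL")
})

test_that("evidence naming a different gene is rejected in single-gene use", {
  p <- pred_row()
  ev <- trnacurate:::as_evidence(kind = "CRISPR_OVERLAP", genome_id = "g",
                                 seq_id = "c1", subject = "tRNA-Other-AAA-1-1")
  expect_error(classify(p, evidence = ev), "references gene")
})

test_that("raising the lower band never converts non-canonical calls to canonical", {
  listing <- thermococcaceae_listing()
  ev <- trnacurate:::thermococcaceae_evidence()
  lo <- trnacurate:::curate_with_evidence(listing, NULL, ev,
                                          triage_cfg = triage_config(band_low = 60))
  hi <- trnacurate:::curate_with_evidence(listing, NULL, ev,
                                          triage_cfg = triage_config(band_low = 75))
  noncanon <- c("FRAGMENT_ATTR", "FRAGMENT_CRISPR", "NONCANONICAL_OTHER")
  was_non <- tibble::as_tibble(lo)$category %in% noncanon
  still <- tibble::as_tibble(hi)$category
  expect_true(all(still[was_non] %in% noncanon))
})

test_that("curation of already-curated canonical output is a fixed point", {
  spec <- fixture_spec(seed = 505, genome_length = 20000, n_canonical = 12,
                       integrations = list(list(target = 1, repeat_length = 44,
                                                mismatches = 1,
                                                element_length = 2000)))
  fx <- generate_fixture(spec)
  first <- curate_genes(fx$predictions, fx$genome)
  tb <- tibble::as_tibble(first)
  keep <- tb$category %in% c("CANONICAL", "LEGITIMATE_DUPLICATE")
  again <- curate_genes(fx$predictions[keep, ], fx$genome)
  # the genome still contains the element, so the full copy may accumulate
  # fresh attR evidence; the verdicts themselves are a fixed point
  cols <- setdiff(names(tb), "evidence_kinds")
  expect_equal(tibble::as_tibble(again)[cols], tb[keep, cols],
               ignore_attr = TRUE)
})

test_that("curating an empty prediction table returns an empty call table", {
  g <- Biostrings::DNAStringSet(setNames("ACGTACGT", "c1"))
  empty <- trnacurate:::empty_predictions()
  out <- curate_genes(empty, g)
  expect_equal(nrow(out), 0)
  expect_true(all(c("category", "band", "rationale") %in% names(out)))
})

test_that("glance summarizes per-genome category counts", {
  fx <- make_screen_fixture(seed = 506)
  cur <- curate_genes(fx$predictions, fx$genome)
  gl <- generics::glance(cur)
  expect_equal(gl$n_genes, nrow(fx$predictions))
  expect_equal(gl$n_fragment_attr, 1L)
  expect_equal(gl$n_fragment_crispr, 1L)
  expect_equal(gl$n_canonical,
               sum(fx$prediction_roles == "canonical"))
})
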