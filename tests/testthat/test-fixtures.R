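test_that("generation is deterministic: same spec, identical bytes", {
  spec <- fixture_spec(seed = 701, genome_length = 12000, n_canonical = 8,
                       integrations = list(list(target = 2, repeat_length = 44,
                                                mismatches = 1,
                                                element_length = 2000)),
                       arrays = list(list(n_repeats = 4)))
  f1 <- generate_fixture(spec)
  f2 <- generate_fixture(spec)
  expect_identical(as.character(f1$genome), as.character(f2$genome))
  expect_identical(f1$predictions, f2$predictions)
  expect_identical(f1$truth, f2$truth)
})

test_that("gene construction is seeded and validated by the annotator", {
  set.seed(702)
  g1 <- make_canonical_gene("Gln", "TTG")
  set.seed(702)
  g2 <- make_canonical_gene("Gln", "TTG")
  expect_identical(g1, g2)
  expect_equal(nchar(g1), 76L)
  set.seed(703)
  leu <- make_canonical_gene("Leu", "CAA")
  expect_gt(nchar(leu), 82)
  expect_true(is_canonical_structure(annotate_structure(leu)))
  expect_equal(annotate_structure(leu)$anticodon, "CAA")
})

test_that("planted canonical genes annotate cleanly; planted fragments do not", {
  for (seed in 704:708) {
    fx <- make_screen_fixture(seed = seed, genome_length = 10000,
                              n_canonical = 6)
    genes <- fx$truth$genes
    for (i in seq_len(nrow(genes))) {
      seq <- extract_span(fx$genome, "ctg1", genes$start[i], genes$end[i],
                          genes$strand[i])
      canonical <- is_canonical_structure(annotate_structure(seq))
      if (genes$role[i] %in% c("canonical", "masked")) {
        expect_true(canonical, info = paste(seed, genes$role[i]))
      } else {
        expect_false(canonical, info = paste(seed, genes$role[i]))
      }
    }
  }
})

test_that("a no-event fixture triggers no screens", {
  spec <- fixture_spec(seed = 709, genome_length = 50000, n_canonical = 46)
  fx <- generate_fixture(spec)
  expect_equal(nrow(fx$truth$genes), 46)
  expect_equal(nrow(find_attr_pairs(fx$predictions, fx$genome)), 0)
  expect_equal(nrow(detect_crispr_arrays(fx$genome)), 0)
})

test_that("curation reproduces the planted truth partition across seeds", {
  for (seed in 711:716) {
    spec <- fixture_spec(seed = seed, genome_length = 15000, n_canonical = 10,
                         integrations = list(list(target = 1,
                                                  repeat_length = 44,
                                                  mismatches = 1,
                                                  element_length = 2500)),
                         arrays = list(list(n_repeats = 5,
                                            embed_fragment = TRUE,
                                            fragment_target = 2)))
    fx <- generate_fixture(spec)
    cur <- tibble::as_tibble(curate_genes(fx$predictions, fx$genome))
    expected <- c(canonical = "CANONICAL", fragment_attr = "FRAGMENT_ATTR",
                  fragment_crispr = "FRAGMENT_CRISPR",
                  masked = "MISASSIGNED_AMBIGUOUS")
    expect_equal(cur$category, unname(expected[fx$prediction_roles]),
                 info = seed)
    expect_equal(sum(cur$category == "CANONICAL"),
                 sum(fx$truth$genes$role == "canonical"), info = seed)
  }
})

test_that("N-masked genes are rescued to their original type", {
  spec <- fixture_spec(seed = 717, genome_length = 60000, n_canonical = 46,
                       maskings = list(list(gene = 24, positions = "anticodon")))
  fx <- generate_fixture(spec)
  cur <- tibble::as_tibble(curate_genes(fx$predictions, fx$genome))
  masked <- cur[grepl("N", cur$anticodon), ]
  expect_equal(nrow(masked), 1)
  expect_equal(masked$category, "MISASSIGNED_AMBIGUOUS")
  expect_equal(masked$reassigned_isotype, fx$truth$maskings$original_isotype)
  expect_equal(masked$reassigned_anticodon, fx$truth$maskings$original_anticodon)
  # curated-mode comparison sees a complete standard set
  expect_equal(nrow(compare_to_standard(cur, standard_archaea46(), "curated")), 0)
})

test_that("truth features match the emitted genome sequence", {
  fx <- make_screen_fixture(seed = 718, genome_length = 10000, n_canonical = 5)
  truth <- fx$truth
  # the partial copy's repeat equals the target gene terminal up to the
  # planted mismatches
  pair <- truth$attr_pairs
  target <- truth$genes[truth$genes$role == "canonical" &
                          truth$genes$gene_index == pair$gene_index, ]
  gene_seq <- extract_span(fx$genome, "ctg1", target$start, target$end, "+")
  partial_seq <- extract_span(fx$genome, "ctg1", pair$partial_start,
                              pair$partial_end, pair$partial_strand)
  m <- oracle_terminal_match(gene_seq, partial_seq, "3p", max_mm = pair$mismatches)
  expect_equal(m$length, pair$repeat_length)
  expect_equal(m$mismatches, pair$mismatches)
})

test_that("fixtures serialize to FASTA, predictions, JSON truth and BED", {
  fx <- make_screen_fixture(seed = 719, genome_length = 8000, n_canonical = 4)
  dir <- withr::local_tempdir()
  paths <- write_fixture(fx, dir)
  expect_true(all(file.exists(paths)))
  g <- read_genome(paths[["fasta"]])
  expect_identical(as.character(g[["ctg1"]]),
                   as.character(fx$genome[["ctg1"]]))
  preds <- read_trnascan(paths[["predictions"]], genome_id = "fixture")
  expect_equal(preds$start, fx$predictions$start)
  expect_equal(preds$isotype_score, fx$predictions$isotype_score)
  bed <- read_bed(paths[["truth_bed"]])
  expect_equal(nrow(bed), nrow(fx$truth$genes))
  truth <- jsonlite::read_json(paths[["truth_json"]], simplifyVector = TRUE)
  expect_equal(nrow(truth$genes), nrow(fx$truth$genes))
})

test_that("impossible placements raise an error rather than overlapping", {
  spec <- fixture_spec(seed = 720, genome_length = 3000, n_canonical = 2,
                       integrations = list(list(target = 1,
                                                element_length = 5000)))
  expect_error(generate_fixture(spec), "longer than the genome|placed")
})
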