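# Independent brute-force oracles used to cross-check the screens and the
# structure rules. These deliberately use naive loops / all-shift
# comparisons, not the implementations under test.

# maximal shared terminal run of two strings with a mismatch budget,
# computed by a plain character loop (N matches anything)
oracle_terminal_match <- function(a, b, side, max_mm) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  if (side == "3p") {
    ca <- rev(ca)
    cb <- rev(cb)
  }
  n <- min(length(ca), length(cb))
  mm <- 0L
  best_len <- 0L
  best_mm <- 0L
  for (i in seq_len(n)) {
    same <- ca[i] == cb[i] || ca[i] == "N" || cb[i] == "N"
    if (!same) mm <- mm + 1L
    if (mm <= max_mm) {
      best_len <- i
      best_mm <- mm
    }
  }
  list(length = best_len, mismatches = best_mm)
}

# quadratic genome scan for copies of a gene's 3'-terminal segment: for every
# candidate 3'-end position p (and strand), accumulate mismatches outward and
# keep positions whose maximal terminal run passes the thresholds
oracle_denovo_hits <- function(gene_seq, genome_seq, max_mm = 1,
                               min_len = 20, max_len = 100) {
  hits <- list()
  gl <- nchar(gene_seq)
  gchars <- strsplit(gene_seq, "")[[1]]
  scan_one <- function(subject, strand) {
    n <- nchar(subject)
    schars <- strsplit(subject, "")[[1]]
    for (p in seq_len(n)) {
      mm <- 0L
      best <- 0L
      t <- 0L
      while (t < min(max_len, gl, p)) {
        t <- t + 1L
        a <- gchars[gl - t + 1L]
        b <- schars[p - t + 1L]
        if (!(a == b || a == "N" || b == "N")) mm <- mm + 1L
        if (mm > max_mm) break
        best <- t
      }
      if (best >= min_len) {
        span <- if (strand == "+") c(p - best + 1L, p) else
          c(nchar(subject) - p + 1L, nchar(subject) - p + best)
        hits[[length(hits) + 1L]] <<- list(strand = strand,
                                           start = span[1], end = span[2],
                                           length = best)
      }
    }
  }
  scan_one(genome_seq, "+")
  scan_one(revcomp(genome_seq), "-")
  hits
}

# all-shift direct-repeat certificate: for every admissible period d, find
# maximal runs of positionwise equality; chain anchor positions whose
# consecutive gaps stay admissible. Returns per-array anchor positions.
oracle_crispr_chains <- function(seq, period_range = c(40, 110),
                                 min_run = 20, min_repeats = 3) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  anchors <- list()
  for (d in seq(period_range[1], period_range[2])) {
    if (n <= d) next
    eq <- chars[seq_len(n - d)] == chars[(d + 1):n]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (q in which(r$values & r$lengths >= min_run)) {
      anchors[[length(anchors) + 1L]] <- list(start = starts[q], d = d,
                                              len = r$lengths[q])
    }
  }
  if (length(anchors) == 0) return(list())
  # positions participating in repeats
  pos <- sort(unique(unlist(lapply(anchors, function(a) c(a$start, a$start + a$d)))))
  # cluster positions into arrays by admissible consecutive gaps
  cl <- cumsum(c(TRUE, diff(pos) > period_range[2]))
  out <- list()
  for (g in unique(cl)) {
    p <- pos[cl == g]
    if (length(p) >= min_repeats) out[[length(out) + 1L]] <- p
  }
  out
}

# one small planted-event fixture used across screen tests
make_screen_fixture <- function(seed, genome_length = 8000, n_canonical = 6,
                                element_length = 2000, repeat_length = 44,
                                mismatches = 1, n_repeats = 5,
                                crispr = TRUE, invert = FALSE) {
  spec <- fixture_spec(
    seed = seed, genome_length = genome_length, n_canonical = n_canonical,
    integrations = list(list(target = 1, repeat_length = repeat_length,
                             mismatches = mismatches,
                             element_length = element_length,
                             invert = invert)),
    arrays = if (crispr) {
      list(list(n_repeats = n_repeats, repeat_length = 30, spacer_length = 36,
                embed_fragment = TRUE, fragment_target = 2))
    } else {
      list()
    })
  generate_fixture(spec)
}

# independent full-scan T-arm oracle: test every 17-nt window by direct
# definition (loop, no shared code) and return the rightmost admissible one
oracle_t_arm <- function(seq, tolerance = 0) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  pair_ok <- function(x, y) {
    paste0(x, y) %in% c("AT", "TA", "GC", "CG", "GT", "TG") || x == "N" || y == "N"
  }
  best <- NULL
  if (n < 17) return(NULL)
  for (s in 1:(n - 16)) {
    loop <- chars[(s + 5):(s + 11)]
    ok <- (loop[1] %in% c("T", "N")) && (loop[2] %in% c("T", "N")) &&
      (loop[3] %in% c("C", "N")) && (loop[4] %in% c("A", "G", "N")) &&
      (loop[5] %in% c("A", "N"))
    if (!ok) next
    mm <- 0L
    for (k in 0:4) {
      if (!pair_ok(chars[s + k], chars[s + 16 - k])) mm <- mm + 1L
    }
    if (mm <= tolerance) best <- c(s, s + 16L)
  }
  best
}

# compare a detected array against the all-shift certificate: oracle anchor
# positions cluster one group per repeat copy; pairwise equality runs may
# start a few chance-matched bases 5' of the common repeat, so each group's
# rightmost anchor must sit at or a little before the detected repeat start
expect_array_certified <- function(repeat_spans, chain, slack = 25) {
  starts <- sort(repeat_spans[, 1])
  cl <- cumsum(c(TRUE, diff(chain) > 30))
  groups <- tapply(chain, cl, max)
  testthat::expect_equal(length(groups), length(starts))
  delta <- starts - sort(as.integer(groups))
  testthat::expect_true(all(delta >= 0 & delta <= slack))
}
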