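# Low-level nucleotide helpers. Sequences are plain uppercase character
# strings in the DNA alphabet (T, not U); N is the only ambiguity code given
# special meaning (wildcard for motif/pairing tests, tallied for triage).

IUPAC_DNA <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")

#' Reverse complement of a DNA string
#'
#' Plain-string reverse complement over the full IUPAC alphabet.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# uppercase, U -> T, validate alphabet
normalize_seq <- function(x, what = "sequence") {
  x <- chartr("u", "t", x)
  x <- toupper(x)
  x <- chartr("U", "T", x)
  bad <- setdiff(unique(strsplit(paste(x, collapse = ""), "")[[1]]), IUPAC_DNA)
  if (length(bad) > 0) {
    abort(sprintf("invalid %s character(s): %s", what, paste(bad, collapse = ", ")))
  }
  x
}

# Watson-Crick plus G:T wobble; N pairs with anything. Vectorized over
# equal-length character vectors of single bases.
bases_pair <- function(a, b) {
  (a == "N" | b == "N") |
    (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G") |
    (a == "G" & b == "T") | (a == "T" & b == "G")
}

# N matches any base in motif comparisons
bases_match <- function(a, b) a == b | a == "N" | b == "N"

seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

# mismatches between two equal-length strings, N wildcard
count_mismatches <- function(a, b) {
  ca <- seq_chars(a)
  cb <- seq_chars(b)
  stopifnot(length(ca) == length(cb))
  sum(!bases_match(ca, cb))
}

# number of non-pairing positions when s5 (5'->3') is folded against
# s3 (5'->3', so its last base pairs with the first base of s5)
stem_mismatches <- function(chars, start5, start3, len) {
  a <- chars[start5 + seq_len(len) - 1]
  b <- chars[start3 + len - seq_len(len)]
  sum(!bases_pair(a, b))
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

wc_complement <- function(x) chartr("ACGT", "TGCA", x)
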