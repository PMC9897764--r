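# Readers and writers for the formats the curation pipeline touches.
# All internal coordinates are 1-based inclusive (the convention of
# tRNAscan-SE output and genome-browser gene tables); conversion to the
# 0-based half-open BED convention happens only inside write_bed()/read_bed().

ISOTYPES <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
              "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
              "Tyr", "Val", "iMet", "Ile2", "Und", "Sup", "SeC")

#' Normalize a tRNA isotype label
#'
#' Accepts the spellings used by tRNAscan-SE, GtRNAdb gene names and common
#' variants ("MET", "fMet", "undet", "SelCys", ...) and maps them onto a single
#' vocabulary: the 20 amino-acid three-letter codes plus `iMet`, `Ile2`, `Und`,
#' `Sup` and `SeC`. The three CAT-anticodon isotypes (initiator Met, elongator
#' Met, Ile2) are kept distinct.
#'
#' @param x Character vector of isotype labels.
#' @return Character vector over the normalized vocabulary.
#' @export
normalize_isotype <- function(x) {
  key <- tolower(str_trim(x))
  special <- c(imet = "iMet", fmet = "iMet", met_i = "iMet", ile2 = "Ile2",
               und = "Und", undet = "Und", unknown = "Und", sup = "Sup",
               sec = "SeC", selcys = "SeC", selc = "SeC")
  out <- unname(special[key])
  plain <- is.na(out)
  if (any(plain)) {
    cand <- paste0(toupper(substr(key[plain], 1, 1)), substr(key[plain], 2, 3))
    bad <- !cand %in% ISOTYPES
    if (any(bad)) {
      abort(sprintf("unrecognized isotype label(s): %s",
                    paste(unique(x[plain][bad]), collapse = ", ")))
    }
    out[plain] <- cand
  }
  out
}

empty_predictions <- function() {
  tibble(
    genome_id = character(), seq_id = character(), trna_no = integer(),
    gene_name = character(), start = integer(), end = integer(),
    strand = character(), isotype = character(), anticodon = character(),
    length_bp = integer(), general_score = double(), isotype_score = double(),
    hmm_score = double(), ss_score = double(), pseudo_flag = logical(),
    intron_start = integer(), intron_end = integer(), note = character()
  )
}

validate_predictions <- function(preds) {
  stopifnot(is.data.frame(preds))
  if (nrow(preds) == 0) return(preds)
  if (any(preds$start < 1 | preds$end < preds$start)) {
    abort("predictions must satisfy 1 <= start <= end")
  }
  if (any(preds$length_bp != preds$end - preds$start + 1)) {
    abort("length_bp must equal end - start + 1")
  }
  if (any(nchar(preds$anticodon) != 3) ||
      any(!grepl("^[ACGTN]{3}$", preds$anticodon))) {
    abort("anticodon must be exactly 3 characters over {A,C,G,T,N}")
  }
  if (any(!preds$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  preds
}

num_or_na <- function(x) suppressWarnings(as.numeric(x))

#' Parse tRNAscan-SE tabular output
#'
#' Reads the tab-delimited gene table written by tRNAscan-SE (`-o`), with or
#' without the extended score columns added by `-H`/`--detail`. Header lines
#' are tolerated; a begin coordinate greater than the end coordinate encodes
#' the minus strand and is normalized to `start <= end` with an explicit
#' `strand` column. Rows whose note column contains "pseudo" set `pseudo_flag`.
#'
#' Accepted column layouts (tab- or whitespace-separated):
#' \itemize{
#'   \item 9 columns: seq id, tRNA number, begin, end, isotype, anticodon,
#'     intron begin, intron end, general score (isotype score absent; a
#'     warning is raised once per file).
#'   \item 11 columns: the 9 above plus isotype model and isotype score.
#'   \item 13+ columns: the 9 above plus HMM score, secondary-structure score,
#'     isotype model, isotype score, and an optional trailing note.
#' }
#'
#' @param file Path to a tRNAscan-SE output file, or a character vector of its
#'   lines.
#' @param genome_id Genome identifier attached to every record; defaults to
#'   the file name without extension.
#' @return A tibble with one row per predicted gene: coordinates
#'   (1-based inclusive), strand, normalized isotype, anticodon, scores,
#'   pseudogene flag, intron span and note.
#' @export
read_trnascan <- function(file, genome_id = NULL) {
  if (length(file) == 1 && !grepl("\n", file) && file.exists(file)) {
    lines <- readLines(file, warn = FALSE)
    if (is.null(genome_id)) {
      genome_id <- sub("\\.[^.]*$", "", basename(file))
    }
  } else {
    lines <- unlist(strsplit(file, "\n", fixed = TRUE))
    if (is.null(genome_id)) genome_id <- "genome"
  }
  keep <- !grepl("^\\s*$", lines) &
    !grepl("^(Sequence|Name|-+\\s|#)", lines) &
    !grepl("^-+$", str_trim(lines))
  rows <- which(keep)
  if (length(rows) == 0) return(empty_predictions())

  missing_isoscore <- FALSE
  parse_row <- function(i) {
    ln <- lines[i]
    f <- if (grepl("\t", ln)) str_trim(strsplit(ln, "\t")[[1]]) else
      strsplit(str_trim(ln), "\\s+")[[1]]
    f <- f[!is.na(f)]
    if (length(f) < 9) {
      abort(sprintf("line %d: expected >= 9 columns, found %d", i, length(f)))
    }
    begin <- suppressWarnings(as.integer(f[3]))
    end <- suppressWarnings(as.integer(f[4]))
    if (is.na(begin) || is.na(end)) {
      abort(sprintf("line %d: non-numeric begin/end coordinates", i))
    }
    strand <- if (begin > end) "-" else "+"
    se <- sort(c(begin, end))
    hmm <- ss <- iso_score <- NA_real_
    note <- ""
    n <- length(f)
    if (n >= 13) {
      hmm <- num_or_na(f[10]); ss <- num_or_na(f[11]); iso_score <- num_or_na(f[13])
      if (n > 13) note <- paste(f[14:n], collapse = " ")
    } else if (n >= 11) {
      iso_score <- num_or_na(f[11])
      if (n > 11) note <- paste(f[12:n], collapse = " ")
    } else {
      missing_isoscore <<- TRUE
      if (n > 9) note <- paste(f[10:n], collapse = " ")
    }
    ib <- suppressWarnings(as.integer(f[7]))
    ie <- suppressWarnings(as.integer(f[8]))
    if (!is.na(ib) && ib == 0) ib <- NA_integer_
    if (!is.na(ie) && ie == 0) ie <- NA_integer_
    isotype <- normalize_isotype(f[5])
    anticodon <- toupper(f[6])
    if (!grepl("^[ACGTN]{3}$", anticodon)) {
      abort(sprintf("line %d: malformed anticodon '%s'", i, f[6]))
    }
    tibble(
      genome_id = genome_id, seq_id = f[1],
      trna_no = suppressWarnings(as.integer(f[2])),
      gene_name = sprintf("tRNA-%s-%s-%s-1", isotype, anticodon, f[2]),
      start = se[1], end = se[2], strand = strand,
      isotype = isotype, anticodon = anticodon,
      length_bp = se[2] - se[1] + 1L,
      general_score = num_or_na(f[9]), isotype_score = iso_score,
      hmm_score = hmm, ss_score = ss,
      pseudo_flag = grepl("pseudo", note, ignore.case = TRUE),
      intron_start = if (!is.na(ib) && !is.na(ie)) min(ib, ie) else NA_integer_,
      intron_end = if (!is.na(ib) && !is.na(ie)) max(ib, ie) else NA_integer_,
      note = note
    )
  }
  out <- list_rbind(map(rows, parse_row))
  if (missing_isoscore) {
    warn("isotype-score column absent from input; isotype_score set to NA")
  }
  validate_predictions(out)
}

#' Write predictions as a tRNAscan-SE style gene table
#'
#' Serializes a prediction tibble back into the extended (`-H --detail`)
#' tab-delimited layout read by [read_trnascan()]; `write_trnascan()` followed
#' by `read_trnascan()` is lossless for every serialized field.
#'
#' @param predictions Prediction tibble (see [read_trnascan()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trnascan <- function(predictions, path) {
  validate_predictions(predictions)
  fmt_num <- function(x) ifelse(is.na(x), "NA", format(x, trim = TRUE, scientific = FALSE))
  hdr <- c(
    paste("Name", "tRNA#", "Begin", "End", "Type", "Codon", "IntronBegin",
          "IntronEnd", "Score", "HMMSc", "StrSc", "IsoCM", "IsoScore", "Note",
          sep = "\t"),
    paste(rep("--------", 14), collapse = "\t")
  )
  body <- predictions |>
    mutate(
      begin = ifelse(.data$strand == "-", .data$end, .data$start),
      stop = ifelse(.data$strand == "-", .data$start, .data$end),
      ib = ifelse(is.na(.data$intron_start), 0L, .data$intron_start),
      ie = ifelse(is.na(.data$intron_end), 0L, .data$intron_end)
    )
  lines <- sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s\t%s\t%s\t%s\t%s",
                   body$seq_id, body$trna_no, body$begin, body$stop,
                   body$isotype, body$anticodon, body$ib, body$ie,
                   fmt_num(body$general_score), fmt_num(body$hmm_score),
                   fmt_num(body$ss_score), body$isotype,
                   fmt_num(body$isotype_score), body$note)
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Load a genome FASTA
#'
#' Reads a (multi-)FASTA of chromosome/plasmid contigs, normalizes sequences
#' to uppercase DNA (U is converted to T; IUPAC ambiguity codes, including N,
#' are kept) and names each contig by the first whitespace-delimited token of
#' its header.
#'
#' @param path FASTA file path.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_genome <- function(path) {
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0) abort(sprintf("no sequences found in '%s'", path))
  ids <- vapply(strsplit(names(raw), "\\s+"), `[`, character(1), 1)
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate contig id(s): %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  seqs <- normalize_seq(as.character(raw), what = "FASTA")
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Extract the oriented sequence of a genomic span
#'
#' @param genome A named [Biostrings::DNAStringSet] (see [read_genome()]).
#' @param seq_id Contig identifier.
#' @param start,end 1-based inclusive coordinates.
#' @param strand `"+"` or `"-"`; minus-strand spans are reverse-complemented.
#' @return The spanned sequence as an uppercase character string.
#' @export
extract_span <- function(genome, seq_id, start, end, strand = "+") {
  if (!seq_id %in% names(genome)) {
    abort(sprintf("contig '%s' not present in genome", seq_id))
  }
  len <- length(genome[[seq_id]])
  if (start < 1 || end > len || start > end) {
    abort(sprintf("span %d-%d outside contig '%s' (length %d)", start, end, seq_id, len))
  }
  s <- as.character(Biostrings::subseq(genome[[seq_id]], start, end))
  if (strand == "-") revcomp(s) else s
}

# oriented gene sequences for a prediction table (introns spliced out)
prediction_sequences <- function(predictions, genome) {
  pmap(list(predictions$seq_id, predictions$start, predictions$end,
            predictions$strand, predictions$intron_start, predictions$intron_end),
       function(sid, s, e, str, is_, ie_) {
         x <- extract_span(genome, sid, s, e, str)
         if (!is.na(is_) && !is.na(ie_)) {
           # intron coords are genomic; map into the oriented gene sequence
           if (str == "+") {
             a <- is_ - s + 1; b <- ie_ - s + 1
           } else {
             a <- e - ie_ + 1; b <- e - is_ + 1
           }
           if (a >= 1 && b <= nchar(x) && a <= b) {
             x <- paste0(substr(x, 1, a - 1), substr(x, b + 1, nchar(x)))
           }
         }
         x
       }) |> unlist()
}

#' Read a standard tRNA gene set definition
#'
#' A standard set is the minimal domain-typical complement of tRNA types: a
#' TSV with columns `isotype`, `anticodon` and `expected_copies`. `#` comment
#' lines are ignored.
#'
#' @param path TSV file path.
#' @return A tibble with one row per tRNA type.
#' @export
read_standard_set <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("isotype", "anticodon", "expected_copies")
  if (!all(need %in% names(df))) {
    abort(sprintf("standard set must have columns: %s", paste(need, collapse = ", ")))
  }
  df$isotype <- normalize_isotype(df$isotype)
  df$anticodon <- toupper(df$anticodon)
  if (any(!grepl("^[ACGTN]{3}$", df$anticodon))) {
    abort("standard set anticodons must be 3 characters over {A,C,G,T,N}")
  }
  if (anyDuplicated(df[c("isotype", "anticodon")])) {
    abort("duplicate (isotype, anticodon) entries in standard set")
  }
  if (any(df$expected_copies < 1 | df$expected_copies != round(df$expected_copies))) {
    abort("expected_copies must be positive integers")
  }
  as_tibble(df[need]) |> mutate(expected_copies = as.integer(.data$expected_copies))
}

#' The standard archaeal tRNA gene set (46 single-copy types)
#'
#' Loads the packaged archaeal standard set: 46 tRNA types, each expected as a
#' single-copy gene, with initiator Met, elongator Met and Ile2 (all with CAT
#' anticodons) as distinct types. The set ships as an editable TSV under
#' `inst/extdata/archaea46.tsv`.
#'
#' @return A 46-row standard-set tibble (see [read_standard_set()]).
#' @export
standard_archaea46 <- function() {
  read_standard_set(system.file("extdata", "archaea46.tsv",
                                package = "trnacurate", mustWork = TRUE))
}

#' Convert between 1-based inclusive and BED half-open coordinates
#'
#' @param start,end 1-based inclusive span.
#' @param chrom_start,chrom_end 0-based half-open span.
#' @return A two-column tibble in the other convention.
#' @export
coords_to_bed <- function(start, end) tibble(chrom_start = start - 1L, chrom_end = end)

#' @rdname coords_to_bed
#' @export
coords_from_bed <- function(chrom_start, chrom_end) {
  tibble(start = chrom_start + 1L, end = chrom_end)
}

#' Write curation calls (or predictions) as BED6
#'
#' Output is 0-based half-open. The name field is `gene_name|category` when a
#' category column is present, else the bare gene name; the score field is the
#' isotype score rounded and clamped to `[0, 1000]`.
#'
#' @param calls Tibble with `seq_id`, `start`, `end`, `strand`, `gene_name`
#'   and optionally `category` and `isotype_score` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(calls, path) {
  if (nrow(calls) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  name <- if ("category" %in% names(calls)) {
    paste(calls$gene_name, calls$category, sep = "|")
  } else {
    calls$gene_name
  }
  score <- if ("isotype_score" %in% names(calls)) {
    pmin(1000L, pmax(0L, as.integer(round(replace_na(calls$isotype_score, 0)))))
  } else {
    rep(0L, nrow(calls))
  }
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s", calls$seq_id, calls$start - 1L,
                   calls$end, name, score, calls$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED interval track
#'
#' Converts BED's 0-based half-open spans to the package's 1-based inclusive
#' convention. Used e.g. for user-supplied tmRNA gene tracks or externally
#' detected CRISPR arrays.
#'
#' @param path BED file path (3+ columns).
#' @return Tibble with `seq_id`, `start`, `end`, `name`, `strand`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(str_trim(lines))]
  if (length(lines) == 0) {
    return(tibble(seq_id = character(), start = integer(), end = integer(),
                  name = character(), strand = character()))
  }
  f <- str_split(lines, "\t")
  tibble(
    seq_id = map_chr(f, 1),
    start = as.integer(map_chr(f, 2)) + 1L,
    end = as.integer(map_chr(f, 3)),
    name = map_chr(f, ~ if (length(.x) >= 4) .x[4] else NA_character_),
    strand = map_chr(f, ~ if (length(.x) >= 6) .x[6] else "+")
  )
}

#' Write curation calls as GFF3
#'
#' One `tRNA` feature per call, with attributes carrying the isotype,
#' anticodon, triage band, category and evidence summary.
#'
#' @inheritParams write_bed
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(calls, path) {
  out <- "##gff-version 3"
  if (nrow(calls) > 0) {
    attr_of <- function(i) {
      kv <- c(ID = calls$gene_name[i],
              isotype = calls$isotype[i],
              anticodon = calls$anticodon[i],
              category = if ("category" %in% names(calls)) calls$category[i] else NULL,
              band = if ("band" %in% names(calls)) calls$band[i] else NULL,
              evidence = if ("evidence_kinds" %in% names(calls) &&
                             !is.na(calls$evidence_kinds[i]) &&
                             nzchar(calls$evidence_kinds[i])) calls$evidence_kinds[i] else NULL)
      paste(paste0(names(kv), "=", kv), collapse = ";")
    }
    score <- if ("isotype_score" %in% names(calls)) {
      ifelse(is.na(calls$isotype_score), ".", format(calls$isotype_score, trim = TRUE))
    } else {
      rep(".", nrow(calls))
    }
    out <- c(out, sprintf("%s\ttrnacurate\ttRNA\t%d\t%d\t%s\t%s\t.\t%s",
                          calls$seq_id, calls$start, calls$end, score,
                          calls$strand, vapply(seq_len(nrow(calls)), attr_of, character(1))))
  }
  writeLines(out, path)
  invisible(path)
}
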