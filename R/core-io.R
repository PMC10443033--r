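# Domain types, coordinate conventions, and readers/writers shared by all
# pipeline stages. Reads travel as tibbles with columns id / seq / qual, where
# qual is the phred+33-encoded quality string (clamped to <= 40 on input).
# All internal coordinates are 0-based half-open; report files render 1-based.

MAX_QUAL <- 40L
QUAL_OFFSET <- 33L

#' Decode a phred+33 quality string
#'
#' @param qual Character vector of phred+33 quality strings.
#' @return A list of integer vectors of per-base phred scores.
#' @export
phred_decode <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - QUAL_OFFSET)
}

#' Encode integer phred scores as a phred+33 string
#'
#' Scores above 40 are clamped to 40, mirroring the cap applied on input.
#'
#' @param scores Integer vector of phred scores, or a list of such vectors.
#' @return Character vector of quality strings.
#' @export
phred_encode <- function(scores) {
  if (!is.list(scores)) scores <- list(scores)
  vapply(scores, function(s) {
    s <- pmin(pmax(as.integer(s), 0L), MAX_QUAL)
    intToUtf8(s + QUAL_OFFSET)
  }, character(1))
}

# Clamp a phred+33 quality string at phred 40 ('I'); chars above 'I' map to 'I'.
clamp_qual <- function(qual) {
  hi <- rawToChar(as.raw(74:126))
  chartr(hi, strrep("I", nchar(hi)), qual)
}

#' Construct a read tibble
#'
#' @param id,seq,qual Parallel character vectors: read identifier, nucleotide
#'   sequence over A/C/G/T/N, and phred+33 quality string of matching length.
#' @return A tibble with columns `id`, `seq`, `qual`.
#' @export
read_set <- function(id, seq, qual) {
  stopifnot(length(id) == length(seq), length(seq) == length(qual))
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad) > 0) {
    stop("seq/qual length mismatch for read(s): ",
         paste(head(id[bad], 5), collapse = ", "), call. = FALSE)
  }
  tibble::tibble(id = unname(as.character(id)),
                 seq = unname(toupper(seq)),
                 qual = unname(clamp_qual(qual)))
}

#' Read a FASTQ file
#'
#' Qualities are interpreted as phred+33 and clamped to a maximum score of 40.
#'
#' @param path Path to a 4-line-per-record FASTQ file.
#' @return A read tibble (`id`, `seq`, `qual`).
#' @export
read_fastq <- function(path) {
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) {
      stop("malformed FASTQ '", path, "': ", conditionMessage(e), call. = FALSE)
    }
  )
  qual <- as.character(S4Vectors::mcols(x)$qualities)
  read_set(names(x), as.character(x), qual)
}

#' Write a FASTQ file
#'
#' @param reads A read tibble as returned by [read_fastq()] or [read_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' Construct an amplicon reference
#'
#' @param name Reference name.
#' @param seq Nucleotide sequence (A/C/G/T only; no ambiguity codes).
#' @param window Integer pair `c(start, end)`, 0-based half-open, marking the
#'   targeted window. Defaults to the full sequence.
#' @return An object of class `amplicon_reference`: a list with fields
#'   `name`, `seq`, `window`.
#' @export
amplicon_reference <- function(name, seq, window = NULL) {
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq)) {
    stop("reference sequence may contain only A/C/G/T", call. = FALSE)
  }
  L <- nchar(seq)
  if (is.null(window)) window <- c(0L, L)
  window <- as.integer(window)
  if (!(window[1] >= 0 && window[1] < window[2] && window[2] <= L)) {
    stop("window must satisfy 0 <= start < end <= length(seq)", call. = FALSE)
  }
  structure(list(name = name, seq = seq, window = window),
            class = "amplicon_reference")
}

#' @export
print.amplicon_reference <- function(x, ...) {
  cat("<amplicon_reference> ", x$name, ": ", nchar(x$seq), " bp, window [",
      x$window[1], ", ", x$window[2], ")\n", sep = "")
  invisible(x)
}

#' Read a single-record FASTA amplicon reference
#'
#' @param path Path to a FASTA file holding exactly one record.
#' @param window Optional targeted window (0-based half-open); defaults to the
#'   full sequence.
#' @return An [amplicon_reference()].
#' @export
read_amplicon_fasta <- function(path, window = NULL) {
  x <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(x) != 1) {
    stop("expected a single-record FASTA (single amplicon), got ",
         length(x), " records", call. = FALSE)
  }
  amplicon_reference(names(x)[1], as.character(x[[1]]), window = window)
}

#' Write the amplicon reference to FASTA
#'
#' @param reference An [amplicon_reference()].
#' @param path Output path.
#' @export
write_amplicon_fasta <- function(reference, path) {
  x <- Biostrings::DNAStringSet(reference$seq)
  names(x) <- reference$name
  Biostrings::writeXStringSet(x, path, format = "fasta")
  invisible(path)
}

#' Read a sample sheet
#'
#' Columns: `sample_id`, `role` (treated/parental), `genotype`, `replicate`,
#' `guides` (semicolon-separated guide names, empty for parental),
#' `fastq_r1`, `fastq_r2`.
#'
#' @param path Path to a tab-separated sample sheet.
#' @return A tibble, validated so that every treated sample has at least one
#'   parental sample of matching genotype.
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_tsv(path, show_col_types = FALSE)
  validate_sample_sheet(sheet)
}

#' Validate a sample-sheet tibble
#'
#' @param sheet Tibble with the sample-sheet columns.
#' @return The validated sheet (invisibly unchanged).
#' @export
validate_sample_sheet <- function(sheet) {
  needed <- c("sample_id", "role", "genotype", "replicate", "guides",
              "fastq_r1", "fastq_r2")
  miss <- setdiff(needed, names(sheet))
  if (length(miss) > 0) {
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!all(sheet$role %in% c("treated", "parental"))) {
    stop("role must be 'treated' or 'parental'", call. = FALSE)
  }
  treated <- sheet[sheet$role == "treated", ]
  parental_geno <- unique(sheet$genotype[sheet$role == "parental"])
  orphan <- setdiff(unique(treated$genotype), parental_geno)
  if (length(orphan) > 0) {
    stop("treated genotype(s) without a parental control: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  sheet
}

#' Read a CFU count table for the reversion assay
#'
#' Columns: `sample_id`, `selective_cfu`, `total_cfu`, and optionally
#' `selective_dilution` / `total_dilution` (fold dilutions of the plated
#' aliquots; both default to 1). Counts are scaled by their dilution factor to
#' a common volume before any frequency is computed.
#'
#' @param path Path to a tab-separated CFU table.
#' @return A validated tibble with dilution columns filled in.
#' @export
read_cfu_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  needed <- c("sample_id", "selective_cfu", "total_cfu")
  miss <- setdiff(needed, names(tbl))
  if (length(miss) > 0) {
    stop("CFU table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"selective_dilution" %in% names(tbl)) tbl$selective_dilution <- 1
  if (!"total_dilution" %in% names(tbl)) tbl$total_dilution <- 1
  if (any(tbl$total_cfu <= 0)) {
    stop("total_cfu must be positive", call. = FALSE)
  }
  if (any(tbl$selective_cfu < 0)) {
    stop("selective_cfu must be nonnegative", call. = FALSE)
  }
  bad <- tbl$selective_cfu * tbl$selective_dilution >
    tbl$total_cfu * tbl$total_dilution
  if (any(bad)) {
    stop("dilution-corrected selective count exceeds total for sample(s): ",
         paste(tbl$sample_id[bad], collapse = ", "), call. = FALSE)
  }
  tbl
}

#' Write a result table as sorted TSV
#'
#' Rows are sorted by the key column(s) so output is deterministic regardless
#' of input order; numeric columns are rendered with 10 significant digits.
#'
#' @param rows A data frame / tibble.
#' @param path Output path.
#' @param key Column name(s) to sort by; defaults to the first column.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path, key = names(rows)[1]) {
  rows <- dplyr::as_tibble(rows)
  if (nrow(rows) > 0 && length(key) > 0) {
    rows <- dplyr::arrange(rows, dplyr::across(dplyr::all_of(key)))
  }
  out <- dplyr::mutate(rows, dplyr::across(
    dplyr::where(is.double), ~ as.numeric(formatC(.x, digits = 10, format = "g"))
  ))
  readr::write_tsv(out, path)
  invisible(path)
}

#' Convert internal 0-based positions to 1-based report positions
#' @param pos0 Integer vector of 0-based positions.
#' @export
to_report_pos <- function(pos0) as.integer(pos0) + 1L

#' Convert 1-based report positions to internal 0-based positions
#' @param pos1 Integer vector of 1-based positions.
#' @export
from_report_pos <- function(pos1) as.integer(pos1) - 1L

#' Reverse-complement nucleotide strings
#'
#' @param x Character vector of sequences over A/C/G/T/N.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
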