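# Align merged reads to the amplicon reference and accumulate a per-position
# allele pileup. Because the reference is a single short amplicon, an exact
# glocal (global in the read, local in the reference) dynamic-programming
# alignment with affine gaps replaces index-based mapping: deterministic, no
# mapper-version variance. Ambiguous equal-scoring alignments resolve to the
# leftmost reference offset with substitutions preferred over indels.

#' Alignment scoring parameters
#'
#' A gap of length g costs `gap_open + g * gap_extend`.
#'
#' @param match,mismatch,gap_open,gap_extend Scores (defaults +1/-4/-6/-1,
#'   common short-read practice).
#' @param min_score_frac Reads scoring below `min_score_frac * match *
#'   read_length` are flagged unaligned and excluded.
#' @return A list of class `align_scoring`.
#' @export
align_scoring <- function(match = 1, mismatch = -4, gap_open = -6,
                          gap_extend = -1, min_score_frac = 0.4) {
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, min_score_frac = min_score_frac),
            class = "align_scoring")
}

#' Align reads to the amplicon reference
#'
#' @param reads Read tibble, or a character vector of sequences.
#' @param reference An [amplicon_reference()].
#' @param scoring An [align_scoring()].
#' @param counts Optional per-read weights (occurrence counts of dereplicated
#'   reads); defaults to 1.
#' @return A tibble: `read_id`, `seq`, `count`, `ref_start` (0-based),
#'   `cigar` (ops `=`/`X`/`I`/`D`), `score`, `aligned`.
#' @export
align_reads <- function(reads, reference, scoring = align_scoring(),
                        counts = NULL) {
  if (is.character(reads)) {
    reads <- tibble::tibble(id = sprintf("read%06d", seq_along(reads)),
                            seq = reads)
  }
  if (is.null(counts)) counts <- rep(1, nrow(reads))
  res <- .align_glocal_cpp(reads$seq, reference$seq,
                           scoring$match, scoring$mismatch,
                           scoring$gap_open, scoring$gap_extend)
  tibble::tibble(
    read_id = reads$id,
    seq = reads$seq,
    count = counts,
    ref_start = res$ref_start,
    cigar = res$cigar,
    score = res$score,
    aligned = res$score >= scoring$min_score_frac * scoring$match *
      nchar(reads$seq)
  )
}

#' Align a single read
#'
#' @param read A one-row read tibble or list with `id` and `seq`.
#' @inheritParams align_reads
#' @return A one-row alignment tibble (see [align_reads()]).
#' @export
align_read <- function(read, reference, scoring = align_scoring()) {
  align_reads(tibble::tibble(id = read$id, seq = read$seq), reference,
              scoring)
}

#' Dereplicate merged reads for weighted alignment
#'
#' @param reads Read tibble of merged reads.
#' @return Tibble `seq`, `count`, sorted by decreasing count then sequence.
#' @export
dereplicate_reads <- function(reads) {
  reads |>
    dplyr::count(.data$seq, name = "count") |>
    dplyr::arrange(dplyr::desc(.data$count), .data$seq)
}

#' Accumulate a per-position allele pileup
#'
#' Counts each aligned read's base (or deletion) at every reference position
#' it covers, weighted by `count`. Insertions are tallied at the reference
#' position following their anchor and are excluded from depth; N bases are
#' tallied but excluded from depth. Depth is capped at `max_depth` in input
#' order.
#'
#' @param alignments Alignment tibble from [align_reads()]; unaligned rows
#'   are dropped.
#' @param reference An [amplicon_reference()].
#' @param max_depth Per-position depth cap (default 600000).
#' @param sample_id Optional sample label attached to the table.
#' @return A tibble: `position` (0-based), `ref`, `A`, `C`, `G`, `T`, `del`,
#'   `ins`, `N`, `depth`.
#' @export
pileup <- function(alignments, reference, max_depth = 600000,
                   sample_id = NA_character_) {
  al <- alignments[alignments$aligned, , drop = FALSE]
  L <- nchar(reference$seq)
  M <- .pileup_cpp(L, as.integer(al$ref_start), al$cigar, al$seq,
                   as.numeric(al$count), as.numeric(max_depth))
  colnames(M) <- c("A", "C", "G", "T", "del", "ins", "N")
  out <- tibble::as_tibble(M)
  out$position <- 0:(L - 1L)
  out$ref <- strsplit(reference$seq, "")[[1]]
  out$depth <- out$A + out$C + out$G + out$T + out$del
  out$sample_id <- sample_id
  dplyr::select(out, "sample_id", "position", "ref", "A", "C", "G", "T",
                "del", "ins", "N", "depth")
}

#' Merge, dereplicate, align and pile up one sample
#'
#' @param merged Read tibble of merged reads.
#' @inheritParams pileup
#' @param scoring An [align_scoring()].
#' @return A list: `alignments` (weighted unique-read alignments), `pileup`.
#' @export
pile_sample <- function(merged, reference, scoring = align_scoring(),
                        max_depth = 600000, sample_id = NA_character_) {
  uniq <- dereplicate_reads(merged)
  al <- align_reads(tibble::tibble(id = sprintf("u%06d", seq_len(nrow(uniq))),
                                   seq = uniq$seq),
                    reference, scoring, counts = uniq$count)
  list(alignments = al,
       pileup = pileup(al, reference, max_depth = max_depth,
                       sample_id = sample_id))
}

# parse a cigar string into a two-column matrix of (length, op)
cigar_runs <- function(cigar) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[=XID]", cigar))[[1]]
  list(len = lens, op = ops)
}

#' Emit alignments as minimal SAM text
#'
#' Convenience output for inspection in standard tools; not used by the
#' pipeline itself.
#'
#' @param alignments Alignment tibble from [align_reads()].
#' @param reference An [amplicon_reference()].
#' @param path Output path.
#' @export
write_sam <- function(alignments, reference, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               paste0("@SQ\tSN:", reference$name, "\tLN:",
                      nchar(reference$seq))), con)
  al <- alignments[alignments$aligned, , drop = FALSE]
  if (nrow(al) > 0) {
    cig <- vapply(al$cigar, function(cg) {
      runs <- cigar_runs(cg)
      op <- ifelse(runs$op %in% c("=", "X"), "M", runs$op)
      len <- runs$len
      grp <- cumsum(c(TRUE, op[-1] != op[-length(op)]))
      paste0(tapply(len, grp, sum), op[!duplicated(grp)], collapse = "")
    }, character(1), USE.NAMES = FALSE)
    writeLines(sprintf("%s\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
                       al$read_id, reference$name, al$ref_start + 1L,
                       cig, al$seq), con)
  }
  invisible(path)
}
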