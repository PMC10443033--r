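# Merge perfectly overlapping complementary paired-end reads into single
# full-length amplicon reads. All relative offsets reaching min_overlap are
# scanned exhaustively; with max_mismatch = 0 (the default) an offset is
# valid only when every overlapping base pair matches exactly (N matches
# nothing). The largest valid overlap wins; an exact tie at the maximal
# overlap is rejected as ambiguous; reads too short to ever reach
# min_overlap are rejected as too_short. Overlap qualities take the max of
# the two scores, capped at 40.

#' Merge one read pair
#'
#' @param r1,r2 Single reads: one-row read tibbles or lists with `id`, `seq`,
#'   `qual`.
#' @param min_overlap Minimum acceptable overlap length (bp).
#' @param max_mismatch Mismatches tolerated in the overlap (default 0).
#' @param max_qual Quality cap for merged bases (default 40).
#' @return A list: `status` (`"merged"`/`"rejected"`), `merged` (one-row read
#'   tibble or `NULL`), `overlap_len`, `reject_reason` (`NA`,
#'   `"no_perfect_overlap"`, `"too_short"`, or `"ambiguous"`).
#' @export
merge_pair <- function(r1, r2, min_overlap = 20L, max_mismatch = 0L,
                       max_qual = 40L) {
  res <- .merge_pairs_cpp(r1$seq, r1$qual, r2$seq, r2$qual,
                          as.integer(min_overlap), as.integer(max_mismatch),
                          as.integer(max_qual))
  reason <- c(NA, "no_perfect_overlap", "too_short", "ambiguous")[res$status + 1L]
  if (res$status == 0L) {
    list(status = "merged",
         merged = read_set(r1$id, res$seq, res$qual),
         overlap_len = res$overlap_len, reject_reason = NA_character_)
  } else {
    list(status = "rejected", merged = NULL, overlap_len = res$overlap_len,
         reject_reason = reason)
  }
}

#' Merge paired read tibbles in memory
#'
#' Pairs are dereplicated on (seq, qual) before the offset scan so deeply
#' sequenced amplicons merge in time proportional to the number of distinct
#' pairs, then results are expanded back in input order.
#'
#' @param r1,r2 Read tibbles of equal length, pair-synchronized.
#' @inheritParams merge_pair
#' @return A list: `merged` (read tibble of merged reads, input order),
#'   `stats` (tibble with counts: total, merged, and each reject reason).
#' @export
merge_reads <- function(r1, r2, min_overlap = 20L, max_mismatch = 0L,
                        max_qual = 40L) {
  if (nrow(r1) != nrow(r2)) {
    stop("R1/R2 are desynchronized: ", nrow(r1), " vs ", nrow(r2), " reads",
         call. = FALSE)
  }
  if (nrow(r1) == 0) {
    return(list(merged = read_set(character(0), character(0), character(0)),
                stats = merge_stats(integer(0))))
  }
  id1 <- sub("/[12]$", "", r1$id)
  id2 <- sub("/[12]$", "", r2$id)
  if (!identical(id1, id2)) {
    bad <- which(id1 != id2)[1]
    stop("R1/R2 are desynchronized at record ", bad, ": '", id1[bad],
         "' vs '", id2[bad], "'", call. = FALSE)
  }
  key <- paste(r1$seq, r1$qual, r2$seq, r2$qual, sep = "\r")
  uk <- !duplicated(key)
  map <- match(key, key[uk])
  res <- .merge_pairs_cpp(r1$seq[uk], r1$qual[uk], r2$seq[uk], r2$qual[uk],
                          as.integer(min_overlap), as.integer(max_mismatch),
                          as.integer(max_qual))
  status <- res$status[map]
  ok <- status == 0L
  merged <- read_set(r1$id[ok], res$seq[map][ok], res$qual[map][ok])
  list(merged = merged, stats = merge_stats(status),
       overlap_len = res$overlap_len[map])
}

merge_stats <- function(status) {
  tibble::tibble(
    total = length(status),
    merged = sum(status == 0L),
    no_perfect_overlap = sum(status == 1L),
    too_short = sum(status == 2L),
    ambiguous = sum(status == 3L)
  )
}

#' Merge paired FASTQ files
#'
#' @param fastq_r1,fastq_r2 Paths to the paired FASTQ files.
#' @param out Optional output path for the merged FASTQ.
#' @inheritParams merge_pair
#' @return As [merge_reads()]; when `out` is given the merged reads are also
#'   written there.
#' @export
merge_files <- function(fastq_r1, fastq_r2, out = NULL, min_overlap = 20L,
                        max_mismatch = 0L, max_qual = 40L) {
  r1 <- read_fastq(fastq_r1)
  r2 <- read_fastq(fastq_r2)
  res <- merge_reads(r1, r2, min_overlap = min_overlap,
                     max_mismatch = max_mismatch, max_qual = max_qual)
  if (!is.null(out)) write_fastq(res$merged, out)
  res
}
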