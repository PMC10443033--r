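# Read-level diversity analysis: window projection, unique-read tallies,
# indel removal via the Hamming-vs-edit-distance discrepancy, occurrence and
# parental filters, depth normalization, Hamming spectra, and
# transition/transversion substitution spectra.

#' Project aligned reads onto the targeted window
#'
#' Each read's aligned bases are projected onto reference window coordinates
#' through its cigar: matched/mismatched bases inside the window are kept,
#' deletions shorten the windowed string, insertions anchored strictly inside
#' the window lengthen it. Reads whose alignment does not fully span the
#' window are dropped and counted.
#'
#' @param alignments Alignment tibble from [align_reads()] (weighted unique
#'   reads); unaligned rows are dropped.
#' @param window 0-based half-open interval `c(start, end)` on the reference.
#' @return A list: `table` (tibble `seq`, `count` of windowed read strings,
#'   aggregated) and `dropped` (tibble of counted drop reasons).
#' @export
trim_to_window <- function(alignments, window) {
  ws <- window[1]; we <- window[2]
  al <- alignments[alignments$aligned, , drop = FALSE]
  n_unaligned <- sum(!alignments$aligned)
  out_seq <- character(nrow(al))
  spans <- logical(nrow(al))
  for (i in seq_len(nrow(al))) {
    runs <- cigar_runs(al$cigar[i])
    p <- al$ref_start[i]  # reference cursor
    q <- 0L               # read cursor (0-based)
    chars <- character(0)
    for (k in seq_along(runs$op)) {
      len <- runs$len[k]; op <- runs$op[k]
      if (op == "=" || op == "X") {
        lo <- max(p, ws); hi <- min(p + len, we)
        if (hi > lo) {
          chars <- c(chars, substr(al$seq[i], q + (lo - p) + 1L,
                                   q + (hi - p)))
        }
        p <- p + len; q <- q + len
      } else if (op == "D") {
        p <- p + len
      } else if (op == "I") {
        if (p > ws && p < we) {
          chars <- c(chars, substr(al$seq[i], q + 1L, q + len))
        }
        q <- q + len
      }
    }
    ref_end <- p
    spans[i] <- al$ref_start[i] <= ws && ref_end >= we
    out_seq[i] <- paste(chars, collapse = "")
  }
  kept <- tibble::tibble(seq = out_seq[spans], count = al$count[spans]) |>
    dplyr::group_by(.data$seq) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$count), .data$seq)
  dropped <- tibble::tibble(
    reason = c("unaligned", "not_spanning"),
    n = c(n_unaligned, sum(al$count[!spans]))
  )
  list(table = kept, dropped = dropped)
}

#' Hamming distance between two strings
#'
#' Position-wise mismatch count; `NA` when the lengths differ (the distance
#' is undefined for unequal lengths).
#'
#' @param a,b Character scalars or vectors (recycled).
#' @return Integer vector; `NA_integer_` for unequal-length pairs.
#' @export
hamming_distance <- function(a, b) {
  mapply(function(x, y) {
    if (nchar(x) != nchar(y)) return(NA_integer_)
    sum(charToRaw(x) != charToRaw(y))
  }, a, b, USE.NAMES = FALSE)
}

#' Levenshtein edit distance between two strings
#'
#' Unit-cost substitution, insertion, deletion.
#'
#' @param a,b Character scalars or vectors (recycled).
#' @return Integer vector.
#' @export
edit_distance <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  vapply(seq_len(n), function(i) as.integer(adist(a[i], b[i])),
         integer(1))
}

#' Compute distances and flag indel-bearing reads
#'
#' A read contains indels when its length differs from the reference window
#' or when its edit distance is smaller than its Hamming distance
#' (compensating insertion/deletion pairs).
#'
#' @param table Unique-read tibble (`seq`, `count`) from [trim_to_window()].
#' @param reference_window Reference window string.
#' @return The table with `hamming`, `edit`, `has_indel` columns.
#' @export
flag_indels <- function(table, reference_window) {
  table$hamming <- hamming_distance(table$seq, reference_window)
  table$edit <- edit_distance(table$seq, reference_window)
  table$has_indel <- is.na(table$hamming) | table$edit < table$hamming
  table
}

#' Drop unique reads below an occurrence threshold
#'
#' @param table Unique-read tibble with a `count` column.
#' @param min_count Minimum occurrence (default 5); rows with
#'   `count < min_count` are dropped.
#' @return The filtered table.
#' @export
filter_occurrence <- function(table, min_count = 5L) {
  table[table$count >= min_count, , drop = FALSE]
}

#' Remove reads present in the parental strain
#'
#' Any unique read string occurring at least `min_count` times in the
#' parental table (raw counts) is removed from the treated table; this
#' removes the reference-identical read and any standing parental variants.
#'
#' @param table Treated unique-read tibble.
#' @param parental_table Parental unique-read tibble of matching genotype.
#' @param min_count Parental occurrence threshold (default 5).
#' @return The filtered treated table.
#' @export
subtract_parental_reads <- function(table, parental_table, min_count = 5L) {
  parental_seqs <- parental_table$seq[parental_table$count >= min_count]
  table[!(table$seq %in% parental_seqs), , drop = FALSE]
}

#' List substitutions carried by indel-free unique reads
#'
#' Position-wise comparison to the reference window (valid because
#' indel-bearing reads have been removed).
#'
#' @param table Unique-read tibble with `has_indel` set.
#' @param reference_window Reference window string.
#' @param window_start 0-based reference coordinate of the window start
#'   (positions in the result are reference coordinates).
#' @return A tibble: `seq`, `count`, `position`, `ref`, `alt` (one row per
#'   substitution per unique read).
#' @export
read_substitutions <- function(table, reference_window, window_start = 0L) {
  tbl <- table[!table$has_indel, , drop = FALSE]
  ref_chars <- strsplit(reference_window, "")[[1]]
  out <- lapply(seq_len(nrow(tbl)), function(i) {
    chars <- strsplit(tbl$seq[i], "")[[1]]
    at <- which(chars != ref_chars & chars != "N")
    if (length(at) == 0) return(NULL)
    tibble::tibble(seq = tbl$seq[i], count = tbl$count[i],
                   position = window_start + at - 1L,
                   ref = ref_chars[at], alt = chars[at])
  })
  dplyr::bind_rows(out)
}

#' The 12 ordered substitution categories
#'
#' @return A tibble `ref`, `alt`, `class` (`transition`/`transversion`) in
#'   fixed display order.
#' @export
substitution_types <- function() {
  b <- c("A", "C", "G", "T")
  grid <- expand.grid(alt = b, ref = b, stringsAsFactors = FALSE)
  grid <- grid[grid$ref != grid$alt, c("ref", "alt")]
  transitions <- c("A>G", "G>A", "C>T", "T>C")
  tibble::tibble(
    ref = grid$ref, alt = grid$alt,
    class = ifelse(paste0(grid$ref, ">", grid$alt) %in% transitions,
                   "transition", "transversion")
  )
}

#' Depth-normalized Hamming and substitution spectra
#'
#' Normalizes unique-read counts by the sample mean read depth, aggregates
#' normalized abundance per Hamming distance, classifies substitutions of
#' indel-free reads into the 12 ordered categories weighted by read count,
#' and reports summary statistics: the fraction of reads carrying at least
#' one substitution and the count-weighted mean Hamming distance.
#'
#' @param table Unique-read tibble with `hamming` and `has_indel` columns
#'   (post-filter).
#' @param mean_depth Sample mean read depth over the retained window.
#' @param reference_window Reference window string.
#' @param window_start 0-based coordinate of the window start.
#' @return A list: `hamming_spectrum` (tibble `hamming`,
#'   `normalized_abundance`), `substitution_spectrum` (tibble `ref`, `alt`,
#'   `class`, `count`), `summary` (tibble `fraction_mutated` = summed count
#'   of mutated kept reads over `mean_depth`, `mean_hamming` (count-weighted,
#'   over kept reads), `total_reads`).
#' @export
normalize_and_spectrum <- function(table, mean_depth, reference_window,
                                   window_start = 0L) {
  stopifnot(mean_depth > 0)
  tbl <- table[!table$has_indel, , drop = FALSE]
  tbl$normalized_abundance <- tbl$count / mean_depth
  hspec <- tbl |>
    dplyr::filter(.data$hamming > 0) |>
    dplyr::group_by(hamming = .data$hamming) |>
    dplyr::summarise(normalized_abundance = sum(.data$normalized_abundance),
                     .groups = "drop") |>
    dplyr::arrange(.data$hamming)
  subs <- read_substitutions(tbl, reference_window, window_start)
  sspec <- substitution_types()
  if (nrow(subs) > 0) {
    agg <- subs |>
      dplyr::group_by(.data$ref, .data$alt) |>
      dplyr::summarise(count = sum(.data$count), .groups = "drop")
    sspec <- dplyr::left_join(sspec, agg, by = c("ref", "alt"))
    sspec$count[is.na(sspec$count)] <- 0
  } else {
    sspec$count <- 0
  }
  total <- sum(tbl$count)
  mutated <- sum(tbl$count[tbl$hamming > 0])
  summary <- tibble::tibble(
    fraction_mutated = mutated / mean_depth,
    mean_hamming = if (total > 0) sum(tbl$count * tbl$hamming) / total else 0,
    total_reads = total
  )
  list(hamming_spectrum = hspec, substitution_spectrum = sspec,
       summary = summary)
}

#' Full read-level analysis for one treated sample
#'
#' Window projection, indel flagging/removal, occurrence filter, parental
#' read subtraction, and spectra. The fraction of mutated reads is reported
#' both before the occurrence/parental filters (`fraction_mutated_all`,
#' total mutational load among indel-free reads) and after them
#' (`fraction_mutated`, the filtered unique-read surface).
#'
#' @param sample_alignments Weighted unique-read alignment tibble of the
#'   treated sample.
#' @param parental_alignments Same for the parental control.
#' @param reference An [amplicon_reference()].
#' @param window 0-based half-open window; defaults to the reference's
#'   targeted window.
#' @param min_count Occurrence threshold (default 5) for both the treated
#'   table and the parental subtraction.
#' @param mean_depth Sample mean read depth used for normalization; defaults
#'   to the total spanning read count (every merged read spans the window
#'   when pairs fully overlap).
#' @return A list: `table` (filtered unique-read table with distances and
#'   normalized abundance), `spectra` (see [normalize_and_spectrum()]),
#'   `summary` (one-row tibble incl. `fraction_mutated_all`), `dropped`.
#' @export
read_level_analysis <- function(sample_alignments, parental_alignments,
                                reference, window = NULL, min_count = 5L,
                                mean_depth = NULL) {
  if (is.null(window)) window <- reference$window
  refwin <- substr(reference$seq, window[1] + 1L, window[2])
  tw <- trim_to_window(sample_alignments, window)
  pw <- trim_to_window(parental_alignments, window)
  tbl <- flag_indels(tw$table, refwin)
  ptbl <- flag_indels(pw$table, refwin)
  if (is.null(mean_depth)) mean_depth <- sum(tw$table$count)

  indel_free <- tbl[!tbl$has_indel, , drop = FALSE]
  total_all <- sum(indel_free$count)
  frac_all <- if (total_all > 0)
    sum(indel_free$count[indel_free$hamming > 0]) / total_all else 0

  filtered <- tbl |>
    filter_occurrence(min_count) |>
    subtract_parental_reads(ptbl, min_count)
  spectra <- normalize_and_spectrum(filtered, mean_depth, refwin,
                                    window_start = window[1])
  filtered$normalized_abundance <- filtered$count / mean_depth
  summary <- dplyr::mutate(spectra$summary,
                           fraction_mutated_all = frac_all,
                           mean_depth = mean_depth)
  list(table = filtered, spectra = spectra, summary = summary,
       dropped = tw$dropped)
}
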