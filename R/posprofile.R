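# Per-position mutation-frequency profiles: depth filtering, end trimming,
# nonreference proportions, parental background subtraction, flooring.

#' Filter samples (or positions) on sequencing depth
#'
#' A sample is discarded when its median depth over the retained window is
#' below `min_depth` (mode "sample", the default); mode "region" instead
#' masks individual positions below the threshold.
#'
#' @param pileups Named list of pileup tibbles ([pileup()]), one per sample.
#' @param min_depth Depth threshold (default 40000).
#' @param window Optional 0-based half-open interval over which the median is
#'   taken; defaults to all positions.
#' @param mode `"sample"` or `"region"`.
#' @return A list: `retained` (filtered pileup list; in mode "region" each
#'   pileup gains a logical `depth_ok` column), `discarded` (sample names),
#'   `log` (tibble sample_id, median_depth, retained).
#' @export
depth_filter <- function(pileups, min_depth = 40000, window = NULL,
                         mode = c("sample", "region")) {
  mode <- match.arg(mode)
  stopifnot(is.list(pileups), length(pileups) > 0)
  meds <- vapply(pileups, function(p) {
    d <- if (is.null(window)) p$depth else
      p$depth[p$position >= window[1] & p$position < window[2]]
    median(d)
  }, numeric(1))
  keep <- meds >= min_depth
  log <- tibble::tibble(sample_id = names(pileups),
                        median_depth = unname(meds),
                        retained = unname(keep))
  if (mode == "region") {
    pileups <- lapply(pileups, function(p) {
      p$depth_ok <- p$depth >= min_depth
      p
    })
    return(list(retained = pileups, discarded = character(0), log = log))
  }
  if (!any(keep)) {
    stop("all samples fall below min_depth = ", min_depth,
         " (median depths: ", paste(round(meds), collapse = ", "), ")",
         call. = FALSE)
  }
  list(retained = pileups[keep], discarded = names(pileups)[!keep], log = log)
}

#' Compute raw per-position mutation frequencies from a pileup
#'
#' The mutation frequency at a position is the fraction of nonreference
#' reads: `(depth - reference-base count) / depth`. Deletions count as
#' nonreference; insertions and N bases do not.
#'
#' @param pileup A pileup tibble.
#' @return A tibble: `sample_id`, `position`, `ref`, `depth`, `raw`.
#'   Zero-depth positions are dropped with a warning.
#' @export
mutation_frequency <- function(pileup) {
  zero <- pileup$depth == 0
  if (any(zero)) {
    warning(sum(zero), " zero-depth position(s) dropped", call. = FALSE)
    pileup <- pileup[!zero, , drop = FALSE]
  }
  refcount <- as.matrix(pileup[, c("A", "C", "G", "T")])[
    cbind(seq_len(nrow(pileup)), match(pileup$ref, c("A", "C", "G", "T")))]
  tibble::tibble(sample_id = pileup$sample_id, position = pileup$position,
                 ref = pileup$ref, depth = pileup$depth,
                 raw = (pileup$depth - refcount) / pileup$depth)
}

#' Mark end regions as not retained
#'
#' End regions are excluded because of reduced base-call quality near read
#' termini.
#'
#' @param profile A profile tibble with a `position` column.
#' @param left_trim,right_trim Number of positions masked at each end.
#' @param length Total region length; defaults to `max(position) + 1`.
#' @return The profile with a logical `retained` column (existing `retained`
#'   is AND-ed).
#' @export
trim_ends <- function(profile, left_trim = 10L, right_trim = 10L,
                      length = NULL) {
  if (is.null(length)) length <- max(profile$position) + 1L
  if (left_trim + right_trim >= length) {
    stop("left_trim + right_trim (", left_trim + right_trim,
         ") must be smaller than the region length (", length, ")",
         call. = FALSE)
  }
  keep <- profile$position >= left_trim & profile$position < length - right_trim
  profile$retained <- if ("retained" %in% names(profile))
    profile$retained & keep else keep
  profile
}

#' Subtract parental background and floor low values
#'
#' The adjusted frequency is the raw frequency minus the aggregated parental
#' frequency at the same position (mean over parental replicates by default),
#' clipped at zero; adjusted values below `floor` are set to zero.
#'
#' @param sample_profile Profile tibble from [mutation_frequency()] (with or
#'   without a `retained` column).
#' @param parental_profiles List of parental profile tibbles of the matching
#'   genotype.
#' @param floor Values below this proportion are zeroed (default 1e-4).
#' @param agg `"mean"` or `"median"` across parental replicates.
#' @return The sample profile with `background` and `adjusted` columns.
#' @export
subtract_background <- function(sample_profile, parental_profiles,
                                floor = 1e-4, agg = c("mean", "median")) {
  agg <- match.arg(agg)
  if (length(parental_profiles) == 0) {
    stop("no parental profile available for background subtraction",
         call. = FALSE)
  }
  bg_tbl <- dplyr::bind_rows(parental_profiles) |>
    dplyr::group_by(.data$position) |>
    dplyr::summarise(background = if (agg == "mean") mean(.data$raw) else
      median(.data$raw), .groups = "drop")
  out <- dplyr::left_join(sample_profile, bg_tbl, by = "position")
  out$background[is.na(out$background)] <- 0
  adj <- pmax(out$raw - out$background, 0)
  adj[adj < floor] <- 0
  out$adjusted <- adj
  out
}

#' Per-position profile for one treated sample
#'
#' Convenience wrapper: raw frequencies, end trimming, background
#' subtraction, flooring.
#'
#' @param sample_pileup Pileup tibble of the treated sample.
#' @param parental_pileups List of parental pileup tibbles (matching
#'   genotype).
#' @inheritParams trim_ends
#' @inheritParams subtract_background
#' @return Profile tibble: `sample_id`, `position`, `ref`, `depth`, `raw`,
#'   `background`, `adjusted`, `retained`.
#' @export
position_profile <- function(sample_pileup, parental_pileups,
                             left_trim = 10L, right_trim = 10L,
                             floor = 1e-4, agg = "mean") {
  prof <- mutation_frequency(sample_pileup)
  prof <- trim_ends(prof, left_trim, right_trim,
                    length = max(sample_pileup$position) + 1L)
  parental <- lapply(parental_pileups, mutation_frequency)
  subtract_background(prof, parental, floor = floor, agg = agg)
}
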