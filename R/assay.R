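# Reversion-assay statistics: per-replicate reversion frequency and
# per-group summaries. The phenotypic readout counts colonies regaining
# prototrophy on selective plates; reversion and stop-codon suppression are
# not distinguishable by this assay, so the statistic is reported as the
# observed frequency without mechanistic attribution.

#' Per-sample reversion frequency
#'
#' Frequency = selective CFUs divided by total CFUs, after scaling each count
#' by its plating dilution factor to a common volume.
#'
#' @param cfu A CFU tibble ([read_cfu_table()]): `sample_id`,
#'   `selective_cfu`, `total_cfu`, optional `selective_dilution` /
#'   `total_dilution` (default 1), plus any grouping columns which are
#'   carried through.
#' @return The tibble with a `frequency` column.
#' @export
reversion_frequency <- function(cfu) {
  if (!"selective_dilution" %in% names(cfu)) cfu$selective_dilution <- 1
  if (!"total_dilution" %in% names(cfu)) cfu$total_dilution <- 1
  if (any(cfu$total_cfu <= 0)) {
    stop("total_cfu must be positive to define a frequency", call. = FALSE)
  }
  cfu$frequency <- (cfu$selective_cfu * cfu$selective_dilution) /
    (cfu$total_cfu * cfu$total_dilution)
  cfu
}

#' Summarize reversion frequencies per group
#'
#' Reports the median frequency across biological replicates per group (the
#' bar statistic of the assay), plus min, max and n; optionally the
#' fold-change of each group's median over an off-target control group's
#' median.
#'
#' @param results Tibble from [reversion_frequency()].
#' @param group_by Character vector of grouping columns (e.g. `"guides"`,
#'   `"genotype"`).
#' @param control Optional named list identifying the control group, e.g.
#'   `list(guides = "off_target")`; when given, a `fold_change` column is
#'   added.
#' @param boot_ci Number of bootstrap resamples for an optional percentile CI
#'   on the median (0 = none).
#' @param conf Confidence level for the bootstrap CI.
#' @return A tibble with one row per group: `median`, `min`, `max`, `n`, and
#'   optionally `fold_change`, `ci_lo`, `ci_hi`.
#' @export
summarize_groups <- function(results, group_by, control = NULL,
                             boot_ci = 0L, conf = 0.95) {
  out <- results |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_by))) |>
    dplyr::summarise(median = median(.data$frequency),
                     min = min(.data$frequency),
                     max = max(.data$frequency),
                     n = dplyr::n(), .groups = "drop")
  if (boot_ci > 0) {
    ci <- results |>
      dplyr::group_by(dplyr::across(dplyr::all_of(group_by))) |>
      dplyr::summarise(ci = list({
        meds <- replicate(boot_ci, median(sample(.data$frequency,
                                                 replace = TRUE)))
        stats::quantile(meds, c((1 - conf) / 2, 1 - (1 - conf) / 2))
      }), .groups = "drop")
    out$ci_lo <- vapply(ci$ci, `[`, numeric(1), 1)
    out$ci_hi <- vapply(ci$ci, `[`, numeric(1), 2)
  }
  if (!is.null(control)) {
    sel <- rep(TRUE, nrow(out))
    for (k in names(control)) sel <- sel & out[[k]] == control[[k]]
    if (!any(sel)) {
      stop("control group not found: ",
           paste(names(control), unlist(control), sep = "=", collapse = ", "),
           call. = FALSE)
    }
    ctrl_median <- out$median[sel][1]
    out$fold_change <- out$median / ctrl_median
  }
  out
}
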