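# End-to-end orchestration: one config drives merge -> align/pileup ->
# per-position profiles and read-level analysis for every sample in a sample
# sheet, with per-stage tallies so every discarded read and sample is
# accounted for. Rerunning with the same config and seed reproduces
# byte-identical outputs.

#' Build a run configuration
#'
#' @param reference Path to the single-record amplicon FASTA.
#' @param sample_sheet Path to the sample sheet TSV.
#' @param output_dir Output directory (created if needed).
#' @param window Optional targeted window `c(start, end)`, 0-based half-open;
#'   defaults to the full reference.
#' @param min_overlap,max_mismatch,max_qual Merge parameters.
#' @param max_depth Pileup depth cap.
#' @param min_depth Sample depth filter threshold.
#' @param depth_mode `"sample"` or `"region"` ([depth_filter()]).
#' @param floor Profile flooring threshold.
#' @param left_trim,right_trim End-region trims (positions).
#' @param min_count Unique-read occurrence threshold.
#' @param depth_agg `"mean"` or `"median"`: depth aggregate used to normalize
#'   unique-read counts.
#' @param background_agg `"mean"` or `"median"` across parental replicates.
#' @param match,mismatch,gap_open,gap_extend,min_score_frac Alignment
#'   scoring.
#' @param seed Integer seed recorded with the run (the analysis itself is
#'   deterministic; the seed drives any simulation that produced the inputs).
#' @return A list of class `run_config`.
#' @export
run_config <- function(reference, sample_sheet, output_dir,
                       window = NULL, min_overlap = 20L, max_mismatch = 0L,
                       max_qual = 40L, max_depth = 600000, min_depth = 40000,
                       depth_mode = "sample", floor = 1e-4, left_trim = 10L,
                       right_trim = 10L, min_count = 5L, depth_agg = "mean",
                       background_agg = "mean", match = 1, mismatch = -4,
                       gap_open = -6, gap_extend = -1, min_score_frac = 0.4,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(depth_agg %in% c("mean", "median"),
            background_agg %in% c("mean", "median"),
            depth_mode %in% c("sample", "region"))
  for (k in c("min_overlap", "max_mismatch", "max_qual", "left_trim",
              "right_trim", "min_count", "seed")) {
    cfg[[k]] <- as.integer(cfg[[k]])
  }
  for (k in c("max_depth", "min_depth", "floor", "match", "mismatch",
              "gap_open", "gap_extend", "min_score_frac")) {
    cfg[[k]] <- as.numeric(cfg[[k]])
  }
  if (!is.null(cfg$window)) cfg$window <- as.integer(cfg$window)
  structure(cfg, class = "run_config")
}

#' Write a run configuration as YAML
#' @param config A [run_config()].
#' @param path Output path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a run configuration from YAML
#' @param path Path to a YAML file written by [write_run_config()] or by
#'   hand.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' Run the full pipeline
#'
#' Stages, in order: merge (pair merging), align (dereplication, glocal
#' alignment, pileup), profile (depth filter, per-position
#' mutation-frequency profiles with background subtraction), reads
#' (read-level unique-read analysis and spectra). Each stage's outputs are
#' written as sorted TSV under `output_dir` together with a run log and a
#' config snapshot.
#'
#' @param config A [run_config()].
#' @param stages Subset of `c("merge", "align", "profile", "reads")`;
#'   later stages require the earlier ones in the same call.
#' @return Invisibly, a list with per-sample results: `merge_stats`,
#'   `pileups`, `alignments`, `profiles`, `readlevel`, `depth_log`.
#' @export
run_all <- function(config, stages = c("merge", "align", "profile", "reads")) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  reference <- read_amplicon_fasta(config$reference, window = config$window)
  sheet <- read_sample_sheet(config$sample_sheet)
  scoring <- align_scoring(config$match, config$mismatch, config$gap_open,
                           config$gap_extend, config$min_score_frac)
  log_lines <- c(sprintf("evolvamp run: %d samples, reference %s (%d bp)",
                         nrow(sheet), reference$name, nchar(reference$seq)))
  out <- list(reference = reference, sheet = sheet)

  # --- merge ---------------------------------------------------------------
  merged <- list(); mstats <- list()
  for (i in seq_len(nrow(sheet))) {
    sid <- sheet$sample_id[i]
    res <- tryCatch(
      merge_files(sheet$fastq_r1[i], sheet$fastq_r2[i],
                  min_overlap = config$min_overlap,
                  max_mismatch = config$max_mismatch,
                  max_qual = config$max_qual),
      error = function(e) stop("stage merge failed for sample '", sid, "': ",
                               conditionMessage(e), call. = FALSE))
    merged[[sid]] <- res$merged
    mstats[[sid]] <- dplyr::mutate(res$stats, sample_id = sid,
                                   .before = 1)
    log_lines <- c(log_lines,
                   sprintf("merge %s: %d pairs in, %d merged, %d rejected",
                           sid, res$stats$total, res$stats$merged,
                           res$stats$total - res$stats$merged))
  }
  out$merge_stats <- dplyr::bind_rows(mstats)
  write_table(out$merge_stats, file.path(config$output_dir,
                                         "merge_stats.tsv"))
  if (!"align" %in% stages) {
    finish_run(config, log_lines)
    return(invisible(out))
  }

  # --- align + pileup ------------------------------------------------------
  pileups <- list(); alignments <- list()
  for (sid in names(merged)) {
    ps <- tryCatch(
      pile_sample(merged[[sid]], reference, scoring = scoring,
                  max_depth = config$max_depth, sample_id = sid),
      error = function(e) stop("stage align failed for sample '", sid, "': ",
                               conditionMessage(e), call. = FALSE))
    pileups[[sid]] <- ps$pileup
    alignments[[sid]] <- ps$alignments
    n_un <- sum(ps$alignments$count[!ps$alignments$aligned])
    log_lines <- c(log_lines,
                   sprintf("align %s: %d unique reads, %d reads unaligned",
                           sid, nrow(ps$alignments), n_un))
    pu <- dplyr::mutate(ps$pileup, position = to_report_pos(.data$position))
    write_table(pu, file.path(config$output_dir,
                              paste0("pileup_", sid, ".tsv")),
                key = "position")
  }
  out$pileups <- pileups
  out$alignments <- alignments
  if (!"profile" %in% stages && !"reads" %in% stages) {
    finish_run(config, log_lines)
    return(invisible(out))
  }

  # --- depth filter --------------------------------------------------------
  df <- tryCatch(
    depth_filter(pileups, min_depth = config$min_depth,
                 window = reference$window, mode = config$depth_mode),
    error = function(e) stop("stage profile failed (depth filter): ",
                             conditionMessage(e), call. = FALSE))
  out$depth_log <- df$log
  write_table(df$log, file.path(config$output_dir, "depth_filter.tsv"))
  for (sid in df$discarded) {
    log_lines <- c(log_lines, sprintf("depth filter: sample %s discarded", sid))
  }
  kept <- df$retained
  sheet_kept <- sheet[sheet$sample_id %in% names(kept), , drop = FALSE]
  treated <- sheet_kept[sheet_kept$role == "treated", , drop = FALSE]

  parental_of <- function(genotype) {
    ids <- sheet_kept$sample_id[sheet_kept$role == "parental" &
                                  sheet_kept$genotype == genotype]
    if (length(ids) == 0) {
      stop("stage profile failed: no parental sample of genotype '",
           genotype, "' passed the depth filter", call. = FALSE)
    }
    ids
  }

  # --- per-position profiles -----------------------------------------------
  if ("profile" %in% stages) {
    profiles <- list()
    for (i in seq_len(nrow(treated))) {
      sid <- treated$sample_id[i]
      par_ids <- parental_of(treated$genotype[i])
      prof <- position_profile(kept[[sid]], kept[par_ids],
                               left_trim = config$left_trim,
                               right_trim = config$right_trim,
                               floor = config$floor,
                               agg = config$background_agg)
      profiles[[sid]] <- prof
      rep_prof <- dplyr::mutate(prof, position = to_report_pos(.data$position))
      write_table(rep_prof, file.path(config$output_dir,
                                      paste0("profile_", sid, ".tsv")),
                  key = "position")
    }
    out$profiles <- profiles
  }

  # --- read-level analysis -------------------------------------------------
  if ("reads" %in% stages) {
    readlevel <- list()
    agg_fun <- if (config$depth_agg == "mean") mean else median
    for (i in seq_len(nrow(treated))) {
      sid <- treated$sample_id[i]
      par_ids <- parental_of(treated$genotype[i])
      par_al <- dplyr::bind_rows(alignments[par_ids])
      win <- reference$window
      pu <- kept[[sid]]
      in_win <- pu$position >= win[1] & pu$position < win[2]
      mean_depth <- agg_fun(pu$depth[in_win])
      rl <- read_level_analysis(alignments[[sid]], par_al, reference,
                                window = win, min_count = config$min_count,
                                mean_depth = mean_depth)
      readlevel[[sid]] <- rl
      write_table(rl$table, file.path(config$output_dir,
                                      paste0("unique_reads_", sid, ".tsv")),
                  key = "seq")
      write_table(rl$spectra$hamming_spectrum,
                  file.path(config$output_dir,
                            paste0("hamming_spectrum_", sid, ".tsv")),
                  key = "hamming")
      write_table(rl$spectra$substitution_spectrum,
                  file.path(config$output_dir,
                            paste0("substitution_spectrum_", sid, ".tsv")),
                  key = c("ref", "alt"))
      write_table(dplyr::mutate(rl$summary, sample_id = sid, .before = 1),
                  file.path(config$output_dir,
                            paste0("readlevel_summary_", sid, ".tsv")))
      log_lines <- c(log_lines,
                     sprintf("reads %s: %d unique reads kept, %.4f mutated fraction",
                             sid, nrow(rl$table),
                             rl$summary$fraction_mutated_all))
    }
    out$readlevel <- readlevel
  }

  finish_run(config, log_lines)
  invisible(out)
}

finish_run <- function(config, log_lines) {
  writeLines(log_lines, file.path(config$output_dir, "run_log.txt"))
  write_run_config(config, file.path(config$output_dir, "config.yaml"))
}

# ---------------------------------------------------------------------------
# fixture scenarios

#' Available fixture scenarios
#'
#' Scenario names mirror the study design around a targeted window flanked by
#' four guides: individual guides, the four-guide multiplex, the multiplex in
#' an MMR-deficient background, an off-target control (guide directed
#' elsewhere: background mutation only), and the untransformed parental
#' control.
#'
#' @return Character vector of scenario names.
#' @export
fixture_scenarios <- function() {
  c("single-guide", "multiplexed-4", "msh6d", "off-target-control",
    "parental")
}

#' Simulate a named fixture dataset
#'
#' Generates paired FASTQ files, ground-truth tables and a sample sheet for
#' one scenario on the built-in synthetic amplicon. Each non-parental
#' scenario includes a matching parental control sample so the dataset is
#' runnable end-to-end. All randomness derives from `seed`.
#'
#' @param seed Integer seed.
#' @param scenario One of [fixture_scenarios()].
#' @param dir Output directory.
#' @param n_molecules Molecules simulated per sample.
#' @param variant Nickase variant, `"H840A"` or `"D10A"`.
#' @param guide For `"single-guide"`: which guide (`"g1"`..`"g4"`).
#' @param model A [mutagenesis_profile()].
#' @param repair A [repair_model()].
#' @param error_rate Per-base sequencing error rate.
#' @param read_len Read length.
#' @param dsb_synergy Synergy multiplier for opposite-strand nick pairs.
#' @return A list: `dir`, `sample_sheet` (path), `reference` (path),
#'   `truth` (tibble), `profile` (truth probability vector of the treated
#'   sample), `nicks`, `config` (a ready [run_config()] using defaults with
#'   `min_depth` scaled to the simulated depth).
#' @export
make_fixture <- function(seed, scenario, dir = tempfile("fixture"),
                         n_molecules = 20000L, variant = "H840A",
                         guide = "g2", model = mutagenesis_profile(),
                         repair = repair_model(), error_rate = 0,
                         read_len = 150L, dsb_synergy = 1) {
  if (!scenario %in% fixture_scenarios()) {
    stop("unknown scenario '", scenario, "'; available: ",
         paste(fixture_scenarios(), collapse = ", "), call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  amp <- synthetic_amplicon()
  reference <- amp$reference
  genotype <- if (scenario == "msh6d") "msh6" else "WT"
  guide_names <- switch(scenario,
    "single-guide" = guide,
    "multiplexed-4" = c("g1", "g2", "g3", "g4"),
    "msh6d" = c("g1", "g2", "g3", "g4"),
    "off-target-control" = character(0),
    "parental" = character(0))
  nicks <- if (length(guide_names) > 0) {
    dplyr::bind_rows(lapply(guide_names, function(g) {
      find_nick(reference, amp$guides[amp$guides$name == g, ], variant)
    }))
  } else {
    NULL
  }
  treated_profile <- build_position_profile(reference, nicks, model, repair,
                                            genotype = genotype,
                                            dsb_synergy = dsb_synergy)
  parental_profile <- build_position_profile(reference, NULL, model, repair,
                                             genotype = genotype)

  ref_path <- file.path(dir, "reference.fasta")
  write_amplicon_fasta(reference, ref_path)

  samples <- list()
  if (scenario != "parental") {
    samples[[1]] <- list(sample_id = paste0(scenario, "_1"), role = "treated",
                         profile = treated_profile, seed_off = 1L)
    samples[[2]] <- list(sample_id = paste0("parental_", genotype, "_1"),
                         role = "parental", profile = parental_profile,
                         seed_off = 2L)
  } else {
    samples[[1]] <- list(sample_id = "parental_WT_1", role = "parental",
                         profile = parental_profile, seed_off = 1L)
  }

  truth_all <- list()
  rows <- list()
  for (s in samples) {
    sim <- simulate_molecules(reference, s$profile, model$subst_matrix,
                              n_molecules, seed = seed * 13L + s$seed_off)
    reads <- sequence_reads(sim$seqs, read_len = read_len,
                            error_rate = error_rate,
                            seed = seed * 13L + s$seed_off + 100L)
    f1 <- file.path(dir, paste0(s$sample_id, "_R1.fastq"))
    f2 <- file.path(dir, paste0(s$sample_id, "_R2.fastq"))
    write_fastq(reads$r1, f1)
    write_fastq(reads$r2, f2)
    truth_all[[s$sample_id]] <- dplyr::mutate(sim$truth,
                                              sample_id = s$sample_id,
                                              .before = 1)
    rows[[s$sample_id]] <- tibble::tibble(
      sample_id = s$sample_id, role = s$role, genotype = genotype,
      replicate = 1L, guides = paste(guide_names, collapse = ";"),
      fastq_r1 = f1, fastq_r2 = f2)
  }
  sheet <- dplyr::bind_rows(rows)
  sheet_path <- file.path(dir, "samples.tsv")
  readr::write_tsv(sheet, sheet_path)
  truth <- dplyr::bind_rows(truth_all)
  write_truth(truth, treated_profile, dir)

  cfg <- run_config(reference = ref_path, sample_sheet = sheet_path,
                    output_dir = file.path(dir, "out"),
                    window = reference$window,
                    min_depth = min(40000, floor(n_molecules / 2)),
                    seed = seed)
  list(dir = dir, sample_sheet = sheet_path, reference = ref_path,
       truth = truth, profile = treated_profile,
       parental_profile = parental_profile, nicks = nicks, config = cfg,
       genotype = genotype)
}
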