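test_that("hamming distance counts substitutions and is undefined across lengths", {
  expect_equal(hamming_distance("GAG", "TAG"), 1L) # one substitution from WT
  expect_equal(hamming_distance("ACGT", "ACGT"), 0L)
  expect_true(is.na(hamming_distance("ACGT", "ACG")))
})

test_that("edit distance matches the textbook DP and known cases", {
  expect_equal(edit_distance("ACGT", "ACGT"), 0L)
  expect_equal(edit_distance("ACGT", "ACT"), 1L)
  expect_equal(edit_distance("AACGT", "ACGTT"), 2L)
  expect_equal(hamming_distance("AACGT", "ACGTT"), 3L)
  withr::with_seed(88, {
    for (i in 1:50) {
      a <- random_dna(sample(3:25, 1)); b <- random_dna(sample(3:25, 1))
      expect_equal(edit_distance(a, b), oracle_levenshtein(a, b),
                   info = paste(a, b))
    }
  })
})

test_that("edit distance never exceeds hamming distance on equal lengths", {
  withr::with_seed(89, {
    len <- 12L
    a <- vapply(1:1000, function(i) random_dna(len), character(1))
    b <- vapply(1:1000, function(i) random_dna(len), character(1))
    expect_true(all(edit_distance(a, b) <= hamming_distance(a, b)))
  })
})

test_that("window projection yields reference-coordinate read strings", {
  amp <- synthetic_amplicon()
  win <- amp$reference$window
  refwin <- substr(amp$reference$seq, win[1] + 1, win[2])

  full <- align_read(mk_read(amp$reference$seq), amp$reference)
  full$count <- 1
  tw <- trim_to_window(full, win)
  expect_equal(tw$table$seq, refwin)

  mut <- amp$reference$seq
  old <- substr(mut, 101, 101) # 0-based 100, inside the window
  substr(mut, 101, 101) <- setdiff(c("A", "C", "G", "T"), old)[1]
  am <- align_read(mk_read(mut), amp$reference); am$count <- 1
  wm <- trim_to_window(am, win)$table$seq
  expect_equal(hamming_distance(wm, refwin), 1L)
  expect_equal(substr(wm, 21, 21), substr(mut, 101, 101))

  # a deletion inside the window shortens the projected string
  del <- paste0(substr(amp$reference$seq, 1, 100),
                substr(amp$reference$seq, 104, 260))
  ad <- align_read(mk_read(del), amp$reference); ad$count <- 1
  wd <- trim_to_window(ad, win)$table$seq
  expect_equal(nchar(wd), 97L)

  # reads not spanning the window are dropped and counted
  part <- align_read(mk_read(substr(amp$reference$seq, 90, 260)),
                     amp$reference)
  part$count <- 3
  tp <- trim_to_window(part, win)
  expect_equal(nrow(tp$table), 0L)
  expect_equal(tp$dropped$n[tp$dropped$reason == "not_spanning"], 3)
})

test_that("indel flagging uses length and the edit/hamming discrepancy", {
  refwin <- "AACGTACGTA"
  tbl <- tibble::tibble(
    seq = c("AACGTACGTA",  # identical
            "AACGAACGTA",  # 1 substitution
            "TACGAACGTA",  # 2 substitutions
            "AACGACGTA",   # 1 bp deletion: length differs
            "ACGTACGTAT"), # shifted: compensating indels, edit < hamming
    count = c(50, 10, 6, 5, 5))
  fl <- flag_indels(tbl, refwin)
  expect_equal(fl$has_indel, c(FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(fl$hamming[1:3], c(0L, 1L, 2L))
  expect_equal(fl$edit[1:3], c(0L, 1L, 2L))
  expect_true(fl$edit[5] < fl$hamming[5])
})

test_that("occurrence and parental filters apply their thresholds exactly", {
  tbl <- tibble::tibble(seq = c("AA", "CC", "GG", "TT"),
                        count = c(4, 5, 100, 7))
  kept <- filter_occurrence(tbl)
  expect_setequal(kept$seq, c("CC", "GG", "TT"))

  parental <- tibble::tibble(seq = c("GG", "TT"), count = c(5, 4))
  after <- subtract_parental_reads(kept, parental)
  # GG is parental (count 5); TT stays (parental count 4 < 5)
  expect_setequal(after$seq, c("CC", "TT"))
})

test_that("filter bookkeeping on a constructed fixture matches brute force", {
  refwin <- "ACGTACGTACGT"
  reads <- c(rep("ACGTACGTACGT", 3),      # ref-like, treated count 3
             rep("ACGAACGTACGT", 6),      # variant kept
             rep("ACGTACGTACGA", 5),      # variant kept (boundary 5)
             rep("ACGTACGTACTT", 4),      # below occurrence threshold
             rep("ACGTACGACGT", 6),       # 1 bp deletion: indel
             rep("CCGTACGTACGT", 7))      # parental standing variant
  treated <- tibble::tibble(seq = reads) |> dplyr::count(seq, name = "count")
  parental <- tibble::tibble(
    seq = c(rep(refwin, 20), rep("CCGTACGTACGT", 6))) |>
    dplyr::count(seq, name = "count")

  out <- flag_indels(treated, refwin) |>
    filter_occurrence(5L) |>
    subtract_parental_reads(parental, 5L)
  out <- out[!out$has_indel, ]

  # brute force: tally, then apply the three rules by enumeration
  tab <- table(reads)
  keep <- names(tab)[tab >= 5]
  keep <- setdiff(keep, c(refwin, "CCGTACGTACGT")) # parental >= 5
  keep <- keep[nchar(keep) == nchar(refwin)]
  expect_setequal(out$seq, keep)
  expect_equal(sort(out$count), sort(as.numeric(tab[keep])))
})

test_that("spectra normalize by depth and classify substitutions", {
  refwin <- "ACGTACGTAC"
  tbl <- tibble::tibble(seq = "ACGAACGTAC", count = 50) # T>A at offset 3
  tbl <- flag_indels(tbl, refwin)
  sp <- normalize_and_spectrum(tbl, mean_depth = 1000, refwin,
                               window_start = 80L)
  expect_equal(sp$hamming_spectrum,
               tibble::tibble(hamming = 1L, normalized_abundance = 0.05))
  ss <- sp$substitution_spectrum
  expect_equal(ss$count[ss$ref == "T" & ss$alt == "A"], 50)
  expect_equal(sum(ss$count), 50)
  expect_equal(nrow(ss), 12L)
  expect_setequal(ss$class[ss$ref == "A"],
                  c("transversion", "transition", "transversion"))
  subs <- read_substitutions(tbl, refwin, window_start = 80L)
  expect_equal(subs$position, 83L)

  # all reads reference-identical: empty spectra
  ref_only <- flag_indels(tibble::tibble(seq = refwin, count = 9), refwin)
  sp0 <- normalize_and_spectrum(ref_only, 100, refwin)
  expect_equal(nrow(sp0$hamming_spectrum), 0L)
  expect_equal(sum(sp0$substitution_spectrum$count), 0)
  expect_equal(sp0$summary$fraction_mutated, 0)
})

test_that("the 12 substitution categories split 4 transitions / 8 transversions", {
  st <- substitution_types()
  expect_equal(nrow(st), 12L)
  expect_equal(sum(st$class == "transition"), 4L)
  expect_true(all(st$ref != st$alt))
})

test_that("fraction of mutated reads is invariant under read order", {
  amp <- synthetic_amplicon()
  nick <- find_nick(amp$reference, amp$guides[2, ], "H840A")
  p <- build_position_profile(amp$reference, nick, mutagenesis_profile(),
                              repair_model(escape_prob = 1))
  s <- sim_sample(p, 4000L, seed = 71, sample_id = "t")
  par <- sim_sample(rep(1e-3, length(p)), 4000L, seed = 72, sample_id = "p")
  rl1 <- read_level_analysis(s$alignments, par$alignments, amp$reference)
  perm <- withr::with_seed(1, s$merged[sample.int(nrow(s$merged)), ])
  ps2 <- pile_sample(perm, amp$reference, sample_id = "t")
  rl2 <- read_level_analysis(ps2$alignments, par$alignments, amp$reference)
  expect_equal(rl1$summary$fraction_mutated_all,
               rl2$summary$fraction_mutated_all)
  expect_equal(rl1$summary$fraction_mutated, rl2$summary$fraction_mutated)
})

test_that("substitution-only simulation flags no indels and matches truth totals", {
  amp <- synthetic_amplicon()
  win <- amp$reference$window
  nick <- find_nick(amp$reference, amp$guides[3, ], "H840A")
  p <- build_position_profile(amp$reference, nick, mutagenesis_profile(),
                              repair_model(escape_prob = 1))
  s <- sim_sample(p, 4000L, seed = 73, sample_id = "t")
  refwin <- substr(amp$reference$seq, win[1] + 1, win[2])
  tw <- trim_to_window(s$alignments, win)
  tbl <- flag_indels(tw$table, refwin)
  expect_false(any(tbl$has_indel))
  # every simulated substitution inside the window is recovered
  subs <- read_substitutions(tbl, refwin, window_start = win[1])
  total <- sum(subs$count)
  truth_in_win <- sum(s$sim$truth$position >= win[1] &
                        s$sim$truth$position < win[2])
  expect_equal(total, truth_in_win)
})

test_that("mean hamming distance rises with the simulated peak rate", {
  # computed over all indel-free window reads (zero-distance included): the
  # occurrence filter censors rare multi-substitution haplotypes, so the
  # conditional post-filter mean would not track the mutational load
  amp <- synthetic_amplicon()
  win <- amp$reference$window
  refwin <- substr(amp$reference$seq, win[1] + 1, win[2])
  nick <- find_nick(amp$reference, amp$guides[2, ], "H840A")
  means <- ses <- numeric(3)
  rates <- c(0.005, 0.02, 0.05)
  for (k in seq_along(rates)) {
    p <- build_position_profile(amp$reference, nick,
                                mutagenesis_profile(peak_rate = rates[k]),
                                repair_model(escape_prob = 1))
    s <- sim_sample(p, 15000L, seed = 80 + k, sample_id = "t")
    tbl <- flag_indels(trim_to_window(s$alignments, win)$table, refwin)
    tbl <- tbl[!tbl$has_indel, ]
    n <- sum(tbl$count)
    mu <- sum(tbl$count * tbl$hamming) / n
    means[k] <- mu
    ses[k] <- sqrt(sum(tbl$count * (tbl$hamming - mu)^2) / n / n)
  }
  expect_gt(means[2] - means[1], 3 * sqrt(ses[1]^2 + ses[2]^2))
  expect_gt(means[3] - means[2], 3 * sqrt(ses[2]^2 + ses[3]^2))
})
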