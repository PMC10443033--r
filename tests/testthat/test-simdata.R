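test_that("nick placement follows the variant strand rule and cut geometry", {
  toy <- toy_guide_reference()
  n_h <- find_nick(toy$reference, toy$guide, "H840A")
  expect_equal(n_h$nick_pos, 40L - 3L) # 3 nt 5' of the PAM
  expect_equal(n_h$nicked_strand, "+") # protospacer strand
  expect_equal(n_h$direction, 1L)

  n_d <- find_nick(toy$reference, toy$guide, "D10A")
  expect_equal(n_d$nick_pos, 37L)
  expect_equal(n_d$nicked_strand, "-") # complementary strand
  expect_equal(n_d$direction, -1L)
})

test_that("guide validation rejects PAM and spacer mismatches", {
  toy <- toy_guide_reference()
  bad_pam <- guide_spec("bp", substr(toy$reference$seq, 11, 30), "+", 30L)
  expect_error(find_nick(toy$reference, bad_pam, "H840A"), "NGG")
  bad_spacer <- toy$guide
  bad_spacer$spacer <- chartr("ACGT", "TGCA", bad_spacer$spacer)
  expect_error(find_nick(toy$reference, bad_spacer, "H840A"),
               "does not match spacer")
})

test_that("minus-strand guides validate and nick with direction -1", {
  amp <- synthetic_amplicon()
  g2 <- amp$guides[amp$guides$name == "g2", ]
  expect_equal(g2$strand, "-")
  nk <- find_nick(amp$reference, g2, "H840A")
  expect_equal(nk$nick_pos, g2$pam_start + 6L)
  expect_equal(nk$direction, -1L)
  # D10A flips to the reference (+) strand
  expect_equal(find_nick(amp$reference, g2, "D10A")$direction, 1L)
})

test_that("position profile has the stated closed forms", {
  amp <- synthetic_amplicon()
  ref <- amp$reference
  L <- nchar(ref$seq)
  rep_free <- repair_model(escape_prob = 1, background_rate = 0)

  # zero nicks: flat background
  bg <- repair_model(escape_prob = 1, background_rate = 1e-3)
  expect_equal(build_position_profile(ref, NULL, mutagenesis_profile(), bg),
               rep(1e-3, L))

  # decay 0: step profile, constant inside each window, zero outside
  model <- mutagenesis_profile(peak_rate = 0.1, fwd_window = 40L,
                               rev_window = 15L, decay = 0,
                               rev_fraction = 0.25)
  nick <- tibble::tibble(guide = "g", nick_pos = 107L, nicked_strand = "+",
                         direction = 1L)
  p <- build_position_profile(ref, nick, model, rep_free)
  expect_equal(unique(p[108:147]), 0.1)         # fwd: positions 107..146
  expect_equal(unique(p[93:107]), 0.025)        # rev: positions 92..106
  expect_equal(unique(p[c(1:92, 148:L)]), 0)

  # two co-located nicks combine as independent events: 1 - 0.9^2
  p2 <- build_position_profile(ref, dplyr::bind_rows(nick, nick), model,
                               rep_free)
  expect_equal(p2[108], 1 - 0.9^2)
})

test_that("multi-nick profiles respect the union bounds pointwise", {
  amp <- synthetic_amplicon()
  rep_free <- repair_model(escape_prob = 1, background_rate = 0)
  model <- mutagenesis_profile()
  nicks <- dplyr::bind_rows(lapply(1:4, function(i) {
    find_nick(amp$reference, amp$guides[i, ], "H840A")
  }))
  singles <- lapply(1:4, function(i) {
    build_position_profile(amp$reference, nicks[i, ], model, rep_free)
  })
  combined <- build_position_profile(amp$reference, nicks, model, rep_free)
  for (s in singles) expect_true(all(combined >= s - 1e-12))
  expect_true(all(combined <= Reduce(`+`, singles) + 1e-12))
})

test_that("opposite-strand nick pairs within range trigger the synergy multiplier", {
  amp <- synthetic_amplicon()
  rep_free <- repair_model(escape_prob = 1, background_rate = 0)
  model <- mutagenesis_profile()
  nicks <- dplyr::bind_rows(
    find_nick(amp$reference, amp$guides[1, ], "H840A"), # + strand
    find_nick(amp$reference, amp$guides[2, ], "H840A")  # - strand
  )
  base <- build_position_profile(amp$reference, nicks, model, rep_free)
  boosted <- build_position_profile(amp$reference, nicks, model, rep_free,
                                    dsb_synergy = 2)
  expect_equal(boosted, pmin(base * 2, 1))
  # same-strand pair: no synergy regardless of the knob
  ss <- dplyr::bind_rows(find_nick(amp$reference, amp$guides[1, ], "H840A"),
                         find_nick(amp$reference, amp$guides[3, ], "H840A"))
  expect_equal(
    build_position_profile(amp$reference, ss, model, rep_free,
                           dsb_synergy = 2),
    build_position_profile(amp$reference, ss, model, rep_free))
})

test_that("molecule simulation honors the profile and records truth", {
  amp <- synthetic_amplicon()
  L <- nchar(amp$reference$seq)

  flat <- simulate_molecules(amp$reference, rep(0, L),
                             substitution_matrix(), 50, seed = 1)
  expect_true(all(flat$seqs == amp$reference$seq))
  expect_equal(nrow(flat$truth), 0L)

  # deterministic substitution at one site
  p <- rep(0, L); p[31] <- 1
  ref_base <- substr(amp$reference$seq, 31, 31)
  alt <- setdiff(c("A", "C", "G", "T"), ref_base)[1]
  bias <- stats::setNames(list(stats::setNames(1, alt)), ref_base)
  sure <- simulate_molecules(amp$reference, p, substitution_matrix(bias),
                             30, seed = 2)
  expect_true(all(substr(sure$seqs, 31, 31) == alt))
  expect_true(all(sure$truth$position == 30L & sure$truth$alt == alt))
  expect_equal(nrow(sure$truth), 30L)

  # binomial sampling: observed alt fraction within 3 SE of p = 0.05
  n <- 20000L
  p <- rep(0, L); p[101] <- 0.05
  sim <- simulate_molecules(amp$reference, p, substitution_matrix(), n,
                            seed = 3)
  obs <- nrow(sim$truth) / n
  se <- sqrt(0.05 * 0.95 / n)
  expect_lt(abs(obs - 0.05), 3 * se)
})

test_that("paired reads cover the amplicon with the expected overlap geometry", {
  for (L in c(250L, 260L, 270L, 280L)) {
    mol <- withr::with_seed(L, random_dna(L))
    rd <- sequence_reads(mol, read_len = 150L, seed = 1)
    expect_equal(nchar(rd$r1$seq), 150L)
    mg <- merge_pair(rd$r1, rd$r2)
    expect_equal(mg$status, "merged")
    expect_equal(mg$merged$seq, mol)
    expect_equal(mg$overlap_len, 2L * 150L - L)
  }
  expect_warning(sequence_reads(withr::with_seed(1, random_dna(295)),
                                min_overlap = 20L, seed = 1), "overlap")
  expect_error(sequence_reads(withr::with_seed(1, random_dna(310)), seed = 1),
               "exceeds")
})

test_that("sequencing errors appear at the configured rate", {
  amp <- synthetic_amplicon()
  n <- 3000L
  mols <- rep(amp$reference$seq, n)
  rd <- sequence_reads(mols, error_rate = 0.01, seed = 9)
  truth_r1 <- substr(amp$reference$seq, 1, 150)
  mism <- sum(hamming_distance(rd$r1$seq, truth_r1))
  rate <- mism / (n * 150)
  se <- sqrt(0.01 * 0.99 / (n * 150))
  expect_lt(abs(rate - 0.01), 3 * se)
})

test_that("simulation is reproducible from its seed", {
  amp <- synthetic_amplicon()
  p <- build_position_profile(amp$reference, NULL, mutagenesis_profile(),
                              repair_model())
  a <- simulate_molecules(amp$reference, p, substitution_matrix(), 500,
                          seed = 11)
  b <- simulate_molecules(amp$reference, p, substitution_matrix(), 500,
                          seed = 11)
  expect_identical(a, b)
})
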