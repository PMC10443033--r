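# Independent reference implementations used to cross-check the package's
# C-level alignment and distance code, plus small fixture builders. These are
# deliberately written as plain, slow R: full matrices, no affine-gap state
# machine sharing with the implementation under test.

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Optimal glocal (read-global, reference-local) affine-gap score by direct
# evaluation of the three-state recurrence over full matrices. A gap of
# length g costs gap_open + g * gap_extend.
oracle_glocal_score <- function(read, ref, match = 1, mismatch = -4,
                                gap_open = -6, gap_extend = -1) {
  n <- nchar(read); m <- nchar(ref)
  rc <- strsplit(read, "")[[1]]; gc <- strsplit(ref, "")[[1]]
  NEG <- -1e30
  H <- matrix(NEG, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)  # gap consuming read
  F_ <- matrix(NEG, n + 1, m + 1) # gap consuming reference
  H[1, ] <- 0
  for (i in 2:(n + 1)) {
    for (j in 1:(m + 1)) {
      E[i, j] <- max(H[i - 1, j] + gap_open + gap_extend,
                     E[i - 1, j] + gap_extend)
      if (j > 1) {
        F_[i, j] <- max(H[i, j - 1] + gap_open + gap_extend,
                        F_[i, j - 1] + gap_extend)
        s <- if (rc[i - 1] == gc[j - 1]) match else mismatch
        H[i, j] <- max(H[i - 1, j - 1] + s, E[i, j], F_[i, j])
      } else {
        H[i, j] <- E[i, j]
      }
    }
  }
  max(H[n + 1, ])
}

# Levenshtein distance by the textbook two-row dynamic program.
oracle_levenshtein <- function(a, b) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  prev <- 0:length(B)
  for (i in seq_along(A)) {
    cur <- c(i, integer(length(B)))
    for (j in seq_along(B)) {
      cur[j + 1] <- min(prev[j + 1] + 1, cur[j] + 1,
                        prev[j] + (A[i] != B[j]))
    }
    prev <- cur
  }
  prev[length(B) + 1]
}

# Build a read tibble directly from strings, default quality 'I' (phred 40).
mk_read <- function(seq, id = "r1", qual = NULL) {
  if (is.null(qual)) qual <- strrep("I", nchar(seq))
  read_set(id, seq, qual)
}

# A 60-bp toy reference carrying one valid + strand guide site (PAM at 40).
toy_guide_reference <- function() {
  seq <- withr::with_seed(42L, random_dna(60))
  chars <- strsplit(seq, "")[[1]]
  chars[c(42, 43)] <- c("G", "G") # NGG at 0-based 40..42
  seq <- paste(chars, collapse = "")
  ref <- amplicon_reference("toy", seq)
  guide <- guide_spec("tg", substr(seq, 21, 40), "+", 40L)
  list(reference = ref, guide = guide)
}

# In-memory simulated sample: molecules -> paired reads -> merged reads ->
# weighted unique-read alignments and pileup.
sim_sample <- function(profile, n, seed, reference = NULL,
                       subst = substitution_matrix(), error_rate = 0,
                       sample_id = "s") {
  if (is.null(reference)) reference <- synthetic_amplicon()$reference
  sim <- simulate_molecules(reference, profile, subst, n, seed = seed)
  rd <- sequence_reads(sim$seqs, error_rate = error_rate, seed = seed + 1L)
  mg <- merge_reads(rd$r1, rd$r2)
  ps <- pile_sample(mg$merged, reference, sample_id = sample_id)
  list(sim = sim, merged = mg$merged, stats = mg$stats,
       alignments = ps$alignments, pileup = ps$pileup)
}
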