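# Synthetic-data generator: forward-simulates the directional mutational
# footprint of a nickase-guided error-prone polymerase on a short amplicon and
# emits paired reads plus ground truth, so every downstream stage is testable
# without external data.
#
# Model: each guide/nickase combination places a single-strand nick 3 nt
# 5' of the PAM (between protospacer bases 17 and 18). Polymerase synthesis
# runs 5'->3' along the nicked strand, elevating per-molecule substitution
# probability in a window downstream of the nick (default 40 bp) with an
# exponential fall-off, plus a weaker mirrored window in the opposite
# direction (default 15 bp). Multiple nicks combine as independent events;
# templated mismatches become mutations with an escape probability that is
# raised in an MMR-deficient (msh6-null) background; a uniform background
# rate emulates off-target mutation plus residual error.

#' Construct a guide specification
#'
#' @param name Guide name.
#' @param spacer 20-nt spacer sequence (equal to the protospacer-strand
#'   sequence).
#' @param strand `"+"` or `"-"`: the strand carrying the protospacer.
#' @param pam_start 0-based reference coordinate of the leftmost base of the
#'   3-bp PAM on the reference axis (for `-` strand guides the PAM reads NGG
#'   on the minus strand, i.e. CCN on the reference).
#' @return A one-row tibble.
#' @export
guide_spec <- function(name, spacer, strand, pam_start) {
  stopifnot(strand %in% c("+", "-"), nchar(spacer) == 20)
  tibble::tibble(name = name, spacer = toupper(spacer), strand = strand,
                 pam_start = as.integer(pam_start))
}

#' Validate a guide against the reference
#'
#' Checks that the protospacer sequence matches the spacer on the stated
#' strand and that the PAM is NGG on that strand.
#'
#' @param reference An [amplicon_reference()].
#' @param guide A one-row guide tibble from [guide_spec()].
#' @return `TRUE` invisibly; errors on mismatch.
#' @export
validate_guide <- function(reference, guide) {
  seq <- reference$seq
  L <- nchar(seq)
  p <- guide$pam_start
  if (guide$strand == "+") {
    if (p < 20 || p + 3 > L) stop("guide '", guide$name, "' out of bounds",
                                  call. = FALSE)
    pam <- substr(seq, p + 1, p + 3)
    if (substr(pam, 2, 3) != "GG") {
      stop("guide '", guide$name, "': PAM site reads '", pam,
           "', expected NGG", call. = FALSE)
    }
    proto <- substr(seq, p - 20 + 1, p)
  } else {
    if (p < 0 || p + 23 > L) stop("guide '", guide$name, "' out of bounds",
                                  call. = FALSE)
    pam_ref <- substr(seq, p + 1, p + 3)
    pam <- reverse_complement(pam_ref)
    if (substr(pam, 2, 3) != "GG") {
      stop("guide '", guide$name, "': PAM site reads '", pam,
           "', expected NGG", call. = FALSE)
    }
    proto <- reverse_complement(substr(seq, p + 3 + 1, p + 23))
  }
  if (proto != guide$spacer) {
    stop("guide '", guide$name, "': protospacer '", proto,
         "' does not match spacer '", guide$spacer, "'", call. = FALSE)
  }
  invisible(TRUE)
}

#' Locate the nick produced by a guide and nickase variant
#'
#' The nick sits between protospacer bases 17 and 18 (3 nt 5' of the PAM;
#' canonical SpCas9 cut geometry, configurable via `cut_offset`). The D10A
#' variant nicks the strand complementary to the protospacer strand, H840A
#' nicks the protospacer strand; polymerase synthesis then runs 5'->3' along
#' the nicked strand, i.e. direction +1 on the reference axis for a `+`
#' strand nick and -1 for a `-` strand nick.
#'
#' @param reference An [amplicon_reference()].
#' @param guide A one-row guide tibble.
#' @param variant `"D10A"` or `"H840A"`.
#' @param cut_offset Nick distance in nt 5' of the PAM (default 3).
#' @return A one-row tibble: `guide`, `nick_pos` (0-based between-base index:
#'   the nick lies between positions `nick_pos - 1` and `nick_pos`),
#'   `nicked_strand`, `direction` (+1/-1).
#' @export
find_nick <- function(reference, guide, variant = c("H840A", "D10A"),
                      cut_offset = 3L) {
  variant <- match.arg(variant)
  validate_guide(reference, guide)
  p <- guide$pam_start
  if (guide$strand == "+") {
    nick_pos <- p - cut_offset
  } else {
    nick_pos <- p + 3L + cut_offset
  }
  L <- nchar(reference$seq)
  if (!(nick_pos > 0 && nick_pos < L)) {
    stop("nick position ", nick_pos, " outside reference interior",
         call. = FALSE)
  }
  nicked_strand <- if (variant == "H840A") guide$strand else
    (if (guide$strand == "+") "-" else "+")
  direction <- if (nicked_strand == "+") 1L else -1L
  tibble::tibble(guide = guide$name, nick_pos = as.integer(nick_pos),
                 nicked_strand = nicked_strand, direction = direction)
}

#' Default conditional substitution matrix
#'
#' Row-stochastic 4x4 matrix over A/C/G/T with zero diagonal; the default is
#' uniform (each alternative base 1/3), reflecting that all 12 substitution
#' types are observed without published per-type rates.
#'
#' @param bias Optional named list, e.g. `list(C = c(A = .05, G = .05, T = .9))`
#'   overriding individual rows.
#' @return A 4x4 numeric matrix with dimnames A/C/G/T.
#' @export
substitution_matrix <- function(bias = NULL) {
  b <- c("A", "C", "G", "T")
  M <- matrix(1 / 3, 4, 4, dimnames = list(b, b))
  diag(M) <- 0
  if (!is.null(bias)) {
    for (ref in names(bias)) {
      row <- setNames(rep(0, 4), b)
      row[names(bias[[ref]])] <- bias[[ref]]
      if (row[ref] != 0 || abs(sum(row) - 1) > 1e-8) {
        stop("bias row for ", ref, " must sum to 1 with 0 on the diagonal",
             call. = FALSE)
      }
      M[ref, ] <- row
    }
  }
  M
}

#' Mutagenesis footprint parameters
#'
#' @param peak_rate Per-molecule substitution probability at the base adjacent
#'   to the nick in the direction of synthesis.
#' @param fwd_window Window length (bp) in the direction of synthesis.
#' @param rev_window Window length (bp) opposite the direction of synthesis.
#' @param decay Exponential fall-off per bp within each window
#'   (`p(d) = peak * exp(-decay * d)` at offset `d` from the nick).
#' @param rev_fraction Peak in the reverse window as a fraction of
#'   `peak_rate`.
#' @param subst_matrix Conditional substitution matrix
#'   ([substitution_matrix()]).
#' @return A list of class `mutagenesis_profile`.
#' @export
mutagenesis_profile <- function(peak_rate = 0.02, fwd_window = 40L,
                                rev_window = 15L, decay = 0.1,
                                rev_fraction = 0.25,
                                subst_matrix = substitution_matrix()) {
  stopifnot(peak_rate >= 0, peak_rate <= 1, fwd_window >= 0, rev_window >= 0,
            decay >= 0, rev_fraction >= 0, rev_fraction <= 1)
  stopifnot(all(diag(subst_matrix) == 0),
            all(abs(rowSums(subst_matrix) - 1) < 1e-8))
  structure(list(peak_rate = peak_rate, fwd_window = as.integer(fwd_window),
                 rev_window = as.integer(rev_window), decay = decay,
                 rev_fraction = rev_fraction, subst_matrix = subst_matrix),
            class = "mutagenesis_profile")
}

#' Repair-model parameters
#'
#' @param escape_prob Probability a templated mismatch escapes mismatch
#'   repair and is fixed as a mutation.
#' @param msh6_multiplier Factor applied to `escape_prob` in the MMR-deficient
#'   msh6-null genotype (clipped at 1).
#' @param background_rate Per-base per-molecule off-target mutation
#'   probability added everywhere (default 1e-4, the residual scale left
#'   after both mates of a perfectly overlapping pair must agree; the
#'   analysis floors adjusted frequencies at this same scale).
#' @return A list of class `repair_model`.
#' @export
repair_model <- function(escape_prob = 0.6, msh6_multiplier = 1.5,
                         background_rate = 1e-4) {
  stopifnot(escape_prob >= 0, escape_prob <= 1, msh6_multiplier >= 1,
            background_rate >= 0, background_rate <= 1)
  structure(list(escape_prob = escape_prob, msh6_multiplier = msh6_multiplier,
                 background_rate = background_rate), class = "repair_model")
}

# per-position probability vector contributed by a single nick (pre-repair)
nick_profile_vector <- function(L, nick, model) {
  p <- numeric(L)
  dirn <- nick$direction
  # first base in the direction of synthesis adjacent to the nick
  fwd0 <- if (dirn == 1L) nick$nick_pos else nick$nick_pos - 1L
  rev0 <- if (dirn == 1L) nick$nick_pos - 1L else nick$nick_pos
  if (model$fwd_window > 0) {
    d <- 0:(model$fwd_window - 1L)
    pos <- fwd0 + dirn * d
    keep <- pos >= 0 & pos < L
    p[pos[keep] + 1L] <- pmax(p[pos[keep] + 1L],
                              model$peak_rate * exp(-model$decay * d[keep]))
  }
  if (model$rev_window > 0) {
    d <- 0:(model$rev_window - 1L)
    pos <- rev0 - dirn * d
    keep <- pos >= 0 & pos < L
    p[pos[keep] + 1L] <- pmax(p[pos[keep] + 1L],
                              model$peak_rate * model$rev_fraction *
                                exp(-model$decay * d[keep]))
  }
  p
}

#' Build the per-position substitution-probability vector
#'
#' Each nick contributes an exponentially decaying probability profile in its
#' direction of synthesis plus a weaker mirrored profile opposite it; nicks
#' combine as independent events (`1 - prod(1 - p_i)`). When two nicks on
#' opposite strands lie within `dsb_max_dist` bp of each other -- the
#' double-strand-break configuration -- the combined targeted probability is
#' multiplied by `dsb_synergy` (default 1: no synergy). The result is scaled
#' by the repair escape probability (times the msh6 multiplier for the
#' msh6-null genotype), the uniform background rate is added, and the vector
#' is clipped to [0, 1].
#'
#' @param reference An [amplicon_reference()].
#' @param nicks Tibble of nicks from [find_nick()] (zero or more rows).
#' @param model A [mutagenesis_profile()].
#' @param repair A [repair_model()].
#' @param genotype `"WT"` or `"msh6"` (MMR-deficient).
#' @param dsb_synergy Multiplier applied to the combined targeted probability
#'   when an opposite-strand nick pair lies within `dsb_max_dist`.
#' @param dsb_max_dist Distance threshold (bp) for the synergy condition.
#' @return Numeric vector of per-position substitution probabilities.
#' @export
build_position_profile <- function(reference, nicks, model, repair,
                                   genotype = "WT", dsb_synergy = 1,
                                   dsb_max_dist = 100L) {
  L <- nchar(reference$seq)
  not_mut <- rep(1, L)
  if (!is.null(nicks) && nrow(nicks) > 0) {
    for (i in seq_len(nrow(nicks))) {
      not_mut <- not_mut * (1 - nick_profile_vector(L, nicks[i, ], model))
    }
  }
  combined <- 1 - not_mut
  if (dsb_synergy != 1 && !is.null(nicks) && nrow(nicks) > 1) {
    pairs <- which(outer(nicks$nicked_strand, nicks$nicked_strand, "!=") &
                     abs(outer(nicks$nick_pos, nicks$nick_pos, "-")) <=
                       dsb_max_dist, arr.ind = TRUE)
    if (nrow(pairs) > 0) combined <- combined * dsb_synergy
  }
  escape <- repair$escape_prob *
    (if (identical(genotype, "msh6")) repair$msh6_multiplier else 1)
  escape <- min(escape, 1)
  pmin(pmax(combined * escape + repair$background_rate, 0), 1)
}

#' Forward-simulate mutated amplicon molecules
#'
#' Each molecule independently mutates position `x` with probability
#' `profile[x]`; the alternative base is drawn from the substitution matrix
#' row of the reference base. Substitutions only; ground truth is recorded.
#'
#' @param reference An [amplicon_reference()].
#' @param profile Per-position probability vector
#'   ([build_position_profile()]).
#' @param subst_matrix Conditional substitution matrix.
#' @param n Number of molecules.
#' @param seed Optional integer seed for reproducibility.
#' @return A list: `seqs` (character vector of n molecule sequences) and
#'   `truth` (tibble `molecule_id`, `position` 0-based, `ref`, `alt`).
#' @export
simulate_molecules <- function(reference, profile, subst_matrix, n,
                               seed = NULL) {
  stopifnot(n >= 1, length(profile) == nchar(reference$seq))
  run <- function() {
    L <- length(profile)
    ref_chars <- strsplit(reference$seq, "")[[1]]
    mol <- integer(0); pos <- integer(0); alt <- character(0)
    bases <- c("A", "C", "G", "T")
    for (x in which(profile > 0)) {
      hit <- which(runif(n) < profile[x])
      if (length(hit) == 0) next
      probs <- subst_matrix[ref_chars[x], ]
      a <- sample(bases, length(hit), replace = TRUE, prob = probs)
      mol <- c(mol, hit); pos <- c(pos, rep.int(x - 1L, length(hit)))
      alt <- c(alt, a)
    }
    seqs <- rep.int(reference$seq, n)
    if (length(mol) > 0) {
      ord <- order(mol, pos)
      mol <- mol[ord]; pos <- pos[ord]; alt <- alt[ord]
      for (id in unique(mol)) {
        sel <- which(mol == id)
        chars <- ref_chars
        chars[pos[sel] + 1L] <- alt[sel]
        seqs[id] <- paste(chars, collapse = "")
      }
    }
    truth <- tibble::tibble(molecule_id = mol, position = pos,
                            ref = ref_chars[pos + 1L], alt = alt)
    list(seqs = seqs, truth = truth)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Generate paired-end reads from molecules
#'
#' R1 is the first `read_len` bases of each molecule, R2 the reverse
#' complement of the last `read_len` bases (whole molecule when shorter), so
#' a short amplicon is fully spanned and the pair overlaps in the middle.
#' Sequencing errors are independent per base at `error_rate` (uniform over
#' the three other bases); base qualities are constant at `qual`, capped
#' at 40.
#'
#' @param molecules Character vector of molecule sequences.
#' @param read_len Read length (default 150, as for 2x150 bp sequencing).
#' @param error_rate Per-base sequencing error probability.
#' @param qual Constant phred score assigned to every base.
#' @param min_overlap Overlap below which a geometry warning is issued.
#' @param seed Optional integer seed.
#' @return A list of two read tibbles, `r1` and `r2`.
#' @export
sequence_reads <- function(molecules, read_len = 150L, error_rate = 0,
                           qual = 40L, min_overlap = 20L, seed = NULL) {
  L <- unique(nchar(molecules))
  if (length(L) != 1) stop("molecules must share one length", call. = FALSE)
  if (L > 2L * read_len) {
    stop("amplicon length ", L, " exceeds 2 * read_len = ", 2L * read_len,
         "; pairs cannot span it", call. = FALSE)
  }
  overlap <- 2L * read_len - L
  if (overlap < min_overlap) {
    warning("paired-end overlap ", overlap, " bp is below min_overlap ",
            min_overlap, call. = FALSE)
  }
  rl <- min(read_len, L)
  run <- function() {
    r1 <- substr(molecules, 1L, rl)
    r2 <- reverse_complement(substr(molecules, L - rl + 1L, L))
    if (error_rate > 0) {
      r1 <- inject_errors(r1, error_rate)
      r2 <- inject_errors(r2, error_rate)
    }
    n <- length(molecules)
    ids <- sprintf("mol%06d", seq_len(n))
    q <- strrep(substr(phred_encode(qual), 1, 1), rl)
    list(r1 = read_set(ids, r1, rep(q, n)),
         r2 = read_set(ids, r2, rep(q, n)))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# independent per-base miscalls at rate e, uniform over the other 3 bases
inject_errors <- function(seqs, e) {
  n <- length(seqs)
  len <- nchar(seqs[1])
  n_err <- rbinom(n, len, e)
  idx <- which(n_err > 0)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    pos <- sample.int(len, n_err[i])
    chars <- strsplit(seqs[i], "")[[1]]
    for (p in pos) {
      alt <- bases[bases != chars[p]]
      chars[p] <- alt[sample.int(3L, 1L)]
    }
    seqs[i] <- paste(chars, collapse = "")
  }
  seqs
}

#' Built-in synthetic amplicon with four guide sites
#'
#' Constructs a deterministic 260-bp synthetic amplicon (labelled synthetic;
#' it is not any genomic locus) whose central ~100-bp targeted window is
#' flanked by four guide sites on alternating strands, mirroring a multiplexed
#' guide layout around a site of interest. PAM motifs are stamped into the
#' sequence and spacers are read back off it, so all guides validate by
#' construction.
#'
#' @return A list: `reference` ([amplicon_reference()] with window
#'   `[80, 180)`) and `guides` (4-row guide tibble `g1`..`g4`).
#' @export
synthetic_amplicon <- function() {
  L <- 260L
  base <- withr::with_seed(104729L, {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  })
  chars <- strsplit(base, "")[[1]]
  # + strand guides need G,G at pam_start+1, pam_start+2 (0-based);
  # - strand guides need C,C at pam_start, pam_start+1.
  chars[c(112, 113)] <- c("G", "G")   # g1: + strand, pam_start 110
  chars[c(121, 122)] <- c("C", "C")   # g2: - strand, pam_start 120
  chars[c(157, 158)] <- c("G", "G")   # g3: + strand, pam_start 155
  chars[c(161, 162)] <- c("C", "C")   # g4: - strand, pam_start 160
  seq <- paste(chars, collapse = "")
  reference <- amplicon_reference("synthetic_amplicon", seq,
                                  window = c(80L, 180L))
  spacer_plus <- function(p) substr(seq, p - 20 + 1, p)
  spacer_minus <- function(p) reverse_complement(substr(seq, p + 4, p + 23))
  guides <- dplyr::bind_rows(
    guide_spec("g1", spacer_plus(110), "+", 110L),
    guide_spec("g2", spacer_minus(120), "-", 120L),
    guide_spec("g3", spacer_plus(155), "+", 155L),
    guide_spec("g4", spacer_minus(160), "-", 160L)
  )
  for (i in 1:4) validate_guide(reference, guides[i, ])
  list(reference = reference, guides = guides)
}

#' Write simulation ground truth as TSV
#'
#' @param truth Truth tibble from [simulate_molecules()].
#' @param profile Truth probability vector.
#' @param dir Output directory.
#' @return Paths of the two files, invisibly.
#' @export
write_truth <- function(truth, profile, dir) {
  p1 <- file.path(dir, "truth_substitutions.tsv")
  p2 <- file.path(dir, "truth_profile.tsv")
  write_table(truth, p1, key = c("molecule_id", "position"))
  write_table(tibble::tibble(position = to_report_pos(seq_along(profile) - 1L),
                             probability = profile), p2, key = "position")
  invisible(c(p1, p2))
}
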