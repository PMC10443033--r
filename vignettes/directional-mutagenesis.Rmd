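---
title: "Quantifying directional in vivo mutagenesis from amplicon deep sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying directional in vivo mutagenesis from amplicon deep sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evolvamp)
library(dplyr)
```

## The measurement problem

A CRISPR-guided error-prone DNA polymerase (a Cas9 nickase fused to a
low-fidelity DNA polymerase I) diversifies a short genomic window in vivo:
the nickase cuts one strand at a gRNA-determined site, and the polymerase
re-synthesizes downstream DNA with frequent misincorporation. Mismatches
that escape mismatch repair (MMR) become heritable substitutions. The
mutational footprint is *directional*: substitution rates are highest at the
base adjacent to the nick on the synthesized strand and fall off over a few
tens of base pairs in the direction of synthesis, with a weaker echo in the
opposite direction.

Quantifying this footprint from paired-end amplicon deep sequencing takes a
chain of small but consequential processing decisions: merging read pairs,
aligning to the amplicon, counting alleles, separating signal from parental
background, and classifying read-level diversity. `evolvamp` implements
that chain as a deterministic, testable pipeline, together with a forward
simulator of the mutational process so every stage can be validated against
known ground truth.

## Pipeline model

**Merging.** The amplicon is short enough that the 2x150 bp mates overlap.
Pairs merge only when an offset exists at which every overlapping base call
agrees exactly (`max_mismatch = 0`); candidate offsets shorter than
`min_overlap` (default 20 bp) are not considered, because with zero
mismatches allowed a random few-bp agreement is common and would otherwise
masquerade as a merge. Two distinct offsets tied at the maximal overlap
indicate repetitive sequence; such pairs are rejected as ambiguous rather
than resolved arbitrarily. Overlap qualities take the maximum of the mates'
phred scores, capped at 40 (the cap also applies on input). The practical
consequence of the exact-agreement rule is that a merged base call is backed
by two independent reads, which suppresses sequencing error in everything
downstream roughly quadratically.

**Alignment.** The reference is a single short amplicon, so instead of an
index-based mapper the pipeline uses an exact glocal dynamic program: global
in the read, local in the reference, affine gaps (a gap of length $g$ costs
`gap_open` $+ g\,\cdot$ `gap_extend`; defaults $+1/-4/-6/-1$ for
match/mismatch/open/extend). Exact DP removes mapper-version
nondeterminism; equal-scoring alternatives resolve to the leftmost reference
offset with substitutions preferred over indels. Reads scoring below
$0.4 \times$ length are excluded as unalignable. Merged reads are
dereplicated before alignment, so runtime scales with the number of distinct
haplotypes rather than with depth.

**Pileup and the per-position profile.** Aligned reads are tallied per
reference position (A/C/G/T/deletion; insertions are anchored at the
following position and excluded from depth, as is N). The raw mutation
frequency at a position is the nonreference fraction of its depth.
Samples whose median depth over the targeted window falls below `min_depth`
(default 40000) are discarded; end regions are masked (`left_trim` /
`right_trim`, default 10 bp each, configurable because base-call quality at
amplicon termini varies by run). The adjusted frequency subtracts the mean
(or median) raw frequency of the parental control replicates, clips at
zero, and floors values below `1e-4` to zero — the floor encodes the scale
at which residual error is indistinguishable from signal.

**Read-level diversity.** Reads are projected through their alignments onto
the targeted window. Unique window strings are tallied; the Hamming
distance (defined only at equal length) and Levenshtein edit distance to
the reference window classify each string: a length change or
`edit < hamming` (compensating indels) flags an indel-bearing read, which
is removed. Unique reads occurring fewer than 5 times are dropped, and any
string occurring at least 5 times in the parental control is removed from
treated samples. Counts are normalized by the sample's mean window depth
(`depth_agg = "median"` is available; captions and methods of published
analyses disagree on this aggregate, and the difference is negligible at
uniform amplicon coverage). Substitutions of the surviving indel-free reads
are classified into the 12 ordered categories (4 transitions, 8
transversions).

Two summary fractions are reported. `fraction_mutated_all` is the mutational
load: the count-weighted share of indel-free window reads carrying at least
one substitution, before the occurrence/parental filters.
`fraction_mutated` is the filtered surface: summed counts of kept mutated
unique reads divided by mean depth — a post-filter read-total denominator
would be degenerate, since the parental filter removes the
reference-identical read itself.

**Reversion assay.** Phenotypic reversion frequency is selective CFUs over
total CFUs after scaling each count by its plating dilution; groups
summarize as the replicate median (with optional bootstrap CI), plus fold
change over a designated off-target control group. Reversion and stop-codon
suppression are not distinguishable by this assay and are deliberately not
attributed.

## The forward simulator

The generator emulates the directional footprint on a built-in synthetic
260-bp amplicon (it is not any genomic locus) whose central 100-bp targeted
window is flanked by four guide sites on alternating strands. Its
components:

- **Nick geometry.** The nick sits between protospacer bases 17 and 18,
  3 nt 5' of the PAM (the canonical SpCas9 cut position; `cut_offset` is
  configurable). The D10A variant nicks the strand complementary to the
  protospacer strand, H840A the protospacer strand; synthesis runs 5'→3'
  along the nicked strand, so a minus-strand nick mutagenizes leftward on
  the reference axis.
- **Footprint.** Per-molecule substitution probability
  $p(d) = \mathrm{peak\_rate}\cdot e^{-\mathrm{decay}\cdot d}$ at offset
  $d$ from the nick inside a forward window (default 40 bp), and
  $\mathrm{rev\_fraction}$ (default 0.25) of that inside a reverse window
  (default 15 bp). Defaults: `peak_rate = 0.02` (puts single-guide
  per-position frequencies on the observed $10^{-2}$ scale),
  `decay = 0.1`/bp (halves the rate every ~7 bp, so the forward window
  tapers rather than stepping), windows 40/15 bp as observed. The reverse
  fraction is a modeling choice; the opposite-direction increase is
  reported qualitatively as "smaller" without a published rate.
- **Multiplexing.** Nicks combine as independent events,
  $1-\prod_i(1-p_i)$. When two nicks on opposite strands lie within
  `dsb_max_dist` (default 100 bp) — the configuration that creates a
  double-strand break — the combined targeted probability is multiplied by
  `dsb_synergy` (default 1). The knob exists because double-strand-break
  repair plausibly has different fidelity than nick repair; no published
  value quantifies it, so super-additivity is off by default and enabled
  explicitly (the validation suite uses 3 as its example value).
- **Repair.** A templated mismatch becomes a mutation with `escape_prob`
  (default 0.6), multiplied by `msh6_multiplier` (default 1.5, the
  approximate ratio of mutated-read fractions reported between MMR-deficient
  and wild-type backgrounds) for the msh6-null genotype, clipped at 1.
- **Background.** A uniform per-base per-molecule rate (default `1e-4`)
  stands in for off-target mutation plus residual error surviving the
  both-mates-agree merge; the default matches the scale of the analysis'
  own flooring threshold. Runs emulating noisier conditions can raise it
  (the validation suite's standard recovery run uses `1e-3`).
- **Sequencing.** R1 is the first 150 bases of the molecule, R2 the
  reverse complement of the last 150; errors are independent per base,
  uniform over the three other bases; qualities are a constant phred 40.
  Substitutions only by default — the analysis removes indel reads, so
  substitution recovery is the acceptance surface; an indel-bearing read
  can be constructed directly where the indel filter needs exercising.

All randomness flows from a single integer seed; fixtures are
byte-reproducible.

### What the simulator does not emulate

No PCR amplification bias or chimeras, no per-cycle quality decay, no
sequence-context dependence of polymerase errors, no correlated error
between mates, and no indel component of the polymerase error spectrum.
Passing tests therefore demonstrate that the *pipeline arithmetic* is
correct under a faithful rendering of the directional model — not that real
libraries are free of the artifacts above. On real data the parental
control absorbs position-specific PCR/sequencing artifacts, which is
exactly why the subtraction and string-removal steps exist.

## Numerical and design choices

- **Coordinates** are 0-based half-open internally; report files are
  1-based. One conversion pair, tested by inversion.
- **Depth cap** (600000, far above desk-scale depth) applies in input
  order; with dereplicated weighted reads the haplotype crossing the cap
  contributes its remaining headroom, deterministically.
- **Degenerate inputs**: N is allowed in reads (never matches; excluded
  from depth and from substitution calls) and forbidden in the reference;
  zero-depth positions drop with a warning; over-trimming, empty parental
  sets, unknown scenarios, and desynchronized pair files are errors.
- **Window clipping** for read-level analysis defaults to the reference's
  annotated targeted window. Published descriptions of the corresponding
  clipping step are amplicon-specific and ambiguous, so the offsets are
  configuration, not constants.
- **Parental aggregation** defaults to the mean across replicates
  (variance-minimizing; median selectable) — published methods name the
  plural "samples" without an aggregation rule.
- **Occurrence-filter censoring.** A fixed count threshold (≥5) interacts
  with depth: at depth $n$, any background process with per-string rate
  above $\sim 5/n$ puts *every* single-substitution string over the
  parental threshold, and parental string-removal would then delete all
  single-substitution haplotypes from treated samples. The published
  filter implicitly relies on low post-merge error; the simulator's default
  background respects that regime. Statistics meant to track total
  mutational load (synergy comparisons, spectrum shares) are therefore
  computed on the unfiltered indel-free table, where the count threshold
  cannot censor rare multi-substitution haplotypes.

## Validation problem sizes

The test suite validates parameter recovery on a 200000-molecule
error-free run (relative error of the adjusted profile below 15% where the
truth is at least $10^{-2}$; peak located at the nick-adjacent base;
forward > reverse > background at 3-SE separation), synergy and spectrum
recovery on 40000–80000-molecule runs, merging against its closed-form
rejection rate on 2000 error-injected pairs, and the aligner and edit
distance against exhaustive DP oracles on hundreds of short random cases.
`scripts/acceptance.R` re-runs the same computations from scratch and
writes the resulting numbers as JSON.

## A worked run

```{r example, eval = FALSE}
fx <- make_fixture(seed = 1, scenario = "multiplexed-4",
                   n_molecules = 50000)
res <- run_all(fx$config)

prof <- res$profiles[[1]]
head(prof[prof$retained & prof$adjusted > 0, ])

rl <- res$readlevel[[1]]
rl$summary
rl$spectra$substitution_spectrum
```

Outputs land in `fx$config$output_dir` as sorted TSV (pileups, profiles,
unique reads, spectra, summaries), alongside `run_log.txt` (per-stage read
and filter tallies, so every discarded read or sample is accounted for) and
`config.yaml` (the exact configuration; re-running it reproduces the
outputs byte for byte).

## Known limitations

Exact-match merging discards pairs with any overlap disagreement, so
effective depth falls quickly as raw error rises (the closed form
$1-(1-e)^{2\cdot\mathrm{overlap}}$ is tested); haplotype identity is exact
string identity (no clustering or denoising); the per-position profile does
not model linkage between positions; and the count-threshold censoring
described above is inherent to fixed-occurrence filters at finite depth.
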