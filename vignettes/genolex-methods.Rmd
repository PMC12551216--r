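---
title: "Linguistic statistics of coding and non-coding DNA: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linguistic statistics of coding and non-coding DNA: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, which
choices were genuinely open, how they were settled, and what the
synthetic-data tests do and do not demonstrate about real genomes.

## The analysis in one paragraph

Given a genome sequence and its feature annotations, the pipeline
partitions every position into *coding* (the merged union of CDS
feature intervals, by default) or *non-coding* (the complement), and
computes, per region class: the k-mer rank–frequency table and its OLS
Zipf exponent; a discrete maximum-likelihood power-law fit of the k-mer
count distribution with data-driven lower cutoff and AIC/BIC comparison
against lognormal and exponential alternatives; the scaling exponent of
the purine–pyrimidine DNA walk by rescaled range and detrended
fluctuation analysis; and Shannon block entropy with redundancy.
Bootstrap resampling quantifies uncertainty, and permutation or
Markov-chain nulls give empirical p-values that guard against
attributing "linguistic" structure to composition or low-order
dependencies alone.

## Coordinates, partitioning and the two base-pair conventions

Internally every interval is 0-based half-open, converted from the
1-based inclusive coordinates of GenBank and GFF3 on ingest; this makes
interval arithmetic (union, complement, lengths) exact integer
operations with no fencepost ambiguity. Joined/compound feature
locations stay one feature with several intervals.

Coding base pairs are reported under **two conventions**: the merged
union (`coding_bp_union`, which with the non-coding complement always
sums exactly to the sequence length) and the raw per-feature sum
(`coding_bp_summed`, where overlapping features are double-counted).
Published coding/non-coding totals for annotated genomes sometimes add
up to slightly more than the chromosome length, which is the signature
of the second convention; reporting both lets a reader reconcile either
style. For the Yarrowia lipolytica chromosome NC_090774.1 the published
totals exceed the sequence length by 140 bp, so the replication test
accepts a match under either convention and flags the discrepancy
rather than guessing which feature types or overlap rules produced it.

Minus-strand CDS features are analysed on the forward strand as stored.
k-mer spectra are not strand-symmetric, so this is a real choice; the
forward strand is the simpler, fully reproducible default, and
reverse-complementing per feature is left to the caller who has a
biological reason for it.

## k-mer counting and the Zipf fit

Windows slide within each region segment independently — concatenating
segments first would fabricate junction tokens that exist in no
molecule. Windows containing any non-ACGT symbol are skipped and
tallied, never silently dropped. The default window step is 1
(overlapping); a step equal to k gives non-overlapping block counts,
and because the right choice for replicating published trigram numbers
is not documented anywhere, the pipeline reports the non-overlapping
and tail-trimmed variants in a sensitivity block alongside the
headline fit.

Ranking breaks count ties lexicographically, making the table — and
every statistic downstream of it — bit-reproducible. The Zipf exponent
is the negated OLS slope of log10 relative frequency on log10 rank over
all non-zero ranks by default (at k = 3 the vocabulary is at most 64,
so no tail trimming is needed); the slope is identical for counts or
relative frequencies. r² is computed directly from the residuals; a
flat table (all counts equal) has zero total sum of squares and r² is
reported as NA rather than provoking a spurious perfect-fit answer.

## Discrete power-law fitting

k-mer counts are integers, so the power law is fitted in its discrete
form, `p(x) = x^(−α) / ζ(α, xmin)`, with the Hurwitz zeta
normalization. The implementation evaluates ζ(α, q) by a 1000-term
partial sum plus an Euler–Maclaurin tail, which is free of the
catastrophic cancellation that a "Riemann zeta minus head" formulation
suffers at large α, and is cross-checked in the tests against an
independent zeta implementation. α is found by golden-section
maximization of the exact log-likelihood on (1, 20]; tests verify it
against a brute-force likelihood grid at 10⁻⁴ resolution on 100 seeded
samples.

When `xmin` is free, every observed value (keeping at least two tail
observations) is a candidate, and the cutoff minimizing the
Kolmogorov–Smirnov distance between the tail empirical CDF and the
fitted CDF wins. Both CDFs are step functions with atoms on the
integers, so the sup-norm is evaluated at the observed support points
only — inserting the "just below the atom" comparison appropriate for
continuous models would inflate the distance by the full mass of the
largest atom. Alternatives (lognormal, exponential) are discretized by
the probability mass between consecutive integers and truncated at the
same cutoff, so all three likelihoods live on the identical sample; the
exponential MLE has a closed form, the lognormal is fitted by
Nelder–Mead with upper-tail-difference evaluation to avoid underflow.
Degenerate inputs (all values identical) are an error, not a fit.

Bootstrap confidence intervals are percentile intervals — at up to
10,000 replicates the added machinery of BCa buys little — with
multinomial resampling of token counts for rank-frequency tables and
iid resampling for plain value vectors. For `mle_alpha` the cutoff is
held at the original fit's value inside the resamples; re-selecting
xmin per replicate is supported by refitting manually but is an order
of magnitude slower and changes little at the sample sizes used here.

## DNA walk and scaling exponents

A, G map to +1 and C, T to −1; ambiguous symbols are skipped and
counted. Both estimators use ~20 log-spaced window sizes from 16 to a
quarter of the series length, non-overlapping windows, partial end
windows discarded. R/S is the classical estimator: range of the
mean-adjusted cumulative sum over the window standard deviation,
averaged per scale; it carries a well-known upward small-sample bias on
uncorrelated input, which the tests acknowledge by allowing means up to
~0.6 on iid walks. DFA-1 detrends the cumulative profile linearly per
window (one shared QR decomposition per scale) and regresses log RMS
fluctuation on log scale; it is the headline estimator in the pipeline
report because it is the standard choice for DNA-walk scaling
exponents, with R/S printed alongside. A constant profile has zero
fluctuation at every scale and is reported as a degenerate-input error.

The walk for a region class is built on the concatenation of its
segments in genomic order. Junction steps are a vanishing fraction of
the series for genome-scale input; per-segment estimation is available
by calling `dfa()` on individual segments when segments are long enough
to support the scale range.

## Entropy

Base-2 logarithms throughout, so entropies are in bits and redundancy
is taken against the 2 bits/symbol maximum of the four-letter alphabet.
The plug-in estimator is the default: at genome scale its downward bias
at k ≤ 3 (order V/2n nats) is far below the differences of interest,
and it is transparent. Miller–Madow is available behind a flag for
short sequences. The conditional rate `h_k = H_k − H_{k−1}` is
non-increasing for the true distribution; observed increases are a
plug-in undersampling signature and are flagged rather than clipped.

## Null models

Permutation preserves composition exactly; Markov nulls of order 1 or 2
preserve the fitted transition structure. Chains are started from the
observed sequence's context distribution, the simplest seeded choice.
Contexts never observed get uniform rows and are flagged. Empirical
p-values use the add-one rule, `p = (b + 1)/(n + 1)`, so p is never
zero at finite n. Direction is declared per statistic — Zipf exponent
and DFA exponent test "larger than null", entropy tests "smaller" —
and recorded in the result.

One degeneracy worth knowing about: when a sequence is dominated by a
single repeated motif, the fitted order-1 chain becomes
quasi-deterministic and its samples can show *steeper* Zipf curves than
the data, so a Markov-null comparison loses power exactly when the
structure is most extreme. The null-power test therefore uses a
moderately skewed motif mixture (32 motifs of 4 bp, usage exponent
1.2, 10 kb), chosen by a power analysis of the check itself, where the
3-mer structure genuinely exceeds first-order dependencies.

## Linguistic laws

Heaps curves stream tokens in a seeded random segment order (so the
curve does not hinge on an arbitrary file ordering) and fit
`V = K n^β` by OLS on logs over the pre-saturation checkpoints; a
vocabulary saturated at every checkpoint returns the curve but refuses
the fit. For the law of abbreviation, frequencies of different token
lengths are not commensurate, so each top token is scored by its log2
enrichment over the uniform expectation for its length,
`log2(4^k · f)`; a negative Spearman correlation between length and
enrichment is the abbreviation signature. Menzerath's law uses the
intervals of multi-interval (joined) features as exon-like parts:
x = part count, y = mean part length, fitted as `y = a x^b` on logs,
requiring at least five distinct construct sizes.

## The synthetic-data generators

The generators define the conditions under which the pipeline is
validated:

* `gen_iid` — the uncorrelated, maximum-entropy null emulating
  coding-like statistics (α ≈ 0.5, flat Zipf, ~2 bits/symbol).
* `gen_zipf_motifs` — concatenation of a fixed random vocabulary (V
  motifs of length L, derived deterministically from the seed) with
  usage probability ∝ rank^(−s): power-law k-mer spectrum, depressed
  entropy, elevated redundancy — the non-coding-like profile.
* `gen_correlated` — fractional Gaussian noise synthesized by circulant
  embedding (Davies–Harte), thresholded at its median to ±1 and mapped
  to purines/pyrimidines. Dichotomization attenuates the realized
  scaling exponent slightly: calibration runs over 20 seeds at n = 2¹⁶
  measured mean DFA exponents of 0.504, 0.679, 0.777 and 0.871 for
  targets 0.5, 0.7, 0.8 and 0.9, and the recovery tests use bands of
  roughly ±0.06 around those attenuated means (e.g. [0.63, 0.75] for
  target 0.7; [0.81, 0.93] for 0.9).
* `gen_toy_genome` — alternating 5 kb coding-like and non-coding-like
  blocks (10 blocks by default), emitted as FASTA + GFF3 with a
  ground-truth JSON sidecar; tests assert against the sidecar, never
  against copied numbers.

Every generator is a pure function of (spec, seed); regeneration is
byte-identical.

What these fixtures do **not** emulate: codon structure and
reading-frame periodicity in real coding sequence, isochores and GC
heterogeneity, repeat families, or annotation noise. Passing the
toy-genome tests shows the estimators recover designed contrasts of
exactly the kind claimed for real genomes; it does not by itself
establish those contrasts in any particular organism — that is what the
NC_090774.1 replication path is for, which requires fetching the
record once with `inst/scripts/fetch_ncbi.sh`.

## Problem sizes and reproducibility

The test suite validates estimator behaviour at deliberately moderate
sizes — walks of 2¹⁴–2¹⁶ steps, toy genomes of 20–50 kb, 100-sample
likelihood-grid comparisons, 200-replicate bootstrap-coverage runs —
sizes at which every property under test is already stable while the
whole suite stays fast. All randomness flows through explicit integer
seeds via an internal scoped-RNG helper that never touches the global
RNG state, and derived child seeds stay below 2³¹. The pipeline's
determinism contract is byte-level: identical configuration and seed
reproduce `report.json` exactly.

## Known limitations

* The GenBank parser covers the location grammar found in NCBI
  nucleotide records (`join`, `complement`, `order`, fuzzy ends); it is
  not a validator for arbitrary INSDC files.
* OLS on log–log rank-frequency axes is a descriptive slope, kept
  because it is how published Zipf exponents for trigrams are defined;
  the MLE machinery is the statistically principled route and both are
  reported.
* R/S carries small-sample bias; prefer DFA-1 for short inputs.
* Markov nulls lose power against quasi-deterministic repetition (see
  above); permutation nulls do not capture dinucleotide constraints —
  an Euler-shuffle null preserving exact dinucleotide counts would be a
  useful extension.
* Heaps' and abbreviation analyses are property-tested only; no
  published quantitative targets exist for them on DNA.
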