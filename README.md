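# genolex

Quantitative "DNA linguistics" in R: partition an annotated genome into
coding and non-coding regions and measure, in each, the
linguistic-statistical signatures that have repeatedly been compared
with natural language — the Zipf rank-frequency law of k-mers,
power-law behaviour of the k-mer count distribution, long-range
correlations of the purine–pyrimidine DNA walk, and Shannon
entropy/redundancy — with bootstrap uncertainty and permutation/Markov
null models to keep the comparisons honest.

The package is aimed at researchers studying statistical structure in
genomic sequence: it gives a one-call pipeline for the coding vs
non-coding contrast, the individual estimators as composable functions,
and seeded generators for synthetic sequences and annotated toy genomes
with known ground truth.

## The statistics it computes

* **Zipf rank–frequency.** k-mer tokens are counted per region segment
  (overlapping windows by default; no tokens span region junctions),
  ranked, and fitted on log–log axes: `f_r ∝ r^(−ζ)`, with ζ the Zipf
  exponent (reported as the positive magnitude of the OLS slope).
* **Discrete power-law MLE.** For k-mer count distributions,
  `p(x) ∝ x^(−α)` on integers `x ≥ xmin`, normalized by the Hurwitz
  zeta function; `xmin` is selected by minimizing the Kolmogorov–Smirnov
  distance between the tail empirical CDF and the fitted CDF, and the
  model is compared against discretized lognormal and exponential
  alternatives by AIC/BIC on the identical tail. Percentile bootstrap
  (up to 10,000 iterations) gives confidence intervals.
* **DNA-walk scaling.** Purines (A,G) map to +1, pyrimidines (C,T) to
  −1; the Hurst/scaling exponent of the cumulative walk is estimated by
  classical rescaled range (R/S) and detrended fluctuation analysis
  (DFA-1): `F(s) ∝ s^α`, with α = 0.5 for an uncorrelated walk and
  α > 0.5 for persistent long-range correlation.
* **Entropy and redundancy.** Shannon block entropy `H_k` in bits,
  `H_k/k` bits per symbol, and redundancy `1 − H_k/(2k)` against the
  2-bit maximum of the four-letter alphabet, plus the conditional
  entropy rate `h_k = H_k − H_{k−1}`.
* **Linguistic laws.** Heaps' vocabulary growth `V ≈ K n^β`, Zipf's law
  of abbreviation (length vs frequency enrichment), and Menzerath's law
  `y = a x^b` over multi-interval features (exon-like parts).
* **Null models.** Random permutations and first-/second-order Markov
  chains fitted to the observed sequence, with add-one empirical
  p-values for any of the named statistics.

## Worked example

```r
library(genolex)

# a 50 kb annotated toy genome: 5 coding-like iid blocks alternating
# with 5 non-coding-like Zipf-motif blocks of 5 kb each
tg  <- gen_toy_genome(toy_genome_spec(seed = 11))
rep <- run_replication(tg$fasta, tg$gff3, "gff3", seed = 5)
rep
#> <replication_report> toy_genome - 50,000 bp, 5 features
#>   coding: 25,000 bp (union) / 25,000 bp (summed); non-coding: 25,000 bp
#>   coding     zeta = 0.0509 (r2 = 0.784)  H_dfa = 0.5199  H1 = 2.000 bits/sym  red_k = 0.0003
#>   noncoding  zeta = 0.4776 (r2 = 0.878)  H_dfa = 0.6842  H1 = 1.976 bits/sym  red_k = 0.0266

compare_regions(rep)
#>                      feature       coding  noncoding        direction
#> 1 correlation_exponent_alpha 0.5199300131 0.68415399 noncoding>coding
#> 2         zipf_exponent_zeta 0.0508629862 0.47757816 noncoding>coding
#> 3      zipf_loglog_r_squared 0.7839447137 0.87770224 noncoding>coding
#> 4    entropy_bits_per_symbol 1.9993693822 1.94684564 coding>noncoding
#> 5                 redundancy 0.0003153089 0.02657718 noncoding>coding
```

Reading the output: the motif-built non-coding blocks show a much
steeper Zipf slope (ζ = 0.48 vs 0.05), a better power-law alignment of
the log–log points (r² 0.88 vs 0.78), persistent long-range correlation
in the DNA walk (α = 0.68 vs 0.52), slightly lower entropy and ~80-fold
higher 3-mer redundancy than the iid coding-like blocks — the designed
contrast, recovered end to end from FASTA + GFF3 input.

The discrete power-law machinery works standalone:

```r
x <- rpowerlaw_discrete(10000, alpha = 2.5, xmin = 1, seed = 42)
fit_powerlaw_discrete(x)
#> <powerlaw_fit> alpha = 2.4952  xmin = 1  KS = 0.0020  n_tail = 10000
```

A thin command-line wrapper is included:

```sh
Rscript inst/scripts/genolex.R run --fasta genome.fa --features ann.gff3 \
    --k 3 --nboot 200 --seed 1 --out results/
Rscript inst/scripts/genolex.R simulate --spec spec.json --seed 3 --out sim/
Rscript inst/scripts/genolex.R fit-powerlaw --input counts.txt
```

`run` writes `report.json`, `zipf_coding.tsv`, `zipf_noncoding.tsv`,
`loglog_points.tsv` and `partition.bed`; reruns with the same seed and
configuration are byte-identical.

To run the full published-genome replication (Yarrowia lipolytica
chromosome NC_090774.1), fetch the record once with
`inst/scripts/fetch_ncbi.sh` (network required) and pass the cached
FASTA/GenBank pair to `run_replication()`.

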