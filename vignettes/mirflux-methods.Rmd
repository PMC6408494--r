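---
title: "mirflux: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirflux: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirflux)
```

# The quantification model

Small-RNA reads are short enough (18–24 nt) that a non-trivial fraction
maps to several genomic positions — miRNA paralog families are the
canonical cause, since distinct loci can produce an identical mature
sequence. `mirflux` resolves this with a two-pass weighted assignment:

1. Every retained mapping position of a read (primary plus secondary
   alignments, capped at `position_cap = 100`; reads exceeding the cap
   are discarded entirely, as a mapper run with a report limit of 100
   and a suppression limit of 101 would do) is intersected with the
   annotation by strand-aware interval overlap of at least 1 bp.
2. **Pass 1** enumerates all (position, mature miRNA) overlap pairs.
   Only when a read has *no* mature overlap does **pass 2** enumerate
   (position, precursor) pairs — the read is then evidence for the
   hairpin but not for a processed arm.
3. The read's unit weight is split equally over its k pairs, so every
   assigned read contributes total weight exactly 1, and column sums of
   the count table can never exceed the number of assigned reads.

Assumptions worth stating: overlap is binary (1 bp suffices — mature
annotations are much longer than the positional jitter of real reads);
assignment is position-based only, with no sequence re-examination; and
the two passes are exclusive by construction, so precursor counts never
absorb reads that already have a mature explanation.

## Decisions where the convention was genuinely open

* **Pair-level vs miRNA-level weights.** When one miRNA is overlapped at
  two retained positions of the same read, the default gives it weight
  2/k (pair-level). The alternative — collapse to distinct miRNAs first
  — is `collapse = "mir"`. Pair-level is the default because it treats
  every reported alignment as equal evidence and keeps the assignment a
  pure function of the (position, feature) overlap multiset; both modes
  conserve per-read weight 1.
* **Strandedness.** miRNA annotation is strand-specific, so overlap
  requires matching strands by default; `ignore_strand = TRUE` exists
  for unstranded protocols.
* **CPM denominator.** Mapped reads that overlap no annotation still
  occupied sequencing depth; they count in the library size by default
  (pass `library_sizes = NULL` to `build_count_table()` to use assigned
  reads instead). Normalized column sums therefore reach 1e6 exactly
  only when every mapped read was assigned.
* **Coordinates.** GFF3 and SAM are 1-based inclusive; the package keeps
  that representation throughout rather than converting, since all
  interval arithmetic goes through `IRanges`, which is closed-interval
  native.

# Read preprocessing

`trim_policy()` defaults encode the published cleanup: clip leading and
trailing bases below Q3, then scan 5′→3′ with a window of 4 bases and
truncate at the start of the first window whose mean quality drops
below 15, then discard reads shorter than 18 bp. Two numerical details:

* Window means are compared via exact integer window *sums*
  (`sum < mean_threshold × window_len`), not floating-point means — a
  convolution-based moving average can sit 1 ulp below an integer
  threshold and truncate a read the exact arithmetic would keep.
* Adapter removal is a deliberate simplification: the leftmost full or
  3′-suffix occurrence (≥ `adapter_min_overlap` bases, ≤
  `adapter_max_mismatch` mismatches) of any configured adapter is cut,
  rather than a seed-and-extend scoring scheme. The original two-round
  score-based adapter pass is collapsed into this single configurable
  pass; for the synthetic data (which plants no adapter chimeras) this
  is exact, and for real data it is a documented approximation.

# Differential display filter

The differential stage is intentionally *only* the selection surface:
median-of-ratios size factors, baseMean over all samples, log2 fold
change of group means with pseudocount 0.5, and the filter |FC| > 1.5
and baseMean > 5 (both strict). No dispersion estimation, testing, or
shrinkage is performed — the package's claims are limited to the filter.
Two conventions adopted: "fold change > 1.5" is read on the linear scale
(|log2fc| > log2 1.5 ≈ 0.585), and the size-factor median is taken over
linear ratios (for an even number of all-positive features this differs
in the last decimals from a log-scale median, and the linear form is
what the per-feature-ratio definition states).

# Ago-RIP targetome scoring

RPKM = count / (length/1000) / (mapped/1e6) per gene and condition. The
expressed filter keeps genes with RPKM ≥ 1.0 in at least one condition —
the boundary is inclusive because the criterion names 1.0 as a passing
value. The enrichment score is the double difference

$$\mathrm{score} = (x_{\mathrm{Ago,mimic}} - x_{\mathrm{IgG,mimic}}) -
(x_{\mathrm{Ago,ctrl}} - x_{\mathrm{IgG,ctrl}}), \qquad
x = \log_2(\mathrm{RPKM} + c)$$

The defining formula does not say whether the differences are taken on
raw or log RPKM; because the target rule is phrased as a log2 fold
change being positive, the differences are computed on the log2 scale,
which makes the double difference itself a log2 fold change of ratios.
Both interpretations are available (`pseudocount = 0` gives the pure
log-ratio; raw-scale users can difference `rip_rpkm()` directly). The
default pseudocount c = 1 bounds the score for low-expression genes at
the cost of shrinking it toward 0; the shrinkage vanishes as expression
grows (tested as a monotone property). Targets are genes that are
expressed *and* score strictly positive — a score of exactly 0 is never
a target.

# qPCR analytics

* ΔΔCt assumes perfect doubling (base 2); an efficiency-adjusted mode
  uses base 1 + E with E from `fit_standard_curve()` (E = 10^(−1/slope)
  − 1, E = 1 at slope −1/log10 2 ≈ −3.3219 cycles per decade).
* Spike-in correction multiplies by 2^(spike Ct_sample − spike Ct_ref):
  one cycle of delayed spike amplification means half the material
  survived purification.
* Half-life: the default is OLS of ln(percent) on time — "exponential
  regression" is ambiguous between log-linear and nonlinear least
  squares, and the log-linear form is closed-form, exactly invertible,
  and exact on noiseless exponentials; `method = "nls"` provides the
  nonlinear fit as a sensitivity check (with a convergence-criterion
  offset so zero-residual data does not stall the iteration). For
  multiplicative lognormal noise the log-linear fit is also the natural
  estimator, since the noise is additive Gaussian on the log scale.

# What the synthetic data emulates — and what it does not

The generators are first-class, tested code; their defaults are the
study conditions every recovery property is stated under.

* **Reference** (`generate_reference`): precursors of 60–120 bp each
  containing mature arms of 18–24 nt, random strand, placed on a grid of
  150 bp slots so spacing is never pathological. A configurable fraction
  (default 0.2) of precursor loci is duplicated verbatim elsewhere and
  annotated as a paralog locus with its own ids — exactly the structure
  that produces true multimappers, and the reason a read from such a
  locus carries truth weight 0.5 per copy.
* **Reads** (`simulate_reads`): exact copies of mature sequences (or of
  a mature-free precursor window, to exercise pass 2), constant Q40.
  Multimapping arises *only* from genuine duplication, so the per-read
  truth is unambiguous and computable by exhaustive substring search —
  no mismatch model, no sequencing-error model, no adapter chimeras, no
  quality realism, no ligation bias. Passing tests therefore demonstrate
  correctness of the assignment logic, not robustness to alignment
  noise.
* **Count matrices** (`simulate_count_matrix`): negative-binomial counts
  for a control vs coculture design (default 4 per group, matching the
  profiled donor design; recovery properties are additionally exercised
  at 3 vs 3), expected depth 1e5 reads/sample over a lognormal abundance
  profile, planted log2 fold changes on named features. The default
  dispersion is 0.02 — cell-line-like technical variability, of the
  order of the asymptotic dispersion highly expressed features reach in
  NB fits of homogeneous material. This is a deliberate calibration: the
  display filter is a pure threshold with no test statistic, and its
  planted-truth property (≥0.95 sensitivity at FC 3 with zero false
  positives in ≥90% of seeds) is a property of the low-dispersion
  regime. At donor-level biological dispersion (~0.1) a bare |FC| > 1.5
  filter *will* admit false positives — which is precisely why real
  analyses put an NB test in front of it, and why this package claims
  only the filter.
* **RIP experiments** (`simulate_rip_experiment`): the planted effect
  lives on the RPKM scale (so it is invariant to the varying gene
  lengths of 500–5000 bp and per-condition depths around 2e6), IgG
  pulldowns capture a 25% nonspecific background, expected reads/gene
  default 100. Noiseless mode emits expected counts and holds the four
  depths equal so forward and inverse RPKM computations round
  identically — planted scores and null zeros are then recovered
  bit-exactly, which the strict `score > 0` target rule requires.
* **Decay series** (`simulate_decay_series`): 100·2^(−t/t½) with
  multiplicative lognormal noise (mean-one parameterization,
  `sdlog = sqrt(log(1 + cv²))`), renormalized so t = 0 reads exactly
  100 — the measurement convention of shutoff time courses. Default
  planted t½ 3.07 h over 0–8 h, 5% CV.

Determinism: each generator derives its own RNG stream from the master
seed via a stable string-hash sub-seed, so identical configs give
byte-identical outputs and adding one artifact never perturbs another.

# Problem sizes

Test and acceptance runs use deliberately small instances — toy genomes
of 2 × 10 kb, tens of annotations, hundreds of reads, 50-feature count
matrices at 1e5 reads/sample (20 seeds), 100-gene RIP experiments (100
seeds), 200 replicate decay series — chosen so the whole suite completes
in about a minute while each property is still measured at the depth its
statement requires.

# Known limitations

* The assigner consumes alignments; it does not produce them, and it
  never rescues reads a mapper suppressed.
* No isomiR resolution: counts are per annotated feature.
* The differential stage contains no statistical test; its output is
  heatmap/MA-plot membership, not significance.
* The RIP score operates on RPKM summaries; read-level RIP processing
  (library chemistry, strandedness) is out of scope, as is any
  seed-site sequence analysis.
* The adapter clipper is an approximation of score-based trimmers and
  is not validated against them.
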