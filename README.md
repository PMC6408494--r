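# mirflux

Quantifying microRNAs from small-RNA sequencing is complicated by
multimapping: a mature miRNA of ~22 nt often occurs at several genomic
loci (paralog families), so a read cannot always be attributed to a
single feature. `mirflux` implements a two-pass weighted assignment rule
for this problem, together with the downstream analytics used in studies
of tumor-educated macrophages: a fold-change/baseMean display filter for
differential miRNAs, Ago-RIP-Seq targetome scoring, and the qPCR-side
computations (ΔΔCt, standard curves, mRNA half-life regression, simple
morphometrics). Every input the pipeline consumes can be generated
synthetically with recorded ground truth, so the whole chain is testable
without any external download.

Intended users: bioinformaticians analysing small-RNA-seq or RIP-seq
experiments, and method developers who need a miRNA quantifier with a
verifiable truth model.

## The core model

**Two-pass weighted assignment.** After trimming (leading/trailing clip
below Q3, 5′→3′ sliding window of length 4 truncating where mean quality
drops below 15, reads < 18 bp discarded), each read's retained mapping
positions (at most 100; reads with more are dropped, mirroring a
`-k 100 -m 101` mapper call) are compared against miRBase-style
annotations by strand-aware interval overlap. Pass 1 considers mature
miRNAs only; only if a read overlaps no mature feature are precursor
hairpins considered in pass 2. If the read yields k (position, miRNA)
overlap pairs, each pair receives weight 1/k, so

```
Σ_pairs w(read, pair) = 1        for every assigned read.
```

Weighted counts sum into a features × samples table; depth normalization
is counts per million over mapped reads.

**Differential filter.** Counts are normalized by median-of-ratios size
factors; a miRNA is reported as differential when its absolute linear
fold change (coculture vs control group means, pseudocount 0.5) exceeds
1.5 **and** its baseMean (grand mean of normalized counts) exceeds 5.
This is deliberately the display filter only — no NB testing.

**Ago-RIP targetome.** For the 2×2 design (pan-Ago vs IgG pulldown ×
miR-375 mimic vs nonspecific control), genes passing an expressed filter
(RPKM ≥ 1.0 in ≥ 1 condition) are scored by the log2 double difference

```
score = (x_Ago.mimic − x_IgG.mimic) − (x_Ago.control − x_IgG.control),
x = log2(RPKM + pseudocount)
```

and called targets when the score is strictly positive.

**qPCR analytics.** Relative expression 2^(−ΔΔCt); spike-in recovery
correction by 2^(ΔCt of the spike); absolute copies from an OLS standard
curve of Ct on log10 copies (efficiency = 10^(−1/slope) − 1); mRNA
half-life ln 2 / k from a log-linear fit of percent remaining over time;
tumor volume 0.5·L·W²; percent gap closure relative to the 0 h area.

## Worked example

```r
library(mirflux)

cfg <- sim_config(seed = 42, n_precursors = 6, frac_multimapping = 0.3)
d   <- tempfile()
ref <- generate_reference(cfg, outdir = d)           # genome.fa + annotation.gff3
mat <- ref$annotation$id[ref$annotation$kind == "mature"]
sim <- simulate_reads(cfg, ref, setNames(rep(5L, length(mat)), mat), outdir = d)

q   <- quantify_sample(file.path(d, "alignments.sam"),
                       file.path(d, "annotation.gff3"))
tab <- build_count_table(list(s1 = q$assignments), features = ref$annotation$id,
                         library_sizes = c(s1 = q$n_mapped_reads))
tab
#> mir_count_table: 16 features x 1 samples
#> library sizes: s1=40
#>           s1
#> MI0001     0
#> MIMAT0001  5
#> MI0002     0
#> MIMAT0002  5
#> ...
all.equal(tab$counts[, "s1"], sim$truth$counts)
#> [1] TRUE
```

Every one of the 40 simulated reads was assigned with total weight 1;
reads from the duplicated (paralog) loci were split 0.5/0.5 between the
two copies, and the weighted table equals the simulator's ground truth
exactly. The same works for the RIP arm — a planted +2 log2 target
scores exactly 2 in noiseless mode and is called a target — and for
decay series:

```r
s <- simulate_decay_series(sim_config(seed = 9, decay_halflife_h = 3.07,
                                      noise_cv = 0.05))
fit_decay(s)
#> decay_fit (loglinear): k = 0.2136 /h, t1/2 = 3.245 h, R^2 = 0.9993
```

i.e. a 3.07 h half-life recovered to ~6% from a single 5-point series
with 5% multiplicative noise.

A thin CLI over the same functions is at `inst/scripts/mirflux.R`
(subcommands `simulate`, `trim`, `quantify`, `de`, `rip-score`, `qpcr`,
`run`); `run_pipeline()` executes any subset of stages from a YAML
config and writes a manifest with per-file MD5 digests.

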