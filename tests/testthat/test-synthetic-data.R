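test_that("reference generation respects miRNA geometry and containment", {
  ref <- generate_reference(sim_config(seed = 42, n_precursors = 8,
                                       mature_per_precursor = 2,
                                       frac_multimapping = 0))
  ann <- ref$annotation
  prec <- ann[ann$kind == "precursor", ]
  mat <- ann[ann$kind == "mature", ]
  expect_equal(nrow(prec), 8)
  expect_equal(nrow(mat), 16)
  expect_true(all(prec$end - prec$start + 1 >= 60 &
                    prec$end - prec$start + 1 <= 120))
  expect_true(all(mat$end - mat$start + 1 >= 18 &
                    mat$end - mat$start + 1 <= 24))
  # every mature lies inside its precursor, same chrom and strand
  idx <- match(mat$derives_from, prec$id)
  expect_false(anyNA(idx))
  expect_true(all(mat$chrom == prec$chrom[idx]))
  expect_true(all(mat$strand == prec$strand[idx]))
  expect_true(all(mat$start >= prec$start[idx] & mat$end <= prec$end[idx]))
})

test_that("without duplication every mature sequence is genomically unique", {
  ref <- generate_reference(sim_config(seed = 7, n_precursors = 10,
                                       frac_multimapping = 0))
  mat <- ref$annotation[ref$annotation$kind == "mature", ]
  for (i in seq_len(nrow(mat))) {
    s <- as.character(Biostrings::subseq(ref$genome[[mat$chrom[i]]],
                                         mat$start[i], mat$end[i]))
    n_occ <- sum(vapply(names(ref$genome), function(ch) {
      length(Biostrings::matchPattern(s, ref$genome[[ch]])) +
        length(Biostrings::matchPattern(
          Biostrings::reverseComplement(Biostrings::DNAString(s)),
          ref$genome[[ch]]))
    }, numeric(1)))
    expect_equal(n_occ, 1)
  }
})

test_that("duplicated loci carry a verbatim copy annotated as a paralog", {
  ref <- generate_reference(sim_config(seed = 3, n_precursors = 4,
                                       frac_multimapping = 0.5))
  ann <- ref$annotation
  paralogs <- ann[grepl("_2$", ann$id) & ann$kind == "precursor", ]
  expect_equal(nrow(paralogs), 2)
  for (i in seq_len(nrow(paralogs))) {
    src <- ann[ann$id == sub("_2$", "", paralogs$id[i]), ]
    s1 <- as.character(Biostrings::subseq(ref$genome[[src$chrom]],
                                          src$start, src$end))
    s2 <- as.character(Biostrings::subseq(ref$genome[[paralogs$chrom[i]]],
                                          paralogs$start[i], paralogs$end[i]))
    expect_identical(s1, s2)
  }
})

test_that("reference generation is byte-deterministic and fails on overfull genomes", {
  d1 <- tempfile(); d2 <- tempfile()
  cfg <- sim_config(seed = 99, n_precursors = 5)
  generate_reference(cfg, d1)
  generate_reference(cfg, d2)
  for (f in c("genome.fa", "annotation.gff3"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  expect_error(generate_reference(sim_config(seed = 1, n_chromosomes = 1,
                                             chrom_length = 300,
                                             n_precursors = 50)),
               "does not fit")
})

test_that("simulated reads list every genomic occurrence and truth weights conserve", {
  cfg <- sim_config(seed = 5, n_precursors = 6, frac_multimapping = 0.5)
  ref <- generate_reference(cfg)
  mat <- ref$annotation$id[ref$annotation$kind == "mature"]
  sim <- simulate_reads(cfg, ref, stats::setNames(rep(2L, length(mat)), mat))
  # read-truth consistency: re-discover occurrences by substring search
  for (rid in unique(sim$reads$id)) {
    s <- sim$reads$seq[sim$reads$id == rid]
    expected <- 0L
    for (ch in names(ref$genome)) {
      expected <- expected +
        length(Biostrings::matchPattern(s, ref$genome[[ch]])) +
        length(Biostrings::matchPattern(
          Biostrings::reverseComplement(Biostrings::DNAString(s)),
          ref$genome[[ch]]))
    }
    expect_equal(sum(sim$alignments$qname == rid), expected)
  }
  # conservation: per-read truth weights sum to 1
  sums <- tapply(sim$truth$assignments$weight,
                 sim$truth$assignments$read_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # multimapped mature reads split 0.5/0.5 over the two loci
  dup_mats <- grep("_2$", ref$annotation$id[ref$annotation$kind == "mature"],
                   value = TRUE)
  for (m2 in dup_mats) {
    m1 <- sub("_2$", "", m2)
    w <- sim$truth$assignments[sim$truth$assignments$mir_id %in% c(m1, m2), ]
    expect_true(all(abs(w$weight - 0.5) < 1e-12))
  }
})

test_that("unique-locus reads yield exactly one SAM record; empty and error cases", {
  cfg <- sim_config(seed = 8, n_precursors = 4, frac_multimapping = 0)
  ref <- generate_reference(cfg)
  mat <- ref$annotation$id[ref$annotation$kind == "mature"]
  sim <- simulate_reads(cfg, ref, stats::setNames(1L, mat[1]))
  expect_equal(nrow(sim$alignments), 1)
  expect_equal(sim$alignments$flag %% 32 %in% c(0, 16), TRUE)

  d <- tempfile()
  empty <- simulate_reads(cfg, ref, stats::setNames(integer(0), character(0)),
                          outdir = d)
  expect_equal(nrow(empty$reads), 0)
  expect_identical(readLines(file.path(d, "reads.fastq")), character(0))
  sam <- readLines(file.path(d, "alignments.sam"))
  expect_true(all(startsWith(sam, "@")))

  expect_error(simulate_reads(cfg, ref, c(nonexistent = 5L)), "unknown")
})

test_that("count matrix plants fold changes recoverable by Monte Carlo", {
  lfc <- c(F003 = 3)
  ratios <- vapply(1:200, function(s) {
    sim <- simulate_count_matrix(sim_config(seed = s, n_features = 10,
                                            n_per_group = 2,
                                            reads_per_sample = 20000,
                                            planted_log2fc = lfc))
    m <- sim$table$counts
    mean(m["F003", sim$groups == "coculture"]) /
      mean(m["F003", sim$groups == "control"])
  }, numeric(1))
  expect_equal(mean(ratios), 8, tolerance = 0.05)

  # null case: no planted effect, high depth, group ratio near 1
  sim0 <- simulate_count_matrix(sim_config(seed = 1, n_features = 20,
                                           reads_per_sample = 1e6))
  m <- sim0$table$counts
  r <- rowMeans(m[, sim0$groups == "coculture"]) /
    rowMeans(m[, sim0$groups == "control"])
  expect_true(all(abs(log2(r)) < 0.5))
  expect_identical(sim0$truth$true_de_set, character(0))

  # determinism and error path
  a <- simulate_count_matrix(sim_config(seed = 2))
  b <- simulate_count_matrix(sim_config(seed = 2))
  expect_identical(a$table$counts, b$table$counts)
  expect_error(sim_config(nb_dispersion = 0), "nb_dispersion")
})

test_that("RIP simulator plants the double-difference on the RPKM scale", {
  cfg <- sim_config(seed = 6, n_genes = 30,
                    planted_rip_targets = c(G005 = 2, G010 = 1.5))
  sim <- simulate_rip_experiment(cfg, noiseless = TRUE)
  sc <- enrichment_score(rip_rpkm(sim$experiment), pseudocount = 0)
  names(sc) <- rownames(sim$experiment$counts)
  expect_equal(unname(sc["G005"]), 2)
  expect_equal(unname(sc["G010"]), 1.5)
  expect_true(all(sc[setdiff(names(sc), c("G005", "G010"))] == 0))
  expect_setequal(sim$truth$true_target_set, c("G005", "G010"))
  # determinism
  sim2 <- simulate_rip_experiment(cfg, noiseless = TRUE)
  expect_identical(sim$experiment$counts, sim2$experiment$counts)
})

test_that("decay series follows the closed form and renormalizes t=0 to 100", {
  s <- simulate_decay_series(sim_config(seed = 1, decay_halflife_h = 2,
                                        noise_cv = 0), c(0, 2, 4, 8))
  expect_equal(s$percent_remaining, c(100, 50, 25, 6.25))
  sn <- simulate_decay_series(sim_config(seed = 1, noise_cv = 0.05),
                              c(0, 1, 2, 4, 8))
  expect_equal(sn$percent_remaining[1], 100)
  expect_error(simulate_decay_series(sim_config(seed = 1), c(-1, 0, 2)),
               "negative")
  # log-linear slope of a lightly noisy series approximates -ln2 / t_half
  slopes <- vapply(1:100, function(seed) {
    s <- simulate_decay_series(sim_config(seed = seed, noise_cv = 0.05),
                               c(0, 2, 4, 6, 8))
    unname(coef(stats::lm(log(s$percent_remaining) ~ s$timepoints_h))[2])
  }, numeric(1))
  expect_equal(median(slopes), -log(2) / 3.07, tolerance = 0.05)
})
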