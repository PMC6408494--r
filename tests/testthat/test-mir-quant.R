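gff_lines <- function(rows) {
  c("##gff-version 3",
    vapply(rows, function(r)
      paste(r$chrom, "synthetic", r$type, r$start, r$end, ".", r$strand, ".",
            r$attr, sep = "\t"), character(1)))
}

test_that("GFF3 parsing resolves Derives_from links and tolerates unknown types", {
  f <- tempfile(fileext = ".gff3")
  writeLines(gff_lines(list(
    list(chrom = "chr1", type = "miRNA_primary_transcript", start = 100,
         end = 180, strand = "+", attr = "ID=MI0001;Name=syn-mir-1"),
    list(chrom = "chr1", type = "miRNA", start = 110, end = 131,
         strand = "+", attr = "ID=MIMAT0001;Name=syn-miR-1;Derives_from=MI0001"),
    list(chrom = "chr1", type = "gene", start = 500, end = 600,
         strand = "+", attr = "ID=other"))), f)
  expect_warning(ann <- parse_annotation(f), "unknown type")
  expect_equal(nrow(ann), 2)
  expect_identical(ann$kind, c("precursor", "mature"))
  expect_identical(ann$derives_from[ann$kind == "mature"], "MI0001")
  expect_equal(ann$length, c(81L, 22L))
})

test_that("GFF3 parsing of an empty file gives an empty set; bad containment errors", {
  f <- tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", f)
  expect_equal(nrow(parse_annotation(f)), 0)

  f2 <- tempfile(fileext = ".gff3")
  writeLines(gff_lines(list(
    list(chrom = "chr1", type = "miRNA_primary_transcript", start = 100,
         end = 180, strand = "+", attr = "ID=MI0001;Name=p"),
    list(chrom = "chr1", type = "miRNA", start = 300, end = 321,
         strand = "+", attr = "ID=MIMAT1;Name=m;Derives_from=MI0001"))), f2)
  expect_error(parse_annotation(f2), "not contained")
})

test_that("round trip: written GFF3 is parsed back identically", {
  ref <- generate_reference(sim_config(seed = 10, n_precursors = 5,
                                       mature_per_precursor = 2,
                                       frac_multimapping = 0.2))
  f <- tempfile(fileext = ".gff3")
  write_mir_gff3(ref$annotation, f)
  ann <- parse_annotation(f)
  orig <- ref$annotation[order(ref$annotation$id), ]
  back <- ann[order(ann$id), names(orig)]
  rownames(orig) <- rownames(back) <- NULL
  expect_equal(back, orig)
})

write_test_sam <- function(records, path, sq = c(chr1 = 5000L, chr2 = 5000L)) {
  con <- file(path, "wb")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", names(sq), sq),
               records), con)
  close(con)
  path
}

test_that("alignment loading collects all positions, derives ends from CIGAR, caps reads", {
  sam <- write_test_sam(c(
    "r1\t0\tchr1\t100\t255\t22M\t*\t0\t0\t*\t*",
    "r2\t0\tchr1\t200\t255\t10M5N10M\t*\t0\t0\t*\t*",
    "r2\t256\tchr2\t300\t255\t25M\t*\t0\t0\t*\t*",
    "r2\t272\tchr1\t400\t255\t25M\t*\t0\t0\t*\t*",
    "r3\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*"), tempfile(fileext = ".sam"))
  aln <- load_alignments(sam)
  expect_equal(aln$n_mapped_reads, 2)
  p1 <- aln$positions[aln$positions$read_id == "r1", ]
  expect_equal(p1$end, 121)                       # 22M span
  p2 <- aln$positions[aln$positions$read_id == "r2", ]
  expect_equal(nrow(p2), 3)                       # primary + 2 secondary
  expect_equal(sort(p2$end), c(224, 324, 424))    # 10M5N10M spans 25 bp
  expect_setequal(p2$strand[p2$start == 400], "-")
})

test_that("reads exceeding the position cap are discarded entirely", {
  recs <- sprintf("deep\t%d\tchr1\t%d\t255\t20M\t*\t0\t0\t*\t*",
                  c(0L, rep(256L, 100L)), seq(1, by = 30, length.out = 101))
  sam <- write_test_sam(c(recs, "ok\t0\tchr1\t4000\t255\t20M\t*\t0\t0\t*\t*"),
                        tempfile(fileext = ".sam"))
  aln <- load_alignments(sam, position_cap = 100)
  expect_equal(aln$n_discarded, 1)
  expect_identical(unique(aln$positions$read_id), "ok")
  # cap 101 retains the read
  aln2 <- load_alignments(sam, position_cap = 101)
  expect_equal(aln2$n_discarded, 0)
  expect_equal(sum(aln2$positions$read_id == "deep"), 101)
})

toy_ann <- function() {
  data.frame(
    id = c("matA", "matB", "precP"),
    name = c("matA", "matB", "precP"),
    kind = c("mature", "mature", "precursor"),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(100L, 500L, 900L),
    end = c(121L, 521L, 980L),
    strand = c("+", "+", "+"),
    derives_from = c(NA, NA, NA),
    stringsAsFactors = FALSE)
}

test_that("two-pass assignment weights and pass exclusivity on hand-built cases", {
  ann <- toy_ann()
  mk <- function(df) list(positions = df)
  # single mature overlap -> weight 1, pass 1
  a1 <- assign_reads(mk(data.frame(read_id = "r1", chrom = "chr1",
                                   start = 105L, end = 126L, strand = "+")),
                     ann)
  expect_equal(a1$weight, 1)
  expect_equal(a1$pass, 1L)
  # two positions, two matures -> 0.5 each
  a2 <- assign_reads(mk(data.frame(read_id = "r2", chrom = "chr1",
                                   start = c(110L, 510L),
                                   end = c(131L, 531L), strand = "+")), ann)
  expect_equal(sort(a2$mir_id), c("matA", "matB"))
  expect_equal(a2$weight, c(0.5, 0.5))
  # no mature, one precursor -> pass 2, weight 1
  a3 <- assign_reads(mk(data.frame(read_id = "r3", chrom = "chr2",
                                   start = 910L, end = 931L, strand = "+")),
                     ann)
  expect_equal(a3$pass, 2L)
  expect_equal(a3$weight, 1)
  # mixed: two mature positions plus one precursor-only -> precursor ignored
  a4 <- assign_reads(mk(data.frame(read_id = "r4", chrom = c("chr1", "chr1", "chr2"),
                                   start = c(110L, 510L, 910L),
                                   end = c(131L, 531L, 931L), strand = "+")),
                     ann)
  expect_equal(nrow(a4), 2)
  expect_true(all(a4$pass == 1L))
  expect_equal(a4$weight, c(0.5, 0.5))
  expect_false("precP" %in% a4$mir_id)
  # strand-aware: antisense position does not overlap
  a5 <- assign_reads(mk(data.frame(read_id = "r5", chrom = "chr1",
                                   start = 105L, end = 126L, strand = "-")),
                     ann)
  expect_equal(nrow(a5), 0)
  a5b <- assign_reads(mk(data.frame(read_id = "r5", chrom = "chr1",
                                    start = 105L, end = 126L, strand = "-")),
                      ann, ignore_strand = TRUE)
  expect_equal(nrow(a5b), 1)
})

test_that("per-miR collapse mode splits weight over distinct miRNAs", {
  ann <- toy_ann()
  pos <- data.frame(read_id = "r1", chrom = "chr1",
                    start = c(100L, 102L, 500L),
                    end = c(121L, 123L, 521L), strand = "+")
  pair <- assign_reads(list(positions = pos), ann, collapse = "pair")
  expect_equal(nrow(pair), 3)                      # matA twice, matB once
  expect_equal(sum(pair$weight[pair$mir_id == "matA"]), 2 / 3)
  mir <- assign_reads(list(positions = pos), ann, collapse = "mir")
  expect_equal(nrow(mir), 2)
  expect_equal(mir$weight, c(0.5, 0.5))
})

test_that("indexed assigner equals the brute-force oracle on random instances", {
  for (seed in 0:49) {
    inst <- random_assign_instance(seed)
    got <- assign_reads(list(positions = inst$positions), inst$annotation)
    want <- brute_force_assign(inst$positions, inst$annotation)
    expect_identical(assignment_multiset(got), assignment_multiset(want))
    if (nrow(got)) {
      sums <- tapply(got$weight, got$read_id, sum)
      expect_true(all(abs(sums - 1) < 1e-9))
      # pass exclusivity
      np <- tapply(got$pass, got$read_id, function(p) length(unique(p)))
      expect_true(all(np == 1))
    }
  }
})

test_that("count table aggregates weights, conserves totals, and normalizes", {
  ann <- toy_ann()
  pos <- data.frame(read_id = c("r1", "r2", "r2"),
                    chrom = "chr1", start = c(100L, 100L, 500L),
                    end = c(121L, 121L, 521L), strand = "+")
  a <- assign_reads(list(positions = pos), ann)
  tab <- build_count_table(list(s1 = a), features = ann$id,
                           library_sizes = c(s1 = 2))
  expect_equal(unname(tab$counts["matA", "s1"]), 1.5)
  expect_equal(unname(tab$counts["matB", "s1"]), 0.5)
  expect_equal(unname(colSums(tab$counts)), 2)     # == reads with >= 1 overlap
  cpm <- depth_normalize(tab)
  expect_equal(unname(cpm$counts["matA", "s1"]), 1.5 / 2 * 1e6)
  expect_equal(unname(colSums(cpm$counts)), 1e6)
  # unassigned mapped reads dilute CPM below 1e6
  tab2 <- build_count_table(list(s1 = a), features = ann$id,
                            library_sizes = c(s1 = 4))
  expect_equal(unname(colSums(depth_normalize(tab2)$counts)), 5e5)
  # duplicate assignment is an upstream bug
  dup <- rbind(a, a[1, ])
  expect_error(build_count_table(list(s1 = dup)), "duplicate")
  # zero library size refuses to normalize
  tab0 <- mir_count_table(matrix(0, 1, 1, dimnames = list("m", "s")),
                          library_sizes = c(s = 0))
  expect_error(depth_normalize(tab0), "zero library size")
})

test_that("count tables round-trip through TSV with library-size headers", {
  tab <- mir_count_table(matrix(c(2, 0.5, 0, 3.25), 2, 2,
                                dimnames = list(c("mA", "mB"), c("s1", "s2"))),
                         library_sizes = c(s1 = 10, s2 = 7))
  f <- tempfile(fileext = ".tsv")
  write_count_table(tab, f)
  expect_true(any(grepl("^#library_size=s1:10$", readLines(f))))
  back <- read_count_table(f)
  expect_equal(back$counts, tab$counts)
  expect_equal(back$library_sizes, tab$library_sizes)
})

test_that("end-to-end: quantifying simulated reads reproduces ground truth exactly", {
  cfg <- sim_config(seed = 21, n_precursors = 8, frac_multimapping = 0.25)
  d <- tempfile()
  ref <- generate_reference(cfg, d)
  ids <- ref$annotation$id
  mat <- ids[ref$annotation$kind == "mature"]
  prec <- ids[ref$annotation$kind == "precursor"]
  ab <- c(stats::setNames(sample(1:5, length(mat), replace = TRUE), mat),
          stats::setNames(rep(2L, 2), prec[1:2]))
  sim <- simulate_reads(cfg, ref, ab, outdir = d)
  q <- quantify_sample(file.path(d, "alignments.sam"),
                       parse_annotation(file.path(d, "annotation.gff3")))
  tab <- build_count_table(list(s1 = q$assignments), features = ids,
                           library_sizes = c(s1 = q$n_mapped_reads))
  expect_equal(tab$counts[ids, "s1"], sim$truth$counts[ids])
  # pass 2 fired exactly for the precursor-only reads
  p2 <- unique(q$assignments$read_id[q$assignments$pass == 2L])
  t2 <- unique(sim$truth$assignments$read_id[sim$truth$assignments$pass == 2L])
  expect_setequal(p2, t2)
  # no read carries both passes
  np <- tapply(q$assignments$pass, q$assignments$read_id,
               function(p) length(unique(p)))
  expect_true(all(np == 1))
})
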