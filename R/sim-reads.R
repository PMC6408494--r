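#' Simulate small-RNA reads with per-read assignment ground truth
#'
#' Draws reads as exact copies of annotated sequences (mature miRNAs, or a
#' mature-free window of a precursor for features given by precursor id),
#' enumerates every genomic occurrence of each read by exhaustive substring
#' search over both strands, and records the alignment set a mapper
#' reporting all positions would emit: one primary SAM record plus
#' secondary records (FLAG 0x100) for further occurrences. Alongside, it
#' computes each read's expected miRNA assignments under the two-pass
#' weighting rule (mature features first; precursors only for reads with no
#' mature overlap; unit weight split equally over the resulting
#' position-feature pairs) by direct enumeration, independent of the
#' package's interval-indexed quantifier.
#'
#' Reads are exact copies by design: multimapping arises only from genuine
#' sequence duplication in the genome, so the ground truth is unambiguous.
#' No sequencing-error or quality model is applied (qualities are constant
#' Q40).
#'
#' @param config A [sim_config()] object.
#' @param reference Output of [generate_reference()] (list with `genome`
#'   and `annotation`).
#' @param abundance Named integer vector: reads to draw per feature id.
#'   Names must be annotation ids; mature ids yield mature-sequence reads,
#'   precursor ids yield reads from a precursor-only (mature-free) window.
#' @param outdir Optional directory; when given, `reads.fastq` (Phred+33)
#'   and `alignments.sam` are written there.
#' @return A list with `reads` (data.frame: `id`, `seq`, `qual`),
#'   `alignments` (data.frame of SAM fields: `qname`, `flag`, `rname`,
#'   `pos`, `cigar`, `strand`, one row per occurrence), and `truth`, a list
#'   with `assignments` (data.frame: `read_id`, `mir_id`, `weight`, `pass`)
#'   and `counts` (named vector of expected weighted counts per feature);
#'   plus `fastq_path`/`sam_path` when `outdir` was used.
#' @examples
#' ref <- generate_reference(sim_config(seed = 3, n_precursors = 3,
#'                                      frac_multimapping = 0))
#' mat <- subset(ref$annotation, kind == "mature")$id
#' sim <- simulate_reads(sim_config(seed = 3), ref,
#'                       abundance = setNames(c(2L, 1L), mat[1:2]))
#' sim$truth$counts
#' @export
simulate_reads <- function(config, reference, abundance, outdir = NULL) {
  config <- validate_sim_config(config)
  ann <- reference$annotation
  genome <- reference$genome
  if (is.null(names(abundance)) || !all(names(abundance) %in% ann$id))
    stop("simulate_reads: abundance names must be annotation ids; unknown: ",
         paste(setdiff(names(abundance), ann$id), collapse = ", "),
         call. = FALSE)
  set.seed(sub_seed(config$seed, "reads"))

  feature_seq <- function(fid) {
    rec <- ann[ann$id == fid, ]
    if (rec$kind == "mature") {
      s <- subseq_str(genome, rec$chrom, rec$start, rec$end)
      if (rec$strand == "-") s <- revcomp_str(s)
      return(s)
    }
    # precursor-only read: a window of the hairpin disjoint from its matures
    mats <- ann[ann$kind == "mature" & !is.na(ann$derives_from) &
                  ann$derives_from == rec$id, ]
    free_start <- if (nrow(mats)) max(mats$end) + 1L else rec$start
    if (rec$end - free_start + 1L < 18L)
      stop("simulate_reads: precursor ", fid,
           " has no mature-free window of >= 18 bp", call. = FALSE)
    len <- min(20L, rec$end - free_start + 1L)
    s <- subseq_str(genome, rec$chrom, free_start, free_start + len - 1L)
    if (rec$strand == "-") s <- revcomp_str(s)
    s
  }

  seqs <- vapply(names(abundance), feature_seq, character(1))
  occ_by_feature <- lapply(seqs, find_occurrences, genome = genome)

  reads <- list(); alns <- list(); truth <- list()
  ridx <- 0L
  for (f in names(abundance)) {
    n <- abundance[[f]]
    occ <- occ_by_feature[[f]]
    for (r in seq_len(n)) {
      ridx <- ridx + 1L
      rid <- sprintf("r%06d", ridx)
      reads[[ridx]] <- data.frame(
        id = rid, seq = seqs[[f]],
        qual = strrep("I", nchar(seqs[[f]])), stringsAsFactors = FALSE)
      a <- occ
      a$qname <- rid
      a$flag <- ifelse(a$strand == "-", 16L, 0L)
      if (nrow(a) > 1L) a$flag[-1L] <- a$flag[-1L] + 256L
      a$cigar <- sprintf("%dM", nchar(seqs[[f]]))
      alns[[ridx]] <- a
      truth[[ridx]] <- enumerate_truth(rid, occ, ann)
    }
  }
  reads <- if (length(reads)) do.call(rbind, reads) else
    data.frame(id = character(0), seq = character(0), qual = character(0))
  alignments <- if (length(alns)) do.call(rbind, alns) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               strand = character(0), qname = character(0), flag = integer(0),
               cigar = character(0))
  rownames(alignments) <- NULL
  assignments <- do.call(rbind, truth[!vapply(truth, is.null, logical(1))])
  if (is.null(assignments))
    assignments <- data.frame(read_id = character(0), mir_id = character(0),
                              weight = numeric(0), pass = integer(0))
  counts <- stats::setNames(numeric(nrow(ann)), ann$id)
  if (nrow(assignments)) {
    agg <- tapply(assignments$weight, assignments$mir_id, sum)
    counts[names(agg)] <- agg
  }

  out <- list(reads = reads, alignments = alignments,
              truth = list(assignments = assignments, counts = counts))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    out$fastq_path <- file.path(outdir, "reads.fastq")
    out$sam_path <- file.path(outdir, "alignments.sam")
    write_fastq(reads, out$fastq_path)
    write_sam(alignments, genome, out$sam_path)
  }
  out
}

# every genomic occurrence of `s`, both strands, as a data.frame
find_occurrences <- function(s, genome) {
  hits <- list()
  for (ch in names(genome)) {
    fwd <- Biostrings::matchPattern(s, genome[[ch]])
    if (length(fwd))
      hits[[length(hits) + 1L]] <- data.frame(
        chrom = ch, start = BiocGenerics::start(fwd),
        end = BiocGenerics::end(fwd), strand = "+",
        stringsAsFactors = FALSE)
    rev <- Biostrings::matchPattern(
      Biostrings::reverseComplement(Biostrings::DNAString(s)), genome[[ch]])
    if (length(rev))
      hits[[length(hits) + 1L]] <- data.frame(
        chrom = ch, start = BiocGenerics::start(rev),
        end = BiocGenerics::end(rev), strand = "-",
        stringsAsFactors = FALSE)
  }
  occ <- do.call(rbind, hits)
  occ <- occ[order(occ$chrom, occ$start, occ$strand), , drop = FALSE]
  rownames(occ) <- NULL
  occ
}

# two-pass assignment truth for one read, by plain enumeration
enumerate_truth <- function(rid, occ, ann) {
  pairs_for <- function(kind) {
    sub <- ann[ann$kind == kind, ]
    out <- list()
    for (p in seq_len(nrow(occ))) {
      hit <- sub$chrom == occ$chrom[p] & sub$strand == occ$strand[p] &
        sub$start <= occ$end[p] & sub$end >= occ$start[p]
      for (m in which(hit))
        out[[length(out) + 1L]] <- data.frame(
          read_id = rid, mir_id = sub$id[m], position = p,
          stringsAsFactors = FALSE)
    }
    if (length(out)) do.call(rbind, out) else NULL
  }
  pairs <- pairs_for("mature"); pass <- 1L
  if (is.null(pairs)) { pairs <- pairs_for("precursor"); pass <- 2L }
  if (is.null(pairs)) return(NULL)
  pairs$weight <- 1 / nrow(pairs)
  pairs$pass <- pass
  pairs[c("read_id", "mir_id", "weight", "pass")]
}

subseq_str <- function(genome, chrom, start, end)
  as.character(Biostrings::subseq(genome[[chrom]], start, end))

revcomp_str <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

#' Write reads as FASTQ (Phred+33)
#'
#' @param reads data.frame with columns `id`, `seq`, `qual`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "wb")  # binary mode: byte-identical across platforms
  on.exit(close(con))
  if (nrow(reads))
    writeLines(as.vector(rbind(paste0("@", reads$id), reads$seq,
                               "+", reads$qual)), con)
  invisible(path)
}

#' Write an alignment table as SAM
#'
#' Emits a minimal valid SAM file: `@HD`/`@SQ` header lines (lengths taken
#' from the genome) and one record per alignment row, 1-based POS,
#' multimappers as one primary plus FLAG-0x100 secondary records.
#'
#' @param alignments data.frame with columns `qname`, `flag`, `chrom`,
#'   `start`, `cigar` (as from [simulate_reads()]).
#' @param genome `DNAStringSet` used for `@SQ` lines.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, genome, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", names(genome),
                       Biostrings::width(genome))), con)
  if (nrow(alignments))
    writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t*\t*",
                       alignments$qname, alignments$flag, alignments$chrom,
                       alignments$start, alignments$cigar), con)
  invisible(path)
}
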