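#' Parse a miRBase-dialect GFF3 annotation
#'
#' Reads `miRNA` (mature) and `miRNA_primary_transcript` (precursor)
#' records with their `ID`, `Name` and `Derives_from` attributes; 1-based
#' inclusive coordinates. Records of any other feature type are skipped
#' with a warning (tolerant reader). A record with start > end, or a
#' mature record whose `Derives_from` precursor does not contain it on the
#' same chromosome and strand, is an error.
#'
#' @param path GFF3 file path.
#' @return Annotation data.frame with columns `id`, `name`, `kind`
#'   (`"mature"`/`"precursor"`), `chrom`, `start`, `end`, `strand`,
#'   `derives_from`, `length`.
#' @export
parse_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  types <- as.character(mc$type)
  known <- types %in% c("miRNA", "miRNA_primary_transcript")
  if (any(!known))
    warning("parse_annotation: skipping ", sum(!known),
            " record(s) of unknown type: ",
            paste(unique(types[!known]), collapse = ", "), call. = FALSE)
  gr <- gr[known]
  mc <- S4Vectors::mcols(gr)
  if (!length(gr))
    return(data.frame(id = character(0), name = character(0),
                      kind = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), derives_from = character(0),
                      length = integer(0)))
  dfrom <- if ("Derives_from" %in% colnames(mc))
    as.character(mc$Derives_from) else rep(NA_character_, length(gr))
  ann <- data.frame(
    id = as.character(mc$ID),
    name = if ("Name" %in% colnames(mc)) as.character(mc$Name)
           else as.character(mc$ID),
    kind = ifelse(as.character(mc$type) == "miRNA", "mature", "precursor"),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    derives_from = dfrom,
    stringsAsFactors = FALSE)
  if (any(bad <- ann$start > ann$end))
    stop("parse_annotation: start > end for record(s) ",
         paste(ann$id[bad], collapse = ", "), call. = FALSE)
  ann$length <- ann$end - ann$start + 1L
  # containment check for resolved Derives_from links
  mat <- ann[ann$kind == "mature" & !is.na(ann$derives_from), ]
  if (nrow(mat)) {
    prec <- ann[ann$kind == "precursor", ]
    idx <- match(mat$derives_from, prec$id)
    ok <- !is.na(idx) & mat$chrom == prec$chrom[idx] &
      mat$strand == prec$strand[idx] &
      mat$start >= prec$start[idx] & mat$end <= prec$end[idx]
    if (any(!ok))
      stop("parse_annotation: mature record(s) not contained in their ",
           "precursor: ", paste(mat$id[!ok], collapse = ", "), call. = FALSE)
  }
  rownames(ann) <- NULL
  ann
}

#' Load per-read alignment sets from SAM/BAM
#'
#' Collects, for every read, all reported mapping positions (primary plus
#' FLAG-0x100 secondary records sharing the QNAME). Unmapped records are
#' ignored; the end coordinate is the CIGAR reference span; strand comes
#' from the reverse-complement flag. Reads whose number of positions
#' exceeds `position_cap` are discarded entirely, mirroring a mapper run
#' that reports up to k positions and suppresses reads with more.
#'
#' @param path SAM or BAM file.
#' @param position_cap Maximum retained positions per read (default 100).
#' @return A list with `positions` (data.frame: `read_id`, `chrom`,
#'   `start`, `end`, `strand`, one row per retained position),
#'   `n_mapped_reads` (reads retained after the cap) and
#'   `n_discarded` (reads dropped by the cap).
#' @export
load_alignments <- function(path, position_cap = 100L) {
  bam <- if (grepl("\\.bam$", path, ignore.case = TRUE)) path else
    Rsamtools::asBam(path,
                     destination = tempfile(fileext = ""),
                     overwrite = TRUE, indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "strand"))
  rec <- Rsamtools::scanBam(bam, param = p)[[1L]]
  mapped <- !bitwAnd(rec$flag, 4L)
  if (any(mapped & (is.na(rec$cigar) | rec$cigar == "*")))
    stop("load_alignments: unparsable CIGAR for record(s) ",
         paste(utils::head(rec$qname[mapped &
             (is.na(rec$cigar) | rec$cigar == "*")], 3L), collapse = ", "),
         call. = FALSE)
  pos <- data.frame(
    read_id = rec$qname[mapped],
    chrom = as.character(rec$rname[mapped]),
    start = rec$pos[mapped],
    end = rec$pos[mapped] +
      GenomicAlignments::cigarWidthAlongReferenceSpace(rec$cigar[mapped]) - 1L,
    strand = as.character(rec$strand[mapped]),
    stringsAsFactors = FALSE)
  pos <- unique(pos)
  n_pos <- table(pos$read_id)
  over <- names(n_pos)[n_pos > position_cap]
  discarded <- length(over)
  if (discarded) pos <- pos[!(pos$read_id %in% over), , drop = FALSE]
  rownames(pos) <- NULL
  list(positions = pos,
       n_mapped_reads = length(unique(pos$read_id)),
       n_discarded = discarded)
}

#' Assign reads to miRNAs by two-pass weighted overlap
#'
#' The core quantification rule. For each read, every retained mapping
#' position is compared against the annotation by strand-aware interval
#' overlap (at least `min_overlap` shared bp on the same chromosome; set
#' `ignore_strand = TRUE` to drop the strand requirement). Pass 1
#' enumerates all (position, mature-miRNA) overlap pairs; only if a read
#' has none are precursors considered in pass 2. The read's unit weight is
#' split equally over its k resulting pairs, so per-read weights always
#' sum to 1; with `collapse = "mir"` the pairs are first collapsed to
#' distinct miRNAs and the weight split over those instead. Reads
#' overlapping nothing in either pass yield no assignments.
#'
#' @param alignments Output of [load_alignments()] (or any list with a
#'   `positions` data.frame of that shape).
#' @param annotation Annotation data.frame from [parse_annotation()] /
#'   [generate_reference()].
#' @param min_overlap Minimum overlapping bp (default 1).
#' @param ignore_strand Ignore strand when overlapping (default FALSE).
#' @param collapse `"pair"` (default) weights over (position, miR) pairs;
#'   `"mir"` weights over distinct miRNAs.
#' @return data.frame with columns `read_id`, `mir_id`, `position_index`,
#'   `weight`, `pass`.
#' @export
assign_reads <- function(alignments, annotation, min_overlap = 1L,
                         ignore_strand = FALSE,
                         collapse = c("pair", "mir")) {
  collapse <- match.arg(collapse)
  pos <- alignments$positions
  empty <- data.frame(read_id = character(0), mir_id = character(0),
                      position_index = integer(0), weight = numeric(0),
                      pass = integer(0))
  if (!nrow(pos)) return(empty)

  pos_gr <- GenomicRanges::GRanges(
    pos$chrom, IRanges::IRanges(pos$start, pos$end),
    strand = if (ignore_strand) "*" else pos$strand)
  ann_gr <- GenomicRanges::GRanges(
    annotation$chrom, IRanges::IRanges(annotation$start, annotation$end),
    strand = if (ignore_strand) "*" else annotation$strand)

  hits <- GenomicRanges::findOverlaps(pos_gr, ann_gr,
                                      minoverlap = min_overlap,
                                      ignore.strand = ignore_strand)
  if (!length(hits)) return(empty)
  pairs <- data.frame(
    read_id = pos$read_id[S4Vectors::queryHits(hits)],
    position_index = S4Vectors::queryHits(hits),
    mir_id = annotation$id[S4Vectors::subjectHits(hits)],
    kind = annotation$kind[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE)

  has_mature <- unique(pairs$read_id[pairs$kind == "mature"])
  keep <- (pairs$kind == "mature" & pairs$read_id %in% has_mature) |
          (pairs$kind == "precursor" & !(pairs$read_id %in% has_mature))
  pairs <- pairs[keep, , drop = FALSE]
  if (!nrow(pairs)) return(empty)
  pairs$pass <- ifelse(pairs$kind == "mature", 1L, 2L)

  if (collapse == "mir")
    pairs <- pairs[!duplicated(pairs[c("read_id", "mir_id")]), , drop = FALSE]
  k <- table(pairs$read_id)
  pairs$weight <- 1 / as.numeric(k[pairs$read_id])
  # position_index local to the read, in position order
  ord <- order(pairs$read_id, pairs$position_index, pairs$mir_id)
  pairs <- pairs[ord, , drop = FALSE]
  rownames(pairs) <- NULL
  pairs[c("read_id", "mir_id", "position_index", "weight", "pass")]
}

#' Build a weighted count table from per-sample assignments
#'
#' `count(miR, sample)` is the sum of that miRNA's assignment weights in
#' the sample; features present in `features` but never assigned get 0.
#' The recorded library size per sample is, by default, the number of
#' mapped reads supplied via `library_sizes` (so depth normalization
#' reflects total mapped depth); when `library_sizes` is `NULL` it falls
#' back to the number of distinct assigned reads.
#'
#' A duplicated (read, miR, position) assignment indicates an upstream bug
#' and is an error.
#'
#' @param assignments Named list: sample id -> assignment data.frame from
#'   [assign_reads()].
#' @param features Character vector of feature ids fixing row order
#'   (default: union of assigned miRNAs, sorted).
#' @param library_sizes Optional named numeric vector (per sample) of
#'   mapped-read totals.
#' @return A [mir_count_table].
#' @export
build_count_table <- function(assignments, features = NULL,
                              library_sizes = NULL) {
  stopifnot(is.list(assignments), length(assignments) > 0L,
            !is.null(names(assignments)),
            !anyDuplicated(names(assignments)))
  for (s in names(assignments)) {
    a <- assignments[[s]]
    if (anyDuplicated(a[c("read_id", "mir_id", "position_index")]))
      stop("build_count_table: duplicate (read, miR, position) assignment ",
           "in sample ", s, call. = FALSE)
  }
  if (is.null(features))
    features <- sort(unique(unlist(lapply(assignments, `[[`, "mir_id"))))
  counts <- sapply(assignments, function(a) {
    v <- stats::setNames(numeric(length(features)), features)
    if (nrow(a)) {
      agg <- tapply(a$weight, a$mir_id, sum)
      v[names(agg)] <- agg
    }
    v
  })
  counts <- matrix(counts, nrow = length(features),
                   dimnames = list(features, names(assignments)))
  if (is.null(library_sizes))
    library_sizes <- vapply(assignments,
                            function(a) length(unique(a$read_id)), numeric(1))
  mir_count_table(counts, library_sizes = library_sizes[names(assignments)])
}

#' Quantify one sample from SAM + GFF3
#'
#' Convenience wrapper: [load_alignments()] then [assign_reads()], with the
#' mapped-read total carried along for depth normalization.
#'
#' @param sam_path SAM/BAM file.
#' @param annotation Annotation data.frame (or a GFF3 path).
#' @param position_cap,min_overlap,ignore_strand,collapse Passed through.
#' @return A list with `assignments` and `n_mapped_reads`.
#' @export
quantify_sample <- function(sam_path, annotation, position_cap = 100L,
                            min_overlap = 1L, ignore_strand = FALSE,
                            collapse = "pair") {
  if (is.character(annotation)) annotation <- parse_annotation(annotation)
  aln <- load_alignments(sam_path, position_cap = position_cap)
  list(assignments = assign_reads(aln, annotation, min_overlap = min_overlap,
                                  ignore_strand = ignore_strand,
                                  collapse = collapse),
       n_mapped_reads = aln$n_mapped_reads)
}
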