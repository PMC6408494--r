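#' Generate a toy genome with miRNA annotations
#'
#' Builds a random multi-chromosome genome and places miRNA precursor
#' hairpins (60-120 bp) each containing one or two mature miRNAs (18-24 nt)
#' fully inside the hairpin, on a random strand. A configurable fraction of
#' precursor loci is duplicated verbatim at a second genomic position and
#' annotated as a paralog locus (own ids, identical sequence) -- the
#' situation that produces genuinely multimapping reads, as for miRNA
#' families with several genomic copies.
#'
#' Loci are placed on a grid of non-overlapping 150 bp slots so spacing is
#' never pathological; if the requested loci (including duplicates) do not
#' fit in the genome the function fails rather than packing them.
#'
#' @param config A [sim_config()] object.
#' @param outdir Optional directory; when given, `genome.fa` (FASTA) and
#'   `annotation.gff3` (miRBase-dialect GFF3 with `miRNA_primary_transcript`
#'   and `miRNA` features carrying `ID`, `Name` and `Derives_from`
#'   attributes) are written there.
#' @return A list with `genome` (a [Biostrings::DNAStringSet]) and
#'   `annotation` (a data.frame with columns `id`, `name`, `kind`
#'   (`"mature"`/`"precursor"`), `chrom`, `start`, `end` (1-based
#'   inclusive), `strand`, `derives_from`), plus the file paths when
#'   `outdir` was used.
#' @examples
#' ref <- generate_reference(sim_config(seed = 7, n_precursors = 4))
#' subset(ref$annotation, kind == "mature")
#' @export
generate_reference <- function(config, outdir = NULL) {
  config <- validate_sim_config(config)
  set.seed(sub_seed(config$seed, "reference"))

  slot_len <- 150L
  slots_per_chrom <- config$chrom_length %/% slot_len
  n_dup <- round(config$frac_multimapping * config$n_precursors)
  n_loci <- config$n_precursors + n_dup
  if (slots_per_chrom < 1L ||
      n_loci > config$n_chromosomes * slots_per_chrom)
    stop("generate_reference: annotation does not fit in the genome (",
         n_loci, " loci need ", n_loci * slot_len, " bp of ",
         config$n_chromosomes * config$chrom_length, ")", call. = FALSE)

  chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
  genome_chars <- lapply(chroms, function(ch)
    sample(c("A", "C", "G", "T"), config$chrom_length, replace = TRUE))
  names(genome_chars) <- chroms

  all_slots <- expand.grid(chrom = chroms,
                           slot = seq_len(slots_per_chrom) - 1L,
                           stringsAsFactors = FALSE)
  picked <- all_slots[sample.int(nrow(all_slots), n_loci), , drop = FALSE]

  ann <- list()
  primary <- vector("list", config$n_precursors)
  for (i in seq_len(config$n_precursors)) {
    prec_len <- sample(60:120, 1L)
    mat_lens <- sample(18:24, config$mature_per_precursor, replace = TRUE)
    strand <- sample(c("+", "-"), 1L)
    chrom <- picked$chrom[i]
    offset <- sample.int(slot_len - prec_len, 1L) - 1L
    start <- picked$slot[i] * slot_len + offset + 1L
    end <- start + prec_len - 1L
    # mature arms: 5' arm near one end, 3' arm near the other
    m_start <- start + 5L
    arms <- list(c(m_start, m_start + mat_lens[1L] - 1L))
    if (config$mature_per_precursor == 2L) {
      m2_end <- end - 5L
      arms[[2L]] <- c(m2_end - mat_lens[2L] + 1L, m2_end)
      if (arms[[2L]][1L] <= arms[[1L]][2L])
        arms[[2L]] <- c(arms[[1L]][2L] + 2L, arms[[1L]][2L] + 1L + mat_lens[2L])
    }
    primary[[i]] <- list(prec_len = prec_len, strand = strand,
                         arms = lapply(arms, function(a) a - start + 1L))
    pid <- sprintf("MI%04d", i)
    ann[[length(ann) + 1L]] <- data.frame(
      id = pid, name = sprintf("syn-mir-%d", i), kind = "precursor",
      chrom = chrom, start = start, end = end, strand = strand,
      derives_from = NA_character_, stringsAsFactors = FALSE)
    suffix <- if (config$mature_per_precursor == 2L) c("-5p", "-3p") else ""
    for (a in seq_along(arms)) {
      ann[[length(ann) + 1L]] <- data.frame(
        id = sprintf("MIMAT%04d%s", i, c("", "b")[a]),
        name = sprintf("syn-miR-%d%s", i, suffix[a]), kind = "mature",
        chrom = chrom, start = arms[[a]][1L], end = arms[[a]][2L],
        strand = strand, derives_from = pid, stringsAsFactors = FALSE)
    }
  }
  ann <- do.call(rbind, ann)

  # paralog copies: duplicate the precursor's genomic sequence verbatim at a
  # fresh locus and annotate it with its own precursor/mature records
  if (n_dup > 0L) {
    dup_idx <- sample.int(config$n_precursors, n_dup)
    for (j in seq_len(n_dup)) {
      i <- dup_idx[j]
      src <- ann[ann$id == sprintf("MI%04d", i), ]
      info <- primary[[i]]
      chrom <- picked$chrom[config$n_precursors + j]
      offset <- sample.int(slot_len - info$prec_len, 1L) - 1L
      start <- picked$slot[config$n_precursors + j] * slot_len + offset + 1L
      end <- start + info$prec_len - 1L
      genome_chars[[chrom]][start:end] <-
        genome_chars[[src$chrom]][src$start:src$end]
      pid <- sprintf("MI%04d_2", i)
      ann <- rbind(ann, data.frame(
        id = pid, name = sprintf("syn-mir-%d-2", i), kind = "precursor",
        chrom = chrom, start = start, end = end, strand = info$strand,
        derives_from = NA_character_, stringsAsFactors = FALSE))
      suffix <- if (config$mature_per_precursor == 2L) c("-5p", "-3p") else ""
      for (a in seq_along(info$arms)) {
        rel <- info$arms[[a]]
        ann <- rbind(ann, data.frame(
          id = sprintf("MIMAT%04d%s_2", i, c("", "b")[a]),
          name = sprintf("syn-miR-%d-2%s", i, suffix[a]), kind = "mature",
          chrom = chrom, start = start + rel[1L] - 1L,
          end = start + rel[2L] - 1L, strand = info$strand,
          derives_from = pid, stringsAsFactors = FALSE))
      }
    }
  }
  rownames(ann) <- NULL

  genome <- Biostrings::DNAStringSet(vapply(genome_chars, paste0,
                                            character(1), collapse = ""))
  names(genome) <- chroms

  out <- list(genome = genome, annotation = ann)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    out$genome_path <- file.path(outdir, "genome.fa")
    out$gff_path <- file.path(outdir, "annotation.gff3")
    Biostrings::writeXStringSet(genome, out$genome_path)
    write_mir_gff3(ann, out$gff_path)
  }
  out
}

#' Write a miRNA annotation table as miRBase-dialect GFF3
#'
#' Emits `miRNA_primary_transcript` rows for precursors and `miRNA` rows for
#' matures, with `ID`, `Name` and (for matures) `Derives_from` attributes,
#' 1-based inclusive coordinates.
#'
#' @param annotation Annotation data.frame as produced by
#'   [generate_reference()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mir_gff3 <- function(annotation, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(annotation$start, annotation$end),
    strand = annotation$strand)
  S4Vectors::mcols(gr)$source <- "mirflux"
  S4Vectors::mcols(gr)$type <- ifelse(annotation$kind == "precursor",
                                      "miRNA_primary_transcript", "miRNA")
  S4Vectors::mcols(gr)$ID <- annotation$id
  S4Vectors::mcols(gr)$Name <- annotation$name
  S4Vectors::mcols(gr)$Derives_from <- annotation$derives_from
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
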