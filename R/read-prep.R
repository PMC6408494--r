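#' Read trimming policy
#'
#' Parameters of the small-RNA read cleanup applied before mapping:
#' leading/trailing clipping of bases below a quality floor, a 5'-to-3'
#' sliding-window scan that truncates the read at the start of the first
#' window whose mean quality falls below a threshold, optional 3' adapter
#' removal by suffix-overlap matching, and a minimum-length filter. The
#' defaults are the published settings: clip below Q3 at either end, window
#' of length 4 with mean-quality threshold 15, discard reads shorter than
#' 18 bp.
#'
#' Adapter removal here is a deliberate simplification of score-based
#' adapter trimmers: the leftmost full or 3'-suffix occurrence (at least
#' `adapter_min_overlap` bases, at most `adapter_max_mismatch` mismatches)
#' of any configured adapter, and everything 3' of it, is removed.
#'
#' @param leading_q,trailing_q Quality floor for leading/trailing clipping.
#' @param window_len Sliding-window length in bases.
#' @param window_meanq Mean-quality threshold of the window scan.
#' @param min_len Minimum read length retained, in bp.
#' @param adapters Character vector of 3' adapter sequences (may be empty).
#' @param adapter_min_overlap Minimum suffix overlap for an adapter match.
#' @param adapter_max_mismatch Maximum mismatches tolerated in a match.
#' @return A `trim_policy` object (validated named list).
#' @examples
#' trim_policy()
#' @export
trim_policy <- function(leading_q = 3L, trailing_q = 3L,
                        window_len = 4L, window_meanq = 15,
                        min_len = 18L, adapters = character(0),
                        adapter_min_overlap = 5L, adapter_max_mismatch = 1L) {
  p <- list(leading_q = as.integer(leading_q),
            trailing_q = as.integer(trailing_q),
            window_len = as.integer(window_len),
            window_meanq = window_meanq,
            min_len = as.integer(min_len),
            adapters = toupper(adapters),
            adapter_min_overlap = as.integer(adapter_min_overlap),
            adapter_max_mismatch = as.integer(adapter_max_mismatch))
  stopifnot(p$leading_q >= 0L, p$trailing_q >= 0L, p$window_len >= 1L,
            p$window_meanq >= 0, p$min_len >= 0L,
            p$adapter_min_overlap >= 1L, p$adapter_max_mismatch >= 0L)
  class(p) <- "trim_policy"
  p
}

#' @export
print.trim_policy <- function(x, ...) {
  cat("trim_policy: leading/trailing < Q", x$leading_q, "/", x$trailing_q,
      ", window ", x$window_len, " @ mean < ", x$window_meanq,
      ", min length ", x$min_len, " bp, ", length(x$adapters),
      " adapter(s)\n", sep = "")
  invisible(x)
}

#' Quality-clip a read
#'
#' Removes leading and trailing bases whose quality is below the policy
#' floor, then scans 5' to 3' with a sliding window of `window_len` bases
#' and truncates the read at the start of the first window whose mean
#' quality drops below `window_meanq` (windows are evaluated at every
#' position that fits entirely inside the read). The input is not
#' modified; an empty read is a legal result.
#'
#' @param read List (or data.frame row) with `seq` (character) and `quals`
#'   (integer vector of Phred scores, one per base).
#' @param policy A [trim_policy()].
#' @return The clipped read in the same `list(seq=, quals=)` form.
#' @examples
#' quality_clip(list(seq = "ACGTACGT", quals = c(40,40,40,40,10,10,10,10)),
#'              trim_policy())
#' @export
quality_clip <- function(read, policy = trim_policy()) {
  q <- read$quals
  stopifnot(nchar(read$seq) == length(q))
  keep_from <- 1L
  while (keep_from <= length(q) && q[keep_from] < policy$leading_q)
    keep_from <- keep_from + 1L
  keep_to <- length(q)
  while (keep_to >= keep_from && q[keep_to] < policy$trailing_q)
    keep_to <- keep_to - 1L
  if (keep_to < keep_from) return(list(seq = "", quals = integer(0)))
  q <- q[keep_from:keep_to]
  s <- substr(read$seq, keep_from, keep_to)

  w <- policy$window_len
  if (length(q) >= w) {
    # integer window sums keep the threshold comparison exact
    cs <- cumsum(c(0, as.numeric(q)))
    wsum <- cs[(w + 1L):(length(q) + 1L)] - cs[seq_len(length(q) - w + 1L)]
    bad <- which(wsum < policy$window_meanq * w)
    if (length(bad)) {
      cut <- bad[1L] - 1L                  # keep bases before the window
      q <- q[seq_len(cut)]
      s <- substr(s, 1L, cut)
    }
  }
  list(seq = s, quals = q)
}

#' Clip a 3' adapter from a read
#'
#' Searches for the leftmost occurrence of any configured adapter, either
#' in full anywhere in the read or as a read-terminal prefix-of-adapter
#' overlap of at least `adapter_min_overlap` bases, tolerating up to
#' `adapter_max_mismatch` mismatches; the match and everything 3' of it are
#' removed. Qualities are cut alongside.
#'
#' @inheritParams quality_clip
#' @return The clipped read as `list(seq=, quals=)`.
#' @examples
#' adapter_clip(list(seq = paste0("ACGTACGTACGTACGTAC", "TGGAATTC"),
#'                   quals = rep(40L, 26)),
#'              trim_policy(adapters = "TGGAATTCTCGG"))
#' @export
adapter_clip <- function(read, policy) {
  if (!length(policy$adapters)) return(read)
  s <- toupper(read$seq)
  n <- nchar(s)
  best <- n + 1L
  for (ad in policy$adapters) {
    al <- nchar(ad)
    for (start in seq_len(n)) {
      if (start >= best) break
      span <- min(al, n - start + 1L)           # suffix overlap allowed
      if (span < al && span < policy$adapter_min_overlap) next
      mism <- sum(strsplit(substr(s, start, start + span - 1L), "")[[1L]] !=
                    strsplit(substr(ad, 1L, span), "")[[1L]])
      if (mism <= policy$adapter_max_mismatch) { best <- start; break }
    }
  }
  if (best > n) return(read)
  list(seq = substr(read$seq, 1L, best - 1L),
       quals = read$quals[seq_len(best - 1L)])
}

#' Length-filter reads
#'
#' Keeps exactly the reads whose sequence length is at least
#' `policy$min_len`, preserving order. Reads shorter than the floor are
#' discarded (an 18-mer passes the default 18 bp floor).
#'
#' @param reads List of reads (`list(seq=, quals=)` each).
#' @param policy A [trim_policy()].
#' @return The retained sublist.
#' @export
length_filter <- function(reads, policy = trim_policy()) {
  reads[vapply(reads, function(r) nchar(r$seq) >= policy$min_len,
               logical(1))]
}

#' Trim a FASTQ file
#'
#' Applies [quality_clip()], then [adapter_clip()], then [length_filter()]
#' to every read of a Phred+33 FASTQ file and writes the survivors.
#'
#' @param infile,outfile Input/output FASTQ paths (plain or gzip input).
#' @param policy A [trim_policy()].
#' @return Invisibly, a named vector with `n_in` and `n_out`.
#' @export
trim_fastq <- function(infile, outfile, policy = trim_policy()) {
  fq <- read_fastq(infile)
  out <- vector("list", nrow(fq))
  for (i in seq_len(nrow(fq))) {
    r <- list(seq = fq$seq[i],
              quals = utf8ToInt(fq$qual[i]) - 33L)
    r <- quality_clip(r, policy)
    r <- adapter_clip(r, policy)
    out[[i]] <- c(r, id = fq$id[i])
  }
  keep <- vapply(out, function(r) nchar(r$seq) >= policy$min_len, logical(1))
  out <- out[keep]
  df <- data.frame(
    id = vapply(out, `[[`, character(1), "id"),
    seq = vapply(out, `[[`, character(1), "seq"),
    qual = vapply(out, function(r) intToUtf8(r$quals + 33L), character(1)),
    stringsAsFactors = FALSE)
  write_fastq(df, outfile)
  invisible(c(n_in = nrow(fq), n_out = nrow(df)))
}

#' Read a Phred+33 FASTQ file into a data.frame
#'
#' @param path FASTQ path (plain or gzip).
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stop("read_fastq: truncated FASTQ (", length(lines), " lines)",
         call. = FALSE)
  if (!length(lines))
    return(data.frame(id = character(0), seq = character(0),
                      qual = character(0)))
  i <- seq(1L, length(lines), by = 4L)
  data.frame(id = sub("^@", "", sub("\\s.*$", "", lines[i])),
             seq = lines[i + 1L], qual = lines[i + 3L],
             stringsAsFactors = FALSE)
}
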