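# Independent brute-force oracles used to cross-check the package's
# vectorized/indexed implementations on small instances.

# Two-pass assignment by plain nested loops over positions x annotations.
# Returns the same columns as assign_reads(); no interval index, no GRanges.
brute_force_assign <- function(positions, annotation, min_overlap = 1L) {
  out <- list()
  for (rid in unique(positions$read_id)) {
    pp <- positions[positions$read_id == rid, , drop = FALSE]
    pairs <- list()
    for (kind in c("mature", "precursor")) {
      sub <- annotation[annotation$kind == kind, , drop = FALSE]
      for (pi in seq_len(nrow(pp))) {
        for (ai in seq_len(nrow(sub))) {
          if (pp$chrom[pi] != sub$chrom[ai]) next
          if (pp$strand[pi] != sub$strand[ai]) next
          ov <- min(pp$end[pi], sub$end[ai]) -
            max(pp$start[pi], sub$start[ai]) + 1L
          if (ov >= min_overlap)
            pairs[[length(pairs) + 1L]] <-
              data.frame(read_id = rid, mir_id = sub$id[ai],
                         pass = if (kind == "mature") 1L else 2L,
                         stringsAsFactors = FALSE)
        }
      }
      if (length(pairs)) break   # pass 2 only when pass 1 found nothing
    }
    if (!length(pairs)) next
    df <- do.call(rbind, pairs)
    df$weight <- 1 / nrow(df)
    out[[length(out) + 1L]] <- df
  }
  if (!length(out))
    return(data.frame(read_id = character(0), mir_id = character(0),
                      pass = integer(0), weight = numeric(0)))
  do.call(rbind, out)
}

# random assignment instance: toy annotation plus random read positions,
# some overlapping, some not, some multimapping
random_assign_instance <- function(seed, max_reads = 200L, max_ann = 50L) {
  set.seed(seed)
  n_ann <- sample.int(max_ann, 1L)
  chroms <- c("c1", "c2")
  ann <- data.frame(
    id = sprintf("a%02d", seq_len(n_ann)),
    name = sprintf("a%02d", seq_len(n_ann)),
    kind = sample(c("mature", "precursor"), n_ann, replace = TRUE),
    chrom = sample(chroms, n_ann, replace = TRUE),
    start = sample.int(2000L, n_ann, replace = TRUE),
    strand = sample(c("+", "-"), n_ann, replace = TRUE),
    stringsAsFactors = FALSE)
  ann$end <- ann$start + sample(17:90, n_ann, replace = TRUE)
  ann$derives_from <- NA_character_
  n_reads <- sample.int(max_reads, 1L)
  pos <- do.call(rbind, lapply(seq_len(n_reads), function(i) {
    k <- sample.int(4L, 1L)
    st <- sample.int(2100L, k)
    data.frame(read_id = sprintf("r%03d", i),
               chrom = sample(chroms, k, replace = TRUE),
               start = st, end = st + 21L,
               strand = sample(c("+", "-"), k, replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  list(annotation = ann, positions = unique(pos))
}

# canonical multiset form of an assignment table for comparison
assignment_multiset <- function(a) {
  key <- paste(a$read_id, a$mir_id, a$pass, round(a$weight, 9), sep = "|")
  sort(key)
}

# all-windows sliding-window trimming oracle, brute force over every
# window position; mirrors the documented clip semantics independently
brute_force_trim <- function(quals, leading_q, trailing_q, window_len,
                             window_meanq) {
  n <- length(quals)
  from <- 1L
  while (from <= n && quals[from] < leading_q) from <- from + 1L
  to <- n
  while (to >= from && quals[to] < trailing_q) to <- to - 1L
  if (to < from) return(integer(0))
  q <- quals[from:to]
  cut <- length(q)
  if (length(q) >= window_len) {
    for (i in seq_len(length(q) - window_len + 1L)) {
      if (mean(q[i:(i + window_len - 1L)]) < window_meanq) {
        cut <- i - 1L
        break
      }
    }
  }
  if (cut == 0L) integer(0) else q[seq_len(cut)]
}

# per-feature-ratio median oracle for size factors
brute_force_size_factors <- function(counts) {
  all_pos <- apply(counts, 1L, function(r) all(r > 0))
  sub <- counts[all_pos, , drop = FALSE]
  gm <- apply(sub, 1L, function(r) prod(r)^(1 / length(r)))
  vapply(seq_len(ncol(sub)),
         function(j) stats::median(sub[, j] / gm), numeric(1))
}

# rank-based AUC of scores for a binary truth labelling
score_auc <- function(scores, is_positive) {
  r <- rank(scores)
  n1 <- sum(is_positive); n0 <- sum(!is_positive)
  (sum(r[is_positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
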