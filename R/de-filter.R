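#' Median-of-ratios size factors
#'
#' Per-sample scaling factors in the median-of-ratios convention: for each
#' feature with strictly positive counts in every sample, form the ratio
#' of each sample's count to the feature's geometric mean across samples;
#' the sample's factor is the median of its ratios. Requires at least one
#' all-positive feature.
#'
#' @param table A [mir_count_table] or a plain numeric matrix
#'   (features x samples).
#' @return Named numeric vector of positive per-sample factors.
#' @examples
#' m <- cbind(s1 = c(10, 20, 30), s2 = c(20, 40, 60))
#' rownames(m) <- paste0("f", 1:3)
#' size_factors(m)  # ratio 2 between samples
#' @export
size_factors <- function(table) {
  counts <- if (inherits(table, "mir_count_table")) table$counts else
    as.matrix(table)
  if (ncol(counts) < 2L)
    stop("size_factors: need >= 2 samples", call. = FALSE)
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos))
    stop("size_factors: no feature with positive counts in all samples",
         call. = FALSE)
  sub <- counts[all_pos, , drop = FALSE]
  gm <- exp(rowMeans(log(sub)))
  apply(sub, 2L, function(col) stats::median(col / gm))
}

#' Fold-change / baseMean differential table
#'
#' Divides counts by median-of-ratios size factors, computes each
#' feature's baseMean (grand mean of normalized counts over all samples)
#' and its log2 fold change of the coculture group over the control group
#' (group means stabilized with a pseudocount), and applies the display
#' filter used for heatmap membership: a feature passes when its absolute
#' linear fold change exceeds `fc_threshold` and its baseMean exceeds
#' `basemean_threshold`.
#'
#' This is deliberately a filter, not a test: no dispersion estimation or
#' p-values, only the selection surface.
#'
#' @param table A [mir_count_table] or numeric matrix.
#' @param groups Named character vector mapping each sample id to
#'   `"control"` or `"coculture"`.
#' @param pseudocount Added to each normalized group mean (default 0.5).
#' @param fc_threshold Linear fold-change threshold (default 1.5, i.e.
#'   |log2fc| > log2 1.5).
#' @param basemean_threshold baseMean threshold (default 5), strict.
#' @return data.frame with columns `feature`, `base_mean`, `log2fc`,
#'   `passes_filter`, one row per feature.
#' @examples
#' sim <- simulate_count_matrix(sim_config(seed = 4, n_features = 8,
#'   planted_log2fc = c(F002 = 2)))
#' de <- de_table(sim$table, sim$groups)
#' de[de$passes_filter, ]
#' @export
de_table <- function(table, groups, pseudocount = 0.5,
                     fc_threshold = 1.5, basemean_threshold = 5) {
  counts <- if (inherits(table, "mir_count_table")) table$counts else
    as.matrix(table)
  if (!all(colnames(counts) %in% names(groups)))
    stop("de_table: samples without a group label: ",
         paste(setdiff(colnames(counts), names(groups)), collapse = ", "),
         call. = FALSE)
  g <- groups[colnames(counts)]
  if (!all(g %in% c("control", "coculture")))
    stop("de_table: unknown group label(s): ",
         paste(unique(g[!g %in% c("control", "coculture")]), collapse = ", "),
         call. = FALSE)
  if (!any(g == "control") || !any(g == "coculture"))
    stop("de_table: both groups must be non-empty", call. = FALSE)

  norm <- sweep(counts, 2L, size_factors(counts), "/")
  base_mean <- rowMeans(norm)
  m_ctrl <- rowMeans(norm[, g == "control", drop = FALSE])
  m_coc <- rowMeans(norm[, g == "coculture", drop = FALSE])
  log2fc <- log2((m_coc + pseudocount) / (m_ctrl + pseudocount))
  data.frame(feature = rownames(counts),
             base_mean = unname(base_mean),
             log2fc = unname(log2fc),
             passes_filter = unname(abs(log2fc) > log2(fc_threshold) &
                                      base_mean > basemean_threshold),
             stringsAsFactors = FALSE)
}

#' MA-plot coordinates
#'
#' One row per feature with positive baseMean: `A = log2(baseMean)`,
#' `M = log2fc`. Zero-baseMean features are dropped (outside the domain of
#' the log).
#'
#' @param results data.frame from [de_table()].
#' @return data.frame with columns `feature`, `A`, `M`.
#' @export
ma_data <- function(results) {
  keep <- results$base_mean > 0
  data.frame(feature = results$feature[keep],
             A = log2(results$base_mean[keep]),
             M = results$log2fc[keep],
             stringsAsFactors = FALSE)
}
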