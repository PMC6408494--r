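#' Ago-RIP experiment container
#'
#' Gene-level counts and exonic lengths for the four pulldown conditions
#' of a miR-375 Ago-RIP design -- `ago_mir375`, `igg_mir375`,
#' `ago_control`, `igg_control` -- plus per-condition mapped-read totals.
#'
#' @param counts Numeric gene x condition matrix; column names must be the
#'   four conditions above; non-negative.
#' @param lengths Named numeric vector of exonic lengths in bp (> 0),
#'   aligned with the rows.
#' @param mapped_totals Named numeric vector of total mapped reads per
#'   condition (> 0).
#' @return An object of class `rip_experiment`.
#' @export
rip_experiment <- function(counts, lengths, mapped_totals) {
  counts <- as.matrix(counts)
  cond <- c("ago_mir375", "igg_mir375", "ago_control", "igg_control")
  if (!identical(sort(colnames(counts)), sort(cond)))
    stop("rip_experiment: counts must have exactly the four condition ",
         "columns ", paste(cond, collapse = ", "), call. = FALSE)
  counts <- counts[, cond, drop = FALSE]
  stopifnot(all(counts >= 0), !is.null(rownames(counts)))
  if (is.null(names(lengths))) names(lengths) <- rownames(counts)
  lengths <- lengths[rownames(counts)]
  if (any(is.na(lengths)) || any(lengths <= 0))
    stop("rip_experiment: every gene needs a positive length", call. = FALSE)
  mapped_totals <- mapped_totals[cond]
  if (any(is.na(mapped_totals)) || any(mapped_totals <= 0))
    stop("rip_experiment: every condition needs a positive mapped total",
         call. = FALSE)
  structure(list(counts = counts, lengths = lengths,
                 mapped_totals = mapped_totals),
            class = "rip_experiment")
}

#' @export
print.rip_experiment <- function(x, ...) {
  cat("rip_experiment: ", nrow(x$counts), " genes x 4 conditions\n", sep = "")
  cat("mapped totals: ",
      paste0(names(x$mapped_totals), "=", x$mapped_totals, collapse = ", "),
      "\n", sep = "")
  print(utils::head(x$counts, 4L))
  invisible(x)
}

#' RPKM matrix of a RIP experiment
#'
#' `rpkm = count / (length / 1000) / (mapped_total / 1e6)` -- reads per
#' kilobase of exon model per million mapped reads, per gene and condition.
#'
#' @param experiment A [rip_experiment].
#' @return Numeric gene x condition matrix of RPKM values.
#' @examples
#' e <- rip_experiment(
#'   matrix(10, 1, 4, dimnames = list("g", c("ago_mir375", "igg_mir375",
#'                                           "ago_control", "igg_control"))),
#'   lengths = c(g = 1000), mapped_totals = stats::setNames(rep(1e6, 4),
#'     c("ago_mir375", "igg_mir375", "ago_control", "igg_control")))
#' rip_rpkm(e)  # 10.0 everywhere
#' @export
rip_rpkm <- function(experiment) {
  stopifnot(inherits(experiment, "rip_experiment"))
  sweep(sweep(experiment$counts, 1L, experiment$lengths / 1000, "/"),
        2L, experiment$mapped_totals / 1e6, "/")
}

#' Expressed-transcript filter
#'
#' Keeps genes whose RPKM reaches `threshold` in at least one condition;
#' the boundary is inclusive (a gene at exactly 1.0 in one sample passes
#' the default filter).
#'
#' @param rpkm Gene x condition RPKM matrix.
#' @param threshold RPKM threshold (default 1.0).
#' @return Character vector of retained gene ids.
#' @export
expressed_filter <- function(rpkm, threshold = 1.0) {
  if (!nrow(rpkm)) return(character(0))
  rownames(rpkm)[apply(rpkm, 1L, max) >= threshold]
}

#' Double-difference enrichment score
#'
#' The log2-scale Ago-vs-IgG double difference
#' `(x_ago_mir375 - x_igg_mir375) - (x_ago_control - x_igg_control)` with
#' `x = log2(rpkm + pseudocount)`. The IgG arm subtracts nonspecific
#' pulldown; the control arm subtracts mimic-independent Ago loading, so a
#' positive score means specific Ago recruitment after the miR-375 mimic.
#' With `pseudocount = 0` the score is exactly the log2 ratio of RPKM
#' ratios; the default pseudocount 1 bounds the score for low-expression
#' genes.
#'
#' @param rpkm Numeric vector (one gene; names as the four conditions) or
#'   gene x condition matrix.
#' @param pseudocount Added inside the log2 (default 1.0).
#' @return Numeric score (vector for a matrix input).
#' @examples
#' enrichment_score(c(ago_mir375 = 15, igg_mir375 = 1,
#'                    ago_control = 3, igg_control = 1),
#'                  pseudocount = 0)  # log2(15/1) - log2(3/1)
#' @export
enrichment_score <- function(rpkm, pseudocount = 1.0) {
  if (is.null(dim(rpkm))) rpkm <- matrix(rpkm, 1L,
                                         dimnames = list(NULL, names(rpkm)))
  cond <- c("ago_mir375", "igg_mir375", "ago_control", "igg_control")
  stopifnot(all(cond %in% colnames(rpkm)))
  if (any(rpkm < 0))
    stop("enrichment_score: negative RPKM", call. = FALSE)
  x <- log2(rpkm[, cond, drop = FALSE] + pseudocount)
  unname((x[, "ago_mir375"] - x[, "igg_mir375"]) -
           (x[, "ago_control"] - x[, "igg_control"]))
}

#' Call miR-375 targets from a RIP experiment
#'
#' The full targetome pipeline: RPKM, the expressed-transcript filter
#' (RPKM >= `rpkm_min` in at least one condition), the double-difference
#' enrichment score, and the target rule `expressed AND score > 0`
#' (strict: a score of exactly 0 is never a target). Genes failing the
#' expressed filter are kept in the output with `expressed = FALSE` for
#' auditability. Results are sorted by descending score.
#'
#' @param experiment A [rip_experiment].
#' @param rpkm_min Expressed-filter threshold (default 1.0).
#' @param pseudocount Passed to [enrichment_score()] (default 1.0).
#' @return data.frame with columns `gene`, the four `rpkm_*` columns,
#'   `expressed`, `score`, `is_target`.
#' @examples
#' sim <- simulate_rip_experiment(sim_config(seed = 5, n_genes = 10,
#'   planted_rip_targets = c(G002 = 2)), noiseless = TRUE)
#' head(call_targets(sim$experiment, pseudocount = 0), 3)
#' @export
call_targets <- function(experiment, rpkm_min = 1.0, pseudocount = 1.0) {
  rpkm <- rip_rpkm(experiment)
  expressed <- rownames(rpkm) %in% expressed_filter(rpkm, rpkm_min)
  score <- enrichment_score(rpkm, pseudocount = pseudocount)
  out <- data.frame(gene = rownames(rpkm),
                    rpkm_ago_mir375 = rpkm[, "ago_mir375"],
                    rpkm_igg_mir375 = rpkm[, "igg_mir375"],
                    rpkm_ago_control = rpkm[, "ago_control"],
                    rpkm_igg_control = rpkm[, "igg_control"],
                    expressed = expressed,
                    score = score,
                    is_target = expressed & score > 0,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score), ]
  rownames(out) <- NULL
  out
}
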