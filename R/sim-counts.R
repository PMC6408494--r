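#' Simulate a miRNA count matrix with planted fold changes
#'
#' Draws negative-binomial counts for a two-group (control vs coculture)
#' design. Expected depth per sample is `reads_per_sample`, distributed
#' over features by a lognormal relative-abundance profile; features named
#' in `planted_log2fc` have their coculture-group mean multiplied by
#' `2^log2fc`. Features whose planted absolute fold change exceeds 1.5 are
#' recorded as the true differential set.
#'
#' @param config A [sim_config()] object; uses `n_features`, `n_per_group`,
#'   `reads_per_sample`, `nb_dispersion`, `planted_log2fc`.
#' @return A list with `table` (a [mir_count_table] with samples
#'   `ctrl_1..n` then `cocx_1..n`), `groups` (named character vector,
#'   `"control"`/`"coculture"`), and `truth` (list: `true_de_set`,
#'   `planted_log2fc`, `mu` matrix of expected counts).
#' @examples
#' sim <- simulate_count_matrix(sim_config(seed = 2, n_features = 10,
#'   planted_log2fc = c(F001 = 2)))
#' sim$truth$true_de_set
#' @export
simulate_count_matrix <- function(config) {
  config <- validate_sim_config(config)
  set.seed(sub_seed(config$seed, "counts"))
  nf <- config$n_features
  npg <- config$n_per_group
  if (npg < 2L)
    stop("simulate_count_matrix: need >= 2 samples per group", call. = FALSE)

  features <- sprintf("F%03d", seq_len(nf))
  unknown <- setdiff(names(config$planted_log2fc), features)
  if (length(unknown))
    stop("simulate_count_matrix: planted_log2fc names not among features: ",
         paste(unknown, collapse = ", "), call. = FALSE)

  rel <- stats::rlnorm(nf, meanlog = 0, sdlog = 1)
  mu_ctrl <- config$reads_per_sample * rel / sum(rel)
  lfc <- stats::setNames(numeric(nf), features)
  lfc[names(config$planted_log2fc)] <- config$planted_log2fc
  mu_coc <- mu_ctrl * 2^lfc

  samples <- c(sprintf("ctrl_%d", seq_len(npg)),
               sprintf("cocx_%d", seq_len(npg)))
  groups <- stats::setNames(rep(c("control", "coculture"), each = npg),
                            samples)
  mu <- cbind(matrix(mu_ctrl, nf, npg), matrix(mu_coc, nf, npg))
  dimnames(mu) <- list(features, samples)
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / config$nb_dispersion),
                   nf, 2L * npg, dimnames = dimnames(mu))

  tab <- mir_count_table(counts, library_sizes = colSums(counts))
  true_de <- names(lfc)[abs(lfc) > log2(1.5)]
  list(table = tab, groups = groups,
       truth = list(true_de_set = true_de, planted_log2fc = lfc, mu = mu))
}
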