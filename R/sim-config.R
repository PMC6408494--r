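#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generators into a single
#' validated object. The defaults describe the study conditions the package
#' is calibrated against: a small multi-chromosome toy genome carrying
#' miRNA precursor/mature annotations (some duplicated to create true
#' multimappers), negative-binomial count matrices for a control vs
#' coculture design, a 2x2 Ago/IgG x mimic/control RIP experiment, and
#' actinomycin-D style mRNA decay time courses.
#'
#' @param seed Integer master seed. Every generator derives an independent
#'   RNG stream from it by stable sub-seeding, so the seed fully determines
#'   every output byte and adding one output never perturbs another.
#' @param n_chromosomes Number of toy chromosomes.
#' @param chrom_length Length of each chromosome in bp.
#' @param n_precursors Number of miRNA precursor loci to place.
#' @param mature_per_precursor Mature miRNAs per precursor hairpin (1 = one
#'   arm, 2 = both 5p and 3p arms).
#' @param frac_multimapping Fraction of precursor loci duplicated verbatim
#'   at a second genomic locus (annotated as a paralog), creating reads
#'   that map to multiple positions.
#' @param reads_per_sample Expected sequencing depth per sample of simulated
#'   count matrices (total expected assigned reads).
#' @param n_per_group Samples per group in simulated count matrices
#'   (the profiled design had four donors per group).
#' @param n_features Number of miRNA features in simulated count matrices.
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2) of simulated counts.
#' @param planted_log2fc Named numeric vector mapping feature ids to the
#'   log2 fold change planted between control and coculture groups.
#' @param n_genes Number of genes in simulated RIP experiments.
#' @param planted_rip_targets Named numeric vector mapping gene ids to the
#'   planted log2 double-difference enrichment.
#' @param rip_mean_count Expected reads per gene in RIP experiments.
#' @param decay_halflife_h Planted mRNA half-life in hours (default 3.07 h,
#'   a destabilized-transcript scenario).
#' @param noise_cv Coefficient of variation of multiplicative lognormal
#'   noise on decay series (and of RIP library-size jitter).
#'
#' @return An object of class `mir_sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(seed = 1, n_precursors = 5)
#' cfg$seed
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chrom_length = 10000L,
                       n_precursors = 10L,
                       mature_per_precursor = 1L,
                       frac_multimapping = 0.2,
                       reads_per_sample = 100000L,
                       n_per_group = 4L,
                       n_features = 50L,
                       nb_dispersion = 0.02,
                       planted_log2fc = numeric(0),
                       n_genes = 100L,
                       planted_rip_targets = numeric(0),
                       rip_mean_count = 100,
                       decay_halflife_h = 3.07,
                       noise_cv = 0.05) {
  cfg <- list(
    seed = as.integer(seed),
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.integer(chrom_length),
    n_precursors = as.integer(n_precursors),
    mature_per_precursor = as.integer(mature_per_precursor),
    frac_multimapping = frac_multimapping,
    reads_per_sample = as.integer(reads_per_sample),
    n_per_group = as.integer(n_per_group),
    n_features = as.integer(n_features),
    nb_dispersion = nb_dispersion,
    planted_log2fc = planted_log2fc,
    n_genes = as.integer(n_genes),
    planted_rip_targets = planted_rip_targets,
    rip_mean_count = rip_mean_count,
    decay_halflife_h = decay_halflife_h,
    noise_cv = noise_cv
  )
  class(cfg) <- "mir_sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  pos_int <- c("n_chromosomes", "chrom_length", "n_precursors",
               "mature_per_precursor", "n_per_group", "n_features", "n_genes")
  for (f in pos_int) {
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] < 1L)
      stop("sim_config: '", f, "' must be a positive integer", call. = FALSE)
  }
  if (cfg$reads_per_sample < 0L)
    stop("sim_config: 'reads_per_sample' must be non-negative", call. = FALSE)
  if (cfg$mature_per_precursor > 2L)
    stop("sim_config: 'mature_per_precursor' must be 1 or 2", call. = FALSE)
  for (f in c("frac_multimapping", "noise_cv")) {
    if (cfg[[f]] < 0 || (f == "frac_multimapping" && cfg[[f]] > 1))
      stop("sim_config: '", f, "' out of range", call. = FALSE)
  }
  if (cfg$nb_dispersion <= 0)
    stop("sim_config: 'nb_dispersion' must be positive", call. = FALSE)
  if (cfg$decay_halflife_h <= 0)
    stop("sim_config: 'decay_halflife_h' must be positive", call. = FALSE)
  if (cfg$rip_mean_count <= 0)
    stop("sim_config: 'rip_mean_count' must be positive", call. = FALSE)
  if (length(cfg$planted_log2fc) &&
      is.null(names(cfg$planted_log2fc)))
    stop("sim_config: 'planted_log2fc' must be a named vector", call. = FALSE)
  if (length(cfg$planted_rip_targets) &&
      is.null(names(cfg$planted_rip_targets)))
    stop("sim_config: 'planted_rip_targets' must be a named vector",
         call. = FALSE)
  cfg
}

#' @export
print.mir_sim_config <- function(x, ...) {
  cat("mir_sim_config (seed ", x$seed, ")\n", sep = "")
  cat("  genome: ", x$n_chromosomes, " x ", x$chrom_length, " bp, ",
      x$n_precursors, " precursors (", x$mature_per_precursor,
      " mature each), ", round(100 * x$frac_multimapping),
      "% duplicated loci\n", sep = "")
  cat("  counts: ", x$n_features, " features, ", x$n_per_group,
      " per group, NB dispersion ", x$nb_dispersion, "\n", sep = "")
  cat("  RIP: ", x$n_genes, " genes, ", length(x$planted_rip_targets),
      " planted targets\n", sep = "")
  cat("  decay: t1/2 ", x$decay_halflife_h, " h, noise CV ", x$noise_cv,
      "\n", sep = "")
  invisible(x)
}

# Stable sub-seed for an artifact-specific RNG stream. A small string hash
# keeps streams independent of the order generators are called in; result
# stays inside the 32-bit signed range set.seed() accepts.
sub_seed <- function(seed, label) {
  h <- 0
  for (b in utf8ToInt(label)) h <- (h * 131 + b) %% 1977326743
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647L)
}
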