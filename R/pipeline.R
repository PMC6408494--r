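#' Run the full pipeline from a config
#'
#' Executes the configured stages in dependency order -- `simulate`
#' (reference genome, annotation, reads, alignments), `trim`, `quantify`,
#' `de` (simulated count matrix + fold-change/baseMean filter), `rip`
#' (simulated Ago-RIP experiment + target calling) and `qpcr` (simulated
#' decay series + half-life fit) -- writing every stage output as a
#' plain-text file under `outdir` and finishing with a run manifest that
#' records the master seed, a digest of the config, and the path, row
#' count and MD5 digest of every output. All randomness derives from the
#' single `seed` by stable sub-seeding, so re-running an identical config
#' reproduces every output byte for byte.
#'
#' The config is a YAML file (or an equivalent named list) validated
#' against a strict schema: an unknown key anywhere is an error naming the
#' key, before any stage runs.
#'
#' @param config Path to a YAML config file, or a named list.
#' @param outdir Output directory (created if needed).
#' @return The manifest, invisibly (also written to
#'   `<outdir>/manifest.yaml`).
#' @examples
#' dir <- tempfile()
#' m <- run_pipeline(list(seed = 1,
#'   simulate = list(n_precursors = 4, reads_per_mature = 3),
#'   quantify = list()), dir)
#' names(m$outputs)
#' @export
run_pipeline <- function(config, outdir) {
  cfg_text <- NULL
  if (is.character(config) && length(config) == 1L) {
    cfg_text <- readLines(config)
    config <- yaml::read_yaml(config)
  }
  validate_pipeline_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  outputs <- list()
  note <- function(name, path, n_rows) {
    outputs[[name]] <<- list(path = path, rows = n_rows,
                             md5 = unname(tools::md5sum(path)))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ref <- NULL; sim <- NULL
  if (!is.null(config$simulate)) {
    sc <- config$simulate
    stage("simulate", {
      ref <- generate_reference(sim_config(
        seed = seed,
        n_chromosomes = sc$n_chromosomes %||% 2L,
        chrom_length = sc$chrom_length %||% 10000L,
        n_precursors = sc$n_precursors %||% 10L,
        mature_per_precursor = sc$mature_per_precursor %||% 1L,
        frac_multimapping = sc$frac_multimapping %||% 0.2), outdir)
      mat <- ref$annotation$id[ref$annotation$kind == "mature"]
      abundance <- stats::setNames(
        rep(sc$reads_per_mature %||% 10L, length(mat)), mat)
      if ((sc$precursor_reads %||% 0L) > 0L) {
        prec <- ref$annotation$id[ref$annotation$kind == "precursor"]
        abundance <- c(abundance, stats::setNames(
          rep(sc$precursor_reads, length(prec)), prec))
      }
      sim <- simulate_reads(sim_config(seed = seed), ref, abundance, outdir)
    })
    note("genome", ref$genome_path, length(ref$genome))
    note("annotation", ref$gff_path, nrow(ref$annotation))
    note("reads", sim$fastq_path, nrow(sim$reads))
    note("alignments", sim$sam_path, nrow(sim$alignments))
  }

  if (!is.null(config$trim)) {
    tc <- config$trim
    if (is.null(sim)) stop("pipeline: 'trim' requires 'simulate'",
                           call. = FALSE)
    trimmed <- file.path(outdir, "trimmed.fastq")
    stage("trim", {
      pol <- trim_policy(leading_q = tc$leading_q %||% 3L,
                         trailing_q = tc$trailing_q %||% 3L,
                         window_len = tc$window_len %||% 4L,
                         window_meanq = tc$window_meanq %||% 15,
                         min_len = tc$min_len %||% 18L,
                         adapters = unlist(tc$adapters) %||% character(0))
      trim_fastq(sim$fastq_path, trimmed, pol)
    })
    note("trimmed", trimmed, nrow(read_fastq(trimmed)))
  }

  if (!is.null(config$quantify)) {
    qc <- config$quantify
    if (is.null(sim)) stop("pipeline: 'quantify' requires 'simulate'",
                           call. = FALSE)
    counts_path <- file.path(outdir, "counts.tsv")
    stage("quantify", {
      q <- quantify_sample(sim$sam_path, ref$annotation,
                           position_cap = qc$position_cap %||% 100L,
                           min_overlap = qc$min_overlap %||% 1L,
                           ignore_strand = isTRUE(qc$ignore_strand),
                           collapse = qc$collapse %||% "pair")
      tab <- build_count_table(list(s1 = q$assignments),
                               features = ref$annotation$id,
                               library_sizes = c(s1 = q$n_mapped_reads))
      if (isTRUE(qc$cpm)) tab <- depth_normalize(tab)
      write_count_table(tab, counts_path)
    })
    note("counts", counts_path, nrow(ref$annotation))
  }

  if (!is.null(config$de)) {
    dc <- config$de
    de_path <- file.path(outdir, "de.tsv")
    stage("de", {
      msim <- simulate_count_matrix(sim_config(
        seed = seed,
        n_features = dc$n_features %||% 50L,
        n_per_group = dc$n_per_group %||% 4L,
        reads_per_sample = dc$reads_per_sample %||% 100000L,
        nb_dispersion = dc$nb_dispersion %||% 0.02,
        planted_log2fc = unlist(dc$planted_log2fc) %||% numeric(0)))
      de <- de_table(msim$table, msim$groups,
                     pseudocount = dc$pseudocount %||% 0.5,
                     fc_threshold = dc$fc %||% 1.5,
                     basemean_threshold = dc$basemean %||% 5)
      write_tsv(de, de_path)
    })
    note("de", de_path, dc$n_features %||% 50L)
  }

  if (!is.null(config$rip)) {
    rc <- config$rip
    rip_path <- file.path(outdir, "rip_targets.tsv")
    stage("rip", {
      rsim <- simulate_rip_experiment(sim_config(
        seed = seed,
        n_genes = rc$n_genes %||% 100L,
        rip_mean_count = rc$rip_mean_count %||% 100,
        planted_rip_targets = unlist(rc$planted_targets) %||% numeric(0)),
        noiseless = isTRUE(rc$noiseless))
      tg <- call_targets(rsim$experiment,
                         rpkm_min = rc$rpkm_min %||% 1.0,
                         pseudocount = rc$pseudocount %||% 1.0)
      write_tsv(tg, rip_path)
    })
    note("rip_targets", rip_path, rc$n_genes %||% 100L)
  }

  if (!is.null(config$qpcr)) {
    qq <- config$qpcr
    decay_path <- file.path(outdir, "decay_fit.tsv")
    stage("qpcr", {
      ser <- simulate_decay_series(sim_config(
        seed = seed,
        decay_halflife_h = qq$halflife_h %||% 3.07,
        noise_cv = qq$noise_cv %||% 0.05),
        timepoints_h = unlist(qq$timepoints_h) %||% c(0, 2, 4, 6, 8))
      fit <- fit_decay(ser, method = qq$method %||% "loglinear")
      write_tsv(data.frame(k = fit$k, halflife_h = fit$halflife_h,
                           r_squared = fit$r_squared,
                           true_halflife_h = ser$true_halflife_h),
                decay_path)
    })
    note("decay_fit", decay_path, 1L)
  }

  manifest <- list(
    tool = "mirflux",
    version = as.character(utils::packageVersion("mirflux")),
    seed = seed,
    config_digest = if (!is.null(cfg_text))
      digest_text(cfg_text) else digest_text(yaml::as.yaml(config)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = outputs)
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

digest_text <- function(lines) {
  f <- tempfile()
  con <- file(f, "wb"); writeLines(lines, con); close(con)
  on.exit(unlink(f))
  unname(tools::md5sum(f))
}

write_tsv <- function(df, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# strict schema: unknown keys anywhere are rejected by name
validate_pipeline_config <- function(config) {
  if (!is.list(config)) stop("pipeline config must be a named list",
                             call. = FALSE)
  schema <- list(
    seed = NA,
    simulate = c("n_chromosomes", "chrom_length", "n_precursors",
                 "mature_per_precursor", "frac_multimapping",
                 "reads_per_mature", "precursor_reads"),
    trim = c("leading_q", "trailing_q", "window_len", "window_meanq",
             "min_len", "adapters"),
    quantify = c("position_cap", "min_overlap", "ignore_strand",
                 "collapse", "cpm"),
    de = c("n_features", "n_per_group", "reads_per_sample",
           "nb_dispersion", "planted_log2fc", "pseudocount", "fc",
           "basemean"),
    rip = c("n_genes", "rip_mean_count", "planted_targets", "noiseless",
            "rpkm_min", "pseudocount"),
    qpcr = c("halflife_h", "noise_cv", "timepoints_h", "method"))
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown))
    stop("pipeline config: unknown key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (is.null(config$seed) || !is.numeric(config$seed))
    stop("pipeline config: 'seed' (integer) is required", call. = FALSE)
  for (sec in setdiff(names(config), "seed")) {
    bad <- setdiff(names(config[[sec]]), schema[[sec]])
    if (length(bad))
      stop("pipeline config: unknown key(s) in '", sec, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(config)
}
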