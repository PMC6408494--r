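#' Simulate an mRNA decay time course
#'
#' Generates percent-remaining values for a transcription-shutoff (e.g.
#' actinomycin D) experiment: the true curve is `100 * 2^(-t / t_half)`,
#' perturbed by multiplicative lognormal noise with coefficient of
#' variation `noise_cv`, then renormalized so the value at t = 0 is exactly
#' 100 (the measurement convention that sets mRNA content at the time of
#' shutoff to 100%).
#'
#' @param config A [sim_config()] object; uses `decay_halflife_h` and
#'   `noise_cv`.
#' @param timepoints_h Numeric vector of sampling times in hours; must
#'   include 0 and contain no negative value.
#' @return A `decay_series` object: list with `timepoints_h`,
#'   `percent_remaining`, and the planted `true_halflife_h`.
#' @examples
#' simulate_decay_series(sim_config(seed = 1, decay_halflife_h = 2,
#'                                  noise_cv = 0), c(0, 2, 4, 6, 8))
#' @export
simulate_decay_series <- function(config, timepoints_h = c(0, 2, 4, 6, 8)) {
  config <- validate_sim_config(config)
  if (any(timepoints_h < 0))
    stop("simulate_decay_series: negative timepoint", call. = FALSE)
  if (!any(timepoints_h == 0))
    stop("simulate_decay_series: timepoints must include 0", call. = FALSE)
  set.seed(sub_seed(config$seed, "decay"))

  true <- 100 * 2^(-timepoints_h / config$decay_halflife_h)
  if (config$noise_cv > 0) {
    sdlog <- sqrt(log(1 + config$noise_cv^2))
    noise <- stats::rlnorm(length(true), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    true <- true * noise
  }
  pct <- 100 * true / true[which(timepoints_h == 0)[1L]]
  structure(list(timepoints_h = timepoints_h, percent_remaining = pct,
                 true_halflife_h = config$decay_halflife_h),
            class = "decay_series")
}

#' @export
print.decay_series <- function(x, ...) {
  cat("decay_series (", length(x$timepoints_h), " timepoints, true t1/2 ",
      x$true_halflife_h, " h)\n", sep = "")
  print(data.frame(t_h = x$timepoints_h, percent = round(x$percent_remaining, 2)))
  invisible(x)
}
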