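#' Poisson droplet-occupancy probability
#'
#' Probability that a droplet contains exactly `k` cells when cells are
#' partitioned uniformly at random over a large droplet train, so that the
#' per-droplet occupancy is Poisson with mean `lam` (expected cells per
#' droplet): `exp(-lam) * lam^k / k!`.
#'
#' @param lam expected cells per droplet, `>= 0`.
#' @param k non-negative integer occupancy (vectorised).
#' @return probability vector.
#' @export
poisson_pmf <- function(lam, k) {
  if (!is.numeric(lam) || length(lam) != 1 || !is.finite(lam) || lam < 0) {
    stop_cmc("lam must be a single finite value >= 0", "cmcflow_domain_error")
  }
  if (!is_count(k)) {
    stop_cmc("k must be non-negative integer(s)", "cmcflow_domain_error")
  }
  if (lam == 0) return(as.numeric(k == 0))
  exp(k * log(lam) - lam - lgamma(k + 1))
}

#' Expected number of occupied droplets
#'
#' With `n_cells` cells distributed uniformly over `n_droplets` droplets the
#' occupancy is Poisson with mean `lambda = n_cells / n_droplets`. The
#' expected number of droplets holding at least one cell is
#' `n * (1 - exp(-lambda))`; holding exactly one cell,
#' `n * lambda * exp(-lambda)`. At 33 cells over 1000 droplets the
#' exactly-one expectation is about 31.9 — i.e. nearly every cell sits alone
#' in its droplet.
#'
#' @param n_cells non-negative integer.
#' @param n_droplets positive integer.
#' @param mode `"at_least_one"` or `"exactly_one"`.
#' @return expected droplet count (real).
#' @export
expected_occupied <- function(n_cells, n_droplets,
                              mode = c("at_least_one", "exactly_one")) {
  mode <- match.arg(mode)
  if (!is_count(n_cells) || length(n_cells) != 1) {
    stop_cmc("n_cells must be a non-negative integer", "cmcflow_domain_error")
  }
  if (!is_count(n_droplets) || length(n_droplets) != 1 || n_droplets < 1) {
    stop_cmc("n_droplets must be a positive integer", "cmcflow_domain_error")
  }
  lam <- n_cells / n_droplets
  switch(mode,
         at_least_one = n_droplets * (1 - exp(-lam)),
         exactly_one  = n_droplets * lam * exp(-lam))
}

#' Probability of multiple occupancy
#'
#' Probability that a droplet holds two or more cells under Poisson
#' occupancy: `P(k >= 2) = 1 - exp(-lam) * (1 + lam)`. At `lam = 0.5`
#' (500 cells over 1000 droplets) this is 0.0902; the single-occupancy
#' undercount this causes is what [corrected_count()] inverts.
#'
#' @param lam expected cells per droplet, `>= 0`.
#' @return probability.
#' @export
multi_occupancy_prob <- function(lam) {
  if (!is.numeric(lam) || length(lam) != 1 || !is.finite(lam) || lam < 0) {
    stop_cmc("lam must be a single finite value >= 0", "cmcflow_domain_error")
  }
  -expm1(-lam) - lam * exp(-lam)
}

#' Partition cells uniformly over droplets
#'
#' Assigns each of `n_cells` cells independently and uniformly to one of
#' `n_droplets` droplets (an equal-probability multinomial), emulating
#' two-phase flow of a well-mixed suspension. Uses R's global RNG stream.
#'
#' @param n_cells non-negative integer.
#' @param n_droplets positive integer.
#' @return integer occupancy vector of length `n_droplets` summing to
#'   `n_cells`.
#' @export
partition_cells <- function(n_cells, n_droplets) {
  if (!is_count(n_cells) || length(n_cells) != 1) {
    stop_cmc("n_cells must be a non-negative integer", "cmcflow_domain_error")
  }
  if (!is_count(n_droplets) || length(n_droplets) != 1 || n_droplets < 1) {
    stop_cmc("n_droplets must be a positive integer", "cmcflow_domain_error")
  }
  as.integer(stats::rmultinom(1, n_cells, rep(1 / n_droplets, n_droplets)))
}

#' Droplet run configuration
#'
#' Parameters for one simulated enumeration run. The defaults mirror the
#' instrument's operating point: a 1 ml sample split into ~1 microlitre
#' droplets (1000 droplets), a 60 microlitre/min flow rate (metadata only;
#' it sets assay duration, not statistics), and a detection threshold at 3x
#' the noise floor.
#'
#' The amplitude model is declared synthetic scaffolding — the instrument
#' literature specifies no amplitude distribution. Per-cell amplitudes are
#' log-normal with median `amp_median_rel` times the noise floor and
#' log-scale sd `amp_sdlog`, representing pigmentation heterogeneity. A
#' droplet's signal is the maximum over its cells (point absorbers; the
#' loudest dominates) plus additive Gaussian noise with sd
#' `noise_floor / 3`; empty droplets carry the noise magnitude alone.
#'
#' @param n_cells non-negative integer, cells placed in the sample.
#' @param sample_volume sample volume in microlitres (default 1000 = 1 ml).
#' @param droplet_volume droplet volume in microlitres (default 1).
#' @param flow_rate flow rate in microlitres/min, metadata only (default 60).
#' @param noise_floor positive amplitude of the blank noise floor
#'   (dimensionless units; default 1).
#' @param threshold_multiplier detection threshold as a multiple of the
#'   noise floor (default 3).
#' @param amp_median_rel median per-cell amplitude relative to the noise
#'   floor (default 10).
#' @param amp_sdlog log-scale sd of the per-cell amplitude law (default 0.5).
#' @param rng_seed integer seed; every run is reproducible given the seed.
#' @return an object of class `droplet_run_config`.
#' @export
droplet_run_config <- function(n_cells,
                               sample_volume = 1000,
                               droplet_volume = 1,
                               flow_rate = 60,
                               noise_floor = 1,
                               threshold_multiplier = 3,
                               amp_median_rel = 10,
                               amp_sdlog = 0.5,
                               rng_seed = 1L) {
  if (!is_count(n_cells) || length(n_cells) != 1) {
    stop_cmc("n_cells must be a non-negative integer", "cmcflow_config_error")
  }
  if (noise_floor <= 0) {
    stop_cmc("noise_floor must be positive", "cmcflow_config_error")
  }
  if (threshold_multiplier <= 0) {
    stop_cmc("threshold_multiplier must be positive", "cmcflow_config_error")
  }
  n_droplets <- floor(sample_volume / droplet_volume)
  if (n_droplets < 1) {
    stop_cmc("sample_volume / droplet_volume must give at least one droplet",
             "cmcflow_config_error")
  }
  if (amp_median_rel <= 0) {
    stop_cmc("amp_median_rel must be positive", "cmcflow_config_error")
  }
  structure(
    list(n_cells = as.integer(n_cells), sample_volume = sample_volume,
         droplet_volume = droplet_volume, n_droplets = as.integer(n_droplets),
         flow_rate = flow_rate, noise_floor = noise_floor,
         threshold_multiplier = threshold_multiplier,
         amp_median_rel = amp_median_rel, amp_sdlog = amp_sdlog,
         rng_seed = as.integer(rng_seed)),
    class = "droplet_run_config"
  )
}

#' Simulate one droplet enumeration run
#'
#' Partitions the cells over the droplet train, draws per-droplet signal
#' amplitudes, classifies each droplet against the strict threshold
#' (`amplitude > threshold_multiplier * noise_floor`; a droplet exactly at
#' threshold is negative, a conservative false-positive rule matching blank
#' runs yielding no detections), and enumerates. One positive droplet counts
#' as one cell in `raw_count`; `corrected_count` additionally inverts the
#' Poisson occupancy bias (see [corrected_count()]).
#'
#' Draw order under the seed is fixed and documented: partition first, then
#' per-cell amplitudes in droplet order, then per-droplet noise.
#'
#' @param config a [droplet_run_config()].
#' @return an object of class `droplet_run_result`: a list with `droplets`
#'   (data.frame: `index` 0-based, `occupancy`, `amplitude`, `positive`),
#'   `raw_count`, `corrected_count`, `true_cells` and the echoed `config`.
#' @export
simulate_run <- function(config) {
  stopifnot(inherits(config, "droplet_run_config"))
  set.seed(config$rng_seed)
  n <- config$n_droplets
  occ <- partition_cells(config$n_cells, n)
  amp <- numeric(n)
  occupied <- which(occ > 0)
  meanlog <- log(config$amp_median_rel * config$noise_floor)
  for (i in occupied) {
    cell_amps <- stats::rlnorm(occ[i], meanlog = meanlog,
                               sdlog = config$amp_sdlog)
    amp[i] <- max(cell_amps)
  }
  noise <- stats::rnorm(n, mean = 0, sd = config$noise_floor / 3)
  # empty droplets show only the noise magnitude; occupied droplets the
  # signal plus noise, floored at zero (amplitudes are magnitudes)
  amp[occ == 0] <- abs(noise[occ == 0])
  amp[occ > 0] <- pmax(amp[occ > 0] + noise[occ > 0], 0)
  thr <- config$threshold_multiplier * config$noise_floor
  pos <- amp > thr
  m <- sum(pos)
  corrected <- if (m < n) corrected_count(m, n) else NA_real_
  structure(
    list(droplets = data.frame(index = seq_len(n) - 1L, occupancy = occ,
                               amplitude = amp, positive = pos),
         raw_count = as.integer(m), corrected_count = corrected,
         true_cells = config$n_cells, config = config),
    class = "droplet_run_result"
  )
}

#' @export
print.droplet_run_result <- function(x, ...) {
  cat(sprintf(
    "<droplet_run_result> %d droplets: %d positive (raw), %.2f corrected, %d true cells\n",
    nrow(x$droplets), x$raw_count, x$corrected_count, x$true_cells))
  invisible(x)
}

#' Estimate the noise floor from a blank run
#'
#' Operational definition used throughout: the peak absolute amplitude over
#' a blank (cell-free, PBS-like) droplet train of `n_blank` droplets whose
#' per-droplet noise is Gaussian with sd `noise_sd`.
#'
#' @param noise_sd Gaussian noise sd of the blank signal.
#' @param n_blank number of blank droplets (default 1000).
#' @return estimated noise floor (positive amplitude).
#' @export
estimate_noise_floor <- function(noise_sd, n_blank = 1000) {
  if (noise_sd <= 0) stop_cmc("noise_sd must be positive",
                              "cmcflow_domain_error")
  max(abs(stats::rnorm(n_blank, 0, noise_sd)))
}

#' Occupancy-corrected cell count
#'
#' A positive droplet is counted as one cell, so multiply-occupied droplets
#' cause an undercount. Under Poisson occupancy the maximum-likelihood
#' estimate of the true cell number given `m` positive droplets out of `n`
#' is `-n * log(1 - m/n)`, the exact inverse of the at-least-one expectation
#' in [expected_occupied()]; it equals `m` to first order when `m << n`.
#'
#' @param m_positive number of positive droplets, `0 <= m < n`.
#' @param n_droplets total droplets.
#' @return real-valued corrected estimate.
#' @export
corrected_count <- function(m_positive, n_droplets) {
  if (!is_count(m_positive) || !is_count(n_droplets) ||
      length(m_positive) != 1 || length(n_droplets) != 1 || n_droplets < 1) {
    stop_cmc("m_positive and n_droplets must be non-negative integers",
             "cmcflow_domain_error")
  }
  if (m_positive >= n_droplets) {
    stop_cmc("all droplets positive: occupancy estimate saturates (m = n)",
             "cmcflow_saturation_error")
  }
  -n_droplets * log1p(-m_positive / n_droplets)
}

#' Export a run result
#'
#' Writes the per-droplet records as CSV and a JSON summary (raw and
#' corrected counts, ground truth, and the config echo).
#'
#' @param result a `droplet_run_result`.
#' @param csv_file,json_file output paths; either may be `NULL` to skip.
#' @return invisibly, the list of paths written.
#' @export
write_run_result <- function(result, csv_file = NULL, json_file = NULL) {
  stopifnot(inherits(result, "droplet_run_result"))
  if (!is.null(csv_file)) {
    utils::write.csv(result$droplets, csv_file, row.names = FALSE,
                     quote = FALSE)
  }
  if (!is.null(json_file)) {
    jsonlite::write_json(
      list(raw_count = result$raw_count,
           corrected_count = result$corrected_count,
           true_cells = result$true_cells,
           config = unclass(result$config)),
      json_file, auto_unbox = TRUE, digits = NA)
  }
  invisible(list(csv = csv_file, json = json_file))
}
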