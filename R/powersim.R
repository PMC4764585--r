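#' Configuration for the two-lineage power simulation
#'
#' Describes one simulation condition for assessing the power of the
#' rate-comparison framework. One lineage decays at `base_rate` per Myr; the
#' second decays faster by `rate_delta` (its rate is `base_rate - rate_delta`).
#' At every divergence time in `distances_myr`, `draws_per_distance` similarity
#' values per lineage are drawn from a normal distribution centred on the
#' expected decay value \eqn{\exp(\mathrm{rate} \cdot t)} with standard
#' deviation `noise_sd` (on the similarity scale, so 0.005 is 0.5 percentage
#' points around a similarity near 1).
#'
#' The default distance panel spans roughly 2--100 Myrs, mirroring the species
#' pairs used in the occupancy analyses (e.g. mouse--human at 91 Myrs,
#' mouse--dog at 97.4 Myrs).
#'
#' @param base_rate Per-Myr decay rate of the slower lineage (negative).
#' @param rate_delta Absolute rate difference >= 0.
#' @param noise_sd Similarity-scale standard deviation (> 0).
#' @param distances_myr Divergence-time panel in Myrs.
#' @param draws_per_distance Draws per (lineage, distance); default 2.
#' @param n_sims Number of simulated datasets per condition; default 1000.
#' @return A `power_config` list.
#' @export
power_config <- function(base_rate = -0.005, rate_delta = 0,
                         noise_sd = 0.005,
                         distances_myr = c(2, 7, 13, 25, 45, 60, 91, 97),
                         draws_per_distance = 2, n_sims = 1000) {
  stopifnot(noise_sd > 0, n_sims >= 1, length(distances_myr) > 0,
            all(distances_myr >= 0), rate_delta >= 0, draws_per_distance >= 1)
  structure(
    list(base_rate = base_rate, rate_delta = rate_delta, noise_sd = noise_sd,
         distances_myr = distances_myr,
         draws_per_distance = as.integer(draws_per_distance),
         n_sims = as.integer(n_sims)),
    class = "power_config"
  )
}

#' Simulate similarity observations for two lineages
#'
#' Draws one simulated dataset under a `power_config`: for each lineage and
#' each divergence time, `draws_per_distance` values from
#' \eqn{N(\exp(\mathrm{rate} \cdot t), \mathrm{noise\_sd})}. Lineage `"L1"`
#' decays at `base_rate`, lineage `"L2"` at `base_rate - rate_delta`.
#'
#' @param config A [power_config()].
#' @return A tibble of similarity observations (columns `pair_id`, `lineage`,
#'   `divergence_myr`, `similarity`). Negative draws are possible at high
#'   noise; the fitting step drops them (they cannot be log-transformed).
#' @export
simulate_two_lineages <- function(config) {
  stopifnot(inherits(config, "power_config"))
  rates <- c(L1 = config$base_rate, L2 = config$base_rate - config$rate_delta)
  d <- config$distances_myr
  r <- config$draws_per_distance
  t_all <- rep(rep(d, each = r), times = 2L)
  lin <- rep(names(rates), each = length(d) * r)
  mu <- exp(rates[lin] * t_all)
  tibble::tibble(
    pair_id = paste0(lin, "_t", t_all, "_d", rep(seq_len(r), times = 2L * length(d))),
    lineage = lin,
    divergence_myr = t_all,
    similarity = stats::rnorm(length(mu), mean = mu, sd = config$noise_sd)
  )
}

#' Detection frequency of the rate-comparison framework
#'
#' Runs [compare_rates()] on `n_sims` datasets simulated under `config` and
#' returns the fraction whose verdict is `"different"`. Set the RNG seed
#' before calling for reproducibility.
#'
#' @param config A [power_config()].
#' @param alpha,effect_threshold,horizon_myr Decision parameters passed to
#'   [compare_rates()].
#' @param keep_verdicts If `TRUE`, include the per-simulation verdict vector.
#' @return A one-row tibble with the configuration values, `n_detected` and
#'   `detection_frequency` (and a `verdicts` list-column when requested).
#' @export
detection_frequency <- function(config, alpha = 0.05, effect_threshold = 5,
                                horizon_myr = 100, keep_verdicts = FALSE) {
  stopifnot(inherits(config, "power_config"))
  verdicts <- character(config$n_sims)
  for (i in seq_len(config$n_sims)) {
    obs <- simulate_two_lineages(config)
    # suppress the non-positive-similarity drop warning inside the sweep;
    # drops are expected at high noise and counted by the fit itself
    cmp <- suppressWarnings(
      compare_rates(obs, alpha = alpha, effect_threshold = effect_threshold,
                    horizon_myr = horizon_myr)
    )
    verdicts[i] <- cmp$verdict
  }
  n_det <- sum(verdicts == "different")
  out <- tibble::tibble(
    base_rate = config$base_rate, rate_delta = config$rate_delta,
    noise_sd = config$noise_sd, n_sims = config$n_sims,
    n_detected = n_det,
    detection_frequency = n_det / config$n_sims
  )
  if (keep_verdicts) out$verdicts <- list(verdicts)
  out
}

#' Power grid over rate differences, base rates and noise levels
#'
#' Full factorial sweep of [detection_frequency()] over the supplied rate
#' differences, base rates and noise standard deviations. The paper-style
#' headline numbers aggregate the three base rates at a given
#' (noise, delta): use [aggregate_power()] on the result.
#'
#' @param deltas Absolute rate differences to test.
#' @param base_rates Base decay rates (default the three used throughout:
#'   -0.007, -0.005, -0.003).
#' @param noise_sds Noise levels (default 0.005 and 0.05).
#' @param n_sims Simulations per grid cell.
#' @param seed Integer seed; each cell gets an independent derived seed.
#' @param ... Passed to [detection_frequency()].
#' @return A tibble with one row per (base_rate, noise_sd, delta).
#' @export
power_grid <- function(deltas, base_rates = c(-0.007, -0.005, -0.003),
                       noise_sds = c(0.005, 0.05), n_sims = 1000,
                       seed = 1, ...) {
  stopifnot(length(deltas) > 0, length(base_rates) > 0, length(noise_sds) > 0)
  cells <- tidyr::expand_grid(base_rate = base_rates, noise_sd = noise_sds,
                              rate_delta = deltas)
  purrr::pmap_dfr(cells, function(base_rate, noise_sd, rate_delta) {
    cfg <- power_config(base_rate = base_rate, rate_delta = rate_delta,
                        noise_sd = noise_sd, n_sims = n_sims)
    set.seed(split_seed(seed, sprintf("power_%g_%g_%g", base_rate, noise_sd, rate_delta)))
    detection_frequency(cfg, ...)
  })
}

#' Aggregate a power grid over base rates
#'
#' @param grid Output of [power_grid()].
#' @return A tibble keyed by (noise_sd, rate_delta) with the detection
#'   frequency pooled over base rates.
#' @export
aggregate_power <- function(grid) {
  grid |>
    dplyr::group_by(.data$noise_sd, .data$rate_delta) |>
    dplyr::summarise(
      n_sims = sum(.data$n_sims),
      n_detected = sum(.data$n_detected),
      detection_frequency = sum(.data$n_detected) / sum(.data$n_sims),
      .groups = "drop"
    )
}

#' Plot a power grid
#'
#' Detection frequency against rate difference, one panel per base rate,
#' coloured by noise level.
#'
#' @param grid Output of [power_grid()].
#' @return A ggplot object.
#' @export
plot_power_grid <- function(grid) {
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$rate_delta,
                                     y = .data$detection_frequency,
                                     colour = factor(.data$noise_sd))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~.data$base_rate, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Absolute rate difference (per Myr)",
                  y = "Detection frequency", colour = "noise sd") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
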