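#' Simulation configuration for the synthetic herd generator
#'
#' Bundles every knob of the synthetic positioning system. Defaults emulate
#' the study conditions: a herd tracked at 0.1 Hz (one fix per 10 s) for
#' full days, three daily milking absences (centred on 05:00, 13:00 and
#' 21:00), positional noise with a 50% circular error probability (CEP50)
#' of 1.90 m as measured for a collar-mounted sensor on a standing cow, and
#' occasional stuck-sensor and out-of-barn artifacts.
#'
#' @param n_cows number of animals (>= 2).
#' @param n_days number of simulated days.
#' @param sample_interval seconds between fixes (default 10 s = 0.1 Hz).
#' @param day_seconds length of the simulated day in seconds. Defaults to a
#'   full 86400 s day; calibration studies may use shorter days.
#' @param milking_windows list of numeric length-2 vectors, in-day seconds
#'   during which cows are absent for milking. Default: 80 min windows
#'   centred on 05:00, 13:00, 21:00.
#' @param milking_mode `"absent"` drops records during milking windows;
#'   `"parlor"` emits records at a parlor location outside the barn
#'   (mirroring the real system, where parlor fixes were recorded and later
#'   filtered out).
#' @param noise_cep50 metres; CEP50 of the isotropic Gaussian positional
#'   noise added by [inject_artifacts()]. The Gaussian sigma is
#'   `cep50 / sqrt(2 log 2)`.
#' @param stuck_rate expected number of stuck-sensor runs per cow-day.
#' @param stuck_mean_len mean length (in samples) of a stuck run; lengths
#'   are `min_len + Geometric`, with `min_len = 12`.
#' @param oob_rate per-record probability of replacement by a far
#'   out-of-barn erroneous fix.
#' @param affinity_spread dispersion of dyadic preference weights; 0 means
#'   no preference structure (all dyads equivalent).
#' @param assortment_effect coupling of attribute similarity to affinity;
#'   0 means no attribute assortment.
#' @param truth_radius metres; planted (noise-free) inter-cow distances at
#'   or below this radius are logged as ground-truth contact.
#' @param move list of movement-model parameters: AR(1) coefficient `phi`
#'   per tick; around-station jitter standard deviations `sd_rest`,
#'   `sd_feed`, `sd_loaf` (metres); `sd_anchor`, the per-bout scatter of a
#'   structured cow's station around its personal anchor; `p_loaf`, the
#'   probability a bout switch goes to loafing; `sync`, the probability a
#'   structured cow follows its affinity cluster's shared bout schedule
#'   (bout-start synchronization) rather than its own clock; and mean bout
#'   durations in seconds (`mean_feed`, `mean_rest`, `mean_loaf`).
#' @param record_truth logical; log ground-truth contact intervals.
#' @param seed integer master seed for the generator.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_cows = 10, n_days = 1, seed = 1)
#' cfg$noise_cep50
#' @export
sim_config <- function(n_cows = 92,
                       n_days = 28,
                       sample_interval = 10,
                       day_seconds = 86400,
                       milking_windows = default_milking_windows(),
                       milking_mode = c("absent", "parlor"),
                       noise_cep50 = 1.90,
                       stuck_rate = 0.3,
                       stuck_mean_len = 30,
                       oob_rate = 5e-4,
                       affinity_spread = 0.6,
                       assortment_effect = 0,
                       truth_radius = 3,
                       move = list(),
                       record_truth = TRUE,
                       seed = 1L) {
  milking_mode <- match.arg(milking_mode)
  stopifnot(n_cows >= 2, n_days >= 1, sample_interval > 0, day_seconds > 0)
  if (!all(is.finite(c(noise_cep50, stuck_rate, stuck_mean_len, oob_rate,
                       affinity_spread, assortment_effect, truth_radius))))
    stop("non-finite configuration parameter")
  if (noise_cep50 < 0 || stuck_rate < 0 || oob_rate < 0 ||
      affinity_spread < 0 || truth_radius <= 0)
    stop("rates and scales must be non-negative (truth_radius > 0)")
  for (w in milking_windows)
    if (length(w) != 2 || w[1] >= w[2]) stop("malformed milking window")
  move_defaults <- list(phi = 0.8, sd_rest = 0.8, sd_feed = 0.6, sd_loaf = 1.5,
                        sd_anchor = 0.5, p_loaf = 0.2, sync = 0.6,
                        mean_feed = 2400, mean_rest = 4200, mean_loaf = 600)
  move <- utils::modifyList(move_defaults, move)
  cfg <- list(
    n_cows = as.integer(n_cows), n_days = as.integer(n_days),
    sample_interval = sample_interval, day_seconds = day_seconds,
    milking_windows = milking_windows, milking_mode = milking_mode,
    noise_cep50 = noise_cep50, stuck_rate = stuck_rate,
    stuck_mean_len = stuck_mean_len, oob_rate = oob_rate,
    affinity_spread = affinity_spread, assortment_effect = assortment_effect,
    truth_radius = truth_radius, move = move,
    record_truth = isTRUE(record_truth), seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Default daily milking absence windows
#'
#' Three 80-minute windows centred on the study farm's milking times
#' (05:00, 13:00, 21:00), expressed in in-day seconds.
#'
#' @param width_s window width in seconds (default 4800 s = 80 min).
#' @return list of numeric length-2 vectors `c(start, end)`.
#' @export
default_milking_windows <- function(width_s = 4800) {
  centres <- c(5, 13, 21) * 3600
  lapply(centres, function(ct) c(ct - width_s / 2, ct + width_s / 2))
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Herd simulation config: %d cows x %d days @ %.0f s/fix\n",
              x$n_cows, x$n_days, x$sample_interval))
  cat(sprintf("  day length %.0f s, %d milking window(s), mode '%s'\n",
              x$day_seconds, length(x$milking_windows), x$milking_mode))
  cat(sprintf("  noise CEP50 %.2f m; stuck %.2g/cow-day (mean %d pts); oob %.2g\n",
              x$noise_cep50, x$stuck_rate, as.integer(x$stuck_mean_len),
              x$oob_rate))
  cat(sprintf("  affinity spread %.2f, assortment effect %.2f, seed %d\n",
              x$affinity_spread, x$assortment_effect, x$seed))
  invisible(x)
}

# number of samples per day and in-day tick times (seconds) after removing
# milking windows (interval [start, end) in in-day seconds)
day_tick_times <- function(config) {
  if (config$day_seconds < config$sample_interval)
    stop("zero-length day: day_seconds smaller than sample_interval")
  ticks <- seq(0, config$day_seconds - config$sample_interval,
               by = config$sample_interval)
  keep <- rep(TRUE, length(ticks))
  for (w in config$milking_windows)
    keep <- keep & !(ticks >= w[1] & ticks < w[2])
  list(all = ticks, keep = keep)
}
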