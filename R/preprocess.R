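#' Trajectory cleaning pipeline
#'
#' The cleaning stages mirror the field workflow for indoor positioning
#' data, applied in a fixed order:
#' 1. [filter_to_region()] — drop fixes further than a buffer outside the
#'    barn (removes parlor/collecting-yard fixes and gross errors);
#' 2. [remove_stuck_runs()] — drop runs where a sensor repeats (almost)
#'    the same coordinate for many consecutive samples;
#' 3. [smooth_trajectory()] — centred moving average (default 15 samples
#'    = 150 s at 0.1 Hz), losing half a window at each segment end;
#' 4. [remove_stationary_days()] — drop whole cow-days that stayed
#'    essentially in one spot.
#'
#' Each stage reports the fraction of the *original* record count it
#' removed; only smoothing ever alters coordinates, and no stage alters a
#' retained record's animal id or timestamp.
#'
#' @name preprocess
NULL

validate_positions <- function(positions) {
  need <- c("animal_id", "day_index", "timestamp", "x_m", "y_m")
  if (!all(need %in% names(positions)))
    stop("positions must have columns: ", paste(need, collapse = ", "))
  invisible(positions)
}

# error if any animal's timestamps are not strictly increasing
check_sorted <- function(positions) {
  dt <- data.table::as.data.table(positions)
  bad <- dt[, .(ok = !is.unsorted(timestamp, strictly = TRUE)), by = animal_id]
  if (any(!bad$ok))
    stop("timestamps must be strictly increasing within each animal ",
         "(offending: ", paste(utils::head(bad$animal_id[!bad$ok], 3),
                               collapse = ", "), ")")
  invisible(positions)
}

#' Filter positions to the (buffered) barn region
#'
#' Retains records whose point lies inside the barn rectangle dilated by
#' `buffer_m`. The buffer avoids excluding data due to minor positional
#' inaccuracy at the barn edge; what falls outside it is parlor/yard time
#' or gross sensor error.
#'
#' @param positions positions data.frame.
#' @param geometry a [barn_geometry()].
#' @param buffer_m dilation in metres (default 3).
#' @return list with `positions` (retained records) and `removed_fraction`
#'   relative to the input count.
#' @export
filter_to_region <- function(positions, geometry, buffer_m = 3) {
  validate_positions(positions)
  stopifnot(inherits(geometry, "barn_geometry"), buffer_m >= 0)
  n0 <- nrow(positions)
  if (n0 == 0) return(list(positions = positions, removed_fraction = 0))
  rect <- zone_rect(geometry, "full_barn", buffer_m)
  keep <- points_in_rect(positions$x_m, positions$y_m, rect)
  list(positions = positions[keep, , drop = FALSE],
       removed_fraction = 1 - sum(keep) / n0)
}

#' Remove stuck-sensor runs
#'
#' Per cow and day, finds maximal runs of at least `min_run` consecutive
#' records all within `eps_m` of the run's first point, and removes every
#' record of such runs. Genuine lying bouts survive because sensor noise
#' jitters fixes far more than the default 5 cm tolerance; exact (or
#' near-exact) repeats are reset/stuck artifacts.
#'
#' @param positions positions data.frame (timestamps must be strictly
#'   increasing per animal; unsorted input is rejected, not sorted).
#' @param min_run minimum run length in samples (default 12 = 2 min).
#' @param eps_m tolerance radius in metres (default 0.05).
#' @return list with `positions` and `removed_fraction`.
#' @export
remove_stuck_runs <- function(positions, min_run = 12, eps_m = 0.05) {
  validate_positions(positions)
  stopifnot(min_run >= 2, eps_m >= 0)
  check_sorted(positions)
  n0 <- nrow(positions)
  if (n0 == 0) return(list(positions = positions, removed_fraction = 0))
  grp <- paste(positions$animal_id, positions$day_index)
  remove <- logical(n0)
  for (g in split(seq_len(n0), grp)) {
    x <- positions$x_m[g]; y <- positions$y_m[g]
    m <- length(g)
    if (m < min_run) next
    # fast path: an anchored run implies consecutive displacements <= 2 eps
    step_close <- c(FALSE, (diff(x)^2 + diff(y)^2) <= (2 * eps_m)^2 + 1e-12)
    if (!any(step_close)) next
    i <- 1L
    eps2 <- eps_m^2 + 1e-12
    while (i <= m - min_run + 1L) {
      if (!step_close[i + 1L]) { i <- i + 1L; next }
      j <- i + 1L
      while (j <= m && (x[j] - x[i])^2 + (y[j] - y[i])^2 <= eps2) j <- j + 1L
      if (j - i >= min_run) remove[g[i:(j - 1L)]] <- TRUE
      i <- j
    }
  }
  list(positions = positions[!remove, , drop = FALSE],
       removed_fraction = sum(remove) / n0)
}

#' Moving-average trajectory smoothing
#'
#' Replaces each coordinate by the unweighted mean of a centred window of
#' `window` samples, computed per cow within contiguous same-day segments
#' (a time gap larger than `sample_interval` breaks a segment, so milking
#' absences never smear across). The `(window - 1) / 2` records at each
#' segment end, which lack a full window, are dropped; segments shorter
#' than `window` are dropped whole.
#'
#' @param positions positions data.frame.
#' @param window odd window size in samples (default 15 = 150 s at 0.1 Hz).
#' @param sample_interval seconds between nominal fixes (gap threshold).
#' @return list with `positions` (smoothed, edge records dropped) and
#'   `removed_fraction`.
#' @export
smooth_trajectory <- function(positions, window = 15, sample_interval = 10) {
  validate_positions(positions)
  if (window %% 2 == 0) stop("window must be odd")
  stopifnot(window >= 3)
  check_sorted(positions)
  n0 <- nrow(positions)
  if (n0 == 0) return(list(positions = positions, removed_fraction = 0))
  half <- (window - 1) / 2
  dt <- data.table::as.data.table(positions)
  dt[, `:=`(.row = .I)]
  dt[, seg := cumsum(c(TRUE, diff(timestamp) > sample_interval + 1e-9) |
                       c(TRUE, diff(day_index) != 0)),
     by = animal_id]
  kern <- rep(1 / window, window)
  roll <- function(v) {
    if (length(v) < window) return(rep(NA_real_, length(v)))
    as.numeric(stats::filter(v, kern, sides = 2))
  }
  dt[, `:=`(xs = roll(x_m), ys = roll(y_m)), by = .(animal_id, seg)]
  dt <- dt[!is.na(xs) & !is.na(ys)]
  out <- positions[dt$.row, , drop = FALSE]
  out$x_m <- dt$xs
  out$y_m <- dt$ys
  rownames(out) <- NULL
  list(positions = out, removed_fraction = 1 - nrow(out) / n0)
}

#' Remove stationary cow-days
#'
#' Drops every record of a cow-day in which the animal stayed essentially
#' in one spot for most of the day: if at least `min_span_fraction` of the
#' day's records lie within `max_daily_displacement_m / 2` of the day's
#' componentwise median point (so their bounding extent is at most the
#' displacement threshold), the whole cow-day is removed.
#'
#' @param positions positions data.frame.
#' @param max_daily_displacement_m bounding-extent threshold in metres
#'   (default 5).
#' @param min_span_fraction fraction of the day's records that must be
#'   confined for the day to count as stationary (default 0.9).
#' @return list with `positions` and `removed_fraction`.
#' @export
remove_stationary_days <- function(positions, max_daily_displacement_m = 5,
                                   min_span_fraction = 0.9) {
  validate_positions(positions)
  stopifnot(max_daily_displacement_m > 0,
            min_span_fraction > 0, min_span_fraction <= 1)
  n0 <- nrow(positions)
  if (n0 == 0) return(list(positions = positions, removed_fraction = 0))
  r2 <- (max_daily_displacement_m / 2)^2
  dt <- data.table::as.data.table(positions)
  flag <- dt[, {
    near <- (x_m - stats::median(x_m))^2 + (y_m - stats::median(y_m))^2 <= r2
    .(stationary = mean(near) >= min_span_fraction)
  }, by = .(animal_id, day_index)]
  dt <- merge(dt, flag, by = c("animal_id", "day_index"), sort = FALSE)
  keep_dt <- dt[!(stationary)]
  out <- as.data.frame(keep_dt[, names(positions), with = FALSE])
  out <- out[order(out$animal_id, out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  list(positions = out, removed_fraction = 1 - nrow(out) / n0)
}

#' Run the full cleaning pipeline
#'
#' Applies region filtering, stuck-run removal, smoothing and
#' stationary-day removal in that fixed order, accounting for each stage's
#' removal as a fraction of the *original* record count.
#'
#' @param positions raw positions data.frame.
#' @param geometry a [barn_geometry()].
#' @param params list of stage parameters; recognised entries
#'   `region_buffer_m` (3), `stuck_min_run` (12), `stuck_eps_m` (0.05),
#'   `smooth_window` (15), `sample_interval` (10),
#'   `stationary_max_disp_m` (5), `stationary_min_fraction` (0.9).
#' @return object of class `clean_result`: list with `positions` (cleaned),
#'   `stages` (data.frame: stage, removed_count, removed_fraction) and
#'   `total_removed_fraction`.
#' @examples
#' geom <- barn_geometry()
#' pos <- data.frame(animal_id = "c1", day_index = 1,
#'                   timestamp = seq(0, 990, 10),
#'                   x_m = seq(1, 50, length.out = 100),
#'                   y_m = rep(5, 100))
#' res <- clean_pipeline(pos, geom)
#' res$stages
#' @export
clean_pipeline <- function(positions, geometry, params = list()) {
  validate_positions(positions)
  p <- utils::modifyList(list(
    region_buffer_m = 3, stuck_min_run = 12, stuck_eps_m = 0.05,
    smooth_window = 15, sample_interval = 10,
    stationary_max_disp_m = 5, stationary_min_fraction = 0.9), params)
  n0 <- nrow(positions)
  s1 <- filter_to_region(positions, geometry, p$region_buffer_m)
  s2 <- remove_stuck_runs(s1$positions, p$stuck_min_run, p$stuck_eps_m)
  s3 <- smooth_trajectory(s2$positions, p$smooth_window, p$sample_interval)
  s4 <- remove_stationary_days(s3$positions, p$stationary_max_disp_m,
                               p$stationary_min_fraction)
  counts <- c(nrow(s1$positions), nrow(s2$positions),
              nrow(s3$positions), nrow(s4$positions))
  removed <- c(n0, counts[-4]) - counts
  stages <- data.frame(
    stage = c("region_filter", "stuck_removal", "smoothing",
              "stationary_day_removal"),
    removed_count = removed,
    removed_fraction = if (n0 > 0) removed / n0 else rep(0, 4),
    stringsAsFactors = FALSE)
  out <- list(positions = s4$positions, stages = stages,
              total_removed_fraction = if (n0 > 0) 1 - counts[4] / n0 else 0,
              params = p, n_original = n0)
  class(out) <- "clean_result"
  out
}

#' @export
print.clean_result <- function(x, ...) {
  cat(sprintf("Cleaned positions: %d of %d records retained (%.2f%% removed)\n",
              nrow(x$positions), x$n_original,
              100 * x$total_removed_fraction))
  for (i in seq_len(nrow(x$stages)))
    cat(sprintf("  %-24s removed %8d (%.3f%%)\n", x$stages$stage[i],
                x$stages$removed_count[i],
                100 * x$stages$removed_fraction[i]))
  invisible(x)
}
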