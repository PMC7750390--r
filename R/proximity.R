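#' Proximity interaction protocol
#'
#' Defines what counts as a sustained proximity interaction: all (strict
#' mode) or a fraction `lenient_fraction` (lenient mode) of the inter-cow
#' distances over `window_points` consecutive, gap-free samples must lie
#' within radius `r`. The default follows the study protocol: r = 3 m over
#' t = 60 s, i.e. 6 samples at 0.1 Hz (`window_points = round(t /
#' sample_interval)`). `windowing` controls how qualifying windows are
#' counted: `"tumbling"` consumes a match (advances a full window past it),
#' making daily counts proportional to sustained contact time; `"sliding"`
#' counts every qualifying window.
#'
#' @param r radius in metres (> 0).
#' @param t duration in seconds (> 0).
#' @param sample_interval seconds between samples.
#' @param window_points samples per window; derived from `t` by default.
#' @param mode `"strict"` or `"lenient"`; strict is lenient with f = 1.
#' @param lenient_fraction fraction f in (0, 1] of in-radius samples
#'   required in lenient mode.
#' @param windowing `"tumbling"` (default) or `"sliding"`.
#' @param inclusive_threshold logical; distances equal to `r` qualify
#'   (default TRUE).
#' @return object of class `proximity_protocol`.
#' @examples
#' proximity_protocol()                      # 3 m, 60 s, strict, tumbling
#' proximity_protocol(r = 2, t = 100)        # 10 samples
#' @export
proximity_protocol <- function(r = 3, t = 60, sample_interval = 10,
                               window_points = NULL,
                               mode = c("strict", "lenient"),
                               lenient_fraction = 1,
                               windowing = c("tumbling", "sliding"),
                               inclusive_threshold = TRUE) {
  mode <- match.arg(mode)
  windowing <- match.arg(windowing)
  stopifnot(r > 0, t > 0, sample_interval > 0,
            lenient_fraction > 0, lenient_fraction <= 1)
  if (is.null(window_points)) window_points <- as.integer(round(t / sample_interval))
  window_points <- as.integer(window_points)
  if (window_points < 2) stop("window_points must be >= 2")
  if (mode == "strict") lenient_fraction <- 1
  proto <- list(r = r, t = t, sample_interval = sample_interval,
                window_points = window_points, mode = mode,
                lenient_fraction = lenient_fraction, windowing = windowing,
                inclusive_threshold = isTRUE(inclusive_threshold))
  class(proto) <- "proximity_protocol"
  proto
}

#' @export
print.proximity_protocol <- function(x, ...) {
  cat(sprintf(
    "Proximity protocol: r = %.2f m over %d samples (%.0f s), %s%s, %s windows\n",
    x$r, x$window_points, x$t, x$mode,
    if (x$mode == "lenient") sprintf(" (f = %.2f)", x$lenient_fraction) else "",
    x$windowing))
  invisible(x)
}

#' Number of dyads in a herd
#'
#' @param n herd size (>= 2).
#' @return n(n-1)/2, the number of unordered pairs.
#' @examples
#' dyad_count(92)  # 4186
#' dyad_count(48)  # 1128
#' @export
dyad_count <- function(n) {
  if (any(n < 2)) stop("need at least 2 animals")
  n * (n - 1) / 2
}

#' Filter positions into a functional zone
#'
#' Retains records inside the zone's rectangle dilated by `buffer_m`.
#' The `full_barn` zone is the barn rectangle itself (the union of the two
#' functional zones' unbuffered extents).
#'
#' @param positions positions data.frame.
#' @param geometry a [barn_geometry()].
#' @param zone `"full_barn"`, `"feeding"` or `"non_feeding"`.
#' @param buffer_m dilation in metres; defaults to the geometry's
#'   `zone_buffer` for the functional zones and 0 for `full_barn`.
#' @return filtered positions data.frame.
#' @export
zone_filter <- function(positions, geometry, zone,
                        buffer_m = if (zone == "full_barn") 0 else geometry$zone_buffer) {
  validate_positions(positions)
  rect <- zone_rect(geometry, zone, buffer_m)
  keep <- points_in_rect(positions$x_m, positions$y_m, rect)
  out <- positions[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pair two animals' tracks into a distance series
#'
#' Joins on common timestamps and emits the Euclidean inter-animal
#' distance per shared sample. Timestamps present in only one track leave
#' gaps, which later break window contiguity in [detect_interactions()].
#'
#' @param track_a,track_b positions data.frames, one animal each, sorted.
#' @return data.frame with columns `time` and `dist`.
#' @examples
#' a <- data.frame(animal_id = "a", day_index = 1, timestamp = 0,
#'                 x_m = 0, y_m = 0)
#' b <- data.frame(animal_id = "b", day_index = 1, timestamp = 0,
#'                 x_m = 3, y_m = 4)
#' align_dyad(a, b)$dist  # 5
#' @export
align_dyad <- function(track_a, track_b) {
  if (length(unique(track_a$animal_id)) > 1 ||
      length(unique(track_b$animal_id)) > 1)
    stop("each track must contain a single animal")
  idx <- match(track_a$timestamp, track_b$timestamp)
  sel <- !is.na(idx)
  if (!any(sel))
    return(data.frame(time = numeric(0), dist = numeric(0)))
  ta <- track_a[sel, , drop = FALSE]
  tb <- track_b[idx[sel], , drop = FALSE]
  data.frame(time = ta$timestamp,
             dist = sqrt((ta$x_m - tb$x_m)^2 + (ta$y_m - tb$y_m)^2))
}

# qualifying window start positions for a distance series under a protocol
qualifying_starts <- function(time, dist, protocol) {
  n <- length(dist)
  w <- protocol$window_points
  if (is.unsorted(time, strictly = TRUE)) stop("distance series must be time-ordered")
  if (n < w) return(integer(0))
  ok <- if (protocol$inclusive_threshold) dist <= protocol$r + 1e-12
        else dist < protocol$r
  contig <- c(TRUE, abs(diff(time) - protocol$sample_interval) < 1e-9)
  # window [i, i+w-1] is contiguous iff contig[i+1..i+w-1] all TRUE
  cs_ok <- cumsum(ok)
  cs_ct <- cumsum(contig)
  i <- seq_len(n - w + 1L)
  n_ok <- cs_ok[i + w - 1L] - cs_ok[i] + ok[i]
  n_ct <- cs_ct[i + w - 1L] - cs_ct[i]          # counts contig[i+1 .. i+w-1]
  kmin <- ceiling(protocol$lenient_fraction * w - 1e-9)
  which(n_ct == w - 1L & n_ok >= kmin)
}

#' Detect sustained proximity interactions in a distance series
#'
#' Scans the paired distance series for qualifying windows under the
#' protocol. A candidate window is `window_points` consecutive samples
#' whose timestamps are exactly `sample_interval` apart; it qualifies if
#' all (strict) or at least fraction f (lenient) of its distances are
#' within radius r. Tumbling counting scans left to right and advances a
#' full window past each match; sliding counting counts every qualifying
#' window.
#'
#' @param series data.frame with columns `time`, `dist` (or two vectors via
#'   `time` and `dist` arguments).
#' @param protocol a [proximity_protocol()].
#' @return list with `count` (integer) and `window_starts` (times at which
#'   counted windows begin).
#' @examples
#' s <- data.frame(time = seq(0, 110, 10), dist = rep(2, 12))
#' detect_interactions(s, proximity_protocol())$count  # 2 (tumbling)
#' @export
detect_interactions <- function(series, protocol) {
  stopifnot(inherits(protocol, "proximity_protocol"))
  time <- series$time; dist <- series$dist
  if (length(time) != length(dist)) stop("time/dist length mismatch")
  q <- qualifying_starts(time, dist, protocol)
  if (length(q) == 0L)
    return(list(count = 0L, window_starts = numeric(0)))
  w <- protocol$window_points
  if (protocol$windowing == "sliding")
    return(list(count = length(q), window_starts = time[q]))
  # tumbling: greedy consume-on-match over runs of consecutive qualifying starts
  counted <- integer(0)
  brk <- which(diff(q) > 1L)
  run_start <- q[c(1L, brk + 1L)]
  run_end <- q[c(brk, length(q))]
  p <- 1L
  for (k in seq_along(run_start)) {
    s <- max(run_start[k], p)
    if (s > run_end[k]) next
    hits <- seq.int(s, run_end[k], by = w)
    counted <- c(counted, hits)
    p <- hits[length(hits)] + w
  }
  list(count = length(counted), window_starts = time[counted])
}

#' Daily interaction matrix for a zone
#'
#' Applies the zone filter, then for every dyad pairs the two animals'
#' tracks within the day and counts sustained proximity interactions under
#' the protocol. Returns a symmetric count matrix over the full roster
#' (animals with no surviving records simply contribute zero counts), with
#' NA on the diagonal.
#'
#' @param positions cleaned positions data.frame (may span several days).
#' @param geometry a [barn_geometry()].
#' @param zone zone label.
#' @param protocol a [proximity_protocol()].
#' @param day_index which day to score.
#' @param roster character vector of animal ids fixing matrix dimension
#'   and order; defaults to the ids present in `positions`.
#' @param collect_windows logical; also return the counted window start
#'   times per dyad (needed for sensitivity validation).
#' @return an `interaction_matrix`: integer matrix with attributes
#'   `day_index` and `zone`; if `collect_windows`, a list with elements
#'   `matrix` and `windows` (data.frame id_a, id_b, start, end).
#' @export
daily_interaction_matrix <- function(positions, geometry, zone, protocol,
                                     day_index, roster = NULL,
                                     collect_windows = FALSE) {
  validate_positions(positions)
  if (is.null(roster)) roster <- sort(unique(positions$animal_id))
  n <- length(roster)
  if (n < 2) stop("roster must contain at least 2 animals")
  if (!all(unique(positions$animal_id) %in% roster))
    stop("positions contain animals missing from the roster")
  day_pos <- positions[positions$day_index == day_index, , drop = FALSE]
  zp <- zone_filter(day_pos, geometry, zone)
  tracks <- split(zp, factor(zp$animal_id, levels = roster))
  M <- matrix(0L, n, n, dimnames = list(roster, roster))
  win <- if (collect_windows) vector("list", dyad_count(n)) else NULL
  k <- 0L
  w_span <- (protocol$window_points - 1) * protocol$sample_interval
  for (i in seq_len(n - 1)) {
    ti <- tracks[[i]]
    for (j in (i + 1):n) {
      k <- k + 1L
      tj <- tracks[[j]]
      if (nrow(ti) == 0 || nrow(tj) == 0) next
      ser <- align_dyad(ti, tj)
      det <- detect_interactions(ser, protocol)
      M[i, j] <- M[j, i] <- det$count
      if (collect_windows && det$count > 0)
        win[[k]] <- data.frame(id_a = roster[i], id_b = roster[j],
                               start = det$window_starts,
                               end = det$window_starts + w_span,
                               stringsAsFactors = FALSE)
    }
  }
  diag(M) <- NA_integer_
  attr(M, "day_index") <- day_index
  attr(M, "zone") <- zone
  class(M) <- c("interaction_matrix", class(M))
  if (!collect_windows) return(M)
  windows <- do.call(rbind, win[!vapply(win, is.null, logical(1))])
  if (is.null(windows))
    windows <- data.frame(id_a = character(), id_b = character(),
                          start = numeric(), end = numeric(),
                          stringsAsFactors = FALSE)
  list(matrix = M, windows = windows)
}

#' Sensitivity of the detection protocol against ground truth
#'
#' Fraction of true contact intervals overlapped by at least one detected
#' window for the same dyad (true positive rate).
#'
#' @param windows detected windows data.frame (`id_a`, `id_b`, `start`,
#'   `end`), e.g. from [daily_interaction_matrix()] with
#'   `collect_windows = TRUE`.
#' @param truth ground-truth contact intervals data.frame (`id_a`, `id_b`,
#'   `start`, `end`), e.g. `simulate_herd()$truth$intervals`.
#' @param min_true_length seconds; ignore true intervals shorter than this
#'   (default 0 keeps all).
#' @return sensitivity in [0, 1].
#' @export
validate_sensitivity <- function(windows, truth, min_true_length = 0) {
  if (nrow(truth) == 0) stop("empty ground-truth set")
  truth <- truth[truth$end - truth$start >= min_true_length, , drop = FALSE]
  if (nrow(truth) == 0) stop("no ground-truth intervals after length filter")
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  tk <- key(truth$id_a, truth$id_b)
  wk <- if (nrow(windows)) key(windows$id_a, windows$id_b) else character(0)
  hit <- logical(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    sel <- wk == tk[i]
    if (!any(sel)) next
    hit[i] <- any(windows$start[sel] <= truth$end[i] &
                    windows$end[sel] >= truth$start[i])
  }
  mean(hit)
}

#' Sweep protocol parameters over a radius/duration grid
#'
#' Re-scores a day's interactions for every combination of radius and
#' duration, mirroring the robustness sweep (r in 1..5 m at t = 60 s and
#' t in 40..100 s at r = 3 m in the study).
#'
#' @param positions cleaned positions data.frame.
#' @param geometry a [barn_geometry()].
#' @param zone zone label.
#' @param day_index day to score.
#' @param r_grid radii in metres.
#' @param t_grid durations in seconds.
#' @param ... further arguments passed to [proximity_protocol()].
#' @return data.frame with columns `r`, `t`, `total_interactions`,
#'   `edge_density`.
#' @export
sweep_protocol <- function(positions, geometry, zone, day_index,
                           r_grid = 1:5, t_grid = c(40, 60, 80, 100), ...) {
  grid <- expand.grid(r = r_grid, t = t_grid)
  res <- lapply(seq_len(nrow(grid)), function(k) {
    proto <- proximity_protocol(r = grid$r[k], t = grid$t[k], ...)
    M <- daily_interaction_matrix(positions, geometry, zone, proto, day_index)
    data.frame(r = grid$r[k], t = grid$t[k],
               total_interactions = sum(M[upper.tri(M)]),
               edge_density = edge_density(M))
  })
  do.call(rbind, res)
}
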