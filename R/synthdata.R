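#' Generate a synthetic cow-attributes table
#'
#' Draws parity, days in milk (DIM) and three fortnightly mobility-score
#' sessions for a herd, then derives the lameness class with
#' [classify_lameness()]. Mobility scores use the 0-3 scale (0 good,
#' 3 severely impaired); 2-3 count as clinically lame. A small fraction of
#' sessions are "NS" (not scored), which excludes the cow from the lameness
#' classification, as in the field protocol.
#'
#' @param n_cows herd size.
#' @param seed integer seed.
#' @param p_lame marginal probability a session scores 2-3.
#' @param p_ns probability a session is not scored.
#' @return data.frame with columns `animal_id`, `parity`, `days_in_milk`,
#'   `score_1`..`score_3`, `lameness_class`.
#' @examples
#' attrs <- make_cow_attributes(10, seed = 1)
#' table(attrs$lameness_class)
#' @export
make_cow_attributes <- function(n_cows, seed = 1L, p_lame = 0.3, p_ns = 0.03) {
  stopifnot(n_cows >= 2)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  # per-cow latent lameness propensity keeps sessions correlated, so the
  # dominant-status patterns (L-L-NL etc.) actually occur
  prop <- stats::rbeta(n_cows, 2 * p_lame / (1 - p_lame), 2)
  draw_session <- function() {
    lame <- stats::runif(n_cows) < prop
    sc <- ifelse(lame, sample(c("2", "3"), n_cows, replace = TRUE),
                 sample(c("0", "1"), n_cows, replace = TRUE))
    sc[stats::runif(n_cows) < p_ns] <- "NS"
    sc
  }
  s1 <- draw_session(); s2 <- draw_session(); s3 <- draw_session()
  cls <- vapply(seq_len(n_cows),
                function(i) classify_lameness(c(s1[i], s2[i], s3[i])),
                character(1))
  data.frame(
    animal_id = cow_ids(n_cows),
    parity = pmax(1L, stats::rpois(n_cows, 2) + 1L),
    days_in_milk = pmax(0L, as.integer(round(stats::rnorm(n_cows, 136, 60)))),
    score_1 = s1, score_2 = s2, score_3 = s3,
    lameness_class = cls,
    stringsAsFactors = FALSE
  )
}

cow_ids <- function(n) sprintf("cow_%03d", seq_len(n))

#' Plant a dyadic affinity structure
#'
#' Builds a symmetric positive affinity matrix over all dyads. Affinities
#' combine an idiosyncratic preference term (log-normal with dispersion
#' `affinity_spread`) with an attribute-assortment term: the log affinity
#' decreases by `assortment_effect` per standard deviation of absolute
#' attribute difference, so a large positive effect makes similar animals
#' strongly preferred partners. With `affinity_spread = 0` and
#' `assortment_effect = 0` every off-diagonal entry equals 1 (no structure).
#'
#' @param n_cows herd size (>= 2).
#' @param affinity_spread standard deviation of the idiosyncratic log
#'   preference (>= 0).
#' @param assortment_effect coupling of attribute similarity to affinity.
#' @param attr_values numeric vector of length `n_cows` (e.g. days in milk
#'   or parity); standardised internally. Ignored when
#'   `assortment_effect = 0` (may be `NULL` then).
#' @param seed integer seed.
#' @return symmetric `n_cows` x `n_cows` matrix, positive off-diagonal,
#'   zero diagonal, row/col names set to the cow ids.
#' @examples
#' a <- plant_affinity(5, affinity_spread = 0.5, assortment_effect = 1,
#'                     attr_values = 1:5, seed = 1)
#' isSymmetric(a)
#' @export
plant_affinity <- function(n_cows, affinity_spread, assortment_effect,
                           attr_values = NULL, seed = 1L) {
  stopifnot(n_cows >= 2)
  if (!all(is.finite(c(affinity_spread, assortment_effect))) ||
      affinity_spread < 0)
    stop("affinity parameters must be finite, spread >= 0")
  if (assortment_effect != 0) {
    if (is.null(attr_values) || length(attr_values) != n_cows ||
        !all(is.finite(attr_values)))
      stop("attr_values of length n_cows required when assortment_effect != 0")
  }
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  logA <- matrix(0, n_cows, n_cows)
  if (affinity_spread > 0) {
    eps <- matrix(stats::rnorm(n_cows^2, 0, affinity_spread), n_cows, n_cows)
    eps[lower.tri(eps)] <- t(eps)[lower.tri(eps)]
    logA <- logA + eps
  }
  if (assortment_effect != 0) {
    z <- as.numeric(scale(attr_values))
    if (all(!is.finite(z))) z <- rep(0, n_cows)  # constant attribute
    d <- abs(outer(z, z, "-"))
    logA <- logA - assortment_effect * d
  }
  A <- exp(logA)
  diag(A) <- 0
  dimnames(A) <- list(cow_ids(n_cows), cow_ids(n_cows))
  A
}

rescale_to <- function(v, r) {
  s <- diff(range(v))
  if (s < 1e-12) return(rep(mean(r), length(v)))
  (v - min(v)) / s * diff(r) + r[1]
}

# is there any planted dyadic structure in the affinity matrix? For a
# single dyad (n = 2) dispersion is unobservable, so any departure from
# the neutral unit weight counts as structure
affinity_structured <- function(affinity) {
  off <- affinity[upper.tri(affinity)]
  if (length(off) < 2) return(abs(off - 1) > 1e-12)
  stats::sd(off) > 1e-12
}

# rectangle shrunk around its centre to a herd-size-dependent area
# (constant stocking density, so small test herds remain as crowded as a
# full barn)
pack_rect <- function(rect, n, margin = 1, density = 0.1) {
  xr <- rect$x + c(margin, -margin)
  yr <- rect$y + c(margin, -margin)
  full_area <- diff(xr) * diff(yr)
  target <- n / density
  if (target < full_area) {
    s <- sqrt(target / full_area)
    xr <- mean(xr) + c(-0.5, 0.5) * s * diff(xr)
    yr <- mean(yr) + c(-0.5, 0.5) * s * diff(yr)
  }
  list(x = xr, y = yr)
}

# 2-D personal station anchors from the affinity structure: classical MDS
# on -log(normalised affinity), scaled into the packed rectangle, so
# high-affinity dyads hold nearby anchors. Only meaningful for structured
# affinity; with n = 2 the single dyad's scale is arbitrary and both
# anchors sit at the rectangle's centre (maximal affinity reading).
affinity_anchors <- function(affinity, rect) {
  n <- nrow(affinity)
  if (n < 3)
    return(cbind(rep(mean(rect$x), n), rep(mean(rect$y), n)))
  d <- -log(affinity / max(affinity) + 1e-12)
  diag(d) <- 0
  emb <- suppressWarnings(stats::cmdscale(d, k = 2))
  if (ncol(emb) < 2) emb <- cbind(emb, stats::rnorm(n, 0, 1e-3))
  cbind(rescale_to(emb[, 1], rect$x), rescale_to(emb[, 2], rect$y))
}

# x-range of the crowded feed face (roughly 1 m of feed space per cow)
feed_face_range <- function(n, rect, spacing = 1) {
  len <- min(max(n * spacing, 6), diff(rect$x) - 2)
  mean(rect$x) + c(-0.5, 0.5) * len
}

# 1-D feed-face anchors along the affinity embedding's leading axis
feed_face_stations <- function(affinity, xr) {
  n <- nrow(affinity)
  if (n < 3) return(rep(mean(xr), n))
  d <- -log(affinity / max(affinity) + 1e-12)
  diag(d) <- 0
  emb <- suppressWarnings(stats::cmdscale(d, k = 1))
  rescale_to(emb[, 1], xr)
}

#' Simulate herd trajectories with known ground truth
#'
#' Generates noise-free positional records for every cow: a semi-Markov
#' bout process alternates feeding-zone bouts (at a feed-face station),
#' resting bouts (at a cubicle station) and short loafing excursions, with
#' Ornstein-Uhlenbeck-style jitter around the active station. Station
#' anchors are placed by a spectral embedding of the affinity matrix so
#' high-affinity dyads hold nearby stations and therefore co-locate;
#' bout switching follows a shared daily template (feed delivery after
#' morning milking, push-ups during the day) plus per-cow noise. Records
#' during milking windows are absent (or parlor-located, see
#' [sim_config()]). Ground-truth contact intervals are logged whenever the
#' planted inter-cow distance is at or below `config$truth_radius`.
#'
#' @param config a [sim_config()].
#' @param geometry a [barn_geometry()].
#' @param affinity symmetric affinity matrix from [plant_affinity()]; if
#'   `NULL`, planted from `config$affinity_spread` / `assortment_effect`
#'   with attributes drawn by [make_cow_attributes()].
#' @param attributes optional cow-attributes table (used for assortment).
#' @return list of class `herd_sim` with elements `positions` (data.frame:
#'   `animal_id`, `day_index`, `timestamp` in epoch-style seconds, `x_m`,
#'   `y_m`), `truth` (list: `intervals` data.frame of per-dyad contact
#'   intervals, `affinity` matrix), `attributes`, and the echoed `config`
#'   and `geometry`.
#' @examples
#' cfg <- sim_config(n_cows = 4, n_days = 1, day_seconds = 1800,
#'                   milking_windows = list(), seed = 2)
#' sim <- simulate_herd(cfg, barn_geometry())
#' head(sim$positions)
#' @export
simulate_herd <- function(config, geometry, affinity = NULL,
                          attributes = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(geometry, "barn_geometry"))
  n <- config$n_cows
  if (is.null(attributes)) attributes <- make_cow_attributes(n, seed = config$seed + 101L)
  if (is.null(affinity)) {
    affinity <- plant_affinity(n, config$affinity_spread,
                               config$assortment_effect,
                               attr_values = attributes$days_in_milk,
                               seed = config$seed + 202L)
  }
  if (nrow(affinity) != n || !isSymmetric(unname(affinity)))
    stop("affinity matrix must be symmetric with dimension n_cows")

  old <- local_seed(config$seed)
  on.exit(restore_seed(old))

  tk <- day_tick_times(config)
  ticks <- tk$all
  nt <- length(ticks)
  if (nt < 1) stop("zero-length day: day_seconds smaller than sample_interval")
  si <- config$sample_interval
  mv <- config$move

  # station geometry: packed resting area and crowded feed face; personal
  # anchors exist only when the affinity matrix carries planted structure,
  # otherwise every bout's station is drawn fresh (no dyadic structure)
  structured <- affinity_structured(affinity)
  rest_rect <- pack_rect(geometry$non_feeding, n, margin = 1)
  feed_y <- geometry$feeding$y[2] - 0.7  # at the feed face
  feed_xr <- feed_face_range(n, geometry$barn)
  rest_anchor <- if (structured) affinity_anchors(affinity, rest_rect) else NULL
  feed_x <- if (structured) feed_face_stations(affinity, feed_xr) else NULL

  ids <- rownames(affinity)
  if (is.null(ids)) ids <- cow_ids(n)

  # shared daily template: feeding pressure peaks after each milking window
  # (fresh feed / push-ups); used to bias bout-type choice
  feed_pressure <- function(t_in_day) {
    p <- 0.3
    for (w in config$milking_windows) {
      dt <- t_in_day - w[2]
      p <- p + 0.55 * exp(-pmax(dt, 0) / 3600) * (dt >= 0)
    }
    pmin(p, 0.95)
  }

  clamp <- function(v, r) pmin(pmax(v, r[1] + 0.05), r[2] - 0.05)

  # semi-Markov bout state schedule over the day's ticks
  make_schedule <- function() {
    state <- integer(0)
    cur <- 0L
    s <- if (stats::runif(1) < 0.5) 1L else 2L
    while (cur < nt) {
      mean_len <- switch(s, mv$mean_rest, mv$mean_feed, mv$mean_loaf) / si
      len <- 1L + stats::rgeom(1, 1 / mean_len)
      len <- min(len, nt - cur)
      state <- c(state, rep(s, len))
      cur <- cur + len
      fp <- feed_pressure(ticks[min(cur + 1L, nt)])
      s <- if (s == 2L) {
        if (stats::runif(1) < mv$p_loaf) 3L else 1L
      } else {
        if (stats::runif(1) < fp) 2L
        else if (stats::runif(1) < mv$p_loaf) 3L else 1L
      }
    }
    state
  }

  # affinity clusters drive bout-start synchronization: cows in the same
  # cluster tend to begin feeding/resting bouts together
  cluster_of <- rep(1L, n)
  if (structured && n > 2) {
    k <- max(1L, as.integer(round(n / 6)))
    if (k > 1) {
      km <- tryCatch(stats::kmeans(rest_anchor, centers = k, nstart = 3),
                     error = function(e) NULL)
      if (!is.null(km)) cluster_of <- km$cluster
    }
  }

  pos_list <- vector("list", n * config$n_days)
  nk <- sum(tk$keep)
  XY <- if (config$record_truth)
    array(NA_real_, dim = c(nk, 2, n, config$n_days)) else NULL

  for (day in seq_len(config$n_days)) {
    cluster_schedules <- lapply(seq_len(max(cluster_of)),
                                function(k) make_schedule())
    for (i in seq_len(n)) {
      # bout schedule: synchronized cows follow their affinity cluster's
      # schedule; the rest switch on their own clock
      state <- if (structured && stats::runif(1) < mv$sync)
        cluster_schedules[[cluster_of[i]]] else make_schedule()
      # per-bout station targets
      bouts <- rle(state)
      ends <- cumsum(bouts$lengths)
      starts <- ends - bouts$lengths + 1L
      tgt_x <- numeric(nt); tgt_y <- numeric(nt)
      for (b in seq_along(bouts$values)) {
        idx <- starts[b]:ends[b]
        st <- switch(bouts$values[b],
          {  # rest: personal cubicle anchor (structured) or any free spot
            if (structured)
              c(rest_anchor[i, 1] + stats::rnorm(1, 0, mv$sd_anchor),
                rest_anchor[i, 2] + stats::rnorm(1, 0, mv$sd_anchor))
            else
              c(stats::runif(1, rest_rect$x[1], rest_rect$x[2]),
                stats::runif(1, rest_rect$y[1], rest_rect$y[2]))
          },
          {  # feed: preferred feed-face position (structured) or any slot
            fx <- if (structured)
              feed_x[i] + stats::rnorm(1, 0, mv$sd_anchor)
            else stats::runif(1, feed_xr[1], feed_xr[2])
            c(fx, feed_y)
          },
          {  # loaf: anywhere in the barn
            c(stats::runif(1, geometry$barn$x[1] + 1, geometry$barn$x[2] - 1),
              stats::runif(1, geometry$barn$y[1] + 1, geometry$barn$y[2] - 1))
          })
        tgt_x[idx] <- st[1]; tgt_y[idx] <- st[2]
      }
      sdv <- c(mv$sd_rest, mv$sd_feed, mv$sd_loaf)[state]
      innov_x <- stats::rnorm(nt, 0, sdv * sqrt(1 - mv$phi^2))
      innov_y <- stats::rnorm(nt, 0, sdv * sqrt(1 - mv$phi^2))
      dev_x <- as.numeric(stats::filter(innov_x, mv$phi, method = "recursive"))
      dev_y <- as.numeric(stats::filter(innov_y, mv$phi, method = "recursive"))
      x <- clamp(tgt_x + dev_x, geometry$barn$x)
      y <- clamp(tgt_y + dev_y, geometry$barn$y)

      if (config$record_truth) {
        XY[, 1, i, day] <- x[tk$keep]
        XY[, 2, i, day] <- y[tk$keep]
      }
      keep <- tk$keep
      tt <- (day - 1) * 86400 + ticks
      if (config$milking_mode == "parlor") {
        # parlor sits outside the barn, beyond the feed face
        x[!keep] <- mean(geometry$barn$x) + stats::rnorm(sum(!keep), 0, 2)
        y[!keep] <- geometry$barn$y[2] + 12 + stats::rnorm(sum(!keep), 0, 2)
        keep <- rep(TRUE, nt)
      }
      pos_list[[(day - 1) * n + i]] <- data.frame(
        animal_id = ids[i], day_index = day, timestamp = tt[keep],
        x_m = x[keep], y_m = y[keep], stringsAsFactors = FALSE)
    }
  }
  positions <- do.call(rbind, pos_list)
  positions <- positions[order(positions$animal_id, positions$timestamp), ]
  rownames(positions) <- NULL

  truth_intervals <- NULL
  if (config$record_truth) {
    truth_intervals <- truth_contacts(XY, ticks[tk$keep], ids, config)
  }
  out <- list(positions = positions,
              truth = list(intervals = truth_intervals, affinity = affinity),
              attributes = attributes, config = config, geometry = geometry)
  class(out) <- "herd_sim"
  out
}

# ground-truth contact intervals from the noise-free position array
# XY[kept tick, coord, cow, day]; ticks are the kept in-day tick times.
# A contact run is consecutive kept samples with distance <= truth_radius;
# runs break across gaps (milking absences)
truth_contacts <- function(XY, ticks, ids, config) {
  n <- dim(XY)[3]
  gap_before <- c(FALSE, diff(ticks) > config$sample_interval + 1e-9)
  res <- list()
  k <- 0L
  for (day in seq_len(dim(XY)[4])) {
    base_t <- (day - 1) * 86400
    for (i in seq_len(n - 1)) {
      dx0 <- XY[, 1, i, day]; dy0 <- XY[, 2, i, day]
      for (j in (i + 1):n) {
        d2 <- (dx0 - XY[, 1, j, day])^2 + (dy0 - XY[, 2, j, day])^2
        inc <- d2 <= config$truth_radius^2
        if (!any(inc)) next
        change <- c(TRUE, inc[-1] != inc[-length(inc)]) | gap_before
        firsts <- which(change)
        lasts <- c(firsts[-1] - 1L, length(inc))
        w <- which(inc[firsts])
        k <- k + 1L
        res[[k]] <- data.frame(
          day_index = day, id_a = ids[i], id_b = ids[j],
          start = base_t + ticks[firsts[w]], end = base_t + ticks[lasts[w]],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (k == 0L)
    return(data.frame(day_index = integer(), id_a = character(),
                      id_b = character(), start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Inject sensor artifacts into clean simulated positions
#'
#' Applies, in order: (a) isotropic Gaussian positional noise with the
#' configured CEP50 (`sigma = cep50 / sqrt(2 log 2)`, the circular-normal
#' identity); (b) stuck-sensor runs, in which a random stretch of a cow-day
#' repeats the stretch's first (noisy) coordinate exactly; (c) isolated
#' erroneous fixes far outside the barn. An `artifact` column records which
#' records were altered by (b) or (c) so the cleaning stages can be
#' validated against the bookkeeping.
#'
#' @param positions positions data.frame (see [simulate_herd()]).
#' @param config a [sim_config()]; uses `noise_cep50`, `stuck_rate`,
#'   `stuck_mean_len`, `oob_rate` and `seed`.
#' @param geometry a [barn_geometry()] (for placing out-of-barn points).
#' @return positions data.frame with perturbed coordinates and an
#'   `artifact` column in `{"none","stuck","oob"}`.
#' @export
inject_artifacts <- function(positions, config, geometry = barn_geometry()) {
  stopifnot(inherits(config, "sim_config"))
  if (config$stuck_rate < 0 || config$oob_rate < 0 || config$noise_cep50 < 0)
    stop("negative artifact rates")
  out <- positions
  out$artifact <- "none"
  if (config$noise_cep50 == 0 && config$stuck_rate == 0 && config$oob_rate == 0)
    return(out)
  old <- local_seed(config$seed + 404L)
  on.exit(restore_seed(old))
  nr <- nrow(out)
  if (config$noise_cep50 > 0) {
    sigma <- cep50_to_sigma(config$noise_cep50)
    out$x_m <- out$x_m + stats::rnorm(nr, 0, sigma)
    out$y_m <- out$y_m + stats::rnorm(nr, 0, sigma)
  }
  if (config$stuck_rate > 0) {
    grp <- paste(out$animal_id, out$day_index)
    idx <- split(seq_len(nr), grp)
    for (g in idx) {
      n_ev <- stats::rpois(1, config$stuck_rate)
      if (n_ev == 0) next
      for (e in seq_len(n_ev)) {
        len <- 12L + stats::rgeom(1, 1 / max(config$stuck_mean_len - 12, 1))
        if (length(g) <= len) next
        s <- sample.int(length(g) - len, 1)
        run <- g[s:(s + len - 1L)]
        out$x_m[run] <- out$x_m[run[1]]
        out$y_m[run] <- out$y_m[run[1]]
        out$artifact[run] <- "stuck"
      }
    }
  }
  if (config$oob_rate > 0) {
    hit <- which(stats::runif(nr) < config$oob_rate)
    if (length(hit)) {
      ang <- stats::runif(length(hit), 0, 2 * pi)
      rad <- stats::runif(length(hit), 20, 60)
      cx <- mean(geometry$barn$x); cy <- mean(geometry$barn$y)
      half_diag <- sqrt(diff(geometry$barn$x)^2 + diff(geometry$barn$y)^2) / 2
      out$x_m[hit] <- cx + (half_diag + rad) * cos(ang)
      out$y_m[hit] <- cy + (half_diag + rad) * sin(ang)
      out$artifact[hit] <- "oob"
    }
  }
  out
}

#' CEP50 to Gaussian sigma (circular normal)
#'
#' For isotropic bivariate Gaussian noise the median radial error (CEP50)
#' is `sigma * sqrt(2 log 2)`; this inverts that identity.
#'
#' @param cep50 median radial error in metres.
#' @return per-axis standard deviation in metres.
#' @export
cep50_to_sigma <- function(cep50) cep50 / sqrt(2 * log(2))

# -- seed hygiene: run RNG under a seed, restore the caller's state --------
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed %% 2147483646L))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
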