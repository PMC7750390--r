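# fixtures and independent oracles used across the suite; everything is
# generated in code under fixed seeds

toy_track <- function(id, timestamps, x, y, day = 1L) {
  data.frame(animal_id = id, day_index = day, timestamp = timestamps,
             x_m = x, y_m = y, stringsAsFactors = FALSE)
}

# random symmetric count matrix with NA diagonal
random_count_matrix <- function(n, lambda = 3, seed = 1) {
  set.seed(seed)
  m <- matrix(0L, n, n)
  m[upper.tri(m)] <- stats::rpois(n * (n - 1) / 2, lambda)
  m <- m + t(m)
  diag(m) <- NA_integer_
  dimnames(m) <- list(sprintf("c%02d", 1:n), sprintf("c%02d", 1:n))
  m
}

# --- independent detection oracle: enumerate every candidate window ------
naive_detect <- function(time, dist, r, w, si, f = 1,
                         windowing = "tumbling", inclusive = TRUE) {
  n <- length(time)
  n_start <- max(n - w + 1L, 0L)
  if (n_start == 0L) return(0L)
  qual <- logical(n_start)
  for (i in seq_len(n_start)) {
    idx <- i:(i + w - 1L)
    contig <- all(abs(diff(time[idx]) - si) < 1e-9)
    ok <- if (inclusive) dist[idx] <= r + 1e-12 else dist[idx] < r
    qual[i] <- contig && (mean(ok) >= f - 1e-9)
  }
  if (windowing == "sliding") return(sum(qual))
  cnt <- 0L; i <- 1L
  while (i <= n_start) {
    if (qual[i]) { cnt <- cnt + 1L; i <- i + w } else i <- i + 1L
  }
  cnt
}

# random distance series with occasional timestamp gaps
random_series <- function(len, si = 10, gap_prob = 0.05, r_scale = 4) {
  steps <- ifelse(stats::runif(len - 1) < gap_prob,
                  si * (1 + stats::rpois(len - 1, 2)), si)
  time <- cumsum(c(0, steps))
  dist <- stats::runif(len, 0, r_scale)
  data.frame(time = time, dist = dist)
}

# --- independent connected-components oracle: BFS on the binary graph ----
bfs_components <- function(m) {
  m <- as.matrix(m); diag(m) <- 0; m[is.na(m)] <- 0
  n <- nrow(m)
  comp <- integer(n); cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(m[v, ] >= 1 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# --- independent stuck-run removal oracle: anchored O(n^2) scan ----------
naive_stuck_removed <- function(x, y, min_run, eps) {
  n <- length(x)
  removed <- logical(n)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j <= n && sqrt((x[j] - x[i])^2 + (y[j] - y[i])^2) <= eps + 1e-12)
      j <- j + 1L
    if (j - i >= min_run) removed[i:(j - 1L)] <- TRUE
    i <- max(j, i + 1L)
  }
  removed
}

# a small noise-free structured herd used by several tests
small_sim <- function(n_cows = 6, n_days = 1, seed = 11, spread = 0.8,
                      effect = 0, day_seconds = 3600,
                      milking = list(), truth = TRUE, ...) {
  cfg <- sim_config(n_cows = n_cows, n_days = n_days,
                    day_seconds = day_seconds, milking_windows = milking,
                    noise_cep50 = 0, stuck_rate = 0, oob_rate = 0,
                    affinity_spread = spread, assortment_effect = effect,
                    record_truth = truth, seed = seed, ...)
  simulate_herd(cfg, barn_geometry())
}
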