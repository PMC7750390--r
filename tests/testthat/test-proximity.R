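geom <- barn_geometry()

test_that("dyad counts follow n(n-1)/2", {
  expect_equal(dyad_count(2), 1)
  expect_equal(dyad_count(5), 10)
  expect_error(dyad_count(1), "at least 2")
})

test_that("zone filtering respects the buffered rectangles", {
  pos <- toy_track("c1", c(0, 10, 20), c(10, 10, 10), c(12, 9, 1))
  # y = 12 inside the feeding zone proper
  expect_equal(nrow(zone_filter(pos[1, ], geom, "feeding")), 1)
  # y = 9 outside [10.5, 17.2] but within the 3 m buffer
  expect_equal(nrow(zone_filter(pos[2, ], geom, "feeding")), 1)
  # y = 1 beyond the buffered bound
  expect_equal(nrow(zone_filter(pos[3, ], geom, "feeding")), 0)
  expect_error(zone_filter(pos, geom, "lounge"), "unknown zone")
})

test_that("dyad alignment pairs common timestamps and computes distance", {
  a <- toy_track("a", seq(0, 50, 10), rep(0, 6), rep(0, 6))
  b <- toy_track("b", seq(0, 50, 10), rep(3, 6), rep(4, 6))
  ser <- align_dyad(a, b)
  expect_equal(nrow(ser), 6)
  expect_true(all(ser$dist == 5))  # 3-4-5 triangle
  # disjoint grids: empty series
  b2 <- toy_track("b", seq(100, 150, 10), rep(3, 6), rep(4, 6))
  expect_equal(nrow(align_dyad(a, b2)), 0)
  # partial overlap
  b3 <- toy_track("b", seq(30, 80, 10), rep(0, 6), rep(1, 6))
  expect_equal(align_dyad(a, b3)$time, c(30, 40, 50))
})

test_that("detection handles the protocol's worked examples", {
  p_strict <- proximity_protocol()
  # 12 consecutive samples at 2.0 m: tumbling counts 2
  s <- data.frame(time = seq(0, 110, 10), dist = rep(2, 12))
  expect_equal(detect_interactions(s, p_strict)$count, 2)
  # sliding counts every one of the 7 qualifying windows
  p_slide <- proximity_protocol(windowing = "sliding")
  expect_equal(detect_interactions(s, p_slide)$count, 7)

  # 6 samples with one excursion to 3.2 m: strict 0, lenient f = 5/6 one
  s2 <- data.frame(time = seq(0, 50, 10), dist = c(2, 2, 3.2, 2, 2, 2))
  expect_equal(detect_interactions(s2, p_strict)$count, 0)
  p_len <- proximity_protocol(mode = "lenient", lenient_fraction = 5 / 6)
  expect_equal(detect_interactions(s2, p_len)$count, 1)

  # boundary-inclusive: 6 samples at exactly 3.0 m qualify
  s3 <- data.frame(time = seq(0, 50, 10), dist = rep(3, 6))
  expect_equal(detect_interactions(s3, p_strict)$count, 1)

  # a timestamp gap inside the only candidate window breaks contiguity
  s4 <- data.frame(time = c(0, 10, 20, 40, 50, 60), dist = rep(1, 6))
  expect_equal(detect_interactions(s4, p_strict)$count, 0)

  # series shorter than the window: zero, not an error
  s5 <- data.frame(time = seq(0, 30, 10), dist = rep(1, 4))
  expect_equal(detect_interactions(s5, p_strict)$count, 0)
  expect_error(detect_interactions(data.frame(time = c(10, 0), dist = c(1, 1)),
                                   p_strict), "time-ordered")
})

test_that("the production detector matches naive all-window enumeration", {
  set.seed(101)
  for (rep in 1:200) {
    len <- sample(5:120, 1)
    ser <- random_series(len)
    w <- sample(3:8, 1)
    r <- runif(1, 1, 4)
    f <- sample(c(1, 0.8, 0.5), 1)
    for (win in c("tumbling", "sliding")) {
      proto <- proximity_protocol(
        r = r, t = w * 10, window_points = w,
        mode = if (f < 1) "lenient" else "strict", lenient_fraction = f,
        windowing = win)
      expect_equal(detect_interactions(ser, proto)$count,
                   naive_detect(ser$time, ser$dist, r, w, 10, f, win),
                   info = sprintf("rep %d win %s", rep, win))
    }
  }
})

test_that("strict mode equals lenient mode with f = 1", {
  set.seed(55)
  for (rep in 1:50) {
    ser <- random_series(sample(10:80, 1))
    for (win in c("tumbling", "sliding")) {
      ps <- proximity_protocol(windowing = win)
      pl <- proximity_protocol(mode = "lenient", lenient_fraction = 1,
                               windowing = win)
      expect_identical(detect_interactions(ser, ps)$count,
                       detect_interactions(ser, pl)$count)
    }
  }
})

test_that("counts are monotone in radius and window length", {
  set.seed(66)
  for (rep in 1:30) {
    ser <- random_series(sample(20:100, 1))
    for (win in c("tumbling", "sliding")) {
      counts <- sapply(1:5, function(r)
        detect_interactions(ser, proximity_protocol(r = r, windowing = win))$count)
      expect_true(all(diff(counts) >= 0))
    }
    # sliding counts are non-increasing in window_points
    cw <- sapply(3:8, function(w)
      detect_interactions(ser, proximity_protocol(
        window_points = w, t = w * 10, windowing = "sliding"))$count)
    expect_true(all(diff(cw) <= 0))
  }
})

test_that("daily matrices count co-stationed dyads and stay symmetric", {
  # two cows 1 m apart for 10 min: 60 samples -> 10 tumbling windows
  tt <- seq(0, by = 10, length.out = 60)
  pos <- rbind(toy_track("a", tt, rep(10, 60), rep(5, 60)),
               toy_track("b", tt, rep(11, 60), rep(5, 60)))
  M <- daily_interaction_matrix(pos, geom, "full_barn",
                                proximity_protocol(), 1)
  expect_equal(M["a", "b"], 10)
  expect_equal(M["b", "a"], 10)
  expect_true(is.na(M["a", "a"]))

  # cows never within r: zero matrix
  pos2 <- rbind(toy_track("a", tt, rep(5, 60), rep(5, 60)),
                toy_track("b", tt, rep(50, 60), rep(5, 60)))
  M2 <- daily_interaction_matrix(pos2, geom, "full_barn",
                                 proximity_protocol(), 1)
  expect_true(all(M2[upper.tri(M2)] == 0))

  # random synthetic day: symmetric by construction
  sim <- small_sim(n_cows = 6, seed = 41)
  M3 <- daily_interaction_matrix(sim$positions, geom, "full_barn",
                                 proximity_protocol(), 1)
  expect_true(isSymmetric(unname(unclass(M3))))
  expect_error(daily_interaction_matrix(pos, geom, "full_barn",
                                        proximity_protocol(), 1,
                                        roster = c("a", "x")),
               "missing from the roster")
})

test_that("zone counts never exceed full-barn counts (sliding, zero buffer)", {
  sim <- small_sim(n_cows = 8, seed = 43)
  proto <- proximity_protocol(windowing = "sliding")
  geom0 <- barn_geometry(zone_buffer = 0)
  Mfb <- daily_interaction_matrix(sim$positions, geom0, "full_barn", proto, 1)
  for (z in c("feeding", "non_feeding")) {
    Mz <- daily_interaction_matrix(sim$positions, geom0, z, proto, 1,
                                   roster = rownames(Mfb))
    ut <- upper.tri(Mz)
    expect_true(all(Mz[ut] <= Mfb[ut]))
  }
})

test_that("sensitivity is the overlapped fraction of true intervals", {
  truth <- data.frame(id_a = rep("a", 35), id_b = rep("b", 35),
                      start = seq(0, by = 1000, length.out = 35),
                      end = seq(0, by = 1000, length.out = 35) + 200)
  # windows overlapping all truths
  win_all <- data.frame(id_a = "a", id_b = "b", start = truth$start + 50,
                        end = truth$start + 110)
  expect_equal(validate_sensitivity(win_all, truth), 1)
  # none overlapped
  win_none <- data.frame(id_a = "a", id_b = "b", start = truth$end + 100,
                         end = truth$end + 160)
  expect_equal(validate_sensitivity(win_none, truth), 0)
  # 29 of 35: the unique count consistent with the protocol's 0.83
  win_29 <- win_all[1:29, ]
  expect_equal(validate_sensitivity(win_29, truth), 29 / 35)
  expect_equal(round(29 / 35, 2), 0.83)
  expect_error(validate_sensitivity(win_all, truth[0, ]), "empty")
})

test_that("planted contacts with margin are always detected on noise-free data", {
  # truth radius 2.5 m < protocol radius 3 m gives a distance margin
  sim <- small_sim(n_cows = 6, seed = 47, day_seconds = 5400,
                   truth_radius = 2.5)
  det <- daily_interaction_matrix(sim$positions, geom, "full_barn",
                                  proximity_protocol(), 1,
                                  collect_windows = TRUE)
  sens <- validate_sensitivity(det$windows, sim$truth$intervals,
                               min_true_length = 60)
  expect_equal(sens, 1)
})

test_that("the parameter sweep covers the r/t grid", {
  sim <- small_sim(n_cows = 5, seed = 53)
  sw <- sweep_protocol(sim$positions, geom, "full_barn", 1,
                       r_grid = c(1, 3, 5), t_grid = c(40, 60))
  expect_equal(nrow(sw), 6)
  # totals are monotone in r at fixed t
  for (tt in unique(sw$t)) {
    sub <- sw[sw$t == tt, ]
    expect_true(all(diff(sub$total_interactions[order(sub$r)]) >= 0))
  }
})
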