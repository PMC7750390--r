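test_that("the permutation p-value follows the counting rule with bias guard", {
  t_p <- c(rep(3, 250), rep(1, 9750))
  expect_equal(permutation_p(2, t_p), 250 / 10000)
  expect_equal(permutation_p(99, rep(1, 10000)), 1 / 10001)
  expect_equal(permutation_p(0, rep(1, 10000)), 1)
  expect_equal(permutation_p(99, rep(1, 10000), biased_if_zero = FALSE), 0)
  expect_error(permutation_p(NA, 1:5), "non-finite")
})

test_that("Bonferroni correction multiplies and caps", {
  expect_equal(bonferroni(0.002, m = 28), 0.056)
  expect_equal(bonferroni(0.2, m = 28), 1)
  expect_equal(bonferroni(0.04), 0.04)  # m defaults to length 1
  expect_equal(bonferroni(c(0.01, 0.03)), c(0.02, 0.06))
  expect_error(bonferroni(0), "0, 1")
  expect_error(bonferroni(c(0.1, 0.2), m = 1), ">=")
})

test_that("lameness classification covers every pattern", {
  # all eight L/NL patterns; 2-3 = lame session, 0-1 = non-lame session
  expect_equal(classify_lameness(c(0, 1, 0)), "non_lame")  # NL-NL-NL
  expect_equal(classify_lameness(c(0, 1, 2)), "non_lame")  # NL-NL-L dominant NL
  expect_equal(classify_lameness(c(3, 0, 1)), "non_lame")  # L-NL-NL dominant NL
  expect_equal(classify_lameness(c(2, 3, 2)), "lame")      # L-L-L
  expect_equal(classify_lameness(c(2, 3, 1)), "lame")      # L-L-NL dominant L
  expect_equal(classify_lameness(c(0, 2, 3)), "lame")      # NL-L-L dominant L
  expect_equal(classify_lameness(c(0, 2, 0)), "excluded")  # NL-L-NL
  expect_equal(classify_lameness(c(2, 0, 2)), "excluded")  # L-NL-L
  expect_equal(classify_lameness(c(0, "NS", 1)), "excluded")
  expect_error(classify_lameness(c(0, 1)), "three")
  expect_error(classify_lameness(c(0, 1, 7)), "invalid")
})

test_that("attribute difference matrices are absolute differences", {
  attrs <- data.frame(
    animal_id = c("a", "b", "c"), parity = c(1, 3, 3),
    days_in_milk = c(100, 100, 250),
    lameness_class = c("lame", "non_lame", "excluded"),
    stringsAsFactors = FALSE)
  pm <- attribute_difference_matrix(attrs, "parity")
  expect_equal(pm["a", "b"], 2)
  expect_equal(pm["b", "c"], 0)
  dm <- attribute_difference_matrix(attrs, "days_in_milk")
  expect_equal(dm["a", "b"], 0)
  expect_warning(lm <- attribute_difference_matrix(attrs, "lameness"),
                 "excluded")
  expect_equal(dim(lm), c(2, 2))
  expect_equal(lm["a", "b"], 1)
})

test_that("social differentiation reproduces its closed-form cases", {
  # uniform counts: S = 0
  u <- matrix(2, 4, 4); diag(u) <- NA
  expect_equal(social_differentiation(u, q = 50, seed = 1)$S, 0)

  # 3 cows with dyad counts (4, 0, 2): E = 2, S = (4 + 4 + 0)/3 = 8/3
  m <- matrix(c(NA, 4, 0, 4, NA, 2, 0, 2, NA), 3, 3)
  res <- social_differentiation(m, q = 200, seed = 2)
  expect_equal(res$S, 8 / 3)
  expect_equal(res$expected, 2)

  # zero matrix: S = 0, p = 1, with a warning
  z <- matrix(0, 3, 3); diag(z) <- NA
  expect_warning(rz <- social_differentiation(z, q = 10, seed = 1), "zero total")
  expect_equal(rz$S, 0)
  expect_equal(rz$p, 1)
})

test_that("the ordered-sum and dyad-sum forms of S agree", {
  for (rep in 1:20) {
    m <- random_count_matrix(sample(4:10, 1), lambda = 4, seed = 300 + rep)
    n <- nrow(m)
    m0 <- m; diag(m0) <- 0
    off <- row(m0) != col(m0)
    E <- sum(m0) / (n * (n - 1))            # ordered-pair expectation
    S_ordered <- sum((m0[off] - E)^2) / (n * (n - 1))
    res <- social_differentiation(m, q = 10, seed = 1)
    expect_equal(res$S, S_ordered, tolerance = 1e-12)
  }
})

test_that("S is relabeling-invariant and scales quadratically", {
  m <- random_count_matrix(8, lambda = 5, seed = 9)
  s0 <- social_differentiation(m, q = 10, seed = 3)$S
  perm <- sample(8)
  expect_equal(social_differentiation(m[perm, perm], q = 10, seed = 3)$S, s0)
  expect_equal(social_differentiation(m * 2L, q = 10, seed = 3)$S, 4 * s0)
})

test_that("differentiation p-values calibrate against the multinomial null", {
  # matrices drawn FROM the uniform null must reject at about alpha
  set.seed(404)
  n <- 10; D <- dyad_count(n)
  p_vals <- replicate(120, {
    m <- matrix(0, n, n)
    m[upper.tri(m)] <- stats::rmultinom(1, 400, rep(1 / D, D))[, 1]
    m <- m + t(m); diag(m) <- NA
    social_differentiation(m, q = 200, seed = sample.int(1e6, 1))$p
  })
  expect_gt(mean(p_vals < 0.05), 0.005)
  expect_lt(mean(p_vals < 0.05), 0.12)
})

test_that("permuted rank tests match their base-R observed statistics", {
  set.seed(5)
  X <- matrix(rpois(40, 10), nrow = 8)  # 8 cows x 5 days
  kw <- kw_permutation_test(X, "inter_individual", q = 50, seed = 1)
  expect_equal(kw$t_o,
               unname(kruskal.test(as.vector(X),
                                   factor(rep(1:8, times = 5)))$statistic))
  vals <- rnorm(20); grp <- rep(c("a", "b"), each = 10)
  wt <- wilcoxon_permutation_test(vals, grp, q = 50, seed = 1)
  expect_equal(wt$W,
               unname(wilcox.test(vals[grp == "a"], vals[grp == "b"],
                                  exact = FALSE)$statistic))
})

test_that("identical data give p = 1 under any permutation scheme", {
  X <- matrix(5, nrow = 6, ncol = 4)
  expect_equal(kw_permutation_test(X, "inter_individual", q = 100,
                                   seed = 1)$p, 1)
  expect_equal(kw_permutation_test(X, "between_days", q = 100, seed = 1)$p, 1)
  expect_equal(wilcoxon_permutation_test(rep(2, 10), rep(c("a", "b"), 5),
                                         q = 100, seed = 1)$p, 1)
})

test_that("the two-group permutation test sees a planted location shift", {
  set.seed(6)
  vals <- c(rnorm(20, 0, 1), rnorm(20, 2, 1))   # shift of 2 pooled SDs
  grp <- rep(c("a", "b"), each = 20)
  wt <- wilcoxon_permutation_test(vals, grp, q = 1000, seed = 2)
  expect_lt(wt$p, 0.01)
  expect_error(wilcoxon_permutation_test(1:4, c("a", "a", "a", "b")), ">= 2")
})

test_that("Mantel-Spearman matches vegan and honours monotone invariance", {
  m <- random_count_matrix(8, lambda = 4, seed = 77) * 1.0
  diag(m) <- 0
  self <- mantel_spearman(m, m, q = 50, seed = 1)
  expect_equal(self$R_s, 1)

  # rank reversal gives R_s = -1
  rev <- max(m) - m; diag(rev) <- 0
  expect_equal(mantel_spearman(m, rev, q = 50, seed = 1)$R_s, -1)

  # statistic agrees with vegan::mantel (spearman) on random pairs
  skip_if_not_installed("vegan")
  for (rep in 1:5) {
    a <- random_count_matrix(7, lambda = 4, seed = 500 + rep) * 1.0
    b <- random_count_matrix(7, lambda = 4, seed = 600 + rep) * 1.0
    diag(a) <- 0; diag(b) <- 0
    ours <- mantel_spearman(a, b, q = 20, seed = 1)$R_s
    ref <- vegan::mantel(a, b, method = "spearman", permutations = 0)$statistic
    expect_equal(ours, unname(ref), tolerance = 1e-12)
  }

  # invariant to strictly monotone transforms of either matrix
  a <- random_count_matrix(7, lambda = 4, seed = 800) * 1.0; diag(a) <- 0
  b <- random_count_matrix(7, lambda = 4, seed = 801) * 1.0; diag(b) <- 0
  expect_equal(mantel_spearman(exp(a / 4), b, q = 20, seed = 1)$R_s,
               mantel_spearman(a, b, q = 20, seed = 1)$R_s)
  con <- matrix(1, 7, 7); diag(con) <- 0
  expect_error(mantel_spearman(con, b, q = 10, seed = 1), "constant")
})

test_that("Mantel p-values calibrate on independent random matrices", {
  set.seed(31)
  rej <- replicate(200, {
    a <- matrix(0, 10, 10); b <- matrix(0, 10, 10)
    a[upper.tri(a)] <- rnorm(45); b[upper.tri(b)] <- rnorm(45)
    a <- a + t(a); b <- b + t(b)
    mantel_spearman(a, b, q = 300, seed = sample.int(1e6, 1))$p < 0.05
  })
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.09)
})

test_that("temporal block comparison builds the right number of networks", {
  days <- lapply(1:28, function(d) random_count_matrix(6, lambda = 3, seed = d))
  tb <- temporal_block_comparison(days, block_days = 4, q = 50, seed = 1)
  expect_equal(nrow(tb), 6)           # 7 block networks, 6 comparisons
  expect_equal(tb$m[1], 6)
  # identical days correlate perfectly
  same <- lapply(1:8, function(d) days[[1]])
  tb2 <- temporal_block_comparison(same, 4, q = 50, seed = 1)
  expect_equal(tb2$R_s, rep(1, nrow(tb2)))
  expect_error(temporal_block_comparison(days[1:4], 4), "2 complete blocks")
})

test_that("assortment testing wires the matrices together correctly", {
  m <- random_count_matrix(6, lambda = 4, seed = 91) * 1.0
  diag(m) <- 0
  # attribute matrix identical to the interaction matrix: R_s = 1
  at <- assortment_test(m, m, q = 50, seed = 1, alternative = "greater")
  expect_equal(at$R_s, 1)
  con <- matrix(2, 6, 6); diag(con) <- 0
  expect_error(assortment_test(m, con), "degenerate")
})

test_that("Pearson daily-series correlation behaves at the extremes", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expect_equal(correlate_daily_series(x, x)$rho, 1)
  expect_equal(correlate_daily_series(x, -x)$rho, -1)
  expect_error(correlate_daily_series(x, rep(1, 8)), "zero variance")
  expect_error(correlate_daily_series(x, x[-1]), "mismatch")
  # independent Gaussian pairs: mean correlation near zero
  set.seed(8)
  rhos <- replicate(500, correlate_daily_series(rnorm(28), rnorm(28))$rho)
  expect_lt(abs(mean(rhos)), 0.05)
})

test_that("permutation results are reproducible given the seed", {
  m <- random_count_matrix(8, lambda = 4, seed = 13) * 1.0; diag(m) <- 0
  b <- random_count_matrix(8, lambda = 4, seed = 14) * 1.0; diag(b) <- 0
  r1 <- mantel_spearman(m, b, q = 100, seed = 42)
  r2 <- mantel_spearman(m, b, q = 100, seed = 42)
  expect_identical(r1$t_p, r2$t_p)
  expect_identical(r1$p, r2$p)
})
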