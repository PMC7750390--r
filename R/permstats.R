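#' Permutation p-value (one-sided, with biased estimator)
#'
#' Computes `p = #(t_p >= t_o) / q`. When no permuted statistic reaches
#' the observed one the estimate would be zero, which is impossible for a
#' finite permutation sample; the biased estimator then adds one to both
#' numerator and denominator, giving `1 / (q + 1)`.
#'
#' @param t_o observed statistic (finite scalar).
#' @param t_p numeric vector of permuted statistics.
#' @param biased_if_zero apply the biased estimator when the count is 0.
#' @return p-value in (0, 1].
#' @examples
#' permutation_p(2, c(rep(3, 250), rep(1, 9750)))  # 0.025
#' @export
permutation_p <- function(t_o, t_p, biased_if_zero = TRUE) {
  if (!is.finite(t_o) || !all(is.finite(t_p))) stop("non-finite statistics")
  if (length(t_p) == 0) stop("empty permutation sample")
  q <- length(t_p)
  cnt <- sum(t_p >= t_o)
  if (cnt == 0 && biased_if_zero) return(1 / (q + 1))
  cnt / q
}

#' Bonferroni correction
#'
#' @param p_values numeric vector of raw p-values in (0, 1].
#' @param m number of comparisons (defaults to `length(p_values)`; must be
#'   at least that).
#' @return adjusted p-values `min(1, p * m)`.
#' @examples
#' bonferroni(0.002, m = 28)  # 0.056
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(p_values <= 0 | p_values > 1)) stop("p-values must lie in (0, 1]")
  if (m < length(p_values)) stop("m must be >= number of p-values")
  pmin(1, p_values * m)
}

#' Classify lameness from three fortnightly mobility scores
#'
#' Sessions scoring 2-3 are lame (L), 0-1 non-lame (NL). All-NL and the
#' dominant-NL patterns (NL-NL-L, L-NL-NL) classify as `"non_lame"`;
#' all-L and the dominant-L patterns (L-L-NL, NL-L-L) as `"lame"`; cows
#' that changed status twice (NL-L-NL, L-NL-L) or with any unscored
#' session ("NS") are `"excluded"`.
#'
#' @param scores character or numeric vector of length 3, values in
#'   `0:3` or `"NS"`.
#' @return one of `"lame"`, `"non_lame"`, `"excluded"`.
#' @examples
#' classify_lameness(c(0, 1, 2))  # non_lame (dominant not lame)
#' classify_lameness(c(2, 3, 1))  # lame (dominant lame)
#' classify_lameness(c(0, 2, 0))  # excluded (changed status twice)
#' @export
classify_lameness <- function(scores) {
  if (length(scores) != 3) stop("exactly three scoring sessions required")
  scores <- as.character(scores)
  valid <- c("0", "1", "2", "3", "NS")
  if (!all(scores %in% valid))
    stop("invalid mobility score: ", paste(setdiff(scores, valid), collapse = ", "))
  if (any(scores == "NS")) return("excluded")
  st <- ifelse(scores %in% c("2", "3"), "L", "NL")
  nl <- sum(st == "NL")
  if (nl == 3 || (nl == 2 && st[2] == "NL")) return("non_lame")  # NL-NL-L, L-NL-NL
  if (nl == 0 || (nl == 1 && st[2] == "L")) return("lame")       # L-L-NL, NL-L-L
  "excluded"                                                     # NL-L-NL, L-NL-L
}

#' Absolute-difference matrix for a cow attribute
#'
#' Entry (i, j) is `|value_i - value_j|`. Lameness is coded 1 (lame) /
#' 0 (non-lame), so entries are 0 for same-status and 1 for mixed dyads;
#' cows with class `"excluded"` are dropped (with a warning).
#'
#' @param attributes cow-attributes data.frame (see
#'   [make_cow_attributes()]).
#' @param field `"parity"`, `"days_in_milk"` or `"lameness"`.
#' @return symmetric numeric matrix with animal-id dimnames (zero
#'   diagonal).
#' @export
attribute_difference_matrix <- function(attributes,
                                        field = c("parity", "days_in_milk",
                                                  "lameness")) {
  field <- match.arg(field)
  at <- attributes
  if (field == "lameness") {
    drop <- at$lameness_class == "excluded"
    if (any(drop)) {
      warning(sum(drop), " animal(s) excluded from lameness classification")
      at <- at[!drop, , drop = FALSE]
    }
    v <- as.numeric(at$lameness_class == "lame")
  } else {
    v <- at[[field]]
    miss <- !is.finite(v)
    if (any(miss)) {
      warning(sum(miss), " animal(s) with missing ", field, " excluded")
      at <- at[!miss, , drop = FALSE]
      v <- v[!miss]
    }
  }
  if (nrow(at) < 2) stop("fewer than 2 animals with usable ", field)
  m <- abs(outer(v, v, "-"))
  dimnames(m) <- list(at$animal_id, at$animal_id)
  m
}

#' Social differentiation of an interaction matrix
#'
#' Measures how far dyadic interaction counts deviate from the uniform
#' null in which the day's total interactions are spread equally over all
#' dyads: S is the mean squared deviation of observed from expected counts
#' over dyads (the ordered double-sum form divided by n(n-1) is
#' algebraically identical to the unordered dyad sum divided by
#' n(n-1)/2, which is what is computed). The null distribution
#' redistributes the observed total uniformly at random over dyads
#' (multinomial) `q` times; the p-value for S follows the one-sided
#' permutation rule of [permutation_p()]. Each dyad is additionally
#' flagged as differentiated when its squared deviation exceeds the null's
#' 95th percentile of per-dyad squared deviations.
#'
#' @param matrix symmetric interaction count matrix (n >= 3).
#' @param q number of null draws (default 10000).
#' @param seed integer seed.
#' @return object of class `differentiation_result`: list with `S`,
#'   `p`, `expected` (scalar E per dyad), `dyads` (data.frame: id_a, id_b,
#'   observed, sq_dev, differentiated, and `positive` for dyads flagged
#'   above expectation), `differentiated_fraction`, `q`, `seed`.
#' @examples
#' m <- matrix(c(NA, 4, 0, 4, NA, 2, 0, 2, NA), 3, 3)
#' social_differentiation(m, q = 100, seed = 1)$S  # 8/3
#' @export
social_differentiation <- function(matrix, q = 10000, seed = 1L) {
  m <- as.matrix(matrix)
  n <- nrow(m)
  if (n < 3) stop("need at least 3 animals")
  ids <- rownames(m)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  ut <- which(upper.tri(m))
  O <- m[ut]
  if (any(!is.finite(O))) stop("non-finite off-diagonal counts")
  D <- dyad_count(n)
  total <- sum(O)
  E <- total / D
  sq <- (O - E)^2
  S <- sum(sq) / D
  pairs <- which(upper.tri(m), arr.ind = TRUE)
  if (total == 0) {
    warning("zero total interactions: S = 0, p = 1")
    dy <- data.frame(id_a = ids[pairs[, 1]], id_b = ids[pairs[, 2]],
                     observed = O, sq_dev = sq, differentiated = FALSE,
                     positive = FALSE, stringsAsFactors = FALSE)
    out <- list(S = 0, p = 1, expected = 0, dyads = dy,
                differentiated_fraction = 0, q = q, seed = seed)
    class(out) <- "differentiation_result"
    return(out)
  }
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  S_null <- numeric(q)
  # pooled per-dyad squared deviations under the null for the 95th pctile
  qs <- numeric(q)
  for (b in seq_len(q)) {
    x <- stats::rmultinom(1, total, rep(1 / D, D))[, 1]
    sqb <- (x - E)^2
    S_null[b] <- sum(sqb) / D
    qs[b] <- stats::quantile(sqb, 0.95, names = FALSE, type = 7)
  }
  p <- permutation_p(S, S_null)
  thr <- mean(qs)   # null 95th percentile of per-dyad squared deviation
  flag <- sq > thr
  # positively differentiated = flagged AND interacting above expectation
  # (the "preferred partner" direction)
  dy <- data.frame(id_a = ids[pairs[, 1]], id_b = ids[pairs[, 2]],
                   observed = O, sq_dev = sq, differentiated = flag,
                   positive = flag & O > E,
                   stringsAsFactors = FALSE)
  out <- list(S = S, p = p, expected = E, dyads = dy,
              differentiated_fraction = mean(flag), q = q, seed = seed,
              null_S = S_null, sq_dev_threshold = thr)
  class(out) <- "differentiation_result"
  out
}

#' @export
print.differentiation_result <- function(x, ...) {
  cat(sprintf("Social differentiation: S = %.4g (p = %.4g, q = %d)\n",
              x$S, x$p, x$q))
  cat(sprintf("  differentiated dyads: %.2f%% (threshold %.4g)\n",
              100 * x$differentiated_fraction,
              if (!is.null(x$sq_dev_threshold)) x$sq_dev_threshold else NA))
  invisible(x)
}

# internal: build a perm_result object
perm_result <- function(statistic, t_o, t_p, q, seed, p = NULL, extra = list()) {
  if (is.null(p)) p <- permutation_p(t_o, t_p)
  out <- c(list(statistic = statistic, t_o = t_o, t_p = t_p, q = q,
                seed = seed, p = p), extra)
  class(out) <- "perm_result"
  out
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("%s permutation test: statistic = %.4g, p = %.4g (q = %d)\n",
              x$statistic, x$t_o, x$p, x$q))
  invisible(x)
}

# Kruskal-Wallis chi-squared statistic; 0 when all values tie
kw_stat <- function(values, groups) {
  if (length(unique(values)) == 1) return(0)
  unname(stats::kruskal.test(values, groups)$statistic)
}

#' Node-level permutation Kruskal-Wallis tests on daily interaction totals
#'
#' `daily_totals` holds one row per cow and one column per day (each entry
#' the cow's total interactions that day). Two designs are offered:
#' * `"inter_individual"` — groups are the cows; do some cows consistently
#'   interact more than others? The null permutes each day's totals across
#'   cows independently, preserving day structure while breaking cow
#'   identity (a node-label randomization).
#' * `"between_days"` — groups are the days; does the herd interact more
#'   on some days? The null permutes each cow's totals across days,
#'   preserving cow identity while breaking day structure.
#'
#' The observed Kruskal-Wallis rank-sum statistic comes from
#' [stats::kruskal.test()]; the p-value follows [permutation_p()].
#'
#' @param daily_totals numeric matrix, cows x days.
#' @param design `"inter_individual"` or `"between_days"`.
#' @param q permutation count (default 10000).
#' @param seed integer seed.
#' @return a `perm_result`.
#' @export
kw_permutation_test <- function(daily_totals,
                                design = c("inter_individual", "between_days"),
                                q = 10000, seed = 1L) {
  design <- match.arg(design)
  X <- as.matrix(daily_totals)
  n <- nrow(X); d <- ncol(X)
  if (n < 2 || d < 1) stop("need >= 2 cows and >= 1 day")
  if (design == "between_days" && d < 2) stop("need >= 2 days")
  values <- as.vector(X)                       # column-major: cow fastest
  cow_g <- factor(rep(seq_len(n), times = d))
  day_g <- factor(rep(seq_len(d), each = n))
  groups <- if (design == "inter_individual") cow_g else day_g
  t_o <- kw_stat(values, groups)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  t_p <- numeric(q)
  for (b in seq_len(q)) {
    Xp <- X
    if (design == "inter_individual") {
      for (j in seq_len(d)) Xp[, j] <- X[sample.int(n), j]
    } else {
      for (i in seq_len(n)) Xp[i, ] <- X[i, sample.int(d)]
    }
    t_p[b] <- kw_stat(as.vector(Xp), groups)
  }
  perm_result("Kruskal-Wallis", t_o, t_p, q, seed,
              extra = list(design = design))
}

#' Two-group permutation Wilcoxon test
#'
#' Compares per-cow summary values (e.g. mean daily interactions, mean
#' degree, mean clustering) between two groups (e.g. lame vs non-lame).
#' The observed statistic is the two-sample Wilcoxon rank-sum W from
#' [stats::wilcox.test()]; because the test is two-tailed, the statistic
#' fed to the one-sided permutation rule is the absolute centred form
#' `|W - n1 n2 / 2|`. The null shuffles group labels across cows.
#'
#' @param values numeric vector, one entry per cow.
#' @param groups two-level factor (or coercible).
#' @param q permutation count (default 10000).
#' @param seed integer seed.
#' @return a `perm_result`; element `W` holds the uncentred observed W.
#' @export
wilcoxon_permutation_test <- function(values, groups, q = 10000, seed = 1L) {
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups required")
  if (any(table(groups) < 2)) stop("each group needs >= 2 observations")
  if (length(values) != length(groups)) stop("length mismatch")
  n1 <- sum(groups == levels(groups)[1])
  n2 <- sum(groups == levels(groups)[2])
  rk <- rank(values)                  # average ranks for ties
  centre <- n1 * n2 / 2
  offset <- n1 * (n1 + 1) / 2
  g1 <- groups == levels(groups)[1]
  W_obs <- sum(rk[g1]) - offset       # Mann-Whitney W as in wilcox.test
  t_o <- abs(W_obs - centre)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  t_p <- numeric(q)
  nn <- length(values)
  for (b in seq_len(q)) {
    idx <- sample.int(nn, n1)
    t_p[b] <- abs(sum(rk[idx]) - offset - centre)
  }
  perm_result("Wilcoxon (two-tailed)", t_o, t_p, q, seed,
              extra = list(W = W_obs))
}

#' Group-comparison permutation tests (dispatcher)
#'
#' Thin wrapper selecting among the supported designs: the
#' inter-individual and between-day Kruskal-Wallis tests on a cows x days
#' totals matrix, or the two-group Wilcoxon on per-cow summaries.
#'
#' @param data cows x days matrix (K-W designs) or numeric vector
#'   (Wilcoxon).
#' @param design `"inter_individual"`, `"between_days"` or `"two_group"`.
#' @param groups two-level factor, required for `"two_group"`.
#' @param q permutation count.
#' @param seed integer seed.
#' @return a `perm_result`.
#' @export
group_statistic_tests <- function(data,
                                  design = c("inter_individual",
                                             "between_days", "two_group"),
                                  groups = NULL, q = 10000, seed = 1L) {
  design <- match.arg(design)
  if (design == "two_group") {
    if (is.null(groups)) stop("groups required for the two-group design")
    wilcoxon_permutation_test(data, groups, q = q, seed = seed)
  } else {
    kw_permutation_test(data, design, q = q, seed = seed)
  }
}

# Spearman correlation of the upper triangles of two symmetric matrices
upper_tri_spearman <- function(m1, m2) {
  v1 <- m1[upper.tri(m1)]; v2 <- m2[upper.tri(m2)]
  keep <- is.finite(v1) & is.finite(v2)
  v1 <- v1[keep]; v2 <- v2[keep]
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop("constant matrix: Spearman correlation undefined")
  stats::cor(v1, v2, method = "spearman")
}

#' Mantel test with Spearman rank correlation
#'
#' The statistic R_s is the Spearman rank correlation between the upper
#' triangles of the two matrices. The null permutes one matrix's node
#' labels (simultaneous row and column permutation) `q` times. One-sided
#' p (`alternative = "greater"`) applies the permutation rule to R_s;
#' `"less"` to -R_s; `"two.sided"` to |R_s|.
#'
#' @param m1,m2 symmetric matrices with matching dimension and roster.
#' @param q permutation count (default 10000).
#' @param seed integer seed.
#' @param alternative `"greater"`, `"less"` or `"two.sided"`.
#' @return a `perm_result` with element `R_s`.
#' @export
mantel_spearman <- function(m1, m2, q = 10000, seed = 1L,
                            alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  m1 <- as.matrix(m1); m2 <- as.matrix(m2)
  if (!all(dim(m1) == dim(m2))) stop("matrices must share dimension")
  if (!is.null(rownames(m1)) && !is.null(rownames(m2)) &&
      !identical(rownames(m1), rownames(m2)))
    stop("matrices must share the roster (row names differ)")
  n <- nrow(m1)
  orient <- switch(alternative, greater = identity, less = function(z) -z,
                   two.sided = abs)
  R_s <- upper_tri_spearman(m1, m2)
  t_o <- orient(R_s)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  t_p <- numeric(q)
  for (b in seq_len(q)) {
    perm <- sample.int(n)
    t_p[b] <- orient(upper_tri_spearman(m1, m2[perm, perm]))
  }
  perm_result("Mantel-Spearman", t_o, t_p, q, seed,
              extra = list(R_s = R_s, alternative = alternative))
}

#' Temporal stability via block-averaged network comparisons
#'
#' Averages the daily matrices in consecutive blocks of `block_days` days
#' (a trailing partial block is dropped), runs a Mantel-Spearman test on
#' each consecutive pair of block networks, and Bonferroni-corrects over
#' the number of comparisons.
#'
#' @param daily_matrices list of daily interaction matrices (same roster).
#' @param block_days days per block (default 4).
#' @param q permutation count.
#' @param seed integer seed.
#' @param alternative passed to [mantel_spearman()] (default
#'   `"greater"`, matching the stability question: are consecutive
#'   networks positively correlated?).
#' @return data.frame with columns `block_a`, `block_b`, `R_s`, `p_raw`,
#'   `p_adjusted`, `m`, `q`.
#' @export
temporal_block_comparison <- function(daily_matrices, block_days = 4,
                                      q = 10000, seed = 1L,
                                      alternative = "greater") {
  d <- length(daily_matrices)
  n_blocks <- d %/% block_days
  if (n_blocks < 2) stop("need at least 2 complete blocks")
  blocks <- lapply(seq_len(n_blocks), function(b) {
    idx <- ((b - 1) * block_days + 1):(b * block_days)
    average_matrices(daily_matrices[idx])
  })
  m <- n_blocks - 1
  res <- lapply(seq_len(m), function(k) {
    mt <- mantel_spearman(blocks[[k]], blocks[[k + 1]], q = q,
                          seed = seed + k, alternative = alternative)
    data.frame(block_a = k, block_b = k + 1, R_s = mt$R_s, p_raw = mt$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- bonferroni(out$p_raw, m)
  out$m <- m
  out$q <- q
  out
}

#' Attribute assortment test (Mantel)
#'
#' Compares an interaction matrix with an attribute absolute-difference
#' matrix by Mantel-Spearman. A negative R_s means similar animals
#' interact more (differences small where counts high). The default
#' alternative is two-sided, so assortment in either direction is
#' detected.
#'
#' @param interaction_matrix symmetric count matrix.
#' @param attr_diff_matrix symmetric absolute-difference matrix from
#'   [attribute_difference_matrix()]; rosters must match (the interaction
#'   matrix is subset to the attribute matrix's animals if needed).
#' @param q permutation count.
#' @param seed integer seed.
#' @param alternative passed to [mantel_spearman()].
#' @return a `perm_result` with element `R_s`.
#' @export
assortment_test <- function(interaction_matrix, attr_diff_matrix,
                            q = 10000, seed = 1L,
                            alternative = "two.sided") {
  am <- as.matrix(attr_diff_matrix)
  if (length(unique(am[upper.tri(am)])) < 2)
    stop("degenerate attribute: all dyadic differences equal")
  im <- as.matrix(interaction_matrix)
  if (!is.null(rownames(am)) && !is.null(rownames(im)) &&
      !identical(rownames(am), rownames(im))) {
    if (!all(rownames(am) %in% rownames(im)))
      stop("attribute roster contains animals missing from the interaction matrix")
    im <- im[rownames(am), rownames(am)]
  }
  mantel_spearman(im, am, q = q, seed = seed, alternative = alternative)
}

#' Pearson correlation between two daily series
#'
#' Standard product-moment correlation with a two-sided p-value, used for
#' relating mean daily interactions to the day index or to mean daily
#' temperature.
#'
#' @param series_a,series_b equal-length numeric vectors (length >= 3).
#' @return list with `rho` and `p`.
#' @export
correlate_daily_series <- function(series_a, series_b) {
  if (length(series_a) != length(series_b)) stop("length mismatch")
  if (length(series_a) < 3) stop("need at least 3 paired days")
  if (!all(is.finite(series_a)) || !all(is.finite(series_b)))
    stop("non-finite values")
  if (stats::sd(series_a) == 0 || stats::sd(series_b) == 0)
    stop("zero variance series")
  ct <- stats::cor.test(series_a, series_b, method = "pearson")
  list(rho = unname(ct$estimate), p = ct$p.value)
}
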