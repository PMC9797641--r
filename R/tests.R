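# Significance tests for parallelism of change-vector angle sets, plus the
# correlation and paired set-comparison analyses. Each test returns a
# `cv_test` result: method, statistic, p_value, n, and method-specific
# extras, so results can be row-bound into one summary table.

.cv_test <- function(method, statistic, p_value, n, ...) {
  structure(
    c(list(method = method, statistic = unname(statistic),
           p_value = unname(p_value), n = as.integer(n)), list(...)),
    class = "cv_test"
  )
}

#' @export
print.cv_test <- function(x, digits = 4, ...) {
  cat(sprintf("%s: statistic = %.*g, p = %.*g, n = %d\n",
              x$method, digits, x$statistic, digits, x$p_value, x$n))
  extras <- setdiff(names(x), c("method", "statistic", "p_value", "n"))
  for (e in extras) {
    v <- x[[e]]
    if (is.numeric(v) && length(v) == 1L) cat(sprintf("  %s = %.*g\n", e, digits, v))
  }
  invisible(x)
}

#' @export
as.data.frame.cv_test <- function(x, ...) {
  data.frame(
    method = x$method, n = x$n, statistic = x$statistic, p_value = x$p_value,
    mean_angle = if (is.null(x$mean_angle)) NA_real_ else x$mean_angle,
    d = if (is.null(x$d)) NA_integer_ else x$d,
    iterations = if (is.null(x$iterations)) NA_integer_ else x$iterations,
    seed = if (is.null(x$seed)) NA_integer_ else x$seed,
    stringsAsFactors = FALSE
  )
}

#' Shapiro-Wilk normality gate for angle sets
#'
#' Drives automatic test selection: the one-sample t-test is appropriate
#' when the angles look normal, the Wilcoxon signed-rank test otherwise.
#'
#' @param angles Numeric vector, n >= 3, not all identical.
#' @param alpha Gate level (default 0.05).
#' @return `"normal"` if the Shapiro-Wilk p-value is >= `alpha`, else
#'   `"non_normal"`; the p-value is attached as attribute `"p_value"`.
#' @export
shapiro_gate <- function(angles, alpha = 0.05) {
  if (length(angles) < 3L) .cv_error("shapiro_gate needs n >= 3", "cv_degenerate_error")
  if (stats::sd(angles) == 0) .cv_error("constant sample: normality undefined", "cv_degenerate_error")
  p <- stats::shapiro.test(angles)$p.value
  structure(if (p >= alpha) "normal" else "non_normal", p_value = p)
}

#' One-sample t-test of angles against the 90-degree null
#'
#' `t = (mean - 90) / (sd / sqrt(n))` with the usual n-1 sample standard
#' deviation; the p-value is one-sided toward angles below 90 (parallelism),
#' `p = P(T_{n-1} <= t)`. In high-dimensional spaces random angles are
#' approximately normal around 90 degrees, which motivates this simple
#' first test.
#'
#' @param angles Numeric vector of pairwise angles in degrees, n >= 2.
#' @return A `cv_test` with extras `mean_angle` and `df`.
#' @export
t_test_vs_90 <- function(angles) {
  n <- length(angles)
  if (n < 2L) .cv_error("t-test needs n >= 2", "cv_value_error")
  if (stats::sd(angles) == 0) .cv_error("zero variance: t statistic undefined", "cv_degenerate_error")
  ht <- stats::t.test(angles, mu = 90, alternative = "less")
  .cv_test("t_vs_90", ht$statistic, ht$p.value, n,
           mean_angle = mean(angles), df = unname(ht$parameter))
}

#' One-sample Wilcoxon signed-rank test of angles against 90 degrees
#'
#' Signed-rank test on `angles - 90`, one-sided toward negative
#' differences (parallelism). Zero differences are dropped. The exact
#' distribution is used for n <= 25 without ties; otherwise the normal
#' approximation with continuity correction.
#'
#' @param angles Numeric vector of pairwise angles in degrees.
#' @return A `cv_test` with extras `mean_angle` and `exact`.
#' @export
wilcoxon_vs_90 <- function(angles) {
  d <- angles - 90
  d <- d[d != 0]
  if (!length(d)) .cv_error("all differences from 90 are zero", "cv_degenerate_error")
  n <- length(d)
  exact <- n <= 25L && !anyDuplicated(abs(d))
  ht <- suppressWarnings(stats::wilcox.test(d, mu = 0, alternative = "less",
                                            exact = exact, correct = TRUE))
  .cv_test("wilcoxon_vs_90", ht$statistic, ht$p.value, n,
           mean_angle = mean(angles), exact = exact)
}

#' Null distribution of mean pairwise angles among random directions
#'
#' For each iteration, draws `k` independent uniformly random unit
#' directions in `d` dimensions (independent standard-normal components,
#' normalized) and records the mean of all `choose(k, 2)` pairwise angles.
#' Simulating whole vector sets, rather than pooling independent single
#' angles, preserves the non-independence among pairwise angles that share
#' a vector. The distribution is centered at 90 degrees.
#'
#' @param k Vectors per draw (>= 2).
#' @param d Dimensionality (>= 2).
#' @param iterations Number of draws.
#' @param seed Integer seed.
#' @return Object of class `random_angle_null`: list with `samples`
#'   (length `iterations`, degrees), `k`, `d`, `iterations`, `seed`.
#' @export
random_angle_null <- function(k, d, iterations, seed) {
  .assert_scalar_count(k, "k"); .assert_scalar_count(d, "d")
  .assert_scalar_count(iterations, "iterations")
  if (k < 2L) .cv_error("k must be >= 2", "cv_value_error")
  if (d < 2L) .cv_error("d must be >= 2", "cv_value_error")
  if (missing(seed) || is.null(seed)) .cv_error("random_angle_null requires a seed", "cv_value_error")
  iterations <- as.integer(iterations)
  set.seed(as.integer(seed))
  if (k == 2L) {
    # single-pair case fully vectorized
    a <- matrix(stats::rnorm(iterations * d), iterations, d)
    b <- matrix(stats::rnorm(iterations * d), iterations, d)
    ct <- rowSums(a * b) / sqrt(rowSums(a * a) * rowSums(b * b))
    samples <- acos(.clamp(ct, -1, 1)) * 180 / pi
  } else {
    pr <- .pair_index(k)
    samples <- numeric(iterations)
    for (b in seq_len(iterations)) {
      u <- matrix(stats::rnorm(k * d), k, d)
      u <- u / sqrt(rowSums(u * u))
      g <- tcrossprod(u)
      samples[b] <- mean(acos(.clamp(g[pr], -1, 1))) * 180 / pi
    }
  }
  structure(list(samples = samples, k = as.integer(k), d = as.integer(d),
                 iterations = iterations, seed = as.integer(seed)),
            class = "random_angle_null")
}

#' Monte-Carlo test of parallelism against the random-angle null
#'
#' Compares the observed mean pairwise angle with the null distribution of
#' mean pairwise angles among uniformly random directions in the same
#' dimensionality (see [random_angle_null()]), with add-one correction:
#' `p = (1 + #\{null <= observed\}) / (iterations + 1)`, so a finite
#' simulation never reports exactly zero.
#'
#' @param vs A `change_vectors` object or `cva` fit; alternatively supply
#'   `k`, `d` and `observed_mean` directly and pass `vs = NULL`.
#' @param k,d,observed_mean Used when `vs` is `NULL`.
#' @param iterations Number of null draws (default `1e5`, the conventional
#'   resolution for this test); below 1000 a warning is issued.
#' @param seed Integer seed (required: the null is stochastic).
#' @return A `cv_test` with extras `mean_angle`, `d`, `k`, `iterations`,
#'   `seed`, `null_mean`. The statistic is the observed mean angle.
#' @export
monte_carlo_parallelism <- function(vs = NULL, k = NULL, d = NULL, observed_mean = NULL,
                                    iterations = 100000L, seed) {
  if (missing(seed) || is.null(seed)) .cv_error("monte_carlo_parallelism requires a seed", "cv_value_error")
  if (!is.null(vs)) {
    v <- .as_vector_matrix(vs)
    k <- nrow(v)
    d <- ncol(v)
    observed_mean <- mean(pairwise_angles(v)$theta_deg)
  }
  if (is.null(k) || is.null(d) || is.null(observed_mean)) {
    .cv_error("supply either a vector set or (k, d, observed_mean)", "cv_value_error")
  }
  if (k < 2L) .cv_error("k must be >= 2", "cv_value_error")
  if (d < 2L) .cv_error("d must be >= 2", "cv_value_error")
  if (iterations < 1000L) warning("fewer than 1000 Monte-Carlo iterations: p-value resolution is coarse")
  null <- random_angle_null(k, d, iterations, seed)
  p <- (1 + sum(null$samples <= observed_mean)) / (iterations + 1)
  .cv_test("monte_carlo", observed_mean, p, choose(k, 2L),
           mean_angle = observed_mean, d = as.integer(d), k = as.integer(k),
           iterations = as.integer(iterations), seed = as.integer(seed),
           null_mean = mean(null$samples))
}

#' Rayleigh test of directional concentration of change-vectors
#'
#' Tests whether the vector directions are unimodally concentrated rather
#' than uniform on the d-sphere. With unit directions `u_i = v_i / |v_i|`
#' and mean resultant length `Rbar = |mean(u_i)|`, the statistic is
#' `S = k * d * Rbar^2`, referred to the upper tail of a chi-square
#' distribution with `d` degrees of freedom. Only directions matter:
#' `S` is invariant to the vectors' lengths.
#'
#' @param vs A `change_vectors` object, `cva` fit, or k x d matrix (k >= 2).
#' @return A `cv_test` with extras `Rbar`, `d`, `k`. Statistic is `S`.
#' @export
rayleigh_test <- function(vs) {
  v <- .as_vector_matrix(vs)
  k <- nrow(v)
  if (k < 2L) .cv_error("Rayleigh test needs k >= 2 vectors", "cv_value_error")
  d <- ncol(v)
  u <- .unit_rows(v)
  rbar <- sqrt(sum(colMeans(u)^2))
  s <- k * d * rbar^2
  p <- stats::pchisq(s, df = d, lower.tail = FALSE)
  .cv_test("rayleigh", s, p, k, Rbar = rbar, d = as.integer(d), k = as.integer(k))
}

#' Spearman rank correlation
#'
#' Nonparametric correlation with average-rank tie handling; exact
#' p-value for n <= 10 without ties, large-sample approximation otherwise.
#' Used e.g. to relate angle sets across taxonomic levels or diversity
#' metrics, and angles to magnitudes (meanL).
#'
#' @param x,y Equal-length numeric vectors, n >= 3.
#' @return A `cv_test` with extra `rho` (also the statistic).
#' @export
spearman_cor <- function(x, y) {
  n <- length(x)
  if (length(y) != n) .cv_error("x and y must have equal length", "cv_value_error")
  if (n < 3L) .cv_error("spearman needs n >= 3", "cv_value_error")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) .cv_error("constant input: correlation undefined", "cv_degenerate_error")
  exact <- n <= 10L && !anyDuplicated(x) && !anyDuplicated(y)
  ht <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = exact))
  .cv_test("spearman", unname(ht$estimate), ht$p.value, n, rho = unname(ht$estimate))
}

#' Paired comparison of two angle sets
#'
#' Paired two-sided t-test of `anglesA - anglesB` over comparisons indexed
#' identically in both sets (e.g. taxonomic composition vs inferred
#' function for the same population pairs). With
#' `restrict_below_90 = TRUE` only comparisons where both sets show
#' parallelism-side angles (< 90 degrees) are kept before testing.
#'
#' @param anglesA,anglesB Paired numeric vectors of angles in degrees.
#' @param restrict_below_90 Keep only pairs with both values below 90.
#' @return A `cv_test` with extras `mean_A`, `mean_B`, `n_used`.
#' @export
compare_angle_sets <- function(anglesA, anglesB, restrict_below_90 = FALSE) {
  if (length(anglesA) != length(anglesB)) .cv_error("angle sets must be paired (equal length)", "cv_value_error")
  keep <- rep(TRUE, length(anglesA))
  if (restrict_below_90) keep <- anglesA < 90 & anglesB < 90
  a <- anglesA[keep]
  b <- anglesB[keep]
  if (length(a) < 2L) .cv_error("fewer than 2 surviving pairs", "cv_value_error")
  diffs <- a - b
  if (stats::sd(diffs) == 0) {
    # degenerate paired t: identical sets give the exact no-difference
    # result; an exactly constant nonzero shift gives the limiting t
    stat <- if (diffs[1] == 0) 0 else sign(diffs[1]) * Inf
    return(.cv_test("paired_set", stat, if (diffs[1] == 0) 1 else 0, length(a),
                    mean_A = mean(a), mean_B = mean(b), n_used = length(a)))
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  .cv_test("paired_set", ht$statistic, ht$p.value, length(a),
           mean_A = mean(a), mean_B = mean(b), n_used = length(a))
}
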