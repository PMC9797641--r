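# Parallelism significance tests, correlations and set comparisons.

test_that("t-test against 90 matches its closed form and sidedness contract", {
  res <- t_test_vs_90(c(80, 85, 90))
  expect_equal(res$statistic, -sqrt(3), tolerance = 1e-10)
  expect_equal(res$p_value, stats::pt(-sqrt(3), df = 2), tolerance = 1e-12)
  expect_equal(res$mean_angle, 85)
  # centered data: t = 0, p = 0.5
  r0 <- t_test_vs_90(c(88, 90, 92))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 0.5)
  # mean above 90 puts the one-sided p above 0.5
  expect_gt(t_test_vs_90(c(95, 100, 110))$p_value, 0.5)
  expect_error(t_test_vs_90(c(90, 90, 90)), class = "cv_degenerate_error")
  expect_error(t_test_vs_90(85), class = "cv_value_error")
})

test_that("Wilcoxon signed-rank test matches exact enumeration", {
  # 5 distinct concordant angles: minimal statistic, exact p = 2^-5
  res <- wilcoxon_vs_90(c(70, 75, 80, 85, 89))
  expect_equal(unname(res$statistic), 0)
  expect_equal(res$p_value, 1 / 32)
  expect_true(res$exact)
  # enumeration oracle for a mixed pattern: P(V <= v_obs) over all 2^n signs
  angles <- c(70, 80, 85, 96)
  d <- angles - 90
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), length(d))))
  v_all <- apply(signs, 1, function(s) sum(r[s]))
  expect_equal(wilcoxon_vs_90(angles)$p_value, mean(v_all <= v_obs))
  expect_error(wilcoxon_vs_90(rep(90, 4)), class = "cv_degenerate_error")
})

test_that("the Shapiro-Wilk gate separates normal from bimodal samples", {
  set.seed(1)
  gn <- shapiro_gate(rnorm(100, mean = 90, sd = 5))
  expect_identical(as.character(gn), "normal")
  gb <- shapiro_gate(c(rep(0, 50), rep(180, 50)))
  expect_identical(as.character(gb), "non_normal")
  expect_lt(attr(gb, "p_value"), 1e-6)
  expect_error(shapiro_gate(c(1, 2)), class = "cv_degenerate_error")
  expect_error(shapiro_gate(rep(5, 10)), class = "cv_degenerate_error")
})

test_that("Monte-Carlo p-values hit their boundary cases and add-one correction", {
  n_it <- 2000
  p_min <- monte_carlo_parallelism(k = 5, d = 10, observed_mean = 0,
                                   iterations = n_it, seed = 4)
  expect_equal(p_min$p_value, 1 / (n_it + 1))
  p_max <- monte_carlo_parallelism(k = 5, d = 10, observed_mean = 180,
                                   iterations = n_it, seed = 4)
  expect_equal(p_max$p_value, 1)
  # observed at the null center lands near p = 0.5
  p_mid <- monte_carlo_parallelism(k = 10, d = 50, observed_mean = 90,
                                   iterations = 4000, seed = 9)
  expect_lt(abs(p_mid$p_value - 0.5), 0.1)
  expect_warning(monte_carlo_parallelism(k = 3, d = 5, observed_mean = 50,
                                         iterations = 500, seed = 1),
                 "1000")
})

test_that("the random-angle null is reproducible and uniform for a single pair in the plane", {
  n1 <- random_angle_null(4, 8, 200, seed = 6)
  n2 <- random_angle_null(4, 8, 200, seed = 6)
  expect_identical(n1$samples, n2$samples)
  expect_length(n1$samples, 200)
  expect_true(all(n1$samples >= 0 & n1$samples <= 180))
  # d = 2, k = 2: the angle between two random directions is uniform on [0, 180]
  u <- random_angle_null(2, 2, 3000, seed = 8)
  ks <- suppressWarnings(stats::ks.test(u$samples, "punif", 0, 180))
  expect_gt(ks$p.value, 0.01)
})

test_that("Rayleigh statistic hits its closed forms and ignores vector lengths", {
  k <- 5; d <- 7
  ident <- matrix(rep(c(1, rep(0, d - 1)), each = k), k, d)
  res <- rayleigh_test(ident)
  expect_equal(res$statistic, k * d)
  expect_equal(res$p_value, stats::pchisq(k * d, df = d, lower.tail = FALSE))
  anti <- rbind(c(1, 0, 0), c(-1, 0, 0))
  res0 <- rayleigh_test(anti)
  expect_equal(res0$statistic, 0, tolerance = 1e-12)
  expect_equal(res0$p_value, 1)
  # invariance to lengths: only directions enter
  set.seed(2)
  v <- matrix(rnorm(6 * 4), 6, 4)
  expect_equal(rayleigh_test(v)$statistic,
               rayleigh_test(v * runif(6, 0.1, 50))$statistic, tolerance = 1e-9)
})

test_that("Rayleigh S has null mean approximately d for uniform directions", {
  set.seed(17)
  d <- 10; k <- 200
  s_vals <- replicate(40, {
    u <- matrix(rnorm(k * d), k, d)
    rayleigh_test(u)$statistic
  })
  # under uniformity S is asymptotically chi-square_d: mean d, var 2d
  expect_lt(abs(mean(s_vals) - d), 3 * sqrt(2 * d / 40))
})

test_that("Spearman correlation matches hand-computed ranks and flags degenerate input", {
  expect_equal(spearman_cor(1:5, (1:5)^3)$rho, 1)
  expect_equal(spearman_cor(1:5, 6 - (1:5))$rho, -1)
  r <- spearman_cor(c(1, 2, 3), c(1, 3, 2))
  expect_equal(r$rho, 0.5)  # sum d^2 = 2 -> 1 - 12/24
  expect_error(spearman_cor(1:3, rep(2, 3)), class = "cv_degenerate_error")
  expect_error(spearman_cor(1:4, 1:5), class = "cv_value_error")
  # agreement with the reference implementation, ties included
  set.seed(10)
  x <- round(rnorm(20), 1); y <- round(x + rnorm(20), 1)
  ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  got <- spearman_cor(x, y)
  expect_equal(got$rho, unname(ref$estimate))
  expect_equal(got$p_value, ref$p.value)
})

test_that("paired angle-set comparison honours orientation and the below-90 filter", {
  a <- c(80, 95, 40)
  b <- c(85, 70, 30)
  res <- compare_angle_sets(a, b, restrict_below_90 = TRUE)
  expect_equal(res$n_used, 2L)  # (80,85) and (40,30) survive
  expect_equal(res$mean_A, 60)
  expect_equal(res$mean_B, 57.5)
  ident <- compare_angle_sets(c(50, 60, 70), c(50, 60, 70))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)
  shifted <- compare_angle_sets(c(50, 60, 70, 90), c(40, 52, 58, 82))
  expect_gt(shifted$statistic, 0)  # A - B orientation
  # exact constant shift: the limiting paired t
  const <- compare_angle_sets(c(50, 60, 70), c(40, 50, 60))
  expect_gt(const$statistic, 0)
  expect_equal(const$p_value, 0)
  expect_error(compare_angle_sets(c(95, 95, 40), c(96, 97, 95), restrict_below_90 = TRUE),
               class = "cv_value_error")
})

test_that("t and Wilcoxon agree in rejection on clearly parallel angle sets", {
  set.seed(23)
  for (i in 1:5) {
    angles <- runif(12, 10, 55)  # all well below 60
    expect_lt(t_test_vs_90(angles)$p_value, 0.05)
    expect_lt(wilcoxon_vs_90(angles)$p_value, 0.05)
  }
})
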