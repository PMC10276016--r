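test_that("Shapiro-Wilk agrees with an independent reference implementation", {
  # fixed sample; reference W computed with scipy.stats.shapiro (1.17.1)
  x <- c(12.741917, 8.870604, 10.726257, 11.265725, 10.808537, 9.787751,
         13.023044, 9.810682, 14.036847, 9.874572, 12.609739, 14.573291,
         7.222279, 9.442422, 9.733357, 11.271901, 9.431494, 4.687089,
         5.119066, 12.640227, 9.386723, 6.437383, 9.656165, 12.429349,
         13.790387, 9.139062, 9.485461, 6.473674, 10.920195, 8.72001,
         10.9109, 11.409675, 12.070207, 8.782147, 11.00991, 6.565983,
         8.431082, 8.298185, 5.171585, 10.072245)
  ref_W <- 0.973135269513
  res <- normality_test(x)
  expect_lt(abs(unname(res$statistic) - ref_W), 1e-6)
  expect_gt(res$p.value, 0.05)
})

test_that("normality test rejects skewed data and validates its input", {
  set.seed(8)
  reject <- mean(replicate(60, normality_test(exp(rnorm(100)))$p.value < 0.05))
  expect_gte(reject, 0.95)
  expect_error(normality_test(rep(1, 10)), "constant")
  expect_error(normality_test(c(1, 2)), "3 <= n")
})

test_that("Pearson correlations match the definitional formula to 1e-12", {
  set.seed(12)
  m <- as.data.frame(matrix(rnorm(200), ncol = 4))
  names(m) <- c("a", "b", "c", "d")
  m$b <- m$a * 0.5 + m$b
  cm <- correlation_matrix(m, params = names(m))
  for (i in 1:3) for (j in (i + 1):4) {
    expect_lt(abs(cm$r[i, j] - brute_pearson(m[[i]], m[[j]])), 1e-12)
    ct <- stats::cor.test(m[[i]], m[[j]])
    expect_equal(cm$p[i, j], ct$p.value)
  }
  expect_equal(cm$r, t(cm$r))
  expect_equal(unname(diag(cm$r)), rep(1, 4))
})

test_that("exact linear relations give r = +/-1 with significance flags", {
  x <- seq(1, 25)
  m <- data.frame(x = x, y = 2 * x + 1, z = -x)
  cm <- correlation_matrix(m, params = c("x", "y", "z"))
  expect_equal(cm$r["x", "y"], 1)
  expect_equal(cm$r["x", "z"], -1)
  expect_true(cm$significant["x", "y"])
})

test_that("correlations are invariant to affine rescaling", {
  set.seed(4)
  m <- data.frame(a = rnorm(50), b = rnorm(50))
  m$b <- m$a + 0.3 * m$b
  r1 <- correlation_matrix(m, params = c("a", "b"))$r["a", "b"]
  m2 <- data.frame(a = 100 + 7 * m$a, b = -3 + 0.01 * m$b)
  r2 <- correlation_matrix(m2, params = c("a", "b"))$r["a", "b"]
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("zero-variance columns yield NA correlations with a warning", {
  m <- data.frame(a = rnorm(20), b = rep(3, 20))
  expect_warning(cm <- correlation_matrix(m, params = c("a", "b")),
                 "zero variance")
  expect_true(is.na(cm$r["a", "b"]))
})

test_that("layer proportions reproduce single-eye arithmetic and additivity", {
  one <- data.frame(GCLp_FC = 13.95, ONL_FC = 150.52, RT_FC = 247.09)
  pr <- layer_proportions(one)
  expect_equal(pr$per_eye$ratio_combined, (13.95 + 150.52) / 247.09)
  expect_equal(round(pr$per_eye$ratio_combined, 4), 0.6656)
  # boundary case: no GCL+, ONL fills the whole retina
  lim <- layer_proportions(data.frame(GCLp_FC = 0, ONL_FC = 200, RT_FC = 200))
  expect_equal(lim$per_eye$ratio_combined, 1)
  # additivity per eye
  m <- sample_cohort_metrics(cohort_spec("ept_norop", 200, seed = 14))
  pe <- layer_proportions(m)$per_eye
  expect_equal(pe$ratio_combined, pe$ratio_onl + pe$ratio_gclp)
  expect_true(all(pe$ratio_combined >= 0 & pe$ratio_combined <= 1))
})

test_that("rows with non-positive retinal thickness are dropped with a warning", {
  m <- data.frame(GCLp_FC = c(5, 5), ONL_FC = c(100, 100), RT_FC = c(200, 0))
  expect_warning(pr <- layer_proportions(m), "non-positive")
  expect_equal(nrow(pr$per_eye), 1)
})

test_that("summary-based Welch test reconstructs the gestational-age comparison", {
  w <- group_compare_summary(25.83, 0.39, 12, 25.71, 0.49, 7)
  expect_gt(w$p, 0.55)
  expect_lt(w$p, 0.63)
  expect_lt(abs(w$p - 0.591), 0.01)
})

test_that("summary-based tests agree with t.test on raw data", {
  # vectors constructed to have exactly the requested means and SDs
  make <- function(n, m, s, seed) {
    set.seed(seed)
    z <- rnorm(n)
    m + s * (z - mean(z)) / sd(z)
  }
  x <- make(12, 25.83, 0.39, 1)
  y <- make(7, 25.71, 0.49, 2)
  for (welch in c(TRUE, FALSE)) {
    ref <- stats::t.test(x, y, var.equal = !welch)
    w <- group_compare_summary(mean(x), sd(x), length(x),
                               mean(y), sd(y), length(y), welch = welch)
    expect_equal(w$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(w$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(w$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("identical groups give t = 0 and p = 1", {
  d <- data.frame(v = rep(c(1, 2, 3), 2),
                  group_label = rep(c("a", "b"), each = 3))
  res <- group_compare(d, "v")
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  w <- group_compare_summary(5, 1, 10, 5, 1, 10)
  expect_equal(w$t, 0)
  expect_equal(w$p, 1)
})

test_that("Welch p agrees with a permutation test within Monte Carlo error", {
  set.seed(21)
  x <- rnorm(9, 0.3, 1)
  y <- rnorm(8, 0.0, 1)
  w <- group_compare_summary(mean(x), sd(x), 9, mean(y), sd(y), 8)
  pooled <- c(x, y)
  obs <- abs(mean(x) - mean(y))
  perm <- replicate(4000, {
    idx <- sample(17, 9)
    abs(mean(pooled[idx]) - mean(pooled[-idx]))
  })
  p_perm <- mean(perm >= obs - 1e-12)
  expect_lt(abs(w$p - p_perm), 0.05)
})

test_that("group_compare validates group structure", {
  d <- data.frame(v = 1:5, group_label = c("a", "a", "a", "a", "b"))
  expect_error(group_compare(d, "v"), "n >= 2")
  d3 <- data.frame(v = 1:6, group_label = c("a", "a", "b", "b", "c", "c"))
  expect_error(group_compare(d3, "v"), "two levels")
})
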