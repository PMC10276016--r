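test_that("mean +/- 2 SD limits match the calibrated reference to one decimal", {
  def <- cohort_defaults("control")
  lim <- limits_from_summary(def$means, def$sds)
  get <- function(p) lim$limit[lim$parameter == p]
  expect_equal(get("GCLp_FC"), 3.47 + 2 * 2.11)   # 7.69 -> prints 7.7
  expect_equal(get("FD"), 131.15 - 2 * 16.73)     # 97.69 -> prints 97.7
  expect_identical(lim$direction[lim$parameter == "FD"], "lower")
  expect_lt(abs(get("GCLp_FC") - def$reference_limits[["GCLp_FC"]]), 0.051)
  expect_lt(abs(get("GCLp_Q2Q") - def$reference_limits[["GCLp_Q2Q"]]), 0.051)
  expect_lt(abs(get("RT_FC") - def$reference_limits[["RT_FC"]]), 0.051)
  expect_lt(abs(get("FD") - def$reference_limits[["FD"]]), 0.051)
})

test_that("zero-SD controls give limit = mean with a warning", {
  ctrl <- data.frame(GCLp_FC = rep(5, 10), GCLp_Q2Q = rep(10, 10),
                     ONL_FC = rep(100, 10), RT_FC = rep(200, 10),
                     FD = rep(130, 10))
  expect_warning(compute_limits(ctrl, params = "GCLp_FC"), "zero variance")
  suppressWarnings(lim <- compute_limits(ctrl))
  expect_equal(lim$limit, c(5, 10, 100, 200, 130))
})

test_that("limits require at least two control eyes and complete columns", {
  ctrl <- data.frame(GCLp_FC = 5, GCLp_Q2Q = 10, ONL_FC = 100,
                     RT_FC = 200, FD = 130)
  expect_error(compute_limits(ctrl), "at least 2")
  expect_error(compute_limits(ctrl[, -3], params = foveal_parameters()),
               "ONL_FC")
})

test_that("classification uses strict exceedance with equality as within", {
  lim <- limits_from_summary(c(GCLp_FC = 5, FD = 100), c(GCLp_FC = 1, FD = 10))
  # upper limit 7, lower limit 80
  m <- data.frame(eye_id = c("a", "b", "c", "d"),
                  GCLp_FC = c(7, 7.0001, 6.9999, 0),
                  FD = c(80, 79.9999, 80.0001, 200))
  cls <- classify_eyes(m, lim)
  expect_equal(cls$calls$GCLp_FC, c("within", "outside", "within", "within"))
  expect_equal(cls$calls$FD, c("within", "outside", "within", "within"))
  expect_equal(cls$summary$proportion_outside, c(0.25, 0.25))
  # exact binomial CI bounds
  ci <- stats::binom.test(1, 4)$conf.int
  expect_equal(cls$summary$ci_lower[1], ci[1])
  expect_equal(cls$summary$ci_upper[1], ci[2])
})

test_that("a preterm group mean falls outside the control GCL+ limit", {
  lim <- limits_from_summary(cohort_defaults("control")$means,
                             cohort_defaults("control")$sds)
  ept_mean <- cohort_defaults("ept_norop")$means
  cls <- classify_eyes(as.data.frame(as.list(ept_mean)), lim)
  expect_equal(cls$calls$GCLp_FC, "outside")
  expect_equal(cls$calls$RT_FC, "outside")
  expect_equal(cls$calls$FD, "outside")
})

test_that("classification is equivariant under translation and scaling", {
  set.seed(31)
  ctrl <- data.frame(GCLp_FC = rnorm(60, 3.5, 2))
  test <- data.frame(GCLp_FC = rnorm(40, 10, 5))
  lim <- compute_limits(ctrl, params = "GCLp_FC")
  base <- classify_eyes(test, lim)$calls$GCLp_FC
  for (f in list(function(x) x + 57.3, function(x) x * 3.7)) {
    lim2 <- compute_limits(data.frame(GCLp_FC = f(ctrl$GCLp_FC)),
                           params = "GCLp_FC")
    cls2 <- classify_eyes(data.frame(GCLp_FC = f(test$GCLp_FC)), lim2)
    expect_identical(cls2$calls$GCLp_FC, base)
  }
})

test_that("degenerate zero-variance controls classify any larger value outside", {
  suppressWarnings(lim <- compute_limits(
    data.frame(GCLp_FC = rep(5, 5)), params = "GCLp_FC"))
  cls <- classify_eyes(data.frame(GCLp_FC = c(5, 5.001, 4.9)), lim)
  expect_equal(cls$calls$GCLp_FC, c("within", "outside", "within"))
})

test_that("the inconsistent reference ONL limit is flagged", {
  def <- cohort_defaults("control")
  lim <- limits_from_summary(def$means, def$sds)
  expect_warning(chk <- verify_limit_consistency(lim, def$reference_limits),
                 "ONL_FC")
  expect_false(chk$consistent[chk$parameter == "ONL_FC"])
  expect_true(all(chk$consistent[chk$parameter != "ONL_FC"]))
  # the recomputed ONL limit is mean + 2 SD, not the reference 136.9
  expect_equal(chk$computed[chk$parameter == "ONL_FC"],
               107.78 + 2 * 12.43)
})
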