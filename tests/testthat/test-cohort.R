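test_that("degenerate zero-SD spec reproduces the calibration means exactly", {
  spec <- cohort_spec("control", n_eyes = 4, seed = 1,
                      sds = setNames(rep(0, 5), foveal_parameters()),
                      residual_sd = 0, fwm_asym_sd = 0)
  m <- sample_cohort_metrics(spec)
  expect_equal(m$GCLp_FC, rep(3.47, 4))
  expect_equal(m$ONL_FC, rep(107.78, 4))
  expect_equal(m$RT_FC, rep(208.36, 4), tolerance = 1e-12)
  expect_equal(m$FD, rep(131.15, 4))
  expect_equal(m$RT_FWM_nasal, m$RT_FWM_temporal)
})

test_that("sampling is deterministic under a fixed seed", {
  spec <- cohort_spec("ept_norop", n_eyes = 25, seed = 42)
  expect_identical(sample_cohort_metrics(spec), sample_cohort_metrics(spec))
  spec2 <- cohort_spec("ept_norop", n_eyes = 25, seed = 43)
  expect_false(identical(sample_cohort_metrics(spec),
                         sample_cohort_metrics(spec2)))
})

test_that("marginal means converge to the spec means (3 SE bound)", {
  n <- 10000
  # controls: GCL+ is decoupled from ONL and FD, so rejecting the rare
  # negative-GCL+ draws does not shift those marginals
  m <- sample_cohort_metrics(cohort_spec("control", n_eyes = n, seed = 7))
  expect_lt(abs(mean(m$ONL_FC) - 107.78), 3 * 12.43 / sqrt(n) + 0.05)
  expect_lt(abs(mean(m$FD) - 131.15), 3 * 16.73 / sqrt(n) + 0.05)
  # preterm eyes: truncating GCL+ at zero pulls the correlated ONL and FD
  # marginals slightly along; the shift stays small against their SDs
  e <- sample_cohort_metrics(cohort_spec("ept_norop", n_eyes = n, seed = 7))
  expect_gt(mean(e$GCLp_FC), 13.95)  # truncation elevates the mean
  expect_lt(abs(mean(e$ONL_FC) - 150.52), 5)
  expect_lt(abs(mean(e$FD) - 89.46), 5)
})

test_that("thickness truncation at zero and structural identities hold", {
  m <- sample_cohort_metrics(cohort_spec("ept_norop", n_eyes = 3000, seed = 9))
  expect_true(all(m$GCLp_FC >= 0))
  expect_true(all(m$ONL_FC >= 0))
  expect_true(all(m$FD > 0))
  expect_true(all(m$RT_FC >= m$GCLp_FC + m$ONL_FC))
  expect_equal(m$RT_FWM_mean, (m$RT_FWM_nasal + m$RT_FWM_temporal) / 2)
  expect_equal(m$FD, m$RT_FWM_mean - m$RT_FC)
})

test_that("invalid specs are rejected with diagnostics", {
  bad_corr <- diag(5)
  bad_corr[1, 2] <- bad_corr[2, 1] <- 0.9
  bad_corr[1, 3] <- bad_corr[3, 1] <- 0.9
  bad_corr[2, 3] <- bad_corr[3, 2] <- -0.9  # not PSD
  expect_error(cohort_spec("control", n_eyes = 5, seed = 1,
                           correlation = bad_corr),
               "positive semi-definite")
  expect_error(cohort_spec("control", n_eyes = 5, seed = 1,
                           means = c(GCLp_FC = 150, GCLp_Q2Q = 10,
                                     ONL_FC = 107, RT_FC = 208, FD = 131)),
               "infeasible")
  expect_error(cohort_spec("control", n_eyes = 0, seed = 1), "n_eyes")
  expect_error(cohort_spec("control", n_eyes = 5, seed = 1,
                           sds = c(GCLp_FC = -1, GCLp_Q2Q = 4.76,
                                   ONL_FC = 12.43, RT_FC = 12.53,
                                   FD = 16.73)),
               ">= 0")
})

test_that("laterality policy controls the laterality column", {
  lat <- sample_cohort_metrics(cohort_spec("control", 10, 1,
                                           laterality_policy = "all-right"))
  expect_true(all(lat$laterality == "OD"))
  mix <- sample_cohort_metrics(cohort_spec("control", 200, 1,
                                           laterality_policy = "mixed"))
  expect_setequal(unique(mix$laterality), c("OD", "OS"))
})
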