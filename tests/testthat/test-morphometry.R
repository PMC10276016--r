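test_that("the programmed pit centre is recovered at the IS/OS peak", {
  b <- build_boundaries(control_like_targets())
  p <- thickness_profiles(flatten_to_rpe(b))
  fc <- locate_foveal_centre(p)
  expect_equal(fc$method, "isos_peak")
  expect_lt(abs(fc$lateral_um), p$lateral_scale)  # within 1 A-scan of 0
  expect_length(fc$flags, 0)
})

test_that("flat IS/OS triggers the minimum-RT fallback", {
  b <- build_boundaries(control_like_targets(),
                        geometry = eye_geometry(os_bump_um = 0))
  p <- thickness_profiles(flatten_to_rpe(b))
  fc <- locate_foveal_centre(p)
  expect_equal(fc$method, "min_rt")
  expect_lt(abs(fc$lateral_um), 2 * p$lateral_scale)
})

test_that("exact symmetric ties resolve toward the temporal side", {
  # two equal IS/OS peaks equidistant from the scan centre
  scan <- scan_geometry(n_ascans = 65, n_axial = 512)
  rpe <- rep(400, 65)
  elev <- rep(40, 65)
  elev[33 - 8] <- elev[33 + 8] <- 60  # symmetric double peak
  b <- boundary_set(list(
    ILM = rpe - 150, GCLp_inner = rpe - 145, GCLp_outer = rpe - 120,
    ONL_inner = rpe - 110, ONL_outer = rpe - elev - 2, ISOS = rpe - elev,
    RPE_posterior = rpe), laterality = "OD", scan = scan)
  p <- thickness_profiles(b)
  fc <- locate_foveal_centre(p, flatness_threshold_um = 1)
  # OD: temporal = lower index; both candidates tie on centre distance
  expect_equal(fc$index, 33 - 8)
})

test_that("rims are found at programmed GCL+ annulus peaks", {
  for (t in list(control_like_targets(), ept_like_targets())) {
    b <- build_boundaries(t)
    p <- thickness_profiles(flatten_to_rpe(b))
    fc <- locate_foveal_centre(p)
    rims <- locate_rims(p, fc)
    tr <- attr(b, "truth")
    expect_lt(abs(rims$nasal$index - 1L - tr$rim_index_nasal), 3)
    expect_lt(abs(rims$temporal$index - 1L - tr$rim_index_temporal), 3)
    expect_length(rims$nasal$flags, 0)
    expect_length(rims$temporal$flags, 0)
  }
})

test_that("a flat GCL+ profile yields the innermost window index, flagged", {
  b <- flat_stack_bset(n = 512, scan = scan_geometry())
  p <- thickness_profiles(b)
  fc <- list(index = 257L)
  rims <- locate_rims(p, fc)
  # ties resolve toward FC: first index at >= 300 um on each side
  min_off <- ceiling(300 / p$lateral_scale)
  expect_equal(rims$nasal$index, 257L + min_off)
  expect_equal(rims$temporal$index, 257L - min_off)
  expect_true("nasal_rim_plateau" %in% rims$nasal$flags)
  expect_true("temporal_rim_plateau" %in% rims$temporal$flags)
})

test_that("foveal depth arithmetic follows from its definition", {
  # hand-built profile with known reads at the landmarks
  scan <- scan_geometry(n_ascans = 512, n_axial = 1024)
  as_ <- scan$axial_scale
  rpe <- rep(900, 512)
  rt_px <- rep(247.09 / as_, 512)
  rt_px[400] <- 340 / as_
  rt_px[100] <- 330 / as_
  b <- boundary_set(list(
    ILM = rpe - rt_px, GCLp_inner = rpe - rt_px + 1,
    GCLp_outer = rpe - rt_px + 6, ONL_inner = rpe - rt_px + 10,
    ONL_outer = rpe - 30, ISOS = rpe - 25, RPE_posterior = rpe),
    laterality = "OD", scan = scan)
  p <- thickness_profiles(b)
  m <- compute_metrics(p, fc = list(index = 257L, flags = character(0)),
                       rims = list(nasal = list(index = 400L, flags = character(0)),
                                   temporal = list(index = 100L, flags = character(0))))
  expect_equal(m$RT_FWM_nasal, 340)
  expect_equal(m$RT_FWM_temporal, 330)
  expect_equal(m$RT_FC, 247.09, tolerance = 1e-9)
  expect_equal(m$FD, 87.91, tolerance = 1e-9)
  expect_equal(m$FD, m$RT_FWM_mean - m$RT_FC)
})

test_that("a symmetric eye has equal quarter-point GCL+ on both sides", {
  t <- control_like_targets()
  t$RT_FWM_nasal <- t$RT_FWM_temporal <- 340
  b <- build_boundaries(t)
  p <- thickness_profiles(flatten_to_rpe(b))
  fc <- locate_foveal_centre(p)
  rims <- locate_rims(p, fc)
  i_qn <- fc$index + round(0.25 * (rims$nasal$index - fc$index))
  i_qt <- fc$index + round(0.25 * (rims$temporal$index - fc$index))
  m <- compute_metrics(p, fc, rims)
  expect_equal(p$gclp[i_qn], p$gclp[i_qt], tolerance = 1e-9)
  expect_equal(m$GCLp_Q2Q, p$gclp[i_qn], tolerance = 1e-9)
})

test_that("mirroring the scan and toggling laterality leaves metrics unchanged", {
  for (t in list(control_like_targets(), ept_like_targets())) {
    b <- build_boundaries(t)
    m1 <- extract_foveal_metrics(b)
    m2 <- extract_foveal_metrics(mirror_boundary_set(b))
    for (col in c("GCLp_FC", "GCLp_Q2Q", "ONL_FC", "RT_FC",
                  "RT_FWM_nasal", "RT_FWM_temporal", "FD"))
      expect_equal(m2[[col]], m1[[col]], tolerance = 1e-9, label = col)
  }
})

test_that("foveal depth responds monotonically to its inputs", {
  base <- control_like_targets()
  fd_of <- function(t) extract_foveal_metrics(build_boundaries(t))$FD
  fd0 <- fd_of(base)
  up <- base
  up$RT_FWM_nasal <- up$RT_FWM_nasal + 20
  up$RT_FWM_temporal <- up$RT_FWM_temporal + 20
  expect_gt(fd_of(up), fd0)
  thick <- base
  thick$RT_FC <- thick$RT_FC + 20
  expect_lt(fd_of(thick), fd0)
})

test_that("zero central GCL+ is read back as exactly zero", {
  b <- build_boundaries(control_like_targets(gclp_fc = 0))
  m <- extract_foveal_metrics(b)
  expect_identical(m$GCLp_FC, 0)
})
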