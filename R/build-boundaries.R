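#' Construct ground-truth boundaries realizing target foveal metrics
#'
#' Solves the inverse problem of the morphometry: given one eye's target
#' metrics (as produced by [sample_cohort_metrics()]), build smooth
#' pit-shaped boundary polylines whose extracted parameters reproduce the
#' targets. The retinal-thickness profile is a raised-cosine pit rising
#' from `RT_FC` at the centre to the per-side rim thickness at the pit
#' half-width, with zero slope at both centre and rim so that point reads
#' at the detected landmarks are insensitive to one-A-scan localization
#' error. The GCL+ profile rises from `GCLp_FC` to an annulus peak at the
#' rim whose height is chosen so that the quarter-point value equals the
#' `GCLp_Q2Q` target; the ONL thins by a fixed fraction towards the rim;
#' the residual bands absorb the remainder, with a Gaussian outer-segment
#' elevation bump that marks the foveal centre on the IS/OS boundary.
#'
#' @param targets One-row data frame or named list with `GCLp_FC`,
#'   `GCLp_Q2Q`, `ONL_FC`, `RT_FC`, `RT_FWM_nasal`, `RT_FWM_temporal`
#'   (micrometres) and optionally `eye_id`, `laterality`.
#' @param geometry An [eye_geometry()].
#' @param scan A [scan_geometry()].
#' @param laterality Eye side; overrides `targets$laterality` if given.
#' @return A [boundary_set()] with attributes `truth` (the realized target
#'   metrics, including the pit-centre A-scan and rim indices) and `flags`
#'   (character vector; e.g. `"q2q_floor"` when the Q2Q target is not
#'   achievable with a rising annulus and was floored, `"os_scaled"` when
#'   the outer-segment band was shrunk to keep all bands non-negative).
#' @export
build_boundaries <- function(targets, geometry = eye_geometry(),
                             scan = scan_geometry(), laterality = NULL) {
  t <- as.list(targets)
  need <- c("GCLp_FC", "GCLp_Q2Q", "ONL_FC", "RT_FC",
            "RT_FWM_nasal", "RT_FWM_temporal")
  missing <- setdiff(need, names(t))
  if (length(missing))
    stop("targets missing: ", paste(missing, collapse = ", "))
  for (nm in need) t[[nm]] <- as.numeric(t[[nm]])
  if (is.null(laterality))
    laterality <- if (!is.null(t$laterality)) as.character(t$laterality) else "OD"
  eye_id <- if (!is.null(t$eye_id)) as.character(t$eye_id) else "eye"
  flags <- character(0)

  g_c <- t$GCLp_FC; q2q <- t$GCLp_Q2Q; o_c <- t$ONL_FC; rt_c <- t$RT_FC
  if (g_c < 0 || o_c < 0)
    stop("violated constraint: layer thicknesses must be >= 0")
  if (rt_c < g_c + o_c)
    stop("violated constraint: RT_FC must be >= GCLp_FC + ONL_FC (",
         format(rt_c, digits = 6), " < ",
         format(g_c + o_c, digits = 6), ")")
  if (t$RT_FWM_nasal <= rt_c || t$RT_FWM_temporal <= rt_c)
    stop("violated constraint: rim retinal thickness must exceed RT_FC ",
         "(foveal depth must be positive)")

  d <- geometry$pit_half_width_um
  x <- lateral_positions(scan)
  # snap pit centre to the nearest A-scan so landmark reads are exact
  fc_idx <- which.min(abs(x - geometry$pit_center_um))
  u <- abs(x - x[fc_idx])
  nasal_high_index <- laterality == "OD"  # temporal-to-nasal raster for OD
  nasal_side <- if (nasal_high_index) x > x[fc_idx] else x < x[fc_idx]

  # per-side rim amplitude for retinal thickness (raised-cosine pit)
  s2 <- .rim_ramp(u, d, floor = geometry$peripheral_decay, squared = TRUE)
  rim <- ifelse(nasal_side, t$RT_FWM_nasal, t$RT_FWM_temporal)
  rim[fc_idx] <- (t$RT_FWM_nasal + t$RT_FWM_temporal) / 2
  rt <- rt_c + (rim - rt_c) * s2

  # GCL+ annulus: peak height from the quarter-point (Q2Q) target
  s1 <- .rim_ramp(u, d, floor = geometry$peripheral_decay, squared = FALSE)
  s_quarter <- sin(pi / 8)  # ramp value at u = d/4
  if (q2q <= g_c + 0.5) {
    q2q_eff <- g_c + 0.5 + 1e-6
    flags <- c(flags, "q2q_floor")
  } else q2q_eff <- q2q
  g_peak <- g_c + (q2q_eff - g_c) / s_quarter
  gclp <- g_c + (g_peak - g_c) * s1

  onl <- o_c * (1 - geometry$onl_rim_drop * s2)

  resid <- rt - gclp - onl
  if (min(resid) <= geometry$elm_band_um + 0.5)
    stop("violated constraint: GCL+ and ONL profiles exceed the ",
         "retinal-thickness profile (residual bands would be negative; ",
         "min residual ", format(min(resid), digits = 4), " um)")
  t_os <- geometry$os_base_um +
    geometry$os_bump_um * exp(-u^2 / (2 * geometry$os_bump_sigma_um^2))
  inner_rest <- resid - t_os - geometry$elm_band_um
  if (min(inner_rest) < 1) {
    # shrink the outer-segment band uniformly; preserves its argmax
    c_os <- min((resid - geometry$elm_band_um - 1) / t_os)
    if (c_os < 0.2)
      stop("violated constraint: residual bands too thin to host the ",
           "outer-segment layer (scale factor ",
           format(c_os, digits = 3), ")")
    t_os <- c_os * t_os
    inner_rest <- resid - t_os - geometry$elm_band_um
    flags <- c(flags, "os_scaled")
  }
  rnfl <- geometry$rnfl_frac * inner_rest
  inl_opl <- inner_rest - rnfl

  as_ <- scan$axial_scale
  half <- max(abs(x))
  rpe <- geometry$rpe_row_frac * (scan$n_axial - 1L) +
    (geometry$rpe_tilt_um * (x / half) +
       geometry$rpe_curve_um * (x / half)^2) / as_
  isos <- rpe - t_os / as_
  onl_outer <- isos - geometry$elm_band_um / as_
  onl_inner <- onl_outer - onl / as_
  gclp_outer <- onl_inner - inl_opl / as_
  gclp_inner <- gclp_outer - gclp / as_
  ilm <- gclp_inner - rnfl / as_

  bset <- boundary_set(
    list(ILM = ilm, GCLp_inner = gclp_inner, GCLp_outer = gclp_outer,
         ONL_inner = onl_inner, ONL_outer = onl_outer, ISOS = isos,
         RPE_posterior = rpe),
    laterality = laterality, scan = scan, eye_id = eye_id)

  rim_offset <- round(d / scan$lateral_scale)
  truth <- list(
    fc_index = fc_idx - 1L,  # 0-based
    rim_index_nasal = fc_idx - 1L + if (nasal_high_index) rim_offset else -rim_offset,
    rim_index_temporal = fc_idx - 1L + if (nasal_high_index) -rim_offset else rim_offset,
    GCLp_FC = g_c, GCLp_Q2Q = q2q_eff, ONL_FC = o_c, RT_FC = rt_c,
    RT_FWM_nasal = t$RT_FWM_nasal, RT_FWM_temporal = t$RT_FWM_temporal,
    FD = (t$RT_FWM_nasal + t$RT_FWM_temporal) / 2 - rt_c)
  attr(bset, "truth") <- truth
  attr(bset, "flags") <- flags
  bset
}
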