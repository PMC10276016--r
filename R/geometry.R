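#' Scan geometry of a macular B-scan raster
#'
#' Defaults follow the macular-cube convention of a 6 mm line of 512
#' A-scans with a 2 mm axial range over 1024 pixels: lateral scale
#' 6000/512 = 11.71875 um/px and axial scale 2000/1024 = 1.953125 um/px.
#' Axial coordinates are 0-based with 0 at the anterior (vitreous) edge,
#' increasing posteriorly. The A-scan at index `n_ascans/2` (0-based) sits
#' at lateral position 0 (the scan centre).
#'
#' @param n_ascans Number of A-scans (image columns).
#' @param n_axial Number of axial pixels (image rows).
#' @param lateral_scale,axial_scale Micrometres per pixel; both > 0.
#' @return Object of class `scan_geometry`.
#' @export
scan_geometry <- function(n_ascans = 512L, n_axial = 1024L,
                          lateral_scale = 6000 / 512,
                          axial_scale = 2000 / 1024) {
  stopifnot(n_ascans >= 8, n_axial >= 8, lateral_scale > 0, axial_scale > 0)
  structure(list(n_ascans = as.integer(n_ascans),
                 n_axial = as.integer(n_axial),
                 lateral_scale = lateral_scale,
                 axial_scale = axial_scale),
            class = "scan_geometry")
}

#' Lateral raster positions of the A-scans
#'
#' @param scan A [scan_geometry()].
#' @return Numeric vector (um) in raster index order, 0 at the centre
#'   A-scan; sign is raster orientation, not yet laterality-resolved.
#' @export
lateral_positions <- function(scan) {
  (seq_len(scan$n_ascans) - 1L - scan$n_ascans %/% 2L) * scan$lateral_scale
}

#' Parametric eye geometry for boundary construction
#'
#' Shape parameters of the synthetic foveal anatomy used by
#' [build_boundaries()]: a raised-cosine pit of half-width
#' `pit_half_width_um`, an outer-segment band with a Gaussian elevation
#' bump at the centre (this is what makes the IS/OS junction peak at the
#' foveal centre), a fractional thinning of the ONL towards the rim, and a
#' peripheral decay floor that makes the rim a genuine maximum.
#'
#' @param pit_half_width_um Centre-to-rim distance (um); > 0.
#' @param pit_center_um Lateral pit-centre offset from the scan centre
#'   (um); snapped to the nearest A-scan during construction.
#' @param onl_rim_drop Fractional ONL thinning at the rim relative to the
#'   centre, in `[0, 0.9]`.
#' @param peripheral_decay Floor (fraction of the rim elevation) to which
#'   profiles decay beyond twice the rim distance, in `[0, 0.95]`.
#' @param os_base_um,os_bump_um,os_bump_sigma_um Outer-segment band:
#'   baseline thickness, central bump amplitude and bump width (um).
#' @param elm_band_um Thin band between ONL and IS/OS (um).
#' @param rnfl_frac Fraction of the inner residual assigned to the nerve
#'   fibre layer band (rest goes to the INL+OPL band), in `(0, 1)`.
#' @param rpe_row_frac Posterior RPE baseline row as a fraction of raster
#'   height.
#' @param rpe_tilt_um,rpe_curve_um Linear and quadratic RPE baseline
#'   deviation across the half-scan (um); nonzero values produce tilted or
#'   curved scans for exercising flattening.
#' @return Object of class `eye_geometry`.
#' @export
eye_geometry <- function(pit_half_width_um = 1000,
                         pit_center_um = 0,
                         onl_rim_drop = 0.25,
                         peripheral_decay = 0.35,
                         os_base_um = 25,
                         os_bump_um = 12,
                         os_bump_sigma_um = 150,
                         elm_band_um = 3,
                         rnfl_frac = 0.2,
                         rpe_row_frac = 0.75,
                         rpe_tilt_um = 0,
                         rpe_curve_um = 0) {
  stopifnot(pit_half_width_um > 0,
            onl_rim_drop >= 0, onl_rim_drop <= 0.9,
            peripheral_decay >= 0, peripheral_decay <= 0.95,
            os_base_um > 0, os_bump_um >= 0, os_bump_sigma_um > 0,
            elm_band_um >= 0, rnfl_frac > 0, rnfl_frac < 1,
            rpe_row_frac > 0, rpe_row_frac < 1)
  structure(list(pit_half_width_um = pit_half_width_um,
                 pit_center_um = pit_center_um,
                 onl_rim_drop = onl_rim_drop,
                 peripheral_decay = peripheral_decay,
                 os_base_um = os_base_um,
                 os_bump_um = os_bump_um,
                 os_bump_sigma_um = os_bump_sigma_um,
                 elm_band_um = elm_band_um,
                 rnfl_frac = rnfl_frac,
                 rpe_row_frac = rpe_row_frac,
                 rpe_tilt_um = rpe_tilt_um,
                 rpe_curve_um = rpe_curve_um),
            class = "eye_geometry")
}

# ramp with value 0 at u = 0, 1 at u = d (zero slope there), decaying to
# `floor` beyond 2d. `squared = TRUE` additionally has zero slope at u = 0
# (raised-cosine pit); FALSE rises promptly off-centre (GCL+ annulus).
.rim_ramp <- function(u, d, floor = 0.35, squared = TRUE) {
  s <- numeric(length(u))
  inside <- u <= d
  base <- sin(pi * pmin(u, d) / (2 * d))
  if (squared) base <- base^2
  s[inside] <- base[inside]
  out <- !inside
  if (any(out)) {
    v <- pmin(u[out] - d, d)
    s[out] <- floor + (1 - floor) * cos(pi * v / (2 * d))^2
  }
  s
}
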