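#' Per-A-scan thickness profiles in micrometres
#'
#' Converts boundary separations to thickness profiles: GCL+ thickness
#' (`GCLp_outer - GCLp_inner`), ONL thickness (`ONL_outer - ONL_inner`)
#' and retinal thickness (`RPE_posterior - ILM`), each multiplied by the
#' axial scale. Thickness is shift-invariant, so flattened and unflattened
#' boundary sets give identical profiles. The lateral axis is resolved to
#' a signed nasal-positive coordinate: for OD the raster runs temporal to
#' nasal (nasal = increasing index), for OS the reverse.
#'
#' Smoothed copies (`gclp_sm`, `onl_sm`, `rt_sm`) are computed with a
#' centred moving average of `smooth_window` A-scans (odd; 1 disables),
#' with windows shrunk symmetrically at the scan edges. Smoothing is used
#' only for landmark localization; point reads use the raw profiles.
#'
#' @param bset A [boundary_set()].
#' @param smooth_window Odd window length in A-scans.
#' @return Object of class `thickness_profile`: list with `lateral_um`
#'   (signed, nasal positive), `raster_um` (raster-order position, 0 at
#'   the scan centre), `gclp`, `onl`, `rt`, smoothed variants, `elevation_isos`
#'   (IS/OS height above the posterior RPE, um), `laterality`,
#'   `smooth_window`, and the pixel scales.
#' @export
thickness_profiles <- function(bset, smooth_window = 5L) {
  if (smooth_window %% 2L == 0L)
    stop("smooth_window must be odd (got ", smooth_window, ")")
  b <- bset$boundaries
  as_ <- bset$scan$axial_scale
  gclp <- (b$GCLp_outer - b$GCLp_inner) * as_
  onl <- (b$ONL_outer - b$ONL_inner) * as_
  rt <- (b$RPE_posterior - b$ILM) * as_
  elev <- (b$RPE_posterior - b$ISOS) * as_
  raster <- lateral_positions(bset$scan)
  signed <- if (bset$laterality == "OD") raster else -raster
  structure(list(
    lateral_um = signed, raster_um = raster,
    gclp = gclp, onl = onl, rt = rt,
    gclp_sm = moving_average(gclp, smooth_window),
    onl_sm = moving_average(onl, smooth_window),
    rt_sm = moving_average(rt, smooth_window),
    elevation_isos = elev,
    laterality = bset$laterality,
    smooth_window = as.integer(smooth_window),
    axial_scale = as_, lateral_scale = bset$scan$lateral_scale,
    n_ascans = bset$n_ascans, eye_id = bset$eye_id),
    class = "thickness_profile")
}

#' Centred moving average with edge shrinkage
#'
#' Boxcar smoother of odd window `w`: element `i` is the mean of the
#' values within `(w-1)/2` positions of `i`, with the half-width reduced
#' near the edges so the window always fits (an element never averages
#' beyond the array). `w = 1` returns the input unchanged.
#'
#' @param x Numeric vector.
#' @param w Odd positive window length.
#' @return Numeric vector of the same length.
#' @export
moving_average <- function(x, w) {
  w <- as.integer(w)
  if (w < 1L || w %% 2L == 0L) stop("window must be odd and >= 1")
  if (w == 1L) return(x)
  h <- (w - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  out <- numeric(n)
  for (i in seq_len(n)) {
    hh <- min(h, i - 1L, n - i)
    out[i] <- (cs[i + hh + 1L] - cs[i - hh]) / (2L * hh + 1L)
  }
  out
}

#' @export
print.thickness_profile <- function(x, ...) {
  cat("<thickness_profile>", x$n_ascans, "A-scans, laterality",
      x$laterality, ", smooth_window", x$smooth_window, "\n")
  cat("  RT range ", format(min(x$rt), digits = 5), "-",
      format(max(x$rt), digits = 5), " um\n", sep = "")
  invisible(x)
}

#' Export a thickness profile as CSV
#'
#' @param profile A [thickness_profiles()] result.
#' @param path Output CSV (columns `lateral_um`, `gclp_um`, `onl_um`,
#'   `rt_um`).
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(
    data.frame(lateral_um = profile$lateral_um, gclp_um = profile$gclp,
               onl_um = profile$onl, rt_um = profile$rt),
    path, row.names = FALSE)
  invisible(path)
}
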