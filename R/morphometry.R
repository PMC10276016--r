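#' Locate the foveal centre
#'
#' The foveal centre (FC) is the A-scan where the photoreceptor IS/OS
#' junction is most elevated above the posterior RPE, searched within
#' `search_halfwidth_um` of the scan centre. If the IS/OS elevation range
#' inside the window is below `flatness_threshold_um` (no usable
#' photoreceptor peak), the detector falls back to the A-scan of minimum
#' smoothed retinal thickness (the deepest point of the pit). Ties are
#' broken toward the window centre; at an exactly symmetric tie the
#' temporal candidate wins.
#'
#' @param profile A [thickness_profiles()] result.
#' @param search_halfwidth_um Half-width of the search window around the
#'   scan centre (um); > 0.
#' @param flatness_threshold_um IS/OS elevation range below which the
#'   retinal-thickness fallback is used (um).
#' @return List with `index` (1-based A-scan), `lateral_um` (signed),
#'   `method` (`"isos_peak"` or `"min_rt"`), and `flags` (contains
#'   `"fc_on_window_edge"` when the optimum sits on the window boundary).
#' @export
locate_foveal_centre <- function(profile, search_halfwidth_um = 750,
                                 flatness_threshold_um = 2) {
  stopifnot(search_halfwidth_um > 0)
  in_win <- which(abs(profile$raster_um) <= search_halfwidth_um)
  if (length(in_win) == 0L)
    stop("search window contains no A-scans")
  elev <- profile$elevation_isos[in_win]
  if (max(elev) - min(elev) >= flatness_threshold_um) {
    crit <- elev
    method <- "isos_peak"
  } else {
    crit <- -moving_average(profile$rt, profile$smooth_window)[in_win]
    method <- "min_rt"
  }
  idx <- in_win[.argmax_tiebreak(crit, centre = profile$raster_um[in_win],
                                 temporal = profile$lateral_um[in_win])]
  flags <- if (method == "min_rt") "fc_fallback_min_rt" else character(0)
  if (idx == in_win[1] || idx == in_win[length(in_win)])
    flags <- c(flags, "fc_on_window_edge")
  list(index = idx, lateral_um = profile$lateral_um[idx],
       method = method, flags = flags)
}

# argmax with tie-break toward the smallest |centre| (distance criterion),
# then toward the temporal side (smaller signed lateral)
.argmax_tiebreak <- function(crit, centre, temporal) {
  best <- which(crit >= max(crit) - 1e-12)
  if (length(best) == 1L) return(best)
  d <- abs(centre[best])
  best <- best[d <= min(d) + 1e-9]
  if (length(best) == 1L) return(best)
  best[which.min(temporal[best])]
}

#' Locate the nasal and temporal foveal wall maxima
#'
#' On each side of the foveal centre, the foveal wall maximum (FWM) is the
#' A-scan where the smoothed GCL+ thickness attains its maximum within a
#' lateral window of `window_um` (distance from FC). Ties are broken
#' toward the FC; tied maxima (a plateau, e.g. a degenerate flat profile)
#' are flagged. A maximum attained at the outer window edge is flagged
#' too (the rim may lie outside the scan).
#'
#' @param profile A [thickness_profiles()] result.
#' @param fc Result of [locate_foveal_centre()] (or a list with `index`).
#' @param window_um Length-2 numeric: minimum and maximum distance from FC
#'   (um) searched on each side.
#' @return List with elements `nasal` and `temporal`, each a list with
#'   `index`, `lateral_um`, `distance_um` and `flags`.
#' @export
locate_rims <- function(profile, fc, window_um = c(300, 3000)) {
  stopifnot(length(window_um) == 2L, window_um[1] >= 0,
            window_um[2] > window_um[1])
  rel <- profile$lateral_um - profile$lateral_um[fc$index]
  g <- profile$gclp_sm
  one_side <- function(sgn, label) {
    dist <- sgn * rel
    in_win <- which(dist >= window_um[1] & dist <= window_um[2])
    if (length(in_win) == 0L)
      stop(label, " rim search window is empty")
    crit <- g[in_win]
    best <- which(crit >= max(crit) - 1e-12)
    flags <- character(0)
    if (length(best) > 1L) {
      flags <- c(flags, paste0(label, "_rim_plateau"))
      best <- best[which.min(dist[in_win][best])]
    }
    idx <- in_win[best]
    outer <- in_win[which.max(dist[in_win])]
    if (idx == outer) flags <- c(flags, paste0(label, "_rim_on_window_edge"))
    list(index = idx, lateral_um = profile$lateral_um[idx],
         distance_um = dist[idx], flags = flags)
  }
  list(nasal = one_side(+1, "nasal"), temporal = one_side(-1, "temporal"))
}

#' Compute the foveal parameter set for one eye
#'
#' Point thicknesses are read from the unsmoothed profiles: `GCLp_FC`,
#' `ONL_FC` and `RT_FC` at the foveal centre A-scan; `RT_FWM_nasal` and
#' `RT_FWM_temporal` at the respective wall-maximum A-scans. Foveal depth
#' is `FD = (RT_FWM_nasal + RT_FWM_temporal)/2 - RT_FC`. `GCLp_Q2Q` is the
#' mean GCL+ thickness at the two quarter points, each located at
#' one quarter of the FC-to-FWM index distance from the FC on its side
#' (rounded to the nearest A-scan). Landmark quality flags are propagated
#' into the `quality` field.
#'
#' @param profile A [thickness_profiles()] result.
#' @param fc Result of [locate_foveal_centre()].
#' @param rims Result of [locate_rims()].
#' @param eye_id,group_label Identifiers copied into the output.
#' @return One-row data frame of class `foveal_metrics` with the six
#'   parameters, landmark positions and a semicolon-joined `quality`
#'   string (empty when clean).
#' @export
compute_metrics <- function(profile, fc, rims, eye_id = profile$eye_id,
                            group_label = NA_character_) {
  i_fc <- fc$index
  i_n <- rims$nasal$index
  i_t <- rims$temporal$index
  q_idx <- function(i_rim) i_fc + .round_half_up(0.25 * (i_rim - i_fc))
  i_qn <- q_idx(i_n)
  i_qt <- q_idx(i_t)
  rt_fwm_n <- profile$rt[i_n]
  rt_fwm_t <- profile$rt[i_t]
  rt_fc <- profile$rt[i_fc]
  flags <- c(fc$flags, rims$nasal$flags, rims$temporal$flags)
  out <- data.frame(
    eye_id = eye_id,
    group_label = group_label,
    laterality = profile$laterality,
    fc_lateral_um = profile$lateral_um[i_fc],
    rim_lateral_nasal_um = profile$lateral_um[i_n],
    rim_lateral_temporal_um = profile$lateral_um[i_t],
    GCLp_FC = profile$gclp[i_fc],
    GCLp_Q2Q = (profile$gclp[i_qn] + profile$gclp[i_qt]) / 2,
    ONL_FC = profile$onl[i_fc],
    RT_FC = rt_fc,
    RT_FWM_nasal = rt_fwm_n,
    RT_FWM_temporal = rt_fwm_t,
    RT_FWM_mean = (rt_fwm_n + rt_fwm_t) / 2,
    FD = (rt_fwm_n + rt_fwm_t) / 2 - rt_fc,
    quality = paste(flags, collapse = ";"),
    stringsAsFactors = FALSE
  )
  class(out) <- c("foveal_metrics", class(out))
  out
}

#' Extract foveal metrics from a boundary set
#'
#' Convenience wrapper chaining [flatten_to_rpe()],
#' [thickness_profiles()], [locate_foveal_centre()], [locate_rims()] and
#' [compute_metrics()].
#'
#' @param bset A [boundary_set()].
#' @param smooth_window Odd moving-average window for landmark
#'   localization (A-scans).
#' @param search_halfwidth_um Foveal-centre search half-width (um).
#' @param rim_window_um Rim search window, distance from FC (um).
#' @param group_label Copied into the output row.
#' @param flatten Flatten to the posterior RPE first (thickness reads are
#'   shift-invariant, so this only matters for IS/OS elevation under
#'   extreme tilt; kept on by default to mirror the measurement protocol).
#' @return One-row `foveal_metrics` data frame.
#' @export
extract_foveal_metrics <- function(bset, smooth_window = 5L,
                                   search_halfwidth_um = 750,
                                   rim_window_um = c(300, 3000),
                                   group_label = NA_character_,
                                   flatten = TRUE) {
  if (flatten) bset <- flatten_to_rpe(bset)
  profile <- thickness_profiles(bset, smooth_window = smooth_window)
  fc <- locate_foveal_centre(profile,
                             search_halfwidth_um = search_halfwidth_um)
  rims <- locate_rims(profile, fc, window_um = rim_window_um)
  compute_metrics(profile, fc, rims, eye_id = bset$eye_id,
                  group_label = group_label)
}
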