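#' Flatten a scan to the posterior RPE boundary
#'
#' Shifts every A-scan axially by an integer pixel offset so that the
#' posterior RPE boundary becomes a horizontal line at its (rounded)
#' median input row, removing tilt and curvature before thickness reads.
#' Because the shift is an integer applied to all boundaries of an A-scan
#' alike, every pairwise boundary distance - and hence every thickness -
#' is preserved exactly, and the operation is idempotent. No image
#' resampling is performed.
#'
#' @param bset A [boundary_set()] with `RPE_posterior` defined at every
#'   A-scan.
#' @param bscan Optional [bscan()] to flatten with the same per-A-scan
#'   offsets; vacated pixels are filled with 0.
#' @return If `bscan` is `NULL`, the flattened `boundary_set`; otherwise a
#'   list with elements `bset` and `bscan`. The flattened `boundary_set`
#'   carries the integer offsets in attribute `offsets_px`.
#' @export
flatten_to_rpe <- function(bset, bscan = NULL) {
  rpe <- bset$boundaries$RPE_posterior
  target <- .round_half_up(stats::median(rpe))
  offsets <- target - .round_half_up(rpe)
  b <- lapply(bset$boundaries, function(v) v + offsets)
  lo <- min(unlist(b, use.names = FALSE))
  hi <- max(unlist(b, use.names = FALSE))
  if (lo < 0 || hi > bset$scan$n_axial - 1L)
    stop("flattening would shift a boundary off the raster (rows ",
         format(lo, digits = 5), " to ", format(hi, digits = 5), ")")
  out <- boundary_set(b, laterality = bset$laterality, scan = bset$scan,
                      eye_id = bset$eye_id)
  attr(out, "offsets_px") <- offsets
  attr(out, "truth") <- attr(bset, "truth")
  attr(out, "flags") <- attr(bset, "flags")
  if (is.null(bscan)) return(out)

  px <- bscan$pixels
  for (i in seq_len(ncol(px))) {
    s <- offsets[i]
    if (s == 0) next
    col <- px[, i]
    shifted <- rep(0, length(col))
    if (s > 0) shifted[(1 + s):length(col)] <- col[1:(length(col) - s)]
    else shifted[1:(length(col) + s)] <- col[(1 - s):length(col)]
    px[, i] <- shifted
  }
  flat_scan <- bscan
  flat_scan$pixels <- px
  list(bset = out, bscan = flat_scan)
}

# deterministic half-up rounding (avoids banker's-rounding edge cases in
# the idempotence argument)
.round_half_up <- function(x) floor(x + 0.5)
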