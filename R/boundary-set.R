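#' Construct and validate a boundary set
#'
#' A `boundary_set` holds, for each of the seven retinal boundaries (`ILM`,
#' `GCLp_inner`, `GCLp_outer`, `ONL_inner`, `ONL_outer`, `ISOS`,
#' `RPE_posterior`), one axial position (pixels, anterior = 0, possibly
#' fractional) per A-scan. Boundaries must be single-valued, ordered
#' anterior-to-posterior without crossings at every A-scan, and lie within
#' the raster.
#'
#' @param boundaries Named list of equal-length numeric vectors, one per
#'   boundary name.
#' @param laterality `"OD"` (right eye) or `"OS"` (left eye); determines
#'   which raster side is nasal.
#' @param scan A [scan_geometry()] (carried for unit conversion).
#' @param eye_id Identifier string.
#' @return Object of class `boundary_set`.
#' @export
boundary_set <- function(boundaries, laterality = c("OD", "OS"),
                         scan = scan_geometry(), eye_id = "eye") {
  laterality <- match.arg(laterality)
  missing <- setdiff(.boundary_names, names(boundaries))
  if (length(missing))
    stop("missing boundaries: ", paste(missing, collapse = ", "))
  boundaries <- boundaries[.boundary_names]
  n <- unique(vapply(boundaries, length, integer(1)))
  if (length(n) != 1L)
    stop("all boundaries must have the same number of A-scans")
  if (anyNA(unlist(boundaries, use.names = FALSE)))
    stop("boundary positions contain missing values")
  obj <- structure(list(boundaries = boundaries, n_ascans = n,
                        laterality = laterality, scan = scan,
                        eye_id = eye_id),
                   class = "boundary_set")
  validate_boundary_set(obj)
  obj
}

#' Check boundary ordering and raster containment
#'
#' @param bset A `boundary_set`.
#' @param tol Crossing tolerance in pixels (small negative separations from
#'   floating-point arithmetic are accepted).
#' @return The object, invisibly; stops naming the first offending A-scan
#'   and boundary pair otherwise.
#' @export
validate_boundary_set <- function(bset, tol = 1e-9) {
  b <- bset$boundaries
  for (k in seq_len(length(.boundary_names) - 1L)) {
    upper <- .boundary_names[k]
    lower <- .boundary_names[k + 1L]
    diffs <- b[[lower]] - b[[upper]]
    bad <- which(diffs < -tol)
    if (length(bad))
      stop("boundary crossing: ", upper, " below ", lower,
           " at A-scan index ", bad[1] - 1L,
           " (separation ", format(diffs[bad[1]], digits = 4), " px)")
  }
  lo <- min(unlist(b, use.names = FALSE))
  hi <- max(unlist(b, use.names = FALSE))
  if (lo < 0 || hi > bset$scan$n_axial - 1L)
    stop("boundary position outside raster height [0, ",
         bset$scan$n_axial - 1L, "]: range ",
         format(lo, digits = 5), " to ", format(hi, digits = 5))
  invisible(bset)
}

#' @export
print.boundary_set <- function(x, ...) {
  cat("<boundary_set> eye", x$eye_id, "laterality", x$laterality,
      "|", x$n_ascans, "A-scans,", length(x$boundaries), "boundaries\n")
  invisible(x)
}

#' Mirror a boundary set horizontally and toggle laterality
#'
#' Reverses the A-scan order of every boundary and swaps OD/OS. Thickness
#' profiles on the signed (nasal-positive) lateral axis are invariant under
#' this operation, which the morphometry tests exploit.
#'
#' @param bset A `boundary_set`.
#' @return The mirrored `boundary_set`.
#' @export
mirror_boundary_set <- function(bset) {
  b <- lapply(bset$boundaries, rev)
  boundary_set(b, laterality = if (bset$laterality == "OD") "OS" else "OD",
               scan = bset$scan, eye_id = bset$eye_id)
}
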