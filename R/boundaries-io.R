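#' Write a boundary set to CSV or JSON
#'
#' CSV layout is long format with columns `boundary_name`, `a_scan_index`
#' (0-based) and `axial_px`; laterality and scan geometry are not stored
#' in the CSV and must be re-supplied on reading. JSON stores the complete
#' object (boundaries, laterality, eye id and pixel scales).
#'
#' @param bset A [boundary_set()].
#' @param path Output file; format inferred from the extension unless
#'   `format` is given.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_boundaries <- function(bset, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "csv") {
    df <- do.call(rbind, lapply(names(bset$boundaries), function(nm) {
      data.frame(boundary_name = nm,
                 a_scan_index = seq_len(bset$n_ascans) - 1L,
                 axial_px = bset$boundaries[[nm]])
    }))
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(eye_id = bset$eye_id, laterality = bset$laterality,
           n_ascans = bset$n_ascans,
           axial_scale = bset$scan$axial_scale,
           lateral_scale = bset$scan$lateral_scale,
           n_axial = bset$scan$n_axial,
           boundaries = bset$boundaries),
      path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read and validate boundary annotations
#'
#' Ingests a boundary file written by [write_boundaries()] (or any file in
#' the same layout), validates the anterior-to-posterior ordering at every
#' A-scan, and repairs isolated gaps: runs of up to `max_gap` consecutive
#' missing or NA A-scans interior to the scan are filled by linear
#' interpolation between their neighbours (with a message); longer runs,
#' or gaps touching the scan edge, are rejected.
#'
#' @param path File to read.
#' @param format `"csv"` or `"json"` (default: by extension).
#' @param laterality Eye side for CSV input (JSON carries its own).
#' @param scan A [scan_geometry()] for CSV input (JSON carries its own).
#' @param eye_id Identifier for CSV input.
#' @param max_gap Longest interior gap (A-scans) repaired by
#'   interpolation.
#' @return A validated [boundary_set()].
#' @export
read_boundaries <- function(path, format = c("auto", "csv", "json"),
                            laterality = "OD", scan = scan_geometry(),
                            eye_id = NULL, max_gap = 3L) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (!file.exists(path)) stop("file not found: ", path)

  if (format == "json") {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    scan <- scan_geometry(n_ascans = j$n_ascans, n_axial = j$n_axial,
                          lateral_scale = j$lateral_scale,
                          axial_scale = j$axial_scale)
    b <- lapply(j$boundaries, as.numeric)
    b <- lapply(b, .fill_gaps, max_gap = max_gap)
    return(boundary_set(b, laterality = j$laterality, scan = scan,
                        eye_id = if (is.null(eye_id)) j$eye_id else eye_id))
  }

  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("boundary_name", "a_scan_index", "axial_px")
  if (!all(need %in% names(df)))
    stop("boundary CSV must have columns: ", paste(need, collapse = ", "))
  n <- max(df$a_scan_index) + 1L
  b <- lapply(.boundary_names, function(nm) {
    sub <- df[df$boundary_name == nm, ]
    if (nrow(sub) == 0L) stop("missing boundaries: ", nm)
    v <- rep(NA_real_, n)
    v[sub$a_scan_index + 1L] <- sub$axial_px
    .fill_gaps(v, max_gap = max_gap, name = nm)
  })
  names(b) <- .boundary_names
  boundary_set(b, laterality = laterality, scan = scan,
               eye_id = if (is.null(eye_id)) basename(path) else eye_id)
}

# interpolate interior NA runs of length <= max_gap; reject longer runs
.fill_gaps <- function(v, max_gap = 3L, name = "boundary") {
  na <- is.na(v)
  if (!any(na)) return(v)
  r <- rle(na)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    if (starts[k] == 1L || ends[k] == length(v))
      stop(name, ": gap touching scan edge cannot be interpolated ",
           "(A-scans ", starts[k] - 1L, "-", ends[k] - 1L, ")")
    if (r$lengths[k] > max_gap)
      stop(name, ": gap of ", r$lengths[k], " A-scans (indices ",
           starts[k] - 1L, "-", ends[k] - 1L, ") exceeds max_gap = ",
           max_gap)
  }
  idx <- seq_along(v)
  out <- stats::approx(idx[!na], v[!na], xout = idx, method = "linear")$y
  message(name, ": interpolated ", sum(na), " missing A-scan(s)")
  out
}
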