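#' Default per-layer reflectivities for rendering
#'
#' Arbitrary units in \[0, 1\]; bands are named by the boundary pair they
#' lie between, plus `vitreous` (above the ILM) and `choroid` (below the
#' posterior RPE). The pattern mimics the usual OCT contrast: bright nerve
#' fibre and plexiform layers, dark nuclear layers, a bright
#' photoreceptor/RPE complex.
#'
#' @return Named numeric vector of reflectivities.
#' @export
default_reflectivities <- function() {
  c(vitreous = 0.04, rnfl = 0.55, gclp = 0.45, inl_opl = 0.50,
    onl = 0.22, elm = 0.60, os_rpe = 0.85, choroid = 0.30)
}

#' Render a speckled B-scan raster from boundaries
#'
#' Produces a piecewise-constant layered intensity image from a boundary
#' set (one reflectivity per band) corrupted by multiplicative speckle:
#' each pixel is the band reflectivity times a unit-mean gamma variate
#' with coefficient of variation `noise_level` (shape `1/noise_level^2`).
#' `noise_level = 0` yields the noiseless layered image; a fixed seed
#' yields a bit-identical raster.
#'
#' @param bset A [boundary_set()].
#' @param reflectivity Named vector as [default_reflectivities()].
#' @param noise_level Speckle coefficient of variation; >= 0.
#' @param seed Integer seed for the speckle field.
#' @return Object of class `bscan`: list with `pixels` (numeric matrix,
#'   rows = axial, columns = A-scans), `axial_scale`, `lateral_scale`,
#'   `laterality`, `eye_id`.
#' @export
render_bscan <- function(bset, reflectivity = default_reflectivities(),
                         noise_level = 0.2, seed = 1L) {
  stopifnot(noise_level >= 0)
  validate_boundary_set(bset)
  scan <- bset$scan
  nr <- scan$n_axial
  nc <- bset$n_ascans
  b <- bset$boundaries
  band_names <- c("rnfl", "gclp", "inl_opl", "onl", "elm", "os_rpe")
  missing <- setdiff(c("vitreous", band_names, "choroid"),
                     names(reflectivity))
  if (length(missing))
    stop("reflectivity missing bands: ", paste(missing, collapse = ", "))

  rows <- matrix(seq_len(nr) - 1L, nrow = nr, ncol = nc)
  img <- matrix(reflectivity[["vitreous"]], nrow = nr, ncol = nc)
  tops <- list(b$ILM, b$GCLp_inner, b$GCLp_outer, b$ONL_inner,
               b$ONL_outer, b$ISOS)
  bottoms <- list(b$GCLp_inner, b$GCLp_outer, b$ONL_inner, b$ONL_outer,
                  b$ISOS, b$RPE_posterior)
  for (k in seq_along(band_names)) {
    top <- matrix(.round_half_up(tops[[k]]), nrow = nr, ncol = nc,
                  byrow = TRUE)
    bot <- matrix(.round_half_up(bottoms[[k]]), nrow = nr, ncol = nc,
                  byrow = TRUE)
    img[rows >= top & rows < bot] <- reflectivity[[band_names[k]]]
  }
  rpe <- matrix(.round_half_up(b$RPE_posterior), nrow = nr, ncol = nc,
                byrow = TRUE)
  img[rows >= rpe] <- reflectivity[["choroid"]]

  if (noise_level > 0) {
    set.seed(seed)
    shape <- 1 / noise_level^2
    speckle <- matrix(stats::rgamma(nr * nc, shape = shape,
                                    scale = 1 / shape), nrow = nr)
    img <- img * speckle
  }
  structure(list(pixels = img, axial_scale = scan$axial_scale,
                 lateral_scale = scan$lateral_scale,
                 laterality = bset$laterality, eye_id = bset$eye_id),
            class = "bscan")
}

#' @export
print.bscan <- function(x, ...) {
  cat("<bscan>", x$eye_id, dim(x$pixels)[1], "x", dim(x$pixels)[2],
      "px |", format(x$axial_scale, digits = 4), "um/px axial,",
      format(x$lateral_scale, digits = 4), "um/px lateral\n")
  invisible(x)
}

#' Write a B-scan as a grayscale image with a JSON sidecar
#'
#' Intensities are clipped at `max_intensity` and scaled to full range:
#' 16-bit for TIFF output, 8-bit for PNG. The sidecar (`<path>.json`)
#' records the pixel scales, laterality, eye id and the clip level so the
#' image is interpretable on its own.
#'
#' @param bscan A [render_bscan()] result.
#' @param path Output path ending in `.tif`/`.tiff` or `.png`.
#' @param max_intensity Intensity mapped to white.
#' @return `path`, invisibly.
#' @export
write_bscan_image <- function(bscan, path, max_intensity = 1.5) {
  img <- pmin(pmax(bscan$pixels / max_intensity, 0), 1)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::writeTIFF(img, path, bits.per.sample = 16L)
  } else if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(img, target = path)
  } else stop("unsupported image extension: ", path)
  jsonlite::write_json(
    list(eye_id = bscan$eye_id, laterality = bscan$laterality,
         axial_scale_um_per_px = bscan$axial_scale,
         lateral_scale_um_per_px = bscan$lateral_scale,
         max_intensity = max_intensity),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
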