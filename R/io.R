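#' Write a B-scan as 16-bit TIFF plus JSON metadata sidecar
#'
#' Intensities are scaled by the image maximum and quantized to 16-bit
#' grayscale; the scale factor is stored in the sidecar so the quantized
#' values round-trip exactly. The sidecar carries the scan geometry, session
#' metadata and (for synthetic scans) the ground-truth boundary curves as
#' sampled arrays.
#'
#' @param bscan An `oct_bscan`.
#' @param stem Output path without extension; writes `<stem>.tiff` and
#'   `<stem>.json`.
#' @return The TIFF path, invisibly.
#' @export
write_bscan <- function(bscan, stem) {
  stopifnot(inherits(bscan, "oct_bscan"))
  img <- bscan$intensity
  scale <- max(img, 1e-12)
  q <- round(pmin(pmax(img / scale, 0), 1) * 65535) / 65535
  tiff_path <- paste0(stem, ".tiff")
  tiff::writeTIFF(q, tiff_path, bits.per.sample = 16L)

  g <- bscan$geometry
  meta <- list(
    geometry = list(lateral_width_mm = g$lateral_width_mm,
                    n_ascans = g$n_ascans,
                    axial_depth_air_mm = g$axial_depth_air_mm,
                    n_samples = g$n_samples,
                    axial_psf_fwhm_um = g$axial_psf_fwhm_um),
    meridian = bscan$meridian,
    eye = bscan$eye,
    test_index = bscan$test_index,
    intensity_scale = scale
  )
  if (!is.null(bscan$truth)) {
    tr <- bscan$truth
    meta$truth <- list(
      x_mm = tr$x_mm,
      front_z_um = tr$front_z_um,
      back_z_um = tr$back_z_um,
      s_mm = tr$s_mm,
      d_mm = tr$d_mm,
      thickness_um = tr$thickness_um,
      valid = tr$valid,
      occluded = tr$occluded,
      apex_x_mm = tr$apex_x_mm,
      apex_z_mm = tr$apex_z_mm,
      central_thickness_um = tr$model$central_thickness_um,
      back_surface = list(x_mm = tr$back_surface$x_mm,
                          z_mm = tr$back_surface$z_mm)
    )
  }
  jsonlite::write_json(meta, paste0(stem, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(tiff_path)
}

#' Read a B-scan written by [write_bscan()]
#'
#' @param stem Path without extension, or the `.tiff` path itself.
#' @return An `oct_bscan`; `$truth`, when present in the sidecar, holds the
#'   sampled ground-truth arrays.
#' @export
read_bscan <- function(stem) {
  stem <- sub("\\.tiff?$", "", stem)
  tiff_path <- paste0(stem, ".tiff")
  json_path <- paste0(stem, ".json")
  if (!file.exists(tiff_path) || !file.exists(json_path))
    stop("missing B-scan file(s): ", stem)
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  img <- tiff::readTIFF(tiff_path) * meta$intensity_scale
  g <- meta$geometry
  geom <- scan_geometry(g$lateral_width_mm, g$n_ascans,
                        g$axial_depth_air_mm, g$n_samples,
                        g$axial_psf_fwhm_um)
  stopifnot(nrow(img) == geom$n_samples, ncol(img) == geom$n_ascans)
  truth <- meta$truth
  if (!is.null(truth)) {
    truth$back_surface <- data.frame(x_mm = truth$back_surface$x_mm,
                                     z_mm = truth$back_surface$z_mm)
  }
  structure(
    list(intensity = img, geometry = geom, meridian = meta$meridian,
         eye = meta$eye, test_index = as.integer(meta$test_index),
         truth = truth),
    class = "oct_bscan"
  )
}
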