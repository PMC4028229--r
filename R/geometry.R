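#' Scan geometry of a spectral-domain OCT B-scan
#'
#' Describes the sampling grid of one B-scan: lateral scan width, number of
#' A-scans, axial scan depth (in air) and number of axial samples, plus the
#' axial point-spread-function width of the system. Defaults match a
#' long-scan-depth anterior-segment SD-OCT with a 13.465 mm scan width,
#' 7.281 mm scan depth in air, 2,048 x 4,096 pixels and a 4.6 um axial
#' resolution in air (about 3.3 um in corneal tissue).
#'
#' @param lateral_width_mm Lateral scan width in mm.
#' @param n_ascans Number of A-scans (lateral pixels).
#' @param axial_depth_air_mm Axial scan depth in air, mm.
#' @param n_samples Number of axial samples per A-scan.
#' @param axial_psf_fwhm_um Full width at half maximum of the axial
#'   point-spread function, in um of optical depth in air.
#' @return An object of class `oct_geometry`.
#' @examples
#' g <- scan_geometry()
#' lateral_pitch_mm(g) * 1000   # lateral pixel pitch, um
#' @export
scan_geometry <- function(lateral_width_mm = 13.465,
                          n_ascans = 2048L,
                          axial_depth_air_mm = 7.281,
                          n_samples = 4096L,
                          axial_psf_fwhm_um = 4.6) {
  stopifnot(
    is.numeric(lateral_width_mm), length(lateral_width_mm) == 1L, lateral_width_mm > 0,
    is.numeric(axial_depth_air_mm), length(axial_depth_air_mm) == 1L, axial_depth_air_mm > 0,
    is.numeric(axial_psf_fwhm_um), length(axial_psf_fwhm_um) == 1L, axial_psf_fwhm_um > 0,
    is.numeric(n_ascans), length(n_ascans) == 1L, n_ascans >= 8,
    is.numeric(n_samples), length(n_samples) == 1L, n_samples >= 8
  )
  structure(
    list(
      lateral_width_mm = lateral_width_mm,
      n_ascans = as.integer(n_ascans),
      axial_depth_air_mm = axial_depth_air_mm,
      n_samples = as.integer(n_samples),
      axial_psf_fwhm_um = axial_psf_fwhm_um
    ),
    class = "oct_geometry"
  )
}

#' Reduced-resolution scan geometry
#'
#' Same physical field of view as [scan_geometry()] but with the pixel grid
#' downsampled by an integer factor in both directions. Intended for fast
#' simulation studies where full instrument resolution is unnecessary.
#'
#' @param factor Integer downsampling factor (default 4, giving 512 x 1024).
#' @return An `oct_geometry`.
#' @export
reduced_geometry <- function(factor = 4L) {
  stopifnot(factor >= 1, 2048 %% factor == 0, 4096 %% factor == 0)
  scan_geometry(n_ascans = 2048L %/% as.integer(factor),
                n_samples = 4096L %/% as.integer(factor))
}

#' @rdname scan_geometry
#' @param geometry An `oct_geometry`.
#' @export
lateral_pitch_mm <- function(geometry) {
  geometry$lateral_width_mm / geometry$n_ascans
}

#' @rdname scan_geometry
#' @export
axial_pitch_mm <- function(geometry) {
  geometry$axial_depth_air_mm / geometry$n_samples
}

#' Lateral A-scan centre positions, mm from the scan centre
#' @param geometry An `oct_geometry`.
#' @return Numeric vector of length `n_ascans`; positive values are nasal
#'   (right eye) or superior depending on the meridian.
#' @export
ascan_positions <- function(geometry) {
  p <- lateral_pitch_mm(geometry)
  (seq_len(geometry$n_ascans) - 0.5) * p - geometry$lateral_width_mm / 2
}

#' Axial sample centre depths, mm of optical depth from the image top
#' @param geometry An `oct_geometry`.
#' @export
sample_depths_mm <- function(geometry) {
  p <- axial_pitch_mm(geometry)
  (seq_len(geometry$n_samples) - 0.5) * p
}

#' @export
print.oct_geometry <- function(x, ...) {
  cat(sprintf(
    "OCT scan geometry: %d A-scans x %d samples, %.3f mm wide x %.3f mm deep (air)\n",
    x$n_ascans, x$n_samples, x$lateral_width_mm, x$axial_depth_air_mm))
  cat(sprintf("  pitch: %.2f um lateral, %.2f um axial (air); axial PSF FWHM %.1f um\n",
              1000 * lateral_pitch_mm(x), 1000 * axial_pitch_mm(x),
              x$axial_psf_fwhm_um))
  invisible(x)
}

# Run code with a temporarily-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# FWHM <-> sigma for a Gaussian
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))
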