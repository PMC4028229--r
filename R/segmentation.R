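#' Segmentation parameters
#'
#' @param smooth_sigma_um Axial Gaussian smoothing sigma applied before
#'   tracing, um of optical depth. `NULL` (default) uses the sigma of the
#'   scan's axial point-spread function.
#' @param jump_limit_um Maximum axial excursion of a boundary path between
#'   adjacent A-scans, um. Must exceed the steepest expected surface slope
#'   times the lateral pitch (60 um accommodates the corneal periphery at
#'   reduced resolution).
#' @param smoothness_penalty Cost added per pixel of axial jump between
#'   adjacent path nodes, in units of normalized intensity.
#' @param min_separation_um Minimum optical separation between the front and
#'   back boundary paths, um.
#' @param max_separation_um Maximum optical separation searched for the back
#'   boundary, um.
#' @param snr_threshold A-scans whose ridge signal-to-noise ratio
#'   (peak minus median, over 1.4826 x MAD of the smoothed column) is below
#'   this are marked invalid. The default of 6 sits above the expected
#'   maximum of a pure-noise column (about 4-5 on this scale), so occluded
#'   or signal-free A-scans are rejected.
#' @param boundary_margin_mm Columns within this lateral distance of an
#'   invalid A-scan are also invalidated: the continuity-constrained path is
#'   unreliable where it enters or leaves a signal-free region (e.g. at the
#'   eyelid occlusion edge).
#' @return A list of class `seg_params`.
#' @export
seg_params <- function(smooth_sigma_um = NULL,
                       jump_limit_um = 60,
                       smoothness_penalty = 0.02,
                       min_separation_um = 20,
                       max_separation_um = 250,
                       snr_threshold = 6,
                       boundary_margin_mm = 0.15) {
  stopifnot(is.null(smooth_sigma_um) || smooth_sigma_um >= 0,
            jump_limit_um > 0, smoothness_penalty >= 0,
            min_separation_um > 0, max_separation_um > min_separation_um,
            snr_threshold > 0, boundary_margin_mm >= 0)
  structure(list(smooth_sigma_um = smooth_sigma_um,
                 jump_limit_um = jump_limit_um,
                 smoothness_penalty = smoothness_penalty,
                 min_separation_um = min_separation_um,
                 max_separation_um = max_separation_um,
                 snr_threshold = snr_threshold,
                 boundary_margin_mm = boundary_margin_mm),
            class = "seg_params")
}

#' Randomly perturb segmentation parameters (synthetic second observer)
#'
#' Multiplies each tunable threshold by an independent log-normal factor
#' `exp(sd * N(0,1))`, emulating a second human operator who configures the
#' semi-automatic software slightly differently. `sd = 0` is the identity.
#'
#' @param params A [seg_params()].
#' @param sd SD of the log-perturbation (dimensionless).
#' @param seed Integer seed.
#' @return Perturbed `seg_params`.
#' @export
jitter_seg_params <- function(params, sd, seed = 1L) {
  stopifnot(inherits(params, "seg_params"), sd >= 0)
  if (sd == 0) return(params)
  with_seed(seed, {
    fac <- exp(sd * stats::rnorm(4))
    params$jump_limit_um <- params$jump_limit_um * fac[1]
    params$snr_threshold <- params$snr_threshold * fac[2]
    params$smoothness_penalty <- params$smoothness_penalty * fac[3]
    if (!is.null(params$smooth_sigma_um))
      params$smooth_sigma_um <- params$smooth_sigma_um * fac[4]
    params
  })
}

# Column-wise Gaussian smoothing with edge replication.
gaussian_smooth_cols <- function(img, sigma_px) {
  if (sigma_px < 0.3) return(img)
  L <- ceiling(3 * sigma_px)
  k <- stats::dnorm(seq(-L, L), sd = sigma_px)
  k <- k / sum(k)
  nr <- nrow(img)
  padded <- rbind(img[rep(1L, L), , drop = FALSE], img,
                  img[rep(nr, L), , drop = FALSE])
  sm <- stats::filter(padded, k, sides = 2)
  matrix(sm[(L + 1):(L + nr), ], nrow = nr)
}

#' Preprocess a B-scan for boundary tracing
#'
#' Applies axial Gaussian smoothing and per-A-scan intensity normalization
#' (each column is rescaled so its median maps to 0 and its maximum to 1;
#' constant columns become 0). Also computes a per-column ridge
#' signal-to-noise ratio from the smoothed, un-normalized image, used by
#' [trace_boundaries()] to flag low-SNR A-scans.
#'
#' @param bscan An `oct_bscan` (or a plain intensity matrix with rows = axial
#'   samples).
#' @param params A [seg_params()].
#' @return A list of class `oct_preprocessed` with `normalized` (matrix, same
#'   shape as the input), `smoothed`, `snr` (per column), and the geometry.
#' @export
preprocess_bscan <- function(bscan, params = seg_params()) {
  if (inherits(bscan, "oct_bscan")) {
    img <- bscan$intensity
    geom <- bscan$geometry
  } else {
    img <- as.matrix(bscan)
    geom <- NULL
  }
  if (length(img) == 0) stop("empty image")
  stopifnot(all(is.finite(img)))
  sigma_um <- params$smooth_sigma_um
  if (is.null(sigma_um)) {
    sigma_um <- if (!is.null(geom)) fwhm_to_sigma(geom$axial_psf_fwhm_um)
    else fwhm_to_sigma(4.6)
  }
  pitch_um <- if (!is.null(geom)) 1000 * axial_pitch_mm(geom) else 1
  sm <- gaussian_smooth_cols(img, sigma_um / pitch_um)

  med <- apply(sm, 2, stats::median)
  mx <- apply(sm, 2, max)
  madv <- apply(sm, 2, stats::mad)
  rng <- mx - med
  snr <- ifelse(madv > 0, rng / madv,
                ifelse(rng > 0, Inf, 0))
  norm <- sweep(sm, 2, med, "-")
  scl <- ifelse(rng > 0, rng, 1)
  norm <- pmax(sweep(norm, 2, scl, "/"), 0)
  structure(list(normalized = norm, smoothed = sm, snr = snr, geometry = geom),
            class = "oct_preprocessed")
}

# Dynamic-programming minimum-cost path through a cost matrix
# (rows = axial position, columns = A-scans), with per-step jump limit J
# (pixels) and a linear jump penalty. Ties broken toward the smallest axial
# index. Returns integer row per column.
dp_min_path <- function(cost, J, penalty) {
  nr <- nrow(cost); nc <- ncol(cost)
  ptr <- matrix(0L, nr, nc)
  D <- cost[, 1]
  big <- .Machine$double.xmax / 4
  for (j in 2:nc) {
    best <- rep(big, nr)
    barg <- integer(nr)
    for (o in -J:J) {
      # predecessor row = current row + o
      if (o < 0) {
        cand <- c(rep(big, -o), D[1:(nr + o)] + penalty * abs(o))
      } else if (o > 0) {
        cand <- c(D[(1 + o):nr] + penalty * abs(o), rep(big, o))
      } else {
        cand <- D
      }
      upd <- cand < best
      best[upd] <- cand[upd]
      barg[upd] <- o
    }
    D <- best + cost[, j]
    ptr[, j] <- barg
  }
  path <- integer(nc)
  path[nc] <- which.min(D)
  for (j in nc:2) path[j - 1] <- path[j] + ptr[path[j], j]
  path
}

# Parabolic sub-pixel refinement of a peak at integer row r in column v.
subpixel_peak <- function(v, r) {
  if (r <= 1 || r >= length(v)) return(0)
  den <- v[r - 1] - 2 * v[r] + v[r + 1]
  if (den >= 0) return(0)  # not a local maximum
  delta <- 0.5 * (v[r - 1] - v[r + 1]) / den
  max(-0.5, min(0.5, delta))
}

#' Trace the front and back epithelial boundaries in a B-scan
#'
#' Finds two laterally continuous boundary curves as minimum-cost paths
#' through the negative smoothed intensity, by dynamic programming with a
#' per-step axial jump limit (ties broken toward the smaller axial index).
#' The front (air-tear) path is traced first over the whole image; the back
#' (epithelium-Bowman) path is then traced in a band
#' `[min_separation, max_separation]` um below the front path. Each path node
#' is refined to sub-pixel accuracy by a parabolic fit through the three
#' samples around it. A-scans whose ridge SNR falls below
#' `params$snr_threshold` (occluded or low-signal columns) are marked
#' invalid in both traces.
#'
#' @param bscan An `oct_bscan`.
#' @param params A [seg_params()].
#' @param preprocessed Optional result of [preprocess_bscan()] (recomputed
#'   otherwise).
#' @return A list with elements `front` and `back`, each a `boundary_trace`
#'   data frame with columns `x_mm`, `z_um` (optical depth), `valid`, and an
#'   `interface` attribute.
#' @export
trace_boundaries <- function(bscan, params = seg_params(), preprocessed = NULL) {
  stopifnot(inherits(bscan, "oct_bscan"))
  if (is.null(preprocessed)) preprocessed <- preprocess_bscan(bscan, params)
  geom <- bscan$geometry
  pitch_um <- 1000 * axial_pitch_mm(geom)
  x <- ascan_positions(geom)
  norm <- preprocessed$normalized
  nr <- nrow(norm); nc <- ncol(norm)

  col_valid <- preprocessed$snr >= params$snr_threshold
  # a genuine surface lights up a contiguous majority of A-scans; isolated
  # passing columns in a signal-free image are noise maxima
  if (mean(col_valid) < 0.05)
    stop("NoSurfaceFound: no surface ridge exceeds the SNR threshold")
  # erode validity near invalid runs: the path is untrustworthy where it
  # enters or leaves signal-free regions
  margin <- as.integer(round(params$boundary_margin_mm / lateral_pitch_mm(geom)))
  if (margin > 0 && any(!col_valid)) {
    bad <- which(!col_valid)
    near <- unique(unlist(lapply(bad, function(b)
      max(1, b - margin):min(nc, b + margin))))
    col_valid[near] <- FALSE
  }

  J <- max(1L, as.integer(ceiling(params$jump_limit_um / pitch_um)))

  # front boundary: global path
  front_px <- dp_min_path(-norm, J, params$smoothness_penalty)

  # back boundary: path in a band below the front
  lo_px <- as.integer(ceiling(params$min_separation_um / pitch_um))
  hi_px <- as.integer(ceiling(params$max_separation_um / pitch_um))
  bw <- hi_px - lo_px + 1L
  band <- matrix(1, bw, nc)  # high cost by default
  for (j in seq_len(nc)) {
    rows <- front_px[j] + lo_px + seq_len(bw) - 1L
    ok <- rows >= 1 & rows <= nr
    band[ok, j] <- -norm[rows[ok], j]
  }
  back_rel <- dp_min_path(band, J, params$smoothness_penalty)
  back_px <- front_px + lo_px + back_rel - 1L
  back_px <- pmin(pmax(back_px, 1L), nr)

  front_z <- back_z <- numeric(nc)
  for (j in seq_len(nc)) {
    v <- norm[, j]
    front_z[j] <- (front_px[j] - 0.5 + subpixel_peak(v, front_px[j])) * pitch_um
    back_z[j] <- (back_px[j] - 0.5 + subpixel_peak(v, back_px[j])) * pitch_um
  }

  mk <- function(z, label, extra_valid = TRUE) {
    tr <- data.frame(x_mm = x, z_um = z, valid = col_valid & extra_valid)
    attr(tr, "interface") <- label
    class(tr) <- c("boundary_trace", "data.frame")
    tr
  }
  # back nodes that sit at the band edge (no true ridge) are suspect; also
  # enforce the ordering contract explicitly
  ordered_ok <- back_z > front_z
  list(front = mk(front_z, "front"),
       back = mk(back_z, "back", ordered_ok))
}

#' Export a boundary trace as CSV
#' @param trace A `boundary_trace`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  df <- as.data.frame(trace)
  df$interface <- attr(trace, "interface")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
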