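#' Refraction-correction parameters
#'
#' @param n_air Refractive index above the cornea (1.0).
#' @param n_tissue Group refractive index of the tear film + epithelium
#'   (default 1.389, applied uniformly).
#' @param normal_fit_halfwidth_mm Half-width of the sliding window used to
#'   fit the front surface locally when estimating normals, mm. Matches the
#'   profiling bin half-width by default.
#' @param normal_fit_degree Degree of the local polynomial fit (2 = local
#'   quadratic; derivatives from finite differences would amplify noise).
#' @return A list of class `refraction_params`.
#' @export
refraction_params <- function(n_air = 1.0,
                              n_tissue = 1.389,
                              normal_fit_halfwidth_mm = 0.25,
                              normal_fit_degree = 2L) {
  stopifnot(n_air >= 1, n_tissue >= 1, normal_fit_halfwidth_mm > 0,
            normal_fit_degree >= 1, normal_fit_degree <= 4)
  structure(list(n_air = n_air, n_tissue = n_tissue,
                 normal_fit_halfwidth_mm = normal_fit_halfwidth_mm,
                 normal_fit_degree = as.integer(normal_fit_degree)),
            class = "refraction_params")
}

#' Estimate inward unit surface normals along a front boundary trace
#'
#' At each A-scan a polynomial of degree `normal_fit_degree` is fitted to the
#' front-surface heights `z_f(x)` over the valid nodes within
#' `normal_fit_halfwidth_mm`; the normal is the unit vector perpendicular to
#' the fitted tangent, oriented into the tissue (positive z component, since
#' z increases downward). Near the trace edges the window shrinks one-sidedly;
#' an A-scan whose window holds fewer than `degree + 1` valid nodes gets an
#' invalid normal.
#'
#' @param front A front `boundary_trace` (from [trace_boundaries()]).
#' @param params A [refraction_params()].
#' @return A data frame with columns `x_mm`, `nx`, `nz`, `valid`.
#' @export
estimate_normals <- function(front, params = refraction_params()) {
  stopifnot(inherits(front, "boundary_trace"))
  x <- front$x_mm
  z <- front$z_um / 1000  # mm, same units as x
  ok <- front$valid & is.finite(z)
  n <- length(x)
  nx <- nz <- rep(NA_real_, n)
  valid <- rep(FALSE, n)
  deg <- params$normal_fit_degree
  hw <- params$normal_fit_halfwidth_mm
  for (i in seq_len(n)) {
    if (!ok[i]) next
    w <- which(ok & abs(x - x[i]) <= hw)
    if (length(w) < deg + 1) next
    xv <- x[w] - x[i]
    fit <- stats::lm.fit(outer(xv, 0:deg, "^"), z[w])
    m <- fit$coefficients[2]  # dz/dx at x[i]
    if (!is.finite(m)) next
    len <- sqrt(1 + m^2)
    nx[i] <- -m / len
    nz[i] <- 1 / len
    valid[i] <- TRUE
  }
  data.frame(x_mm = x, nx = nx, nz = nz, valid = valid)
}

#' Snell refraction of a unit direction at an interface
#'
#' Returns the refracted unit direction, coplanar with the incident direction
#' and the normal, satisfying `n1 sin(theta1) = n2 sin(theta2)`.
#'
#' @param incident Unit incident direction, numeric length 2 (x, z),
#'   travelling toward the interface.
#' @param normal Unit interface normal oriented into the second medium (the
#'   same general direction as `incident`).
#' @param n1,n2 Refractive indices of the first and second medium.
#' @return Refracted unit direction, numeric length 2.
#' @export
snell_refract <- function(incident, normal, n1, n2) {
  stopifnot(length(incident) == 2, length(normal) == 2, n1 > 0, n2 > 0)
  if (abs(sum(incident^2) - 1) > 1e-8) stop("incident direction must be a unit vector")
  if (abs(sum(normal^2) - 1) > 1e-8) stop("normal must be a unit vector")
  eta <- n1 / n2
  ci <- sum(incident * normal)
  if (ci < 0) { normal <- -normal; ci <- -ci }
  st2 <- eta^2 * (1 - ci^2)
  if (st2 > 1) stop("total internal reflection")
  ct <- sqrt(1 - st2)
  r <- eta * (incident - ci * normal) + ct * normal
  r / sqrt(sum(r^2))
}

#' Correct refraction distortion of the back boundary (Snell dewarping)
#'
#' The front boundary sits above the tissue, where optical depth equals
#' physical depth, so it is passed through unchanged (z in mm = optical um /
#' 1000). For each jointly valid A-scan, the in-tissue physical path length is
#' `s = (z_back - z_front) / n_tissue`; the corrected back point is placed at
#' distance `s` from the entry point along the Snell-refracted direction of
#' the (vertical, telecentric) probe ray. With `n_tissue = 1` the correction
#' is the identity on the geometric positions.
#'
#' @param front,back `boundary_trace`s from [trace_boundaries()].
#' @param params A [refraction_params()].
#' @param normals Optional precomputed result of [estimate_normals()].
#' @return A list with `front` and `back` physical surfaces: data frames with
#'   columns `x_mm`, `z_mm`, `valid` and a `provenance` attribute
#'   (`"front"` / `"back_corrected"`).
#' @export
dewarp_back_surface <- function(front, back, params = refraction_params(),
                                normals = NULL) {
  stopifnot(inherits(front, "boundary_trace"), inherits(back, "boundary_trace"),
            nrow(front) == nrow(back))
  if (is.null(normals)) normals <- estimate_normals(front, params)
  ok <- front$valid & back$valid & normals$valid &
    (back$z_um > front$z_um)
  ex <- front$x_mm
  ez <- front$z_um / 1000
  s <- (back$z_um - front$z_um) / 1000 / params$n_tissue
  bx <- bz <- rep(NA_real_, nrow(front))
  for (i in which(ok)) {
    r <- snell_refract(c(0, 1), c(normals$nx[i], normals$nz[i]),
                       params$n_air, params$n_tissue)
    bx[i] <- ex[i] + s[i] * r[1]
    bz[i] <- ez[i] + s[i] * r[2]
  }
  mk <- function(x, z, valid, prov) {
    df <- data.frame(x_mm = x, z_mm = z, valid = valid)
    attr(df, "provenance") <- prov
    class(df) <- c("physical_surface", "data.frame")
    df
  }
  list(front = mk(ex, ifelse(front$valid, ez, NA_real_), front$valid, "front"),
       back = mk(bx, bz, ok, "back_corrected"))
}

#' Export a physical surface as CSV
#' @param surface A `physical_surface`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_surface_csv <- function(surface, path) {
  df <- as.data.frame(surface)
  df$surface <- attr(surface, "provenance")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
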