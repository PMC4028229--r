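#' Standard lateral profile grid for a meridian
#'
#' 0.5-mm steps over the horizontal 10-mm zone (-5.0 ... +5.0 mm) or the
#' vertical 9-mm zone (-4.5 ... +4.5 mm), relative to the corneal apex.
#'
#' @param meridian `"horizontal"` or `"vertical"`.
#' @return Numeric vector of grid positions, mm.
#' @export
profile_grid <- function(meridian = c("horizontal", "vertical")) {
  meridian <- match.arg(meridian)
  half <- if (meridian == "horizontal") 5.0 else 4.5
  seq(-half, half, by = 0.5)
}

#' Locate the corneal apex on a front surface
#'
#' Fits a quadratic to the shallowest region of the front surface (valid
#' points within 0.2 mm of the minimum depth, widened if too few) and returns
#' the lateral position of the fitted minimum. A surface too flat for a
#' well-defined minimum returns 0 with attribute `flat = TRUE`.
#'
#' @param front A `physical_surface` (or any data frame with `x_mm`, `z_mm`,
#'   `valid`).
#' @return Apex lateral position (mm), with attribute `flat`.
#' @export
find_apex <- function(front) {
  ok <- front$valid & is.finite(front$z_mm)
  if (sum(ok) < 3) stop("need at least 3 valid front-surface points")
  x <- front$x_mm[ok]; z <- front$z_mm[ok]
  zmin <- min(z)
  for (band in c(0.2, 0.5, 1.0, Inf)) {
    sel <- z <= zmin + band
    if (sum(sel) >= 5 || (is.infinite(band) && sum(sel) >= 3)) break
  }
  xs <- x[sel]; zs <- z[sel]
  fit <- stats::lm.fit(cbind(1, xs, xs^2), zs)
  a <- fit$coefficients[3]; b <- fit$coefficients[2]
  # curvature below ~ (1 km)^-1 radius: treat as flat
  if (!is.finite(a) || a < 5e-4) {
    return(structure(0, flat = TRUE))
  }
  apex <- -b / (2 * a)
  apex <- min(max(apex, min(x)), max(x))
  structure(as.numeric(apex), flat = FALSE)
}

# Minimum distances from points (px, pz) to the polyline (vx, vz).
# Points whose nearest approach clamps to a polyline endpoint (perpendicular
# foot outside the curve's support) are returned as NA.
point_polyline_distance <- function(px, pz, vx, vz) {
  ns <- length(vx) - 1L
  ax <- vx[-length(vx)]; az <- vz[-length(vz)]
  dxs <- diff(vx); dzs <- diff(vz)
  len2 <- dxs^2 + dzs^2
  np <- length(px)
  best <- rep(Inf, np)
  interior <- rep(FALSE, np)
  for (s in seq_len(ns)) {
    tpar <- ((px - ax[s]) * dxs[s] + (pz - az[s]) * dzs[s]) / len2[s]
    tcl <- pmin(pmax(tpar, 0), 1)
    dx <- px - (ax[s] + tcl * dxs[s])
    dz <- pz - (az[s] + tcl * dzs[s])
    d <- sqrt(dx^2 + dz^2)
    upd <- d < best
    best[upd] <- d[upd]
    interior[upd] <- tpar[upd] > 0 & tpar[upd] < 1
    # first/last segment ends are genuine curve endpoints; clamping there
    # means the foot of the perpendicular lies outside the curve
    if (s > 1) interior[upd & tpar == 0] <- TRUE
    if (s < ns) interior[upd & tpar >= 1] <- TRUE
  }
  ifelse(interior, best, NA_real_)
}

#' Perpendicular epithelial thickness samples
#'
#' At each valid front-surface point, the thickness is the minimum distance
#' from that point to the piecewise-linear corrected back surface, in um.
#' Front points whose perpendicular foot falls beyond the back curve's
#' lateral support are dropped.
#'
#' @param front,back_corrected `physical_surface`s from
#'   [dewarp_back_surface()].
#' @return Data frame with columns `x_mm` (front-point lateral position) and
#'   `t_um`.
#' @export
perpendicular_thickness <- function(front, back_corrected) {
  okf <- front$valid & is.finite(front$z_mm)
  okb <- back_corrected$valid & is.finite(back_corrected$z_mm)
  if (sum(okb) < 2) stop("corrected back surface needs at least 2 valid points")
  ord <- order(back_corrected$x_mm[okb])
  vx <- back_corrected$x_mm[okb][ord]
  vz <- back_corrected$z_mm[okb][ord]
  px <- front$x_mm[okf]; pz <- front$z_mm[okf]
  d <- point_polyline_distance(px, pz, vx, vz)
  keep <- is.finite(d)
  data.frame(x_mm = px[keep], t_um = 1000 * d[keep])
}

#' Bin thickness samples onto the 0.5-mm profile grid
#'
#' Lateral positions are re-expressed relative to the apex; each grid value is
#' the mean of the samples within `halfwidth_mm` of the grid point (a boxcar
#' "average matrix"). Bins with no samples are marked missing.
#'
#' @param samples Data frame from [perpendicular_thickness()].
#' @param meridian,eye Metadata (select the grid and the mirroring rule).
#' @param test_index Metadata: 1 or 2.
#' @param apex_x_mm Apex lateral position from [find_apex()] (0 = anchor at
#'   the scan centre instead).
#' @param halfwidth_mm Bin half-width, mm.
#' @return A `thickness_profile` data frame with columns `position_mm`,
#'   `thickness_um`, `n`, `missing`, and attributes `eye`, `meridian`,
#'   `test_index`.
#' @export
bin_profile <- function(samples, meridian, eye = "OD", test_index = 1L,
                        apex_x_mm = 0, halfwidth_mm = 0.25) {
  meridian <- match.arg(meridian, c("horizontal", "vertical"))
  grid <- profile_grid(meridian)
  xr <- samples$x_mm - as.numeric(apex_x_mm)
  tu <- samples$t_um
  th <- nn <- numeric(length(grid))
  for (k in seq_along(grid)) {
    sel <- abs(xr - grid[k]) <= halfwidth_mm
    nn[k] <- sum(sel)
    th[k] <- if (nn[k] > 0) mean(tu[sel]) else NA_real_
  }
  prof <- data.frame(position_mm = grid, thickness_um = th,
                     n = as.integer(nn), missing = nn == 0)
  attr(prof, "eye") <- eye
  attr(prof, "meridian") <- meridian
  attr(prof, "test_index") <- as.integer(test_index)
  class(prof) <- c("thickness_profile", "data.frame")
  prof
}

#' Mirror a left-eye horizontal profile onto right-eye orientation
#'
#' Left-eye (OS) horizontal profiles have their lateral sign flipped so that
#' nasal/temporal positions line up with right-eye (OD) profiles. OD profiles
#' and vertical profiles pass through unchanged.
#'
#' @param profile A `thickness_profile`.
#' @return A `thickness_profile` on the same grid.
#' @export
mirror_profile <- function(profile) {
  stopifnot(inherits(profile, "thickness_profile"))
  if (attr(profile, "meridian") != "horizontal" || attr(profile, "eye") != "OS")
    return(profile)
  out <- profile
  idx <- order(-profile$position_mm)
  out$thickness_um <- profile$thickness_um[idx]
  out$n <- profile$n[idx]
  out$missing <- profile$missing[idx]
  attr(out, "mirrored") <- !isTRUE(attr(profile, "mirrored"))
  out
}

#' Zonal mean thicknesses of a profile
#'
#' Zones are named by their diameters on the 10-mm analysis zone: central
#' 0-3.0 mm, paracentral 3.0-6.0 mm, peripheral 6.0-10.0 mm, i.e. radii
#' 0-1.5, 1.5-3.0 and 3.0-5.0 mm of |position|. The inner zones are half-open
#' `[lo, hi)`; the peripheral zone is closed at the 5-mm rim so the outermost
#' grid points belong to it. Each zone mean averages the zone's non-missing
#' grid points; an entirely missing zone yields `NA`.
#'
#' @param profile A `thickness_profile`.
#' @return Named numeric vector `c(central=, paracentral=, peripheral=)`, um.
#' @export
zonal_means <- function(profile) {
  stopifnot(inherits(profile, "thickness_profile"))
  r <- abs(profile$position_mm)
  ok <- !profile$missing & is.finite(profile$thickness_um)
  zone_mean <- function(sel) {
    if (!any(sel & ok)) NA_real_ else mean(profile$thickness_um[sel & ok])
  }
  c(central = zone_mean(r < 1.5),
    paracentral = zone_mean(r >= 1.5 & r < 3.0),
    peripheral = zone_mean(r >= 3.0 & r <= 5.0))
}

#' Pointwise average of thickness profiles on a common grid
#'
#' @param profiles List of `thickness_profile`s on identical grids.
#' @return A `thickness_profile` whose value at each grid point is the mean
#'   over the non-missing inputs there, with `n` = number of contributing
#'   profiles; a point is missing only if missing in every input.
#' @export
average_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  g <- profiles[[1]]$position_mm
  for (p in profiles) {
    stopifnot(inherits(p, "thickness_profile"),
              isTRUE(all.equal(p$position_mm, g)))
  }
  vals <- sapply(profiles, function(p) ifelse(p$missing, NA_real_, p$thickness_um))
  vals <- matrix(vals, nrow = length(g))
  n <- rowSums(!is.na(vals))
  th <- rowMeans(vals, na.rm = TRUE)
  th[n == 0] <- NA_real_
  out <- data.frame(position_mm = g, thickness_um = th,
                    n = as.integer(n), missing = n == 0)
  attr(out, "eye") <- "mean"
  attr(out, "meridian") <- attr(profiles[[1]], "meridian")
  attr(out, "test_index") <- NA_integer_
  class(out) <- c("thickness_profile", "data.frame")
  out
}

#' Export one or more thickness profiles as CSV
#' @param profiles A `thickness_profile` or list of them.
#' @param path Output file path.
#' @param extra Optional named list of constant columns to add (e.g. subject).
#' @return `path`, invisibly.
#' @export
write_profiles_csv <- function(profiles, path, extra = NULL) {
  if (inherits(profiles, "thickness_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    df <- as.data.frame(p)
    df$eye <- attr(p, "eye")
    df$meridian <- attr(p, "meridian")
    df$test <- attr(p, "test_index")
    df
  })
  df <- do.call(rbind, rows)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
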