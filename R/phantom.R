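#' Parametric model of a corneal anterior surface and epithelial layer
#'
#' The anterior surface is a sphere (a circle in the meridian plane) of radius
#' `anterior_radius_mm` whose apex sits at (`apex_x_mm`, `apex_z_mm`) in scan
#' coordinates (x lateral from the scan centre, z optical depth from the image
#' top, both mm), optionally tilted about the apex. The epithelium is a thin
#' layer bounded below by a back surface obtained by offsetting the anterior
#' surface inward, along the local surface normal, by the local thickness
#'
#' \deqn{T(d) = T_0 + c_{dir} d^p}
#'
#' where `d` is the signed lateral distance from the apex (mm, measured in the
#' eye's frame), `p` is the thickness exponent and `c_dir` a per-direction
#' coefficient (temporal, nasal, superior, inferior). Because the offset is
#' along the normal, `T(d)` is the exact perpendicular layer thickness.
#'
#' Default coefficients are solved from the layer thickness at `d = 5` mm in
#' each direction (63 um temporal/nasal, 58 um superior, 72 um inferior, with
#' 52 um centrally), so the thickness increases from the centre toward the
#' limbus, faster inferiorly than superiorly and symmetrically
#' nasally/temporally. A cubic (`p = 3`) keeps the paracentral layer thin
#' while still reaching the peripheral values at the 5-mm chord.
#'
#' `anterior_radius_mm = Inf` gives a flat layer of uniform local geometry,
#' useful for closed-form checks.
#'
#' @param anterior_radius_mm Anterior radius of curvature, mm (may be `Inf`).
#' @param apex_x_mm,apex_z_mm Apex position in scan coordinates, mm.
#' @param tilt_deg Rotation of the cornea about its apex, degrees.
#' @param central_thickness_um Epithelial thickness at the apex, um.
#' @param peripheral_thickness_um Named vector: thickness at
#'   `peripheral_distance_mm` for directions temporal, nasal, superior,
#'   inferior, um.
#' @param thickness_exponent Exponent `p` of the radial thickening term.
#' @param peripheral_distance_mm Chord distance at which
#'   `peripheral_thickness_um` applies, mm.
#' @param group_index Group refractive index of the tear film + epithelium
#'   (a single index, 1.389 by default; the tear film is absorbed into the
#'   layer rather than modelled separately).
#' @return An object of class `cornea_model`.
#' @export
cornea_model <- function(anterior_radius_mm = 7.8,
                         apex_x_mm = 0,
                         apex_z_mm = 1.2,
                         tilt_deg = 0,
                         central_thickness_um = 52,
                         peripheral_thickness_um = c(temporal = 63, nasal = 63,
                                                     superior = 58, inferior = 72),
                         thickness_exponent = 3,
                         peripheral_distance_mm = 5,
                         group_index = 1.389) {
  dirs <- c("temporal", "nasal", "superior", "inferior")
  stopifnot(
    anterior_radius_mm > 0,
    is.finite(apex_x_mm), is.finite(apex_z_mm), apex_z_mm > 0,
    is.finite(tilt_deg),
    central_thickness_um > 0,
    all(dirs %in% names(peripheral_thickness_um)),
    thickness_exponent > 0, peripheral_distance_mm > 0,
    group_index >= 1
  )
  coeffs <- (peripheral_thickness_um[dirs] - central_thickness_um) /
    peripheral_distance_mm^thickness_exponent
  # T monotone in |d|, so positivity holds iff both endpoints are positive
  if (any(central_thickness_um + coeffs * peripheral_distance_mm^thickness_exponent <= 0))
    stop("thickness field must stay strictly positive out to the periphery")
  structure(
    list(
      anterior_radius_mm = anterior_radius_mm,
      apex_x_mm = apex_x_mm,
      apex_z_mm = apex_z_mm,
      tilt_deg = tilt_deg,
      central_thickness_um = central_thickness_um,
      peripheral_thickness_um = peripheral_thickness_um[dirs],
      thickness_exponent = thickness_exponent,
      peripheral_distance_mm = peripheral_distance_mm,
      direction_coeffs = coeffs,
      group_index = group_index
    ),
    class = "cornea_model"
  )
}

#' Anatomical direction of a signed lateral offset from the apex
#'
#' Scan-coordinate convention: positive x is nasal for a right eye (OD) and
#' temporal for a left eye (OS) on the horizontal meridian, and superior on
#' the vertical meridian of either eye.
#'
#' @param d_mm Signed lateral distance(s) from the apex, mm.
#' @param meridian `"horizontal"` or `"vertical"`.
#' @param eye `"OD"` or `"OS"`.
#' @return Character vector of directions.
#' @export
thickness_direction <- function(d_mm, meridian, eye = "OD") {
  meridian <- match.arg(meridian, c("horizontal", "vertical"))
  eye <- match.arg(eye, c("OD", "OS"))
  if (meridian == "vertical") {
    ifelse(d_mm >= 0, "superior", "inferior")
  } else if (eye == "OD") {
    ifelse(d_mm >= 0, "nasal", "temporal")
  } else {
    ifelse(d_mm >= 0, "temporal", "nasal")
  }
}

#' Epithelial thickness field of a cornea model
#'
#' @param model A [cornea_model()].
#' @return A function `T(d_mm, meridian, eye = "OD")` returning the
#'   perpendicular epithelial thickness in um at signed lateral distance
#'   `d_mm` from the apex.
#' @examples
#' f <- build_thickness_field(cornea_model())
#' f(0, "horizontal")                    # 52 at the apex
#' f(2.5, "vertical") < f(-2.5, "vertical")  # superior thinner than inferior
#' @export
build_thickness_field <- function(model) {
  stopifnot(inherits(model, "cornea_model"))
  t0 <- model$central_thickness_um
  cf <- model$direction_coeffs
  p <- model$thickness_exponent
  function(d_mm, meridian, eye = "OD") {
    dir <- thickness_direction(d_mm, meridian, eye)
    as.numeric(t0 + cf[dir] * abs(d_mm)^p)
  }
}

#' Speckle and background noise model for rendered B-scans
#'
#' Echo amplitude is attenuated with the echo's optical depth z as
#' `exp(-z / depth_rolloff_mm)`, emulating the sensitivity roll-off of
#' spectral-domain detection, while the background noise floor stays constant,
#' so the signal-to-noise ratio falls with depth (and hence toward the corneal
#' periphery, where the surface sits deeper in the image).
#'
#' @param background_sd SD of the additive background noise floor
#'   (half-normal), in the same arbitrary intensity units as
#'   `surface_amplitude`.
#' @param surface_amplitude Peak echo amplitude of the air-tear interface at
#'   zero depth.
#' @param back_reflectivity Relative amplitude of the epithelium-Bowman echo.
#' @param speckle_factor Multiplicative speckle noise scale on the signal.
#' @param depth_rolloff_mm e-folding optical depth of the sensitivity
#'   roll-off, mm.
#' @param seed Integer seed for the noise draw (`NULL` = use the current RNG
#'   stream).
#' @return An object of class `oct_noise_model`.
#' @export
noise_model <- function(background_sd = 0.04,
                        surface_amplitude = 1,
                        back_reflectivity = 0.6,
                        speckle_factor = 0.35,
                        depth_rolloff_mm = 1.8,
                        seed = 1L) {
  stopifnot(background_sd >= 0, surface_amplitude >= 0,
            back_reflectivity > 0, speckle_factor >= 0, depth_rolloff_mm > 0)
  structure(
    list(background_sd = background_sd,
         surface_amplitude = surface_amplitude,
         back_reflectivity = back_reflectivity,
         speckle_factor = speckle_factor,
         depth_rolloff_mm = depth_rolloff_mm,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "oct_noise_model"
  )
}

#' Acquisition session description for one B-scan
#'
#' @param meridian `"horizontal"` or `"vertical"`.
#' @param eye `"OD"` (right) or `"OS"` (left).
#' @param eyelid_occlusion_from_mm On the vertical meridian, A-scans superior
#'   to this lateral position contain background only (the upper eyelid covers
#'   part of the superior cornea); default +4.5 mm. Ignored (no occlusion) on
#'   the horizontal meridian.
#' @param retest_decentration_sd_mm,retest_tilt_sd_deg SDs of the rigid
#'   alignment jitter added between test 1 and test 2 of the same eye.
#' @return An object of class `oct_session`.
#' @export
session_spec <- function(meridian = c("horizontal", "vertical"),
                         eye = c("OD", "OS"),
                         eyelid_occlusion_from_mm = NULL,
                         retest_decentration_sd_mm = 0.1,
                         retest_tilt_sd_deg = 0.3) {
  meridian <- match.arg(meridian)
  eye <- match.arg(eye)
  if (is.null(eyelid_occlusion_from_mm))
    eyelid_occlusion_from_mm <- if (meridian == "vertical") 4.5 else Inf
  stopifnot(retest_decentration_sd_mm >= 0, retest_tilt_sd_deg >= 0)
  structure(
    list(meridian = meridian, eye = eye,
         eyelid_occlusion_from_mm = eyelid_occlusion_from_mm,
         retest_decentration_sd_mm = retest_decentration_sd_mm,
         retest_tilt_sd_deg = retest_tilt_sd_deg),
    class = "oct_session"
  )
}

#' Full phantom specification: geometry + cornea + noise
#'
#' @param geometry An [scan_geometry()].
#' @param cornea A [cornea_model()].
#' @param noise A [noise_model()].
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(geometry = scan_geometry(),
                         cornea = cornea_model(),
                         noise = noise_model()) {
  stopifnot(inherits(geometry, "oct_geometry"),
            inherits(cornea, "cornea_model"),
            inherits(noise, "oct_noise_model"))
  structure(list(geometry = geometry, cornea = cornea, noise = noise),
            class = "phantom_spec")
}

# Parametric front/back surface of a cornea model, in scan coordinates.
# Returns closures over a scalar/vector surface parameter t:
#   front(t) -> list(x, z); normal_in(t) -> list(x, z) unit inward normal;
#   d_of(t) -> signed eye-frame lateral distance from the apex;
# plus t_of_x() mapping a scan lateral position to the front-surface parameter.
surface_param <- function(model) {
  th <- model$tilt_deg * pi / 180
  R <- model$anterior_radius_mm
  if (is.finite(R)) {
    cx <- model$apex_x_mm + R * sin(th)
    cz <- model$apex_z_mm + R * cos(th)
    list(
      flat = FALSE,
      front = function(t) list(x = cx - R * sin(t), z = cz - R * cos(t)),
      normal_in = function(t) list(x = sin(t), z = cos(t)),
      d_of = function(t) -R * sin(t - th),
      t_of_x = function(x) {
        s <- (cx - x) / R
        ifelse(abs(s) <= 1, asin(pmin(pmax(s, -1), 1)), NA_real_)
      },
      t_range = function(dmax) {
        a <- asin(min(0.995, dmax / R))
        c(th - a, th + a)
      }
    )
  } else {
    ax <- model$apex_x_mm; az <- model$apex_z_mm
    list(
      flat = TRUE,
      front = function(t) list(x = ax + t * cos(th), z = az - t * sin(th)),
      normal_in = function(t) list(x = rep(sin(th), length(t)),
                                   z = rep(cos(th), length(t))),
      d_of = function(t) t,
      t_of_x = function(x) (x - model$apex_x_mm) / cos(th),
      t_range = function(dmax) c(-dmax, dmax)
    )
  }
}

# Unit refracted direction(s) for vertical incident rays (0, 1) hitting a
# surface with inward unit normal (nx, nz), going from index n1 into n2.
refract_vertical <- function(nx, nz, n1, n2) {
  eta <- n1 / n2
  ci <- nz                      # cos(theta_i) = (0,1) . n_in
  st2 <- eta^2 * (1 - ci^2)     # sin^2(theta_t)
  ct <- sqrt(pmax(0, 1 - st2))
  list(x = eta * (0 - ci * nx) + ct * nx,
       z = eta * (1 - ci * nz) + ct * nz)
}

#' Render one synthetic OCT B-scan of a layered cornea
#'
#' Physically forward-models the image an SD-OCT with telecentric (parallel,
#' vertical) A-scans would record. For the A-scan at lateral position x the
#' air-tear interface produces an echo at optical depth `z_f(x)` (air above
#' the cornea, so optical depth equals physical depth), and the
#' epithelium-Bowman interface produces an echo at
#' `z_f(x) + n * s(x)`, where `s(x)` is the physical path length along the
#' Snell-refracted ray from the entry point to the true back surface (found by
#' numerical ray-surface intersection) and `n` the group index. Each echo is
#' spread axially by a Gaussian point-spread function, attenuated by the
#' depth roll-off, and speckle/background noise is added per the noise model.
#' A-scans beyond the eyelid occlusion limit contain background only.
#'
#' The rendered scan carries its full ground truth (`$truth`): per-A-scan
#' boundary depths, refracted ray directions, physical path lengths, true
#' thickness, and a dense sample of the true back surface.
#'
#' @param spec A [phantom_spec()].
#' @param session A [session_spec()].
#' @param test_index 1 or 2 (metadata only; retest perturbations are applied
#'   by [simulate_cohort()]).
#' @return An object of class `oct_bscan` with elements `intensity`
#'   (matrix, rows = axial samples, columns = A-scans), `geometry`,
#'   `meridian`, `eye`, `test_index`, `truth`.
#' @export
render_bscan <- function(spec, session, test_index = 1L) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(session, "oct_session"))
  geom <- spec$geometry
  model <- spec$cornea
  nm <- spec$noise
  n <- model$group_index
  sp <- surface_param(model)
  tfield <- build_thickness_field(model)

  x <- ascan_positions(geom)
  depth <- geom$axial_depth_air_mm
  tpar <- sp$t_of_x(x)
  fr <- sp$front(tpar)
  nrm <- sp$normal_in(tpar)
  zf <- fr$z
  d_entry <- sp$d_of(tpar)
  valid <- is.finite(tpar) & is.finite(zf) & zf > 0 & zf < depth

  rdir <- refract_vertical(nrm$x, nrm$z, 1, n)

  # dense sample of the true back surface (front offset inward by T)
  dmax <- geom$lateral_width_mm / 2 + 0.5
  tr <- sp$t_range(dmax)
  tgrid <- seq(tr[1], tr[2], length.out = 2048L)
  fg <- sp$front(tgrid)
  ng <- sp$normal_in(tgrid)
  dg <- sp$d_of(tgrid)
  Tg <- tfield(dg, session$meridian, session$eye)
  bx <- fg$x + (Tg / 1000) * ng$x
  bz <- fg$z + (Tg / 1000) * ng$z

  # per A-scan: intersect the refracted ray with the back surface.
  # cross(B - E, r) changes sign at the intersection; a coarse scan over the
  # sampled surface brackets the root, then uniroot refines it on the
  # analytic surface.
  g_at <- function(t, ex, ez, rx, rz) {
    f <- sp$front(t); nn <- sp$normal_in(t)
    tt <- tfield(sp$d_of(t), session$meridian, session$eye) / 1000
    bxx <- f$x + tt * nn$x
    bzz <- f$z + tt * nn$z
    rx * (bzz - ez) - rz * (bxx - ex)
  }
  s_mm <- rep(NA_real_, length(x))
  back_x <- rep(NA_real_, length(x))
  back_z <- rep(NA_real_, length(x))
  for (i in which(valid)) {
    win <- which(abs(dg - d_entry[i]) <= 2)
    if (length(win) < 2) { valid[i] <- FALSE; next }
    gi <- rdir$x[i] * (bz[win] - zf[i]) - rdir$z[i] * (bx[win] - fr$x[i])
    sc <- which(gi[-1] * gi[-length(gi)] <= 0)
    if (length(sc) == 0) { valid[i] <- FALSE; next }
    # crossing nearest the entry point's lateral offset
    k <- sc[which.min(abs(dg[win[sc]] - d_entry[i]))]
    lo <- tgrid[win[k]]; hi <- tgrid[win[k + 1]]
    tstar <- if (gi[k] == 0) lo else
      stats::uniroot(g_at, c(lo, hi), ex = fr$x[i], ez = zf[i],
                     rx = rdir$x[i], rz = rdir$z[i],
                     tol = 1e-12)$root
    f2 <- sp$front(tstar); n2 <- sp$normal_in(tstar)
    t2 <- tfield(sp$d_of(tstar), session$meridian, session$eye) / 1000
    bpx <- f2$x + t2 * n2$x
    bpz <- f2$z + t2 * n2$z
    si <- (bpx - fr$x[i]) * rdir$x[i] + (bpz - zf[i]) * rdir$z[i]
    if (!is.finite(si) || si <= 0) { valid[i] <- FALSE; next }
    s_mm[i] <- si
    back_x[i] <- bpx; back_z[i] <- bpz
  }
  zb <- zf + n * s_mm
  valid <- valid & is.finite(zb) & zb < depth

  occluded <- session$meridian == "vertical" & x > session$eyelid_occlusion_from_mm
  signal <- valid & !occluded

  # image formation
  z <- sample_depths_mm(geom)
  pitch <- axial_pitch_mm(geom)
  sigma_f <- max(fwhm_to_sigma(geom$axial_psf_fwhm_um) / 1000, 0.8 * pitch)
  sigma_b <- max(fwhm_to_sigma(geom$axial_psf_fwhm_um * n) / 1000, 0.8 * pitch)
  zf_sig <- ifelse(signal, zf, NA_real_)
  zb_sig <- ifelse(signal, zb, NA_real_)
  amp_f <- nm$surface_amplitude * exp(-zf_sig / nm$depth_rolloff_mm)
  amp_b <- nm$surface_amplitude * nm$back_reflectivity *
    exp(-zb_sig / nm$depth_rolloff_mm)
  ridge <- function(zc, amp, sigma) {
    G <- exp(-(outer(z, zc, "-"))^2 / (2 * sigma^2))
    G <- sweep(G, 2, amp, "*")
    G[is.na(G)] <- 0
    G
  }
  img <- ridge(zf_sig, amp_f, sigma_f) + ridge(zb_sig, amp_b, sigma_b)

  if (nm$speckle_factor > 0 || nm$background_sd > 0) {
    img <- with_seed(nm$seed, {
      out <- img
      if (nm$speckle_factor > 0)
        out <- out * pmax(0, 1 + nm$speckle_factor *
                            matrix(stats::rnorm(length(out)), nrow(out)))
      if (nm$background_sd > 0)
        out <- out + nm$background_sd *
          abs(matrix(stats::rnorm(length(out)), nrow(out)))
      out
    })
  }

  truth <- list(
    x_mm = x,
    front_z_um = zf * 1000,
    back_z_um = zb * 1000,
    s_mm = s_mm,
    d_mm = d_entry,
    normal_x = nrm$x, normal_z = nrm$z,
    refracted_x = rdir$x, refracted_z = rdir$z,
    thickness_um = tfield(d_entry, session$meridian, session$eye),
    valid = valid,
    occluded = occluded,
    back_surface = data.frame(x_mm = bx, z_mm = bz, d_mm = dg),
    apex_x_mm = model$apex_x_mm,
    apex_z_mm = model$apex_z_mm,
    model = model,
    session = session
  )

  structure(
    list(intensity = img, geometry = geom, meridian = session$meridian,
         eye = session$eye, test_index = as.integer(test_index),
         truth = truth),
    class = "oct_bscan"
  )
}

#' @export
print.oct_bscan <- function(x, ...) {
  cat(sprintf("OCT B-scan: %s meridian, %s, test %d, %d x %d pixels%s\n",
              x$meridian, x$eye, x$test_index,
              nrow(x$intensity), ncol(x$intensity),
              if (!is.null(x$truth)) " (synthetic, ground truth attached)" else ""))
  invisible(x)
}

#' Population distribution for a simulated cohort
#'
#' Per-subject central thickness is drawn from a normal distribution with
#' mean 52.0 um and SD 3.2 um; the two eyes of a subject differ by a small
#' additional inter-eye deviation. Anterior radius, apex alignment
#' (decentration, depth, tilt) vary across subjects and acquisitions.
#'
#' @param t0_mean_um,t0_sd_um Population mean and SD of the central
#'   epithelial thickness, um.
#' @param inter_eye_sd_um SD of the between-eye (within-subject) thickness
#'   deviation, um.
#' @param radius_mean_mm,radius_sd_mm Anterior radius distribution, mm.
#' @param apex_depth_mm,apex_depth_sd_mm Nominal apex depth in the image and
#'   its per-acquisition SD, mm.
#' @param decentration_sd_mm SD of per-acquisition lateral decentration, mm.
#' @param tilt_sd_deg SD of per-acquisition tilt, degrees.
#' @return A list of class `cohort_population`.
#' @export
cohort_population <- function(t0_mean_um = 52.0, t0_sd_um = 3.2,
                              inter_eye_sd_um = 0.8,
                              radius_mean_mm = 7.8, radius_sd_mm = 0.25,
                              apex_depth_mm = 1.2, apex_depth_sd_mm = 0.15,
                              decentration_sd_mm = 0.2, tilt_sd_deg = 0.5) {
  stopifnot(t0_mean_um > 0, t0_sd_um >= 0, inter_eye_sd_um >= 0,
            radius_mean_mm > 0, radius_sd_mm >= 0,
            apex_depth_mm > 0, apex_depth_sd_mm >= 0,
            decentration_sd_mm >= 0, tilt_sd_deg >= 0)
  structure(as.list(environment()), class = "cohort_population")
}

#' Simulate a test-retest cohort of corneal B-scans
#'
#' Draws per-subject corneal parameters from `population`, then renders two
#' meridians x two eyes x two tests per subject. Test 2 of each eye differs
#' from test 1 by a fresh noise realisation plus small rigid
#' decentration/tilt jitter (SDs from the session spec). A manifest records
#' every scan's true parameters.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param spec Base [phantom_spec()]; its cornea's shape defaults and noise
#'   model are shared by all subjects, its per-subject parameters are
#'   overridden from `population`.
#' @param population A [cohort_population()].
#' @param seed Integer seed governing all random draws.
#' @param meridians,eyes,tests Subsets of the full design, for reduced runs.
#' @param retest_decentration_sd_mm,retest_tilt_sd_deg SDs of the rigid
#'   alignment jitter between test 1 and test 2 (0 = perfectly repeated
#'   alignment).
#' @param out_dir If non-`NULL`, every scan is written as TIFF + JSON sidecar
#'   (see [write_bscan()]) together with `manifest.csv`, and scans are not
#'   kept in memory.
#' @param scan_callback If non-`NULL`, `scan_callback(bscan, manifest_row)`
#'   is invoked for each rendered scan (streaming use; scans not kept).
#' @return A list with `manifest` (data frame, one row per scan) and `scans`
#'   (list of `oct_bscan`, or `NULL` when streamed or written to disk).
#' @export
simulate_cohort <- function(n_subjects = 21,
                            spec = phantom_spec(geometry = reduced_geometry()),
                            population = cohort_population(),
                            seed = 1L,
                            meridians = c("horizontal", "vertical"),
                            eyes = c("OD", "OS"),
                            tests = 1:2,
                            retest_decentration_sd_mm = 0.1,
                            retest_tilt_sd_deg = 0.3,
                            out_dir = NULL,
                            scan_callback = NULL) {
  stopifnot(n_subjects >= 2, inherits(spec, "phantom_spec"),
            inherits(population, "cohort_population"))
  meridians <- match.arg(meridians, c("horizontal", "vertical"), several.ok = TRUE)
  eyes <- match.arg(eyes, c("OD", "OS"), several.ok = TRUE)
  stopifnot(all(tests %in% 1:2))
  stopifnot(retest_decentration_sd_mm >= 0, retest_tilt_sd_deg >= 0)
  pop <- population
  base <- spec$cornea

  plan <- with_seed(seed, {
    rows <- list()
    for (s in seq_len(n_subjects)) {
      t0_subj <- stats::rnorm(1, pop$t0_mean_um, pop$t0_sd_um)
      radius <- stats::rnorm(1, pop$radius_mean_mm, pop$radius_sd_mm)
      for (eye in eyes) {
        t0_eye <- t0_subj + stats::rnorm(1, 0, pop$inter_eye_sd_um)
        for (mer in meridians) {
          ax0 <- stats::rnorm(1, 0, pop$decentration_sd_mm)
          az0 <- stats::rnorm(1, pop$apex_depth_mm, pop$apex_depth_sd_mm)
          tl0 <- stats::rnorm(1, 0, pop$tilt_sd_deg)
          for (tst in tests) {
            ax <- ax0; az <- az0; tl <- tl0
            if (tst == 2) {
              ax <- ax + stats::rnorm(1, 0, retest_decentration_sd_mm)
              az <- az + stats::rnorm(1, 0, retest_decentration_sd_mm / 2)
              tl <- tl + stats::rnorm(1, 0, retest_tilt_sd_deg)
            }
            rows[[length(rows) + 1L]] <- data.frame(
              subject = s, eye = eye, meridian = mer, test = tst,
              t0_subject_um = t0_subj, t0_um = max(t0_eye, 20),
              radius_mm = radius, apex_x_mm = ax, apex_z_mm = max(az, 0.3),
              tilt_deg = tl,
              noise_seed = sample.int(.Machine$integer.max - 1L, 1),
              stringsAsFactors = FALSE
            )
          }
        }
      }
    }
    do.call(rbind, rows)
  })
  plan$file <- NA_character_

  keep <- is.null(out_dir) && is.null(scan_callback)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  scans <- if (keep) vector("list", nrow(plan)) else NULL

  for (i in seq_len(nrow(plan))) {
    r <- plan[i, ]
    model <- cornea_model(
      anterior_radius_mm = r$radius_mm,
      apex_x_mm = r$apex_x_mm, apex_z_mm = r$apex_z_mm, tilt_deg = r$tilt_deg,
      central_thickness_um = r$t0_um,
      peripheral_thickness_um = base$peripheral_thickness_um -
        base$central_thickness_um + r$t0_um,
      thickness_exponent = base$thickness_exponent,
      peripheral_distance_mm = base$peripheral_distance_mm,
      group_index = base$group_index
    )
    nm <- spec$noise
    nm$seed <- as.integer(r$noise_seed)
    sc_spec <- phantom_spec(spec$geometry, model, nm)
    session <- session_spec(meridian = r$meridian, eye = r$eye)
    bscan <- render_bscan(sc_spec, session, test_index = r$test)
    if (!is.null(out_dir)) {
      stem <- sprintf("s%02d_%s_%s_t%d", r$subject, r$eye, r$meridian, r$test)
      plan$file[i] <- write_bscan(bscan, file.path(out_dir, stem))
    }
    if (!is.null(scan_callback)) scan_callback(bscan, plan[i, ])
    if (keep) scans[[i]] <- bscan
  }
  if (!is.null(out_dir))
    utils::write.csv(plan, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  list(manifest = plan, scans = scans)
}
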