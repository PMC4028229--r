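# Shared fixtures and independent oracles. Heavy renders are cached for the
# duration of the test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, create) {
  if (!exists(name, envir = .fixture_env))
    assign(name, create(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

quiet_noise <- function() noise_model(background_sd = 0, speckle_factor = 0)

# 512 x 1024: the reduced instrument grid, used where sub-pixel accuracy matters
test_geom <- function() reduced_geometry()

# 256 x 512: coarse grid for structural / behavioural tests
coarse_geom <- function() scan_geometry(n_ascans = 256, n_samples = 512)

uniform_flat_model <- function(t_um = 52) {
  cornea_model(anterior_radius_mm = Inf,
               peripheral_thickness_um = c(temporal = t_um, nasal = t_um,
                                           superior = t_um, inferior = t_um),
               central_thickness_um = t_um)
}

# noiseless curved default phantom, horizontal OD, reduced grid
nl_curved_h <- function() fixture("nl_curved_h", function() {
  render_bscan(phantom_spec(test_geom(), cornea_model(), quiet_noise()),
               session_spec("horizontal", "OD"))
})

nl_traces_h <- function() fixture("nl_traces_h", function() {
  trace_boundaries(nl_curved_h())
})

nl_dewarp_h <- function() fixture("nl_dewarp_h", function() {
  tr <- nl_traces_h()
  dewarp_back_surface(tr$front, tr$back)
})

# Independent brute-force ray-trace oracle: for the A-scan at lateral x,
# returns the physical in-tissue path length s and the back-echo optical
# depth, by dense sampling of the analytically-constructed back surface and
# manual bisection on the ray-line cross product. Shares no code with the
# renderer.
oracle_ray_trace <- function(model, session, x) {
  stopifnot(is.finite(model$anterior_radius_mm))
  th <- model$tilt_deg * pi / 180
  R <- model$anterior_radius_mm
  cx <- model$apex_x_mm + R * sin(th)
  cz <- model$apex_z_mm + R * cos(th)
  tf <- build_thickness_field(model)

  psi_e <- asin((cx - x) / R)
  ez <- cz - R * cos(psi_e)
  nx <- sin(psi_e); nz <- cos(psi_e)
  # Snell via angles: incident is vertical, so sin(theta_i) = nx (signed);
  # the refracted ray is the inward normal rotated by the signed theta_t
  theta_t <- asin(nx / model$group_index)
  rot <- function(v, a) c(cos(a) * v[1] - sin(a) * v[2],
                          sin(a) * v[1] + cos(a) * v[2])
  r <- rot(c(nx, nz), theta_t)

  back_pt <- function(psi) {
    fx <- cx - R * sin(psi); fz <- cz - R * cos(psi)
    d <- -R * sin(psi - th)
    t_mm <- tf(d, session$meridian, session$eye) / 1000
    c(fx + t_mm * sin(psi), fz + t_mm * cos(psi))
  }
  cross_g <- function(psi) {
    b <- back_pt(psi)
    r[1] * (b[2] - ez) - r[2] * (b[1] - x)
  }
  # bracket by dense scan, then manual bisection
  grid <- seq(psi_e - 0.3, psi_e + 0.3, length.out = 20000)
  gv <- vapply(grid, cross_g, numeric(1))
  k <- which(gv[-1] * gv[-length(gv)] <= 0)[1]
  stopifnot(length(k) == 1, !is.na(k))
  lo <- grid[k]; hi <- grid[k + 1]
  for (it in 1:80) {
    mid <- (lo + hi) / 2
    if (cross_g(lo) * cross_g(mid) <= 0) hi <- mid else lo <- mid
  }
  b <- back_pt((lo + hi) / 2)
  s <- sqrt((b[1] - x)^2 + (b[2] - ez)^2)
  list(s_mm = s, back_z_optical_mm = ez + model$group_index * s,
       front_z_mm = ez, back_point = b)
}

# In-memory cohort run: simulate + profile every scan, return the long table
# the repeatability module consumes.
cohort_profiles <- function(n_subjects, seed, spec = phantom_spec(geometry = test_geom()),
                            meridians = c("horizontal", "vertical"),
                            eyes = c("OD", "OS"),
                            retest_decentration_sd_mm = 0.1,
                            retest_tilt_sd_deg = 0.3) {
  profs <- list()
  cb <- function(b, row) {
    p <- profile_bscan(b)
    df <- as.data.frame(p)
    df$subject <- row$subject; df$eye <- row$eye
    df$meridian <- row$meridian; df$test <- row$test
    profs[[length(profs) + 1L]] <<- df
  }
  res <- simulate_cohort(n_subjects = n_subjects, spec = spec, seed = seed,
                         meridians = meridians, eyes = eyes,
                         retest_decentration_sd_mm = retest_decentration_sd_mm,
                         retest_tilt_sd_deg = retest_tilt_sd_deg,
                         scan_callback = cb)
  pr <- do.call(rbind, profs)
  pr$thickness_um[pr$missing] <- NA_real_
  list(profiles = pr, manifest = res$manifest)
}

# brute-force statistics oracles (independent of the implementations)
oracle_cor <- function(m1, m2) {
  d <- m1 - m2
  n <- length(d)
  ss <- 0
  for (i in seq_len(n)) ss <- ss + (d[i] - sum(d) / n)^2
  2 * sqrt(ss / (n - 1))
}

oracle_icc21 <- function(m1, m2) {
  df <- data.frame(y = c(m1, m2),
                   subj = factor(c(seq_along(m1), seq_along(m2))),
                   rater = factor(rep(1:2, each = length(m1))))
  aov_tab <- stats::anova(stats::lm(y ~ subj + rater, data = df))
  msr <- aov_tab["subj", "Mean Sq"]
  msc <- aov_tab["rater", "Mean Sq"]
  mse <- aov_tab["Residuals", "Mean Sq"]
  n <- length(m1); k <- 2
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

oracle_paired_t <- function(m1, m2) {
  d <- m1 - m2
  n <- length(d)
  t <- mean(d) / (stats::sd(d) / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), n - 1))
}
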