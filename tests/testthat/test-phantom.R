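test_that("thickness field matches the published zonal ranges and asymmetries", {
  m <- cornea_model()
  f <- build_thickness_field(m)

  expect_equal(f(0, "horizontal"), 52)
  expect_equal(f(0, "vertical"), 52)

  # direction-averaged zone means on a dense grid fall in the published
  # central / paracentral / peripheral ranges
  d <- seq(0, 5, by = 0.001)
  tbar <- (f(d, "horizontal", "OD") + f(-d, "horizontal", "OD") +
             f(d, "vertical") + f(-d, "vertical")) / 4
  zone <- function(lo, hi) mean(tbar[d >= lo & d <= hi])
  expect_gte(zone(0, 1.5), 51); expect_lte(zone(0, 1.5), 53)
  expect_gte(zone(1.5, 3), 52); expect_lte(zone(1.5, 3), 57)
  expect_gte(zone(3, 5), 58); expect_lte(zone(3, 5), 72)

  # endpoints solved from the 5-mm thicknesses
  expect_equal(f(5, "horizontal", "OD"), 63)   # nasal
  expect_equal(f(-5, "horizontal", "OD"), 63)  # temporal
  expect_equal(f(5, "vertical"), 58)           # superior
  expect_equal(f(-5, "vertical"), 72)          # inferior

  # monotone non-decreasing in |d|
  expect_true(all(diff(f(d, "vertical")) >= 0))
  expect_true(all(diff(f(-d, "vertical")) >= 0))

  # inferior thicker than superior at the 2.5-mm point
  expect_gt(f(-2.5, "vertical") - f(2.5, "vertical"), 0)

  # uniform layer when all direction coefficients vanish
  fu <- build_thickness_field(uniform_flat_model())
  expect_equal(fu(c(0, 1, 3, 5), "horizontal"), rep(52, 4))

  # OS horizontal swaps nasal/temporal relative to OD
  expect_equal(f(2, "horizontal", "OS"), f(-2, "horizontal", "OD"))
})

test_that("flat uniform layer renders the closed-form optical separation", {
  b <- render_bscan(phantom_spec(coarse_geom(), uniform_flat_model(), quiet_noise()),
                    session_spec("horizontal", "OD"))
  sep <- b$truth$back_z_um - b$truth$front_z_um
  expect_true(all(b$truth$valid))
  expect_equal(sep, rep(52 * 1.389, length(sep)), tolerance = 1e-9)
})

test_that("rendering is deterministic under a fixed seed", {
  sp <- phantom_spec(coarse_geom(), cornea_model(),
                     noise_model(seed = 42))
  ses <- session_spec("horizontal", "OD")
  b1 <- render_bscan(sp, ses)
  b2 <- render_bscan(sp, ses)
  expect_identical(b1$intensity, b2$intensity)
})

test_that("rendered back echo matches an independent brute-force ray trace", {
  b <- nl_curved_h()
  m <- cornea_model()
  ses <- session_spec("horizontal", "OD")
  for (x_target in c(-4, 0.8, 3)) {
    i <- which.min(abs(b$truth$x_mm - x_target))
    orc <- oracle_ray_trace(m, ses, b$truth$x_mm[i])
    expect_lt(abs(b$truth$s_mm[i] - orc$s_mm), 1e-6)
    expect_lt(abs(b$truth$back_z_um[i] / 1000 - orc$back_z_optical_mm), 1e-6)
    # optical path consistency against the oracle's s
    expect_lt(abs((b$truth$back_z_um[i] - b$truth$front_z_um[i]) / 1000 /
                    orc$s_mm - 1.389), 1e-9)
  }
})

test_that("the forward model conserves Snell's law at every A-scan", {
  tr <- nl_curved_h()$truth
  ok <- tr$valid
  sin_i <- abs(tr$normal_x)  # incident is vertical: sin(theta_i) = |n_x|
  # sin(theta_t) = |r x n|
  sin_t <- abs(tr$refracted_x * tr$normal_z - tr$refracted_z * tr$normal_x)
  expect_lt(max(abs(sin_i - 1.389 * sin_t)[ok]), 1e-9)
  # refracted directions are unit
  expect_lt(max(abs(tr$refracted_x^2 + tr$refracted_z^2 - 1)[ok]), 1e-12)
})

test_that("with unit group index the back echo lands on the true back surface", {
  m <- cornea_model(group_index = 1)
  b <- render_bscan(phantom_spec(coarse_geom(), m, quiet_noise()),
                    session_spec("horizontal", "OD"))
  tr <- b$truth
  ok <- tr$valid
  # vertical rays: back echo depth should equal the back surface sampled at x
  z_interp <- stats::approx(tr$back_surface$x_mm, tr$back_surface$z_mm,
                            xout = tr$x_mm[ok])$y
  expect_lt(max(abs(tr$back_z_um[ok] / 1000 - z_interp)), 1e-5)
})

test_that("cohort simulation has the right design size and population spread", {
  cp <- cohort_population()
  # full design counts, checked on the plan of a small cohort
  res <- simulate_cohort(n_subjects = 2, spec = phantom_spec(geometry = coarse_geom()),
                         seed = 3)
  expect_equal(nrow(res$manifest), 2 * 2 * 2 * 2)
  expect_length(res$scans, 16)
  expect_setequal(unique(res$manifest$eye), c("OD", "OS"))
  expect_setequal(unique(res$manifest$meridian), c("horizontal", "vertical"))

  # population SD of subject-level central thickness near 3.2 at n = 21
  res21 <- simulate_cohort(n_subjects = 21,
                           spec = phantom_spec(geometry = coarse_geom()),
                           seed = 9, meridians = "horizontal", eyes = "OD",
                           tests = 1)
  t0 <- res21$manifest$t0_subject_um
  expect_length(t0, 21)
  expect_lt(abs(stats::sd(t0) - cp$t0_sd_um), 1.5)
  expect_lt(abs(mean(t0) - cp$t0_mean_um), 2.5)
})

test_that("zero jitter and zero noise make the two tests identical", {
  sp <- phantom_spec(coarse_geom(), cornea_model(), quiet_noise())
  res <- simulate_cohort(n_subjects = 2, spec = sp, seed = 4,
                         meridians = "horizontal", eyes = "OD",
                         retest_decentration_sd_mm = 0, retest_tilt_sd_deg = 0)
  m <- res$manifest
  for (s in unique(m$subject)) {
    i1 <- which(m$subject == s & m$test == 1)
    i2 <- which(m$subject == s & m$test == 2)
    expect_identical(res$scans[[i1]]$intensity, res$scans[[i2]]$intensity)
  }
})
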