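make_surface <- function(x, z_mm, valid = TRUE, prov = "front") {
  df <- data.frame(x_mm = x, z_mm = z_mm, valid = rep_len(valid, length(x)))
  attr(df, "provenance") <- prov
  class(df) <- c("physical_surface", "data.frame")
  df
}

arc_surface <- function(R, centre_z, x, prov = "front") {
  make_surface(x, centre_z - sqrt(R^2 - x^2), prov = prov)
}

test_that("apex detection finds the shallowest point", {
  x <- seq(-5, 5, by = 0.02)
  centred <- arc_surface(7.8, 9, x)
  expect_lt(abs(find_apex(centred)), 0.05)

  decentred <- make_surface(x, 9 - sqrt(7.8^2 - (x - 0.3)^2))
  expect_lt(abs(find_apex(decentred) - 0.3), 0.05)

  flat <- make_surface(x, rep(1.2, length(x)))
  a <- find_apex(flat)
  expect_equal(as.numeric(a), 0)
  expect_true(attr(a, "flat"))

  expect_error(find_apex(make_surface(0:1, c(1, 1))), "3 valid")
})

test_that("perpendicular thickness is exact for parallel and concentric layers", {
  x <- seq(-4, 4, by = 0.02)
  f <- make_surface(x, rep(1.0, length(x)))
  b <- make_surface(x, rep(1.052, length(x)), prov = "back_corrected")
  s <- perpendicular_thickness(f, b)
  expect_equal(s$t_um, rep(52, nrow(s)), tolerance = 1e-6)

  # concentric arcs: offset by the radius difference everywhere
  cz <- 9
  f2 <- arc_surface(7.8, cz, x)
  x2 <- seq(-4.2, 4.2, by = 0.005)
  b2 <- arc_surface(7.748, cz, x2, prov = "back_corrected")
  s2 <- perpendicular_thickness(f2, b2)
  expect_gt(nrow(s2), 300)
  expect_lt(max(abs(s2$t_um - 52)), 0.1)
})

test_that("thickness is invariant under rigid motion of both surfaces", {
  x <- seq(-4, 4, by = 0.02)
  cz <- 9
  f <- arc_surface(7.8, cz, x)
  x2 <- seq(-4.2, 4.2, by = 0.005)
  b <- arc_surface(7.748, cz, x2, prov = "back_corrected")
  t_ref <- perpendicular_thickness(f, b)

  th <- 5 * pi / 180; dx <- 0.7; dz <- -0.4
  rot <- function(s) {
    xr <- cos(th) * s$x_mm - sin(th) * s$z_mm + dx
    zr <- sin(th) * s$x_mm + cos(th) * s$z_mm + dz
    make_surface(xr, zr, prov = attr(s, "provenance"))
  }
  t_rot <- perpendicular_thickness(rot(f), rot(b))
  # same front points in the same order; thickness must be unchanged
  expect_equal(nrow(t_rot), nrow(t_ref))
  expect_lt(max(abs(t_rot$t_um - t_ref$t_um)), 0.1)
})

test_that("pipeline recovers the generator's thickness field on a noiseless scan", {
  b <- nl_curved_h()
  prof <- profile_bscan(b)
  f <- build_thickness_field(b$truth$model)
  truth <- f(prof$position_mm, b$meridian, b$eye)
  ok <- !prof$missing
  expect_true(all(ok))
  expect_lt(max(abs(prof$thickness_um - truth)[ok]), 1.5)
})

test_that("binning implements a boxcar average anchored at the apex", {
  # sample offsets avoid landing exactly on bin edges
  samples <- data.frame(x_mm = seq(-5.295, 5.3, by = 0.01))
  samples$t_um <- 52
  p <- bin_profile(samples, "horizontal")
  expect_equal(p$position_mm, seq(-5, 5, by = 0.5))
  expect_equal(p$thickness_um, rep(52, 21))
  expect_true(all(!p$missing))

  # linear ramp: symmetric window average equals the value at the bin centre
  samples$t_um <- 52 + 2 * samples$x_mm
  p2 <- bin_profile(samples, "horizontal")
  expect_equal(p2$thickness_um, 52 + 2 * p2$position_mm, tolerance = 1e-9)

  # apex anchoring shifts the window (interior bins: full sample support)
  p3 <- bin_profile(samples, "horizontal", apex_x_mm = 0.3)
  inner <- abs(p3$position_mm) <= 4.5
  expect_equal(p3$thickness_um[inner], 52 + 2 * (p3$position_mm[inner] + 0.3),
               tolerance = 1e-9)

  # occluded superior region -> missing bin
  sv <- samples[samples$x_mm <= 4.2, ]
  pv <- bin_profile(sv, "vertical")
  expect_true(pv$missing[pv$position_mm == 4.5])
  expect_true(is.na(pv$thickness_um[pv$position_mm == 4.5]))
  expect_false(pv$missing[pv$position_mm == 4.0])
})

test_that("left-eye horizontal profiles mirror and mirroring is an involution", {
  samples <- data.frame(x_mm = seq(-5.3, 5.3, by = 0.01))
  samples$t_um <- 52 + 1.1 * samples$x_mm  # nasal/temporal asymmetric
  pod <- bin_profile(samples, "horizontal", eye = "OD")
  expect_identical(mirror_profile(pod), pod)  # OD unchanged

  pos <- bin_profile(samples, "horizontal", eye = "OS")
  m <- mirror_profile(pos)
  expect_equal(m$thickness_um, rev(pos$thickness_um))
  expect_equal(m$thickness_um[m$position_mm == 5],
               pos$thickness_um[pos$position_mm == -5])
  mm <- mirror_profile(m)
  expect_equal(mm$thickness_um, pos$thickness_um)

  pvert <- bin_profile(samples, "vertical", eye = "OS")
  expect_identical(mirror_profile(pvert), pvert)  # vertical never flipped
})

test_that("zonal means respect zone membership and missing data", {
  samples <- data.frame(x_mm = seq(-5.3, 5.3, by = 0.01), t_um = 52)
  p <- bin_profile(samples, "horizontal")
  z <- zonal_means(p)
  expect_equal(unname(z), rep(52, 3))

  # zone means bracketed by member extremes
  set.seed(2)
  p$thickness_um <- runif(21, 45, 75)
  z2 <- zonal_means(p)
  r <- abs(p$position_mm)
  expect_gte(z2["central"], min(p$thickness_um[r < 1.5]))
  expect_lte(z2["central"], max(p$thickness_um[r < 1.5]))
  expect_gte(z2["peripheral"], min(p$thickness_um[r >= 3]))
  expect_lte(z2["peripheral"], max(p$thickness_um[r >= 3]))

  # a fully missing zone is NA, others unaffected
  p$missing[r >= 3] <- TRUE
  z3 <- zonal_means(p)
  expect_true(is.na(z3["peripheral"]))
  expect_equal(unname(z3["central"]), unname(z2["central"]))
})

test_that("profile averaging pools non-missing points", {
  samples <- data.frame(x_mm = seq(-5.3, 5.3, by = 0.01), t_um = 50)
  p1 <- bin_profile(samples, "horizontal")
  expect_equal(average_profiles(list(p1))$thickness_um, p1$thickness_um)

  samples$t_um <- 54
  p2 <- bin_profile(samples, "horizontal")
  avg <- average_profiles(list(p1, p2))
  expect_equal(avg$thickness_um, rep(52, 21))
  expect_equal(avg$n, rep(2L, 21))

  # a point missing in one input carries the other's value with n = 1
  p2$missing[3] <- TRUE; p2$thickness_um[3] <- NA
  avg2 <- average_profiles(list(p1, p2))
  expect_equal(avg2$thickness_um[3], 50)
  expect_equal(avg2$n[3], 1L)
  expect_false(avg2$missing[3])
})
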