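test_that("CoR follows its definition and scaling laws", {
  m <- c(50, 52, 54, 49, 55)
  expect_equal(cor_repeatability(m, m)$cor_um, 0)
  expect_equal(cor_repeatability(m, m)$cor_pct, 0)

  # hand-computed example: differences (3, -1, 2, 0, -2), sample SD 2.0736
  m2 <- m - c(3, -1, 2, 0, -2)
  r <- cor_repeatability(m, m2)
  expect_equal(r$cor_um, 4.1472882, tolerance = 1e-6)

  # doubling all measurements doubles CoR but not CoR%
  r2 <- cor_repeatability(2 * m, 2 * m2)
  expect_equal(r2$cor_um, 2 * r$cor_um, tolerance = 1e-12)
  expect_equal(r2$cor_pct, r$cor_pct, tolerance = 1e-12)

  # translation leaves CoR unchanged
  r3 <- cor_repeatability(m + 100, m2 + 100)
  expect_equal(r3$cor_um, r$cor_um, tolerance = 1e-12)

  expect_error(cor_repeatability(1, 2))
})

test_that("ICC(2,1) behaves at its variance-component limits", {
  expect_equal(icc_agreement(c(50, 52, 54), c(50, 52, 54)), 1)

  # noise far larger than the between-subject variance drives ICC to 0
  set.seed(11)
  s <- rnorm(200, 52, 3.2)
  icc0 <- icc_agreement(s, s + rnorm(200, 0, 60))
  expect_lt(abs(icc0), 0.1)

  # constant data: undefined, flagged
  z <- icc_agreement(rep(5, 4), rep(5, 4))
  expect_true(is.na(z))
  expect_true(attr(z, "degenerate"))

  # adding a common constant leaves ICC unchanged
  m1 <- c(48, 51, 55, 52, 50); m2 <- c(49, 52, 54, 51, 52)
  expect_equal(icc_agreement(m1 + 7, m2 + 7), icc_agreement(m1, m2),
               tolerance = 1e-12)
})

test_that("ICC decreases monotonically with added measurement noise", {
  set.seed(21)
  base <- rnorm(60, 52, 3.2)
  med_icc <- vapply(c(0.5, 2, 8), function(sdn) {
    stats::median(vapply(1:5, function(r) {
      set.seed(1000 + r)
      icc_agreement(base + rnorm(60, 0, sdn), base + rnorm(60, 0, sdn))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med_icc) < 0))
})

test_that("paired t handles degenerate and forced-rejection cases", {
  p0 <- paired_t(c(50, 52, 54), c(50, 52, 54))
  expect_equal(p0$t, 0)
  expect_equal(p0$p, 1)

  # a constant +1 shift with minute jitter is decisively rejected
  set.seed(3)
  a <- rnorm(10, 52, 3)
  pt <- paired_t(a + 1 + rnorm(10, 0, 1e-4), a)
  expect_lt(pt$p, 0.05)

  # exact constant nonzero difference: flagged degenerate with p = 0
  pd <- paired_t(a + 1, a)
  expect_equal(as.numeric(pd$p), 0)
  expect_true(attr(pd$p, "degenerate"))
})

test_that("all three statistics match brute-force oracles on random datasets", {
  set.seed(42)
  for (case in 1:120) {
    n <- sample(3:12, 1)
    mu <- runif(1, 30, 80)
    m1 <- rnorm(n, mu, runif(1, 0.5, 6))
    m2 <- m1 + rnorm(n, runif(1, -2, 2), runif(1, 0.1, 4))
    expect_equal(cor_repeatability(m1, m2)$cor_um, oracle_cor(m1, m2),
                 tolerance = 1e-10)
    icc <- icc_agreement(m1, m2)
    if (!is.na(icc))
      expect_equal(as.numeric(icc), oracle_icc21(m1, m2), tolerance = 1e-10)
    pt <- paired_t(m1, m2)
    po <- oracle_paired_t(m1, m2)
    expect_lt(abs(pt$t - po$t) / max(1, abs(po$t)), 1e-10)
    expect_equal(pt$p, po$p, tolerance = 1e-10)
  }
})

test_that("a noise-free cohort reports perfect repeatability everywhere", {
  cp <- cohort_profiles(3, seed = 6,
                        spec = phantom_spec(coarse_geom(), cornea_model(),
                                            quiet_noise()),
                        meridians = "horizontal",
                        retest_decentration_sd_mm = 0,
                        retest_tilt_sd_deg = 0)
  rep <- repeatability_report(cp$profiles)
  loc <- rep$locations
  expect_equal(nrow(loc), length(profile_grid("horizontal")))
  done <- is.finite(loc$cor_um)
  expect_gt(sum(done), 15)
  expect_equal(loc$cor_um[done], rep(0, sum(done)), tolerance = 1e-9)
  expect_equal(loc$icc[done], rep(1, sum(done)), tolerance = 1e-9)
})

test_that("report covers every grid point and flags sparse locations", {
  grid_h <- profile_grid("horizontal")
  grid_v <- profile_grid("vertical")
  set.seed(8)
  rows <- expand.grid(subject = 1:5, eye = "OD", test = 1:2,
                      position_mm = grid_h, stringsAsFactors = FALSE)
  rows$meridian <- "horizontal"
  rows$thickness_um <- 52 + rnorm(nrow(rows), 0, 1)
  # one location has too few complete pairs
  rows$thickness_um[rows$position_mm == 5 & rows$subject %in% 1:3] <- NA
  rep <- repeatability_report(rows)
  expect_equal(nrow(rep$locations), length(grid_h))
  expect_true(is.na(rep$locations$cor_um[rep$locations$position_mm == 5]))
  expect_equal(rep$locations$n[rep$locations$position_mm == 5], 2)
  expect_equal(rep$zones$zone, c("central_6mm", "peripheral_4mm"))
})
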