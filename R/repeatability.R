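#' Coefficient of repeatability
#'
#' The CoR is two (sample, n-1 denominator) standard deviations of the
#' difference between two measurements; CoR% expresses it as a percentage of
#' the mean of all measurements (both tests pooled).
#'
#' @param m1,m2 Paired measurements (um), aligned by subject.
#' @return List with `cor_um` and `cor_pct`.
#' @export
cor_repeatability <- function(m1, m2) {
  stopifnot(length(m1) == length(m2), length(m1) >= 2,
            all(is.finite(m1)), all(is.finite(m2)))
  cor_um <- 2 * stats::sd(m1 - m2)
  list(cor_um = cor_um, cor_pct = 100 * cor_um / mean(c(m1, m2)))
}

#' Intraclass correlation coefficient, ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC,
#' computed from the two-way ANOVA mean squares of the subjects-by-tests
#' table:
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' with n subjects and k = 2 tests. This is the standard form for
#' test-retest agreement.
#'
#' @param m1,m2 Paired measurements, aligned by subject (n >= 3).
#' @return The ICC. When the data have zero total variance the ICC is
#'   undefined and `NA` is returned with attribute `degenerate = TRUE`.
#' @export
icc_agreement <- function(m1, m2) {
  stopifnot(length(m1) == length(m2), length(m1) >= 3,
            all(is.finite(m1)), all(is.finite(m2)))
  n <- length(m1); k <- 2
  y <- cbind(m1, m2)
  grand <- mean(y)
  rowm <- rowMeans(y)
  colm <- colMeans(y)
  ssr <- k * sum((rowm - grand)^2)
  ssc <- n * sum((colm - grand)^2)
  sst <- sum((y - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (sst == 0 || denom <= 0) {
    return(structure(NA_real_, degenerate = TRUE))
  }
  (msr - mse) / denom
}

#' Paired t test on two measurements
#'
#' Standard paired t on the within-subject differences, two-tailed. The
#' degenerate case of identical pairs reports t = 0, p = 1; zero-variance
#' differences with nonzero mean report p = 0 with attribute
#' `degenerate = TRUE`.
#'
#' @param m1,m2 Paired measurements, aligned by subject (n >= 2).
#' @return List with `t`, `p`, `df`, `mean_difference`.
#' @export
paired_t <- function(m1, m2) {
  stopifnot(length(m1) == length(m2), length(m1) >= 2,
            all(is.finite(m1)), all(is.finite(m2)))
  d <- m1 - m2
  n <- length(d)
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      return(list(t = 0, p = 1, df = n - 1, mean_difference = 0))
    }
    return(list(t = structure(sign(mean(d)) * Inf, degenerate = TRUE),
                p = structure(0, degenerate = TRUE),
                df = n - 1, mean_difference = mean(d)))
  }
  tt <- stats::t.test(m1, m2, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_difference = unname(tt$estimate))
}

#' Per-location and zonal repeatability report
#'
#' Takes a long table of binned thickness profiles for a cohort and computes,
#' at every grid location of every meridian, the test-retest (or
#' interobserver) CoR, CoR%, ICC(2,1) and paired-t across measurement units.
#' A unit is one eye of one subject (test-retest design) or one scan analysed
#' by two observers (interobserver design); only units with both measurements
#' non-missing at a location enter that location's statistics.
#'
#' Zonal aggregates (mean +/- SD of CoR and ICC over member grid locations,
#' both meridians pooled) are reported for the central 6-mm zone
#' (|position| <= 3.0 mm) and the peripheral 4-mm zone (|position| > 3.0 mm).
#'
#' @param profiles Data frame with columns `subject`, `eye`, `meridian`,
#'   `test` (1/2 for test-retest, or observer 1/2), `position_mm`,
#'   `thickness_um` (NA where missing).
#' @param design `"test_retest"` or `"interobserver"` (metadata; both pair on
#'   the `test` column).
#' @param min_units Minimum complete pairs required at a location (default 3).
#' @return A list of class `repeatability_report` with `locations` (one row
#'   per meridian x grid point: `meridian`, `position_mm`, `n`, `mean_um`,
#'   `cor_um`, `cor_pct`, `icc`, `t`, `p`) and `zones`.
#' @export
repeatability_report <- function(profiles,
                                 design = c("test_retest", "interobserver"),
                                 min_units = 3) {
  design <- match.arg(design)
  need <- c("subject", "eye", "meridian", "test", "position_mm", "thickness_um")
  stopifnot(all(need %in% names(profiles)))
  stopifnot(all(profiles$test %in% 1:2))
  profiles$unit <- interaction(profiles$subject, profiles$eye, drop = TRUE)

  out <- list()
  for (mer in unique(profiles$meridian)) {
    sub <- profiles[profiles$meridian == mer, ]
    for (pos in sort(unique(sub$position_mm))) {
      at <- sub[sub$position_mm == pos, ]
      w <- stats::reshape(at[, c("unit", "test", "thickness_um")],
                          idvar = "unit", timevar = "test", direction = "wide")
      m1 <- w$thickness_um.1
      m2 <- w$thickness_um.2
      if (is.null(m1) || is.null(m2)) {
        stop(sprintf("unmatched test pairs at %s %+.1f mm", mer, pos))
      }
      ok <- is.finite(m1) & is.finite(m2)
      m1 <- m1[ok]; m2 <- m2[ok]
      if (length(m1) < min_units) {
        out[[length(out) + 1L]] <- data.frame(
          meridian = mer, position_mm = pos, n = length(m1),
          mean_um = NA_real_, cor_um = NA_real_, cor_pct = NA_real_,
          icc = NA_real_, t = NA_real_, p = NA_real_)
        next
      }
      cr <- cor_repeatability(m1, m2)
      ic <- icc_agreement(m1, m2)
      pt <- paired_t(m1, m2)
      out[[length(out) + 1L]] <- data.frame(
        meridian = mer, position_mm = pos, n = length(m1),
        mean_um = mean(c(m1, m2)),
        cor_um = cr$cor_um, cor_pct = cr$cor_pct,
        icc = as.numeric(ic), t = as.numeric(pt$t), p = as.numeric(pt$p))
    }
  }
  locations <- do.call(rbind, out)

  zone_of <- ifelse(abs(locations$position_mm) <= 3.0,
                    "central_6mm", "peripheral_4mm")
  zones <- do.call(rbind, lapply(c("central_6mm", "peripheral_4mm"), function(zn) {
    sel <- zone_of == zn & is.finite(locations$cor_um)
    data.frame(zone = zn,
               n_locations = sum(sel),
               mean_cor_um = mean(locations$cor_um[sel]),
               sd_cor_um = stats::sd(locations$cor_um[sel]),
               mean_icc = mean(locations$icc[sel], na.rm = TRUE),
               sd_icc = stats::sd(locations$icc[sel], na.rm = TRUE))
  }))

  structure(list(locations = locations, zones = zones, design = design),
            class = "repeatability_report")
}

#' @export
print.repeatability_report <- function(x, ...) {
  cat(sprintf("Repeatability report (%s): %d locations\n",
              x$design, nrow(x$locations)))
  print(x$zones, row.names = FALSE)
  invisible(x)
}

#' Export a repeatability report as CSV files
#' @param report A `repeatability_report`.
#' @param locations_path,zones_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_report_csv <- function(report, locations_path, zones_path) {
  utils::write.csv(report$locations, locations_path, row.names = FALSE)
  utils::write.csv(report$zones, zones_path, row.names = FALSE)
  invisible(c(locations_path, zones_path))
}
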