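test_that("date tables round-trip and reject invalid rows with diagnostics", {
  tab <- data.frame(site = paste0("S", 1:10), lab_code = paste0("L", 1:10),
                    c14_age = seq(9000, 4500, length.out = 10),
                    c14_error = rep(c(40, 80), 5),
                    lon = seq(36, 77, length.out = 10),
                    lat = seq(36, 16, length.out = 10),
                    affiliation = "test", included = TRUE,
                    exclusion_reason = "", extra_note = letters[1:10],
                    stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab, f, row.names = FALSE)
  got <- load_dates(f)
  expect_equal(nrow(got), 10L)
  expect_equal(got$c14_age, tab$c14_age)
  expect_equal(got$lon, tab$lon)
  expect_equal(got$extra_note, tab$extra_note)  # unknown columns preserved
  expect_true(all(got$included))

  # empty file with header -> empty table
  write.csv(tab[0, ], f, row.names = FALSE)
  expect_equal(nrow(load_dates(f)), 0L)

  # missing column -> format error naming it
  write.csv(tab[, setdiff(names(tab), "c14_error")], f, row.names = FALSE)
  expect_error(load_dates(f), "c14_error")

  # bad rows rejected individually, with row-indexed diagnostics
  bad <- tab
  bad$c14_age[3] <- "not-a-number"
  bad$c14_error[5] <- -10
  bad$lat[7] <- 95
  write.csv(bad, f, row.names = FALSE)
  expect_warning(got <- load_dates(f), "row 3")
  expect_equal(nrow(got), 7L)
  rej <- attr(got, "rejected")
  expect_equal(rej$row, c(3L, 5L, 7L))
  expect_match(rej$reason[1], "non-numeric")
})

test_that("identity-curve calibration reproduces the input age", {
  curve <- identity_curve()
  for (age in c(4000, 5000, 9500)) {
    for (err in c(20, 50, 200)) {
      d <- calibrate(age, err, curve)
      expect_lte(abs(d$median_cal_bp - age), 1)   # within one grid step
      expect_equal(sum(d$prob), 1, tolerance = 1e-9)
      # density is a discretised normal: ~68.3% of mass within +/- 1 sigma
      # (closed-interval grid sums overshoot by ~2*phi(1)/err, so only
      # check where that discretisation bias sits below the 1% tolerance)
      if (err >= 50) {
        inside <- d$cal_bp >= age - err & d$cal_bp <= age + err
        expect_equal(sum(d$prob[inside]), 0.683, tolerance = 0.01)
      }
    }
  }
})

test_that("plateau-curve median matches an independent fine-grid quadrature", {
  # piecewise-linear curve with a radiocarbon plateau between 5200 and 5600
  cal <- seq(4000, 7000, by = 5)
  mu <- ifelse(cal < 5200, cal,
               ifelse(cal < 5600, 5200 + 0.1 * (cal - 5200),
                      5240 + (cal - 5600)))
  curve <- cal_curve(cal, mu, rep(10, length(cal)))
  age <- 5230; err <- 40
  d <- calibrate(age, err, curve)

  # oracle: direct quadrature at 0.1-yr step, written independently
  g <- seq(4000, 7000, by = 0.1)
  mo <- approx(cal, mu, g)$y
  p <- dnorm(age, mo, sqrt(err^2 + 10^2))
  p <- p / sum(p)
  med_oracle <- g[which(cumsum(p) >= 0.5)[1]]
  expect_lte(abs(d$median_cal_bp - med_oracle), 1.1)
  # the plateau should smear the density: wide 95% interval
  cdf <- cumsum(d$prob)
  q <- d$cal_bp[c(which(cdf >= 0.025)[1], which(cdf >= 0.975)[1])]
  expect_gt(diff(q), 400)
})

test_that("calibration is translation-equivariant on identity-slope curves", {
  curve <- identity_curve()
  shifted <- cal_curve(curve$cal_bp, curve$mu + 300, curve$sigma_curve)
  for (age in c(4500, 6000, 8000)) {
    m0 <- calibrate(age, 60, curve)$median_cal_bp
    m1 <- calibrate(age + 300, 60, shifted)$median_cal_bp
    expect_lte(abs(m1 - m0), 1)
  }
})

test_that("ages outside the curve support are rejected", {
  curve <- identity_curve(4000, 6000)
  expect_error(calibrate(9000, 30, curve), "outside")
  expect_error(calibrate(200, 30, curve), "outside")
})

test_that("per-site aggregation keeps the earliest attestation", {
  curve <- identity_curve()
  dates <- data.frame(
    site = c("A", "A", "B", "C"),
    lab_code = paste0("L", 1:4),
    c14_age = c(5400, 6000, 7000, 4800),
    c14_error = c(50, 50, 60, 40),
    lon = c(40, 40, 50, 60), lat = c(30, 30, 31, 28),
    affiliation = "x", included = c(TRUE, TRUE, TRUE, FALSE),
    exclusion_reason = c("", "", "", "late"),
    stringsAsFactors = FALSE)

  expect_warning(obs <- site_observations(dates, curve), "C")
  expect_equal(nrow(obs), 2L)
  a <- obs[obs$site == "A", ]
  expect_equal(a$median_cal_bp, 6000, tolerance = 1)  # max of the medians
  expect_equal(a$n_dates, 2L)

  # all_dates mode: one observation per included determination
  expect_warning(all_obs <- site_observations(dates, curve, "all_dates"))
  expect_equal(nrow(all_obs), 3L)

  # single-date site is identical under both modes
  b1 <- obs[obs$site == "B", c("site", "median_cal_bp")]
  b2 <- all_obs[all_obs$site == "B", c("site", "median_cal_bp")]
  expect_equal(b1, b2, ignore_attr = TRUE)
})

test_that("IntCal-format curve files round-trip (descending rows resorted)", {
  curve <- toy_cal_curve(1000, 3000, step = 10, wiggle_amp = 20,
                         wiggle_period = 400, curve_error = 8)
  f <- withr::local_tempfile(fileext = ".14c")
  write_cal_curve(curve, f, comment = "round-trip test")
  got <- read_cal_curve(f)
  expect_equal(got$cal_bp, curve$cal_bp)
  expect_equal(got$mu, curve$mu)
  expect_equal(got$sigma_curve, curve$sigma_curve)
  expect_true(!is.unsorted(got$cal_bp, strictly = TRUE))
})
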