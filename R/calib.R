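#' Load a radiocarbon date table
#'
#' Reads a CSV of radiocarbon determinations with one row per lab
#' measurement.  Required columns: `site`, `lab_code`, `c14_age`,
#' `c14_error`, `lon`, `lat`, `affiliation`, `included`,
#' `exclusion_reason`; any additional columns are preserved as metadata.
#' Rows violating the invariants (positive age and error, coordinates within
#' bounds, parseable numbers) are rejected with row-indexed diagnostics
#' rather than silently dropped: the returned data frame carries the
#' offending rows in `attr(x, "rejected")` and a warning summarises them.
#'
#' @param path path to the CSV file.
#' @return data.frame of valid determinations, `included` as logical;
#'   attribute `rejected` holds a data.frame of rejected rows with a
#'   `reason` column and original row numbers.
#' @export
load_dates <- function(path) {
  if (!file.exists(path)) stop("date table not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("site", "lab_code", "c14_age", "c14_error", "lon", "lat",
                "affiliation", "included", "exclusion_reason")
  miss <- setdiff(required, names(raw))
  if (length(miss))
    stop("date table is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(raw) == 0L) {
    out <- raw
    out$c14_age <- numeric(0); out$c14_error <- numeric(0)
    out$lon <- numeric(0); out$lat <- numeric(0)
    out$included <- logical(0)
    attr(out, "rejected") <- cbind(raw, reason = character(0))
    return(out)
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  age <- num(raw$c14_age); err <- num(raw$c14_error)
  lon <- num(raw$lon);     lat <- num(raw$lat)
  inc <- tolower(trimws(raw$included)) %in% c("true", "t", "1", "yes")

  reason <- rep(NA_character_, nrow(raw))
  flag <- function(bad, why) {
    bad <- bad & is.na(reason)
    reason[bad] <<- why
  }
  flag(is.na(age) | is.na(err), "non-numeric c14 age or error")
  flag(!is.na(age) & age <= 0, "c14 age must be > 0")
  flag(!is.na(err) & err <= 0, "c14 error must be > 0")
  flag(is.na(lon) | is.na(lat), "non-numeric coordinates")
  flag(!is.na(lon) & (lon < -180 | lon > 180), "longitude outside [-180, 180]")
  flag(!is.na(lat) & (lat < -90 | lat > 90), "latitude outside [-90, 90]")

  bad <- !is.na(reason)
  out <- raw[!bad, , drop = FALSE]
  out$c14_age <- age[!bad]; out$c14_error <- err[!bad]
  out$lon <- lon[!bad];     out$lat <- lat[!bad]
  out$included <- inc[!bad]
  rownames(out) <- NULL
  rejected <- raw[bad, , drop = FALSE]
  if (nrow(rejected)) {
    rejected$reason <- reason[bad]
    rejected$row <- which(bad)
    warning(nrow(rejected), " row(s) rejected: ",
            paste0("row ", rejected$row, " (", rejected$reason, ")",
                   collapse = "; "))
  } else {
    rejected$reason <- character(0)
  }
  attr(out, "rejected") <- rejected
  out
}

#' Construct a calibration curve
#'
#' @param cal_bp calendar ages (years BP), any order; stored ascending.
#' @param mu radiocarbon age of the curve at each `cal_bp`.
#' @param sigma_curve 1-sigma curve uncertainty (>= 0) at each `cal_bp`.
#' @return object of class `cal_curve`.
#' @export
cal_curve <- function(cal_bp, mu, sigma_curve) {
  if (length(cal_bp) != length(mu) || length(mu) != length(sigma_curve))
    stop("cal_bp, mu and sigma_curve must have equal lengths")
  o <- order(cal_bp)
  cal_bp <- as.numeric(cal_bp[o]); mu <- as.numeric(mu[o])
  sigma_curve <- as.numeric(sigma_curve[o])
  if (any(diff(cal_bp) <= 0)) stop("cal_bp grid must be strictly increasing")
  if (any(sigma_curve < 0)) stop("sigma_curve must be >= 0")
  structure(list(cal_bp = cal_bp, mu = mu, sigma_curve = sigma_curve),
            class = "cal_curve")
}

#' Read a calibration curve in IntCal CSV format
#'
#' Expects the IntCal file layout: comment lines starting with `#`, then
#' comma-separated columns `cal BP, 14C age, error` (further columns, as in
#' the published IntCal20 file, are ignored).  IntCal files list ages in
#' descending order; the curve is re-sorted ascending on load.
#'
#' @param path path to the curve file.
#' @return a [cal_curve()] object.
#' @export
read_cal_curve <- function(path) {
  if (!file.exists(path)) stop("calibration curve not found: ", path)
  d <- read.csv(path, comment.char = "#", header = FALSE,
                stringsAsFactors = FALSE)
  if (ncol(d) < 3L) stop("curve file needs >= 3 columns (cal BP, age, error)")
  cols <- lapply(d[1:3], function(x) suppressWarnings(as.numeric(x)))
  if (anyNA(cols[[1]]) || anyNA(cols[[2]]) || anyNA(cols[[3]]))
    stop("not a calibration curve (non-numeric values): ", path)
  cal_curve(cols[[1]], cols[[2]], cols[[3]])
}

#' Write a calibration curve in IntCal CSV format
#' @param curve a [cal_curve()].
#' @param path output path.
#' @param comment optional comment line(s) written with a leading `#`.
#' @export
write_cal_curve <- function(curve, path, comment = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(comment)) writeLines(paste("#", comment), con)
  o <- order(curve$cal_bp, decreasing = TRUE)   # conventional file order
  writeLines(paste(curve$cal_bp[o], curve$mu[o], curve$sigma_curve[o],
                   sep = ","), con)
  invisible(path)
}

#' An invertible toy calibration curve
#'
#' A smooth monotone curve `mu(t) = t + A sin(2 pi t / P)` used by the
#' synthetic-data generator: monotone (hence invertible) whenever
#' `2 pi A / P < 1`, so radiocarbon ages can be back-computed from calendar
#' ages and the full calibrate-then-summarise path exercised end to end.
#' With `wiggle_amp = 0` it is the identity curve.
#'
#' @param cal_min,cal_max calendar range (years BP).
#' @param step grid step (years).
#' @param wiggle_amp amplitude A of the sinusoidal wiggle (years).
#' @param wiggle_period period P of the wiggle (years).
#' @param curve_error constant curve 1-sigma (years).
#' @return a [cal_curve()] object.
#' @export
toy_cal_curve <- function(cal_min = 0, cal_max = 13000, step = 5,
                          wiggle_amp = 0, wiggle_period = 500,
                          curve_error = 0) {
  if (wiggle_amp * 2 * pi / wiggle_period >= 1)
    stop("wiggle too strong: curve would be non-monotone (need 2*pi*A/P < 1)")
  t <- seq(cal_min, cal_max, by = step)
  cal_curve(t, t + wiggle_amp * sin(2 * pi * t / wiggle_period),
            rep(curve_error, length(t)))
}

#' Calibrate one radiocarbon determination
#'
#' Places a posterior density over calendar age on a regular grid spanning
#' the curve: `p(t)` proportional to the normal density of the measured age
#' at mean `mu(t)` and standard deviation `sqrt(error^2 +
#' sigma_curve(t)^2)`, normalised to sum to 1.  The summary statistic used
#' throughout the package is the median, defined as the smallest grid age at
#' which the cumulative probability reaches 0.5 (a deterministic tie-break).
#'
#' @param age,error measured radiocarbon age and 1-sigma error (years BP).
#' @param curve a [cal_curve()].
#' @param grid_step calendar grid step in years (default 1; well below
#'   dating noise).
#' @return object of class `cal_density`: list with `cal_bp`, `prob`
#'   (sums to 1) and `median_cal_bp`.
#' @examples
#' curve <- toy_cal_curve(4000, 6000)
#' calibrate(5000, 50, curve)$median_cal_bp   # 5000 on the identity curve
#' @export
calibrate <- function(age, error, curve, grid_step = 1) {
  stopifnot(inherits(curve, "cal_curve"), length(age) == 1L,
            length(error) == 1L)
  if (error <= 0) stop("error must be > 0")
  slack <- 6 * (error + max(curve$sigma_curve))
  if (age < min(curve$mu) - slack || age > max(curve$mu) + slack)
    stop("age ", age, " BP lies outside the calibration curve support")
  grid <- seq(ceiling(min(curve$cal_bp)), floor(max(curve$cal_bp)),
              by = grid_step)
  mu <- approx(curve$cal_bp, curve$mu, grid)$y
  sg <- approx(curve$cal_bp, curve$sigma_curve, grid)$y
  p <- dnorm(age, mean = mu, sd = sqrt(error^2 + sg^2))
  tot <- sum(p)
  if (tot <= 0 || !is.finite(tot))
    stop("calibrated density is degenerate (age outside curve support?)")
  p <- p / tot
  med <- grid[which(cumsum(p) >= 0.5)[1]]
  structure(list(cal_bp = grid, prob = p, median_cal_bp = med),
            class = "cal_density")
}

#' @export
print.cal_density <- function(x, ...) {
  cat("cal_density: median", x$median_cal_bp, "cal BP on",
      length(x$cal_bp), "grid points\n")
  invisible(x)
}

#' Median calibrated age, vectorised
#'
#' @param age,error vectors of radiocarbon ages and errors.
#' @inheritParams calibrate
#' @return numeric vector of median calibrated ages (cal BP).
#' @export
cal_median <- function(age, error, curve, grid_step = 1) {
  mapply(function(a, e) calibrate(a, e, curve, grid_step)$median_cal_bp,
         age, error)
}

#' Per-site observations from a date table
#'
#' Calibrates every included determination and reduces the table to the
#' observations compared against simulated arrival times.  With mode
#' `earliest_per_site` (default) each site contributes its earliest
#' attestation — the date with the largest median calibrated age — which is
#' the natural reading of "arrival" of the crop package at a place.  With
#' `all_dates` every included determination becomes one observation.
#'
#' @param dates a date table from [load_dates()] (or any data.frame with the
#'   same columns).
#' @param curve a [cal_curve()].
#' @param mode `"earliest_per_site"` or `"all_dates"`.
#' @param grid_step calibration grid step (years).
#' @return data.frame with columns `site`, `lon`, `lat`, `median_cal_bp`,
#'   `n_dates` (number of included dates at the site).
#' @export
site_observations <- function(dates, curve,
                              mode = c("earliest_per_site", "all_dates"),
                              grid_step = 1) {
  mode <- match.arg(mode)
  keep <- dates[dates$included, , drop = FALSE]
  dropped <- setdiff(unique(dates$site), unique(keep$site))
  if (length(dropped))
    warning("site(s) with zero included dates excluded: ",
            paste(dropped, collapse = ", "))
  if (nrow(keep) == 0L)
    return(data.frame(site = character(0), lon = numeric(0),
                      lat = numeric(0), median_cal_bp = numeric(0),
                      n_dates = integer(0)))
  keep$median_cal_bp <- cal_median(keep$c14_age, keep$c14_error, curve,
                                   grid_step)
  if (mode == "all_dates") {
    out <- keep[, c("site", "lon", "lat", "median_cal_bp")]
    out$n_dates <- 1L
    rownames(out) <- NULL
    return(out)
  }
  pieces <- lapply(split(keep, keep$site), function(d) {
    i <- which.max(d$median_cal_bp)
    data.frame(site = d$site[i], lon = d$lon[i], lat = d$lat[i],
               median_cal_bp = d$median_cal_bp[i], n_dates = nrow(d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(-out$median_cal_bp, out$site), , drop = FALSE]
  rownames(out) <- NULL
  out
}
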