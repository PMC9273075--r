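#' Specification of a synthetic dispersal scenario
#'
#' Defines a banded terrain-class raster with known per-class front speeds,
#' an origin, and a set of dated sites, so that the whole pipeline —
#' calibration, cost accumulation, GA fitting — can be exercised against a
#' known truth.  The defaults mimic the real study's geometry: a corridor
#' roughly 4000 km west to east (200 cells of 20 km) crossed by successive
#' biome bands with speeds spanning slow mountain crossings (0.4 km/yr) to
#' fast cultural diffusion (2 km/yr), an origin on the western edge dated to
#' 10000 cal BP, a base speed of 1 km/yr and 60 dated sites.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param cell_size cell edge, km.
#' @param K number of terrain classes (vertical bands, west to east).
#' @param band_widths integer widths (columns) of the K bands; must sum to
#'   `n_cols`.  Default: equal widths.
#' @param true_speeds true per-class front speeds, km/yr (length K).
#' @param origin origin cell `c(row, col)`; default mid-height on the
#'   western edge.
#' @param t0 arrival date at the origin, years cal BP.
#' @param v0 base speed, km/yr.
#' @param n_sites number of dated sites (>= K recommended, so every class
#'   is constrained).
#' @param date_noise_sd Gaussian noise added to observed arrival dates,
#'   years.
#' @param xll,yll,lat0 placement of the grid in the projected frame (km) and
#'   the standard parallel used when back-computing lon/lat for date tables.
#' @param seed RNG seed for site placement and date noise.
#' @return object of class `synth_spec`.
#' @export
synth_spec <- function(n_rows = 100, n_cols = 200, cell_size = 20, K = 4,
                       band_widths = NULL,
                       true_speeds = c(0.4, 0.8, 1.5, 2.0),
                       origin = c(n_rows %/% 2, 1),
                       t0 = 10000, v0 = 1, n_sites = 60,
                       date_noise_sd = 0,
                       xll = 3300, yll = 2200, lat0 = 30, seed = NULL) {
  if (is.null(band_widths)) {
    band_widths <- rep(n_cols %/% K, K)
    band_widths[K] <- band_widths[K] + n_cols - sum(band_widths)
  }
  if (length(band_widths) != K || sum(band_widths) != n_cols)
    stop("band_widths must have length K and sum to n_cols")
  if (length(true_speeds) != K) stop("true_speeds must have length K")
  if (any(true_speeds <= 0)) stop("true_speeds must be positive")
  stopifnot(t0 > 0, v0 > 0, n_sites >= 1, cell_size > 0)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 cell_size = cell_size, K = as.integer(K),
                 band_widths = as.integer(band_widths),
                 true_speeds = true_speeds,
                 true_costs = costs_from_speeds(true_speeds, v0),
                 origin = as.integer(origin), t0 = t0, v0 = v0,
                 n_sites = as.integer(n_sites),
                 date_noise_sd = date_noise_sd,
                 xll = xll, yll = yll, lat0 = lat0, seed = seed),
            class = "synth_spec")
}

#' Banded terrain-class raster for a synthetic scenario
#'
#' Vertical bands of the K classes laid out west to east, mirroring the
#' west-to-east traversal of successive biomes in the real study corridor.
#'
#' @param spec a [synth_spec()].
#' @return a [class_raster()] with legend labels `band_1 .. band_K`.
#' @export
make_banded_raster <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  band_of_col <- rep(seq_len(spec$K), spec$band_widths)
  values <- matrix(rep(band_of_col, each = spec$n_rows),
                   spec$n_rows, spec$n_cols)
  class_raster(values, cell_size = spec$cell_size,
               xll = spec$xll, yll = spec$yll,
               legend = data.frame(class_id = seq_len(spec$K),
                                   label = paste0("band_", seq_len(spec$K)),
                                   stringsAsFactors = FALSE))
}

#' Simulate dated sites on a synthetic raster
#'
#' Samples `n_sites` distinct non-nodata cells uniformly, computes each
#' cell's accumulated cost distance under the true costs, and assigns
#' observed dates `t0 - D / v0 + N(0, date_noise_sd)`.  A site named
#' `"Origin"` is always placed on the origin cell (so fixtures are
#' self-describing and the origin-anchored t0 policy can be exercised).
#'
#' By default the distances come from [reference_cost_distance()] — the
#' igraph-based implementation that shares no code with
#' [accumulate_cost()] — so that recovering the true parameters through the
#' production path is a genuine cross-check (`method = "fast"` switches to
#' the production path for big grids where the check is not needed).
#'
#' @param raster the [make_banded_raster()] output (or any class_raster).
#' @param spec a [synth_spec()].
#' @param method `"reference"` (independent oracle, default) or `"fast"`.
#' @return data.frame `site, x, y, observed_cal_bp, D_true_km, class`.
#' @export
simulate_sites <- function(raster, spec, method = c("reference", "fast")) {
  stopifnot(inherits(raster, "class_raster"), inherits(spec, "synth_spec"))
  method <- match.arg(method)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  open_cells <- which(!is.na(raster$classes))
  if (spec$n_sites > length(open_cells))
    stop("n_sites exceeds the number of non-nodata cells")
  nr <- nrow(raster$classes)
  o_lin <- (spec$origin[2] - 1L) * nr + spec$origin[1]
  pick <- sample(setdiff(open_cells, o_lin), spec$n_sites)
  cells <- c(o_lin, pick)
  row <- (cells - 1L) %% nr + 1L
  col <- (cells - 1L) %/% nr + 1L
  D <- if (method == "reference") {
    Dm <- reference_cost_distance(raster, spec$true_costs, spec$origin)
    Dm[cbind(row, col)]
  } else {
    accumulate_cost(raster, spec$true_costs, origin = spec$origin,
                    targets = cbind(row, col))
  }
  noise <- if (spec$date_noise_sd > 0)
    rnorm(length(cells), 0, spec$date_noise_sd) else 0
  xy <- xy_from_cell(raster, row, col)
  data.frame(site = c("Origin", sprintf("S%03d", seq_len(spec$n_sites))),
             x = xy[, "x"], y = xy[, "y"],
             observed_cal_bp = spec$t0 - D / spec$v0 + noise,
             D_true_km = D,
             class = raster$classes[cbind(row, col)],
             stringsAsFactors = FALSE)
}

#' Back-convert simulated sites to a radiocarbon date table
#'
#' Pushes the observed calendar dates through an invertible calibration
#' curve (`c14_age = mu(observed)`) so the full
#' calibrate-then-median-then-fit path can be exercised end to end on
#' synthetic data.  Coordinates are back-projected to lon/lat so the table
#' satisfies the date-table schema.
#'
#' @param sites output of [simulate_sites()].
#' @param curve an invertible [cal_curve()] (e.g. [toy_cal_curve()]) whose
#'   calendar range covers the observed dates.
#' @param spec the [synth_spec()] (for the projection parameters).
#' @param c14_error reported measurement error assigned to every record,
#'   years.
#' @return data.frame in [load_dates()] format.
#' @export
synth_c14_table <- function(sites, curve, spec, c14_error = 50) {
  stopifnot(inherits(curve, "cal_curve"), inherits(spec, "synth_spec"))
  obs <- sites$observed_cal_bp
  if (any(obs < min(curve$cal_bp)) || any(obs > max(curve$cal_bp)))
    stop("observed dates fall outside the calibration curve range")
  age <- approx(curve$cal_bp, curve$mu, obs)$y
  ll <- unproject_xy(sites$x, sites$y, spec$lat0)
  data.frame(site = sites$site,
             lab_code = sprintf("SYN-%03d", seq_len(nrow(sites)) - 1L),
             c14_age = round(age, 1), c14_error = c14_error,
             lon = round(ll[, "lon"], 5), lat = round(ll[, "lat"], 5),
             affiliation = paste0("synthetic_band_", sites$class),
             included = TRUE, exclusion_reason = "",
             stringsAsFactors = FALSE)
}

#' Write a complete synthetic fixture to disk
#'
#' Produces everything one pipeline run needs: the class raster and legend,
#' a radiocarbon date table derived through an invertible toy calibration
#' curve, the curve itself, and a ready-to-run YAML config naming the
#' `Origin` site present in the dates table.  A written fixture loads back
#' into the in-memory objects exactly.
#'
#' @param dir output directory (created if needed).
#' @param spec a [synth_spec()].
#' @param ga optional list of GA settings stored in the config (defaults:
#'   the published search settings of [ga_config()]).
#' @return invisibly, a named list of the paths written plus the simulated
#'   `sites` data.frame.
#' @export
write_fixture <- function(dir, spec, ga = list()) {
  stopifnot(inherits(spec, "synth_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create fixture directory: ", dir)
  raster <- make_banded_raster(spec)
  sites <- simulate_sites(raster, spec)
  curve <- toy_cal_curve(0, ceiling(spec$t0 * 1.3 / 1000) * 1000, step = 5)
  dates <- synth_c14_table(sites, curve, spec)
  paths <- list(raster = file.path(dir, "raster.asc"),
                legend = file.path(dir, "legend.csv"),
                dates = file.path(dir, "dates.csv"),
                curve = file.path(dir, "curve.14c"),
                config = file.path(dir, "config.yml"))
  write_class_raster(raster, paths$raster, paths$legend)
  write.csv(dates, paths$dates, row.names = FALSE)
  write_cal_curve(curve, paths$curve, comment = "synthetic toy curve")
  cfg <- list(dates = "dates.csv", curve = "curve.14c",
              raster = "raster.asc", legend = "legend.csv",
              origin_site = "Origin", t0 = "origin", v0 = spec$v0,
              aggregation = "earliest_per_site", lat0 = spec$lat0,
              seed = spec$seed, output_dir = "output",
              ga = ga)
  yaml::write_yaml(cfg, paths$config)
  invisible(c(paths, list(sites = sites, spec = spec)))
}

#' Synthetic stand-in for the study's supplementary date table
#'
#' A deterministic, fully synthetic radiocarbon date table with the shape of
#' the real supplementary dataset: 143 included determinations spread over
#' sites running from the Fertile Crescent to peninsular India, with ages
#' declining eastward from ~10,300 to ~3,400 RCYBP, plus the nine published
#' exclusions (their site names, earliest dates, lab codes and exclusion
#' reasons as printed; coordinates approximate) flagged `included = FALSE`.
#' The included records — site names, coordinates, ages — are invented and
#' carry no archaeological information; the table exists so the
#' loading/filtering/reporting path can be tested at realistic size.  A copy
#' ships at `inst/extdata/s1_dates_synthetic.csv`.
#'
#' @return data.frame in [load_dates()] format (152 rows, 143 included).
#' @export
synthetic_s1_table <- function() {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(143L)

  n_sites <- 60L
  per_site <- rep(2L, n_sites)
  per_site[seq_len(143L - sum(per_site))] <- 3L     # 23 sites get 3 dates
  # west -> east transect with latitude drifting south into India
  frac <- seq(0, 1, length.out = n_sites)
  lon <- 36 + 42 * frac + rnorm(n_sites, 0, 0.8)
  lat <- 36 - 20 * frac^1.3 + rnorm(n_sites, 0, 1.2)
  age0 <- 10300 - 6900 * frac + rnorm(n_sites, 0, 150)
  affil <- cut(frac, c(-0.01, 0.12, 0.3, 0.55, 0.7, 0.85, 1.01),
               labels = c("PPNA/PPNB", "Late Neolithic Iran",
                          "Chalcolithic Iran/Baluchistan", "Early Harappan",
                          "Mature Harappan", "Deccan Chalcolithic/Neolithic"))
  site_names <- sprintf("SynthSite-%02d", seq_len(n_sites))
  site_names[1] <- "Dhra"; site_names[2] <- "Mureybet"
  lon[1] <- 35.62; lat[1] <- 31.26; age0[1] <- 10250
  lon[2] <- 38.13; lat[2] <- 36.04; age0[2] <- 10100

  rows <- vector("list", n_sites)
  lab <- 0L
  for (i in seq_len(n_sites)) {
    k <- per_site[i]
    ages <- round(age0[i] - c(0, cumsum(abs(rnorm(k - 1, 120, 60)))))
    errs <- pmax(25L, round(rnorm(k, 75, 30)))
    rows[[i]] <- data.frame(
      site = site_names[i],
      lab_code = sprintf("SYN-%04d", lab + seq_len(k)),
      c14_age = ages, c14_error = errs,
      lon = round(lon[i], 4), lat = round(lat[i], 4),
      affiliation = as.character(affil[i]),
      included = TRUE, exclusion_reason = "",
      stringsAsFactors = FALSE)
    lab <- lab + k
  }
  included <- do.call(rbind, rows)

  excluded <- data.frame(
    site = c("Aq Kupruk", "Mehrgarh", "Budihal", "Hanumantaraopeta",
             "Utnur", "Watgal", "Kodekal", "Bagor",
             "Sannarachamma (Sanganakallu)"),
    lab_code = c("Hy-428", "Beta 1407", "PRL-1532", "R-28680/34", "BM-54",
                 "PRL-1575", "TF-748", "TF-1011&1012", "R-28680/22"),
    c14_age = c(7220, 7328, 7725, 3167, 4125, 4350, 4415, 5240, 5469),
    c14_error = c(100, 290, 210, 40, 150, 100, 105, 80, 35),
    lon = c(66.8, 67.6, 76.7, 79.3, 78.8, 76.5, 76.9, 74.4, 76.9),
    lat = c(36.1, 29.4, 16.4, 14.7, 16.5, 15.9, 16.5, 25.4, 15.1),
    affiliation = c("Aceramic Neolithic", "Aceramic Neolithic",
                    rep("Ashmound Tradition", 2), rep("Ashmound Tradition", 3),
                    "Mesolithic", "Ashmound Tradition"),
    included = FALSE,
    exclusion_reason = c(
      "Pastoralism without evidence for the founder crops",
      "Still isolated",
      rep("Pastoralism with local plant domestication (Ashmound Tradition)", 2),
      rep("Pastoralism with local plant domestication (Ashmound Tradition)", 3),
      "Mesolithic with domesticated animals",
      "Pastoralism with local plant domestication (Ashmound Tradition)"),
    stringsAsFactors = FALSE)

  out <- rbind(included, excluded)
  rownames(out) <- NULL
  out
}
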