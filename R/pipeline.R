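#' Build a pipeline run configuration
#'
#' @param dates,curve,raster paths to the date table CSV, the calibration
#'   curve (IntCal CSV format) and the terrain-class raster (ESRI ASCII).
#' @param legend optional path to the raster legend CSV (`class_id,label`).
#' @param origin_site name of the origin site; must be present in the date
#'   table (the published analysis uses Mureybet, with Dhra as the
#'   documented alternative — a config change only).
#' @param t0 either the string `"origin"` (default: the arrival date at the
#'   origin is the median calibrated age of the origin site's earliest
#'   included date) or a fixed number of years cal BP.
#' @param v0 base front speed, km/yr.
#' @param aggregation `"earliest_per_site"` or `"all_dates"`; see
#'   [site_observations()].
#' @param lat0 standard parallel for projecting site lon/lat into the
#'   raster's km frame (see [project_lonlat()]).
#' @param ga list of [ga_config()] overrides (defaults are the published
#'   search settings).
#' @param seed integer seed for the GA (reproducible runs).
#' @param output_dir directory for the artifact set.
#' @return object of class `run_config`.
#' @export
run_config <- function(dates, curve, raster, legend = NULL, origin_site,
                       t0 = "origin", v0 = 1,
                       aggregation = c("earliest_per_site", "all_dates"),
                       lat0 = 30, ga = list(), seed = NULL,
                       output_dir = "cropwave_output") {
  aggregation <- match.arg(aggregation)
  for (p in c(dates, curve, raster, legend))
    if (!file.exists(p)) stop("configured path does not exist: ", p)
  if (!identical(t0, "origin") && !(is.numeric(t0) && t0 > 0))
    stop("t0 must be \"origin\" or a positive number (years cal BP)")
  structure(list(dates = dates, curve = curve, raster = raster,
                 legend = legend, origin_site = origin_site, t0 = t0,
                 v0 = v0, aggregation = aggregation, lat0 = lat0,
                 ga = ga, seed = seed, output_dir = output_dir),
            class = "run_config")
}

#' Read a pipeline run configuration from a YAML file
#'
#' Relative paths in the file are resolved against the file's directory.
#'
#' @param path YAML file with the fields of [run_config()].
#' @param output_dir optional override of the configured output directory.
#' @return object of class `run_config`.
#' @export
read_run_config <- function(path, output_dir = NULL) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) if (is.null(p) || file.exists(p)) p else file.path(base, p)
  cfg <- run_config(
    dates = rel(y$dates), curve = rel(y$curve), raster = rel(y$raster),
    legend = rel(y$legend),
    origin_site = y$origin_site,
    t0 = if (is.null(y$t0)) "origin" else y$t0,
    v0 = if (is.null(y$v0)) 1 else y$v0,
    aggregation = if (is.null(y$aggregation)) "earliest_per_site"
                  else y$aggregation,
    lat0 = if (is.null(y$lat0)) 30 else y$lat0,
    ga = if (is.null(y$ga)) list() else y$ga,
    seed = y$seed,
    output_dir = if (is.null(output_dir))
      (if (is.null(y$output_dir)) "cropwave_output"
       else file.path(base, y$output_dir))
      else output_dir)
  attr(cfg, "config_path") <- normalizePath(path)
  cfg
}

#' Report on excluded radiocarbon determinations
#'
#' @param dates a date table from [load_dates()].
#' @return data.frame of the `included = FALSE` records (site, lab code,
#'   age, error, reason), with a table of counts by reason in
#'   `attr(x, "counts")`.
#' @export
exclusion_report <- function(dates) {
  ex <- dates[!dates$included,
              c("site", "lab_code", "c14_age", "c14_error",
                "exclusion_reason"), drop = FALSE]
  rownames(ex) <- NULL
  attr(ex, "counts") <- table(reason = ex$exclusion_reason)
  ex
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full dispersal-speed analysis
#'
#' Orchestrates calibrate -> friction surface -> GA fit -> report.  Writes
#' the complete artifact set to `config$output_dir`:
#' \describe{
#'   \item{observations.csv}{per-site median calibrated dates used in the
#'     fit (`site,lon,lat,median_cal_bp,n_dates`).}
#'   \item{exclusions.csv}{excluded determinations with reasons.}
#'   \item{speeds.csv}{fitted per-class costs and speeds
#'     (`class_id,label,cost,speed_km_per_yr`).}
#'   \item{predicted_vs_observed.csv}{per-site distance, simulated arrival,
#'     observed median and residual.}
#'   \item{arrival_times.asc}{simulated arrival-time raster, years cal BP.}
#'   \item{arrival_contours.csv}{arrival isochrones every 1000 years
#'     (`level,line,x,y`).}
#'   \item{speed_map.asc}{local front speed per cell, km/yr.}
#'   \item{ga_trace.csv}{per-generation best and mean RMSE.}
#'   \item{manifest.json}{seed, config (and its MD5 when read from a
#'     file), package version, counts.}
#' }
#'
#' @param config a [run_config()] or path to a YAML config file.
#' @return invisibly, a list with the `ga_fit`, the observation table, the
#'   exclusion report and the named artifact paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  dates <- stage("load dates", load_dates(config$dates))
  if (!config$origin_site %in% dates$site)
    stop("pipeline stage 'load dates' failed: origin site '",
         config$origin_site, "' absent from the date table", call. = FALSE)
  excl <- stage("exclusion report", exclusion_report(dates))

  curve <- stage("load curve", read_cal_curve(config$curve))
  obs <- stage("calibrate",
               site_observations(dates, curve, mode = config$aggregation))

  raster <- stage("load raster",
                  read_class_raster(config$raster, config$legend))

  xy <- project_lonlat(obs$lon, obs$lat, config$lat0)
  sites <- data.frame(site = obs$site, x = xy[, "x"], y = xy[, "y"],
                      observed_cal_bp = obs$median_cal_bp,
                      stringsAsFactors = FALSE)

  o_row <- which(obs$site == config$origin_site)
  if (!length(o_row))
    stop("pipeline stage 'origin' failed: origin site '", config$origin_site,
         "' has no included dates", call. = FALSE)
  o_row <- o_row[1]
  t0 <- if (identical(config$t0, "origin")) obs$median_cal_bp[o_row]
        else config$t0
  sim <- stage("origin", sim_config(t0 = t0, v0 = config$v0,
                                    origin_xy = c(sites$x[o_row],
                                                  sites$y[o_row])))

  ga <- do.call(ga_config, config$ga)
  if (!is.null(config$seed)) ga$seed <- config$seed
  fit <- stage("genetic algorithm", run_ga(raster, sites, sim, ga))

  paths <- c(observations = "observations.csv", exclusions = "exclusions.csv",
             speeds = "speeds.csv",
             predicted = "predicted_vs_observed.csv",
             arrival = "arrival_times.asc",
             contours = "arrival_contours.csv",
             speed_map = "speed_map.asc", trace = "ga_trace.csv",
             manifest = "manifest.json")
  paths <- setNames(file.path(out, paths), names(paths))

  stage("report", {
    write.csv(obs, paths[["observations"]], row.names = FALSE)
    write.csv(excl, paths[["exclusions"]], row.names = FALSE)
    speeds <- data.frame(class_id = raster$legend$class_id,
                         label = raster$legend$label,
                         cost = fit$best_costs,
                         speed_km_per_yr = fit$best_speeds)
    write.csv(speeds, paths[["speeds"]], row.names = FALSE)
    write.csv(fit$fit$residuals, paths[["predicted"]], row.names = FALSE)
    write.csv(fit$trace, paths[["trace"]], row.names = FALSE)

    surf <- accumulate_cost(raster, fit$best_costs,
                            origin_xy = c(sites$x[o_row], sites$y[o_row]))
    arrival <- t0 - surf$D / config$v0
    write_surface(surf, paths[["arrival"]], values = arrival)
    write.csv(arrival_contours(arrival, raster, every = 1000),
              paths[["contours"]], row.names = FALSE)
    speed_map <- matrix(fit$best_speeds[raster$classes],
                        nrow(raster$classes), ncol(raster$classes))
    write_surface(speed_map, paths[["speed_map"]],
                  cell_size = raster$cell_size,
                  xll = raster$xll, yll = raster$yll)

    manifest <- list(
      package = "cropwave",
      version = as.character(packageVersion("cropwave")),
      seed = if (is.null(ga$seed)) NA else ga$seed,
      config = unclass(config),
      config_md5 = if (!is.null(attr(config, "config_path")))
        unname(tools::md5sum(attr(config, "config_path"))) else NA,
      origin_site = config$origin_site, t0 = t0,
      n_dates_loaded = nrow(dates), n_included = sum(dates$included),
      n_excluded = nrow(excl), n_observations = nrow(obs),
      best_rmse = fit$best_rmse)
    jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                         pretty = TRUE, digits = NA, null = "null")
  })

  invisible(list(fit = fit, observations = obs, exclusions = excl,
                 t0 = t0, paths = as.list(paths)))
}

# Isochrones of the arrival surface: contour lines every `every` years.
arrival_contours <- function(arrival, raster, every = 1000) {
  nr <- nrow(arrival); nc <- ncol(arrival)
  cs <- raster$cell_size
  xs <- raster$xll + (seq_len(nc) - 0.5) * cs
  ys <- raster$yll + (seq_len(nr) - 0.5) * cs
  z <- t(arrival[nr:1, , drop = FALSE])      # x along rows, y ascending
  rng <- range(arrival, na.rm = TRUE, finite = TRUE)
  levels <- seq(ceiling(rng[1] / every) * every, floor(rng[2] / every) * every,
                by = every)
  if (!length(levels))
    return(data.frame(level = numeric(0), line = integer(0),
                      x = numeric(0), y = numeric(0)))
  cl <- contourLines(xs, ys, z, levels = levels)
  if (!length(cl))
    return(data.frame(level = numeric(0), line = integer(0),
                      x = numeric(0), y = numeric(0)))
  do.call(rbind, lapply(seq_along(cl), function(i)
    data.frame(level = cl[[i]]$level, line = i,
               x = cl[[i]]$x, y = cl[[i]]$y)))
}
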