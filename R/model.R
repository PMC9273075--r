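#' Simulation configuration for the arrival-time model
#'
#' @param t0 arrival date at the origin (years cal BP, > 0); the front is
#'   assumed to leave the origin at `t0` and later arrivals have smaller
#'   cal BP values.
#' @param v0 base front speed in km/yr (default 1, the canonical
#'   wave-of-advance scale); local speed in a class with cost c is `v0 / c`.
#' @param origin origin cell `c(row, col)` in the raster, or
#' @param origin_xy origin map coordinates `c(x, y)` (km, raster CRS).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(t0, v0 = 1, origin = NULL, origin_xy = NULL) {
  stopifnot(is.numeric(t0), length(t0) == 1L, t0 > 0,
            is.numeric(v0), length(v0) == 1L, v0 > 0)
  if (is.null(origin) && is.null(origin_xy))
    stop("supply `origin` (row, col) or `origin_xy`")
  structure(list(t0 = t0, v0 = v0, origin = origin, origin_xy = origin_xy),
            class = "sim_config")
}

#' Predicted arrival time from accumulated distance
#'
#' The linear front model: `t = t0 - D / v0`, so a cell D km of weighted
#' distance from the origin is reached D/v0 years after the start.
#' Predictions that run past the present (t <= 0 cal BP) are kept — the site
#' still contributes its residual — but flagged with a warning.
#'
#' @param D accumulated weighted distance(s) in km (>= 0).
#' @param config a [sim_config()] (only `t0` and `v0` are used), or a list
#'   with `t0` and `v0`.
#' @return predicted arrival date(s), years cal BP.
#' @examples
#' predict_arrival(4000, sim_config(10000, 1, origin = c(1, 1)))  # 6000
#' @export
predict_arrival <- function(D, config) {
  stopifnot(all(D >= 0, na.rm = TRUE))
  t <- config$t0 - D / config$v0
  n_bp <- sum(t <= 0, na.rm = TRUE)
  if (n_bp > 0)
    warning(n_bp, " predicted arrival(s) beyond the present (<= 0 cal BP)")
  t
}

#' Per-class speeds implied by a cost vector
#'
#' Friction semantics: cost 1 is neutral (the front moves at the base
#' speed), cost 0.5 means the class is crossed twice as fast, cost 2 halves
#' the propagation speed.  Hence `v[k] = v0 / cost[k]`.
#'
#' @param costs per-class friction costs (> 0).
#' @param v0 base speed, km/yr.
#' @return per-class speeds, km/yr.
#' @examples
#' speeds_from_costs(c(0.5, 1, 2))   # 2, 1, 0.5 km/yr
#' @export
speeds_from_costs <- function(costs, v0 = 1) {
  stopifnot(all(costs > 0), v0 > 0)
  v0 / costs
}

#' Cost vector implied by per-class speeds (inverse of [speeds_from_costs()])
#' @param speeds per-class speeds, km/yr (> 0).
#' @param v0 base speed, km/yr.
#' @export
costs_from_speeds <- function(speeds, v0 = 1) {
  stopifnot(all(speeds > 0), v0 > 0)
  v0 / speeds
}

# Internal: resolve site cells and observations against a raster once, so
# repeated scoring (the GA) does not redo coordinate lookups.  Returns NULL
# usable set as an error: scoring needs at least one site.
prepare_sites <- function(raster, sites, config) {
  stopifnot(all(c("x", "y", "observed_cal_bp") %in% names(sites)))
  rc <- cell_from_xy(raster, sites$x, sites$y)
  inside <- !is.na(rc[, "row"])
  on_data <- inside
  on_data[inside] <- !is.na(raster$classes[rc[inside, , drop = FALSE]])
  if (any(!on_data))
    warning(sum(!on_data), " site(s) outside the extent or on nodata; ",
            "excluded from fitness")
  if (!any(on_data)) stop("no usable sites: all outside extent or on nodata")
  origin <- config$origin
  if (is.null(origin)) {
    origin <- cell_from_xy(raster, config$origin_xy[1], config$origin_xy[2])[1, ]
    if (anyNA(origin)) stop("origin coordinates fall outside the raster")
  }
  list(targets = rc[on_data, , drop = FALSE],
       observed = sites$observed_cal_bp[on_data],
       site = if ("site" %in% names(sites)) sites$site[on_data] else
         seq_len(sum(on_data)),
       usable = on_data,
       origin = as.integer(origin))
}

#' Score a cost vector against observed site dates
#'
#' Accumulates cost distance from the origin under `costs`, predicts an
#' arrival date at every usable site and returns the root-mean-square error
#' (years) against the observed median calibrated dates.  Sites outside the
#' raster, on nodata or unreachable are excluded from the mean and counted.
#'
#' @param costs per-class friction costs (length `raster$K`).
#' @param raster a [class_raster()].
#' @param sites data.frame with columns `x`, `y`, `observed_cal_bp` and
#'   optionally `site`.
#' @param config a [sim_config()].
#' @param clamp_floor minimum admissible cost (see [accumulate_cost()]).
#' @return object of class `fit_score`: list with `rmse` (years), `n_used`,
#'   `n_excluded`, and `residuals` — a data.frame `site, D_km,
#'   predicted_cal_bp, observed_cal_bp, residual` (residual = predicted −
#'   observed).
#' @examples
#' r <- class_raster(matrix(1L, 10, 30), cell_size = 10)
#' cfg <- sim_config(t0 = 8000, v0 = 1, origin = c(5, 1))
#' sites <- data.frame(x = c(95, 255), y = c(55, 55),
#'                     observed_cal_bp = c(7910, 7750))
#' score(1, r, sites, cfg)$rmse
#' @export
score <- function(costs, raster, sites, config, clamp_floor = 0.01) {
  prep <- prepare_sites(raster, sites, config)
  D <- accumulate_cost(raster, costs, origin = prep$origin,
                       targets = prep$targets, clamp_floor = clamp_floor)
  reachable <- is.finite(D)
  if (any(!reachable))
    warning(sum(!reachable), " site(s) unreachable from the origin; excluded")
  if (!any(reachable)) stop("no usable sites: none reachable from the origin")
  D <- D[reachable]
  obs <- prep$observed[reachable]
  pred <- suppressWarnings(predict_arrival(D, config))
  if (any(pred <= 0))
    warning(sum(pred <= 0), " predicted arrival(s) beyond the present; ",
            "kept with their residuals")
  res <- pred - obs
  structure(list(
    rmse = sqrt(mean(res^2)),
    n_used = length(res),
    n_excluded = nrow(sites) - length(res),
    residuals = data.frame(site = prep$site[reachable], D_km = D,
                           predicted_cal_bp = pred, observed_cal_bp = obs,
                           residual = res, stringsAsFactors = FALSE)),
    class = "fit_score")
}

#' @export
print.fit_score <- function(x, ...) {
  cat("fit_score: RMSE", round(x$rmse, 1), "yr over", x$n_used,
      "site(s)", if (x$n_excluded) paste0("(", x$n_excluded, " excluded)"),
      "\n")
  invisible(x)
}
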