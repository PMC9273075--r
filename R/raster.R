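#' Terrain-class raster
#'
#' A single-band integer raster assigning each cell a terrain (biome) class,
#' the spatial support of the friction surface.  Cells are square and the
#' coordinate system is assumed projected, with `cell_size` in kilometres, so
#' that accumulated cost distances come out in km and divide cleanly by a
#' front speed in km/yr.  Class ids are remapped on construction to a dense
#' index `1..K`; the original ids and labels are kept in the legend.
#'
#' @param values integer matrix of class ids; row 1 is the northern edge.
#'   `NA` marks nodata (impassable) cells.
#' @param cell_size cell edge length in km (> 0).
#' @param xll,yll map coordinates (km) of the lower-left corner of the grid.
#' @param legend optional `data.frame(class_id, label)` describing the ids
#'   present in `values`.  Ids found in `values` but missing from the legend
#'   are an error.  When omitted, a legend is built from the ids present.
#' @return an object of class `class_raster`: a list with elements `classes`
#'   (dense 1..K integer matrix), `K`, `legend`, `cell_size`, `xll`, `yll`.
#' @examples
#' r <- class_raster(matrix(1L, 4, 6), cell_size = 10)
#' r$K
#' @export
class_raster <- function(values, cell_size, xll = 0, yll = 0, legend = NULL) {
  if (!is.matrix(values)) stop("`values` must be a matrix of class ids")
  storage.mode(values) <- "integer"
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("`cell_size` must be a single positive number (km)")
  ids <- sort(unique(values[!is.na(values)]))
  if (length(ids) == 0L) stop("raster contains no non-nodata cells")
  if (is.null(legend)) {
    legend <- data.frame(class_id = ids,
                         label = paste0("class_", ids),
                         stringsAsFactors = FALSE)
  } else {
    legend <- as.data.frame(legend)
    if (!all(c("class_id", "label") %in% names(legend)))
      stop("legend must have columns `class_id` and `label`")
    missing_ids <- setdiff(ids, legend$class_id)
    if (length(missing_ids))
      stop("raster contains class ids absent from the legend: ",
           paste(missing_ids, collapse = ", "))
  }
  dense <- matrix(match(values, legend$class_id), nrow(values), ncol(values))
  structure(list(classes = dense,
                 K = nrow(legend),
                 legend = legend,
                 cell_size = as.numeric(cell_size),
                 xll = as.numeric(xll), yll = as.numeric(yll)),
            class = "class_raster")
}

#' @export
print.class_raster <- function(x, ...) {
  cat("class_raster:", nrow(x$classes), "x", ncol(x$classes),
      "cells of", x$cell_size, "km,", x$K, "classes\n")
  invisible(x)
}

#' @export
dim.class_raster <- function(x) dim(x$classes)

# --- ESRI ASCII grid I/O ----------------------------------------------------
# Plain-text single-band format: a 6-line header (ncols, nrows, xllcorner,
# yllcorner, cellsize, NODATA_value) followed by rows of values, northern row
# first.  Cells are square by construction.

read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  head_lines <- readLines(path, n = 6L)
  kv <- strsplit(trimws(head_lines), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(vapply(kv, `[`, "", 2L))
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% keys))
    stop("not an ESRI ASCII grid (missing header keys): ", path)
  nodata <- if ("nodata_value" %in% keys) vals[["nodata_value"]] else -9999
  body <- scan(path, what = numeric(), skip = 6L, quiet = TRUE)
  nr <- as.integer(vals[["nrows"]]); nc <- as.integer(vals[["ncols"]])
  if (length(body) != nr * nc)
    stop("grid body has ", length(body), " values, expected ", nr * nc)
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA
  list(values = m, cell_size = vals[["cellsize"]],
       xll = vals[["xllcorner"]], yll = vals[["yllcorner"]])
}

write_ascii_grid <- function(values, cell_size, xll, yll, path,
                             nodata = -9999) {
  m <- values
  m[is.na(m)] <- nodata
  hdr <- c(paste("ncols", ncol(m)), paste("nrows", nrow(m)),
           paste("xllcorner", format(xll, scientific = FALSE)),
           paste("yllcorner", format(yll, scientific = FALSE)),
           paste("cellsize", format(cell_size, scientific = FALSE)),
           paste("NODATA_value", nodata))
  rows <- apply(m, 1L, paste, collapse = " ")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a terrain-class raster from an ESRI ASCII grid
#'
#' @param path path to the `.asc` grid (integer class ids; the header's
#'   `NODATA_value` marks impassable cells).
#' @param legend optional legend `data.frame(class_id, label)` or path to a
#'   legend CSV with those columns.
#' @return a [class_raster()] object.
#' @export
read_class_raster <- function(path, legend = NULL) {
  g <- read_ascii_grid(path)
  if (any(abs(g$values - round(g$values)) > 1e-9, na.rm = TRUE))
    stop("class raster contains non-integer values: ", path)
  if (is.character(legend)) {
    legend <- read.csv(legend, stringsAsFactors = FALSE)
  }
  class_raster(round(g$values), cell_size = g$cell_size,
               xll = g$xll, yll = g$yll, legend = legend)
}

#' Write a terrain-class raster (and optionally its legend) to disk
#'
#' Writes the original class ids (via the legend), not the internal dense
#' index, so a write/read round trip reproduces the raster exactly.
#'
#' @param x a [class_raster()].
#' @param path output `.asc` path.
#' @param legend_path optional path for the legend CSV (`class_id,label`).
#' @export
write_class_raster <- function(x, path, legend_path = NULL) {
  stopifnot(inherits(x, "class_raster"))
  orig <- matrix(x$legend$class_id[x$classes], nrow(x$classes), ncol(x$classes))
  write_ascii_grid(orig, x$cell_size, x$xll, x$yll, path)
  if (!is.null(legend_path))
    write.csv(x$legend, legend_path, row.names = FALSE)
  invisible(path)
}

# --- cell / coordinate helpers ---------------------------------------------

#' Locate the cell containing a map coordinate
#'
#' @param raster a [class_raster()] or `accum_surface`.
#' @param x,y map coordinates (km, same CRS as the raster).
#' @return integer matrix with columns `row`, `col`; `NA` rows for points
#'   outside the raster extent.
#' @export
cell_from_xy <- function(raster, x, y) {
  nr <- nrow(raster$classes %||% raster$D)
  nc <- ncol(raster$classes %||% raster$D)
  cs <- raster$cell_size
  col <- floor((x - raster$xll) / cs) + 1L
  row <- nr - floor((y - raster$yll) / cs)
  bad <- col < 1L | col > nc | row < 1L | row > nr
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Map coordinates of cell centres
#'
#' @param raster a [class_raster()] or `accum_surface`.
#' @param row,col cell indices (row 1 = northern edge).
#' @return matrix with columns `x`, `y` (km).
#' @export
xy_from_cell <- function(raster, row, col) {
  nr <- nrow(raster$classes %||% raster$D)
  cs <- raster$cell_size
  cbind(x = raster$xll + (col - 0.5) * cs,
        y = raster$yll + (nr - row + 0.5) * cs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 0-based linear index (column-major) used by the C++ core
linear_index0 <- function(nr, row, col) (col - 1L) * nr + (row - 1L)

# --- cost accumulation ------------------------------------------------------

#' Accumulated cost distance from an origin cell
#'
#' Computes single-source shortest-path distances on the 16-direction grid
#' graph (8 queen neighbours plus 8 knight's-move neighbours, step lengths
#' \{1, sqrt(2), sqrt(5)\} cells).  The edge weight between adjacent cells a
#' and b is `euclid(a, b) * (f(a) + f(b)) / 2`, where `f(c)` is the friction
#' cost of c's terrain class.  With all costs equal to 1 the result is plain
#' (knight's-move) Euclidean-ish distance in km; a class cost of 0.5 halves
#' the effective distance through that class (the front crosses it twice as
#' fast), a cost of 2 doubles it.
#'
#' @param raster a [class_raster()].
#' @param costs numeric vector of per-class friction costs, length
#'   `raster$K`, each >= `clamp_floor`.
#' @param origin origin cell as `c(row, col)`, or map coordinates via
#'   `origin_xy`.
#' @param origin_xy alternative to `origin`: map coordinates `c(x, y)` whose
#'   containing cell becomes the origin.
#' @param targets optional integer matrix with columns `row`, `col`; when
#'   given, only the distances to these cells are returned (as a numeric
#'   vector, `Inf` for unreachable cells) and the search stops early.
#' @param clamp_floor minimum admissible cost (default 0.01); smaller or
#'   non-positive costs break the shortest-path semantics (they would mean
#'   infinite local speed) and are an error here — clamp upstream.
#' @return with `targets`: a numeric vector of distances (km).  Otherwise an
#'   object of class `accum_surface`: list with `D` (matrix, km; `NA` on
#'   nodata, `Inf` where unreachable), `origin`, `cell_size`, `xll`, `yll`.
#' @examples
#' r <- class_raster(matrix(1L, 5, 5), cell_size = 1)
#' s <- accumulate_cost(r, costs = 1, origin = c(3, 3))
#' s$D[3, 4]      # orthogonal neighbour: 1 km
#' s$D[1, 2]      # knight neighbour: sqrt(5) km
#' @export
accumulate_cost <- function(raster, costs, origin = NULL, origin_xy = NULL,
                            targets = NULL, clamp_floor = 0.01) {
  stopifnot(inherits(raster, "class_raster"))
  costs <- as.numeric(costs)
  if (length(costs) != raster$K)
    stop("`costs` must have one entry per class (K = ", raster$K, ")")
  if (any(!is.finite(costs)) || any(costs < clamp_floor))
    stop("all costs must be finite and >= ", clamp_floor,
         " (clamp before calling)")
  nr <- nrow(raster$classes)
  if (is.null(origin)) {
    if (is.null(origin_xy)) stop("supply `origin` (row, col) or `origin_xy`")
    origin <- cell_from_xy(raster, origin_xy[1], origin_xy[2])[1, ]
    if (anyNA(origin)) stop("origin coordinates fall outside the raster")
  }
  origin <- as.integer(origin)
  if (is.na(raster$classes[origin[1], origin[2]]))
    stop("origin cell is nodata")
  o0 <- linear_index0(nr, origin[1], origin[2])
  if (!is.null(targets)) {
    t0 <- linear_index0(nr, as.integer(targets[, 1]), as.integer(targets[, 2]))
    return(dijkstra_grid_cpp(raster$classes, costs, o0, as.integer(t0),
                             raster$cell_size))
  }
  d <- dijkstra_grid_cpp(raster$classes, costs, o0, integer(0),
                         raster$cell_size)
  structure(list(D = matrix(d, nr, ncol(raster$classes)),
                 origin = origin,
                 cell_size = raster$cell_size,
                 xll = raster$xll, yll = raster$yll),
            class = "accum_surface")
}

#' @export
print.accum_surface <- function(x, ...) {
  cat("accum_surface:", nrow(x$D), "x", ncol(x$D), "cells; origin (",
      x$origin[1], ",", x$origin[2], "); max D",
      round(max(x$D[is.finite(x$D)]), 1), "km\n")
  invisible(x)
}

#' Sample an accumulated-cost surface at site locations
#'
#' Nearest-cell (containing-cell) lookup; distance is a path quantity so no
#' interpolation across class boundaries is attempted.  Sites outside the
#' raster extent or on nodata/unreachable cells are flagged `usable = FALSE`
#' (with a warning) rather than being fatal.
#'
#' @param surface an `accum_surface` from [accumulate_cost()].
#' @param sites data.frame with numeric columns `x` and `y` (km, raster CRS).
#' @return `sites` with added columns `row`, `col`, `D_km`, `usable`.
#' @export
sample_surface <- function(surface, sites) {
  stopifnot(inherits(surface, "accum_surface"),
            all(c("x", "y") %in% names(sites)))
  rc <- cell_from_xy(surface, sites$x, sites$y)
  D <- rep(NA_real_, nrow(sites))
  inside <- !is.na(rc[, "row"])
  D[inside] <- surface$D[cbind(rc[inside, "row"], rc[inside, "col"])]
  usable <- inside & !is.na(D) & is.finite(D)
  if (any(!usable))
    warning(sum(!usable), " site(s) outside the extent or on ",
            "nodata/unreachable cells; excluded from fitness")
  out <- sites
  out$row <- rc[, "row"]; out$col <- rc[, "col"]
  out$D_km <- D
  out$usable <- usable
  out
}

#' Write a numeric surface (distances, arrival times, speeds) as an ASCII grid
#'
#' @param surface an `accum_surface`, or a plain numeric matrix (then
#'   `cell_size`, `xll`, `yll` must be given).
#' @param path output path.
#' @param values optional replacement matrix with the surface's geometry
#'   (e.g. arrival times derived from `surface$D`).
#' @param cell_size,xll,yll geometry when `surface` is a bare matrix.
#' @export
write_surface <- function(surface, path, values = NULL,
                          cell_size = NULL, xll = 0, yll = 0) {
  if (inherits(surface, "accum_surface")) {
    m <- if (is.null(values)) surface$D else values
    m[!is.finite(m)] <- NA
    write_ascii_grid(m, surface$cell_size, surface$xll, surface$yll, path)
  } else {
    stopifnot(is.matrix(surface), !is.null(cell_size))
    m <- surface
    m[!is.finite(m)] <- NA
    write_ascii_grid(m, cell_size, xll, yll, path)
  }
  invisible(path)
}
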