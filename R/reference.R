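#' Reference cost-distance by explicit graph enumeration
#'
#' Independent implementation of the accumulated-cost computation: the full
#' 16-neighbour edge list is enumerated in R and handed to
#' [igraph::distances()].  Deliberately shares no code with
#' [accumulate_cost()]'s grid search, so the two can cross-check each other;
#' the synthetic-data generator uses this path in oracle mode for the same
#' reason.  Much slower than [accumulate_cost()] — intended for tests,
#' fixtures and small grids.
#'
#' @param raster a [class_raster()].
#' @param costs per-class friction costs (length `raster$K`).
#' @param origin origin cell `c(row, col)`.
#' @param knight include the 8 knight's-move edges (default TRUE); with
#'   FALSE only the 8-cell queen neighbourhood is used.
#' @return matrix of distances (km); `NA` on nodata, `Inf` where unreachable.
#' @export
reference_cost_distance <- function(raster, costs, origin, knight = TRUE) {
  stopifnot(inherits(raster, "class_raster"))
  nr <- nrow(raster$classes); nc <- ncol(raster$classes)
  n <- nr * nc
  f <- costs[raster$classes]           # per-cell friction, NA on nodata
  offs <- list(c(0, 1, 1), c(1, 0, 1),
               c(1, 1, sqrt(2)), c(1, -1, sqrt(2)))
  if (knight)
    offs <- c(offs, list(c(1, 2, sqrt(5)), c(2, 1, sqrt(5)),
                         c(1, -2, sqrt(5)), c(2, -1, sqrt(5))))
  ea <- integer(0); eb <- integer(0); ew <- numeric(0)
  for (o in offs) {
    dr <- o[1]; dc <- o[2]; len <- o[3]
    if (nr - dr < 1L) next
    c_lo <- max(1L, 1L - dc); c_hi <- min(nc, nc - dc)
    if (c_hi < c_lo) next
    rows <- seq_len(nr - dr)
    cols <- c_lo:c_hi
    a <- as.vector(outer(rows, (cols - 1L) * nr, `+`))
    b <- a + dc * nr + dr
    w <- len * raster$cell_size * (f[a] + f[b]) / 2
    keep <- !is.na(w)
    ea <- c(ea, a[keep]); eb <- c(eb, b[keep]); ew <- c(ew, w[keep])
  }
  g <- igraph::make_graph(rbind(ea, eb), n = n, directed = FALSE)
  v0 <- (origin[2] - 1L) * nr + origin[1]
  if (is.na(f[v0])) stop("origin cell is nodata")
  d <- igraph::distances(g, v = v0, weights = ew, algorithm = "dijkstra")
  m <- matrix(as.numeric(d), nr, nc)
  m[is.na(f)] <- NA
  m
}
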