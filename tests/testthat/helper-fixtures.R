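# Shared fixture builders.  Everything is generated in code; no binary data.

# Uniform one-class raster.
uniform_raster <- function(nr = 5, nc = 5, cell_size = 1) {
  class_raster(matrix(1L, nr, nc), cell_size = cell_size)
}

# Random multi-class raster with a full legend (so K is fixed even when a
# class happens to be absent) and optional nodata holes.
random_raster <- function(nr, nc, K, cell_size = 1, p_nodata = 0) {
  vals <- matrix(sample.int(K, nr * nc, replace = TRUE), nr, nc)
  if (p_nodata > 0) {
    holes <- matrix(runif(nr * nc) < p_nodata, nr, nc)
    vals[holes] <- NA
    if (all(is.na(vals))) vals[1, 1] <- 1L
  }
  class_raster(vals, cell_size = cell_size,
               legend = data.frame(class_id = seq_len(K),
                                   label = paste0("c", seq_len(K))))
}

# Identity calibration curve (mu(t) = t, no curve error).
identity_curve <- function(cal_min = 0, cal_max = 12000, step = 5) {
  toy_cal_curve(cal_min, cal_max, step = step)
}

# A small synthetic scenario that keeps GA runs fast in unit tests.
small_spec <- function(...) {
  synth_spec(n_rows = 20, n_cols = 60, cell_size = 20, K = 3,
             true_speeds = c(0.5, 1, 2), n_sites = 24, t0 = 8000, ...)
}
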