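test_that("ASCII grid and legend round-trip through write/read", {
  set.seed(42)
  vals <- matrix(sample.int(5L, 100 * 200, replace = TRUE), 100, 200)
  vals[3, 7] <- NA
  leg <- data.frame(class_id = 1:5,
                    label = c("moist forest", "dry forest", "temperate",
                              "desert", "indus"))
  r <- class_raster(vals, cell_size = 20, xll = 100, yll = -50, legend = leg)
  expect_equal(r$K, 5L)
  f <- withr::local_tempfile(fileext = ".asc")
  fl <- withr::local_tempfile(fileext = ".csv")
  write_class_raster(r, f, fl)
  got <- read_class_raster(f, fl)
  expect_equal(got$classes, r$classes)
  expect_equal(got$legend, r$legend)
  expect_equal(got$cell_size, 20)
  expect_equal(got$xll, 100)
  expect_true(is.na(got$classes[3, 7]))

  # one-class raster
  r1 <- uniform_raster(4, 6)
  expect_equal(r1$K, 1L)

  # an id absent from the legend is an error
  expect_error(class_raster(vals, 20, legend = leg[1:3, ]), "absent")
})

test_that("single-edge geometry: orthogonal 1 km, knight sqrt(5) km", {
  r <- uniform_raster(5, 5, cell_size = 1)
  s <- accumulate_cost(r, costs = 1, origin = c(3, 3))
  expect_equal(s$D[3, 3], 0)
  expect_equal(s$D[3, 4], 1)
  expect_equal(s$D[2, 2], sqrt(2))
  expect_equal(s$D[1, 2], sqrt(5))   # knight's move
  expect_true(all(s$D >= 0))
})

test_that("cost semantics and homogeneity: cost 0.5 halves every distance", {
  set.seed(7)
  r <- random_raster(12, 18, K = 3, cell_size = 2)
  o <- c(5, 4)
  D1 <- accumulate_cost(r, rep(1, 3), origin = o)$D
  Dh <- accumulate_cost(r, rep(0.5, 3), origin = o)$D
  expect_equal(Dh, D1 / 2)
  # general homogeneity: scaling all class costs by lambda scales D
  base <- c(0.4, 1.1, 2.3)
  Da <- accumulate_cost(r, base, origin = o)$D
  Db <- accumulate_cost(r, base * 1.7, origin = o)$D
  expect_equal(Db, Da * 1.7)
})

test_that("raising one class cost never decreases any distance", {
  set.seed(8)
  for (i in 1:5) {
    r <- random_raster(8, 8, K = 3)
    costs <- runif(3, 0.2, 2)
    o <- c(sample(8, 1), sample(8, 1))
    D0 <- accumulate_cost(r, costs, origin = o)$D
    k <- sample(3, 1)
    costs2 <- costs; costs2[k] <- costs2[k] + runif(1, 0.1, 2)
    D1 <- accumulate_cost(r, costs2, origin = o)$D
    expect_true(all(D1 - D0 >= -1e-12, na.rm = TRUE))
  }
})

test_that("knight's-move edges never lengthen paths (16-dir <= 8-dir)", {
  set.seed(9)
  for (i in 1:5) {
    r <- random_raster(9, 9, K = 2)
    costs <- runif(2, 0.2, 2)
    o <- c(sample(9, 1), sample(9, 1))
    D16 <- accumulate_cost(r, costs, origin = o)$D
    D8 <- reference_cost_distance(r, costs, o, knight = FALSE)
    expect_true(all(D16 - D8 <= 1e-9, na.rm = TRUE))
  }
})

test_that("accumulation matches the enumerated-edge-list oracle with nodata", {
  set.seed(10)
  for (i in 1:20) {
    r <- random_raster(sample(3:10, 1), sample(3:10, 1), K = sample(1:4, 1),
                       cell_size = runif(1, 0.5, 30), p_nodata = 0.2)
    open <- which(!is.na(r$classes), arr.ind = TRUE)
    o <- open[sample(nrow(open), 1), ]
    costs <- runif(r$K, 0.05, 4)
    a <- accumulate_cost(r, costs, origin = o)$D
    b <- reference_cost_distance(r, costs, o)
    expect_equal(is.na(a), is.na(b))
    expect_equal(is.infinite(a), is.infinite(b))
    fin <- is.finite(a) & is.finite(b)
    expect_lt(max(abs(a[fin] - b[fin]) / pmax(b[fin], 1e-12)), 1e-9)
  }
})

test_that("origin validation: nodata origin and tiny costs are errors", {
  vals <- matrix(1L, 4, 4); vals[2, 2] <- NA
  r <- class_raster(vals, cell_size = 1)
  expect_error(accumulate_cost(r, 1, origin = c(2, 2)), "nodata")
  expect_error(accumulate_cost(r, 0.001, origin = c(1, 1)), ">= 0.01")
})

test_that("surface sampling is nearest-cell and flags unusable sites", {
  r <- uniform_raster(6, 10, cell_size = 1)   # xll = 0, yll = 0
  s <- accumulate_cost(r, costs = 2, origin = c(3, 2))
  sites <- data.frame(
    x = c(1.5, 4.5, 4.4, 20.0),   # origin centre, two in one cell, outside
    y = c(3.5, 3.5, 3.6, 3.0))
  expect_warning(got <- sample_surface(s, sites), "excluded")
  expect_equal(got$D_km[1], 0)                # site at the origin cell
  expect_equal(got$D_km[2], got$D_km[3])      # same cell -> identical D
  # 3 orthogonal steps at uniform cost 2, 1 km cells -> 6 km
  expect_equal(got$D_km[2], 6)
  expect_false(got$usable[4])
  expect_true(all(got$usable[1:3]))
})
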