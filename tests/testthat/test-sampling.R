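test_that("lattice shapes are the most nearly square factor pairs", {
  expect_equal(unname(lattice_dims(4)), c(2, 2))
  expect_equal(unname(lattice_dims(30)), c(5, 6))

  # oracle: enumerate all factor pairs of 120, pick the min-difference pair
  pairs <- lapply(which(120 %% 1:120 == 0), function(d) sort(c(d, 120 / d)))
  best <- pairs[[which.min(vapply(pairs, diff, numeric(1)))]]
  expect_equal(unname(lattice_dims(120)), best)
  expect_equal(unname(lattice_dims(120)), c(10, 12))

  expect_error(lattice_dims(0), "positive")
})

test_that("zero-offset lattice of 4 sits at the quarter points", {
  r <- make_constant(56, 56, 90) # 5040 x 5040 m
  d <- regular_lattice(r, 4, offset = c(0, 0))
  expect_equal(sort(unique(d$x)), c(0.25, 0.75) * 5040)
  expect_equal(sort(unique(d$y)), c(0.25, 0.75) * 5040)
})

test_that("lattices keep exact counts, spacing and stay in extent", {
  r <- make_constant(56, 56, 90)
  ext <- raster_extent(r)
  set.seed(42)
  for (n in c(4, 8, 16, 30, 60, 120)) {
    d <- regular_lattice(r, n)
    expect_equal(nrow(d), n)
    expect_true(all(d$x >= ext["xmin"] & d$x <= ext["xmax"]))
    expect_true(all(d$y >= ext["ymin"] & d$y <= ext["ymax"]))
    # torus-wrapped lattice: min pairwise distance >= min spacing
    dims <- lattice_dims(n)
    spacing <- min(ext["width"] / dims["cols"], ext["height"] / dims["rows"])
    expect_gte(min(dist(cbind(d$x, d$y))), spacing - 1e-6)
    expect_equal(nrow(dplyr::distinct(tibble::as_tibble(d))), n)
  }
})

test_that("repeated draws differ only by their random offset", {
  r <- make_constant(56, 56, 90)
  set.seed(7)
  designs <- lapply(1:10, function(i) regular_lattice(r, 30))
  offsets <- t(vapply(designs, attr, numeric(2), which = "offset"))
  expect_equal(nrow(unique(offsets)), 10L)
  for (d in designs) expect_equal(unname(attr(d, "dims")), c(5, 6))
})

test_that("the RAPELD grid has 30 plots 1 km apart on 6 trails", {
  r <- make_constant(56, 56, 90)
  d <- rapeld_design(r)
  expect_equal(nrow(d), 30L)
  expect_equal(length(unique(d$x)), 6L)

  # consecutive plots along each trail are exactly 1 km apart
  for (tx in unique(d$x)) {
    ys <- sort(d$y[d$x == tx])
    expect_equal(length(ys), 5L)
    expect_equal(diff(ys), rep(1000, 4))
  }

  ext <- raster_extent(r)
  expect_true(all(d$x > ext["xmin"] & d$x < ext["xmax"]))
  expect_true(all(d$y > ext["ymin"] & d$y < ext["ymax"]))

  expect_error(rapeld_design(make_constant(20, 20, 90)), "5 x 5 km")
})

test_that("value extraction takes the nearest cell center", {
  # constant raster: every design point reads the constant
  rc <- make_constant(10, 10, 90, 77)
  set.seed(1)
  d <- regular_lattice(rc, 8)
  expect_true(all(extract_values(rc, d)$value == 77))

  # a point exactly at a cell center reads that cell
  slope <- 0.013
  rr <- make_ramp(10, 10, 90, slope_x = slope, slope_y = 0.002, intercept = 5)
  pt <- tibble::tibble(x = (4 - 0.5) * 90, y = (7 - 0.5) * 90)
  expect_equal(extract_values(rr, pt)$value, rr$values[7, 4])

  # a known off-center point reads the ramp evaluated at the nearest center
  pt2 <- tibble::tibble(x = 130, y = 40) # nearest centers: col 2 (135), row 1 (45)
  expect_equal(
    extract_values(rr, pt2)$value,
    5 + slope * 135 + 0.002 * 45
  )

  # idempotent and order-preserving
  d2 <- tibble::tibble(x = c(500, 100, 300), y = c(500, 100, 300))
  v1 <- extract_values(rr, d2)$value
  expect_equal(extract_values(rr, d2)$value, v1)
  expect_equal(extract_values(rr, d2[3:1, ])$value, v1[3:1])

  expect_error(extract_values(rr, tibble::tibble(x = -1, y = 50)), "outside")
  rna <- rc
  rna$values[1, 2] <- NA
  expect_error(extract_values(rna, tibble::tibble(x = 135, y = 45)), "nodata")
})

test_that("designs round-trip through x_m/y_m CSV", {
  set.seed(3)
  d <- regular_lattice(make_constant(56, 56, 90), 16)
  f <- withr::local_tempfile(fileext = ".csv")
  write_design(d, f)
  d2 <- read_design(f)
  expect_equal(d2$x, d$x)
  expect_equal(d2$y, d$y)
  write.csv(data.frame(a = 1), f, row.names = FALSE)
  expect_error(read_design(f), "x_m")
})
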