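test_that("KS statistic and p behave at the known cases", {
  a <- c(3, 1, 4, 1.5, 9)
  same <- ks_two_sample(a, a)
  expect_equal(same$D, 0)
  expect_equal(same$p, 1)

  expect_equal(ks_two_sample(c(1, 2), c(3, 4))$D, 1) # disjoint supports
  expect_equal(ks_two_sample(c(1, 2, 3, 4), c(2, 3, 4, 5))$D, 0.25)

  expect_error(ks_two_sample(numeric(), a), "non-empty")
  expect_error(ks_two_sample(c(1, NA), a), "finite")
})

test_that("KS D matches the brute-force ECDF sweep on random instances", {
  set.seed(101)
  for (i in 1:100) {
    na <- sample(2:40, 1)
    nb <- sample(2:40, 1)
    # integer draws force ties across and within samples
    a <- sample(0:15, na, replace = TRUE) + ifelse(runif(na) < 0.5, 0, 0.5)
    b <- sample(0:15, nb, replace = TRUE)
    expect_identical(ks_two_sample(a, b)$D, ks_D_oracle(a, b))
  }
})

test_that("KS agrees with the classical test on tie-free data", {
  set.seed(77)
  a <- rnorm(40)
  b <- rnorm(60, 0.5)
  got <- ks_two_sample(a, b)
  ref <- suppressWarnings(stats::ks.test(a, b))
  expect_equal(got$D, unname(ref$statistic))
  # same asymptotic formula at these sizes
  ref_asym <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  expect_equal(got$p, ref_asym$p.value, tolerance = 1e-8)
})

test_that("the KS p-value decreases in D at fixed sample sizes", {
  # shifting one integer sample raises D stepwise at fixed (n_a, n_b)
  a <- 1:20
  res <- lapply(0:15, function(k) ks_two_sample(a, a + k))
  Ds <- vapply(res, `[[`, numeric(1), "D")
  ps <- vapply(res, `[[`, numeric(1), "p")
  expect_true(all(diff(Ds) >= 0))
  expect_true(all(diff(ps) <= 1e-12))
  expect_true(all(ps >= 0 & ps <= 1))
})

test_that("correlation flags the undefined instead of inventing a zero", {
  a <- c(1, 2, 3, 4)
  expect_equal(pearson_r(a, 2 * a + 1), 1)
  expect_equal(pearson_r(a, -a), -1)
  expect_true(is.na(pearson_r(rep(5, 4), a)))
  expect_error(pearson_r(a, 1:3), "equal length")
  expect_error(pearson_r(1, 2), "at least 2")
})

test_that("rmse is the root mean squared difference, symmetric, zero on equality", {
  expect_equal(rmse(1:5, 1:5), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  a <- runif(10)
  b <- runif(10)
  expect_equal(rmse(a, b), rmse(b, a))
  expect_error(rmse(1:3, 1:4), "equal length")
})

test_that("scoring a full census or a constant surface is degenerate-exact", {
  r <- small_field(sd = 20, seed = 13, rows = 12, cols = 12)
  rec <- score(r, r, area_id = "x", sample_size = 144)
  expect_equal(rec$ks_D, 0)
  expect_equal(rec$ks_p, 1)
  expect_equal(rec$pearson_r, 1)
  expect_equal(rec$rmse, 0)
  expect_equal(rec$source, "interpolation")

  rc <- make_constant(10, 10, 90, 5)
  set.seed(1)
  sv <- extract_values(rc, regular_lattice(rc, 8))
  rec2 <- score(sv, rc)
  expect_equal(rec2$ks_D, 0)
  expect_true(is.na(rec2$pearson_r))
  expect_true(is.na(rec2$rmse))
  expect_equal(rec2$area_sd, 0)
  surf <- idw_grid(sv, rc)
  rec3 <- score(surf, rc)
  expect_equal(rec3$rmse, 0)
  expect_true(is.na(rec3$pearson_r)) # constant: undefined, not 0

  expect_error(score(make_constant(5, 5, 90), rc), "geometry")
})

test_that("sample scoring equals the explicit two-list ECDF comparison", {
  rr <- make_ramp(15, 15, 90, slope_x = 0.02, slope_y = 0.01)
  set.seed(21)
  sv <- extract_values(rr, regular_lattice(rr, 16))
  rec <- score(sv, rr, sample_size = 16)
  expect_equal(rec$ks_D, ks_D_oracle(sv$value, raster_values(rr)))
  expect_equal(rec$area_sd, sd(raster_values(rr)))
})

test_that("histogram reports share anchored edges and conserve counts", {
  h <- histogram_report(c(5, 25, 25), c(5, 25, 25), bin_width = 20)
  expect_equal(h$bin_left[1], 0)
  expect_equal(h$n_values[1:2], c(1L, 2L))
  expect_equal(h$n_values, h$n_population)

  # single bin when the range fits in one width
  h1 <- histogram_report(0:19, 0:19, bin_width = 20)
  expect_equal(sum(h1$n_values > 0), 1L)

  set.seed(6)
  v <- rnorm(137, 100, 30)
  p <- rnorm(4021, 110, 40)
  h2 <- histogram_report(v, p)
  expect_equal(sum(h2$n_values), 137L)
  expect_equal(sum(h2$n_population), 4021L)
  expect_equal(h2$bin_left[1], floor(min(v, p) / 20) * 20)
  expect_equal(unique(round(h2$bin_right - h2$bin_left, 9)), 20)

  expect_error(histogram_report(numeric(), 1:3), "non-empty")
})
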