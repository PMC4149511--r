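#' Two-sample Kolmogorov-Smirnov statistic and asymptotic p-value
#'
#' The representativeness measure: D is the exact supremum distance between
#' the two empirical CDFs, computed by a sweep over the pooled sorted values
#' (exact under ties). The p-value comes from the asymptotic Kolmogorov
#' distribution evaluated at `sqrt(n_eff) * D` with
#' `n_eff = n_a * n_b / (n_a + n_b)`, clamped to [0, 1] — the standard
#' large-sample form, appropriate here because the population side is the
#' full raster (thousands of cells). Higher p means the sample distribution
#' is harder to tell apart from the population: more representative.
#'
#' @param a,b Numeric vectors of finite values (e.g. sample values and all
#'   population cells).
#' @return Named list with `D` and `p`.
#' @export
#' @examples
#' ks_two_sample(c(1, 2, 3, 4), c(2, 3, 4, 5))$D # 0.25
ks_two_sample <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) abort("Both inputs must be non-empty.")
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    abort("KS inputs must be finite.")
  }
  na <- length(a)
  nb <- length(b)
  pooled <- sort(unique(c(a, b)))
  fa <- findInterval(pooled, sort(a)) / na
  fb <- findInterval(pooled, sort(b)) / nb
  D <- max(abs(fa - fb))
  lambda <- sqrt(na * nb / (na + nb)) * D
  p <- min(1, max(0, kolmogorov_sf(lambda)))
  list(D = D, p = p)
}

# Survival function of the Kolmogorov distribution:
# Q(lambda) = 2 * sum_{k>=1} (-1)^(k-1) exp(-2 k^2 lambda^2)
kolmogorov_sf <- function(lambda) {
  if (lambda <= 0) return(1)
  k <- seq_len(101)
  terms <- (-1)^(k - 1) * exp(-2 * k^2 * lambda^2)
  min(1, max(0, 2 * sum(terms)))
}

#' Pearson correlation with an explicit undefined flag
#'
#' Standard product-moment correlation, the similarity measure between an
#' interpolated surface and the population. When either side has zero
#' variance the correlation does not exist; `NA` is returned (never coerced
#' to 0) so constant areas can be excluded from trend fits rather than
#' distorting them.
#'
#' @param a,b Equal-length numeric vectors (length >= 2).
#' @return Correlation in [-1, 1], or `NA` if undefined.
#' @export
pearson_r <- function(a, b) {
  if (length(a) != length(b)) abort("Inputs must have equal length.")
  if (length(a) < 2L) abort("Need at least 2 observations.")
  if (var(a) == 0 || var(b) == 0) {
    return(NA_real_)
  }
  cor(a, b)
}

#' Root mean square error
#'
#' The accuracy measure: cell-wise RMSE between an interpolated surface and
#' the population, in meters.
#'
#' @param a,b Equal-length numeric vectors.
#' @return `sqrt(mean((a - b)^2))`.
#' @export
rmse <- function(a, b) {
  if (length(a) != length(b)) abort("Inputs must have equal length.")
  sqrt(mean((a - b)^2))
}

#' Score a sample or interpolated surface against the population
#'
#' Produces one metric record: the KS comparison of the value distribution
#' (sample values, or all interpolated cells) against all non-missing
#' population cells, and — for interpolations only, where a cell-wise
#' pairing exists — Pearson correlation and RMSE. The population SD is
#' recorded alongside as the area's heterogeneity.
#'
#' @param x A `sample_values` tibble (source `"sample"`) or a
#'   [terrain_raster()] with geometry equal to `population` (source
#'   `"interpolation"`).
#' @param population The population [terrain_raster()].
#' @param area_id,sample_size,iteration Bookkeeping recorded in the row.
#' @param ... Passed between methods.
#' @return A one-row tibble with columns `area_id`, `sample_size`,
#'   `iteration`, `source`, `ks_D`, `ks_p`, `pearson_r`, `rmse`, `area_sd`
#'   (the stable column order used in all result tables). `pearson_r` is
#'   `NA` when undefined; `pearson_r` and `rmse` are `NA` for samples.
#' @export
score <- function(x, population, ...) UseMethod("score")

#' @rdname score
#' @export
score.sample_values <- function(x, population, area_id = NULL,
                                sample_size = nrow(x), iteration = 1L, ...) {
  pop <- raster_values(population)
  ks <- ks_two_sample(x$value, pop)
  metric_row(
    area_id %||% attr(x, "area_id"), sample_size, iteration, "sample",
    ks, NA_real_, NA_real_, sd(pop)
  )
}

#' @rdname score
#' @export
score.terrain_raster <- function(x, population, area_id = "area",
                                 sample_size = NA_integer_, iteration = 1L,
                                 ...) {
  if (!identical(dim(x$values), dim(population$values)) ||
    !isTRUE(all.equal(x$cell_size, population$cell_size))) {
    abort("Interpolated surface geometry must match the population raster.")
  }
  ok <- !is.na(population$values) & !is.na(x$values)
  pred <- x$values[ok]
  pop <- population$values[ok]
  ks <- ks_two_sample(pred, pop)
  metric_row(
    area_id, sample_size, iteration, "interpolation",
    ks, pearson_r(pred, pop), rmse(pred, pop), sd(pop)
  )
}

metric_row <- function(area_id, sample_size, iteration, source, ks, r, rm, sdv) {
  tibble::tibble(
    area_id = as.character(area_id %||% "area"),
    sample_size = as.integer(sample_size),
    iteration = as.integer(iteration),
    source = source,
    ks_D = ks$D,
    ks_p = ks$p,
    pearson_r = r,
    rmse = rm,
    area_sd = sdv
  )
}

#' Paired histogram counts for back-to-back distribution reports
#'
#' Bins both value lists on shared edges anchored at
#' `floor(min / bin_width) * bin_width` (pooled minimum), the layout used to
#' compare a sample's altitude distribution against the population's in
#' back-to-back histograms. The default 20 m bin width matches the standard
#' altitude-histogram presentation.
#'
#' @param values Numeric vector (e.g. sample values).
#' @param population Numeric vector (e.g. all population cells).
#' @param bin_width Bin width in meters (> 0).
#' @return Tibble with `bin_left`, `bin_right`, `n_values`, `n_population`;
#'   each count column sums to the corresponding input length.
#' @export
#' @examples
#' histogram_report(c(5, 25, 25), c(5, 25, 25), bin_width = 20)
histogram_report <- function(values, population, bin_width = 20) {
  if (length(values) == 0L || length(population) == 0L) {
    abort("Both inputs must be non-empty.")
  }
  stopifnot_scalar_number(bin_width, "bin_width", positive = TRUE)
  lo <- floor(min(values, population) / bin_width) * bin_width
  hi <- max(values, population)
  edges <- seq(lo, hi + bin_width, by = bin_width)
  bin_of <- function(v) pmin(floor((v - lo) / bin_width) + 1L, length(edges) - 1L)
  nb <- length(edges) - 1L
  tibble::tibble(
    bin_left = edges[-length(edges)],
    bin_right = edges[-1],
    n_values = tabulate(bin_of(values), nbins = nb),
    n_population = tabulate(bin_of(population), nbins = nb)
  )
}
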