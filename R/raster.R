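#' Elevation raster objects
#'
#' A `terrain_raster` is a regular grid of elevation values: the "population"
#' surface against which samples and interpolations are scored. Values are
#' attached to cell centers; the origin is the lower-left corner of the
#' lower-left cell, and row 1 of the value matrix is the southernmost row
#' (y increases with row index). All coordinates are planar meters.
#'
#' @param values Numeric matrix of elevations (m), at least 2 x 2. `NA`
#'   marks nodata cells.
#' @param cell_size Cell edge length in meters (> 0).
#' @param origin Length-2 numeric, (x, y) of the lower-left corner in meters.
#'
#' @return A `terrain_raster` object.
#' @export
#' @examples
#' r <- terrain_raster(matrix(1:12, 3, 4), cell_size = 90)
#' raster_extent(r)
terrain_raster <- function(values, cell_size, origin = c(0, 0)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.")
  }
  if (nrow(values) < 2L || ncol(values) < 2L) {
    abort("A raster needs at least 2 x 2 cells.")
  }
  stopifnot_scalar_number(cell_size, "cell_size", positive = TRUE)
  if (length(origin) != 2L || !is.numeric(origin) || any(!is.finite(origin))) {
    abort("`origin` must be two finite numbers (x, y).")
  }
  if (any(!is.finite(values) & !is.na(values))) {
    abort("Non-missing raster values must be finite.")
  }
  structure(
    list(
      values = values,
      cell_size = as.numeric(cell_size),
      origin = as.numeric(origin)
    ),
    class = "terrain_raster"
  )
}

#' @export
print.terrain_raster <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf(
    "<terrain_raster> %d x %d cells @ %g m (%.0f x %.0f m extent)\n",
    nrow(x$values), ncol(x$values), x$cell_size,
    ncol(x$values) * x$cell_size, nrow(x$values) * x$cell_size
  ))
  cat(sprintf(
    "  mean %.2f m, sd %.2f m, range [%.2f, %.2f], nodata cells: %d\n",
    mean(v), sd(v), min(v), max(v), sum(is.na(x$values))
  ))
  invisible(x)
}

#' @describeIn terrain_raster Extent of a raster: named vector with
#'   `xmin`, `ymin`, `xmax`, `ymax`, `width`, `height` (m).
#' @param x,raster A `terrain_raster`.
#' @export
raster_extent <- function(raster) {
  w <- ncol(raster$values) * raster$cell_size
  h <- nrow(raster$values) * raster$cell_size
  c(
    xmin = raster$origin[1], ymin = raster$origin[2],
    xmax = raster$origin[1] + w, ymax = raster$origin[2] + h,
    width = w, height = h
  )
}

#' @describeIn terrain_raster Non-missing cell values as a vector.
#' @export
raster_values <- function(raster) {
  v <- as.vector(raster$values)
  v[!is.na(v)]
}

# x-coordinates of cell centers (columns) and y-coordinates (rows).
cell_centers_x <- function(raster) {
  raster$origin[1] + (seq_len(ncol(raster$values)) - 0.5) * raster$cell_size
}
cell_centers_y <- function(raster) {
  raster$origin[2] + (seq_len(nrow(raster$values)) - 0.5) * raster$cell_size
}

#' @method as_tibble terrain_raster
#' @export
as_tibble.terrain_raster <- function(x, ...) {
  cx <- cell_centers_x(x)
  cy <- cell_centers_y(x)
  tibble::tibble(
    x = rep(cx, each = nrow(x$values)),
    y = rep(cy, times = ncol(x$values)),
    value = as.vector(x$values)
  )
}

#' Degenerate and gradient rasters
#'
#' Deterministic fixtures: `make_constant()` builds a flat surface (SD 0);
#' `make_ramp()` builds a planar gradient, useful for probing directional
#' (anisotropic) behavior of designs and interpolations. The ramp value at a
#' cell center (x, y) is `intercept + slope_x * x + slope_y * y`.
#'
#' @param rows,cols Grid dimensions (>= 2).
#' @param cell_size Cell edge in meters.
#' @param value Constant elevation (m).
#' @param slope_x,slope_y Gradients in m per m.
#' @param intercept Elevation at (0, 0) in meters.
#' @param origin Lower-left corner (x, y) in meters.
#' @return A [terrain_raster()].
#' @export
#' @examples
#' make_constant(4, 4, 90, 100)
#' make_ramp(4, 4, 90, slope_x = 0.01)
make_constant <- function(rows, cols, cell_size = 90, value = 0,
                          origin = c(0, 0)) {
  check_dims(rows, cols)
  terrain_raster(matrix(value, rows, cols), cell_size, origin)
}

#' @rdname make_constant
#' @export
make_ramp <- function(rows, cols, cell_size = 90, slope_x = 0, slope_y = 0,
                      intercept = 0, origin = c(0, 0)) {
  check_dims(rows, cols)
  cx <- origin[1] + (seq_len(cols) - 0.5) * cell_size
  cy <- origin[2] + (seq_len(rows) - 0.5) * cell_size
  vals <- intercept + outer(cy * slope_y, cx * slope_x, `+`)
  terrain_raster(vals, cell_size, origin)
}

check_dims <- function(rows, cols) {
  if (!is.numeric(rows) || !is.numeric(cols) || rows < 2 || cols < 2) {
    abort("`rows` and `cols` must both be >= 2.")
  }
}

#' Specification of a synthetic terrain tile
#'
#' Parameters for [make_gaussian_field()]: grid geometry, target first and
#' second moments, spatial autocorrelation range, marginal tail behavior,
#' and the seed. The defaults emulate a 5 x 5 km tile at 90 m resolution
#' with the mean elevation (159.5 m) reported for Amazonian terrain; the
#' default SD of 40 m is the value below which 90% of 5 x 5 km Amazonian
#' areas fall.
#'
#' @param rows,cols Grid dimensions (>= 2).
#' @param cell_size Cell edge, meters.
#' @param target_mean Realized raster mean, meters.
#' @param target_sd Realized raster standard deviation, meters (>= 0).
#' @param correlation_length Autocorrelation range, meters (> 0): the lag at
#'   which field correlation has decayed to roughly exp(-1).
#' @param tail `"gaussian"` for a symmetric marginal; `"long_tailed"` applies
#'   a monotone convex transform (exponential of the standardized field)
#'   before rescaling, producing the right-skewed marginals seen in
#'   dissected terrain.
#' @param seed Integer seed; identical spec implies an identical raster.
#' @return A `terrain_spec` list.
#' @export
terrain_spec <- function(rows = 56, cols = 56, cell_size = 90,
                         target_mean = 159.5, target_sd = 40,
                         correlation_length = 1000,
                         tail = c("gaussian", "long_tailed"),
                         seed = 1L) {
  check_dims(rows, cols)
  stopifnot_scalar_number(cell_size, "cell_size", positive = TRUE)
  stopifnot_scalar_number(target_mean, "target_mean")
  stopifnot_scalar_number(target_sd, "target_sd", nonneg = TRUE)
  stopifnot_scalar_number(correlation_length, "correlation_length",
    positive = TRUE
  )
  tail <- match.arg(tail)
  structure(
    list(
      rows = as.integer(rows), cols = as.integer(cols),
      cell_size = as.numeric(cell_size),
      target_mean = as.numeric(target_mean),
      target_sd = as.numeric(target_sd),
      correlation_length = as.numeric(correlation_length),
      tail = tail, seed = as.integer(seed)
    ),
    class = "terrain_spec"
  )
}

#' Simulate a correlated elevation surface
#'
#' Draws a stationary Gaussian random field by spectral synthesis: white
#' noise is convolved (via FFT, on the torus) with an isotropic Gaussian
#' kernel whose width is set by `correlation_length`, then affinely rescaled
#' so the realized raster mean and SD match `target_mean` and `target_sd`
#' exactly. With `tail = "long_tailed"` the standardized field is
#' exponentiated before rescaling, which forces positive skew while keeping
#' the target moments.
#'
#' The construction stands in for real 90 m digital-elevation tiles: it
#' reproduces their first two moments and smooth spatial structure, not any
#' specific site's landforms.
#'
#' @param spec A [terrain_spec()].
#' @return A [terrain_raster()] with realized mean and SD equal to the
#'   targets (to machine precision) whenever `target_sd > 0`; a constant
#'   raster at `target_mean` when `target_sd = 0`.
#' @export
#' @examples
#' r <- make_gaussian_field(terrain_spec(target_sd = 20, seed = 42))
#' c(mean(raster_values(r)), sd(raster_values(r)))
make_gaussian_field <- function(spec) {
  if (!inherits(spec, "terrain_spec")) {
    abort("`spec` must be a terrain_spec.")
  }
  nr <- spec$rows
  nc <- spec$cols
  if (spec$target_sd == 0) {
    return(make_constant(nr, nc, spec$cell_size, spec$target_mean))
  }
  field <- with_seed(spec$seed, {
    noise <- matrix(rnorm(nr * nc), nr, nc)
    # Isotropic Gaussian smoothing kernel on the torus; kernel sd of
    # correlation_length / 2 gives field autocorrelation ~ exp(-(lag/L)^2).
    s <- spec$correlation_length / 2
    dy <- pmin(0:(nr - 1), nr - 0:(nr - 1)) * spec$cell_size
    dx <- pmin(0:(nc - 1), nc - 0:(nc - 1)) * spec$cell_size
    kern <- exp(-outer(dy^2, dx^2, `+`) / (2 * s^2))
    sm <- Re(fft(fft(noise) * fft(kern), inverse = TRUE)) / (nr * nc)
    z <- (sm - mean(sm)) / sd(sm)
    if (spec$tail == "long_tailed") z <- exp(z)
    spec$target_mean + spec$target_sd * (z - mean(z)) / sd(z)
  })
  terrain_raster(field, spec$cell_size)
}
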