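#' Most-nearly-square lattice shape for a sample size
#'
#' Factors `n` into `(rows, cols)` with `rows <= cols`, `rows * cols = n`,
#' minimizing `cols - rows`. For a prime `n > 3` (never the case for the
#' standard sizes 4, 8, 16, 30, 60, 120, all composite) the shape of the
#' largest composite below `n` is returned and the lattice carries fewer
#' points than requested.
#'
#' @param n Requested sample size (>= 1).
#' @return Named integer vector `c(rows = , cols = )`.
#' @export
#' @examples
#' lattice_dims(30) # 5 x 6
#' lattice_dims(120) # 10 x 12
lattice_dims <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != floor(n)) {
    abort("`n` must be a positive integer.")
  }
  n <- as.integer(n)
  best_pair <- function(m) {
    divs <- which(m %% seq_len(floor(sqrt(m))) == 0)
    r <- max(divs)
    c(rows = r, cols = m %/% r)
  }
  p <- best_pair(n)
  if (n > 3L && p[["rows"]] == 1L) {
    # prime: fall back to the largest composite below n
    m <- n - 1L
    while (best_pair(m)[["rows"]] == 1L) m <- m - 1L
    p <- best_pair(m)
  }
  p
}

new_sample_design <- function(points, layout, dims, offset, requested_n) {
  structure(
    tibble::new_tibble(points, nrow = nrow(points)),
    layout = layout, dims = dims, offset = offset,
    requested_n = as.integer(requested_n),
    class = c("sample_design", class(tibble::tibble()))
  )
}

#' Regular lattice sample design with a randomized offset
#'
#' Places `n` points on a most-nearly-square lattice spanning the raster
#' extent: spacing `sx = width / cols`, `sy = height / rows`, base points at
#' the lattice cell centers, plus one uniform random offset
#' `dx ~ U[-sx/2, sx/2)`, `dy ~ U[-sy/2, sy/2)` shared by all points.
#' Points are wrapped torus-fashion back into the extent, so every draw
#' keeps the exact spacing and point count but shifts the anchoring — the
#' "starting point" that varies between iterations of a survey design.
#' Randomness comes from the current RNG state; seed the session for
#' reproducibility.
#'
#' @param raster A [terrain_raster()] (or the result of [raster_extent()])
#'   defining the extent to sample.
#' @param n Requested number of sample points.
#' @param offset Optional fixed offset `c(dx, dy)` in meters; the default
#'   `NULL` draws it uniformly as described above.
#' @return A `sample_design`: a tibble of ordered point coordinates `x`, `y`
#'   (m) with layout metadata in attributes.
#' @export
#' @examples
#' set.seed(1)
#' regular_lattice(make_constant(56, 56, 90), 30)
regular_lattice <- function(raster, n, offset = NULL) {
  ext <- as_extent(raster)
  dims <- lattice_dims(n)
  r <- dims[["rows"]]
  cl <- dims[["cols"]]
  sx <- ext[["width"]] / cl
  sy <- ext[["height"]] / r
  if (sx <= 0 || sy <= 0) abort("Extent smaller than one lattice spacing.")
  if (is.null(offset)) {
    dx <- runif(1, -sx / 2, sx / 2)
    dy <- runif(1, -sy / 2, sy / 2)
  } else {
    dx <- offset[1]
    dy <- offset[2]
  }
  base_x <- (seq_len(cl) - 0.5) * sx
  base_y <- (seq_len(r) - 0.5) * sy
  pts <- tidyr::expand_grid(y0 = base_y, x0 = base_x)
  pts <- tibble::tibble(
    x = ext[["xmin"]] + (pts$x0 + dx) %% ext[["width"]],
    y = ext[["ymin"]] + (pts$y0 + dy) %% ext[["height"]]
  )
  if (nrow(pts) < n) {
    warn(sprintf(
      "n = %d is prime; placing %d points on a %d x %d lattice.",
      n, nrow(pts), r, cl
    ))
  }
  new_sample_design(pts,
    layout = "lattice", dims = c(r, cl),
    offset = c(dx, dy), requested_n = n
  )
}

#' RAPELD trail-grid sample design
#'
#' The standard 25 km2 survey grid: six parallel north-south trails spaced
#' 1 km apart, each carrying five plots at 1 km intervals, giving 30 plots.
#' Trail x-positions at 0, 1, ..., 5 km are clamped half a cell inside the
#' extent so every plot lies on the surface; plot y-positions sit at 0.5,
#' 1.5, ..., 4.5 km. Deterministic: no randomness.
#'
#' @param raster A [terrain_raster()] (or extent) covering 5 x 5 km, within
#'   one cell.
#' @return A `sample_design` of 30 points ordered by trail then plot.
#' @export
#' @examples
#' rapeld_design(make_constant(56, 56, 90))
rapeld_design <- function(raster) {
  ext <- as_extent(raster)
  cell <- attr(ext, "cell_size") %||% 90
  if (abs(ext[["width"]] - 5000) > cell || abs(ext[["height"]] - 5000) > cell) {
    abort("RAPELD design requires a 5 x 5 km extent (within one cell).")
  }
  trail_x <- pmin(
    pmax(seq(0, 5000, by = 1000), cell / 2),
    ext[["width"]] - cell / 2
  )
  plot_y <- seq(500, 4500, by = 1000)
  pts <- tibble::tibble(
    x = ext[["xmin"]] + rep(trail_x, each = length(plot_y)),
    y = ext[["ymin"]] + rep(plot_y, times = length(trail_x))
  )
  new_sample_design(pts,
    layout = "rapeld", dims = c(length(plot_y), length(trail_x)),
    offset = c(0, 0), requested_n = nrow(pts)
  )
}

as_extent <- function(x) {
  if (inherits(x, "terrain_raster")) {
    ext <- raster_extent(x)
    attr(ext, "cell_size") <- x$cell_size
    ext
  } else if (is.numeric(x) && all(c("width", "height") %in% names(x))) {
    if (!"xmin" %in% names(x)) x <- c(x, xmin = 0, ymin = 0)
    x
  } else {
    abort("Expected a terrain_raster or a named extent vector.")
  }
}

#' Extract raster values at design points
#'
#' Each point takes the value of the raster cell whose center is nearest,
#' with ties broken toward the lower row then lower column. No smoothing is
#' applied: sample values are actual population values, so downstream
#' distribution tests compare a true subsample against the population.
#'
#' @param raster A [terrain_raster()].
#' @param design A `sample_design` or any data frame with `x`, `y` columns
#'   (m), e.g. a custom plot list read with [read_design()].
#' @param area_id Label recorded with the values.
#' @return A `sample_values` tibble: the design points plus a `value` column.
#' @export
#' @examples
#' r <- make_ramp(10, 10, 90, slope_x = 0.1)
#' extract_values(r, rapeld_design(make_constant(56, 56, 90))[1:3, ])
extract_values <- function(raster, design, area_id = "area") {
  if (!inherits(raster, "terrain_raster")) {
    abort("`raster` must be a terrain_raster.")
  }
  if (!all(c("x", "y") %in% names(design))) {
    abort("`design` needs `x` and `y` columns.")
  }
  ext <- raster_extent(raster)
  x <- design$x
  y <- design$y
  eps <- 1e-9
  inside <- x >= ext[["xmin"]] - eps & x <= ext[["xmax"]] + eps &
    y >= ext[["ymin"]] - eps & y <= ext[["ymax"]] + eps
  if (any(!inside)) {
    abort(sprintf("%d design point(s) fall outside the raster extent.",
      sum(!inside)))
  }
  # nearest cell center; ceiling() sends exact cell-edge ties to the lower
  # row/column index
  col <- pmin(pmax(ceiling((x - ext[["xmin"]]) / raster$cell_size), 1L),
    ncol(raster$values))
  row <- pmin(pmax(ceiling((y - ext[["ymin"]]) / raster$cell_size), 1L),
    nrow(raster$values))
  vals <- raster$values[cbind(row, col)]
  if (any(is.na(vals))) {
    abort(sprintf("%d design point(s) land on nodata cells.", sum(is.na(vals))))
  }
  out <- tibble::tibble(x = x, y = y, value = vals)
  structure(
    tibble::new_tibble(out, nrow = nrow(out)),
    design = design, area_id = area_id,
    class = c("sample_values", class(tibble::tibble()))
  )
}

#' Read and write sample designs as CSV
#'
#' Designs exchange as CSV with header columns `x_m`, `y_m` (meters).
#'
#' @param design A `sample_design` or data frame with `x`, `y` columns.
#' @param path CSV file path.
#' @param layout Layout label recorded on the imported design.
#' @return `read_design()` returns a `sample_design`; `write_design()`
#'   returns `path` invisibly.
#' @export
write_design <- function(design, path) {
  write.csv(
    data.frame(x_m = design$x, y_m = design$y),
    path,
    row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path, layout = "custom") {
  df <- read.csv(path)
  if (!all(c("x_m", "y_m") %in% names(df))) {
    abort("Design CSV must have columns x_m, y_m.")
  }
  pts <- tibble::tibble(x = df$x_m, y = df$y_m)
  new_sample_design(pts,
    layout = layout, dims = c(NA_integer_, NA_integer_),
    offset = c(0, 0), requested_n = nrow(pts)
  )
}
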