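#' Inverse-distance-weighting configuration
#'
#' @param power Exponent on inverse distance (> 0). Predictions are
#'   `sum(w * z) / sum(w)` with `w = d^(-power)`. Power 2 with a global
#'   neighborhood is the dominant default of the geostatistics tooling this
#'   method is usually run with.
#' @param max_neighbors Number of nearest samples used per prediction;
#'   `Inf` uses all samples.
#' @return An `idw_config` list.
#' @export
idw_config <- function(power = 2, max_neighbors = Inf) {
  stopifnot_scalar_number(power, "power", positive = TRUE)
  if (!(is.infinite(max_neighbors) || (is.numeric(max_neighbors) &&
    max_neighbors >= 1))) {
    abort("`max_neighbors` must be >= 1 or Inf.")
  }
  structure(list(power = power, max_neighbors = max_neighbors),
    class = "idw_config"
  )
}

#' Inverse-distance-weighted prediction at arbitrary points
#'
#' The workhorse interpolator: a positively weighted average of sample
#' values with weights proportional to Euclidean planar distance raised to
#' `-power`, over the `max_neighbors` nearest samples. A target coinciding
#' with a sample location returns that sample's value exactly (the mean, if
#' several samples coincide there). Chosen over kriging because it remains
#' usable at very small sample sizes. Extrapolation outside the sample hull
#' is permitted; predictions always lie within the sample value range.
#'
#' @param samples A `sample_values` tibble (or any data frame with `x`, `y`,
#'   `value` columns).
#' @param target_xy Numeric matrix or data frame of target coordinates, one
#'   row per point (columns x, y); a length-2 vector is a single point.
#' @param config An [idw_config()].
#' @return Numeric vector of predicted elevations, one per target.
#' @export
#' @examples
#' s <- tibble::tibble(x = c(0, 2), y = c(0, 0), value = c(0, 10))
#' idw_predict(s, c(1, 0)) # midpoint: 5
idw_predict <- function(samples, target_xy, config = idw_config()) {
  if (is.null(nrow(target_xy))) target_xy <- matrix(target_xy, ncol = 2)
  target_xy <- as.matrix(target_xy)
  idw_core(
    samples$x, samples$y, samples$value,
    target_xy[, 1], target_xy[, 2], config
  )
}

#' Interpolate a full raster surface from samples
#'
#' Runs [idw_predict()] at every cell center of `template`, returning a
#' raster with identical geometry — the "interpolation" arm that is scored
#' against the population surface.
#'
#' @inheritParams idw_predict
#' @param template A [terrain_raster()] defining the output geometry
#'   (typically the population raster itself, i.e. the 90 m grid).
#' @return A [terrain_raster()].
#' @export
idw_grid <- function(samples, template, config = idw_config()) {
  if (!inherits(template, "terrain_raster")) {
    abort("`template` must be a terrain_raster.")
  }
  cx <- cell_centers_x(template)
  cy <- cell_centers_y(template)
  nr <- nrow(template$values)
  tx <- rep(cx, each = nr)
  ty <- rep(cy, times = length(cx))
  pred <- idw_core(samples$x, samples$y, samples$value, tx, ty, config)
  terrain_raster(matrix(pred, nrow = nr), template$cell_size, template$origin)
}

idw_core <- function(sx, sy, sz, tx, ty, config) {
  ns <- length(sz)
  if (ns == 0L) abort("IDW needs at least one sample.")
  if (any(!is.finite(sz))) abort("Sample values must be finite.")
  if (diff(range(sz)) == 0) {
    # all samples equal: the convex combination is that value exactly
    return(rep(sz[1], length(tx)))
  }
  d2 <- outer(tx, sx, `-`)^2 + outer(ty, sy, `-`)^2 # targets x samples
  zero_tol2 <- 1e-18 # (1e-9 m)^2: coincident within a nanometer
  if (is.finite(config$max_neighbors) && config$max_neighbors < ns) {
    k <- as.integer(config$max_neighbors)
    # mask all but the k nearest samples per target
    keep <- t(apply(d2, 1L, function(r) {
      idx <- order(r)[seq_len(k)]
      m <- rep(FALSE, ns)
      m[idx] <- TRUE
      m
    }))
    d2[!keep] <- Inf
  }
  w <- d2^(-config$power / 2)
  pred <- as.vector(w %*% sz) / rowSums(w)
  hit <- d2 <= zero_tol2
  exact <- which(rowSums(hit) > 0)
  if (length(exact)) {
    pred[exact] <- vapply(
      exact,
      function(i) mean(sz[hit[i, ]]),
      numeric(1)
    )
  }
  pred
}
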