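#' Configure a sampling-design experiment
#'
#' Bundles everything a full run needs: how many synthetic areas to draw,
#' the terrain template and the range its per-area SD is drawn from, the
#' sample sizes and iterations, the interpolation settings, and the
#' threshold-analysis settings. Defaults mirror the standard study
#' conditions: 5 x 5 km tiles at 90 m resolution (56 x 56 cells), sample
#' sizes 4-120 with 10 randomized-offset iterations each, and per-area SD
#' drawn uniformly from 1-56 m — the heterogeneity band covering the large
#' majority of 5 x 5 km Amazonian areas.
#'
#' @param n_areas Number of synthetic areas.
#' @param sizes Sample sizes to simulate.
#' @param iterations Randomized-offset iterations per size.
#' @param sd_range Range (m) the per-area terrain SD is drawn from,
#'   uniformly.
#' @param rows,cols,cell_size,target_mean,correlation_length,tail Terrain
#'   template passed to [terrain_spec()].
#' @param idw An [idw_config()].
#' @param alpha,permutations,min_node Settings for [fit_ctree()].
#' @param master_seed Integer; drives every random draw of the run.
#' @param output_dir Directory for CSV/JSON outputs, or `NULL` to keep
#'   results in memory only.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(n_areas = 50,
                              sizes = c(4, 8, 16, 30, 60, 120),
                              iterations = 10,
                              sd_range = c(1, 56),
                              rows = 56, cols = 56, cell_size = 90,
                              target_mean = 159.5,
                              correlation_length = 1000,
                              tail = "gaussian",
                              idw = idw_config(),
                              alpha = 0.05,
                              permutations = 999,
                              min_node = 20,
                              master_seed = 1L,
                              output_dir = NULL) {
  if (length(sizes) == 0L || any(sizes < 1)) {
    abort("`sizes` must be a non-empty vector of positive sizes.")
  }
  if (iterations < 1) abort("`iterations` must be >= 1.")
  if (n_areas < 1) abort("`n_areas` must be >= 1.")
  if (length(sd_range) != 2L || any(sd_range < 0) ||
    sd_range[2] < sd_range[1]) {
    abort("`sd_range` must be c(lo, hi) with 0 <= lo <= hi.")
  }
  structure(
    list(
      n_areas = as.integer(n_areas), sizes = as.integer(sizes),
      iterations = as.integer(iterations), sd_range = as.numeric(sd_range),
      rows = as.integer(rows), cols = as.integer(cols),
      cell_size = as.numeric(cell_size),
      target_mean = as.numeric(target_mean),
      correlation_length = as.numeric(correlation_length),
      tail = tail, idw = idw,
      alpha = alpha, permutations = as.integer(permutations),
      min_node = as.integer(min_node),
      master_seed = as.integer(master_seed),
      output_dir = output_dir
    ),
    class = "experiment_config"
  )
}

#' Read an experiment configuration from a YAML file
#'
#' Keys mirror the arguments of [experiment_config()]; `idw` may be a map
#' with `power` and `max_neighbors`. Unspecified keys keep their defaults.
#'
#' @param path YAML file.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$idw)) {
    raw$idw <- do.call(idw_config, raw$idw)
  }
  known <- names(formals(experiment_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    warn(paste("Ignoring unknown config keys:", paste(unknown, collapse = ", ")))
    raw <- raw[intersect(names(raw), known)]
  }
  do.call(experiment_config, raw)
}

#' Evaluate one area across sample sizes and iterations
#'
#' For each sample size and iteration: draw a regular lattice with a fresh
#' random offset, extract values at the plots, score the sample against the
#' population, interpolate by IDW onto the population geometry, and score
#' the interpolation — two metric rows per (size, iteration). Randomness
#' (the lattice offsets) comes from the current RNG state.
#'
#' @param raster The population [terrain_raster()].
#' @param sizes Sample sizes.
#' @param iterations Iterations per size.
#' @param idw An [idw_config()].
#' @param area_id Label for the output rows.
#' @return Tibble of metric rows, `2 * length(sizes) * iterations` of them.
#' @export
#' @examples
#' set.seed(7)
#' evaluate_area(make_constant(10, 10, 90), sizes = c(4), iterations = 2)
evaluate_area <- function(raster, sizes = c(4, 8, 16, 30, 60, 120),
                          iterations = 10, idw = idw_config(),
                          area_id = "area") {
  grid <- tidyr::expand_grid(size = sizes, iter = seq_len(iterations))
  purrr::pmap(grid, function(size, iter) {
    design <- regular_lattice(raster, size)
    sv <- extract_values(raster, design, area_id = area_id)
    surf <- idw_grid(sv, raster, idw)
    dplyr::bind_rows(
      score(sv, raster,
        area_id = area_id, sample_size = size, iteration = iter
      ),
      score(surf, raster,
        area_id = area_id, sample_size = size, iteration = iter
      )
    )
  }) |>
    purrr::list_rbind()
}

#' Evaluate the RAPELD trail-grid design on one area
#'
#' Deterministic single evaluation of the standard 30-plot, 1-km-interval
#' trail grid: one sample row and one interpolation row.
#'
#' @param raster A 5 x 5 km population [terrain_raster()].
#' @param idw An [idw_config()].
#' @param area_id Label for the output rows.
#' @return Tibble of 2 metric rows.
#' @export
evaluate_rapeld <- function(raster, idw = idw_config(), area_id = "area") {
  design <- rapeld_design(raster)
  sv <- extract_values(raster, design, area_id = area_id)
  surf <- idw_grid(sv, raster, idw)
  dplyr::bind_rows(
    score(sv, raster, area_id = area_id, sample_size = nrow(design)),
    score(surf, raster, area_id = area_id, sample_size = nrow(design))
  )
}

#' Run the full sampling-design experiment
#'
#' Generates `n_areas` synthetic terrains (per-area SD drawn uniformly from
#' `sd_range`), evaluates each with [evaluate_area()], averages the metrics
#' over iterations within each (area, size, source) cell, then fits
#' penalized-spline trends and conditional-inference trees of each metric
#' against sample size and area SD on the mean rows: KS p for samples, and
#' KS p, Pearson r and RMSE for interpolations. Rows with undefined
#' correlation are kept (flagged `NA`) in the tables and excluded listwise
#' from the r fits.
#'
#' Per-area seeds are derived from `master_seed` by a fixed counter scheme,
#' so runs are reproducible end to end and areas are independent. An area
#' that fails is logged, skipped, and counted in the returned summary.
#'
#' @param config An [experiment_config()].
#' @param quiet Suppress per-area progress messages.
#' @return A `grid_experiment` list: `results` (raw metric rows), `means`
#'   (iteration means), `areas` (per-area SD and seed), `smooths` and
#'   `trees` (named lists over responses), `n_failed`, and the `config`.
#'   If `config$output_dir` is set, CSV tables, JSON trees, smooth-profile
#'   CSVs and a run manifest are written there.
#' @export
run_experiment <- function(config, quiet = FALSE) {
  if (!inherits(config, "experiment_config")) {
    abort("`config` must be an experiment_config.")
  }
  say <- function(...) if (!quiet) message(sprintf(...))
  areas <- tibble::tibble(
    area_id = sprintf("area_%03d", seq_len(config$n_areas)),
    seed = vapply(
      seq_len(config$n_areas),
      function(i) derive_seed(config$master_seed, i), integer(1)
    )
  )
  raw <- vector("list", config$n_areas)
  sds <- numeric(config$n_areas)
  n_failed <- 0L
  for (i in seq_len(config$n_areas)) {
    t0 <- Sys.time()
    res <- tryCatch(
      {
        set.seed(areas$seed[i])
        sd_i <- runif(1, config$sd_range[1], config$sd_range[2])
        spec <- terrain_spec(
          rows = config$rows, cols = config$cols,
          cell_size = config$cell_size,
          target_mean = config$target_mean, target_sd = sd_i,
          correlation_length = config$correlation_length,
          tail = config$tail,
          seed = derive_seed(areas$seed[i], 1)
        )
        raster <- make_gaussian_field(spec)
        rows <- evaluate_area(
          raster, config$sizes, config$iterations,
          config$idw,
          area_id = areas$area_id[i]
        )
        list(rows = rows, sd = sd_i)
      },
      error = function(e) e
    )
    if (inherits(res, "error")) {
      warn(sprintf("Area %s failed and was skipped: %s",
        areas$area_id[i], conditionMessage(res)))
      n_failed <- n_failed + 1L
      sds[i] <- NA_real_
    } else {
      raw[[i]] <- res$rows
      sds[i] <- res$sd
      say(
        "%s: SD %.1f m, %d rows, %.1f s", areas$area_id[i], res$sd,
        nrow(res$rows), as.numeric(difftime(Sys.time(), t0, units = "secs"))
      )
    }
  }
  areas$area_sd <- sds
  results <- purrr::list_rbind(raw)
  means <- summarize_iterations(results)

  responses <- list(
    sample_ks_p = list(source = "sample", metric = "ks_p"),
    interp_ks_p = list(source = "interpolation", metric = "ks_p"),
    interp_r = list(source = "interpolation", metric = "pearson_r"),
    interp_rmse = list(source = "interpolation", metric = "rmse")
  )
  # tiny runs can fall below the fitters' minimum-row preconditions; keep
  # the tables and carry a NULL fit rather than aborting the whole run
  try_fit <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      warn(sprintf("%s failed: %s", what, conditionMessage(e)))
      NULL
    })
  }
  smooths <- purrr::imap(responses, function(r, nm) {
    d <- dplyr::filter(means, .data$source == r$source)
    try_fit(paste("smooth", nm), fit_smooth(d, r$metric))
  })
  trees <- purrr::imap(responses, function(r, nm) {
    d <- dplyr::filter(means, .data$source == r$source)
    try_fit(paste("tree", nm), fit_ctree(d, r$metric,
      alpha = config$alpha,
      permutations = config$permutations, min_node = config$min_node
    ))
  })

  out <- structure(
    list(
      config = config, areas = areas, results = results, means = means,
      smooths = smooths, trees = trees, n_failed = n_failed
    ),
    class = "grid_experiment"
  )
  if (!is.null(config$output_dir)) write_experiment(out)
  out
}

# Iteration means within (area, size, source); r averaged over the defined
# iterations only, NA if none are defined.
summarize_iterations <- function(results) {
  mean_def <- function(v) {
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  }
  results |>
    dplyr::group_by(.data$area_id, .data$sample_size, .data$source) |>
    dplyr::summarize(
      n_iterations = dplyr::n(),
      ks_D = mean(.data$ks_D),
      ks_p = mean(.data$ks_p),
      pearson_r = mean_def(.data$pearson_r),
      rmse = mean_def(.data$rmse),
      area_sd = .data$area_sd[1],
      .groups = "drop"
    )
}

write_experiment <- function(exp) {
  dir.create(exp$config$output_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(exp$config$output_dir, f)
  write.csv(exp$results, p("metrics_raw.csv"), row.names = FALSE)
  write.csv(exp$means, p("metrics_mean.csv"), row.names = FALSE)
  for (nm in names(exp$trees)) {
    if (is.null(exp$trees[[nm]])) next
    write_tree_json(exp$trees[[nm]], p(sprintf("tree_%s.json", nm)))
  }
  for (nm in names(exp$smooths)) {
    fit <- exp$smooths[[nm]]
    if (!is.null(fit) && !is.null(fit$model)) {
      for (cv in fit$covariates) {
        write.csv(smooth_profile(fit, cv),
          p(sprintf("smooth_%s_by_%s.csv", nm, cv)),
          row.names = FALSE
        )
      }
    }
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("gridrep")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC"),
    master_seed = exp$config$master_seed,
    area_seeds = exp$areas$seed,
    n_failed = exp$n_failed,
    config = exp$config[setdiff(names(exp$config), "output_dir")]
  )
  jsonlite::write_json(manifest, p("manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA, force = TRUE
  )
  invisible(exp)
}

#' @export
print.grid_experiment <- function(x, ...) {
  cat(sprintf(
    "<grid_experiment> %d areas x %d sizes x %d iterations (seed %d)\n",
    x$config$n_areas, length(x$config$sizes), x$config$iterations,
    x$config$master_seed
  ))
  cat(sprintf(
    "  %d raw rows, %d mean rows, %d failed area(s)\n",
    nrow(x$results), nrow(x$means), x$n_failed
  ))
  de <- vapply(
    x$smooths,
    function(s) if (is.null(s)) NA_real_ else s$deviance_explained,
    numeric(1)
  )
  cat("  deviance explained:",
    paste(sprintf("%s %.1f%%", names(de), 100 * de), collapse = ", "), "\n")
  invisible(x)
}

#' @method autoplot grid_experiment
#' @export
autoplot.grid_experiment <- function(object,
                                     metric = c("ks_p", "pearson_r", "rmse"),
                                     source = NULL, ...) {
  metric <- match.arg(metric)
  source <- source %||% if (metric == "ks_p") "sample" else "interpolation"
  d <- dplyr::filter(object$means, .data$source == .env$source)
  nm <- paste0(
    if (source == "sample") "sample_" else "interp_",
    if (metric == "pearson_r") "r" else metric
  )
  gg <- ggplot2::ggplot(
    d, ggplot2::aes(x = .data$sample_size, y = .data[[metric]])
  ) +
    ggplot2::geom_point(ggplot2::aes(color = .data$area_sd), alpha = 0.7) +
    ggplot2::scale_color_viridis_c(name = "area SD (m)") +
    ggplot2::labs(
      x = "sample size", y = metric,
      title = sprintf("%s vs sample size (%s)", metric, source)
    ) +
    ggplot2::theme_minimal()
  fit <- object$smooths[[nm]]
  if (!is.null(fit) && !is.null(fit$model) && "sample_size" %in% fit$covariates) {
    prof <- smooth_profile(fit, "sample_size")
    gg <- gg +
      ggplot2::geom_ribbon(
        data = prof,
        ggplot2::aes(
          x = .data$sample_size, ymin = .data$lower, ymax = .data$upper
        ),
        inherit.aes = FALSE, alpha = 0.25, fill = "steelblue"
      ) +
      ggplot2::geom_line(
        data = prof,
        ggplot2::aes(x = .data$sample_size, y = .data$fit),
        inherit.aes = FALSE, color = "steelblue"
      )
  }
  gg
}
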