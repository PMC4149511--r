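#' Penalized-spline trend of a metric over sample size and heterogeneity
#'
#' Fits an additive Gaussian model `y ~ s(sample_size) + s(sd)` with
#' penalized regression splines, the smoothing parameter selected by
#' generalized cross-validation — the trend model behind the
#' metric-vs-sample-size figures. Covariates with a single unique value are
#' dropped from the formula with a warning (a smooth of a constant is
#' unidentifiable); rows with non-finite response (e.g. undefined
#' correlations) are dropped listwise. Basis dimension per smooth adapts to
#' the number of distinct covariate values, which for designed experiments
#' is often small (six sample sizes).
#'
#' @param data Data frame holding the covariates and response.
#' @param response Name of the response column (string), e.g. `"rmse"`.
#' @param covariates Character vector of covariate columns; default
#'   `c("sample_size", "sd")` (an `area_sd` column is accepted for `sd`).
#' @return A `smooth_fit`: the fitted mgcv model plus `deviance_explained`
#'   (1 - RSS/TSS for this Gaussian case) and a `fitted` tibble with
#'   pointwise fit and 95% interval (`fit ± 1.96 * SE`). Supports [tidy()],
#'   [glance()], [autoplot()] and [smooth_profile()].
#' @export
#' @examples
#' d <- tibble::tibble(
#'   sample_size = rep(c(4, 8, 16, 30, 60, 120), each = 10),
#'   sd = runif(60, 1, 56)
#' )
#' d$y <- log(d$sample_size) + rnorm(60, 0, 0.1)
#' glance(fit_smooth(d, "y"))
fit_smooth <- function(data, response,
                       covariates = c("sample_size", "sd")) {
  data <- as.data.frame(data)
  if (!"sd" %in% names(data) && "area_sd" %in% names(data)) {
    data$sd <- data$area_sd
  }
  missing_cols <- setdiff(c(response, covariates), names(data))
  if (length(missing_cols)) {
    abort(paste("Missing columns:", paste(missing_cols, collapse = ", ")))
  }
  keep <- is.finite(data[[response]])
  data <- data[keep, , drop = FALSE]
  if (nrow(data) < 10L) abort("Need at least 10 rows with finite response.")

  y <- data[[response]]
  terms <- character(0)
  used <- character(0)
  for (cv in covariates) {
    u <- length(unique(data[[cv]]))
    if (u < 2L) {
      warn(sprintf("Covariate '%s' has no variation; dropping its smooth.", cv))
      next
    }
    used <- c(used, cv)
    if (u < 4L) {
      terms <- c(terms, cv) # too few levels for a spline: linear term
    } else {
      k <- min(10L, u - 1L)
      terms <- c(terms, sprintf("s(%s, k = %d)", cv, k))
    }
  }

  if (var(y) == 0 || length(terms) == 0L) {
    # constant response or no usable covariate: intercept-only trend
    fit <- NULL
    fitted_tbl <- tibble::tibble(
      fit = rep(mean(y), nrow(data)), se = 0,
      lower = mean(y), upper = mean(y)
    )
    dev_expl <- 0
  } else {
    form <- stats::as.formula(paste(response, "~", paste(terms, collapse = " + ")))
    fit <- mgcv::gam(form, data = data, method = "GCV.Cp")
    sm <- summary(fit)
    dev_expl <- max(0, min(1, sm$dev.expl))
    pr <- predict(fit, se.fit = TRUE)
    fitted_tbl <- tibble::tibble(
      fit = as.numeric(pr$fit), se = as.numeric(pr$se.fit),
      lower = as.numeric(pr$fit - 1.96 * pr$se.fit),
      upper = as.numeric(pr$fit + 1.96 * pr$se.fit)
    )
  }
  structure(
    list(
      response_name = response,
      covariates = used,
      model = fit,
      data = tibble::as_tibble(data[c(used, response)]),
      deviance_explained = dev_expl,
      fitted = fitted_tbl,
      n = nrow(data)
    ),
    class = "smooth_fit"
  )
}

#' @export
print.smooth_fit <- function(x, ...) {
  cat(sprintf(
    "<smooth_fit> %s ~ %s | n = %d, deviance explained = %.1f%%\n",
    x$response_name,
    if (length(x$covariates)) paste(x$covariates, collapse = " + ") else "1",
    x$n, 100 * x$deviance_explained
  ))
  invisible(x)
}

#' @method tidy smooth_fit
#' @export
tidy.smooth_fit <- function(x, ...) {
  if (is.null(x$model)) {
    return(tibble::tibble(
      term = character(), edf = numeric(),
      statistic = numeric(), p.value = numeric()
    ))
  }
  sm <- summary(x$model)
  st <- sm$s.table
  out <- tibble::tibble(
    term = if (is.null(st)) character() else rownames(st),
    edf = if (is.null(st)) numeric() else unname(st[, "edf"]),
    statistic = if (is.null(st)) numeric() else unname(st[, "F"]),
    p.value = if (is.null(st)) numeric() else unname(st[, "p-value"])
  )
  pt <- sm$p.table
  if (!is.null(pt) && nrow(pt) > 1L) {
    lin <- rownames(pt)[-1]
    out <- dplyr::bind_rows(out, tibble::tibble(
      term = lin, edf = 1,
      statistic = unname(pt[-1, "t value"])^2,
      p.value = unname(pt[-1, "Pr(>|t|)"])
    ))
  }
  out
}

#' @method glance smooth_fit
#' @export
glance.smooth_fit <- function(x, ...) {
  tibble::tibble(
    response = x$response_name,
    deviance_explained = x$deviance_explained,
    n = x$n,
    gcv = if (is.null(x$model)) NA_real_ else as.numeric(x$model$gcv.ubre),
    aic = if (is.null(x$model)) NA_real_ else stats::AIC(x$model)
  )
}

#' Marginal trend profile of a fitted smooth
#'
#' Evaluates the fitted trend along one covariate on a regular grid, holding
#' the other covariates at their median — the curve (with 95% band) drawn
#' through metric-vs-sample-size scatters. Export this tibble as CSV to
#' share trend fits.
#'
#' @param fit A `smooth_fit`.
#' @param covariate Covariate to profile (default: the first one).
#' @param n Grid resolution.
#' @return Tibble with the covariate grid, `fit`, `lower`, `upper`.
#' @export
smooth_profile <- function(fit, covariate = fit$covariates[1], n = 100) {
  if (is.null(fit$model)) {
    abort("This smooth_fit is an intercept-only trend; nothing to profile.")
  }
  if (!covariate %in% fit$covariates) {
    abort(sprintf("'%s' is not a covariate of this fit.", covariate))
  }
  grid <- tibble::tibble(
    !!covariate := seq(min(fit$data[[covariate]]), max(fit$data[[covariate]]),
      length.out = n
    )
  )
  for (other in setdiff(fit$covariates, covariate)) {
    grid[[other]] <- stats::median(fit$data[[other]])
  }
  pr <- predict(fit$model, newdata = grid, se.fit = TRUE)
  grid$fit <- as.numeric(pr$fit)
  grid$lower <- grid$fit - 1.96 * as.numeric(pr$se.fit)
  grid$upper <- grid$fit + 1.96 * as.numeric(pr$se.fit)
  grid
}

#' @method autoplot smooth_fit
#' @export
autoplot.smooth_fit <- function(object, covariate = object$covariates[1],
                                ...) {
  prof <- smooth_profile(object, covariate)
  ggplot2::ggplot(
    object$data,
    ggplot2::aes(x = .data[[covariate]], y = .data[[object$response_name]])
  ) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_ribbon(
      data = prof,
      ggplot2::aes(x = .data[[covariate]], ymin = .data$lower, ymax = .data$upper),
      inherit.aes = FALSE, alpha = 0.25, fill = "steelblue"
    ) +
    ggplot2::geom_line(
      data = prof,
      ggplot2::aes(x = .data[[covariate]], y = .data$fit),
      inherit.aes = FALSE, color = "steelblue"
    ) +
    ggplot2::labs(
      y = object$response_name,
      title = sprintf(
        "Trend of %s (deviance explained %.1f%%)",
        object$response_name, 100 * object$deviance_explained
      )
    ) +
    ggplot2::theme_minimal()
}
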