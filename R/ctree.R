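#' Conditional-inference tree for break-point detection
#'
#' Recursive partitioning in the conditional-inference style, used to locate
#' thresholds ("break-points") where sample size or surface heterogeneity
#' changes a metric's response. At each node:
#'
#' 1. Each covariate's association with the response is tested with a
#'    Monte-Carlo permutation test on the absolute centered linear statistic
#'    `|sum((x - mean(x)) * y)|` (the standardization of the classical
#'    asymptotic version is a monotone rescaling, so the permutation p-value
#'    is identical); the p-value is the plus-one-corrected proportion of
#'    permuted statistics at least as large as the observed one.
#' 2. p-values are Bonferroni-adjusted across the covariates tested.
#' 3. Splitting stops when the smallest adjusted p-value is not below
#'    `alpha`, or the node is smaller than `2 * min_node`.
#' 4. Otherwise the covariate with the smallest adjusted p is split at the
#'    cutpoint maximizing the two-sample statistic
#'    `|mean_left - mean_right| * sqrt(n_left * n_right / n)`, scanning the
#'    midpoints between distinct sorted values (ties to the lower cutpoint)
#'    subject to both children holding at least `min_node` rows.
#'
#' Monte-Carlo permutation (rather than the asymptotic conditional
#' distribution) keeps the test exact at small node sizes; seed the session
#' for reproducible trees. Permutations are drawn as index shuffles, so
#' p-values are invariant to affine transforms of the response.
#'
#' @param data Data frame with the covariates and response.
#' @param response Response column name (string).
#' @param covariates Covariate column names; default `c("sample_size", "sd")`
#'   (an `area_sd` column is accepted for `sd`).
#' @param alpha Significance level for splitting, in (0, 1).
#' @param permutations Monte-Carlo permutations per test (default 9999;
#'   values below 100 trigger a warning).
#' @param min_node Minimum rows per leaf.
#' @return A `ctree_fit` holding the root `ctree_node` (fields: `node_id`,
#'   `is_leaf`, `split_covariate`, `split_value`, `adjusted_p`, `node_mean`,
#'   `n_obs`, children `left`/`right` with left = rows `<= split_value`).
#'   Supports [tidy()], [glance()], `print()`, [count_splits_by_covariate()]
#'   and [write_tree_json()].
#' @export
#' @examples
#' set.seed(1)
#' d <- tibble::tibble(
#'   sample_size = rep(c(4, 8, 16, 30, 60, 120), each = 20),
#'   sd = runif(120, 1, 56)
#' )
#' d$y <- ifelse(d$sample_size <= 16, 0, 1) + rnorm(120, 0, 0.05)
#' fit_ctree(d, "y", permutations = 499)
fit_ctree <- function(data, response, covariates = c("sample_size", "sd"),
                      alpha = 0.05, permutations = 9999, min_node = 20) {
  data <- as.data.frame(data)
  if (!"sd" %in% names(data) && "area_sd" %in% names(data)) {
    data$sd <- data$area_sd
  }
  missing_cols <- setdiff(c(response, covariates), names(data))
  if (length(missing_cols)) {
    abort(paste("Missing columns:", paste(missing_cols, collapse = ", ")))
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be in (0, 1).")
  }
  if (permutations < 100) {
    warn("Fewer than 100 permutations gives coarse p-values.")
  }
  keep <- is.finite(data[[response]])
  data <- data[keep, , drop = FALSE]
  if (nrow(data) < 2 * min_node) {
    abort(sprintf("Need at least 2 * min_node = %d rows.", 2 * min_node))
  }
  y <- data[[response]]
  X <- as.matrix(data[covariates])
  counter <- new.env(parent = emptyenv())
  counter$id <- 0L
  root <- grow_node(
    X, y, seq_along(y), covariates, alpha,
    as.integer(permutations), as.integer(min_node), counter
  )
  structure(
    list(
      root = root, response_name = response, covariates = covariates,
      alpha = alpha, permutations = as.integer(permutations),
      min_node = as.integer(min_node), n = length(y)
    ),
    class = "ctree_fit"
  )
}

grow_node <- function(X, y, idx, covariates, alpha, B, min_node, counter) {
  counter$id <- counter$id + 1L
  node <- list(
    node_id = counter$id,
    is_leaf = TRUE,
    split_covariate = NA_character_,
    split_value = NA_real_,
    adjusted_p = NA_real_,
    node_mean = mean(y[idx]),
    n_obs = length(idx),
    left = NULL, right = NULL
  )
  class(node) <- "ctree_node"
  n <- length(idx)
  yy <- y[idx]
  if (n < 2L * min_node || var(yy) == 0) {
    return(node)
  }

  # one shared set of index permutations across covariates
  perm_idx <- vapply(seq_len(B), function(i) sample.int(n), integer(n))
  Yp <- matrix(yy[perm_idx], nrow = n)
  testable <- vapply(
    covariates,
    function(cv) length(unique(X[idx, cv])) > 1L, logical(1)
  )
  if (!any(testable)) {
    return(node)
  }
  pvals <- rep(NA_real_, length(covariates))
  for (j in which(testable)) {
    xc <- X[idx, covariates[j]]
    xc <- xc - mean(xc)
    obs <- abs(sum(xc * yy))
    perm <- abs(as.vector(crossprod(xc, Yp)))
    pvals[j] <- (1 + sum(perm >= obs)) / (B + 1)
  }
  p_adj <- pmin(1, pvals * sum(testable)) # Bonferroni over tested covariates
  if (min(p_adj, na.rm = TRUE) >= alpha) {
    return(node)
  }
  j <- which.min(p_adj)
  cut <- best_cutpoint(X[idx, covariates[j]], yy, min_node)
  if (is.na(cut)) {
    return(node)
  }

  go_left <- X[idx, covariates[j]] <= cut
  node$is_leaf <- FALSE
  node$split_covariate <- covariates[j]
  node$split_value <- cut
  node$adjusted_p <- p_adj[j]
  node$left <- grow_node(
    X, y, idx[go_left], covariates, alpha, B, min_node, counter
  )
  node$right <- grow_node(
    X, y, idx[!go_left], covariates, alpha, B, min_node, counter
  )
  node
}

# Best cutpoint for a single covariate: maximize
# |mean_left - mean_right| * sqrt(nL * nR / n) over midpoints between
# distinct sorted values, ties resolved to the lower cutpoint, children
# constrained to >= min_node rows. Returns NA when no cutpoint is feasible.
best_cutpoint <- function(x, y, min_node) {
  ord <- order(x)
  xs <- x[ord]
  ys <- y[ord]
  n <- length(xs)
  csum <- cumsum(ys)
  total <- csum[n]
  # candidate split after position i (left = 1..i)
  cand <- which(xs[-n] < xs[-1]) # distinct neighbors only
  cand <- cand[cand >= min_node & (n - cand) >= min_node]
  if (!length(cand)) {
    return(NA_real_)
  }
  nl <- cand
  nr <- n - cand
  stat <- abs(csum[cand] / nl - (total - csum[cand]) / nr) * sqrt(nl * nr / n)
  best <- cand[which.max(stat)] # which.max takes the first (lower) tie
  unname((xs[best] + xs[best + 1]) / 2)
}

#' Count internal nodes by split covariate
#'
#' How often each covariate drives a break-point: the per-covariate count of
#' internal nodes of a fitted tree. Counts sum to the number of internal
#' nodes; a single-leaf tree yields an empty table.
#'
#' @param tree A `ctree_fit` (or `ctree_node`).
#' @return Tibble with `covariate` and `n_splits`.
#' @export
count_splits_by_covariate <- function(tree) {
  root <- if (inherits(tree, "ctree_fit")) tree$root else tree
  covs <- character(0)
  walk <- function(nd) {
    if (is.null(nd) || nd$is_leaf) {
      return(invisible())
    }
    covs[[length(covs) + 1L]] <<- nd$split_covariate
    walk(nd$left)
    walk(nd$right)
  }
  walk(root)
  if (!length(covs)) {
    return(tibble::tibble(covariate = character(), n_splits = integer()))
  }
  tibble::tibble(covariate = covs) |>
    dplyr::count(.data$covariate, name = "n_splits")
}

flatten_tree <- function(root, depth = 0) {
  row <- tibble::tibble(
    node_id = root$node_id,
    depth = depth,
    is_leaf = root$is_leaf,
    split_covariate = root$split_covariate,
    split_value = root$split_value,
    adjusted_p = root$adjusted_p,
    node_mean = root$node_mean,
    n_obs = root$n_obs
  )
  if (root$is_leaf) {
    return(row)
  }
  dplyr::bind_rows(
    row,
    flatten_tree(root$left, depth + 1),
    flatten_tree(root$right, depth + 1)
  )
}

#' @method tidy ctree_fit
#' @export
tidy.ctree_fit <- function(x, ...) {
  flatten_tree(x$root)
}

#' @method glance ctree_fit
#' @export
glance.ctree_fit <- function(x, ...) {
  tb <- flatten_tree(x$root)
  tibble::tibble(
    response = x$response_name,
    n = x$n,
    n_nodes = nrow(tb),
    n_internal = sum(!tb$is_leaf),
    n_leaves = sum(tb$is_leaf),
    depth = max(tb$depth),
    alpha = x$alpha,
    permutations = x$permutations
  )
}

#' @export
print.ctree_fit <- function(x, ...) {
  cat(sprintf(
    "<ctree_fit> %s | n = %d, alpha = %g, %d permutations\n",
    x$response_name, x$n, x$alpha, x$permutations
  ))
  cat(format_ctree_node(x$root), sep = "\n")
  invisible(x)
}

format_ctree_node <- function(nd, indent = "") {
  if (nd$is_leaf) {
    return(sprintf(
      "%s[%d] leaf: mean = %.4g (n = %d)",
      indent, nd$node_id, nd$node_mean, nd$n_obs
    ))
  }
  c(
    sprintf(
      "%s[%d] %s <= %.4g (adj. p = %.4g, n = %d)",
      indent, nd$node_id, nd$split_covariate, nd$split_value,
      nd$adjusted_p, nd$n_obs
    ),
    format_ctree_node(nd$left, paste0(indent, "  ")),
    format_ctree_node(nd$right, paste0(indent, "  "))
  )
}

node_to_list <- function(nd) {
  out <- list(
    node_id = nd$node_id, is_leaf = nd$is_leaf,
    node_mean = nd$node_mean, n_obs = nd$n_obs
  )
  if (!nd$is_leaf) {
    out$split_covariate <- nd$split_covariate
    out$split_value <- nd$split_value
    out$adjusted_p <- nd$adjusted_p
    out$left <- node_to_list(nd$left)
    out$right <- node_to_list(nd$right)
  }
  out
}

#' Serialize a fitted tree to JSON
#'
#' Writes the nested node structure (split covariate and value, adjusted
#' p-value, node mean, child links) as a JSON file.
#'
#' @param tree A `ctree_fit`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tree_json <- function(tree, path) {
  obj <- list(
    response = tree$response_name,
    alpha = tree$alpha,
    permutations = tree$permutations,
    min_node = tree$min_node,
    n = tree$n,
    root = node_to_list(tree$root)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
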