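# Independent brute-force oracles kept deliberately naive: these are the
# reference implementations the fast paths are checked against.

# KS D by an explicit double sweep of both ECDFs over every pooled value.
ks_D_oracle <- function(a, b) {
  pooled <- sort(c(a, b))
  d <- vapply(pooled, function(x) {
    abs(mean(a <= x) - mean(b <= x))
  }, numeric(1))
  max(d)
}

# IDW by a double loop over targets and samples, straight from the weight
# formula, with the zero-distance passthrough.
idw_oracle <- function(sx, sy, sz, tx, ty, power = 2) {
  vapply(seq_along(tx), function(i) {
    d <- sqrt((tx[i] - sx)^2 + (ty[i] - sy)^2)
    if (any(d == 0)) {
      return(mean(sz[d == 0]))
    }
    w <- d^(-power)
    sum(w * sz) / sum(w)
  }, numeric(1))
}

# Brute-force argmax of the two-sample split statistic over every cutpoint
# between distinct sorted covariate values, children >= min_node.
cutpoint_oracle <- function(x, y, min_node) {
  ux <- sort(unique(x))
  if (length(ux) < 2L) {
    return(NA_real_)
  }
  cuts <- (ux[-length(ux)] + ux[-1]) / 2
  n <- length(x)
  stat <- vapply(cuts, function(cu) {
    l <- x <= cu
    nl <- sum(l)
    nr <- n - nl
    if (nl < min_node || nr < min_node) {
      return(-Inf)
    }
    abs(mean(y[l]) - mean(y[!l])) * sqrt(nl * nr / n)
  }, numeric(1))
  if (all(!is.finite(stat))) {
    return(NA_real_)
  }
  cuts[which.max(stat)]
}

# Population SD (n - 1 denominator, matching sd()) of an arithmetic sequence.
seq_sd <- function(v) sqrt(sum((v - mean(v))^2) / (length(v) - 1))

# Locate a node by id in a fitted tree.
find_node <- function(nd, id) {
  if (nd$node_id == id) {
    return(nd)
  }
  if (nd$is_leaf) {
    return(NULL)
  }
  left <- find_node(nd$left, id)
  if (!is.null(left)) left else find_node(nd$right, id)
}

# A small correlated test surface.
small_field <- function(sd = 30, seed = 11, rows = 20, cols = 20) {
  make_gaussian_field(terrain_spec(
    rows = rows, cols = cols, cell_size = 90,
    target_mean = 100, target_sd = sd, correlation_length = 400, seed = seed
  ))
}
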