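sizes6 <- c(4, 8, 16, 30, 60, 120)

step_data <- function(n_per = 20, noise = 0.05, break_after = 16) {
  d <- tibble::tibble(
    sample_size = rep(sizes6, each = n_per),
    sd = runif(6 * n_per, 1, 56)
  )
  d$y <- ifelse(d$sample_size <= break_after, 0, 1) + rnorm(nrow(d), 0, noise)
  d
}

test_that("a step in sample size is found at the generating gap", {
  set.seed(31)
  d <- step_data()
  fit <- fit_ctree(d, "y", permutations = 999)
  expect_false(fit$root$is_leaf)
  expect_equal(fit$root$split_covariate, "sample_size")
  expect_gte(fit$root$split_value, 16)
  expect_lt(fit$root$split_value, 30)
  expect_lt(fit$root$adjusted_p, 0.05)
})

test_that("a step in heterogeneity is found near the generating value", {
  set.seed(32)
  n <- 240
  d <- tibble::tibble(
    sample_size = sample(sizes6, n, replace = TRUE),
    sd = runif(n, 1, 56)
  )
  d$y <- ifelse(d$sd <= 20, 0, 1) + rnorm(n, 0, 0.05)
  fit <- fit_ctree(d, "y", permutations = 999)
  expect_equal(fit$root$split_covariate, "sd")
  expect_lt(abs(fit$root$split_value - 20), 3)
})

test_that("a constant response and tiny nodes never split", {
  d <- step_data()
  d$y <- 5
  fit <- fit_ctree(d, "y", permutations = 199)
  expect_true(fit$root$is_leaf)
  expect_equal(fit$root$node_mean, 5)

  expect_error(
    fit_ctree(step_data(n_per = 3), "y", min_node = 20),
    "min_node"
  )
  expect_error(fit_ctree(step_data(), "y", alpha = 1.5), "alpha")
  expect_warning(fit_ctree(step_data(), "y", permutations = 50), "100")
})

test_that("every leaf respects min_node and children partition the parent", {
  set.seed(33)
  d <- step_data(n_per = 30, noise = 0.3)
  fit <- fit_ctree(d, "y", permutations = 499, min_node = 25)
  tb <- tidy(fit)
  expect_true(all(tb$n_obs[tb$is_leaf] >= 25))
  internal <- tb[!tb$is_leaf, ]
  for (id in internal$node_id) {
    nd <- find_node(fit$root, id)
    expect_equal(nd$left$n_obs + nd$right$n_obs, nd$n_obs)
  }
})

test_that("permutation p-values are invariant to affine response transforms", {
  set.seed(34)
  d <- step_data(noise = 0.4)
  d2 <- d
  d2$y <- -3.7 * d$y + 11
  set.seed(2024)
  f1 <- fit_ctree(d, "y", permutations = 499)
  set.seed(2024) # same index permutations for both fits
  f2 <- fit_ctree(d2, "y", permutations = 499)
  t1 <- tidy(f1)
  t2 <- tidy(f2)
  expect_equal(t2$adjusted_p, t1$adjusted_p)
  expect_equal(t2$split_covariate, t1$split_covariate)
  expect_equal(t2$split_value, t1$split_value)
})

test_that("the chosen cutpoint equals the brute-force argmax on two-group data", {
  set.seed(35)
  for (i in 1:5) {
    n <- 120
    x <- sample(sizes6, n, replace = TRUE)
    y <- ifelse(x <= sample(c(8, 16, 30), 1), 0, 10) + rnorm(n, 0, 0.01)
    d <- tibble::tibble(sample_size = x, sd = runif(n, 1, 56), y = y)
    fit <- fit_ctree(d, "y", permutations = 299, min_node = 10)
    expect_equal(
      fit$root$split_value,
      cutpoint_oracle(x, y, min_node = 10)
    )
  }
})

test_that("independent noise usually yields a single leaf", {
  leaves <- vapply(1:20, function(seed) {
    set.seed(seed)
    d <- tibble::tibble(
      sample_size = sample(sizes6, 400, replace = TRUE),
      sd = runif(400, 1, 56),
      y = rnorm(400)
    )
    fit_ctree(d, "y", permutations = 299)$root$is_leaf
  }, logical(1))
  expect_gte(mean(leaves), 0.9)
})

test_that("split counts by covariate are conserved and empty for leaves", {
  set.seed(36)
  d <- step_data()
  d$y <- d$y + ifelse(d$sd > 30, 0.5, 0) # splits on both covariates
  fit <- fit_ctree(d, "y", permutations = 499)
  counts <- count_splits_by_covariate(fit)
  tb <- tidy(fit)
  expect_equal(sum(counts$n_splits), sum(!tb$is_leaf))
  expect_gte(counts$n_splits[counts$covariate == "sample_size"], 1L)

  d$y <- 1
  leaf_fit <- fit_ctree(d, "y", permutations = 199)
  expect_equal(nrow(count_splits_by_covariate(leaf_fit)), 0L)
})

test_that("trees serialize to indented text and JSON", {
  set.seed(37)
  fit <- fit_ctree(step_data(), "y", permutations = 499)
  txt <- capture.output(print(fit))
  expect_true(any(grepl("sample_size <=", txt)))
  expect_true(any(grepl("leaf: mean", txt)))

  f <- withr::local_tempfile(fileext = ".json")
  write_tree_json(fit, f)
  parsed <- jsonlite::read_json(f)
  expect_equal(parsed$response, "y")
  expect_equal(parsed$root$split_covariate, "sample_size")
  expect_false(parsed$root$is_leaf)

  gl <- glance(fit)
  expect_equal(gl$n_nodes, gl$n_internal + gl$n_leaves)
})
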