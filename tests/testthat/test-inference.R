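test_that("breadth-first component search matches igraph on random small graphs", {
  skip_if_not_installed("igraph")
  set.seed(11)
  for (case in 1:12) {
    n_v <- sample(5:20, 1)
    n_e <- sample(1:25, 1)
    edges <- unique(t(replicate(n_e, sort(sample(n_v, 2)))))
    got <- oscdev:::bfs_components(edges)
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    want <- igraph::components(g)$membership
    # edges grouped by the component of their first endpoint
    want_groups <- split(seq_len(nrow(edges)), want[edges[, 1]])
    got_sorted <- lapply(got, sort)
    want_sorted <- lapply(unname(want_groups), sort)
    expect_setequal(lapply(got_sorted, paste, collapse = ","),
                    lapply(want_sorted, paste, collapse = ","))
  }
  expect_equal(oscdev:::bfs_components(matrix(numeric(), 0, 2)), list())
})

test_that("NBS recovers a planted connected cluster and is reproducible", {
  set.seed(12)
  n_sub <- 60; n_reg <- 15
  n_edge <- choose(n_reg, 2)
  pairs <- which(upper.tri(diag(n_reg)), arr.ind = TRUE)
  grp <- rep(c("low", "high"), each = n_sub / 2)
  E <- matrix(rnorm(n_sub * n_edge, 0.4, 0.05), n_sub)
  # a 10-edge chain 1-2-3-...-11 carries a group difference
  chain <- cbind(1:10, 2:11)
  chain_idx <- apply(chain, 1, function(e)
    which(pairs[, 1] == e[1] & pairs[, 2] == e[2]))
  E[grp == "high", chain_idx] <- E[grp == "high", chain_idx] + 0.08
  arr <- edges_to_array(E, n_reg)
  res <- nbs(arr, list(type = "group", group = grp), threshold_p = 0.01,
             n_perm = 300, seed = 5)
  expect_gt(length(res$components), 0)
  big <- which.max(res$component_sizes)
  expect_lte(res$component_p[big], 0.05)
  found <- res$components[[big]]
  planted <- paste(chain[, 1] - 1, chain[, 2] - 1)
  got <- paste(found$region_i, found$region_j)
  expect_gte(length(intersect(planted, got)), 8)
  # bit-for-bit reproducibility with the same seed
  res2 <- nbs(arr, list(type = "group", group = grp), threshold_p = 0.01,
              n_perm = 300, seed = 5)
  expect_identical(res$null_max_size, res2$null_max_size)
  expect_identical(res$component_p, res2$component_p)
  # observed statistics are invariant to subject order
  ord <- sample(n_sub)
  res3 <- nbs(arr[, , ord], list(type = "group", group = grp[ord]),
              threshold_p = 0.01, n_perm = 10, seed = 5)
  expect_equal(res3$observed_max_size, res$observed_max_size)
  expect_true(!is.null(res3$warning))          # n_perm < 100 flagged
})

test_that("NBS handles null data and uses the (b+1)/(n+1) estimator", {
  set.seed(13)
  E <- matrix(rnorm(30 * choose(10, 2), 0.4, 0.05), 30)
  arr <- edges_to_array(E, 10)
  res <- nbs(arr, list(type = "regression", predictor = runif(30, 14, 31)),
             threshold_p = 1e-6, n_perm = 100, seed = 2)
  expect_length(res$components, 0)
  expect_equal(res$observed_max_size, 0L)
  expect_length(res$null_max_size, 100)
  res2 <- nbs(arr, list(type = "regression",
                        predictor = runif(30, 14, 31)),
              threshold_p = 0.2, n_perm = 100, seed = 2)
  expect_true(all(res2$component_p >= 1 / 101))
  expect_true(all(res2$component_p <= 1))
  # covariates are accepted in regression designs
  res3 <- nbs(arr, list(type = "regression", predictor = runif(30, 14, 31),
                        covariates = cbind(motion = runif(30))),
              threshold_p = 0.05, n_perm = 50, seed = 3)
  expect_s3_class(res3, "nbs_result")
})

test_that("mediation paths satisfy the OLS identity and recover planted effects", {
  set.seed(14)
  n <- 200
  x <- runif(n, 14, 31)
  m <- 0.5 * x + rnorm(n, 0, 2)
  y <- 0.4 * m + 0.1 * x + rnorm(n, 0, 1)
  res <- mediate(x, m, y, n_boot = 500, seed = 1)
  expect_equal(res$c, res$c_prime + res$ab, tolerance = 1e-10)
  expect_lt(abs(res$ab - 0.2), res$ab - res$ci[1])
  expect_true(res$ci[1] <= 0.2 && 0.2 <= res$ci[2])
  expect_true(res$significant)
  # independent mediator: indirect effect near zero, CI covers 0
  m0 <- rnorm(n)
  y0 <- 0.1 * x + rnorm(n, 0, 1)
  res0 <- mediate(x, m0, y0, n_boot = 500, seed = 1)
  expect_true(res0$ci[1] <= 0 && 0 <= res0$ci[2])
  expect_equal(res0$c, res0$c_prime + res0$ab, tolerance = 1e-10)
  # identical seeds give identical draws
  res_b <- mediate(x, m, y, n_boot = 500, seed = 1)
  expect_identical(res$ci, res_b$ci)
  expect_error(mediate(x[1:5], m[1:5], y[1:5]), ">= 10")
  expect_error(mediate(rep(1, 20), m[1:20], y[1:20]), "zero variance")
})

test_that("bootstrap CI width shrinks roughly like 1/sqrt(n)", {
  set.seed(15)
  widths <- vapply(c(50, 200), function(n) {
    x <- runif(n, 14, 31)
    m <- 0.5 * x + rnorm(n, 0, 2)
    y <- 0.4 * m + rnorm(n, 0, 1)
    r <- mediate(x, m, y, n_boot = 400, seed = n)
    r$ci[2] - r$ci[1]
  }, 0)
  expect_gt(widths[1] / widths[2], 1.4)
  expect_lt(widths[1] / widths[2], 3.0)
})

test_that("the mediation screen flags only the planted candidate", {
  set.seed(16)
  n <- 150
  x <- runif(n, 14, 31)
  m1 <- -0.02 * x + rnorm(n, 0, 0.05)
  m2 <- rnorm(n, 0, 0.05)
  m3 <- rnorm(n, 0, 0.05)
  y <- 2 + 3 * m1 + rnorm(n, 0, 0.15)
  scr <- mediation_screen(list(planted = m1, null_a = m2, null_b = m3),
                          x, y, n_boot = 500, seed = 4)
  expect_equal(scr$candidate[scr$q < 0.05], "planted")
  expect_true(scr$significant[1])
  expect_false(any(scr$significant[2:3]))
  # identical candidates give identical rows
  scr2 <- mediation_screen(list(a = m1, a = m1), x, y, n_boot = 200,
                           seed = 4)
  expect_equal(scr2$ab[1], scr2$ab[2])
  expect_equal(scr2$ci_lo[1], scr2$ci_lo[2])
  empty <- mediation_screen(list(), x, y)
  expect_equal(nrow(empty), 0)
})
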