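test_that("global metrics equal brute-force means", {
  v <- array(NA_real_, dim = c(3, 3, 2))
  v[, , 1] <- matrix(c(NA, 0.2, 0.4, 0.2, NA, 0.6, 0.4, 0.6, NA), 3)
  v[, , 2] <- matrix(0.5, 3, 3); diag(v[, , 2]) <- NA
  g <- global_metric(make_connectome(v, c(7, 8)))
  expect_equal(g$value, c(0.4, 0.5))          # mean of {0.2, 0.4, 0.6}
  set.seed(2)
  r <- array(runif(5 * 5 * 3), dim = c(5, 5, 3))
  r <- (r + aperm(r, c(2, 1, 3))) / 2
  gr <- global_metric(make_connectome(r, 1:3))
  brute <- sapply(1:3, function(f) {
    s <- 0; n <- 0
    for (i in 1:4) for (j in (i + 1):5) { s <- s + r[i, j, f]; n <- n + 1 }
    s / n
  })
  expect_equal(gr$value, brute, tolerance = 1e-12)
  pw <- make_power_set(matrix(1:6 / 21, 2, 3), 1:3)
  expect_equal(global_metric(pw)$value, colMeans(pw$values))
})

test_that("Benjamini-Hochberg adjustment matches the step-up hand computation", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_true(all(diff(fdr_adjust(sort(runif(20)))) >= 0))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(fdr_adjust(c(0.5, NA)), "\\[0, 1\\]")
})

test_that("per-frequency regressions recover planted slopes and handle constants", {
  set.seed(33)
  n <- 120
  subjects <- data.frame(subject_id = sprintf("S%03d", 1:n),
                         age_years = runif(n, 14, 31),
                         motion = rlnorm(n, log(0.4), 0.5))
  freqs <- 1:49
  tbl <- do.call(rbind, lapply(seq_len(n), function(s) {
    value <- 0.4 + rnorm(49, 0, 0.01)
    value[5:9] <- value[5:9] - 0.01 * (subjects$age_years[s] - 22.5)
    value[20] <- 0.123                      # constant across subjects
    data.frame(subject_id = subjects$subject_id[s], freq_hz = freqs,
               value = value)
  }))
  tbl <- merge(tbl, subjects, by = "subject_id")
  fit <- per_frequency_regression(tbl)
  expect_equal(nrow(fit), 49)
  expect_true(all(fit$q[fit$freq_hz %in% 5:9] < 0.05))
  expect_true(all(fit$beta[fit$freq_hz %in% 5:9] < 0))
  expect_false(any(fit$q[!fit$freq_hz %in% c(5:9)] < 0.05))
  const <- fit[fit$freq_hz == 20, ]
  expect_equal(const$beta, 0)
  expect_equal(const$p, 1)
})

test_that("the age-by-frequency mixed model has 48 interaction parameters and detects planted interactions", {
  set.seed(44)
  n <- 24
  subjects <- data.frame(subject_id = sprintf("S%03d", 1:n),
                         age_years = runif(n, 14, 31))
  make_tbl <- function(interaction) {
    do.call(rbind, lapply(seq_len(n), function(s) {
      base <- 0.4 + rnorm(1, 0, 0.02)      # subject random intercept
      value <- base + rnorm(49, 0, 0.01)
      if (interaction)
        value[5:9] <- value[5:9] - 0.012 * (subjects$age_years[s] - 22.5)
      data.frame(subject_id = subjects$subject_id[s], freq_hz = 1:49,
                 value = value, age_years = subjects$age_years[s])
    }))
  }
  fit <- fit_global_interaction(make_tbl(TRUE))
  expect_equal(fit$interaction$df, 48)      # (49 - 1) x 1 parameters
  expect_lt(fit$interaction$p, 0.05)
  fit0 <- fit_global_interaction(make_tbl(FALSE))
  expect_gt(fit0$interaction$p, 0.001)
})

test_that("edgewise age regression is structurally sound and shift-invariant", {
  set.seed(55)
  n_sub <- 30; n_reg <- 8
  subjects <- data.frame(subject_id = sprintf("S%02d", 1:n_sub),
                         age_years = runif(n_sub, 14, 31),
                         motion = rlnorm(n_sub, log(0.4), 0.5))
  E <- matrix(rnorm(n_sub * choose(n_reg, 2), 0.4, 0.05), n_sub)
  arr <- edges_to_array(E, n_reg)
  ef <- edgewise_age_regression(arr, subjects, nuisance_mode = "motion",
                                band = standard_bands()$theta)
  expect_equal(ef$beta, t(ef$beta))
  expect_true(all(is.na(diag(ef$beta))))
  expect_true(all(ef$se[upper.tri(ef$se)] > 0))
  # adding a constant to every subject's PLV at all edges leaves betas unchanged
  ef2 <- edgewise_age_regression(arr + 0.1, subjects,
                                 nuisance_mode = "motion")
  expect_equal(ef2$beta, ef$beta, tolerance = 1e-10)
  # constant PLV across subjects -> beta 0
  ef3 <- edgewise_age_regression(array(0.4, dim = dim(arr)), subjects,
                                 nuisance_mode = "motion")
  expect_equal(max(abs(ef3$beta), na.rm = TRUE), 0, tolerance = 1e-12)
})

test_that("the full nuisance set runs, floors logs, and flags rank deficiency", {
  set.seed(66)
  n_sub <- 30; n_reg <- 6
  subjects <- data.frame(subject_id = sprintf("S%02d", 1:n_sub),
                         age_years = runif(n_sub, 14, 31),
                         motion = rlnorm(n_sub, log(0.4), 0.5))
  E <- matrix(rnorm(n_sub * choose(n_reg, 2), 0.4, 0.05), n_sub)
  arr <- edges_to_array(E, n_reg)
  pw <- matrix(runif(n_reg * n_sub, 0.05, 0.2), n_reg)
  pw[1, 1] <- 0                              # exercises the log floor
  ef <- edgewise_age_regression(arr, subjects, band_power = pw,
                                nuisance_mode = "full")
  expect_true(all(is.finite(ef$beta[upper.tri(ef$beta)])))
  expect_error(edgewise_age_regression(arr, subjects, band_power = -pw,
                                       nuisance_mode = "full"),
               "negative")
  # age duplicated as motion -> collinear design names the column
  bad <- subjects; bad$motion <- bad$age_years
  expect_error(edgewise_age_regression(arr, bad, nuisance_mode = "motion"),
               "collinear")
})

test_that("summed region effects equal brute-force column sums", {
  b <- matrix(1, 10, 10)
  ef <- make_edge_effect(b)
  v <- summed_region_effect(ef)
  expect_equal(unname(v$summed_beta), rep(9, 10))   # n - 1 partners
  single <- matrix(0, 10, 10); single[2, 7] <- single[7, 2] <- -3
  vs <- summed_region_effect(make_edge_effect(single))
  expect_equal(unname(vs$summed_beta),
               c(0, -3, 0, 0, 0, 0, -3, 0, 0, 0))
  set.seed(77)
  r <- matrix(rnorm(64), 8); r <- (r + t(r)) / 2
  vr <- summed_region_effect(make_edge_effect(r))
  diag(r) <- 0
  expect_equal(unname(vr$summed_beta), colSums(r), tolerance = 1e-12)
})

test_that("regionwise power regressions sum betas over the band bins", {
  set.seed(88)
  n_sub <- 40; n_reg <- 6
  subjects <- data.frame(subject_id = sprintf("S%02d", 1:n_sub),
                         age_years = runif(n_sub, 14, 31),
                         motion = rlnorm(n_sub, log(0.4), 0.5))
  pw <- array(0.02, dim = c(n_reg, 49, n_sub))
  for (s in 1:n_sub)
    pw[, 1:3, s] <- 0.03 - 0.0008 * (subjects$age_years[s] - 22.5) +
      rnorm(n_reg * 3, 0, 0.001)
  bands <- standard_bands()
  dv <- regionwise_power_age_regression(pw, subjects, bands$delta)
  expect_true(all(dv$summed_beta < 0))
  expect_equal(dv$summed_beta,
               rowSums(attr(dv, "per_bin_beta")), tolerance = 1e-12)
  bv <- regionwise_power_age_regression(pw, subjects, bands$beta)
  expect_equal(ncol(attr(bv, "per_bin_beta")), 8)   # 14-16 and 22-26 Hz
  expect_equal(unname(bv$summed_beta), rep(0, n_reg), tolerance = 1e-10)
})

test_that("median split is deterministic with the stated tie rules", {
  g <- median_split(1:68)
  expect_equal(as.vector(table(g)), c(34, 34))
  g7 <- median_split(c(10, 20, 30, 40, 50, 60, 70))
  expect_equal(sum(g7 == "low"), 4)           # median-valued subject low
  expect_equal(which(g7 == "low"), 1:4)
  tied <- median_split(c(5, 5, 5, 1), ids = c("c", "a", "b", "z"))
  expect_equal(sum(tied == "low"), 2)
  expect_error(median_split(rep(3, 5)), "identical")
  expect_error(median_split(3), ">= 2")
})
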