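fs <- 250

test_that("band definitions follow the analysis conventions", {
  b <- standard_bands()
  expect_equal(b$theta$bins, 5:9)
  expect_equal(b$delta$bins, 1:3)
  expect_equal(b$beta$bins, c(14:16, 22:26))   # 8 non-contiguous bins
  expect_length(b$beta$bins, 8)
  bins <- five_hz_bins()
  expect_length(bins, 10)
  expect_equal(bins[[1]]$bins, 1:5)
  expect_equal(bins[["6-10"]]$bins, 6:10)
  expect_equal(bins[[10]]$bins, 46:49)          # final bin is 4 Hz wide
  expect_error(band_definition("bad", 0, 5), "lo")
  expect_error(band_definition("bad", bins = 50), "1-49")
})

test_that("epoching follows the floor rule", {
  ts300 <- roi_timeseries(matrix(rnorm(2 * 300 * fs), 2), fs, "s300")
  e <- epoch_timeseries(ts300, 3)
  expect_equal(dim(e$values), c(100, 2, 750))   # 100 three-second epochs
  ts10 <- roi_timeseries(matrix(rnorm(2 * 10 * fs), 2), fs, "s10")
  e10 <- epoch_timeseries(ts10, 3)
  expect_equal(dim(e10$values)[1], 3)           # 250 samples dropped
  expect_equal(e10$values[2, 1, ], ts10$values[1, 751:1500])
  ts2 <- roi_timeseries(matrix(rnorm(2 * 2 * fs), 2), fs, "s2")
  expect_error(epoch_timeseries(ts2, 3), "shorter")
})

test_that("DPSS tapers are orthonormal and deterministic", {
  tap <- dpss_tapers(750, nw = 2, k = 3)
  expect_equal(crossprod(tap), diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_identical(tap, dpss_tapers(750, nw = 2, k = 3))
  # first taper is symmetric and positive
  expect_equal(tap[, 1], rev(tap[, 1]), tolerance = 1e-9)
  expect_true(all(tap[, 1] > 0))
})

test_that("PLV is 1 for identical and constant-lag signals", {
  t <- (0:(30 * fs - 1)) / fs
  x <- cos(2 * pi * 10 * t + 0.3)
  pl <- compute_plv(epoch_timeseries(roi_timeseries(rbind(x, x), fs, "id")),
                    frequencies = c(5, 10, 20))
  expect_equal(pl$values[1, 2, ], rep(1, 3), tolerance = 1e-9)
  # narrowband signal with a fixed 5-sample lag: constant phase separation
  set.seed(8)
  n <- 60 * fs
  w <- rnorm(n + 5)
  spec <- fft(w)
  f <- c(0:(length(w) %/% 2), -((length(w) - 1) %/% 2):-1) *
    fs / length(w)
  spec[abs(abs(f) - 10) > 2] <- 0   # keep 8-12 Hz
  nb <- Re(fft(spec, inverse = TRUE)) / length(w)
  lagged <- rbind(nb[1:n], nb[1:n + 5])
  pl2 <- compute_plv(epoch_timeseries(roi_timeseries(lagged, fs, "lag")),
                     frequencies = 10)
  expect_gt(pl2$values[1, 2, 1], 0.99)
})

test_that("PLV is bounded, symmetric, amplitude-invariant, with undefined diagonal", {
  set.seed(4)
  x <- matrix(rnorm(3 * 30 * fs), 3)
  pl <- compute_plv(epoch_timeseries(roi_timeseries(x, fs, "w")))
  v <- pl$values
  expect_true(all(v[!is.na(v)] >= 0 & v[!is.na(v)] <= 1))
  expect_equal(v[1, 2, ], v[2, 1, ])
  expect_true(all(is.na(v[cbind(1:3, 1:3, 1)])))
  # scaling a signal's amplitude leaves PLV unchanged (phase-only measure)
  x2 <- x; x2[2, ] <- 13.7 * x2[2, ]
  pl2 <- compute_plv(epoch_timeseries(roi_timeseries(x2, fs, "w2")))
  expect_equal(pl2$values, pl$values, tolerance = 1e-12)
  expect_equal(pl$n_phase_samples, 10 * 3)   # epochs x tapers
})

test_that("uncoupled signals give chance-level PLV that shrinks like 1/sqrt(N)", {
  set.seed(5)
  x <- matrix(rnorm(6 * 60 * fs), 6)
  pl <- compute_plv(epoch_timeseries(roi_timeseries(x, fs, "w")))
  ut <- upper.tri(pl$values[, , 1])
  obs <- mean(apply(pl$values, 3, function(m) mean(m[ut])))
  expect_equal(obs, chance_plv(pl$n_phase_samples), tolerance = 0.05)
  # halving the recording (half the epochs) raises chance PLV ~ sqrt(2)
  pl_half <- compute_plv(epoch_timeseries(
    roi_timeseries(x[, 1:(30 * fs)], fs, "wh")))
  obs_half <- mean(apply(pl_half$values, 3, function(m) mean(m[ut])))
  expect_equal(obs_half / obs, sqrt(2), tolerance = 0.12)
  expect_error(compute_plv(epoch_timeseries(
    roi_timeseries(x[, 1:(3 * fs)], fs, "w1"), 3), n_tapers = 1),
    "phase samples")
})

test_that("taper-then-epoch pooling is a valid alternative", {
  set.seed(6)
  x <- matrix(rnorm(2 * 30 * fs), 2)
  x[2, ] <- x[1, ]
  pl <- compute_plv(epoch_timeseries(roi_timeseries(x, fs, "tm")),
                    frequencies = c(7, 20), pooling = "taper_mean")
  expect_equal(pl$values[1, 2, ], rep(1, 2), tolerance = 1e-9)
  expect_equal(pl$n_phase_samples, 10)   # epochs only
})

test_that("relative power is a proportion with the expected shape", {
  t <- (0:(30 * fs - 1)) / fs
  ts <- roi_timeseries(rbind(sin(2 * pi * 10 * t), rnorm(30 * fs)), fs, "p")
  rp <- compute_relative_power(ts)
  expect_equal(rowSums(rp$values), c(1, 1), tolerance = 1e-9)
  expect_true(all(rp$values >= 0))
  expect_gt(rp$values[1, 10], 0.9)       # pure 10 Hz tone
  set.seed(9)
  w <- matrix(rnorm(8 * 60 * fs), 8)
  rpw <- compute_relative_power(roi_timeseries(w, fs, "w"))
  expect_equal(mean(rpw$values), 1 / 49, tolerance = 1e-12)  # row identity
  expect_lt(max(abs(colMeans(rpw$values) - 1 / 49)), 0.1 / 49)
  zero <- ts; zero$values[1, ] <- 0
  expect_error(compute_relative_power(zero), "zero total power")
})

test_that("band averages equal brute-force means over the band bins", {
  set.seed(10)
  v <- array(runif(4 * 4 * 49), dim = c(4, 4, 49))
  v <- (v + aperm(v, c(2, 1, 3))) / 2
  conn <- make_connectome(v, 1:49)
  th <- standard_bands()$theta
  got <- band_average(conn, th)
  brute <- (v[, , 5] + v[, , 6] + v[, , 7] + v[, , 8] + v[, , 9]) / 5
  expect_equal(got, brute, tolerance = 1e-12)
  const <- make_connectome(array(0.37, dim = c(3, 3, 49)), 1:49)
  expect_equal(band_average(const, th), matrix(0.37, 3, 3))
  pw <- make_power_set(matrix(runif(3 * 49), 3), 1:49)
  bt <- standard_bands()$beta
  expect_equal(band_average(pw, bt), rowMeans(pw$values[, c(14:16, 22:26)]))
  expect_error(band_average(make_power_set(matrix(1, 2, 4), 1:4), th),
               "absent")
})
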