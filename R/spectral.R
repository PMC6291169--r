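# Spectral estimation: epoching, DPSS multitaper phase-locking value (PLV)
# per 1-Hz frequency, and Welch relative power per region.
#
# PLV between regions a and b at frequency f is
#   PLV = (1/N) | sum_n exp(i (theta_a(n) - theta_b(n))) |
# where the N phase-difference samples are the cross-spectral phasors of
# one DPSS-tapered 3-s epoch each: N = n_epochs x n_tapers.

.spectral_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal sequence (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` for time-bandwidth
#' product `nw` via the symmetric tridiagonal eigenproblem (diagonal
#' `((n-1-2t)/2)^2 cos(2 pi W)`, off-diagonal `t (n-t) / 2`, `W = nw/n`).
#' Tapers are unit-energy and orthogonal; results are cached per
#' `(n, nw, k)`.
#'
#' @param n Taper length in samples.
#' @param nw Time-bandwidth product (default 2, which concentrates 3
#'   tapers well on a 3-s window).
#' @param k Number of tapers (default 3).
#' @return `n x k` matrix, one taper per column.
#' @export
dpss_tapers <- function(n, nw = 2, k = 3) {
  n <- as.integer(check_number(n, "n", 8))
  k <- as.integer(check_number(k, "k", 1, n - 1))
  key <- sprintf("dpss_%d_%g_%d", n, nw, k)
  if (!is.null(.spectral_cache[[key]])) return(.spectral_cache[[key]])
  w <- nw / n
  tt <- 0:(n - 1)
  dg <- ((n - 1 - 2 * tt) / 2)^2 * cos(2 * pi * w)
  od <- tt[-1] * (n - tt[-1]) / 2
  A <- matrix(0, n, n)
  diag(A) <- dg
  A[cbind(2:n, 1:(n - 1))] <- od
  A[cbind(1:(n - 1), 2:n)] <- od
  eg <- eigen(A, symmetric = TRUE)
  tap <- eg$vectors[, seq_len(k), drop = FALSE]
  # unit energy; fix sign so each taper has nonnegative mean (even orders)
  # or positive initial slope (odd orders) - sign is irrelevant for PLV but
  # makes output deterministic across LAPACK builds.
  for (j in seq_len(k)) {
    tap[, j] <- tap[, j] / sqrt(sum(tap[, j]^2))
    s <- if (sum(tap[, j]) != 0) sign(sum(tap[, j])) else sign(tap[2, j] - tap[1, j])
    if (s < 0) tap[, j] <- -tap[, j]
  }
  .spectral_cache[[key]] <- tap
  tap
}

#' Construct a per-subject region-by-time signal container
#'
#' @param values Numeric matrix, regions x samples; all values finite.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param subject_id Subject identifier.
#' @return A `roi_timeseries` object.
#' @export
roi_timeseries <- function(values, sampling_rate_hz, subject_id = "subject") {
  values <- as.matrix(values)
  if (!is.numeric(values) || any(!is.finite(values)))
    stop_oscdev("time series for %s contains non-finite values", subject_id)
  check_number(sampling_rate_hz, "sampling_rate_hz", 1)
  structure(list(subject_id = subject_id,
                 sampling_rate_hz = sampling_rate_hz,
                 values = values),
            class = "roi_timeseries")
}

#' @method print roi_timeseries
#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("roi_timeseries '%s': %d regions x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, nrow(x$values), ncol(x$values),
              x$sampling_rate_hz, ncol(x$values) / x$sampling_rate_hz))
  invisible(x)
}

#' Cut a recording into non-overlapping epochs
#'
#' Splits the recording into consecutive non-overlapping epochs of
#' `epoch_length_s` seconds (default 3 s, giving 100 epochs for a 300-s
#' recording); trailing samples that do not fill an epoch are discarded.
#'
#' @param ts A [roi_timeseries()].
#' @param epoch_length_s Epoch length in seconds.
#' @return An `epoch_set` with `values` array `[epoch, region, sample]`.
#' @export
epoch_timeseries <- function(ts, epoch_length_s = 3) {
  stopifnot(inherits(ts, "roi_timeseries"))
  check_number(epoch_length_s, "epoch_length_s", 1e-6)
  spe <- round(epoch_length_s * ts$sampling_rate_hz)
  n_samp <- ncol(ts$values)
  n_epochs <- n_samp %/% spe
  if (n_epochs < 1L)
    stop_oscdev("recording (%d samples) shorter than one %g-s epoch (%d samples)",
                n_samp, epoch_length_s, spe)
  n_reg <- nrow(ts$values)
  flat <- t(ts$values[, seq_len(n_epochs * spe), drop = FALSE])
  dim(flat) <- c(spe, n_epochs * n_reg)  # cols: epoch fast, region slow
  # [sample, epoch, region] -> [epoch, region, sample]
  arr <- aperm(array(flat, dim = c(spe, n_epochs, n_reg)), c(2, 3, 1))
  structure(list(subject_id = ts$subject_id,
                 values = arr,
                 flat = flat,
                 epoch_length_s = epoch_length_s,
                 sampling_rate_hz = ts$sampling_rate_hz),
            class = "epoch_set")
}

#' @method print epoch_set
#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("epoch_set '%s': %d epochs x %d regions x %d samples (%g s @ %g Hz)\n",
              x$subject_id, d[1], d[2], d[3], x$epoch_length_s,
              x$sampling_rate_hz))
  invisible(x)
}

# Unit cross-spectral phasors, real and imaginary parts, as arrays
# [freq, region, epoch*taper]. The DFT is evaluated only at the requested
# bins via two real matrix products (BLAS), which is faster than a full
# FFT when few bins are needed.
epoch_phasors <- function(e, frequencies, n_tapers, nw = 2) {
  d <- dim(e$values)
  n_epochs <- d[1]; n_reg <- d[2]; spe <- d[3]
  fs <- e$sampling_rate_hz
  bin <- frequencies * spe / fs          # DFT bin index (0-based)
  if (any(abs(bin - round(bin)) > 1e-8))
    stop_oscdev("frequencies must align with the epoch DFT grid (resolution %g Hz)",
                fs / spe)
  bin <- as.integer(round(bin))
  if (any(bin < 1L) || any(bin > spe %/% 2L))
    stop_oscdev("requested frequency outside the resolvable range")
  tap <- dpss_tapers(spe, nw = nw, k = n_tapers)
  # columns ordered: epoch fastest, then region, then taper
  x <- if (!is.null(e$flat)) e$flat else {
    f <- aperm(e$values, c(3, 1, 2)); dim(f) <- c(spe, n_epochs * n_reg); f
  }
  ekey <- sprintf("dft_%d_%s", spe, paste(bin, collapse = "_"))
  basis <- .spectral_cache[[ekey]]
  if (is.null(basis)) {
    ang <- (2 * pi / spe) * outer(bin, 0:(spe - 1L))    # e^{-i 2 pi k t / n}
    basis <- list(re = cos(ang), im = -sin(ang))
    .spectral_cache[[ekey]] <- basis
  }
  n_cols <- n_reg * n_epochs
  nf <- length(bin)
  Fre <- matrix(0, nf, n_cols * n_tapers)
  Fim <- matrix(0, nf, n_cols * n_tapers)
  for (k in seq_len(n_tapers)) {
    xt <- x * tap[, k]
    idx <- (k - 1L) * n_cols + seq_len(n_cols)
    Fre[, idx] <- basis$re %*% xt
    Fim[, idx] <- basis$im %*% xt
  }
  md <- sqrt(Fre^2 + Fim^2)
  md[md == 0] <- 1                        # zero-amplitude bins -> 0 phasor
  list(re = Fre / md, im = Fim / md,
       n_epochs = n_epochs, n_reg = n_reg, n_tapers = n_tapers)
}

#' Multitaper phase-locking value connectome
#'
#' For every region pair and frequency, the modulus of the mean unit
#' cross-spectral phasor over all (epoch x taper) samples, using DPSS
#' tapers (default 3 tapers, time-bandwidth product 2) on non-overlapping
#' epochs. With the default `pooling = "pooled"` the number of
#' phase-difference samples N equals `n_epochs * n_tapers`; the alternative
#' `"taper_mean"` first averages phasors across tapers within an epoch,
#' renormalises, then averages across epochs.
#'
#' @param e An [epoch_timeseries()] result.
#' @param frequencies Analysis frequencies in Hz (default 1:49); must lie
#'   on the epoch DFT grid.
#' @param n_tapers Number of DPSS tapers (default 3).
#' @param nw Time-bandwidth product (default 2).
#' @param pooling `"pooled"` (default) or `"taper_mean"`.
#' @return A `spectral_connectome`: `values` array regions x regions x
#'   frequencies with PLV in \[0, 1\], symmetric, diagonal `NA`.
#' @export
compute_plv <- function(e, frequencies = 1:49, n_tapers = 3, nw = 2,
                        pooling = c("pooled", "taper_mean")) {
  stopifnot(inherits(e, "epoch_set"))
  pooling <- match.arg(pooling)
  if (any(frequencies < 1 | frequencies > 49))
    stop_oscdev("frequencies must lie within 1-49 Hz")
  d <- dim(e$values)
  n_epochs <- d[1]; n_reg <- d[2]
  n_samples <- n_epochs * n_tapers
  if (n_samples < 2L)
    stop_oscdev("PLV needs at least 2 phase samples (epochs x tapers), got %d",
                n_samples)
  U <- epoch_phasors(e, frequencies, n_tapers, nw)
  n_f <- length(frequencies)
  out <- array(NA_real_, dim = c(n_reg, n_reg, n_f))
  for (fi in seq_len(n_f)) {
    # [epoch, region, taper] -> regions x (epoch*taper), epoch fastest
    vr <- array(U$re[fi, ], dim = c(n_epochs, n_reg, n_tapers))
    vi <- array(U$im[fi, ], dim = c(n_epochs, n_reg, n_tapers))
    Zr <- matrix(aperm(vr, c(2, 1, 3)), nrow = n_reg)
    Zi <- matrix(aperm(vi, c(2, 1, 3)), nrow = n_reg)
    if (pooling == "taper_mean") {
      Zmr <- matrix(0, n_reg, n_epochs); Zmi <- matrix(0, n_reg, n_epochs)
      for (k in seq_len(n_tapers)) {
        idx <- (k - 1L) * n_epochs + seq_len(n_epochs)
        Zmr <- Zmr + Zr[, idx, drop = FALSE]
        Zmi <- Zmi + Zi[, idx, drop = FALSE]
      }
      m <- sqrt(Zmr^2 + Zmi^2); m[m == 0] <- 1
      Zr <- Zmr / m; Zi <- Zmi / m
      denom <- n_epochs
    } else {
      denom <- n_samples
    }
    Cre <- tcrossprod(Zr) + tcrossprod(Zi)
    Cim <- Zi %*% t(Zr) - Zr %*% t(Zi)
    plv <- sqrt(Cre^2 + Cim^2) / denom
    plv <- (plv + t(plv)) / 2
    plv[plv > 1] <- 1
    diag(plv) <- NA_real_
    out[, , fi] <- plv
  }
  structure(list(subject_id = e$subject_id,
                 values = out,
                 frequencies = frequencies,
                 n_phase_samples = if (pooling == "pooled") n_samples else n_epochs,
                 taper_count = n_tapers,
                 pooling = pooling),
            class = "spectral_connectome")
}

#' @method print spectral_connectome
#' @export
print.spectral_connectome <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "spectral_connectome '%s': %d x %d regions x %d frequencies (N = %d phase samples, %d tapers)\n",
    x$subject_id, d[1], d[2], d[3], x$n_phase_samples, x$taper_count))
  invisible(x)
}

#' Welch relative power spectrum per region
#'
#' Power spectral density by Welch's method (3-s Hamming-windowed segments,
#' 50% overlap), aggregated into 1-Hz bins by summing periodogram bins
#' whose centre lies in `[f - 0.5, f + 0.5)`, then normalised per region by
#' total power over the analysis range so each region's values sum to 1.
#'
#' @param ts A [roi_timeseries()].
#' @param frequencies 1-Hz analysis bins (default 1:49).
#' @param segment_length_s Welch segment length in seconds (default 3).
#' @return A `power_spectrum_set` with `values` matrix regions x
#'   frequencies (rows sum to 1).
#' @export
compute_relative_power <- function(ts, frequencies = 1:49,
                                   segment_length_s = 3) {
  stopifnot(inherits(ts, "roi_timeseries"))
  if (any(frequencies < 1 | frequencies > 49))
    stop_oscdev("frequencies must lie within 1-49 Hz")
  fs <- ts$sampling_rate_hz
  L <- round(segment_length_s * fs)
  n_samp <- ncol(ts$values)
  if (n_samp < L)
    stop_oscdev("recording shorter than one %g-s Welch segment", segment_length_s)
  hop <- L %/% 2L
  starts <- seq.int(1L, n_samp - L + 1L, by = hop)
  win <- 0.54 - 0.46 * cos(2 * pi * (0:(L - 1)) / (L - 1))  # Hamming
  n_reg <- nrow(ts$values)
  n_half <- L %/% 2L
  psd <- matrix(0, n_half, n_reg)     # bins 1..L/2 at freq k*fs/L
  seg_mat <- matrix(0, L, n_reg * length(starts))
  for (si in seq_along(starts)) {
    seg <- t(ts$values[, starts[si] + 0:(L - 1L), drop = FALSE]) * win
    seg_mat[, (si - 1L) * n_reg + seq_len(n_reg)] <- seg
  }
  X <- mvfft(seg_mat)[2:(n_half + 1L), , drop = FALSE]
  P <- Mod(X)^2
  for (si in seq_along(starts))
    psd <- psd + P[, (si - 1L) * n_reg + seq_len(n_reg), drop = FALSE]
  psd <- psd / length(starts)
  bin_freq <- (1:n_half) * fs / L
  vals <- matrix(0, n_reg, length(frequencies))
  for (i in seq_along(frequencies)) {
    f <- frequencies[i]
    sel <- bin_freq >= (f - 0.5) & bin_freq < (f + 0.5)
    vals[, i] <- colSums(psd[sel, , drop = FALSE])
  }
  tot <- rowSums(vals)
  if (any(tot <= 0))
    stop_oscdev("zero total power in region(s) %s; relative power undefined",
                paste(which(tot <= 0) - 1L, collapse = ", "))
  structure(list(subject_id = ts$subject_id,
                 values = vals / tot,
                 frequencies = frequencies),
            class = "power_spectrum_set")
}

#' @method print power_spectrum_set
#' @export
print.power_spectrum_set <- function(x, ...) {
  cat(sprintf("power_spectrum_set '%s': %d regions x %d frequency bins\n",
              x$subject_id, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Average a spectral quantity over a frequency band
#'
#' Unweighted mean over the band's 1-Hz bins: for a connectome, a
#' regions x regions PLV matrix; for a power spectrum set, a per-region
#' vector.
#'
#' @param x A `spectral_connectome` or `power_spectrum_set`.
#' @param band A [band_definition()].
#' @return Matrix (PLV) or named-free numeric vector (power).
#' @export
band_average <- function(x, band) UseMethod("band_average")

band_index <- function(freqs, band) {
  stopifnot(inherits(band, "band_definition"))
  idx <- match(band$bins, freqs)
  if (anyNA(idx))
    stop_oscdev("band '%s' requests frequencies absent from the input", band$name)
  idx
}

#' @export
band_average.spectral_connectome <- function(x, band) {
  idx <- band_index(x$frequencies, band)
  m <- apply(x$values[, , idx, drop = FALSE], c(1, 2), mean)
  m
}

#' @export
band_average.power_spectrum_set <- function(x, band) {
  idx <- band_index(x$frequencies, band)
  rowMeans(x$values[, idx, drop = FALSE])
}

#' Expected chance-level PLV for uncoupled signals
#'
#' For N independent uniform phase-difference samples the expected
#' resultant length is `sqrt(pi / (4 N))`, the finite-sample floor of the
#' PLV estimator.
#'
#' @param n_phase_samples Number of phase samples N (epochs x tapers).
#' @return Expected chance PLV.
#' @export
chance_plv <- function(n_phase_samples) sqrt(pi / (4 * n_phase_samples))
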