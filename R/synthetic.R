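# Synthetic cohort generator: parcellations, subject records, and
# coupled-oscillator ROI time series with planted age effects, anatomical
# gradients of those effects, and a mediation structure linking age,
# frontal edge coupling, and impulsivity.
#
# Coupling model (shared-phase mixing): for band b, a common phase
# Phi_b(t) = 2 pi f_b t + small random walk is shared by all regions; each
# region adds an independent random-walk phase perturbation eta_r(t)
# attenuated by its mixing weight kappa:
#   phi_{b,r}(t) = Phi_b(t) + (1 - kappa_{b,r}) eta_{b,r}(t).
# Achieved pair PLV is monotone in kappa. Because the kappa -> PLV map is
# nonlinear, band targets are specified on the achieved-PLV scale and
# inverted through an empirically calibrated curve (seeded Monte Carlo,
# cached), so planted age slopes are slopes of measured PLV per year.

.calib_cache <- new.env(parent = emptyenv())

#' Default band targets for the synthetic cohort
#'
#' Per band: carrier frequency, baseline pair PLV at the age midpoint
#' (`plv_base`), age slope of pair PLV per year (`plv_age_slope`), the
#' anterior-gradient modulation of that slope per millimetre of MNI y
#' (`plv_slope_y_gradient`; negative values make the decline steeper
#' anteriorly), oscillator amplitude at the midpoint (`amp_base`),
#' fractional amplitude change per year (`amp_age_slope`), and its
#' y-modulation (`amp_slope_y_gradient`). Defaults plant the study's
#' qualitative findings: theta (5-9 Hz) coupling declines with age more
#' steeply anteriorly; delta power falls and beta power rises with age.
#'
#' @return Data frame, one row per band.
#' @export
default_band_targets <- function() {
  data.frame(
    band = c("delta", "theta", "beta_low", "beta_high"),
    freq_hz = c(2, 7, 15, 24),
    plv_base = c(0.30, 0.45, 0.30, 0.28),
    plv_age_slope = c(0, -0.010, 0, 0),
    plv_slope_y_gradient = c(0, -8e-5, 0, 0),
    amp_base = c(1.0, 0.9, 0.55, 0.45),
    amp_age_slope = c(-0.015, 0, 0.015, 0.015),
    amp_slope_y_gradient = c(-5e-5, 0, 5e-5, 5e-5),
    stringsAsFactors = FALSE
  )
}

#' Default mediation structure
#'
#' Three disjoint edges among the six most anterior regions (chosen at
#' cohort generation), whose theta PLV follows
#' `plv_base + path_a * (age - midpoint)`; impulsivity is then generated
#' from the achieved edge PLVs with coefficients `path_b`, a direct age
#' effect `c_prime`, and residual noise, so the planted indirect effect of
#' edge e is `path_a * path_b[e]`. By default only the first edge carries
#' an indirect effect; the other two are null candidates, so a mediation
#' screen should flag exactly one of the three.
#'
#' @param path_a PLV change per year at the mediation edges.
#' @param path_b Impulsivity change per unit PLV, one per edge.
#' @param c_prime Direct age effect on impulsivity (per year).
#' @param intercept Impulsivity at the age midpoint and baseline PLV.
#' @param resid_sd Residual standard deviation of impulsivity.
#' @param plv_base Baseline PLV of the mediation edges at the midpoint.
#' @param edges Optional integer matrix (k x 2) of 0-based region ids;
#'   `NULL` selects the default anterior triple at generation time.
#' @return List describing the mediation structure.
#' @export
default_mediation_spec <- function(path_a = -0.010, path_b = c(1.5, 0, 0),
                                   c_prime = 0, intercept = 2.0,
                                   resid_sd = 0.30, plv_base = 0.45,
                                   edges = NULL) {
  list(edges = edges, path_a = path_a, path_b = path_b, c_prime = c_prime,
       intercept = intercept, resid_sd = resid_sd, plv_base = plv_base)
}

#' Configure a synthetic cohort
#'
#' The defaults are the desk-scale study conditions: 40 subjects aged
#' 14-31, 64 regions, 60 s of signal at 250 Hz; `full_scale = TRUE`
#' switches to 68 subjects, 333 regions, and 300 s. Head motion is drawn
#' independently of age unless `motion_age_slope` is nonzero (confounded
#' mode). The background is 1/f (exponent 1) noise scaled by
#' `noise_floor`.
#'
#' @param n_subjects,n_regions,duration_s,sampling_rate_hz Cohort scale.
#' @param age_range Two-element age range in years.
#' @param band_targets See [default_band_targets()].
#' @param mediation_spec See [default_mediation_spec()]; `NULL` disables
#'   the impulsivity variable.
#' @param noise_floor 1/f background amplitude scale.
#' @param plv_subject_sd Between-subject s.d. of each region's coupling
#'   target on the PLV scale (individual differences in coupling).
#' @param phase_noise_sd Equilibrium s.d. (radians) of each region's
#'   stationary Ornstein-Uhlenbeck phase perturbation.
#' @param phase_noise_tau_s Autocorrelation time of that perturbation in
#'   seconds.
#' @param common_phase_sd Per-sample s.d. of the shared band phase walk.
#' @param motion_mean,motion_sd Log-normal head-motion parameters (mm).
#' @param motion_age_slope Linear dependence of motion on age (0 =
#'   unconfounded default).
#' @param epoch_length_s Epoch length used downstream (duration must be a
#'   positive multiple).
#' @param seed Base seed for cohort generation.
#' @param full_scale If `TRUE`, use 68 subjects / 333 regions / 300 s.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 40, n_regions = 64, duration_s = 60,
                          sampling_rate_hz = 250, age_range = c(14, 31),
                          band_targets = default_band_targets(),
                          mediation_spec = default_mediation_spec(),
                          noise_floor = 1.0, plv_subject_sd = 0.02,
                          phase_noise_sd = 2.2,
                          phase_noise_tau_s = 0.4,
                          common_phase_sd = 0.02,
                          motion_mean = 0.4, motion_sd = 0.5,
                          motion_age_slope = 0,
                          epoch_length_s = 3, seed = 1,
                          full_scale = FALSE) {
  if (full_scale) {
    n_subjects <- 68; n_regions <- 333; duration_s <- 300
  }
  cfg <- list(n_subjects = n_subjects, n_regions = n_regions,
              duration_s = duration_s, sampling_rate_hz = sampling_rate_hz,
              age_range = age_range, band_targets = band_targets,
              mediation_spec = mediation_spec, noise_floor = noise_floor,
              plv_subject_sd = plv_subject_sd,
              phase_noise_sd = phase_noise_sd,
              phase_noise_tau_s = phase_noise_tau_s,
              common_phase_sd = common_phase_sd,
              motion_mean = motion_mean, motion_sd = motion_sd,
              motion_age_slope = motion_age_slope,
              epoch_length_s = epoch_length_s, seed = seed)
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  problems <- character()
  add <- function(msg) problems <<- c(problems, msg)
  if (cfg$n_subjects < 2) add("n_subjects must be >= 2")
  if (cfg$n_regions < 2) add("n_regions must be >= 2")
  if (cfg$sampling_rate_hz < 2 * 49)
    add("sampling_rate_hz must be >= 98 (Nyquist for the 1-49 Hz range)")
  if (cfg$duration_s <= 0 ||
      abs(cfg$duration_s / cfg$epoch_length_s -
          round(cfg$duration_s / cfg$epoch_length_s)) > 1e-9)
    add("duration_s must be a positive multiple of epoch_length_s")
  if (length(cfg$age_range) != 2 || diff(cfg$age_range) <= 0)
    add("age_range must be an increasing pair")
  bt <- cfg$band_targets
  need <- c("band", "freq_hz", "plv_base", "plv_age_slope",
            "plv_slope_y_gradient", "amp_base", "amp_age_slope",
            "amp_slope_y_gradient")
  if (!all(need %in% names(bt))) {
    add(sprintf("band_targets missing column(s): %s",
                paste(setdiff(need, names(bt)), collapse = ", ")))
  } else {
    if (any(bt$freq_hz < 1 | bt$freq_hz > 49))
      add("band target frequency outside 1-49 Hz")
    if (any(bt$plv_base < 0 | bt$plv_base > 1))
      add("plv_base must lie in [0, 1]")
    if (any(bt$amp_base < 0)) add("amp_base must be nonnegative")
  }
  if (cfg$noise_floor < 0) add("noise_floor must be nonnegative")
  if (is.null(cfg$plv_subject_sd) || cfg$plv_subject_sd < 0)
    add("plv_subject_sd must be nonnegative")
  ms <- cfg$mediation_spec
  if (!is.null(ms)) {
    if (!is.null(ms$edges) && ncol(as.matrix(ms$edges)) != 2)
      add("mediation edges must be a k x 2 matrix of region ids")
    if (ms$resid_sd < 0) add("mediation resid_sd must be nonnegative")
    if (length(ms$path_b) < 1) add("mediation path_b must be nonempty")
  }
  if (length(problems))
    stop_oscdev("invalid cohort config:\n  - %s",
                paste(problems, collapse = "\n  - "))
  invisible(cfg)
}

#' Generate a synthetic parcellation
#'
#' Region centres of mass are sampled on an ellipsoidal shell spanning
#' roughly MNI y in \[-80, 80\] mm; hemispheres follow the sign of x.
#' Network labels are drawn from the 13-label set with anterior regions
#' enriched for association networks (DM/FP/SAL/VA/DA/CO/CP/RST) and
#' posterior regions for processing networks (VIS/AUD/SMH/SMM); every
#' label is guaranteed at least two member regions when
#' `n_regions >= 26`.
#'
#' @param n_regions Number of regions (>= 2).
#' @param seed Seed controlling sampling; identical arguments give
#'   identical tables.
#' @return A `parcel_set`.
#' @export
generate_parcellation <- function(n_regions, seed = 1) {
  n_regions <- as.integer(check_number(n_regions, "n_regions", 2))
  with_seed(derive_seed(seed, "parcellation"), {
    u <- matrix(rnorm(3 * n_regions), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    semi <- c(65, 80, 55)           # MNI-ish extents in x, y, z
    coords <- sweep(u, 2, semi, `*`)
    # guarantee both hemispheres
    if (all(coords[, 1] >= 0)) coords[1, 1] <- -abs(coords[1, 1]) - 1
    if (all(coords[, 1] < 0)) coords[1, 1] <- abs(coords[1, 1]) + 1
    hemi <- ifelse(coords[, 1] < 0, "L", "R")
    assoc <- network_classes$association
    proc <- network_classes$processing
    p_assoc <- stats::plogis(coords[, 2] / 25)
    net <- character(n_regions)
    for (i in seq_len(n_regions)) {
      if (runif(1) < 0.05) {
        net[i] <- "None"
      } else if (runif(1) < p_assoc[i]) {
        net[i] <- sample(assoc, 1)
      } else {
        net[i] <- sample(proc, 1)
      }
    }
    # ensure every label has >= 2 members when there is room
    if (n_regions >= 2L * length(network_labels)) {
      for (lab in network_labels) {
        while (sum(net == lab) < 2L) {
          counts <- table(net)
          donor <- names(counts)[which.max(counts)]
          net[which(net == donor)[1L]] <- lab
        }
      }
    }
    area <- exp(rnorm(n_regions, log(350), 0.4))
    df <- data.frame(
      region_id = 0:(n_regions - 1L),
      label = sprintf("%s_%03d", hemi, 0:(n_regions - 1L)),
      hemisphere = hemi,
      x = round(coords[, 1], 2), y = round(coords[, 2], 2),
      z = round(coords[, 3], 2),
      surface_area_mm2 = round(area, 1),
      network = net,
      stringsAsFactors = FALSE
    )
    parcel_set(df)
  })
}

# ---- kappa -> PLV calibration -------------------------------------------

# 1-Hz bins carrying a band's oscillators: the standard band of that name
# if defined, else the single carrier bin.
band_bins_for <- function(band_row) {
  sb <- standard_bands()
  if (band_row$band %in% names(sb)) sb[[band_row$band]]$bins
  else as.integer(round(band_row$freq_hz))
}

# One band's signal for a set of regions: each 1-Hz bin in the band gets
# its own shared carrier phase (common across regions); the region's
# random-walk phase perturbation is shared across the band's bins and
# attenuated by (1 - kappa), so every bin's pair PLV tracks the same
# coupling target. `amp` is the per-region band amplitude (split across
# bins to conserve band power). Returns regions x samples.
simulate_band_signal <- function(n_samples, fs, bins, kappa, amp,
                                 phase_noise_sd, tau_samples,
                                 common_phase_sd) {
  n_reg <- length(kappa)
  if (length(amp) == 1L) amp <- rep(amp, n_reg)
  osc_signal_cpp(n_reg, n_samples, fs, as.numeric(bins),
                 as.numeric(kappa), as.numeric(amp),
                 phase_noise_sd, tau_samples, common_phase_sd)
}

# 1/f background noise (power exponent 1), samples x regions, unit RMS.
# Each inverse-FFT column yields two independent real 1/f series (real
# and imaginary parts of a full-complex random spectrum).
pink_noise <- function(n_reg, n_samples) {
  n_pairs <- (n_reg + 1L) %/% 2L
  spec <- pink_pair_spectrum_cpp(n_pairs, n_samples)
  pink_assemble_cpp(mvfft(spec, inverse = TRUE), n_reg)
}

calib_key <- function(cfg, band_row) {
  sprintf("calib_%g_%g_%g_%g_%g_%g_%g_%g", cfg$sampling_rate_hz, cfg$duration_s,
          cfg$epoch_length_s, band_row$freq_hz, band_row$amp_base,
          cfg$noise_floor, cfg$phase_noise_sd, cfg$phase_noise_tau_s)
}

# Calibrated monotone map kappa -> achieved pair PLV for one band under
# this config, estimated by seeded Monte Carlo on two-region simulations
# (both regions at the same kappa). Returns list(to_plv, to_kappa).
coupling_curve <- function(cfg, band_row, n_rep = 6) {
  key <- calib_key(cfg, band_row)
  if (!is.null(.calib_cache[[key]])) return(.calib_cache[[key]])
  # dense where the mixing -> PLV curve is steep (high kappa)
  grid <- c(seq(0, 0.7, by = 0.1), seq(0.75, 1, by = 0.025))
  n_samples <- round(cfg$duration_s * cfg$sampling_rate_hz)
  bins <- band_bins_for(band_row)
  plv_hat <- with_seed(derive_seed(20240501, key), {
    vapply(grid, function(kap) {
      mean(vapply(seq_len(n_rep), function(r) {
        x <- simulate_band_signal(n_samples, cfg$sampling_rate_hz, bins,
                                  rep(kap, 2), band_row$amp_base,
                                  cfg$phase_noise_sd,
                                  cfg$phase_noise_tau_s * cfg$sampling_rate_hz,
                                  cfg$common_phase_sd)
        if (cfg$noise_floor > 0)
          x <- x + cfg$noise_floor * pink_noise(2, n_samples)
        ts <- roi_timeseries(t(x), cfg$sampling_rate_hz, "calib")
        ep <- epoch_timeseries(ts, cfg$epoch_length_s)
        pl <- compute_plv(ep, frequencies = bins)
        mean(pl$values[1, 2, ])
      }, 0))
    }, 0)
  })
  # Smooth monotone parametric fit: plv(kappa) = p0 + (p1 - p0) *
  # exp(-c (1 - kappa)^2), the Gaussian-phase-jitter form of the coupling
  # curve. A parametric fit (rather than interpolation through the noisy
  # grid estimates) keeps the inversion smooth, so planted PLV
  # trajectories stay linear in age.
  sse <- function(par) {
    p0 <- par[1]; p1 <- par[2]; cc <- par[3]
    if (p1 <= p0 || cc <= 0 || p0 < 0 || p1 > 1) return(1e6)
    sum((plv_hat - (p0 + (p1 - p0) * exp(-cc * (1 - grid)^2)))^2)
  }
  par0 <- c(max(min(plv_hat), 1e-3), min(max(plv_hat), 0.999), 5)
  par <- stats::optim(par0, sse, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))$par
  p0 <- par[1]; p1 <- par[2]; cc <- par[3]
  eps <- 1e-4
  curve <- list(
    grid = grid, plv = plv_hat, p0 = p0, p1 = p1, c = cc,
    to_plv = function(k) {
      k <- pmin(pmax(k, 0), 1)
      p0 + (p1 - p0) * exp(-cc * (1 - k)^2)
    },
    to_kappa = function(p) {
      p <- pmin(pmax(p, p0 + eps), p1 - eps)
      pmin(pmax(1 - sqrt(log((p1 - p0) / (p - p0)) / cc), 0), 1)
    }
  )
  .calib_cache[[key]] <- curve
  curve
}

# ---- subject simulation --------------------------------------------------

# Per-region target PLV level for one band at a given age; mediation
# regions get their override applied by the caller.
region_plv_target <- function(band_row, age, age_mid, y) {
  slope <- band_row$plv_age_slope + band_row$plv_slope_y_gradient * y
  pmin(pmax(band_row$plv_base + slope * (age - age_mid), 0.02), 0.98)
}

region_amplitude <- function(band_row, age, age_mid, y) {
  slope <- band_row$amp_age_slope + band_row$amp_slope_y_gradient * y
  pmax(band_row$amp_base * (1 + slope * (age - age_mid)), 0.01)
}

#' Simulate one subject's ROI time series
#'
#' Each region's signal is a sum over configured bands of an
#' age/position-dependent amplitude times the cosine of a mixed phase
#' (shared band phase plus attenuated independent random-walk
#' perturbation) plus 1/f background noise. Band coupling targets are
#' achieved-PLV levels converted to mixing weights through the calibrated
#' coupling curve; mediation-edge regions follow the mediation target
#' instead of the regional background for the theta band.
#'
#' @param subject One-row data frame (or list) with `subject_id`,
#'   `age_years`.
#' @param parcel A `parcel_set` with `nrow(parcel) == cfg$n_regions`.
#' @param cfg A [cohort_config()].
#' @param seed Seed; identical inputs give identical output.
#' @param mediation_regions Optional integer vector of 0-based region ids
#'   whose theta coupling follows the mediation target.
#' @return A [roi_timeseries()].
#' @export
simulate_subject <- function(subject, parcel, cfg, seed = 1,
                             mediation_regions = integer()) {
  stopifnot(inherits(parcel, "parcel_set"))
  validate_cohort_config(cfg)
  bt <- cfg$band_targets
  if (any(bt$freq_hz < 1 | bt$freq_hz > 49))
    stop_oscdev("band carrier frequency outside 1-49 Hz")
  n_samples <- round(cfg$duration_s * cfg$sampling_rate_hz)
  n_reg <- nrow(parcel)
  age_mid <- mean(cfg$age_range)
  age <- subject$age_years
  y <- parcel$y
  ms <- cfg$mediation_spec
  with_seed(derive_seed(seed, paste0("subject_", subject$subject_id)), {
    x <- matrix(0, n_samples, n_reg)
    for (b in seq_len(nrow(bt))) {
      row <- bt[b, ]
      curve <- coupling_curve(cfg, row)
      target <- region_plv_target(row, age, age_mid, y)
      if (length(mediation_regions) && !is.null(ms) &&
          row$band == "theta") {
        idx <- mediation_regions + 1L
        med_target <- pmin(pmax(
          ms$plv_base + ms$path_a * (age - age_mid), 0.02), 0.98)
        target[idx] <- med_target
      }
      if (cfg$plv_subject_sd > 0)
        target <- pmin(pmax(
          target + rnorm(n_reg, 0, cfg$plv_subject_sd), 0.02), 0.98)
      kappa <- curve$to_kappa(target)
      amp <- region_amplitude(row, age, age_mid, y)
      x <- x + simulate_band_signal(n_samples, cfg$sampling_rate_hz,
                                    band_bins_for(row), kappa, amp,
                                    cfg$phase_noise_sd,
                                    cfg$phase_noise_tau_s * cfg$sampling_rate_hz,
                                    cfg$common_phase_sd)
    }
    if (cfg$noise_floor > 0)
      x <- x + cfg$noise_floor * pink_noise(n_reg, n_samples)
    roi_timeseries(t(x), cfg$sampling_rate_hz, subject$subject_id)
  })
}

# theta-band PLV restricted to the regions involved in mediation edges
mediation_edge_plv <- function(ts, edges, cfg) {
  regs <- sort(unique(c(edges)))          # 0-based ids
  sub <- roi_timeseries(ts$values[regs + 1L, , drop = FALSE],
                        ts$sampling_rate_hz, ts$subject_id)
  ep <- epoch_timeseries(sub, cfg$epoch_length_s)
  th <- standard_bands()$theta
  pl <- compute_plv(ep, frequencies = th$bins)
  m <- band_average(pl, th)
  vapply(seq_len(nrow(edges)), function(k) {
    i <- match(edges[k, 1], regs); j <- match(edges[k, 2], regs)
    m[i, j]
  }, 0)
}

# Three disjoint pairs among the six most anterior regions. Disjoint
# endpoints keep the edge PLVs' realization noise independent, so each
# single-mediator analysis estimates its own planted indirect effect.
default_mediation_edges <- function(parcel) {
  ord <- order(parcel$y, decreasing = TRUE)
  top <- parcel$region_id[ord[1:6]]
  cbind(c(top[1], top[3], top[5]), c(top[2], top[4], top[6]))
}

#' Generate a full synthetic cohort
#'
#' Draws ages uniformly over the configured range, motion from a
#' log-normal distribution (independent of age unless confounding is
#' configured), simulates every subject's ROI time series, and generates
#' impulsivity from the achieved theta PLV of the mediation edges:
#' `impulsivity = intercept + c_prime (age - mid) + sum_e path_b[e]
#' (PLV_e - plv_base) + noise`, clipped to \[1, 4\], so the planted
#' indirect effect through edge e is `path_a * path_b[e]`.
#'
#' @param cfg A [cohort_config()].
#' @param parcel Optional `parcel_set`; generated from the config seed if
#'   omitted.
#' @return List with `parcel`, `subjects` (data frame: `subject_id`,
#'   `age_years`, `motion`, `impulsivity`), `timeseries` (list of
#'   [roi_timeseries()]), `mediation_edges` (k x 2, 0-based), and
#'   `mediation_plv` (subjects x k achieved theta PLV).
#' @export
generate_cohort <- function(cfg, parcel = NULL) {
  validate_cohort_config(cfg)
  if (is.null(parcel))
    parcel <- generate_parcellation(cfg$n_regions, cfg$seed)
  if (nrow(parcel) != cfg$n_regions)
    stop_oscdev("parcellation has %d regions but config says %d",
                nrow(parcel), cfg$n_regions)
  ms <- cfg$mediation_spec
  edges <- NULL
  med_regions <- integer()
  if (!is.null(ms)) {
    edges <- if (is.null(ms$edges)) default_mediation_edges(parcel)
             else as.matrix(ms$edges)
    if (length(ms$path_b) != nrow(edges))
      stop_oscdev("mediation path_b length (%d) must match edge count (%d)",
                  length(ms$path_b), nrow(edges))
    med_regions <- sort(unique(c(edges)))
  }
  age_mid <- mean(cfg$age_range)
  subjects <- with_seed(derive_seed(cfg$seed, "subjects"), {
    age <- runif(cfg$n_subjects, cfg$age_range[1], cfg$age_range[2])
    motion <- exp(rnorm(cfg$n_subjects, log(cfg$motion_mean),
                        cfg$motion_sd)) +
      cfg$motion_age_slope * (age - age_mid)
    motion <- pmax(motion, 0)
    data.frame(subject_id = sprintf("S%03d", seq_len(cfg$n_subjects)),
               age_years = age, motion = motion,
               stringsAsFactors = FALSE)
  })
  timeseries <- vector("list", cfg$n_subjects)
  med_plv <- if (is.null(edges)) NULL else
    matrix(NA_real_, cfg$n_subjects, nrow(edges))
  for (s in seq_len(cfg$n_subjects)) {
    ts <- simulate_subject(subjects[s, ], parcel, cfg, seed = cfg$seed,
                           mediation_regions = med_regions)
    timeseries[[s]] <- ts
    if (!is.null(edges))
      med_plv[s, ] <- mediation_edge_plv(ts, edges, cfg)
  }
  if (!is.null(edges)) {
    imp <- with_seed(derive_seed(cfg$seed, "impulsivity"), {
      ms$intercept + ms$c_prime * (subjects$age_years - age_mid) +
        as.vector(sweep(med_plv, 2, rep(ms$plv_base, ncol(med_plv)))
                  %*% ms$path_b) +
        rnorm(cfg$n_subjects, 0, ms$resid_sd)
    })
    subjects$impulsivity <- pmin(pmax(imp, 1), 4)
  } else {
    subjects$impulsivity <- NA_real_
  }
  list(parcel = parcel, subjects = subjects, timeseries = timeseries,
       mediation_edges = edges, mediation_plv = med_plv)
}

#' Null cohort configuration
#'
#' A [cohort_config()] with every planted age slope, gradient, and
#' mediation path set to zero, for false-positive calibration of the
#' downstream tests.
#'
#' @param ... Passed to [cohort_config()] (e.g. `n_subjects`,
#'   `n_regions`, `duration_s`, `seed`).
#' @param bands Which bands to keep (default all four); restricting to
#'   one band speeds up large replicate runs.
#' @return A `cohort_config`.
#' @export
null_cohort_config <- function(..., bands = NULL) {
  bt <- default_band_targets()
  bt$plv_age_slope[] <- 0
  bt$plv_slope_y_gradient[] <- 0
  bt$amp_age_slope[] <- 0
  bt$amp_slope_y_gradient[] <- 0
  if (!is.null(bands)) bt <- bt[bt$band %in% bands, , drop = FALSE]
  cohort_config(..., band_targets = bt, mediation_spec = NULL)
}
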