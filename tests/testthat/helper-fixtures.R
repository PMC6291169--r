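# Shared fixtures, built once per test session and cached.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

# A tiny but complete cohort for structural and pipeline tests:
# 10 subjects, 12 regions, 24 s at 250 Hz, all bands, mediation planted.
tiny_cohort <- function() {
  cached("tiny_cohort", function() {
    cfg <- cohort_config(n_subjects = 10, n_regions = 12, duration_s = 24,
                         seed = 404)
    list(cfg = cfg, cohort = generate_cohort(cfg))
  })
}

# Spectral summaries of the tiny cohort.
tiny_spectra <- function() {
  cached("tiny_spectra", function() {
    ch <- tiny_cohort()$cohort
    conn <- lapply(ch$timeseries, function(ts)
      compute_plv(epoch_timeseries(ts)))
    pow <- lapply(ch$timeseries, compute_relative_power)
    list(connectomes = conn, power = pow)
  })
}

# Toy parcellation table (valid, 4 regions).
toy_parcel_df <- function() {
  data.frame(
    region_id = 0:3,
    label = c("L_000", "L_001", "R_002", "R_003"),
    hemisphere = c("L", "L", "R", "R"),
    x = c(-40, -30, 35, 45), y = c(60, -70, 55, -65),
    z = c(10, 20, 15, 25),
    surface_area_mm2 = c(300, 400, 350, 380),
    network = c("DM", "VIS", "SAL", "SMH"),
    stringsAsFactors = FALSE
  )
}

# Hand-built spectral containers for oracle tests.
make_connectome <- function(values, frequencies = seq_len(dim(values)[3]),
                            n_phase_samples = 60) {
  structure(list(subject_id = "toy", values = values,
                 frequencies = frequencies,
                 n_phase_samples = n_phase_samples, taper_count = 3,
                 pooling = "pooled"),
            class = "spectral_connectome")
}

make_power_set <- function(values, frequencies = seq_len(ncol(values))) {
  structure(list(subject_id = "toy", values = values,
                 frequencies = frequencies),
            class = "power_spectrum_set")
}

# Symmetric edge-effect object from a beta matrix (diagonal set NA).
make_edge_effect <- function(beta, band = standard_bands()$theta) {
  beta <- (beta + t(beta)) / 2
  diag(beta) <- NA_real_
  se <- abs(beta) * 0 + 1
  diag(se) <- NA_real_
  structure(list(beta = beta, se = se, t = beta, p = beta * 0 + 0.5,
                 band = band, nuisance_mode = "none", n_subjects = 60),
            class = "edge_effect")
}

# Subjects x edges matrix -> regions x regions x subjects PLV-like array.
edges_to_array <- function(E, n_reg) {
  pairs <- which(upper.tri(diag(n_reg)), arr.ind = TRUE)
  arr <- array(0, dim = c(n_reg, n_reg, nrow(E)))
  for (s in seq_len(nrow(E))) {
    m <- matrix(0, n_reg, n_reg)
    m[pairs] <- E[s, ]
    m <- m + t(m)
    diag(m) <- NA_real_
    arr[, , s] <- m
  }
  arr
}
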