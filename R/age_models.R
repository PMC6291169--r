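# Regressions of PLV and relative power on age: the global mixed model
# with the age x frequency likelihood-ratio test, per-frequency OLS with
# FDR correction, and the mass-univariate edgewise band regression with
# the motion/power nuisance set.

#' Global per-frequency metric for one subject
#'
#' Collapses a spectral quantity to one value per frequency: PLV is
#' averaged over the upper-triangle region pairs (diagonal excluded),
#' relative power over regions.
#'
#' @param x A `spectral_connectome` or `power_spectrum_set`.
#' @return Data frame with `subject_id`, `freq_hz`, `value`.
#' @export
global_metric <- function(x) UseMethod("global_metric")

#' @export
global_metric.spectral_connectome <- function(x) {
  idx <- upper.tri(x$values[, , 1])
  vals <- apply(x$values, 3, function(m) mean(m[idx]))
  data.frame(subject_id = x$subject_id, freq_hz = x$frequencies,
             value = vals, stringsAsFactors = FALSE)
}

#' @export
global_metric.power_spectrum_set <- function(x) {
  data.frame(subject_id = x$subject_id, freq_hz = x$frequencies,
             value = colMeans(x$values), stringsAsFactors = FALSE)
}

#' Assemble the subject-by-frequency global table
#'
#' Stacks [global_metric()] rows across subjects and joins the subject
#' covariates (age, motion, impulsivity).
#'
#' @param metrics List of `spectral_connectome` or `power_spectrum_set`,
#'   one per subject.
#' @param subjects Subject data frame with `subject_id`, `age_years`,
#'   `motion` (and optionally `impulsivity`).
#' @return Long data frame, one row per subject x frequency.
#' @export
global_frequency_table <- function(metrics, subjects) {
  tbl <- do.call(rbind, lapply(metrics, global_metric))
  out <- merge(tbl, subjects, by = "subject_id", sort = FALSE)
  out[order(match(out$subject_id, subjects$subject_id), out$freq_hz), ]
}

#' Age-by-frequency likelihood-ratio test (global mixed model)
#'
#' Linear mixed model fit by maximum likelihood with per-subject random
#' intercepts; frequency enters as a categorical factor (48 interaction
#' parameters for 49 levels). The interaction test compares
#' `value ~ age * freq + (1 | subject)` against the additive model by a
#' likelihood-ratio (chi-squared) test; the age main-effect test compares
#' the additive model against `value ~ freq + (1 | subject)`.
#'
#' @param tbl A [global_frequency_table()] result.
#' @return List with `interaction` and `age_main`, each holding
#'   `statistic`, `df`, `p`, and the fitted models.
#' @export
fit_global_interaction <- function(tbl) {
  need <- c("subject_id", "freq_hz", "value", "age_years")
  if (!all(need %in% names(tbl)))
    stop_oscdev("table must have columns: %s", paste(need, collapse = ", "))
  if (length(unique(tbl$subject_id)) < 2)
    stop_oscdev("need at least 2 subjects")
  tbl$freq_f <- factor(tbl$freq_hz)
  fit_full <- lme4::lmer(value ~ age_years * freq_f + (1 | subject_id),
                         data = tbl, REML = FALSE)
  fit_add <- lme4::lmer(value ~ age_years + freq_f + (1 | subject_id),
                        data = tbl, REML = FALSE)
  fit_nofix <- lme4::lmer(value ~ freq_f + (1 | subject_id),
                          data = tbl, REML = FALSE)
  lrt <- function(small, big) {
    a <- stats::anova(small, big)
    list(statistic = a$Chisq[2], df = a$Df[2], p = a$`Pr(>Chisq)`[2])
  }
  int <- lrt(fit_add, fit_full)
  main <- lrt(fit_nofix, fit_add)
  list(interaction = c(int, list(model_full = fit_full, model_null = fit_add)),
       age_main = c(main, list(model_full = fit_add, model_null = fit_nofix)))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q values, monotone and capped at 1, after validating
#' that all p values lie in \[0, 1\].
#'
#' @param pvals Numeric vector of p values.
#' @return Vector of q values, same length.
#' @export
fdr_adjust <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop_oscdev("p values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Per-frequency age regression with FDR
#'
#' Ordinary least squares of the global metric on age at each frequency,
#' with the configured covariates (motion by default), and BH correction
#' across the frequency tests. Frequencies whose metric is constant across
#' subjects return `beta = 0`, `t = 0`, `p = 1`.
#'
#' @param tbl A [global_frequency_table()] result.
#' @param covariates Character vector of covariate columns in `tbl`
#'   (default `"motion"`); use `character()` for age-only models.
#' @return Data frame with `freq_hz`, `beta`, `se`, `t`, `p`, `q`.
#' @export
per_frequency_regression <- function(tbl, covariates = "motion") {
  freqs <- sort(unique(tbl$freq_hz))
  n_sub <- length(unique(tbl$subject_id))
  if (n_sub < 3) stop_oscdev("need at least 3 subjects")
  first <- tbl[tbl$freq_hz == freqs[1], ]
  X <- cbind(intercept = 1, age = first$age_years)
  for (cv in covariates) X <- cbind(X, first[[cv]])
  colnames(X) <- c("intercept", "age", covariates)
  Y <- vapply(freqs, function(f) tbl$value[tbl$freq_hz == f], numeric(n_sub))
  fit <- mass_ols(Y, X, which = 2L)
  data.frame(freq_hz = freqs, beta = fit$beta, se = fit$se, t = fit$t,
             p = fit$p, q = fdr_adjust(fit$p))
}

#' Edgewise age regression of band PLV with nuisance control
#'
#' For every unordered region pair (i, j), regresses the band-averaged
#' PLV on age across subjects. Under `nuisance_mode = "full"` the
#' covariates are head motion, the band relative power of region i and of
#' region j, their product, the log-transformed powers (floored at
#' `power_floor`), and the interaction of the log-transformed powers.
#' `"motion"` keeps only motion; `"none"` fits age alone.
#'
#' @param band_plv Subjects-indexed band PLV: a regions x regions x
#'   subjects array (or list of symmetric matrices).
#' @param subjects Subject data frame (`age_years`, `motion`).
#' @param band_power Optional regions x subjects matrix of band relative
#'   power (required for `"full"`).
#' @param nuisance_mode `"full"` (default), `"motion"`, or `"none"`.
#' @param power_floor Floor applied inside the log transform (default
#'   1e-12).
#' @param band Optional [band_definition()] recorded in the result.
#' @return An `edge_effect` object: symmetric matrices `beta`, `se`, `t`,
#'   `p` for the age coefficient (diagonal `NA`), plus the covariate
#'   specification.
#' @export
edgewise_age_regression <- function(band_plv, subjects, band_power = NULL,
                                    nuisance_mode = c("full", "motion", "none"),
                                    power_floor = 1e-12, band = NULL) {
  nuisance_mode <- match.arg(nuisance_mode)
  if (is.list(band_plv)) band_plv <- simplify2array(band_plv)
  n_reg <- dim(band_plv)[1]
  n_sub <- dim(band_plv)[3]
  if (nrow(subjects) != n_sub)
    stop_oscdev("subject table (%d rows) does not match PLV array (%d subjects)",
                nrow(subjects), n_sub)
  if (nuisance_mode == "full") {
    if (is.null(band_power))
      stop_oscdev("nuisance_mode 'full' requires band_power (regions x subjects)")
    if (any(band_power < 0))
      stop_oscdev("negative relative power; cannot form log nuisance terms")
    logp <- log(pmax(band_power, power_floor))
  }
  n_cov <- switch(nuisance_mode, none = 0L, motion = 1L, full = 7L)
  if (n_sub < n_cov + 4L)
    stop_oscdev("need at least %d subjects for nuisance_mode '%s', got %d",
                n_cov + 4L, nuisance_mode, n_sub)
  pairs <- ut_pairs(n_reg)
  Y <- edges_from_matrices(band_plv)       # subjects x edges
  beta <- se <- tv <- pv <- matrix(NA_real_, n_reg, n_reg)
  base <- cbind(intercept = 1, age = subjects$age_years)
  if (nuisance_mode != "none")
    base <- cbind(base, motion = subjects$motion)
  if (nuisance_mode != "full") {
    fit <- mass_ols(Y, base, which = 2L)
    beta[pairs] <- fit$beta; se[pairs] <- fit$se
    tv[pairs] <- fit$t; pv[pairs] <- fit$p
  } else {
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      pi_ <- band_power[i, ]; pj <- band_power[j, ]
      X <- cbind(base, p_i = pi_, p_j = pj, p_ij = pi_ * pj,
                 logp_i = logp[i, ], logp_j = logp[j, ],
                 logp_ij = logp[i, ] * logp[j, ])
      fit <- mass_ols(Y[, k, drop = FALSE], X, which = 2L)
      beta[i, j] <- fit$beta; se[i, j] <- fit$se
      tv[i, j] <- fit$t; pv[i, j] <- fit$p
    }
  }
  sym <- function(m) { m[lower.tri(m)] <- t(m)[lower.tri(m)]; m }
  structure(list(beta = sym(beta), se = sym(se), t = sym(tv), p = sym(pv),
                 band = band, nuisance_mode = nuisance_mode,
                 n_subjects = n_sub),
            class = "edge_effect")
}

#' @method print edge_effect
#' @export
print.edge_effect <- function(x, ...) {
  cat(sprintf(
    "edge_effect: %d regions, band '%s', nuisance '%s', %d subjects\n",
    nrow(x$beta), if (is.null(x$band)) "?" else x$band$name,
    x$nuisance_mode, x$n_subjects))
  cat(sprintf("  age beta range: [%.4g, %.4g]\n",
              min(x$beta, na.rm = TRUE), max(x$beta, na.rm = TRUE)))
  invisible(x)
}

#' Per-region composite age effect (summed beta weights)
#'
#' Sums each region's edgewise age betas over all other regions (column
#' sums of the symmetric beta matrix, diagonal excluded), giving one
#' composite rate of developmental change per region.
#'
#' @param m An `edge_effect`.
#' @param source Label recorded in the result (`"plv"` or `"power"`).
#' @return A `region_effect` object (numeric vector plus metadata).
#' @export
summed_region_effect <- function(m, source = "plv") {
  stopifnot(inherits(m, "edge_effect"))
  v <- colSums(m$beta, na.rm = TRUE)
  structure(list(summed_beta = v, band = m$band, source = source),
            class = "region_effect")
}

#' Construct a region effect vector directly
#' @param summed_beta Numeric vector, one value per region.
#' @param band Optional [band_definition()].
#' @param source Label (`"plv"` or `"power"`).
#' @return A `region_effect`.
#' @export
region_effect <- function(summed_beta, band = NULL, source = "plv") {
  structure(list(summed_beta = as.numeric(summed_beta), band = band,
                 source = source),
            class = "region_effect")
}

#' @method print region_effect
#' @export
print.region_effect <- function(x, ...) {
  cat(sprintf("region_effect (%s, band '%s'): %d regions, mean %.4g\n",
              x$source, if (is.null(x$band)) "?" else x$band$name,
              length(x$summed_beta), mean(x$summed_beta)))
  invisible(x)
}

#' Region-wise power-on-age regression summed over a band
#'
#' For each region and 1-Hz bin in the band, regresses relative power on
#' age (motion as covariate), then sums the age betas over the band's
#' bins (8 bins for the split beta band).
#'
#' @param power List of `power_spectrum_set` (one per subject) or a
#'   regions x frequencies x subjects array.
#' @param subjects Subject data frame (`age_years`, `motion`).
#' @param band A [band_definition()].
#' @param frequencies Frequency bins of the power array (default 1:49).
#' @return A `region_effect` with the per-bin beta matrix in attribute
#'   `"per_bin_beta"`.
#' @export
regionwise_power_age_regression <- function(power, subjects, band,
                                            frequencies = 1:49) {
  if (is.list(power)) {
    frequencies <- power[[1]]$frequencies
    power <- simplify2array(lapply(power, `[[`, "values"))
  }
  n_reg <- dim(power)[1]
  n_sub <- dim(power)[3]
  if (nrow(subjects) != n_sub)
    stop_oscdev("subject table does not match power array")
  idx <- match(band$bins, frequencies)
  if (anyNA(idx)) stop_oscdev("band '%s' outside the power array", band$name)
  X <- cbind(intercept = 1, age = subjects$age_years,
             motion = subjects$motion)
  betas <- matrix(NA_real_, n_reg, length(idx),
                  dimnames = list(NULL, band$bins))
  for (b in seq_along(idx)) {
    Y <- t(power[, idx[b], , drop = TRUE])       # subjects x regions
    betas[, b] <- mass_ols(Y, X, which = 2L)$beta
  }
  out <- region_effect(rowSums(betas), band = band, source = "power")
  attr(out, "per_bin_beta") <- betas
  out
}

#' Median split of a continuous variable
#'
#' Deterministic dichotomization at the sample median: subjects are
#' ordered by value (ties broken by id order) and the lower
#' `ceiling(n/2)` form the low group, so median-valued subjects fall in
#' the low group and group sizes differ by at most one.
#'
#' @param values Numeric vector.
#' @param ids Optional ids for tie-breaking (defaults to input order).
#' @return Factor with levels `"low"`, `"high"`.
#' @export
median_split <- function(values, ids = seq_along(values)) {
  if (length(values) < 2) stop_oscdev("median split needs >= 2 values")
  if (length(unique(values)) < 2)
    stop_oscdev("all values identical; median split undefined")
  ord <- order(values, ids)
  n_low <- ceiling(length(values) / 2)
  grp <- rep("high", length(values))
  grp[ord[seq_len(n_low)]] <- "low"
  factor(grp, levels = c("low", "high"))
}
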