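# End-to-end orchestration and table IO. All tabular outputs are plain
# tab-separated text with a '#'-prefixed provenance header (config hash,
# seed, stage). A single global seed expands deterministically into
# per-stage seeds.

#' Configure a pipeline run
#'
#' @param cohort A [cohort_config()] for simulation, or `NULL` when
#'   loading a cohort from `manifest`.
#' @param manifest Optional path to a cohort manifest (see
#'   [read_cohort()]).
#' @param parcellation Optional path to a parcellation table (required
#'   with `manifest`).
#' @param out_dir Optional output directory; when given, every stage
#'   writes its tables there.
#' @param bands Band set (default [standard_bands()]).
#' @param nuisance_mode Edgewise nuisance set (default `"full"`).
#' @param gradient_axes Axes for gradient fits (default `"y"`,
#'   `"x-left"`, `"x-right"`).
#' @param nbs_threshold_p,nbs_n_perm NBS settings.
#' @param mediation_n_boot Bootstrap draws for mediation.
#' @param run_mixed_model Fit the global age x frequency mixed model
#'   (default `TRUE`; the slowest single stage on large cohorts).
#' @param run_profile Fit the 10-bin gradient profile (default `TRUE`).
#' @param seed Global seed; expanded per stage.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(), manifest = NULL,
                            parcellation = NULL, out_dir = NULL,
                            bands = standard_bands(),
                            nuisance_mode = "full",
                            gradient_axes = c("y", "x-left", "x-right"),
                            nbs_threshold_p = 0.01, nbs_n_perm = 1000,
                            mediation_n_boot = 5000,
                            run_mixed_model = TRUE, run_profile = TRUE,
                            seed = 1) {
  if (is.null(cohort) && is.null(manifest))
    stop_oscdev("provide either a cohort config or a manifest path")
  structure(list(cohort = cohort, manifest = manifest,
                 parcellation = parcellation, out_dir = out_dir,
                 bands = bands, nuisance_mode = nuisance_mode,
                 gradient_axes = gradient_axes,
                 nbs_threshold_p = nbs_threshold_p,
                 nbs_n_perm = nbs_n_perm,
                 mediation_n_boot = mediation_n_boot,
                 run_mixed_model = run_mixed_model,
                 run_profile = run_profile, seed = seed),
            class = "pipeline_config")
}

config_hash <- function(cfg) {
  s <- paste(deparse(cfg[setdiff(names(cfg), "out_dir")]), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %%
            .Machine$integer.max)
}

write_stage_table <- function(df, path, cfg_hash, seed, stage) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# oscdev stage=%s seed=%d config=%s", stage, seed,
                     cfg_hash), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a cohort to disk
#'
#' Writes a tab-separated manifest (`subject_id age_years motion
#' impulsivity timeseries_path sampling_rate_hz`) and one delimited text
#' file per subject (regions x samples).
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @param digits Signal rounding for the text files (default 5
#'   significant digits).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir, digits = 5) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(nrow(cohort$subjects))
  for (s in seq_along(cohort$timeseries)) {
    ts <- cohort$timeseries[[s]]
    paths[s] <- file.path(dir, paste0(ts$subject_id, ".tsv"))
    write.table(signif(ts$values, digits), paths[s], sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  man <- cohort$subjects
  man$timeseries_path <- basename(paths)
  man$sampling_rate_hz <- vapply(cohort$timeseries, `[[`, 0,
                                 "sampling_rate_hz")
  man_path <- file.path(dir, "manifest.tsv")
  write.table(man, man_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write_parcellation(cohort$parcel, file.path(dir, "parcellation.tsv"))
  invisible(man_path)
}

#' Read a cohort from a manifest
#'
#' Loads the tab-separated manifest and each subject's regions x samples
#' delimited text file. A missing `impulsivity` column is allowed (the
#' mediation stage is then skipped downstream with a warning).
#'
#' @param manifest_path Path to the manifest.
#' @param parcel Optional `parcel_set` to validate region counts against.
#' @return List with `subjects` and `timeseries`.
#' @export
read_cohort <- function(manifest_path, parcel = NULL) {
  if (!file.exists(manifest_path))
    stop_oscdev("manifest not found: %s", manifest_path)
  man <- read.delim(manifest_path, stringsAsFactors = FALSE)
  need <- c("subject_id", "age_years", "motion", "timeseries_path",
            "sampling_rate_hz")
  missing_cols <- setdiff(need, names(man))
  if (length(missing_cols))
    stop_oscdev("manifest missing column(s): %s",
                paste(missing_cols, collapse = ", "))
  if (!"impulsivity" %in% names(man)) man$impulsivity <- NA_real_
  base <- dirname(manifest_path)
  timeseries <- vector("list", nrow(man))
  for (s in seq_len(nrow(man))) {
    p <- man$timeseries_path[s]
    if (!file.exists(p)) p <- file.path(base, p)
    if (!file.exists(p))
      stop_oscdev("time series file for subject %s not found: %s",
                  man$subject_id[s], man$timeseries_path[s])
    vals <- as.matrix(read.delim(p, header = FALSE))
    if (!is.null(parcel) && nrow(vals) != nrow(parcel))
      stop_oscdev("subject %s: %d regions in %s but parcellation has %d",
                  man$subject_id[s], nrow(vals), basename(p), nrow(parcel))
    timeseries[[s]] <- roi_timeseries(vals, man$sampling_rate_hz[s],
                                      man$subject_id[s])
  }
  list(subjects = man[, c("subject_id", "age_years", "motion",
                          "impulsivity")],
       timeseries = timeseries)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order: load or simulate the cohort;
#' per-subject PLV connectomes and relative power; global per-frequency
#' age regressions (PLV and power) with FDR and the mixed-model
#' age-by-frequency test; edgewise theta-band age regression with
#' nuisance control and per-region summed effects; regionwise delta/beta
#' power regressions; anatomical gradient fits and the 5-Hz-bin profile;
#' network heatmap, ANOVA with Tukey, association-vs-processing contrast,
#' hub and hub-edge selection; NBS on the age median-split contrast; and
#' the mediation screen of age -> edge theta PLV -> impulsivity on the
#' NBS-overlap edges (skipped with a warning when impulsivity is absent).
#'
#' @param cfg A [pipeline_config()].
#' @return A result bundle (named list of all stage outputs plus a run
#'   manifest with seed and config hash).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  hash <- config_hash(cfg)
  seed <- cfg$seed
  emit <- function(df, name, stage) {
    if (!is.null(cfg$out_dir)) {
      dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
      write_stage_table(df, file.path(cfg$out_dir, paste0(name, ".tsv")),
                        hash, seed, stage)
    }
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(cfg$out_dir)) {
        dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
        writeLines(sprintf("FAILED stage=%s: %s", name, conditionMessage(e)),
                   file.path(cfg$out_dir, "FAILED"))
      }
      stop_oscdev("pipeline stage '%s' failed: %s", name,
                  conditionMessage(e))
    })
  }

  # ---- load / simulate ---------------------------------------------------
  cohort <- stage("cohort", {
    if (!is.null(cfg$manifest)) {
      parcel <- if (!is.null(cfg$parcellation))
        load_parcellation(cfg$parcellation) else NULL
      ch <- read_cohort(cfg$manifest, parcel)
      list(parcel = parcel, subjects = ch$subjects,
           timeseries = ch$timeseries, mediation_edges = NULL)
    } else {
      ccfg <- cfg$cohort
      ccfg$seed <- derive_seed(seed, "cohort")
      generate_cohort(ccfg)
    }
  })
  parcel <- cohort$parcel
  subjects <- cohort$subjects
  if (is.null(parcel)) stop_oscdev("a parcellation is required")

  bands <- cfg$bands
  theta <- bands$theta

  # ---- spectral ----------------------------------------------------------
  spectra <- stage("spectral", {
    conn <- list(); pow <- list()
    for (s in seq_along(cohort$timeseries)) {
      ts <- cohort$timeseries[[s]]
      ep <- epoch_timeseries(ts, 3)
      conn[[s]] <- compute_plv(ep)
      pow[[s]] <- compute_relative_power(ts)
    }
    list(connectomes = conn, power = pow)
  })
  theta_plv <- simplify2array(lapply(spectra$connectomes,
                                     band_average, band = theta))
  theta_power <- vapply(spectra$power, band_average, band = theta,
                        numeric(nrow(parcel)))

  # ---- global models -----------------------------------------------------
  plv_tbl <- global_frequency_table(spectra$connectomes, subjects)
  pow_tbl <- global_frequency_table(spectra$power, subjects)
  global_plv_fit <- stage("global_plv",
                          per_frequency_regression(plv_tbl))
  global_pow_fit <- stage("global_power",
                          per_frequency_regression(pow_tbl))
  emit(global_plv_fit, "global_plv_age", "global_plv")
  emit(global_pow_fit, "global_power_age", "global_power")
  mixed <- if (cfg$run_mixed_model)
    stage("mixed_model", fit_global_interaction(plv_tbl)) else NULL

  # ---- edgewise + regional ----------------------------------------------
  edge_fit <- stage("edgewise", edgewise_age_regression(
    theta_plv, subjects, band_power = theta_power,
    nuisance_mode = cfg$nuisance_mode, band = theta))
  region_fit <- summed_region_effect(edge_fit, source = "plv")
  pairs <- ut_pairs(nrow(parcel))
  emit(data.frame(region_i = pairs[, 1] - 1L, region_j = pairs[, 2] - 1L,
                  beta_age = edge_fit$beta[pairs], se = edge_fit$se[pairs],
                  t = edge_fit$t[pairs], p = edge_fit$p[pairs],
                  q = fdr_adjust(edge_fit$p[pairs])),
       "edge_age_effects", "edgewise")
  emit(data.frame(region_id = parcel$region_id,
                  summed_beta = region_fit$summed_beta,
                  band = theta$name, source = "plv"),
       "region_effects", "edgewise")
  delta_power_fit <- stage("power_regional", regionwise_power_age_regression(
    spectra$power, subjects, bands$delta))
  beta_power_fit <- regionwise_power_age_regression(
    spectra$power, subjects, bands$beta)

  # ---- gradients ---------------------------------------------------------
  gradients <- stage("gradient", {
    fits <- lapply(setNames(cfg$gradient_axes, cfg$gradient_axes),
                   function(ax) {
                     tryCatch(gradient_fit(region_fit, parcel, axis = ax),
                              error = function(e) {
                                warning(sprintf("gradient axis '%s' skipped: %s",
                                                ax, conditionMessage(e)),
                                        call. = FALSE)
                                NULL
                              })
                   })
    fits[!vapply(fits, is.null, TRUE)]
  })
  profile <- if (cfg$run_profile) stage("gradient_profile", {
    bins <- five_hz_bins()
    effects <- lapply(bins, function(bn) {
      bp <- simplify2array(lapply(spectra$connectomes, band_average,
                                  band = bn))
      ef <- edgewise_age_regression(bp, subjects, nuisance_mode = "motion",
                                    band = bn)
      summed_region_effect(ef)
    })
    gradient_profile(effects, parcel)
  }) else NULL
  if (!is.null(profile))
    emit(cbind(axis = "y", profile), "gradient_profile", "gradient_profile")

  # ---- network level -----------------------------------------------------
  # sub-analyses that are infeasible at very small parcellations are
  # skipped with a warning rather than aborting the run
  net <- stage("network", {
    skip <- function(what, expr) {
      tryCatch(expr, error = function(e) {
        warning(sprintf("%s skipped: %s", what, conditionMessage(e)),
                call. = FALSE)
        NULL
      })
    }
    tbl <- network_effect_heatmap(edge_fit, parcel)
    anova_fit <- skip("network ANOVA",
                      within_network_anova(region_fit, parcel))
    avp <- skip("association-vs-processing test",
                association_vs_processing_test(tbl))
    hubs <- skip("hub selection", select_hubs(region_fit))
    hub_tbl <- if (is.null(hubs)) NULL else hub_edges(edge_fit, hubs)
    list(table = tbl, anova = anova_fit, assoc_vs_proc = avp,
         hubs = hubs, hub_edges = hub_tbl)
  })
  emit(as.data.frame(net$table$heatmap), "network_heatmap", "network")
  if (!is.null(net$anova))
    emit(net$anova$tukey, "network_tukey", "network")
  if (!is.null(net$hub_edges))
    emit(net$hub_edges, "hub_edges", "network")

  # ---- NBS ---------------------------------------------------------------
  nbs_age <- stage("nbs", {
    grp <- median_split(subjects$age_years, subjects$subject_id)
    nbs(theta_plv, list(type = "group", group = grp),
        threshold_p = cfg$nbs_threshold_p, n_perm = cfg$nbs_n_perm,
        seed = derive_seed(seed, "nbs_age"))
  })

  # ---- mediation ---------------------------------------------------------
  mediation <- NULL
  if (all(is.na(subjects$impulsivity))) {
    warning("impulsivity absent from cohort; mediation stage skipped")
  } else {
    mediation <- stage("mediation", {
      edges <- cohort$mediation_edges
      if (is.null(edges)) {
        # fall back to the strongest NBS component's most negative edges
        if (!length(nbs_age$components)) return(NULL)
        cmp <- nbs_age$components[[which.min(nbs_age$component_p)]]
        cmp <- cmp[order(cmp$stat), , drop = FALSE]
        edges <- as.matrix(cmp[seq_len(min(3, nrow(cmp))),
                               c("region_i", "region_j")])
      }
      cand <- lapply(seq_len(nrow(edges)), function(k) {
        theta_plv[edges[k, 1] + 1L, edges[k, 2] + 1L, ]
      })
      names(cand) <- sprintf("edge_%d_%d", edges[, 1], edges[, 2])
      mediation_screen(cand, x = subjects$age_years,
                       y = subjects$impulsivity,
                       n_boot = cfg$mediation_n_boot,
                       seed = derive_seed(seed, "mediation"))
    })
    if (!is.null(mediation))
      emit(mediation, "mediation", "mediation")
  }

  run <- data.frame(seed = seed, config = hash,
                    n_subjects = nrow(subjects),
                    n_regions = nrow(parcel),
                    timestamp = "run")
  emit(run, "run_manifest", "run")
  list(parcel = parcel, subjects = subjects,
       connectomes = spectra$connectomes, power = spectra$power,
       global_plv = global_plv_fit, global_power = global_pow_fit,
       mixed_model = mixed, edge_fit = edge_fit, region_fit = region_fit,
       delta_power_fit = delta_power_fit, beta_power_fit = beta_power_fit,
       gradients = gradients, gradient_profile = profile,
       network = net, nbs_age = nbs_age, mediation = mediation,
       mediation_edges = cohort$mediation_edges,
       seed = seed, config_hash = hash)
}
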