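# Anatomical-gradient synthesis: regression of per-region composite age
# effects on MNI coordinates with distance/area nuisance control, and
# slope-difference z tests across 5-Hz frequency bins.

#' Fit an anatomical gradient of a regional effect
#'
#' Ordinary least squares of the per-region summed age betas on an MNI
#' coordinate, controlling for each region's mean distance to all other
#' regions and its surface area. The `"y"` axis (anterior-to-posterior,
#' +y anterior) pools hemispheres; `"x-left"`/`"x-right"` fit one
#' hemisphere using |x| (increasing lateral) so the medial direction is
#' consistent, or signed x with `abs_x = FALSE`.
#'
#' @param v A `region_effect` (or numeric vector of per-region values).
#' @param parcel The `parcel_set` the effects are indexed by.
#' @param axis `"y"`, `"x-left"`, or `"x-right"`.
#' @param abs_x Use |x| for the lateral axes (default `TRUE`).
#' @return A `gradient_fit`: `slope`, `se`, `t`, `p`, `n`, `axis`,
#'   `label`.
#' @export
gradient_fit <- function(v, parcel, axis = c("y", "x-left", "x-right"),
                         abs_x = TRUE) {
  axis <- match.arg(axis)
  vals <- if (inherits(v, "region_effect")) v$summed_beta else as.numeric(v)
  stopifnot(inherits(parcel, "parcel_set"))
  if (length(vals) != nrow(parcel))
    stop_oscdev("effect vector length (%d) != number of regions (%d)",
                length(vals), nrow(parcel))
  geom <- region_geometry(parcel)
  keep <- switch(axis,
                 "y" = rep(TRUE, nrow(parcel)),
                 "x-left" = parcel$hemisphere == "L",
                 "x-right" = parcel$hemisphere == "R")
  if (sum(keep) < 5) stop_oscdev("too few regions (%d) on axis '%s'",
                                 sum(keep), axis)
  coord <- switch(axis,
                  "y" = parcel$y,
                  "x-left" = if (abs_x) abs(parcel$x) else parcel$x,
                  "x-right" = if (abs_x) abs(parcel$x) else parcel$x)
  coord <- coord[keep]
  if (var(coord) < 1e-12)
    stop_oscdev("degenerate coordinate variance on axis '%s'", axis)
  X <- cbind(intercept = 1, coord = coord,
             mean_dist = geom$mean_distance[keep],
             area = parcel$surface_area_mm2[keep])
  fit <- mass_ols(matrix(vals[keep], ncol = 1), X, which = 2L)
  structure(list(axis = axis, slope = unname(fit$beta), se = unname(fit$se),
                 t = unname(fit$t), p = unname(fit$p), n = sum(keep),
                 df = fit$df,
                 label = if (inherits(v, "region_effect") &&
                             !is.null(v$band)) v$band$name else NA_character_),
            class = "gradient_fit")
}

#' @method print gradient_fit
#' @export
print.gradient_fit <- function(x, ...) {
  cat(sprintf(
    "gradient_fit [%s%s]: slope %.4g (SE %.3g), t = %.2f, p = %.3g, n = %d\n",
    x$axis, if (is.na(x$label)) "" else paste0(", ", x$label),
    x$slope, x$se, x$t, x$p, x$n))
  invisible(x)
}

#' Slope-difference z test between two gradient fits
#'
#' `z = (beta_1 - beta_2) / sqrt(SE_1^2 + SE_2^2)`; values beyond 1.645
#' correspond to one-tailed p < 0.05. Antisymmetric in its arguments.
#'
#' @param f1,f2 Two `gradient_fit` objects on the same axis.
#' @return A `slope_comparison`: `z`, the two slopes and SEs, labels, and
#'   the one-tailed `p`.
#' @export
slope_difference_z <- function(f1, f2) {
  stopifnot(inherits(f1, "gradient_fit"), inherits(f2, "gradient_fit"))
  if (!identical(f1$axis, f2$axis))
    stop_oscdev("gradient fits are on different axes (%s vs %s)",
                f1$axis, f2$axis)
  if (f1$se <= 0 || f2$se <= 0)
    stop_oscdev("slope standard errors must be positive")
  z <- (f1$slope - f2$slope) / sqrt(f1$se^2 + f2$se^2)
  structure(list(z = z, beta_1 = f1$slope, se_1 = f1$se,
                 beta_2 = f2$slope, se_2 = f2$se,
                 reference = f1$label, test = f2$label,
                 p_one_tailed = pnorm(abs(z), lower.tail = FALSE)),
            class = "slope_comparison")
}

#' @method print slope_comparison
#' @export
print.slope_comparison <- function(x, ...) {
  cat(sprintf("slope comparison %s vs %s: z = %.3f (one-tailed p = %.3g)\n",
              x$reference, x$test, x$z, x$p_one_tailed))
  invisible(x)
}

#' Frequency-resolved gradient profile over 5-Hz bins
#'
#' Fits the anatomical gradient in every 5-Hz bin (1-5, 6-10, ...,
#' 46-49 Hz) and compares each bin's slope to the reference bin
#' (default 6-10 Hz, where the developmental decoupling is strongest) by
#' [slope_difference_z()].
#'
#' @param effects_by_bin Named list of `region_effect` (or numeric
#'   vectors), one per 5-Hz bin; names must include the reference.
#' @param parcel The `parcel_set`.
#' @param axis Coordinate axis (default `"y"`).
#' @param reference Name of the reference bin (default `"6-10"`).
#' @return Data frame `bin`, `slope`, `se`, `t`, `p`, `z_vs_ref`,
#'   `p_one_tailed`; fits in attribute `"fits"`.
#' @export
gradient_profile <- function(effects_by_bin, parcel, axis = "y",
                             reference = "6-10") {
  if (!reference %in% names(effects_by_bin))
    stop_oscdev("reference bin '%s' not among the supplied bins", reference)
  fits <- lapply(names(effects_by_bin), function(nm) {
    f <- gradient_fit(effects_by_bin[[nm]], parcel, axis = axis)
    f$label <- nm
    f
  })
  names(fits) <- names(effects_by_bin)
  ref <- fits[[reference]]
  zs <- vapply(fits, function(f) slope_difference_z(ref, f)$z, 0)
  out <- data.frame(
    bin = names(fits),
    slope = vapply(fits, `[[`, 0, "slope"),
    se = vapply(fits, `[[`, 0, "se"),
    t = vapply(fits, `[[`, 0, "t"),
    p = vapply(fits, `[[`, 0, "p"),
    z_vs_ref = zs,
    p_one_tailed = pnorm(abs(zs), lower.tail = FALSE),
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "fits") <- fits
  attr(out, "reference") <- reference
  out
}
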