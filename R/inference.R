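# Confirmatory inference: the network-based statistic (suprathreshold
# cluster permutation test on edgewise models) and bootstrap mediation of
# age -> edge PLV -> impulsivity.

# Connected components of an undirected graph given as an edge index
# matrix (k x 2 of vertex ids); breadth-first search over an adjacency
# list. Returns a list of integer vectors of edge indices, one per
# component, ordered by first edge.
bfs_components <- function(edges) {
  if (!nrow(edges)) return(list())
  verts <- sort(unique(c(edges)))
  adj <- split(rep(seq_len(nrow(edges)), 2L), factor(c(edges), levels = verts))
  vmap <- setNames(seq_along(verts), verts)
  visited_v <- logical(length(verts))
  visited_e <- logical(nrow(edges))
  comps <- list()
  for (start in seq_along(verts)) {
    if (visited_v[start]) next
    queue <- start
    visited_v[start] <- TRUE
    comp_edges <- integer()
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (e in adj[[v]]) {
        if (!visited_e[e]) {
          visited_e[e] <- TRUE
          comp_edges <- c(comp_edges, e)
        }
        for (w in vmap[as.character(edges[e, ])]) {
          if (!visited_v[w]) { visited_v[w] <- TRUE; queue <- c(queue, w) }
        }
      }
    }
    if (length(comp_edges)) comps[[length(comps) + 1L]] <- sort(comp_edges)
  }
  comps
}

# Edgewise test statistics for an NBS design. Y: subjects x edges.
# Returns list(t, df).
nbs_edge_stats <- function(Y, design) {
  if (design$type == "group") {
    g <- design$group
    X <- cbind(intercept = 1, group = as.numeric(g == levels(g)[2]))
    cov <- design$covariates
    if (!is.null(cov)) X <- cbind(X, as.matrix(cov))
    fit <- mass_ols(Y, X, which = 2L)
  } else {
    X <- cbind(intercept = 1, predictor = design$predictor)
    cov <- design$covariates
    if (!is.null(cov)) X <- cbind(X, as.matrix(cov))
    fit <- mass_ols(Y, X, which = 2L)
  }
  fit
}

#' Network-based statistic (NBS)
#'
#' Mass-univariate edgewise models (two-sample t for a group contrast, or
#' the t of a continuous predictor with covariates), thresholded at
#' `threshold_p` (two-tailed); suprathreshold edges form a graph whose
#' connected components are found by breadth-first search. Family-wise
#' significance of each component's size (edge count) is assessed against
#' the permutation distribution of the maximal component size obtained by
#' permuting the predictor/labels, with the `(b + 1) / (n_perm + 1)`
#' estimator.
#'
#' @param band_plv Regions x regions x subjects array (or list of
#'   symmetric matrices) of band PLV.
#' @param design List: either `list(type = "group", group = factor)` or
#'   `list(type = "regression", predictor = numeric)`; optionally
#'   `covariates` (data frame / matrix, kept fixed under permutation).
#' @param threshold_p Two-tailed primary edge threshold (default 0.01).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Seed for the permutation stream.
#' @return An `nbs_result`: `components` (list of data frames
#'   `region_i`, `region_j`, `stat`, 0-based ids), `component_p`,
#'   `observed_max_size`, `null_max_size` (length `n_perm`),
#'   `threshold_p`, `threshold_t`, `n_perm`, `seed`.
#' @export
nbs <- function(band_plv, design, threshold_p = 0.01, n_perm = 1000,
                seed = 1) {
  check_number(threshold_p, "threshold_p", 1e-12, 1 - 1e-12)
  n_perm <- as.integer(check_number(n_perm, "n_perm", 1))
  if (is.list(band_plv) && !is.array(band_plv))
    band_plv <- simplify2array(band_plv)
  n_reg <- dim(band_plv)[1]
  Y <- edges_from_matrices(band_plv)
  pairs <- ut_pairs(n_reg)
  if (!design$type %in% c("group", "regression"))
    stop_oscdev("design$type must be 'group' or 'regression'")
  if (design$type == "group") design$group <- factor(design$group)
  obs <- nbs_edge_stats(Y, design)
  t_crit <- stats::qt(1 - threshold_p / 2, obs$df)
  supra <- which(abs(obs$t) >= t_crit)
  comps <- bfs_components(pairs[supra, , drop = FALSE])
  comp_sizes <- vapply(comps, length, 0L)
  warn <- if (n_perm < 100)
    sprintf("n_perm = %d is low; permutation p resolution is %.3g",
            n_perm, 1 / (n_perm + 1)) else NULL
  null_max <- with_seed(derive_seed(seed, "nbs_perm"), {
    vapply(seq_len(n_perm), function(b) {
      d <- design
      idx <- sample.int(nrow(Y))
      if (d$type == "group") d$group <- d$group[idx]
      else d$predictor <- d$predictor[idx]
      st <- nbs_edge_stats(Y, d)
      s <- which(abs(st$t) >= t_crit)
      if (!length(s)) return(0L)
      max(vapply(bfs_components(pairs[s, , drop = FALSE]), length, 0L))
    }, 0L)
  })
  comp_p <- vapply(comp_sizes, function(sz)
    (sum(null_max >= sz) + 1) / (n_perm + 1), 0)
  comp_dfs <- lapply(comps, function(es) {
    data.frame(region_i = pairs[supra[es], 1] - 1L,
               region_j = pairs[supra[es], 2] - 1L,
               stat = obs$t[supra[es]])
  })
  structure(list(components = comp_dfs,
                 component_sizes = comp_sizes,
                 component_p = comp_p,
                 observed_max_size = if (length(comp_sizes))
                   max(comp_sizes) else 0L,
                 null_max_size = null_max,
                 threshold_p = threshold_p, threshold_t = t_crit,
                 edge_df = obs$df, n_perm = n_perm, seed = seed,
                 warning = warn),
            class = "nbs_result")
}

#' @method print nbs_result
#' @export
print.nbs_result <- function(x, ...) {
  cat(sprintf(
    "nbs_result: %d component(s) at |t| >= %.2f (p < %g two-tailed), %d permutations\n",
    length(x$components), x$threshold_t, x$threshold_p, x$n_perm))
  for (k in seq_along(x$components)) {
    cmp <- x$components[[k]]
    cat(sprintf("  component %d: %d edges, %d regions, p = %.4g\n", k,
                nrow(cmp), length(unique(c(cmp$region_i, cmp$region_j))),
                x$component_p[k]))
  }
  if (!is.null(x$warning)) cat("  warning:", x$warning, "\n")
  invisible(x)
}

ols_paths <- function(x, m, y, covariates = NULL) {
  solve_ols <- function(X, yy) solve(crossprod(X), crossprod(X, yy))
  base <- cbind(1, x)
  if (!is.null(covariates)) base <- cbind(base, covariates)
  a <- solve_ols(base, m)[2]
  X2 <- cbind(1, x, m)
  if (!is.null(covariates)) X2 <- cbind(X2, covariates)
  cf2 <- solve_ols(X2, y)
  c_total <- solve_ols(base, y)[2]
  list(a = a, b = cf2[3], c = c_total, c_prime = cf2[2])
}

#' Single-mediator bootstrap mediation
#'
#' OLS path model: `a` (mediator on predictor), `b` (outcome on mediator,
#' predictor partialed), `c` (total effect), `c_prime` (direct effect);
#' the indirect effect is `a * b`, with a percentile confidence interval
#' over case-resampled refits. For OLS with identical covariate sets,
#' `c = c_prime + a * b` exactly.
#'
#' @param x Predictor (e.g. age).
#' @param m Mediator (e.g. edge PLV).
#' @param y Outcome (e.g. impulsivity).
#' @param covariates Optional data frame/matrix of covariates entering
#'   all three models.
#' @param n_boot Bootstrap draws (default 5000).
#' @param seed Seed for resampling.
#' @param conf Confidence level (default 0.95).
#' @return A `mediation_result` with paths, `ab`, `ci`, bootstrap draws,
#'   two-sided bootstrap `p`, and `significant` (CI excludes 0).
#' @export
mediate <- function(x, m, y, covariates = NULL, n_boot = 5000, seed = 1,
                    conf = 0.95) {
  keep <- stats::complete.cases(x, m, y,
                                if (is.null(covariates)) rep(TRUE, length(x))
                                else covariates)
  x <- x[keep]; m <- m[keep]; y <- y[keep]
  if (!is.null(covariates))
    covariates <- as.matrix(covariates)[keep, , drop = FALSE]
  n <- length(x)
  if (n < 10) stop_oscdev("mediation needs >= 10 complete cases, got %d", n)
  if (var(x) == 0 || var(m) == 0 || var(y) == 0)
    stop_oscdev("zero variance in predictor, mediator, or outcome")
  paths <- ols_paths(x, m, y, covariates)
  ab <- paths$a * paths$b
  draws <- with_seed(derive_seed(seed, "mediation_boot"), {
    vapply(seq_len(n_boot), function(bb) {
      idx <- sample.int(n, replace = TRUE)
      cv <- if (is.null(covariates)) NULL
            else covariates[idx, , drop = FALSE]
      p <- tryCatch(ols_paths(x[idx], m[idx], y[idx], cv),
                    error = function(e) NULL)
      if (is.null(p)) NA_real_ else p$a * p$b
    }, 0)
  })
  draws <- draws[is.finite(draws)]
  alpha <- (1 - conf) / 2
  ci <- unname(quantile(draws, c(alpha, 1 - alpha), type = 6))
  p_boot <- 2 * min((sum(draws <= 0) + 1) / (length(draws) + 1),
                    (sum(draws >= 0) + 1) / (length(draws) + 1))
  structure(list(a = paths$a, b = paths$b, c = paths$c,
                 c_prime = paths$c_prime, ab = ab,
                 ci = ci, conf = conf, p = min(p_boot, 1),
                 significant = ci[1] > 0 || ci[2] < 0,
                 n = n, n_boot = n_boot, seed = seed,
                 boot_draws = draws),
            class = "mediation_result")
}

#' @method print mediation_result
#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf(
    "mediation: a = %.4g, b = %.4g, c = %.4g, c' = %.4g\n  indirect ab = %.4g, %d%% CI [%.4g, %.4g], boot p = %.3g (n = %d, %d draws)\n",
    x$a, x$b, x$c, x$c_prime, x$ab, round(100 * x$conf), x$ci[1], x$ci[2],
    x$p, x$n, x$n_boot))
  invisible(x)
}

#' Screen several candidate mediators with FDR
#'
#' Applies [mediate()] to each candidate mediator and adjusts the
#' bootstrap p values across candidates by Benjamini-Hochberg. Reports
#' both the per-candidate view (`significant`: own CI excludes 0) and the
#' global-FDR view (`q`).
#'
#' @param candidates Named list of mediator vectors (e.g. edge PLVs or
#'   node powers).
#' @param x,y Predictor and outcome vectors.
#' @param covariates Optional covariates for all models.
#' @param n_boot,seed,conf Passed to [mediate()].
#' @return Data frame `candidate`, `a`, `b`, `c`, `c_prime`, `ab`,
#'   `ci_lo`, `ci_hi`, `p`, `q`, `significant`; full results in
#'   attribute `"results"`.
#' @export
mediation_screen <- function(candidates, x, y, covariates = NULL,
                             n_boot = 5000, seed = 1, conf = 0.95) {
  if (!length(candidates))
    return(data.frame(candidate = character(), a = numeric(),
                      b = numeric(), c = numeric(), c_prime = numeric(),
                      ab = numeric(), ci_lo = numeric(), ci_hi = numeric(),
                      p = numeric(), q = numeric(),
                      significant = logical()))
  if (is.null(names(candidates)))
    names(candidates) <- sprintf("m%02d", seq_along(candidates))
  res <- lapply(seq_along(candidates), function(k) {
    mediate(x, candidates[[k]], y, covariates = covariates,
            n_boot = n_boot, seed = derive_seed(seed, names(candidates)[k]),
            conf = conf)
  })
  out <- data.frame(
    candidate = names(candidates),
    a = vapply(res, `[[`, 0, "a"), b = vapply(res, `[[`, 0, "b"),
    c = vapply(res, `[[`, 0, "c"),
    c_prime = vapply(res, `[[`, 0, "c_prime"),
    ab = vapply(res, `[[`, 0, "ab"),
    ci_lo = vapply(res, function(r) r$ci[1], 0),
    ci_hi = vapply(res, function(r) r$ci[2], 0),
    p = vapply(res, `[[`, 0, "p"),
    stringsAsFactors = FALSE
  )
  out$q <- fdr_adjust(out$p)
  out$significant <- vapply(res, `[[`, TRUE, "significant")
  attr(out, "results") <- res
  out
}
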