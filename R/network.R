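# Network-level aggregation of edge and region age effects: mean-beta
# heatmap over the 13-network partition, one-way ANOVA with Tukey HSD,
# the association-vs-processing contrast, and top-5% hub/edge selection.

#' Network-by-network mean age-effect heatmap
#'
#' Cell (A, B) is the mean edgewise age beta over all region pairs with
#' one endpoint in network A and one in B; within-network cells average
#' the i < j pairs inside the network and are `NA` (flagged) for networks
#' with fewer than two member regions.
#'
#' @param m An `edge_effect`.
#' @param parcel The `parcel_set` (provides network labels).
#' @return A `network_effect_table`: symmetric `heatmap` matrix (networks
#'   present, in [network_labels] order), `within_edges` (named list of
#'   within-network edge beta vectors), and `networks`.
#' @export
network_effect_heatmap <- function(m, parcel) {
  stopifnot(inherits(m, "edge_effect"), inherits(parcel, "parcel_set"))
  if (nrow(m$beta) != nrow(parcel))
    stop_oscdev("edge matrix and parcellation disagree on region count")
  nets <- intersect(network_labels, unique(parcel$network))
  k <- length(nets)
  H <- matrix(NA_real_, k, k, dimnames = list(nets, nets))
  within <- setNames(vector("list", k), nets)
  for (a in seq_len(k)) {
    ia <- which(parcel$network == nets[a])
    for (b in a:k) {
      ib <- which(parcel$network == nets[b])
      if (a == b) {
        if (length(ia) >= 2) {
          sub <- m$beta[ia, ia, drop = FALSE]
          vals <- sub[upper.tri(sub)]
          H[a, a] <- mean(vals)
          within[[a]] <- vals
        } else {
          within[[a]] <- numeric()
        }
      } else {
        vals <- m$beta[ia, ib, drop = FALSE]
        H[a, b] <- H[b, a] <- mean(vals)
      }
    }
  }
  structure(list(heatmap = H, within_edges = within, networks = nets,
                 band = m$band),
            class = "network_effect_table")
}

#' @method print network_effect_table
#' @export
print.network_effect_table <- function(x, ...) {
  cat(sprintf("network_effect_table: %d networks\n", length(x$networks)))
  print(round(x$heatmap, 4))
  invisible(x)
}

#' One-way ANOVA of regional age effects across networks
#'
#' Groups the per-region summed age betas by network label and tests for
#' between-network differences (13 groups over 333 regions give
#' df = 12, 320), followed by Tukey HSD post hoc contrasts on all network
#' pairs. Networks with fewer than two members are dropped (reported in
#' `dropped`). Set `level = "edge"` to group within-network edge betas
#' instead of per-region sums.
#'
#' @param v A `region_effect` (for the default region-level ANOVA).
#' @param parcel The `parcel_set`.
#' @param level `"region"` (default) or `"edge"`.
#' @param edge_table A `network_effect_table` (required for
#'   `level = "edge"`).
#' @return List with `F`, `df1`, `df2`, `p`, `tukey` (data frame
#'   `net_a`, `net_b`, `mean_diff`, `p_adj`, `significant`), and the
#'   underlying `aov` fit.
#' @export
within_network_anova <- function(v = NULL, parcel = NULL,
                                 level = c("region", "edge"),
                                 edge_table = NULL) {
  level <- match.arg(level)
  if (level == "region") {
    stopifnot(inherits(v, "region_effect"), inherits(parcel, "parcel_set"))
    dat <- data.frame(value = v$summed_beta, group = parcel$network,
                      stringsAsFactors = FALSE)
  } else {
    stopifnot(inherits(edge_table, "network_effect_table"))
    dat <- do.call(rbind, lapply(names(edge_table$within_edges), function(nm) {
      vals <- edge_table$within_edges[[nm]]
      if (!length(vals)) return(NULL)
      data.frame(value = vals, group = nm, stringsAsFactors = FALSE)
    }))
  }
  counts <- table(dat$group)
  dropped <- names(counts)[counts < 2]
  if (length(dropped)) {
    dat <- dat[!dat$group %in% dropped, , drop = FALSE]
    counts <- table(dat$group)
  }
  if (length(counts) < 2)
    stop_oscdev("need at least 2 network groups with >= 2 members (dropped: %s)",
                paste(dropped, collapse = ", "))
  dat$group <- factor(dat$group,
                      levels = intersect(network_labels, names(counts)))
  fit <- aov(value ~ group, data = dat)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$group
  pairs_nm <- strsplit(rownames(tk), "-", fixed = TRUE)
  tukey <- data.frame(
    net_a = vapply(pairs_nm, `[`, "", 1),
    net_b = vapply(pairs_nm, `[`, "", 2),
    mean_diff = tk[, "diff"],
    p_adj = tk[, "p adj"],
    significant = tk[, "p adj"] < 0.05,
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(F = an$`F value`[1], df1 = an$Df[1], df2 = an$Df[2],
       p = an$`Pr(>F)`[1], tukey = tukey, fit = fit, dropped = dropped)
}

#' Association versus processing network contrast
#'
#' Two-sample t test (pooled variance) comparing within-network edge age
#' betas pooled over association networks against those pooled over
#' processing networks.
#'
#' @param edge_table A [network_effect_heatmap()] result.
#' @param classes Network class map (default [network_classes]).
#' @return List with `t`, `df`, `p`, class means and sizes.
#' @export
association_vs_processing_test <- function(edge_table,
                                           classes = network_classes) {
  stopifnot(inherits(edge_table, "network_effect_table"))
  pool <- function(nets) {
    unlist(edge_table$within_edges[
      intersect(nets, names(edge_table$within_edges))], use.names = FALSE)
  }
  a <- pool(classes$association)
  b <- pool(classes$processing)
  if (length(a) < 2 || length(b) < 2)
    stop_oscdev("each network class needs at least 2 within-network edges")
  ht <- t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_association = mean(a), mean_processing = mean(b),
       n_association = length(a), n_processing = length(b))
}

#' Select developmental hub regions
#'
#' The `floor(fraction * n)` regions with the most negative composite age
#' effects (fastest developmental decoupling); ties broken by region id.
#' Top 5% of 333 regions selects 16 hubs.
#'
#' @param v A `region_effect` (or numeric vector).
#' @param fraction Fraction of regions to retain (default 0.05).
#' @return Integer vector of 0-based region ids, most negative first.
#' @export
select_hubs <- function(v, fraction = 0.05) {
  check_number(fraction, "fraction", 1e-9, 1 - 1e-9)
  vals <- if (inherits(v, "region_effect")) v$summed_beta else as.numeric(v)
  n <- length(vals)
  k <- floor(fraction * n)
  if (k < 1) stop_oscdev("fraction %g of %d regions selects no hubs",
                         fraction, n)
  ids <- 0:(n - 1L)
  ord <- order(vals, ids)
  ids[ord[seq_len(k)]]
}

#' Retain each hub's strongest decoupling edges
#'
#' For every hub region, keeps the `floor(fraction * n)` most negative
#' edgewise age betas among its edges (ties broken by partner region id);
#' entries are counted per hub, so an edge shared by two hubs appears
#' twice. With 16 hubs over 333 regions this retains 16 x 16 = 256
#' entries.
#'
#' @param m An `edge_effect`.
#' @param hubs Integer vector of 0-based hub region ids (from
#'   [select_hubs()]).
#' @param fraction Fraction of each hub's edges to keep (default 0.05).
#' @return Data frame `hub`, `partner` (0-based ids), `beta`.
#' @export
hub_edges <- function(m, hubs, fraction = 0.05) {
  stopifnot(inherits(m, "edge_effect"))
  n <- nrow(m$beta)
  k <- floor(fraction * n)
  if (k < 1) stop_oscdev("fraction %g of %d regions keeps no edges",
                         fraction, n)
  out <- lapply(hubs, function(h) {
    row <- m$beta[h + 1L, ]
    partners <- 0:(n - 1L)
    keep <- partners != h
    ord <- order(row[keep], partners[keep])
    sel <- ord[seq_len(k)]
    data.frame(hub = h, partner = partners[keep][sel],
               beta = row[keep][sel])
  })
  do.call(rbind, out)
}
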