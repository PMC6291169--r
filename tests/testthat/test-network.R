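test_that("network heatmap cells equal brute-force means over member edges", {
  df <- data.frame(
    region_id = 0:5,
    label = sprintf("R_%03d", 0:5),
    hemisphere = rep(c("L", "R"), 3),
    x = c(-10, 20, -30, 40, -50, 60), y = c(0, 10, 20, 30, 40, 50),
    z = rep(0, 6), surface_area_mm2 = rep(300, 6),
    network = c("DM", "DM", "DM", "VIS", "VIS", "SAL"),
    stringsAsFactors = FALSE
  )
  p <- parcel_set(df)
  set.seed(1)
  b <- matrix(rnorm(36), 6); b <- (b + t(b)) / 2
  ef <- make_edge_effect(b)
  tbl <- network_effect_heatmap(ef, p)
  H <- tbl$heatmap
  expect_identical(H, t(H))
  bm <- ef$beta
  expect_equal(H["DM", "DM"], mean(c(bm[1, 2], bm[1, 3], bm[2, 3])))
  expect_equal(H["DM", "VIS"],
               mean(bm[1:3, 4:5]))
  expect_equal(H["VIS", "SAL"], mean(bm[4:5, 6]))
  expect_true(is.na(H["SAL", "SAL"]))          # single-region network
  const <- make_edge_effect(matrix(0.7, 6, 6))
  Hc <- network_effect_heatmap(const, p)$heatmap
  expect_equal(unique(Hc[!is.na(Hc)]), 0.7)
})

test_that("the network ANOVA has (G-1, n-G) degrees of freedom and Tukey flags a planted shift", {
  p <- load_parcellation(system.file("extdata",
                                     "synthetic_parcellation_333.tsv",
                                     package = "oscdev"))
  set.seed(3)
  vals <- rnorm(333)
  res <- within_network_anova(region_effect(vals), p)
  expect_equal(res$df1, 12)                    # 13 networks
  expect_equal(res$df2, 320)                   # 333 - 13
  expect_equal(nrow(res$tukey), choose(13, 2))
  expect_gt(res$p, 1e-4)                       # no planted differences
  shifted <- vals
  shifted[p$network == "SAL"] <- shifted[p$network == "SAL"] - 5
  res2 <- within_network_anova(region_effect(shifted), p)
  expect_lt(res2$p, 1e-6)
  sal_rows <- res2$tukey$net_a == "SAL" | res2$tukey$net_b == "SAL"
  expect_equal(sum(sal_rows), 12)
  expect_true(all(res2$tukey$significant[sal_rows]))
  expect_false(any(res2$tukey$significant[!sal_rows]))
})

test_that("association-vs-processing contrast matches the pooled-variance formula", {
  p <- generate_parcellation(80, seed = 4)
  set.seed(5)
  b <- matrix(rnorm(6400, 0, 0.5), 80); b <- (b + t(b)) / 2
  assoc <- p$network %in% network_classes$association
  b[assoc, assoc] <- b[assoc, assoc] - 0.8     # planted lower association
  ef <- make_edge_effect(b)
  tbl <- network_effect_heatmap(ef, p)
  res <- association_vs_processing_test(tbl)
  expect_lt(res$t, -2)
  expect_lt(res$p, 0.05)
  # formula oracle on the pooled within-class vectors
  a <- unlist(tbl$within_edges[intersect(network_classes$association,
                                         names(tbl$within_edges))])
  pr <- unlist(tbl$within_edges[intersect(network_classes$processing,
                                          names(tbl$within_edges))])
  sp2 <- ((length(a) - 1) * var(a) + (length(pr) - 1) * var(pr)) /
    (length(a) + length(pr) - 2)
  t_hand <- (mean(a) - mean(pr)) /
    sqrt(sp2 * (1 / length(a) + 1 / length(pr)))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$df, length(a) + length(pr) - 2)
})

test_that("hub selection takes the floor of the fraction with id tie-breaks", {
  set.seed(6)
  v333 <- rnorm(333)
  hubs <- select_hubs(region_effect(v333), 0.05)
  expect_length(hubs, 16)                      # floor(0.05 * 333)
  expect_equal(hubs, order(v333)[1:16] - 1L)
  expect_length(select_hubs(rnorm(100), 0.05), 5)
  tied <- c(-1, -1, 0, 1)
  expect_equal(select_hubs(tied, 0.3), 0L)     # lower region_id wins
  expect_equal(select_hubs(tied, 0.5), c(0L, 1L))
  expect_error(select_hubs(rnorm(10), 0.05), "no hubs")
  # scale invariance
  expect_equal(select_hubs(region_effect(3 * v333), 0.05), hubs)
})

test_that("hub edges retain floor(fraction * n) entries per hub, duplicates included", {
  set.seed(7)
  b <- matrix(rnorm(333^2), 333); b <- (b + t(b)) / 2
  ef <- make_edge_effect(b)
  v <- summed_region_effect(ef)
  hubs <- select_hubs(v, 0.05)
  he <- hub_edges(ef, hubs, 0.05)
  expect_equal(nrow(he), 256)                  # 16 hubs x 16 edges
  expect_equal(as.vector(table(factor(he$hub, levels = hubs))),
               rep(16, 16))
  # per-hub edges are that hub's most negative betas
  h1 <- hubs[1]
  row <- ef$beta[h1 + 1, ]
  expect_equal(sort(he$beta[he$hub == h1]),
               sort(row[order(row)][1:16]), tolerance = 1e-12)
  # an edge between two hubs may appear twice (once per hub)
  b2 <- matrix(0, 20, 20); b2[1, 2] <- b2[2, 1] <- -10
  ef2 <- make_edge_effect(b2)
  he2 <- hub_edges(ef2, hubs = c(0L, 1L), fraction = 0.05)
  expect_equal(nrow(he2), 2)
  expect_equal(sort(he2$beta), c(-10, -10))
  # single hub over 20 regions at 5% keeps exactly 1 edge
  expect_equal(nrow(hub_edges(ef2, hubs = 0L, fraction = 0.05)), 1)
  # all-equal betas fall back to partner id order
  ef3 <- make_edge_effect(matrix(1, 20, 20))
  he3 <- hub_edges(ef3, hubs = 5L, fraction = 0.1)
  expect_equal(he3$partner, c(0L, 1L))
})
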