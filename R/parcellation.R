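# Parcellation handling: the ordered region table (labels, hemisphere, MNI
# centre-of-mass coordinates, surface area, 13-network membership) that
# anchors every spatial analysis. Row order in the source file defines the
# matrix index order used by all downstream stages.

#' Functional network labels
#'
#' The 13 network labels used to classify cortical regions: Default Mode
#' (DM), Frontoparietal (FP), Salience (SAL), Ventral Attention (VA),
#' Dorsal Attention (DA), Cinguloopercular (CO), Parietal (CP),
#' Retrosplenial (RST), Auditory (AUD), Visual (VIS), Somatomotor mouth
#' (SMM), Somatomotor hand (SMH), and unassigned (None).
#'
#' @format Character vector of length 13.
#' @export
network_labels <- c("DM", "FP", "SAL", "VA", "DA", "CO", "CP", "RST",
                    "AUD", "VIS", "SMM", "SMH", "None")

#' Association and processing network classes
#'
#' Default partition of the network labels into higher-order association
#' networks and primary sensory/motor processing networks, used by
#' [association_vs_processing_test()]. The membership of RST is
#' configurable there; `None` belongs to neither class.
#'
#' @export
network_classes <- list(
  association = c("DM", "FP", "SAL", "VA", "DA", "CO", "CP", "RST"),
  processing  = c("AUD", "VIS", "SMM", "SMH")
)

parcel_columns <- c("region_id", "label", "hemisphere", "x", "y", "z",
                    "surface_area_mm2", "network")

new_parcel_set <- function(df) {
  structure(df, class = c("parcel_set", "data.frame"))
}

validate_parcel_set <- function(df) {
  missing_cols <- setdiff(parcel_columns, names(df))
  if (length(missing_cols))
    stop_oscdev("parcellation table is missing column(s): %s",
                paste(missing_cols, collapse = ", "))
  n <- nrow(df)
  if (n < 2L) stop_oscdev("parcellation needs at least 2 regions, got %d", n)
  if (anyDuplicated(df$region_id)) {
    dup <- df$region_id[duplicated(df$region_id)][1]
    stop_oscdev("duplicate region_id %s in parcellation", dup)
  }
  if (!identical(as.integer(df$region_id), 0:(n - 1L)))
    stop_oscdev("region_id must be contiguous 0..%d in file order", n - 1L)
  bad_net <- which(!df$network %in% network_labels)
  if (length(bad_net))
    stop_oscdev("unknown network label '%s' at row %d (region_id %s)",
                df$network[bad_net[1]], bad_net[1], df$region_id[bad_net[1]])
  bad_hemi <- which(!df$hemisphere %in% c("L", "R"))
  if (length(bad_hemi))
    stop_oscdev("hemisphere must be 'L' or 'R' (row %d)", bad_hemi[1])
  if (any(!is.finite(df$surface_area_mm2)) || any(df$surface_area_mm2 <= 0))
    stop_oscdev("surface_area_mm2 must be positive for every region")
  coords <- as.matrix(df[, c("x", "y", "z")])
  if (any(!is.finite(coords)))
    stop_oscdev("non-finite coordinate in parcellation")
  invisible(df)
}

#' Construct a parcellation from a region table
#'
#' @param df Data frame with columns `region_id` (0-based, contiguous),
#'   `label`, `hemisphere` (`"L"`/`"R"`), `x`, `y`, `z` (MNI millimetres,
#'   +y anterior), `surface_area_mm2` (> 0), and `network` (one of
#'   [network_labels]).
#' @return A `parcel_set` (data frame subclass) preserving row order.
#' @export
parcel_set <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$region_id <- as.integer(df$region_id)
  validate_parcel_set(df)
  new_parcel_set(df)
}

#' Load a parcellation table from file
#'
#' Reads a tab-separated region table (header
#' `region_id label hemisphere x y z surface_area_mm2 network`) and
#' validates it. Row order in the file defines the region index order used
#' in every downstream matrix.
#'
#' @param path Path to the tab-separated region table.
#' @return A validated `parcel_set`.
#' @export
load_parcellation <- function(path) {
  if (!file.exists(path)) stop_oscdev("parcellation file not found: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  parcel_set(df)
}

#' Write a parcellation table to file
#'
#' @param p A `parcel_set`.
#' @param path Output path (tab-separated, UTF-8).
#' @return `path`, invisibly.
#' @export
write_parcellation <- function(p, path) {
  stopifnot(inherits(p, "parcel_set"))
  write.table(p, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Number of regions in a parcellation
#' @param p A `parcel_set`.
#' @return Integer region count.
#' @export
n_regions <- function(p) nrow(p)

#' Number of unordered region pairs
#'
#' `n * (n - 1) / 2` distinct region pairs, the number of edge-level
#' quantities (e.g. PLVs) per frequency: 55,278 for a 333-region
#' parcellation.
#'
#' @param p A `parcel_set` or an integer region count.
#' @return Integer pair count.
#' @export
n_region_pairs <- function(p) {
  n <- if (inherits(p, "parcel_set")) nrow(p) else as.integer(p)
  n * (n - 1L) / 2L
}

#' Pairwise region geometry
#'
#' Euclidean distances between region centres of mass, and each region's
#' mean distance to all other regions (used as a nuisance covariate in
#' gradient regressions to absorb distance-dependent coupling artifacts).
#'
#' @param p A `parcel_set`.
#' @return List with `distance` (symmetric n x n matrix, zero diagonal,
#'   millimetres) and `mean_distance` (length-n vector, self excluded).
#' @export
region_geometry <- function(p) {
  stopifnot(inherits(p, "parcel_set"))
  coords <- as.matrix(p[, c("x", "y", "z")])
  d <- as.matrix(dist(coords))
  dimnames(d) <- list(p$label, p$label)
  n <- nrow(d)
  list(distance = d, mean_distance = rowSums(d) / (n - 1))
}

#' @method print parcel_set
#' @export
print.parcel_set <- function(x, ...) {
  cat(sprintf("parcel_set: %d regions (%d L / %d R), %d networks\n",
              nrow(x), sum(x$hemisphere == "L"), sum(x$hemisphere == "R"),
              length(unique(x$network))))
  print(head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat(sprintf("... %d more regions\n", nrow(x) - 4L))
  invisible(x)
}
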