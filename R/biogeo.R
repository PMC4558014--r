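#' Weighted range centroid over landscape attributes
#'
#' Summarizes a distribution by the weighted mean latitude, elevation
#' and distance to coast over its cells, each cell weighted by its share
#' of the binary range (equal weights over range cells). A
#' suitability-weighted variant is available by passing a
#' `cs_suitability` as `weights`.
#'
#' @param distribution A `cs_range` (or binary matrix).
#' @param landscape The `cs_landscape` carrying the attribute grids.
#' @param weights Optional `cs_suitability` used as continuous weights
#'   instead of equal binary-range weights.
#' @return A `cs_centroid` list: `species_id`, `season`, `period`,
#'   `scenario`, `latitude` (deg N), `elevation` (m), `dist_coast` (km).
#' @export
weighted_centroid <- function(distribution, landscape, weights = NULL) {
  stopifnot(inherits(landscape, "cs_landscape"))
  cells <- if (inherits(distribution, "cs_range")) distribution$cells else distribution
  if (!identical(dim(cells), dim(landscape$elevation)))
    stop_climsens("distribution and landscape are on different grids")
  w <- if (is.null(weights)) {
    cells * 1.0
  } else {
    stopifnot(inherits(weights, "cs_suitability"))
    cells * weights$values
  }
  tot <- sum(w)
  if (tot <= 0) stop_climsens("empty distribution: centroid undefined")
  w <- w / tot
  structure(list(
    species_id = if (inherits(distribution, "cs_range")) distribution$species_id else NA_character_,
    season = if (inherits(distribution, "cs_range")) distribution$season else NA_character_,
    period = if (inherits(distribution, "cs_range")) distribution$period else NA_character_,
    scenario = if (inherits(distribution, "cs_range")) distribution$scenario else NA_character_,
    latitude = sum(w * latitude_grid(landscape)),
    elevation = sum(w * landscape$elevation),
    dist_coast = sum(w * landscape$dist_coast)),
    class = "cs_centroid")
}

#' Shift between two range centroids
#'
#' Latitude shifts are converted to km at 111.32 km per degree.
#' Positive values mean northward, upslope and inland movement.
#'
#' @param current,future `cs_centroid` summaries for one species-season.
#' @return List with `dlat_km`, `delev_m`, `dcoast_km`.
#' @export
centroid_shift <- function(current, future) {
  stopifnot(inherits(current, "cs_centroid"), inherits(future, "cs_centroid"))
  list(dlat_km = (future$latitude - current$latitude) * 111.32,
       delev_m = future$elevation - current$elevation,
       dcoast_km = future$dist_coast - current$dist_coast)
}

range_stack <- function(ranges) {
  cells <- lapply(ranges, function(r) if (inherits(r, "cs_range")) r$cells else r)
  d <- dim(cells[[1]])
  if (!all(vapply(cells, function(m) identical(dim(m), d), TRUE)))
    stop_climsens("range maps are on different grids")
  # species x cells binary matrix
  m <- do.call(rbind, lapply(cells, as.vector))
  list(m = m, dim = d)
}

#' Per-cell species gains, losses and richness change
#'
#' For aligned current and future range sets (same species order),
#' counts per cell the species gained (absent now, present in the
#' future) and lost (present now, absent in the future). The identity
#' `current richness - loss + gain = future richness` holds cell-wise.
#'
#' @param current_ranges,future_ranges Lists of `cs_range` (or binary
#'   matrices), same length and species order, one grid.
#' @return A `cs_community` list of matrices: `richness_current`,
#'   `richness_future`, `gain`, `loss`.
#' @export
richness_change <- function(current_ranges, future_ranges) {
  if (length(current_ranges) != length(future_ranges))
    stop_climsens("current and future range lists differ in length")
  cur <- range_stack(current_ranges)
  fut <- range_stack(future_ranges)
  if (!identical(cur$dim, fut$dim))
    stop_climsens("current and future ranges are on different grids")
  d <- cur$dim
  gain <- colSums(cur$m == 0 & fut$m == 1)
  loss <- colSums(cur$m == 1 & fut$m == 0)
  structure(list(
    richness_current = matrix(colSums(cur$m), d[1], d[2]),
    richness_future = matrix(colSums(fut$m), d[1], d[2]),
    gain = matrix(gain, d[1], d[2]),
    loss = matrix(loss, d[1], d[2])),
    class = "cs_community")
}

#' Binary Bray-Curtis dissimilarity between two species sets
#'
#' With `a` shared species, `b` unique to the current set and `c` unique
#' to the future set: `d = 1 - 2a / (2a + b + c)`, i.e. one minus the
#' Sorensen similarity. Two empty sets are defined as dissimilarity 0.
#'
#' @param current_set,future_set Vectors of species ids.
#' @return Dissimilarity in `[0, 1]`.
#' @export
bray_curtis_cell <- function(current_set, future_set) {
  current_set <- unique(current_set); future_set <- unique(future_set)
  a <- length(intersect(current_set, future_set))
  b <- length(setdiff(current_set, future_set))
  cc <- length(setdiff(future_set, current_set))
  denom <- 2 * a + b + cc
  if (denom == 0) return(0)
  1 - 2 * a / denom
}

#' Community turnover map (binary Bray-Curtis per cell)
#'
#' Computes the binary Bray-Curtis dissimilarity between the current and
#' future community of every grid cell, and its mean over cells holding
#' at least one species in either period (empty-vs-empty cells are 0 and
#' excluded from the mean).
#'
#' @inheritParams richness_change
#' @return List with `dissimilarity` (matrix; 0 on empty-empty cells)
#'   and `mean` (over occupied cells; `NaN` if no cell is occupied).
#' @export
dissimilarity_map <- function(current_ranges, future_ranges) {
  if (length(current_ranges) != length(future_ranges))
    stop_climsens("current and future range lists differ in length")
  cur <- range_stack(current_ranges)
  fut <- range_stack(future_ranges)
  if (!identical(cur$dim, fut$dim))
    stop_climsens("current and future ranges are on different grids")
  a <- colSums(cur$m == 1 & fut$m == 1)
  b <- colSums(cur$m == 1 & fut$m == 0)
  cc <- colSums(cur$m == 0 & fut$m == 1)
  denom <- 2 * a + b + cc
  d <- ifelse(denom == 0, 0, 1 - 2 * a / denom)
  occupied <- denom > 0
  list(dissimilarity = matrix(d, cur$dim[1], cur$dim[2]),
       mean = mean(d[occupied]))
}
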