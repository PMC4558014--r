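#' Generate a synthetic study landscape
#'
#' Builds a rectangular grid landscape carrying the three attribute
#' layers used for range-centroid summaries: elevation, distance to the
#' coast, and latitude. The coastline runs along the western (column 1)
#' edge, so distance to coast increases linearly inland; latitude
#' increases linearly from the southern row northward; elevation is a
#' smooth, spatially autocorrelated field.
#'
#' @param nx,ny Grid dimensions in cells (both >= 10).
#' @param cell_size Cell edge length in km (default 10, i.e. a
#'   10 x 10 km projection grid).
#' @param seed Integer seed; identical seeds give identical landscapes.
#' @param lat_min Latitude (degrees N) of the southernmost row of cells.
#' @param elev_mean,elev_sd Mean and marginal sd (m) of the elevation
#'   field; negative draws are truncated at sea level.
#' @param elev_range_cells Autocorrelation range of the elevation field,
#'   in cells.
#'
#' @return An object of class `cs_landscape`: a list with `nx`, `ny`,
#'   `cell_size`, `elevation` (ny x nx matrix, m), `dist_coast`
#'   (ny x nx matrix, km) and `latitude` (length-`ny` vector, degrees N,
#'   strictly increasing).
#' @export
make_landscape <- function(nx, ny, cell_size = 10, seed = 1,
                           lat_min = 30,
                           elev_mean = 500, elev_sd = 300,
                           elev_range_cells = 8) {
  if (!is.numeric(nx) || !is.numeric(ny) || nx < 10 || ny < 10)
    stop_climsens("nx and ny must be >= 10 (got nx=%s, ny=%s)", nx, ny)
  if (cell_size <= 0) stop_climsens("cell_size must be positive")
  nx <- as.integer(nx); ny <- as.integer(ny)

  elevation <- with_seed(seed, {
    pmax(elev_mean + gaussian_field(ny, nx, elev_range_cells, elev_sd), 0)
  })
  # straight coast along column 1: nearest coast cell is in the same row
  dist_coast <- matrix(rep((seq_len(nx) - 1) * cell_size, each = ny), ny, nx)
  latitude <- lat_min + (seq_len(ny) - 1) * cell_size / 111.32

  structure(list(nx = nx, ny = ny, cell_size = cell_size,
                 elevation = elevation, dist_coast = dist_coast,
                 latitude = latitude),
            class = "cs_landscape")
}

#' @export
print.cs_landscape <- function(x, ...) {
  cat(sprintf("<cs_landscape> %d x %d cells of %g km; lat %.2f-%.2f N; elev %.0f-%.0f m\n",
              x$nx, x$ny, x$cell_size, min(x$latitude), max(x$latitude),
              min(x$elevation), max(x$elevation)))
  invisible(x)
}

# latitude as a full grid (per-cell), used by centroid summaries
latitude_grid <- function(landscape) {
  matrix(rep(landscape$latitude, landscape$nx), landscape$ny, landscape$nx)
}
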