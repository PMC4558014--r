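#' Compute the standard bioclimatic variables (BIO1-BIO19)
#'
#' Derives the nineteen conventional bioclimatic summaries from monthly
#' minimum temperature, maximum temperature and precipitation grids.
#' Monthly mean temperature is `(tmin + tmax) / 2`. "Quarters" are the
#' twelve consecutive three-month windows with wrap-around (Dec-Jan-Feb
#' included); ties between quarters are broken by the earliest starting
#' month, matching the dominant SDM toolchain convention.
#'
#' Definitions (temperature in deg C, precipitation in mm):
#' BIO1 annual mean temperature; BIO2 mean diurnal range; BIO3
#' isothermality (BIO2/BIO7 x 100, 0 where BIO7 = 0); BIO4 temperature
#' seasonality (sd of monthly means x 100); BIO5/BIO6 max of monthly
#' tmax / min of monthly tmin; BIO7 annual range (BIO5 - BIO6); BIO8/BIO9
#' mean temperature of wettest/driest quarter; BIO10/BIO11 mean
#' temperature of warmest/coldest quarter; BIO12 annual precipitation;
#' BIO13/BIO14 precipitation of wettest/driest month; BIO15
#' precipitation seasonality (sd of monthly precipitation over
#' (mean + 1) x 100); BIO16/BIO17 precipitation of wettest/driest
#' quarter; BIO18/BIO19 precipitation of warmest/coldest quarter.
#'
#' @param monthly A `cs_monthly_climate`.
#' @return A `cs_bioclim` object: an `ny x nx x 19` array with layer
#'   names `bio01`..`bio19` and the provenance labels of the input.
#' @export
compute_bioclim <- function(monthly) {
  if (!inherits(monthly, "cs_monthly_climate"))
    stop_climsens("compute_bioclim expects a cs_monthly_climate")
  d <- dim(monthly$tmin)
  ny <- d[1]; nx <- d[2]; nc <- ny * nx
  # cells x 12 matrices
  tmin <- matrix(monthly$tmin, nc, 12)
  tmax <- matrix(monthly$tmax, nc, 12)
  prec <- matrix(monthly$prec, nc, 12)
  tavg <- (tmin + tmax) / 2

  row_sd <- function(m) {
    mu <- rowMeans(m)
    sqrt(rowSums((m - mu)^2) / (ncol(m) - 1))
  }

  bio <- matrix(NA_real_, nc, 19)
  bio[, 1] <- rowMeans(tavg)
  bio[, 2] <- rowMeans(tmax - tmin)
  bio[, 4] <- row_sd(tavg) * 100
  bio[, 5] <- apply(tmax, 1, max)
  bio[, 6] <- apply(tmin, 1, min)
  bio[, 7] <- bio[, 5] - bio[, 6]
  bio[, 3] <- ifelse(bio[, 7] > 0, bio[, 2] / bio[, 7] * 100, 0)
  bio[, 12] <- rowSums(prec)
  bio[, 13] <- apply(prec, 1, max)
  bio[, 14] <- apply(prec, 1, min)
  bio[, 15] <- row_sd(prec) / (rowMeans(prec) + 1) * 100

  # wrapped quarters: quarter q = months q, q+1, q+2 (mod 12)
  qtemp <- matrix(0, nc, 12)
  qprec <- matrix(0, nc, 12)
  for (q in 1:12) {
    mths <- ((q - 1):(q + 1)) %% 12 + 1
    qtemp[, q] <- rowMeans(tavg[, mths, drop = FALSE])
    qprec[, q] <- rowSums(prec[, mths, drop = FALSE])
  }
  idx <- cbind(seq_len(nc), 0L)
  idx[, 2] <- max.col(qprec, ties.method = "first")
  bio[, 8] <- qtemp[idx]
  bio[, 16] <- qprec[idx]
  idx[, 2] <- max.col(-qprec, ties.method = "first")
  bio[, 9] <- qtemp[idx]
  bio[, 17] <- qprec[idx]
  idx[, 2] <- max.col(qtemp, ties.method = "first")
  bio[, 10] <- qtemp[idx]
  bio[, 18] <- qprec[idx]
  idx[, 2] <- max.col(-qtemp, ties.method = "first")
  bio[, 11] <- qtemp[idx]
  bio[, 19] <- qprec[idx]

  out <- array(bio, c(ny, nx, 19),
               dimnames = list(NULL, NULL, sprintf("bio%02d", 1:19)))
  structure(out,
            period = monthly$period, scenario = monthly$scenario,
            gcm = monthly$gcm, class = c("cs_bioclim", "array"))
}

bioclim_layer <- function(bioclim, name) {
  nms <- dimnames(bioclim)[[3]]
  if (!name %in% nms)
    stop_climsens("bioclim layer '%s' not present", name)
  bioclim[, , match(name, nms)]
}

#' @export
print.cs_bioclim <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<cs_bioclim> %d x %d cells, %d layers, period=%s scenario=%s gcm=%s\n",
              d[1], d[2], d[3], attr(x, "period"), attr(x, "scenario"),
              attr(x, "gcm")))
  invisible(x)
}

#' Build future fine-scale climate by the anomaly (delta) method
#'
#' Subtracts a coarse reference climatology from a coarse future
#' climatology to isolate monthly anomalies, resamples the anomalies to
#' the fine grid by nearest cell, and adds them to the fine-scale
#' baseline, per month and variable. All variables are treated
#' additively; precipitation is floored at 0 afterwards. Provenance
#' labels are inherited from the future climatology.
#'
#' @param baseline_fine Fine-grid `cs_monthly_climate` (the base period).
#' @param future_coarse,reference_coarse Coarse-grid
#'   `cs_monthly_climate`s on a common grid covering the same extent.
#' @return A fine-grid `cs_monthly_climate` for the future period.
#' @export
delta_downscale <- function(baseline_fine, future_coarse, reference_coarse) {
  stopifnot(inherits(baseline_fine, "cs_monthly_climate"),
            inherits(future_coarse, "cs_monthly_climate"),
            inherits(reference_coarse, "cs_monthly_climate"))
  if (!identical(dim(future_coarse$tmin), dim(reference_coarse$tmin)))
    stop_climsens("future and reference climatologies must share a grid")
  df <- dim(baseline_fine$tmin)
  add_anomaly <- function(base, fut, ref, floor0) {
    an <- fut - ref
    an_fine <- resample_nearest_3d(an, df[1], df[2])
    out <- base + an_fine
    if (floor0) out <- pmax(out, 0)
    out
  }
  tmin <- add_anomaly(baseline_fine$tmin, future_coarse$tmin,
                      reference_coarse$tmin, FALSE)
  tmax <- add_anomaly(baseline_fine$tmax, future_coarse$tmax,
                      reference_coarse$tmax, FALSE)
  prec <- add_anomaly(baseline_fine$prec, future_coarse$prec,
                      reference_coarse$prec, TRUE)
  monthly_climate(tmin, tmax, prec,
                  period = future_coarse$period,
                  scenario = future_coarse$scenario,
                  gcm = future_coarse$gcm)
}

# nearest-cell resampling of an ny x nx x k array to nyf x nxf, assuming
# both grids span the same extent with uniform cells
resample_nearest_3d <- function(a, nyf, nxf) {
  d <- dim(a)
  if (d[1] == nyf && d[2] == nxf) return(a)
  ri <- pmin(pmax(ceiling((seq_len(nyf) - 0.5) * d[1] / nyf), 1L), d[1])
  ci <- pmin(pmax(ceiling((seq_len(nxf) - 0.5) * d[2] / nxf), 1L), d[2])
  a[ri, ci, , drop = FALSE]
}

#' Extract grid values at point locations (nearest cell)
#'
#' Looks up the value of the cell containing each point; no
#' interpolation. Coordinates are in km with the grid origin at (0, 0)
#' and cells of edge `cell_size`.
#'
#' @param grid An `ny x nx` matrix, a 3-d array (values returned per
#'   layer), or a `cs_bioclim`.
#' @param points A data.frame with columns `x`, `y` and optionally
#'   `site_id` (used in error messages).
#' @param cell_size Cell edge length in km.
#' @return A numeric vector (matrix input) or a points x layers matrix
#'   (array input).
#' @export
extract_at_points <- function(grid, points, cell_size) {
  stopifnot(is.data.frame(points), all(c("x", "y") %in% names(points)))
  is_arr <- length(dim(grid)) == 3L
  ny <- dim(grid)[1]; nx <- dim(grid)[2]
  pc <- point_to_cell(points$x, points$y, nx, ny, cell_size)
  if (any(!pc$inside)) {
    ids <- if ("site_id" %in% names(points)) points$site_id[!pc$inside]
           else which(!pc$inside)
    stop_climsens("point(s) outside grid bounds: %s",
                  paste(utils::head(ids, 5), collapse = ", "))
  }
  if (!is_arr) return(grid[cbind(pc$row, pc$col)])
  k <- dim(grid)[3]
  out <- vapply(seq_len(k), function(j) grid[, , j][cbind(pc$row, pc$col)],
                numeric(nrow(points)))
  out <- matrix(out, nrow = nrow(points), ncol = k)
  colnames(out) <- dimnames(grid)[[3]]
  out
}
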