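#' Monthly climate stacks
#'
#' A `cs_monthly_climate` holds twelve monthly grids each of minimum
#' temperature, maximum temperature (deg C) and precipitation (mm),
#' tagged with a period (`"base"`, `"2020"`, `"2050"`, `"2080"`), an
#' emissions scenario (`"none"`, `"A2"`, `"A1B"`, `"B2"`) and a GCM
#' label. Grids are `ny x nx x 12` arrays.
#'
#' @param tmin,tmax,prec `ny x nx x 12` arrays.
#' @param period,scenario,gcm Provenance labels.
#' @return A `cs_monthly_climate` object.
#' @export
monthly_climate <- function(tmin, tmax, prec,
                            period = "base", scenario = "none", gcm = "none") {
  stopifnot(is.array(tmin), is.array(tmax), is.array(prec))
  d <- dim(tmin)
  if (length(d) != 3L || d[3] != 12L)
    stop_climsens("monthly grids must be ny x nx x 12 arrays")
  if (!identical(dim(tmax), d) || !identical(dim(prec), d))
    stop_climsens("tmin, tmax and prec grids must share dimensions")
  if (any(tmax < tmin))
    stop_climsens("tmax must be >= tmin in every cell and month")
  if (any(prec < 0))
    stop_climsens("precipitation must be non-negative")
  structure(list(tmin = tmin, tmax = tmax, prec = prec,
                 period = period, scenario = scenario, gcm = gcm),
            class = "cs_monthly_climate")
}

#' @export
print.cs_monthly_climate <- function(x, ...) {
  d <- dim(x$tmin)
  cat(sprintf("<cs_monthly_climate> %d x %d cells, period=%s scenario=%s gcm=%s\n",
              d[1], d[2], x$period, x$scenario, x$gcm))
  invisible(x)
}

#' Generate a synthetic baseline monthly climate
#'
#' Temperature at each cell and month is a latitudinal gradient plus an
#' elevational lapse term plus a seasonal sinusoid (warmest in July)
#' plus optional cell/month noise; maximum temperature is minimum
#' temperature plus a fixed diurnal offset. Monthly precipitation is a
#' coast-to-inland gradient plus noise, floored at zero. With zero noise
#' the mean of the twelve monthly minimum temperatures at a cell equals
#' the configured annual mean there (the sinusoid integrates to zero).
#'
#' @param landscape A [make_landscape()] result.
#' @param lapse_rate Temperature lapse rate in deg C per metre of
#'   elevation (must be <= 0; default -0.0065, the standard environmental
#'   lapse rate).
#' @param seasonal_amplitude Half peak-to-trough amplitude of the
#'   seasonal temperature cycle, deg C.
#' @param seed Integer seed for the noise terms.
#' @param t_ref Annual-mean minimum temperature (deg C) at sea level on
#'   the southernmost row.
#' @param lat_gradient Temperature change per degree latitude (deg C;
#'   negative = cooler poleward).
#' @param diurnal_range Fixed tmax - tmin offset, deg C (> 0).
#' @param noise_sd Cell-by-month temperature noise sd, deg C.
#' @param prec_coast,prec_inland_slope Monthly precipitation (mm) at the
#'   coast and its linear decline per km inland.
#' @param prec_noise_sd Cell-by-month precipitation noise sd, mm.
#'
#' @return A `cs_monthly_climate` with period `"base"`.
#' @export
make_baseline_climate <- function(landscape,
                                  lapse_rate = -0.0065,
                                  seasonal_amplitude = 10,
                                  seed = 1,
                                  t_ref = 16,
                                  lat_gradient = -0.7,
                                  diurnal_range = 8,
                                  noise_sd = 0.3,
                                  prec_coast = 110,
                                  prec_inland_slope = 0.06,
                                  prec_noise_sd = 6) {
  stopifnot(inherits(landscape, "cs_landscape"))
  if (lapse_rate > 0)
    stop_climsens("lapse_rate must be <= 0 degC/m (got %g)", lapse_rate)
  ny <- landscape$ny; nx <- landscape$nx
  lat <- latitude_grid(landscape)
  annual_tmin <- t_ref + lat_gradient * (lat - min(landscape$latitude)) +
    lapse_rate * landscape$elevation

  tmin <- array(0, c(ny, nx, 12))
  prec <- array(0, c(ny, nx, 12))
  with_seed(seed, {
    for (m in 1:12) {
      season <- seasonal_amplitude * cos(2 * pi * (m - 7) / 12)
      tn <- if (noise_sd > 0) matrix(stats::rnorm(ny * nx, 0, noise_sd), ny, nx) else 0
      pn <- if (prec_noise_sd > 0) matrix(stats::rnorm(ny * nx, 0, prec_noise_sd), ny, nx) else 0
      tmin[, , m] <- annual_tmin + season + tn
      prec[, , m] <- pmax(prec_coast - prec_inland_slope * landscape$dist_coast + pn, 0)
    }
  })
  monthly_climate(tmin, tmin + diurnal_range, prec, period = "base")
}

# Default SRES warming (deg C added to tmin/tmax) and precipitation
# multipliers by scenario x period: high (A2), mid (A1B), low (B2)
# trajectories, monotone within scenario, with the characteristic
# late-century acceleration (2080 warming roughly twice the 2050 value).
default_temp_deltas <- function() {
  list(A2  = c(`2020` = 0.8, `2050` = 1.8, `2080` = 3.6),
       A1B = c(`2020` = 0.7, `2050` = 1.6, `2080` = 3.0),
       B2  = c(`2020` = 0.5, `2050` = 1.1, `2080` = 2.4))
}

default_prec_multipliers <- function() {
  list(A2  = c(`2020` = 0.98, `2050` = 0.94, `2080` = 0.90),
       A1B = c(`2020` = 0.98, `2050` = 0.95, `2080` = 0.92),
       B2  = c(`2020` = 0.99, `2050` = 0.97, `2080` = 0.94))
}

#' Generate a synthetic future monthly climate
#'
#' Applies a scenario- and period-specific uniform warming to tmin and
#' tmax, adds a spatially smooth mean-zero per-GCM jitter field (the
#' between-GCM disagreement), and scales precipitation by a scenario
#' multiplier, flooring at zero. Warming is monotone in period within a
#' scenario. Averaging the jittered warming over many GCM draws
#' recovers the configured uniform delta.
#'
#' @param baseline A `cs_monthly_climate` for the base period.
#' @param scenario One of `"A2"`, `"A1B"`, `"B2"`.
#' @param period One of `"2020"`, `"2050"`, `"2080"`.
#' @param gcm_jitter_sd Marginal sd (deg C) of the smooth per-GCM
#'   temperature jitter; 0 disables jitter.
#' @param seed Integer seed for the jitter field.
#' @param gcm GCM label recorded on the output.
#' @param temp_deltas,prec_multipliers Optional overrides of the
#'   built-in scenario trajectories (named lists as returned by the
#'   internal defaults).
#'
#' @return A `cs_monthly_climate` tagged with the scenario, period and
#'   GCM.
#' @export
make_future_climate <- function(baseline, scenario, period,
                                gcm_jitter_sd = 0.3, seed = 1,
                                gcm = "gcm1",
                                temp_deltas = default_temp_deltas(),
                                prec_multipliers = default_prec_multipliers()) {
  stopifnot(inherits(baseline, "cs_monthly_climate"))
  scenario <- as.character(scenario); period <- as.character(period)
  if (!scenario %in% names(temp_deltas))
    stop_climsens("unknown scenario '%s' (expected one of %s)", scenario,
                  paste(names(temp_deltas), collapse = ", "))
  if (!period %in% names(temp_deltas[[scenario]]))
    stop_climsens("unknown period '%s' (expected one of %s)", period,
                  paste(names(temp_deltas[[scenario]]), collapse = ", "))
  delta <- temp_deltas[[scenario]][[period]]
  pmult <- prec_multipliers[[scenario]][[period]]
  d <- dim(baseline$tmin)

  jitter <- if (gcm_jitter_sd > 0) {
    with_seed(seed, gaussian_field(d[1], d[2], range_cells = 10, sd = gcm_jitter_sd))
  } else matrix(0, d[1], d[2])

  tmin <- baseline$tmin; tmax <- baseline$tmax; prec <- baseline$prec
  for (m in 1:12) {
    tmin[, , m] <- tmin[, , m] + delta + jitter
    tmax[, , m] <- tmax[, , m] + delta + jitter
    prec[, , m] <- pmax(prec[, , m] * pmult, 0)
  }
  monthly_climate(tmin, tmax, prec, period = period, scenario = scenario,
                  gcm = gcm)
}
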