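#' Virtual species with Gaussian climate niches
#'
#' A `cs_niche` describes one virtual species-season: for each selected
#' bioclimatic variable an optimum `mu` and breadth `sigma` (independent
#' Gaussian responses), a peak occupancy probability `p_max`, flags for
#' introduced or range-marginal species, and the response archetype the
#' species was generated under (`"shrinker"`, `"shifter"` or
#' `"stable"`).
#'
#' @name cs_niche
NULL

new_niche <- function(species_id, season, mu, sigma, p_max,
                      archetype, introduced = FALSE, marginal = FALSE) {
  stopifnot(length(mu) == length(sigma), all(sigma > 0),
            p_max > 0, p_max <= 1)
  structure(list(species_id = species_id, season = season,
                 mu = mu, sigma = sigma, p_max = p_max,
                 archetype = archetype,
                 introduced = introduced, marginal = marginal),
            class = "cs_niche")
}

#' @export
print.cs_niche <- function(x, ...) {
  cat(sprintf("<cs_niche> %s (%s, %s) p_max=%.2f%s\n", x$species_id,
              x$season, x$archetype, x$p_max,
              if (x$introduced) " [introduced]" else if (x$marginal) " [marginal]" else ""))
  for (v in names(x$mu))
    cat(sprintf("  %s: mu=%.2f sigma=%.2f\n", v, x$mu[[v]], x$sigma[[v]]))
  invisible(x)
}

#' Generate a cohort of virtual species
#'
#' Draws niches for three response archetypes, placed relative to the
#' baseline distribution of the primary niche variable (annual mean
#' temperature by default) so that each archetype's fate under warming
#' is known by construction:
#'
#' * **shrinkers** occupy the cold margin (optimum near the 5th-10th
#'   percentile of the primary variable's cell distribution) with narrow
#'   breadth, so the climate states they occupy largely disappear under
#'   even low-scenario mid-century warming (loss > 50% by 2050) while
#'   few colder cells exist to colonize;
#' * **shifters** sit mid-gradient with intermediate breadth: their
#'   suitable band translates poleward, losing > 50% of the current
#'   range by 2080 under all scenarios while colder cells open up;
#' * **stable** species have broad tolerances and lose little.
#'
#' The first `n_introduced` species are flagged introduced and the next
#' `n_marginal` flagged marginal (both classified "other" downstream);
#' flags are orthogonal to the niche archetype. Seasons alternate
#' between breeding and non-breeding across the cohort.
#'
#' @param n_species Number of species (>= 1).
#' @param archetype_mix Named numeric proportions over
#'   `c("shrinker", "shifter", "stable")`; must sum to 1.
#' @param bioclim Baseline `cs_bioclim` used to place optima.
#' @param seed Integer seed.
#' @param niche_vars Bioclim layer names the niches respond to; the
#'   first carries the archetype geometry, any further variables get
#'   broad responses centred on the landscape mean.
#' @param n_introduced,n_marginal Counts of flagged species.
#' @param p_max_range Range of peak occupancy probabilities.
#' @param sigma_shrinker,sigma_shifter,sigma_stable Breadth ranges (units
#'   of the primary niche variable) per archetype.
#' @param seasons Season labels cycled across species.
#'
#' @return A list of `cs_niche` objects.
#' @export
make_species <- function(n_species,
                         archetype_mix = c(shrinker = 1/3, shifter = 1/3,
                                           stable = 1/3),
                         bioclim,
                         seed = 1,
                         niche_vars = "bio01",
                         n_introduced = 0, n_marginal = 0,
                         p_max_range = c(0.8, 0.95),
                         sigma_shrinker = c(0.5, 0.65),
                         sigma_shifter = c(1.55, 1.65),
                         sigma_stable = c(5, 7),
                         seasons = c("breeding", "nonbreeding")) {
  if (n_species < 1) stop_climsens("n_species must be >= 1")
  if (abs(sum(archetype_mix) - 1) > 1e-8)
    stop_climsens("archetype_mix proportions must sum to 1")
  stopifnot(inherits(bioclim, "cs_bioclim"))
  if (n_introduced + n_marginal > n_species)
    stop_climsens("more flagged species than species")

  primary <- niche_vars[1]
  x <- bioclim_layer(bioclim, primary)
  b_min <- min(x); b_max <- max(x); span <- b_max - b_min

  counts <- round(archetype_mix * n_species)
  while (sum(counts) > n_species) counts[which.max(counts)] <- counts[which.max(counts)] - 1
  while (sum(counts) < n_species) counts[which.min(counts)] <- counts[which.min(counts)] + 1
  archetypes <- rep(names(counts), counts)

  with_seed(seed, {
    archetypes <- sample(archetypes)
    lapply(seq_len(n_species), function(i) {
      a <- archetypes[i]
      hw <- function(s) s * sqrt(2 * log(2))  # half-width at half peak
      if (a == "shrinker") {
        s1 <- stats::runif(1, sigma_shrinker[1], sigma_shrinker[2])
        m1 <- stats::quantile(x, stats::runif(1, 0.05, 0.10), names = FALSE)
      } else if (a == "shifter") {
        s1 <- stats::runif(1, sigma_shifter[1], sigma_shifter[2])
        m1 <- b_min + stats::runif(1, 0.55, 0.7) * span
      } else {
        s1 <- stats::runif(1, sigma_stable[1], sigma_stable[2])
        m1 <- b_min + stats::runif(1, 0.4, 0.6) * span
      }
      mu <- stats::setNames(m1, primary)
      sigma <- stats::setNames(s1, primary)
      for (v in niche_vars[-1]) {
        xv <- bioclim_layer(bioclim, v)
        mu[v] <- mean(xv)
        sigma[v] <- max(2 * stats::sd(xv), 1e-6)
      }
      new_niche(species_id = sprintf("sp%03d", i),
                season = seasons[(i - 1) %% length(seasons) + 1],
                mu = mu, sigma = sigma,
                p_max = stats::runif(1, p_max_range[1], p_max_range[2]),
                archetype = a,
                introduced = i <= n_introduced,
                marginal = i > n_introduced & i <= n_introduced + n_marginal)
    })
  })
}

#' True climatic suitability of a virtual species
#'
#' Evaluates the generating niche on a bioclim stack:
#' `p_max * prod_v exp(-(x_v - mu_v)^2 / (2 sigma_v^2))`, giving values
#' in `[0, p_max]`.
#'
#' @param niche A `cs_niche`.
#' @param bioclim A `cs_bioclim` containing every variable the niche
#'   references.
#' @return A `cs_suitability` surface.
#' @export
true_suitability <- function(niche, bioclim) {
  stopifnot(inherits(niche, "cs_niche"), inherits(bioclim, "cs_bioclim"))
  missing <- setdiff(names(niche$mu), dimnames(bioclim)[[3]])
  if (length(missing))
    stop_climsens("bioclim grid lacks niche variable(s): %s",
                  paste(missing, collapse = ", "))
  d <- dim(bioclim)
  s <- matrix(niche$p_max, d[1], d[2])
  for (v in names(niche$mu)) {
    x <- bioclim_layer(bioclim, v)
    s <- s * exp(-(x - niche$mu[[v]])^2 / (2 * niche$sigma[[v]]^2))
  }
  suitability_surface(s, species_id = niche$species_id,
                      season = niche$season,
                      period = attr(bioclim, "period"),
                      scenario = attr(bioclim, "scenario"),
                      gcm = attr(bioclim, "gcm"))
}

#' Continuous suitability surfaces
#'
#' @param values `ny x nx` matrix of probabilities in `[0, 1]`.
#' @param species_id,season,period,scenario,gcm Labels.
#' @return A `cs_suitability` object.
#' @export
suitability_surface <- function(values, species_id = NA_character_,
                                season = NA_character_, period = "base",
                                scenario = "none", gcm = "none") {
  stopifnot(is.matrix(values))
  if (any(values < -1e-9 | values > 1 + 1e-9))
    stop_climsens("suitability values must lie in [0, 1]")
  structure(list(values = pmin(pmax(values, 0), 1), species_id = species_id,
                 season = season, period = period, scenario = scenario,
                 gcm = gcm),
            class = "cs_suitability")
}

#' @export
print.cs_suitability <- function(x, ...) {
  cat(sprintf("<cs_suitability> %s (%s) period=%s scenario=%s gcm=%s; mean=%.3f\n",
              x$species_id, x$season, x$period, x$scenario, x$gcm,
              mean(x$values)))
  invisible(x)
}

#' Generate a survey design
#'
#' Places survey sites uniformly at random over the landscape and draws
#' per site-year visits. Non-breeding visits carry effort hours
#' (log-normal, the party-hours analog); breeding visits carry an
#' ordinal survey date (uniform over an early-summer window).
#'
#' @param landscape A `cs_landscape`.
#' @param n_sites Number of sites.
#' @param years Integer vector of survey years.
#' @param visit_prob Probability a site is surveyed in a given year.
#' @param effort_meanlog,effort_sdlog Log-normal effort parameters
#'   (hours).
#' @param date_range Inclusive day-of-year window for breeding surveys.
#' @param seed Integer seed.
#' @return A `cs_survey_design`: list with `sites` (site_id, x, y) and
#'   `visits` (site_id, year, effort_hours, ordinal_date).
#' @export
make_survey_design <- function(landscape, n_sites, years, visit_prob = 1,
                               effort_meanlog = 2.3, effort_sdlog = 0.5,
                               date_range = c(130, 190), seed = 1) {
  stopifnot(inherits(landscape, "cs_landscape"), n_sites >= 1,
            length(years) >= 1, visit_prob > 0, visit_prob <= 1)
  with_seed(seed, {
    sites <- data.frame(
      site_id = sprintf("site%04d", seq_len(n_sites)),
      x = stats::runif(n_sites, 0, landscape$nx * landscape$cell_size),
      y = stats::runif(n_sites, 0, landscape$ny * landscape$cell_size),
      stringsAsFactors = FALSE)
    visits <- expand.grid(site_id = sites$site_id, year = years,
                          stringsAsFactors = FALSE)
    visits <- visits[stats::runif(nrow(visits)) <= visit_prob, , drop = FALSE]
    visits$effort_hours <- stats::rlnorm(nrow(visits), effort_meanlog,
                                         effort_sdlog)
    visits$ordinal_date <- round(stats::runif(nrow(visits), date_range[1],
                                              date_range[2]))
    rownames(visits) <- NULL
    structure(list(sites = sites, visits = visits,
                   cell_size = landscape$cell_size,
                   nx = landscape$nx, ny = landscape$ny),
              class = "cs_survey_design")
  })
}

# Gaussian survey-date detection window for breeding-season records.
date_detection <- function(ordinal_date, peak = 160, sd = 30) {
  exp(-(ordinal_date - peak)^2 / (2 * sd^2))
}

#' Sample presence/absence occurrence records
#'
#' Draws one Bernoulli presence per site-year visit. Occupancy and
#' detection are conflated into a single probability: for non-breeding
#' (effort-based) surveys
#' `p = suitability(site) * (1 - exp(-detect_beta * effort_hours))`,
#' the saturating-exponential effort response; for breeding surveys the
#' effort factor is replaced by a Gaussian window in the ordinal survey
#' date (peak day 160, sd 30). Records carry the covariate appropriate
#' to their season (effort hours for non-breeding, ordinal date for
#' breeding; the other column is `NA`).
#'
#' @param suitability A `cs_suitability` (its `season` label selects the
#'   detection formula).
#' @param survey_design A `cs_survey_design` on the same landscape.
#' @param detect_beta Effort saturation rate per hour (>= 0).
#' @param seed Integer seed.
#' @return A data.frame with columns `site_id, x, y, year, season,
#'   species_id, presence, effort_hours, ordinal_date`.
#' @export
sample_occurrences <- function(suitability, survey_design,
                               detect_beta = 0.25, seed = 1) {
  stopifnot(inherits(suitability, "cs_suitability"),
            inherits(survey_design, "cs_survey_design"))
  if (detect_beta < 0) stop_climsens("detect_beta must be >= 0")
  sites <- survey_design$sites
  pc <- point_to_cell(sites$x, sites$y, survey_design$nx, survey_design$ny,
                      survey_design$cell_size)
  if (any(!pc$inside))
    stop_climsens("survey sites outside the landscape: %s",
                  paste(utils::head(sites$site_id[!pc$inside], 5),
                        collapse = ", "))
  site_suit <- stats::setNames(suitability$values[cbind(pc$row, pc$col)],
                               sites$site_id)
  v <- survey_design$visits
  season <- suitability$season
  detect <- if (identical(season, "breeding")) {
    date_detection(v$ordinal_date)
  } else {
    1 - exp(-detect_beta * v$effort_hours)
  }
  p <- site_suit[v$site_id] * detect
  presence <- with_seed(seed, stats::rbinom(nrow(v), 1, p))
  out <- data.frame(
    site_id = v$site_id,
    x = sites$x[match(v$site_id, sites$site_id)],
    y = sites$y[match(v$site_id, sites$site_id)],
    year = v$year,
    season = season,
    species_id = suitability$species_id,
    presence = presence,
    effort_hours = if (identical(season, "breeding")) NA_real_ else v$effort_hours,
    ordinal_date = if (identical(season, "breeding")) v$ordinal_date else NA_real_,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Exact ground truth for a virtual-species cohort
#'
#' Evaluates each species' generating niche on the baseline and on each
#' (jitter-free) future bioclim stack, thresholds true suitability at
#' half its peak to obtain true range maps, computes true loss and
#' expansion per scenario x period, and assigns the true climate
#' sensitivity category with the same classifier used downstream.
#'
#' @param species List of `cs_niche` (from [make_species()]).
#' @param baseline_bioclim Baseline `cs_bioclim`.
#' @param future_bioclims List of future `cs_bioclim` stacks (one per
#'   scenario x period, typically computed from jitter-free climates).
#' @return A `cs_truth_table`: list with `metrics` (long data.frame of
#'   species, season, scenario, period, stability, loss, expansion),
#'   `categories` (species-level data.frame with flags, archetype and
#'   true category) and `ranges` (per species: current and per
#'   scenario-period true range maps).
#' @export
truth_table <- function(species, baseline_bioclim, future_bioclims) {
  stopifnot(is.list(species), inherits(baseline_bioclim, "cs_bioclim"))
  metrics <- list(); ranges <- list(); cats <- list()
  for (niche in species) {
    cur_s <- true_suitability(niche, baseline_bioclim)
    thr <- niche$p_max / 2
    cur <- binarize(cur_s, thr)
    if (range_size(cur)$cells == 0)
      stop_climsens("species %s has an empty true baseline range",
                    niche$species_id)
    sp_ranges <- list(current = cur)
    rows <- list()
    for (fb in future_bioclims) {
      fut_s <- true_suitability(niche, fb)
      fut <- binarize(fut_s, thr)
      key <- paste(attr(fb, "scenario"), attr(fb, "period"), sep = "_")
      sp_ranges[[key]] <- fut
      rows[[key]] <- data.frame(
        species_id = niche$species_id, season = niche$season,
        scenario = attr(fb, "scenario"), period = attr(fb, "period"),
        stability = stability(cur, fut), expansion = expansion(cur, fut),
        stringsAsFactors = FALSE)
    }
    m <- do.call(rbind, rows)
    m$loss <- 1 - m$stability
    rownames(m) <- NULL
    metrics[[niche$species_id]] <- m
    ranges[[niche$species_id]] <- sp_ranges
    rec <- sensitivity_record(niche$species_id, niche$season, m,
                              introduced = niche$introduced,
                              marginal = niche$marginal)
    cats[[niche$species_id]] <- data.frame(
      species_id = niche$species_id, season = niche$season,
      archetype = niche$archetype, introduced = niche$introduced,
      marginal = niche$marginal, category = classify(rec),
      stringsAsFactors = FALSE)
  }
  structure(list(metrics = do.call(rbind, c(metrics, make.row.names = FALSE)),
                 categories = do.call(rbind, c(cats, make.row.names = FALSE)),
                 ranges = ranges),
            class = "cs_truth_table")
}
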