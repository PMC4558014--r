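#' Current-range stability under a future projection
#'
#' The fraction of the current range still inside the future range:
#' `|current intersect future| / |current|`.
#'
#' @param current,future `cs_range` maps (or binary matrices) on one
#'   grid.
#' @return Stability in `[0, 1]`; loss is `1 - stability`.
#' @export
stability <- function(current, future) {
  cur <- if (inherits(current, "cs_range")) current$cells else current
  fut <- if (inherits(future, "cs_range")) future$cells else future
  if (!identical(dim(cur), dim(fut)))
    stop_climsens("current and future ranges are on different grids")
  n_cur <- sum(cur == 1)
  if (n_cur == 0)
    stop_climsens("empty current range: stability undefined")
  sum(cur == 1 & fut == 1) / n_cur
}

#' Potential range expansion under a future projection
#'
#' Newly suitable cells outside the current range as a proportion of
#' current range size: `|future \ current| / |current|`. Values above 1
#' are returned as-is (truncation at 1 is a plotting convention only).
#'
#' @inheritParams stability
#' @return Expansion >= 0.
#' @export
expansion <- function(current, future) {
  cur <- if (inherits(current, "cs_range")) current$cells else current
  fut <- if (inherits(future, "cs_range")) future$cells else future
  if (!identical(dim(cur), dim(fut)))
    stop_climsens("current and future ranges are on different grids")
  n_cur <- sum(cur == 1)
  if (n_cur == 0)
    stop_climsens("empty current range: expansion undefined")
  sum(cur == 0 & fut == 1) / n_cur
}

#' Per-species climate sensitivity record
#'
#' Holds loss and expansion trajectories for one species-season across
#' scenarios and periods, plus the introduced/marginal flags.
#'
#' @param species_id,season Identifiers.
#' @param metrics data.frame with columns `scenario`, `period` and
#'   either `loss` or `stability` (loss = 1 - stability), plus
#'   `expansion`.
#' @param introduced,marginal Logical flags.
#' @return A `cs_sensitivity_record`.
#' @export
sensitivity_record <- function(species_id, season, metrics,
                               introduced = FALSE, marginal = FALSE) {
  stopifnot(is.data.frame(metrics),
            all(c("scenario", "period") %in% names(metrics)))
  if (!"loss" %in% names(metrics)) {
    if (!"stability" %in% names(metrics))
      stop_climsens("metrics need a loss or stability column")
    metrics$loss <- 1 - metrics$stability
  }
  if (!"expansion" %in% names(metrics))
    stop_climsens("metrics need an expansion column")
  if (any(metrics$loss < -1e-9 | metrics$loss > 1 + 1e-9))
    stop_climsens("loss values must lie in [0, 1]")
  if (any(metrics$expansion < -1e-9))
    stop_climsens("expansion values must be >= 0")
  metrics$period <- as.character(metrics$period)
  metrics$scenario <- as.character(metrics$scenario)
  structure(list(species_id = species_id, season = season,
                 metrics = metrics,
                 introduced = isTRUE(introduced), marginal = isTRUE(marginal)),
            class = "cs_sensitivity_record")
}

rec_value <- function(record, scenario, period, what) {
  m <- record$metrics
  i <- which(m$scenario == scenario & m$period == period)
  if (!length(i))
    stop_climsens("record for %s lacks scenario %s period %s",
                  record$species_id, scenario, period)
  m[[what]][i[1]]
}

#' Assign a climate sensitivity category
#'
#' Categories follow the decision cascade:
#' * **other** — species flagged introduced or marginal;
#' * **endangered** — for *all* scenarios considered, projected loss of
#'   more than 50% of current range by 2050 with potential gain smaller
#'   than the loss (`L_2050 > 0.5` and `E_2050 < L_2050`);
#' * **threatened** — otherwise, for all scenarios, loss of more than
#'   50% of current range by 2080 (`L_2080 > 0.5`), net gain possible;
#' * **stable** — otherwise (< 50% loss in some scenario/year).
#'
#' Loss comparisons are strict (`> 0.5`); a species at exactly 50% loss
#' is stable.
#'
#' @param record A `cs_sensitivity_record` with metrics for every
#'   requested scenario at periods 2050 and 2080.
#' @param scenarios Scenarios over which the "all scenarios" conditions
#'   are evaluated (a single scenario gives the per-scenario
#'   classification used for scenario-wise summary tables).
#' @return One of `"endangered"`, `"threatened"`, `"stable"`, `"other"`.
#' @export
classify <- function(record, scenarios = c("A2", "A1B", "B2")) {
  stopifnot(inherits(record, "cs_sensitivity_record"))
  if (record$introduced || record$marginal) return("other")
  l2050 <- vapply(scenarios, rec_value, 0, record = record, period = "2050",
                  what = "loss")
  e2050 <- vapply(scenarios, rec_value, 0, record = record, period = "2050",
                  what = "expansion")
  l2080 <- vapply(scenarios, rec_value, 0, record = record, period = "2080",
                  what = "loss")
  if (all(l2050 > 0.5 & e2050 < l2050)) return("endangered")
  if (all(l2080 > 0.5)) return("threatened")
  "stable"
}

category_severity <- c(endangered = 3, threatened = 2, stable = 1, other = 0)

#' Combine seasonal categories into an overall species category
#'
#' The overall category is the most severe across seasons (endangered >
#' threatened > stable); `"other"` results only from the
#' introduced/marginal flags (in which case both seasons carry it).
#' The one-season/both-seasons distinction is retained.
#'
#' @param breeding,nonbreeding Category strings (or `NA` if the species
#'   was not assessed in that season).
#' @return List with `overall` and `n_seasons_at_overall` (1 or 2).
#' @export
combine_seasons <- function(breeding = NA, nonbreeding = NA) {
  cats <- c(breeding = breeding, nonbreeding = nonbreeding)
  cats <- cats[!is.na(cats)]
  if (!length(cats)) stop_climsens("at least one season must be present")
  bad <- setdiff(cats, names(category_severity))
  if (length(bad)) stop_climsens("unknown category '%s'", bad[1])
  if (any(cats == "other")) {
    return(list(overall = "other",
                n_seasons_at_overall = sum(cats == "other")))
  }
  sev <- category_severity[cats]
  overall <- names(sev)[which.max(sev)]
  overall_cat <- cats[[which.max(sev)]]
  list(overall = overall_cat,
       n_seasons_at_overall = sum(cats == overall_cat))
}

#' Tabulate climate sensitivity categories
#'
#' Counts species per season and scenario set in each category, in the
#' layout of a season x scenario summary table: one row per season and
#' scenario set (each single scenario plus "all"), with columns
#' endangered (loss by 2050), threatened (loss by 2080), stable (< 50%
#' loss) and other (introduced/marginal).
#'
#' @param records List of `cs_sensitivity_record`.
#' @param scenarios Scenario labels present in the records.
#' @return data.frame with columns `season`, `scenario_set`, `n`,
#'   `endangered`, `threatened`, `stable`, `other`.
#' @export
tabulate_categories <- function(records, scenarios = c("A2", "A1B", "B2")) {
  stopifnot(length(records) >= 1)
  seasons <- unique(vapply(records, `[[`, "", "season"))
  sets <- c(as.list(scenarios), list(scenarios))
  set_names <- c(scenarios, "all")
  rows <- list()
  for (season in seasons) {
    recs <- Filter(function(r) identical(r$season, season), records)
    for (k in seq_along(sets)) {
      cats <- vapply(recs, classify, "", scenarios = sets[[k]])
      rows[[length(rows) + 1L]] <- data.frame(
        season = season, scenario_set = set_names[k], n = length(recs),
        endangered = sum(cats == "endangered"),
        threatened = sum(cats == "threatened"),
        stable = sum(cats == "stable"),
        other = sum(cats == "other"),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
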