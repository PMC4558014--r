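#' Read per-species range-change summary tables (S1-style CSV)
#'
#' Parses a CSV export of a per-species supplementary summary into the
#' pipeline's canonical fields: for each scenario (A2, A1B, B2) and
#' period (2050, 2080), the proportional loss of current range
#' `loss_<scenario>_<period>` and the relative change in range size
#' `change_<scenario>_<period>` (from which potential expansion is
#' recovered as `expansion = change + loss`), plus `species_id`,
#' `season` and optional `introduced`/`marginal` flags and a published
#' `category`. Values given as percentages ("62%" strings, or numeric
#' columns exceeding 1.5 in absolute value) are normalized to
#' proportions.
#'
#' @param file CSV path with a header row.
#' @param schema_map Optional named character vector mapping canonical
#'   names (see above) to the file's column names; unmapped canonical
#'   names are looked up directly.
#' @param scenarios,periods Scenario and period labels expected.
#' @return data.frame of typed rows, one per species-season.
#' @export
read_species_summaries <- function(file, schema_map = NULL,
                                   scenarios = c("A2", "A1B", "B2"),
                                   periods = c("2050", "2080")) {
  raw <- utils::read.csv(file, stringsAsFactors = FALSE, check.names = FALSE,
                         comment.char = "#")
  pick <- function(canonical, required = TRUE) {
    nm <- if (!is.null(schema_map) && canonical %in% names(schema_map))
      schema_map[[canonical]] else canonical
    if (!nm %in% names(raw)) {
      if (required)
        stop_climsens("required column '%s' (for %s) not in file; found: %s",
                      nm, canonical, paste(names(raw), collapse = ", "))
      return(NULL)
    }
    raw[[nm]]
  }
  out <- data.frame(species_id = as.character(pick("species_id")),
                    season = as.character(pick("season")),
                    stringsAsFactors = FALSE)
  for (fl in c("introduced", "marginal")) {
    v <- pick(fl, required = FALSE)
    out[[fl]] <- if (is.null(v)) FALSE else parse_flag(v)
  }
  cat_col <- pick("category", required = FALSE)
  if (!is.null(cat_col)) out$category <- tolower(as.character(cat_col))
  for (sc in scenarios) for (pd in periods) {
    lc <- sprintf("loss_%s_%s", sc, pd)
    ch <- sprintf("change_%s_%s", sc, pd)
    out[[lc]] <- normalize_proportion(pick(lc), bounded = TRUE)
    out[[ch]] <- normalize_proportion(pick(ch), bounded = FALSE)
  }
  out
}

parse_flag <- function(v) {
  if (is.logical(v)) return(v)
  tolower(as.character(v)) %in% c("1", "true", "t", "yes", "y")
}

# "62%" or 62 (percent scale) -> 0.62; already-proportions pass through.
# bounded: value is a proportion in [0,1] (loss); unbounded values
# (relative change) are only rescaled when given as explicit percents or
# when the column clearly uses the percent scale.
normalize_proportion <- function(v, bounded = TRUE) {
  if (is.character(v)) {
    pct <- grepl("%", v, fixed = TRUE)
    num <- suppressWarnings(as.numeric(gsub("%", "", v, fixed = TRUE)))
    if (any(is.na(num) & nzchar(trimws(v))))
      stop_climsens("non-numeric value '%s' in numeric column",
                    v[is.na(num) & nzchar(trimws(v))][1])
    num[pct] <- num[pct] / 100
    v <- num
    if (all(pct | is.na(v))) return(v)
  }
  v <- as.numeric(v)
  if (bounded && any(abs(v) > 1.5, na.rm = TRUE)) v <- v / 100
  if (!bounded && any(abs(v) > 5, na.rm = TRUE)) v <- v / 100
  v
}

#' Convert S1-style summary rows to sensitivity records
#'
#' @param rows Output of [read_species_summaries()] (or the pipeline's
#'   own species summary table).
#' @param scenarios Scenario labels.
#' @param periods Period labels.
#' @return List of `cs_sensitivity_record`.
#' @export
summaries_to_records <- function(rows, scenarios = c("A2", "A1B", "B2"),
                                 periods = c("2050", "2080")) {
  lapply(seq_len(nrow(rows)), function(i) {
    grid <- expand.grid(scenario = scenarios, period = periods,
                        stringsAsFactors = FALSE)
    grid$loss <- mapply(function(sc, pd) rows[[sprintf("loss_%s_%s", sc, pd)]][i],
                        grid$scenario, grid$period)
    grid$change <- mapply(function(sc, pd) rows[[sprintf("change_%s_%s", sc, pd)]][i],
                          grid$scenario, grid$period)
    grid$expansion <- pmax(grid$change + grid$loss, 0)
    sensitivity_record(rows$species_id[i], rows$season[i], grid,
                       introduced = isTRUE(rows$introduced[i]),
                       marginal = isTRUE(rows$marginal[i]))
  })
}

#' Read a conservation-status table (S7-style CSV)
#'
#' Canonical columns: `species_id`, and any of `climate_category`,
#' `iucn`, `fed_bcc`, `pif`. Missing values are preserved as `NA` (and
#' drop out of rank correlations pairwise).
#'
#' @param file CSV path.
#' @param schema_map Optional canonical-to-actual column name map.
#' @return data.frame of statuses.
#' @export
read_status_table <- function(file, schema_map = NULL) {
  raw <- utils::read.csv(file, stringsAsFactors = FALSE, check.names = FALSE,
                         comment.char = "#")
  nm_of <- function(canonical) {
    if (!is.null(schema_map) && canonical %in% names(schema_map))
      schema_map[[canonical]] else canonical
  }
  id_col <- nm_of("species_id")
  if (!id_col %in% names(raw))
    stop_climsens("required column '%s' not in file; found: %s", id_col,
                  paste(names(raw), collapse = ", "))
  out <- data.frame(species_id = as.character(raw[[id_col]]),
                    stringsAsFactors = FALSE)
  for (canonical in c("climate_category", "iucn", "fed_bcc")) {
    nm <- nm_of(canonical)
    if (nm %in% names(raw)) {
      v <- trimws(as.character(raw[[nm]]))
      v[v == ""] <- NA
      out[[canonical]] <- v
    }
  }
  nm <- nm_of("pif")
  if (nm %in% names(raw)) out$pif <- suppressWarnings(as.numeric(raw[[nm]]))
  out
}
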