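#' Cohen's Kappa from confusion counts
#'
#' Proportion of correctly predicted sites after removing chance
#' agreement: `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement
#' `p_o = (TP + TN) / n` and chance agreement
#' `p_e = ((TP+FP)(TP+FN) + (FN+TN)(FP+TN)) / n^2`. The degenerate case
#' `p_e = 1` (both margins single-class) is defined as 0.
#'
#' @param tp,fp,fn,tn Non-negative confusion counts, total > 0.
#' @return Kappa in `[-1, 1]`.
#' @export
kappa_stat <- function(tp, fp, fn, tn) {
  if (any(c(tp, fp, fn, tn) < 0)) stop_climsens("confusion counts must be >= 0")
  n <- tp + fp + fn + tn
  if (any(n <= 0)) stop_climsens("total count must be positive")
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  ifelse(abs(1 - pe) < 1e-12, 0, (po - pe) / (1 - pe))
}

#' Maximum-Kappa threshold selection
#'
#' Sweeps every unique predicted value as a candidate threshold
#' (prediction >= t predicts presence), computes Kappa against the
#' observations at each, and returns the threshold maximizing Kappa.
#' Ties are broken toward the smallest threshold, which yields the
#' larger (more conservative for rare species) range.
#'
#' @param observed Binary vector (0/1).
#' @param predicted Numeric vector in `[0, 1]`, same length.
#' @return A list with `threshold`, `kappa_max` and `curve` (data.frame
#'   of threshold, tp, fp, fn, tn, kappa).
#' @export
max_kappa_threshold <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  observed <- as.integer(observed)
  if (!all(observed %in% c(0L, 1L)))
    stop_climsens("observed must be binary 0/1")
  if (length(unique(observed)) < 2L)
    stop_climsens("observations contain a single class; Kappa threshold undefined")
  if (any(predicted < 0 | predicted > 1))
    stop_climsens("predicted values must lie in [0, 1]")

  ord <- order(predicted, decreasing = TRUE)
  ps <- predicted[ord]; os <- observed[ord]
  n <- length(os); pos <- sum(os); neg <- n - pos
  cum_tp <- cumsum(os)
  # last index of each tie group = counts when thresholding at that value
  grp_end <- which(!duplicated(ps, fromLast = TRUE))
  thr <- ps[grp_end]
  tp <- cum_tp[grp_end]
  fp <- grp_end - tp
  fn <- pos - tp
  tn <- neg - fp
  kap <- kappa_stat(tp, fp, fn, tn)
  curve <- data.frame(threshold = thr, tp = tp, fp = fp, fn = fn, tn = tn,
                      kappa = kap)
  curve <- curve[order(curve$threshold), , drop = FALSE]
  rownames(curve) <- NULL
  best <- which(curve$kappa >= max(curve$kappa) - 1e-12)[1]  # smallest threshold
  list(threshold = curve$threshold[best], kappa_max = curve$kappa[best],
       curve = curve)
}

#' Binary range maps
#'
#' @param cells `ny x nx` matrix of 0/1.
#' @param threshold Threshold used to delineate the range.
#' @param species_id,season,scenario,period Labels.
#' @return A `cs_range` object.
#' @export
range_map <- function(cells, threshold = 0.5, species_id = NA_character_,
                      season = NA_character_, scenario = "none",
                      period = "base") {
  stopifnot(is.matrix(cells))
  if (!all(cells %in% c(0, 1)))
    stop_climsens("range map cells must be 0/1")
  structure(list(cells = matrix(as.integer(cells), nrow(cells), ncol(cells)),
                 threshold = threshold, species_id = species_id,
                 season = season, scenario = scenario, period = period),
            class = "cs_range")
}

#' @export
print.cs_range <- function(x, ...) {
  cat(sprintf("<cs_range> %s (%s) scenario=%s period=%s; %d cells at threshold %.3f\n",
              x$species_id, x$season, x$scenario, x$period, sum(x$cells),
              x$threshold))
  invisible(x)
}

#' Threshold a suitability surface into a binary range map
#'
#' A cell belongs to the range iff its suitability is >= the threshold.
#'
#' @param suitability A `cs_suitability` (or plain matrix).
#' @param threshold Threshold in (0, 1).
#' @return A `cs_range`.
#' @export
binarize <- function(suitability, threshold) {
  if (threshold <= 0 || threshold >= 1)
    stop_climsens("threshold must lie in (0, 1)")
  if (inherits(suitability, "cs_suitability")) {
    range_map((suitability$values >= threshold) * 1L, threshold,
              species_id = suitability$species_id,
              season = suitability$season,
              scenario = suitability$scenario,
              period = suitability$period)
  } else {
    range_map((suitability >= threshold) * 1L, threshold)
  }
}

#' Ensemble (consensus) of suitability projections
#'
#' Cell-wise arithmetic mean of suitability surfaces from different
#' GCMs for one scenario x period; the result is labelled
#' `gcm = "consensus"`.
#'
#' @param surfaces Non-empty list of `cs_suitability` on one grid with
#'   identical scenario and period labels.
#' @return A `cs_suitability`.
#' @export
ensemble <- function(surfaces) {
  if (!length(surfaces)) stop_climsens("ensemble of zero surfaces")
  stopifnot(all(vapply(surfaces, inherits, TRUE, "cs_suitability")))
  scen <- unique(vapply(surfaces, `[[`, "", "scenario"))
  per <- unique(vapply(surfaces, `[[`, "", "period"))
  if (length(scen) != 1L || length(per) != 1L)
    stop_climsens("ensemble inputs mix scenario/period labels (%s / %s)",
                  paste(scen, collapse = ","), paste(per, collapse = ","))
  dims <- lapply(surfaces, function(s) dim(s$values))
  if (length(unique(dims)) != 1L)
    stop_climsens("ensemble inputs are on different grids")
  m <- Reduce(`+`, lapply(surfaces, `[[`, "values")) / length(surfaces)
  suitability_surface(m, species_id = surfaces[[1]]$species_id,
                      season = surfaces[[1]]$season, period = per,
                      scenario = scen, gcm = "consensus")
}

#' Range size
#'
#' @param rangemap A `cs_range` (or binary matrix).
#' @param cell_area Cell area in km^2 (default 100, a 10 x 10 km cell).
#' @return List with `cells` (count of occupied cells) and `area_km2`.
#' @export
range_size <- function(rangemap, cell_area = 100) {
  cells <- if (inherits(rangemap, "cs_range")) rangemap$cells else rangemap
  k <- sum(cells == 1)
  list(cells = k, area_km2 = k * cell_area)
}
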