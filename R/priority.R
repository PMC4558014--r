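#' Assign ordinal ranks to conservation statuses
#'
#' Converts controlled status vocabularies to numeric ranks oriented so
#' that rank 1 is the highest threat in every scheme:
#'
#' * climate sensitivity: endangered = 1, threatened = 2, stable = 3
#'   (the stable group gets the highest rank); species categorized
#'   "other" (introduced/marginal) are excluded (`NA`);
#' * FED/BCC: federally listed = 1, conservation concern = 2, neither = 3;
#' * IUCN: endangered group = 1, threatened/vulnerable group = 2, least
#'   concern = 3;
#' * PIF: scores rise with threat, so the returned `pif_rank` is the
#'   negated score (rank correlations are invariant to the monotone
#'   transform; the sign flip aligns threat orientation with the other
#'   schemes). Missing scores stay `NA` and drop out of correlations.
#'
#' @param statuses data.frame with columns `species_id` and any of
#'   `climate_category` (endangered/threatened/stable/other), `fed_bcc`
#'   (FED/BCC/none), `iucn` (endangered/threatened/least_concern, or the
#'   IUCN codes CR/EN, VU/NT, LC), `pif` (numeric score).
#' @return data.frame with `species_id` and the rank columns
#'   `climate_rank`, `fed_bcc_rank`, `iucn_rank`, `pif_rank` (those whose
#'   source column was present).
#' @export
assign_ranks <- function(statuses) {
  stopifnot(is.data.frame(statuses), "species_id" %in% names(statuses))
  out <- data.frame(species_id = statuses$species_id, stringsAsFactors = FALSE)
  map_rank <- function(x, table, scheme) {
    x_low <- tolower(trimws(as.character(x)))
    r <- table[x_low]
    bad <- !is.na(x_low) & x_low != "na" & !(x_low %in% names(table))
    if (any(bad))
      stop_climsens("unknown %s status '%s' for species %s", scheme,
                    x[bad][1], statuses$species_id[bad][1])
    unname(r)
  }
  if ("climate_category" %in% names(statuses)) {
    tab <- c(endangered = 1, threatened = 2, stable = 3, other = NA)
    out$climate_rank <- map_rank(statuses$climate_category, tab, "climate")
  }
  if ("fed_bcc" %in% names(statuses)) {
    tab <- c(fed = 1, bcc = 2, none = 3, neither = 3)
    out$fed_bcc_rank <- map_rank(statuses$fed_bcc, tab, "FED/BCC")
  }
  if ("iucn" %in% names(statuses)) {
    tab <- c(cr = 1, en = 1, endangered = 1,
             vu = 2, nt = 2, threatened = 2, vulnerable = 2,
             lc = 3, least_concern = 3, "least concern" = 3)
    out$iucn_rank <- map_rank(statuses$iucn, tab, "IUCN")
  }
  if ("pif" %in% names(statuses)) {
    if (!is.numeric(statuses$pif))
      stop_climsens("pif scores must be numeric")
    out$pif_rank <- -statuses$pif
  }
  out
}

#' Kendall rank correlation (tau-b) with tie corrections
#'
#' Tau-b over pairwise-complete observations:
#' `tau = (C - D) / sqrt((n0 - n1)(n0 - n2))` with concordant C,
#' discordant D, `n0 = n(n-1)/2` and tie terms `n1`, `n2` for each
#' vector. The two-sided p-value uses the normal approximation with the
#' tie-adjusted variance of `C - D`.
#'
#' @param x,y Numeric vectors of equal length (>= 3 complete pairs).
#' @return List with `tau`, `p_value`, `n` (complete pairs used).
#' @export
kendall_tau <- function(x, y) {
  if (length(x) != length(y)) stop_climsens("x and y lengths differ")
  ok <- stats::complete.cases(x, y)
  x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
  n <- length(x)
  if (n < 3) stop_climsens("need at least 3 complete pairs")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop_climsens("all values tied in one vector; tau undefined")

  dx <- sign(outer(x, x, `-`))
  dy <- sign(outer(y, y, `-`))
  up <- upper.tri(dx)
  s <- dx[up] * dy[up]
  C <- sum(s > 0); D <- sum(s < 0)

  n0 <- n * (n - 1) / 2
  tie_term <- function(v) {
    t <- table(v); t <- t[t > 1]
    sum(t * (t - 1) / 2)
  }
  n1 <- tie_term(x); n2 <- tie_term(y)
  tau <- (C - D) / sqrt((n0 - n1) * (n0 - n2))

  # tie-adjusted variance of C - D (normal approximation)
  tx <- table(x); ty <- table(y)
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(tx * (tx - 1) * (2 * tx + 5))
  vu <- sum(ty * (ty - 1) * (2 * ty + 5))
  v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
  v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
    (9 * n * (n - 1) * (n - 2))
  var_s <- (v0 - vt - vu) / 18 + v1 + v2
  z <- (C - D) / sqrt(var_s)
  p <- 2 * stats::pnorm(-abs(z))
  list(tau = tau, p_value = p, n = n)
}

#' Random-effects variance components
#'
#' Fits a variance-components model (random intercept per factor, no
#' fixed slopes) by restricted maximum likelihood and returns each
#' factor's variance estimate and its proportion of the total (factor
#' components plus residual). Negative estimates are truncated at zero
#' by the REML fit itself. Factors with fewer than two observed levels
#' are dropped with a warning.
#'
#' @param response Numeric vector.
#' @param factors data.frame (or named list) of categorical predictors,
#'   same length as `response`; crossed designs are fine.
#' @return A `cs_variance_components` data.frame with columns `term`,
#'   `variance`, `proportion` (residual included; proportions sum to 1).
#' @export
variance_components <- function(response, factors) {
  factors <- as.data.frame(factors, stringsAsFactors = FALSE)
  stopifnot(length(response) == nrow(factors), ncol(factors) >= 1)
  keep <- vapply(factors, function(f) length(unique(f[!is.na(f)])) >= 2, TRUE)
  if (any(!keep))
    warning(sprintf("dropping factor(s) with < 2 levels: %s",
                    paste(names(factors)[!keep], collapse = ", ")))
  factors <- factors[, keep, drop = FALSE]
  if (!ncol(factors)) stop_climsens("no usable factors remain")

  if (stats::var(response) == 0) {
    out <- data.frame(term = c(names(factors), "residual"),
                      variance = 0, proportion = 0,
                      stringsAsFactors = FALSE)
    out$proportion[out$term == "residual"] <- 1
    class(out) <- c("cs_variance_components", "data.frame")
    return(out)
  }

  dat <- data.frame(.response = response, factors, stringsAsFactors = TRUE)
  terms <- paste(sprintf("(1 | %s)", names(factors)), collapse = " + ")
  form <- stats::as.formula(paste(".response ~ 1 +", terms))
  fit <- lme4::lmer(form, data = dat, REML = TRUE,
                    control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                                check.nobs.vs.nRE = "ignore",
                                                calc.derivs = FALSE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  variance <- stats::setNames(vc$vcov, vc$grp)
  names(variance)[names(variance) == "Residual"] <- "residual"
  variance <- pmax(variance, 0)
  ord <- c(names(factors), "residual")
  variance <- variance[ord]
  out <- data.frame(term = ord, variance = unname(variance),
                    proportion = unname(variance / sum(variance)),
                    stringsAsFactors = FALSE)
  class(out) <- c("cs_variance_components", "data.frame")
  out
}

#' Relative change in range size
#'
#' `(future - current) / current`; -1 means total loss, 0 no change.
#'
#' @param current_size,future_size Range sizes (cells or km^2), current
#'   > 0.
#' @return Relative change.
#' @export
relative_change <- function(current_size, future_size) {
  if (any(current_size <= 0))
    stop_climsens("current range size must be positive")
  (future_size - current_size) / current_size
}
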