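#' Default end-to-end run configuration
#'
#' Bundles every tunable of the synthetic experiment. The defaults give
#' the reference experiment: a 100 x 100 grid of 10 km cells, 500 survey
#' sites, 30 virtual species in equal archetype thirds (plus 2
#' introduced and 1 marginal flagged), 3 emissions scenarios x 3 future
#' periods x 3 GCMs, training years 2000-2009 and test years 1990-1999,
#' and the standard BRT settings.
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @param nx,ny,cell_size Landscape dimensions.
#' @param n_species,archetype_mix,n_introduced,n_marginal Cohort makeup.
#' @param n_sites,train_years,test_years,visit_prob Survey design.
#' @param scenarios,periods,gcms Projection labels.
#' @param gcm_jitter_sd Between-GCM temperature jitter sd, deg C.
#' @param detect_beta Effort-saturation detection rate per hour.
#' @param sdm [model_settings()] for the boosted trees.
#' @param bioclim_vars Bioclim layers used as SDM covariates (default
#'   all 19).
#' @return A `cs_config` list.
#' @export
default_config <- function(seed = 1,
                           nx = 100, ny = 100, cell_size = 10,
                           n_species = 30,
                           archetype_mix = c(shrinker = 1/3, shifter = 1/3,
                                             stable = 1/3),
                           n_introduced = 2, n_marginal = 1,
                           n_sites = 500,
                           train_years = 2000:2009,
                           test_years = 1990:1999,
                           visit_prob = 0.3,
                           scenarios = c("A2", "A1B", "B2"),
                           periods = c("2020", "2050", "2080"),
                           gcms = c("gcm01", "gcm02", "gcm03"),
                           gcm_jitter_sd = 0.3,
                           detect_beta = 0.25,
                           sdm = model_settings(),
                           bioclim_vars = sprintf("bio%02d", 1:19)) {
  structure(list(seed = as.integer(seed), nx = nx, ny = ny,
                 cell_size = cell_size, n_species = n_species,
                 archetype_mix = archetype_mix,
                 n_introduced = n_introduced, n_marginal = n_marginal,
                 n_sites = n_sites, train_years = train_years,
                 test_years = test_years, visit_prob = visit_prob,
                 scenarios = scenarios, periods = periods, gcms = gcms,
                 gcm_jitter_sd = gcm_jitter_sd, detect_beta = detect_beta,
                 sdm = sdm, bioclim_vars = bioclim_vars),
            class = "cs_config")
}

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k) %% (.Machine$integer.max - 1)) + 1L
}

# Polynomial rolling hash of the deparsed config, for output provenance.
config_hash <- function(config) {
  s <- paste(deparse(config), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Generate a synthetic conservation-status table for a cohort
#'
#' Draws IUCN, FED/BCC and PIF statuses per species with a configurable
#' (weak, by default) tilt toward higher priority for species in more
#' severe climate sensitivity categories — emulating priority schemes
#' that predate, and correlate only loosely with, climate sensitivity.
#' Some species carry no PIF score (missing at random).
#'
#' @param categories data.frame with `species_id` and `category`.
#' @param seed Integer seed.
#' @param assoc Strength of the severity tilt in `[0, 1]`.
#' @param pif_missing Probability a species lacks a PIF score.
#' @return A status data.frame consumable by [assign_ranks()].
#' @export
make_status_table <- function(categories, seed = 1, assoc = 0.2,
                              pif_missing = 0.3) {
  stopifnot(is.data.frame(categories),
            all(c("species_id", "category") %in% names(categories)))
  sev <- c(endangered = 2, threatened = 1, stable = 0, other = 0)
  s <- sev[categories$category]
  s[is.na(s)] <- 0
  n <- nrow(categories)
  with_seed(seed, {
    p_listed <- pmin(0.08 + assoc * 0.25 * s, 0.95)
    fed_bcc <- ifelse(stats::runif(n) < p_listed,
                      ifelse(stats::runif(n) < 0.3, "FED", "BCC"), "none")
    p_iucn <- pmin(0.05 + assoc * 0.2 * s, 0.9)
    iucn <- ifelse(stats::runif(n) < p_iucn,
                   ifelse(stats::runif(n) < 0.4, "EN", "VU"), "LC")
    pif <- round(8 + assoc * 3 * s + stats::rnorm(n, 0, 3))
    pif <- pmin(pmax(pif, 5), 20)
    pif[stats::runif(n) < pif_missing] <- NA
    data.frame(species_id = categories$species_id,
               climate_category = categories$category,
               iucn = iucn, fed_bcc = fed_bcc, pif = pif,
               stringsAsFactors = FALSE)
  })
}

#' Run the full synthetic climate-sensitivity experiment
#'
#' Executes every stage end to end: landscape and baseline climate
#' generation; bioclim computation; per-GCM future climates via the
#' anomaly method; virtual species and exact truth; survey design and
#' occurrence sampling; per-species boosted-tree models with
#' cross-validated tree counts; max-Kappa thresholds; consensus
#' projections and binary ranges per scenario x period; stability /
#' expansion metrics and category assignment; category tables; centroid
#' shifts; community gain/loss and turnover grids; variance components
#' and rank correlations against a synthetic status table. All
#' randomness derives from `config$seed`.
#'
#' @param config A [default_config()] list.
#' @param outdir Optional directory; when given, summary tables (CSV),
#'   grids (ESRI ASCII) and a run log are written there.
#' @param verbose Print per-stage progress.
#' @return A `cs_run` list (see the pipeline vignette for the layout).
#' @export
run_end_to_end <- function(config = default_config(), outdir = NULL,
                           verbose = TRUE) {
  stopifnot(inherits(config, "cs_config"))
  t_start <- Sys.time()
  hash <- config_hash(config)
  log_lines <- character()
  say <- function(fmt, ...) {
    msg <- sprintf(paste0("[%s] ", fmt), format(Sys.time(), "%H:%M:%S"), ...)
    log_lines <<- c(log_lines, msg)
    if (verbose) message(msg)
  }
  say("run config hash %s (seed %d)", hash, config$seed)

  ## landscape, baseline climate, baseline bioclim ----
  landscape <- make_landscape(config$nx, config$ny, config$cell_size,
                              seed = derive_seed(config$seed, 1))
  baseline <- make_baseline_climate(landscape,
                                    seed = derive_seed(config$seed, 2))
  bio_base <- compute_bioclim(baseline)
  say("landscape %dx%d and baseline climate ready", config$ny, config$nx)

  ## future climates: per gcm (jittered) and jitter-free truth ----
  future_bio <- list()   # [[scenario_period]][[gcm]]
  truth_bio <- list()    # [[scenario_period]] jitter-free
  for (sc in config$scenarios) for (pd in config$periods) {
    key <- paste(sc, pd, sep = "_")
    future_bio[[key]] <- lapply(seq_along(config$gcms), function(g) {
      fut <- make_future_climate(baseline, sc, pd,
                                 gcm_jitter_sd = config$gcm_jitter_sd,
                                 seed = derive_seed(config$seed, 100 + g),
                                 gcm = config$gcms[g])
      compute_bioclim(delta_downscale(baseline, fut, baseline))
    })
    tf <- make_future_climate(baseline, sc, pd, gcm_jitter_sd = 0,
                              gcm = "truth")
    truth_bio[[key]] <- compute_bioclim(tf)
  }
  say("%d future climates computed (%d consensus sets)",
      length(future_bio) * length(config$gcms), length(future_bio))

  ## species and exact truth ----
  species <- make_species(config$n_species,
                          archetype_mix = config$archetype_mix,
                          bioclim = bio_base,
                          seed = derive_seed(config$seed, 3),
                          n_introduced = config$n_introduced,
                          n_marginal = config$n_marginal)
  truth <- truth_table(species, bio_base, truth_bio)
  say("cohort of %d species generated (truth categories: %s)",
      length(species),
      paste(names(table(truth$categories$category)),
            table(truth$categories$category), collapse = " ", sep = "="))

  ## survey design and occurrences ----
  design <- make_survey_design(landscape, config$n_sites,
                               years = c(config$train_years,
                                         config$test_years),
                               visit_prob = config$visit_prob,
                               seed = derive_seed(config$seed, 4))
  occurrences <- do.call(rbind, lapply(seq_along(species), function(i) {
    s <- true_suitability(species[[i]], bio_base)
    sample_occurrences(s, design, detect_beta = config$detect_beta,
                       seed = derive_seed(config$seed, 200 + i))
  }))
  say("%d occurrence records sampled at %d sites", nrow(occurrences),
      config$n_sites)

  ## covariates at sites ----
  site_bio <- extract_at_points(bio_base,
                                cbind(design$sites,
                                      data.frame(site_id = design$sites$site_id)),
                                config$cell_size)
  rownames(site_bio) <- design$sites$site_id

  ## per-species fit / evaluate / threshold / project ----
  results <- list(); model_meta <- list()
  for (i in seq_along(species)) {
    niche <- species[[i]]
    sp <- niche$species_id
    occ <- occurrences[occurrences$species_id == sp, , drop = FALSE]
    survey_cov <- if (niche$season == "breeding") "ordinal_date" else "effort_hours"
    covs <- c(config$bioclim_vars, survey_cov)
    frame <- cbind(occ, site_bio[occ$site_id, config$bioclim_vars,
                                 drop = FALSE])
    parts <- split_train_test(frame, config$train_years, config$test_years)
    fit <- tryCatch(
      fit_brt(parts$train, covs, settings = config$sdm,
              seed = derive_seed(config$seed, 300 + i)),
      climsens_insufficient_data = function(e) e)
    if (inherits(fit, "condition")) {
      say("species %s skipped: %s", sp, conditionMessage(fit))
      results[[sp]] <- list(niche = niche, skipped = TRUE,
                            reason = conditionMessage(fit))
      next
    }
    ev <- evaluate(fit, parts$test)
    const <- if (niche$season == "breeding")
      list(ordinal_date = stats::median(parts$train$ordinal_date))
    else list(effort_hours = stats::median(parts$train$effort_hours))
    thr <- max_kappa_threshold(parts$train$presence,
                               predict_model(fit, parts$train))
    cur_suit <- predict_suitability(fit, bio_base, const)
    cur_range <- binarize(cur_suit, thr$threshold)
    fut_ranges <- list()
    metrics <- list()
    for (key in names(future_bio)) {
      cons <- ensemble(lapply(future_bio[[key]], predict_suitability,
                              model = fit, constants = const))
      fr <- binarize(cons, thr$threshold)
      fut_ranges[[key]] <- fr
      metrics[[key]] <- data.frame(
        scenario = fr$scenario, period = fr$period,
        stability = if (range_size(cur_range)$cells > 0)
          stability(cur_range, fr) else NA_real_,
        expansion = if (range_size(cur_range)$cells > 0)
          expansion(cur_range, fr) else NA_real_,
        stringsAsFactors = FALSE)
    }
    m <- do.call(rbind, c(metrics, make.row.names = FALSE))
    m$loss <- 1 - m$stability
    results[[sp]] <- list(niche = niche, skipped = FALSE, model = fit,
                          eval = ev, threshold = thr$threshold,
                          current_range = cur_range,
                          future_ranges = fut_ranges, metrics = m)
    model_meta[[sp]] <- data.frame(
      species_id = sp, season = niche$season, archetype = niche$archetype,
      n_trees = fit$n_trees, cv_best_iter = fit$cv_best_iter,
      auc = ev$auc, deviance_explained = ev$deviance_explained,
      kappa_max = ev$kappa_max, tpr = ev$tpr, threshold = thr$threshold,
      stringsAsFactors = FALSE)
    say("species %s (%s/%s): %d trees, AUC %.3f, threshold %.3f", sp,
        niche$season, niche$archetype, fit$n_trees, ev$auc, thr$threshold)
  }
  model_metrics <- do.call(rbind, c(model_meta, make.row.names = FALSE))
  qc <- if (!is.null(model_metrics) && nrow(model_metrics) >= 3)
    model_qc_filter(model_metrics) else model_metrics
  if (!is.null(qc) && any(!qc$keep))
    say("QC flagged: %s", paste(qc$species_id[!qc$keep], qc$reason[!qc$keep],
                                collapse = "; "))

  ## sensitivity records, categories, recovery ----
  records <- list(); cat_rows <- list()
  for (sp in names(results)) {
    r <- results[[sp]]
    truth_cat <- truth$categories$category[truth$categories$species_id == sp]
    if (r$skipped) {
      category <- if (r$niche$introduced || r$niche$marginal) "other" else NA
    } else {
      rec <- sensitivity_record(sp, r$niche$season, r$metrics,
                                introduced = r$niche$introduced,
                                marginal = r$niche$marginal)
      records[[sp]] <- rec
      category <- classify(rec, scenarios = config$scenarios)
    }
    cat_rows[[sp]] <- data.frame(
      species_id = sp, season = r$niche$season,
      archetype = r$niche$archetype,
      introduced = r$niche$introduced, marginal = r$niche$marginal,
      category = category, truth_category = truth_cat,
      recovered = identical(category, truth_cat),
      stringsAsFactors = FALSE)
  }
  categories <- do.call(rbind, c(cat_rows, make.row.names = FALSE))
  recovery <- mean(categories$recovered[!is.na(categories$category)])
  say("category recovery: %.1f%% (%d/%d classified species)",
      100 * recovery, sum(categories$recovered, na.rm = TRUE),
      sum(!is.na(categories$category)))

  table1 <- tabulate_categories(records, scenarios = config$scenarios)

  ## species summary (S1-style) ----
  summary_rows <- list()
  for (sp in names(results)) {
    r <- results[[sp]]
    if (r$skipped) next
    row <- data.frame(species_id = sp, season = r$niche$season,
                      introduced = r$niche$introduced,
                      marginal = r$niche$marginal,
                      category = categories$category[categories$species_id == sp],
                      stringsAsFactors = FALSE)
    cur_n <- range_size(r$current_range)$cells
    for (k in seq_len(nrow(r$metrics))) {
      sc <- r$metrics$scenario[k]; pd <- r$metrics$period[k]
      fut_n <- range_size(r$future_ranges[[paste(sc, pd, sep = "_")]])$cells
      row[[sprintf("loss_%s_%s", sc, pd)]] <- r$metrics$loss[k]
      row[[sprintf("change_%s_%s", sc, pd)]] <- relative_change(cur_n, fut_n)
    }
    summary_rows[[sp]] <- row
  }
  species_summary <- do.call(rbind, c(summary_rows, make.row.names = FALSE))

  ## centroid shifts (current vs 2080 under the high scenario) ----
  shift_key <- paste(config$scenarios[1], "2080", sep = "_")
  shift_rows <- list()
  for (sp in names(results)) {
    r <- results[[sp]]
    if (r$skipped) next
    fut <- r$future_ranges[[shift_key]]
    if (range_size(r$current_range)$cells == 0 ||
        range_size(fut)$cells == 0) next
    ccur <- weighted_centroid(r$current_range, landscape)
    cfut <- weighted_centroid(fut, landscape)
    d <- centroid_shift(ccur, cfut)
    shift_rows[[sp]] <- data.frame(
      species_id = sp, season = r$niche$season, archetype = r$niche$archetype,
      dlat_km = d$dlat_km, delev_m = d$delev_m, dcoast_km = d$dcoast_km,
      stringsAsFactors = FALSE)
  }
  shifts <- do.call(rbind, c(shift_rows, make.row.names = FALSE))

  ## community change per season (current vs 2080, high scenario) ----
  community <- list()
  for (season in unique(categories$season)) {
    sps <- names(Filter(function(r) !r$skipped &&
                          identical(r$niche$season, season), results))
    if (!length(sps)) next
    cur <- lapply(results[sps], `[[`, "current_range")
    fut <- lapply(results[sps], function(r) r$future_ranges[[shift_key]])
    community[[season]] <- list(richness = richness_change(cur, fut),
                                dissimilarity = dissimilarity_map(cur, fut))
  }

  ## variance components per season ----
  varcomp <- list()
  long <- do.call(rbind, lapply(names(records), function(sp) {
    m <- results[[sp]]$metrics
    m <- m[m$period == "2080", , drop = FALSE]
    cbind(species_id = sp, season = results[[sp]]$niche$season,
          archetype = results[[sp]]$niche$archetype, m)
  }))
  if (!is.null(long)) {
    for (season in unique(long$season)) {
      d <- long[long$season == season, , drop = FALSE]
      if (length(unique(d$species_id)) >= 3) {
        varcomp[[season]] <- tryCatch(
          variance_components(d$stability,
                              d[, c("species_id", "archetype", "scenario")]),
          error = function(e) NULL)
      }
    }
  }

  ## rank correlations against a synthetic status table ----
  statuses <- make_status_table(categories[!is.na(categories$category), ],
                                seed = derive_seed(config$seed, 5))
  ranks <- assign_ranks(statuses)
  cors <- list()
  for (scheme in c("iucn_rank", "fed_bcc_rank", "pif_rank")) {
    kt <- tryCatch(kendall_tau(ranks$climate_rank, ranks[[scheme]]),
                   error = function(e) NULL)
    if (!is.null(kt))
      cors[[scheme]] <- data.frame(scheme = sub("_rank$", "", scheme),
                                   tau = kt$tau, p_value = kt$p_value,
                                   n = kt$n, stringsAsFactors = FALSE)
  }
  rank_correlations <- do.call(rbind, c(cors, make.row.names = FALSE))

  elapsed <- as.numeric(Sys.time() - t_start, units = "secs")
  say("run complete in %.1f s", elapsed)

  run <- structure(list(
    config = config, config_hash = hash, landscape = landscape,
    species = species, truth = truth, design = design,
    occurrences = occurrences, results = results,
    model_metrics = qc, categories = categories, recovery = recovery,
    table1 = table1, species_summary = species_summary, shifts = shifts,
    community = community, varcomp = varcomp, statuses = statuses,
    rank_correlations = rank_correlations, log = log_lines,
    elapsed_s = elapsed), class = "cs_run")
  if (!is.null(outdir)) write_run(run, outdir)
  run
}

# Write the run's tables and grids to a directory.
write_run <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stamp <- function(df) { attr(df, "config_hash") <- run$config_hash; df }
  wcsv <- function(df, name) {
    if (is.null(df)) return()
    path <- file.path(outdir, name)
    con <- file(path, "w")
    writeLines(sprintf("# config_hash %s", run$config_hash), con)
    utils::write.csv(stamp(df), con, row.names = FALSE)
    close(con)
  }
  wcsv(run$species_summary, "species_summary.csv")
  wcsv(run$categories, "categories.csv")
  wcsv(run$table1, "category_table.csv")
  wcsv(run$model_metrics, "model_metrics.csv")
  wcsv(run$shifts, "centroid_shifts.csv")
  wcsv(run$rank_correlations, "rank_correlations.csv")
  wcsv(run$statuses, "statuses.csv")
  for (season in names(run$varcomp))
    wcsv(run$varcomp[[season]], sprintf("variance_components_%s.csv", season))
  for (season in names(run$community)) {
    cm <- run$community[[season]]
    write_ascii_grid(cm$richness$gain,
                     file.path(outdir, sprintf("gain_%s.asc", season)),
                     run$config$cell_size)
    write_ascii_grid(cm$richness$loss,
                     file.path(outdir, sprintf("loss_%s.asc", season)),
                     run$config$cell_size)
    write_ascii_grid(cm$dissimilarity$dissimilarity,
                     file.path(outdir, sprintf("dissimilarity_%s.asc", season)),
                     run$config$cell_size)
  }
  writeLines(run$log, file.path(outdir, "run_log.txt"))
  invisible(outdir)
}

#' @export
print.cs_run <- function(x, ...) {
  cat(sprintf("<cs_run> %d species, recovery %.1f%%, %.0f s, hash %s\n",
              length(x$species), 100 * x$recovery, x$elapsed_s,
              x$config_hash))
  invisible(x)
}

#' Re-derive headline results from supplementary-style tables
#'
#' Applies the category classifier ([classify()] + [combine_seasons()])
#' to a per-species range-change summary CSV (S1-style) and the rank
#' correlation analysis ([assign_ranks()] + [kendall_tau()]) to a
#' conservation-status CSV (S7-style), and reports the computed counts
#' and correlations, side by side with published reference values when
#' supplied.
#'
#' @param s1_file CSV of per-species loss/change summaries (see
#'   [read_species_summaries()]); `NULL` skips with a warning.
#' @param s7_file CSV of conservation statuses (see
#'   [read_status_table()]); `NULL` skips with a warning.
#' @param s1_schema,s7_schema Optional schema maps.
#' @param scenarios Scenario labels in the summaries.
#' @param published Optional named list of published reference values
#'   (e.g. `endangered`, `threatened`, `tau_iucn`, ...) echoed alongside
#'   the computed ones.
#' @return A `cs_reproduction` list with elements `categories`
#'   (species-level with per-season detail), `counts` (computed overall
#'   and per-season counts), `correlations`, and `comparison` (computed
#'   vs published where given).
#' @export
reproduce_published <- function(s1_file = NULL, s7_file = NULL,
                                s1_schema = NULL, s7_schema = NULL,
                                scenarios = c("A2", "A1B", "B2"),
                                published = NULL) {
  out <- list()
  if (is.null(s1_file) || !file.exists(s1_file %||% "")) {
    warning("species summary (S1-style) file missing; category counts skipped")
  } else {
    rows <- read_species_summaries(s1_file, schema_map = s1_schema,
                                   scenarios = scenarios)
    recs <- summaries_to_records(rows, scenarios = scenarios)
    per_season <- data.frame(species_id = rows$species_id,
                             season = rows$season,
                             category = vapply(recs, classify, "",
                                               scenarios = scenarios),
                             stringsAsFactors = FALSE)
    species_ids <- unique(per_season$species_id)
    overall <- vapply(species_ids, function(sp) {
      d <- per_season[per_season$species_id == sp, ]
      b <- d$category[d$season == "breeding"]
      w <- d$category[d$season == "nonbreeding"]
      combine_seasons(if (length(b)) b[1] else NA,
                      if (length(w)) w[1] else NA)$overall
    }, "")
    out$categories <- data.frame(species_id = species_ids,
                                 overall = overall,
                                 stringsAsFactors = FALSE)
    out$per_season <- per_season
    cat_count <- function(cats) {
      c(endangered = sum(cats == "endangered"),
        threatened = sum(cats == "threatened"),
        endangered_or_threatened = sum(cats %in% c("endangered", "threatened")),
        stable = sum(cats == "stable"),
        other = sum(cats == "other"))
    }
    counts <- list(overall = cat_count(overall))
    for (season in unique(per_season$season))
      counts[[season]] <- cat_count(per_season$category[per_season$season == season])
    out$counts <- counts
    out$records <- recs
  }
  if (is.null(s7_file) || !file.exists(s7_file %||% "")) {
    warning("status (S7-style) file missing; rank correlations skipped")
  } else {
    statuses <- read_status_table(s7_file, schema_map = s7_schema)
    if (!"climate_category" %in% names(statuses) &&
        !is.null(out$categories)) {
      statuses$climate_category <- out$categories$overall[
        match(statuses$species_id, out$categories$species_id)]
    }
    statuses <- statuses[!is.na(statuses$climate_category) &
                           statuses$climate_category != "other", , drop = FALSE]
    ranks <- assign_ranks(statuses)
    cors <- list()
    for (scheme in intersect(c("iucn_rank", "fed_bcc_rank", "pif_rank"),
                             names(ranks))) {
      kt <- tryCatch(kendall_tau(ranks$climate_rank, ranks[[scheme]]),
                     error = function(e) NULL)
      if (!is.null(kt))
        cors[[scheme]] <- data.frame(scheme = sub("_rank$", "", scheme),
                                     tau = kt$tau, p_value = kt$p_value,
                                     n = kt$n, stringsAsFactors = FALSE)
    }
    out$correlations <- do.call(rbind, c(cors, make.row.names = FALSE))
  }
  if (!is.null(published)) {
    comp <- list()
    flat <- c(if (!is.null(out$counts)) as.list(out$counts$overall),
              if (!is.null(out$correlations))
                stats::setNames(as.list(out$correlations$tau),
                                paste0("tau_", out$correlations$scheme)))
    for (nm in names(published)) {
      comp[[nm]] <- data.frame(quantity = nm,
                               computed = flat[[nm]] %||% NA_real_,
                               published = published[[nm]],
                               stringsAsFactors = FALSE)
    }
    out$comparison <- do.call(rbind, c(comp, make.row.names = FALSE))
  }
  class(out) <- "cs_reproduction"
  out
}
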