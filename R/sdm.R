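#' Boosted regression tree model settings
#'
#' Defaults follow the standard large-survey SDM protocol: learning rate
#' (shrinkage) 0.01, tree complexity (interaction depth) 5, Bernoulli
#' (logistic) loss, 10-fold cross-validation to choose the tree count,
#' at least 1000 trees, bag fraction 0.5.
#'
#' @param learning_rate Shrinkage per tree (> 0).
#' @param tree_complexity Maximum tree depth (>= 1).
#' @param n_folds Cross-validation folds (>= 2).
#' @param min_trees,max_trees Bounds on the selected tree count.
#' @param bag_fraction Stochastic subsampling fraction per tree.
#' @param min_class_n Minimum presences and absences required to fit.
#' @return A `cs_model_settings` list.
#' @export
model_settings <- function(learning_rate = 0.01, tree_complexity = 5,
                           n_folds = 10, min_trees = 1000, max_trees = 3000,
                           bag_fraction = 0.5, min_class_n = 20) {
  if (learning_rate <= 0) stop_climsens("learning_rate must be > 0")
  if (tree_complexity < 1) stop_climsens("tree_complexity must be >= 1")
  if (n_folds < 2) stop_climsens("n_folds must be >= 2")
  if (max_trees < min_trees) stop_climsens("max_trees must be >= min_trees")
  structure(list(learning_rate = learning_rate,
                 tree_complexity = tree_complexity,
                 n_folds = n_folds, min_trees = min_trees,
                 max_trees = max_trees, bag_fraction = bag_fraction,
                 min_class_n = min_class_n),
            class = "cs_model_settings")
}

#' Partition occurrence records into training and test sets by year
#'
#' @param occurrences Occurrence data.frame with a `year` column.
#' @param train_years,test_years Disjoint integer year vectors.
#' @return List with `train` and `test` data.frames.
#' @export
split_train_test <- function(occurrences, train_years, test_years) {
  if (length(intersect(train_years, test_years)))
    stop_climsens("train and test year ranges overlap")
  train <- occurrences[occurrences$year %in% train_years, , drop = FALSE]
  test <- occurrences[occurrences$year %in% test_years, , drop = FALSE]
  if (!nrow(train))
    stop_climsens("no records in training years %s-%s",
                  min(train_years), max(train_years))
  if (!nrow(test))
    stop_climsens("no records in test years %s-%s",
                  min(test_years), max(test_years))
  list(train = train, test = test)
}

#' Restrict a test set to sites never used in training
#'
#' Gives a spatially (as well as temporally) independent evaluation set:
#' test records at sites absent from the training data.
#'
#' @param test,train Occurrence data.frames carrying `site_id`.
#' @return The filtered test data.frame.
#' @export
spatially_independent_subset <- function(test, train) {
  stopifnot("site_id" %in% names(test), "site_id" %in% names(train))
  test[!test$site_id %in% unique(train$site_id), , drop = FALSE]
}

#' Fit a boosted regression tree occurrence model
#'
#' Fits a gradient-boosted classification-tree model (Bernoulli loss)
#' for one species-season. The tree count is chosen by k-fold
#' cross-validated log loss, floored at `min_trees` and capped at
#' `max_trees`. Covariates are the selected bioclim layers plus the
#' season's survey covariate (effort hours for non-breeding, ordinal
#' date for breeding), which must be columns of `train`.
#'
#' @param train Model frame: one row per record, with a 0/1 `presence`
#'   column and every covariate column.
#' @param covariates Character vector of covariate column names.
#' @param settings A [model_settings()] object.
#' @param seed Integer seed (folds and stochastic subsampling).
#' @return A `cs_sdm_model`: the fitted booster plus metadata
#'   (`species_id`, `season`, `n_trees`, `covariates`, `n_train`,
#'   `years`, `cv_best_iter`, `min_trees_waived`).
#' @export
fit_brt <- function(train, covariates, settings = model_settings(), seed = 1) {
  stopifnot(is.data.frame(train), "presence" %in% names(train))
  missing <- setdiff(covariates, names(train))
  if (length(missing))
    stop_climsens("training data lack covariate(s): %s",
                  paste(missing, collapse = ", "))
  y <- as.integer(train$presence)
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos < settings$min_class_n || n_neg < settings$min_class_n)
    stop_climsens(
      "insufficient data (%d presences, %d absences; need >= %d each)",
      n_pos, n_neg, settings$min_class_n,
      class = "climsens_insufficient_data")

  X <- as.matrix(train[, covariates, drop = FALSE])
  params <- list(objective = "binary:logistic",
                 eta = settings$learning_rate,
                 max_depth = settings$tree_complexity,
                 subsample = settings$bag_fraction,
                 tree_method = "hist",
                 nthread = 1, seed = seed)
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  cv_best <- with_seed(seed, {
    cv <- xgboost::xgb.cv(params = params, data = dtrain,
                          nrounds = settings$max_trees,
                          nfold = settings$n_folds,
                          early_stopping_rounds = 50,
                          metrics = "logloss", verbose = 0)
    bi <- cv$early_stop$best_iteration %||% cv$niter
    as.integer(bi)
  })
  n_trees <- min(max(cv_best, settings$min_trees), settings$max_trees)
  booster <- with_seed(seed, {
    xgboost::xgb.train(params = params, data = dtrain, nrounds = n_trees,
                       verbose = 0)
  })
  structure(list(booster = booster,
                 species_id = train$species_id[1] %||% NA_character_,
                 season = train$season[1] %||% NA_character_,
                 covariates = covariates,
                 n_trees = n_trees,
                 cv_best_iter = cv_best,
                 min_trees_waived = cv_best < settings$min_trees,
                 settings = settings,
                 n_train = nrow(train),
                 years = sort(unique(train$year))),
            class = "cs_sdm_model")
}

#' @export
print.cs_sdm_model <- function(x, ...) {
  cat(sprintf("<cs_sdm_model> %s (%s): %d trees (cv best %d), %d covariates, n=%d\n",
              x$species_id, x$season, x$n_trees, x$cv_best_iter,
              length(x$covariates), x$n_train))
  invisible(x)
}

# Predict occurrence probability for arbitrary covariate rows.
predict_model <- function(model, newdata) {
  X <- as.matrix(newdata[, model$covariates, drop = FALSE])
  stats::predict(model$booster, xgboost::xgb.DMatrix(X, nthread = 1))
}

#' Project a fitted model over a bioclim grid
#'
#' Builds the per-cell covariate matrix from the bioclim layers, filling
#' non-climate covariates (survey effort, ordinal date) with the
#' supplied constants (typically the training medians) as uniform
#' layers, and predicts occurrence probability per cell.
#'
#' @param model A `cs_sdm_model`.
#' @param bioclim A `cs_bioclim`.
#' @param constants Named list of scalars for covariates not present in
#'   the bioclim stack.
#' @return A `cs_suitability` labelled with the grid's provenance.
#' @export
predict_suitability <- function(model, bioclim, constants = list()) {
  stopifnot(inherits(model, "cs_sdm_model"), inherits(bioclim, "cs_bioclim"))
  d <- dim(bioclim)
  nc <- d[1] * d[2]
  layers <- dimnames(bioclim)[[3]]
  cols <- lapply(model$covariates, function(v) {
    if (v %in% layers) as.vector(bioclim_layer(bioclim, v))
    else if (v %in% names(constants)) rep(constants[[v]], nc)
    else stop_climsens("covariate '%s' missing from grid and constants", v)
  })
  X <- do.call(cbind, cols)
  colnames(X) <- model$covariates
  p <- stats::predict(model$booster, xgboost::xgb.DMatrix(X, nthread = 1))
  suitability_surface(matrix(p, d[1], d[2]),
                      species_id = model$species_id, season = model$season,
                      period = attr(bioclim, "period"),
                      scenario = attr(bioclim, "scenario"),
                      gcm = attr(bioclim, "gcm"))
}

# Rank (Mann-Whitney) AUC with mid-rank tie handling.
auc_rank <- function(predicted, observed) {
  r <- rank(predicted)
  n1 <- sum(observed == 1); n0 <- sum(observed == 0)
  (sum(r[observed == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a fitted model on held-out records
#'
#' Computes AUC (rank statistic), Bernoulli deviance explained
#' (`1 - residual/null deviance`), the maximum Kappa over candidate
#' thresholds, and the true positive rate at the max-Kappa threshold.
#'
#' @param model A `cs_sdm_model`.
#' @param test Model frame with `presence` and the model's covariates.
#' @return A `cs_eval_metrics` list: `auc`, `deviance_explained`,
#'   `kappa_max`, `threshold`, `tpr`, `n_test`.
#' @export
evaluate <- function(model, test) {
  stopifnot(is.data.frame(test), nrow(test) > 0, "presence" %in% names(test))
  obs <- as.integer(test$presence)
  if (length(unique(obs)) < 2L)
    stop_climsens("test set contains a single class; AUC undefined")
  pred <- predict_model(model, test)
  auc <- auc_rank(pred, obs)
  eps <- 1e-12
  pc <- pmin(pmax(pred, eps), 1 - eps)
  resid_dev <- -2 * sum(obs * log(pc) + (1 - obs) * log(1 - pc))
  p0 <- mean(obs)
  null_dev <- -2 * sum(obs * log(p0) + (1 - obs) * log(1 - p0))
  mk <- max_kappa_threshold(obs, pred)
  tp <- sum(obs == 1 & pred >= mk$threshold)
  structure(list(auc = auc,
                 deviance_explained = 1 - resid_dev / null_dev,
                 kappa_max = mk$kappa_max,
                 threshold = mk$threshold,
                 tpr = tp / sum(obs == 1),
                 n_test = length(obs)),
            class = "cs_eval_metrics")
}

#' Flag under-performing models across a species set
#'
#' Keeps models whose AUC and deviance explained lie within two standard
#' deviations *below* the across-species mean (performing well can only
#' be violated downward); everything else is dropped with a reason.
#' With fewer than 3 species, or zero spread, all models are kept.
#'
#' @param metrics data.frame with columns `species_id`, `auc`,
#'   `deviance_explained`.
#' @return The input with logical `keep` and character `reason` columns.
#' @export
model_qc_filter <- function(metrics) {
  stopifnot(is.data.frame(metrics),
            all(c("species_id", "auc", "deviance_explained") %in% names(metrics)))
  if (nrow(metrics) < 3)
    stop_climsens("QC filter needs metrics for at least 3 species")
  flag_low <- function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) return(rep(FALSE, length(x)))
    x < mean(x) - 2 * s
  }
  low_auc <- flag_low(metrics$auc)
  low_dev <- flag_low(metrics$deviance_explained)
  metrics$keep <- !(low_auc | low_dev)
  metrics$reason <- ifelse(low_auc & low_dev, "auc and deviance > 2 SD below mean",
                    ifelse(low_auc, "auc > 2 SD below mean",
                    ifelse(low_dev, "deviance explained > 2 SD below mean", "")))
  metrics
}
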