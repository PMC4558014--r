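small_settings <- function(...) {
  model_settings(n_folds = 4, min_trees = 100, max_trees = 400,
                 min_class_n = 10, ...)
}

test_that("year-based splits partition the records", {
  occ <- data.frame(site_id = sprintf("s%d", 1:100),
                    year = rep(1995:2004, each = 10),
                    presence = rbinom(100, 1, 0.5))
  parts <- split_train_test(occ, 2000:2004, 1995:1999)
  expect_equal(nrow(parts$train), 50)
  expect_equal(nrow(parts$test), 50)
  expect_equal(nrow(parts$train) + nrow(parts$test), nrow(occ))
  expect_length(intersect(rownames(parts$train), rownames(parts$test)), 0)
  expect_error(split_train_test(occ, 2000:2004, 2004:2006), "overlap")
  expect_error(split_train_test(occ, 1995:2004, 2010:2011), "no records in test")
})

test_that("spatially independent subset equals the set-difference oracle", {
  train <- data.frame(site_id = c("a", "b", "c"))
  test <- data.frame(site_id = c("a", "b", "c", "d", "e", "d"))
  got <- spatially_independent_subset(test, train)
  expect_equal(got$site_id, c("d", "e", "d"))
  # all shared -> empty; disjoint -> unchanged
  expect_equal(nrow(spatially_independent_subset(train, train)), 0)
  disjoint <- data.frame(site_id = c("x", "y"))
  expect_equal(spatially_independent_subset(disjoint, train), disjoint)
  # brute-force oracle on random ids
  set.seed(5)
  tr <- data.frame(site_id = sample(letters, 40, TRUE))
  te <- data.frame(site_id = sample(letters, 60, TRUE))
  got <- spatially_independent_subset(te, tr)
  expect_equal(got$site_id,
               te$site_id[!te$site_id %in% unique(tr$site_id)])
})

test_that("AUC equals the brute-force pairwise concordance oracle", {
  auc_oracle <- function(pred, obs) {
    pos <- pred[obs == 1]; neg <- pred[obs == 0]
    total <- 0
    for (p in pos) for (q in neg)
      total <- total + (p > q) + 0.5 * (p == q)
    total / (length(pos) * length(neg))
  }
  set.seed(13)
  for (k in 1:5) {
    n <- 20
    obs <- rbinom(n, 1, 0.5)
    if (length(unique(obs)) < 2) obs[1:2] <- c(0, 1)
    pred <- round(runif(n), sample(c(1, 3), 1))
    expect_equal(climsens:::auc_rank(pred, obs), auc_oracle(pred, obs))
  }
})

test_that("boosted models learn a monotone response and separate classes", {
  train <- toy_frame(n = 400, seed = 1, noise = 0.3)
  fit <- fit_brt(train, c("x", "effort_hours"), small_settings(), seed = 1)
  expect_s3_class(fit, "cs_sdm_model")
  expect_gte(fit$n_trees, 100)
  # monotone truth -> strong rank correlation with the covariate on a probe
  probe <- data.frame(x = seq(-2, 2, length.out = 100), effort_hours = 8)
  p <- climsens:::predict_model(fit, probe)
  expect_gt(cor(p, probe$x, method = "spearman"), 0.9)

  # perfectly separable labels -> training AUC ~ 1
  sep <- train; sep$presence <- as.integer(sep$x > 0)
  fit2 <- fit_brt(sep, c("x", "effort_hours"), small_settings(), seed = 1)
  expect_gte(evaluate(fit2, sep)$auc, 0.99)

  # deterministic under a fixed seed
  fit3 <- fit_brt(train, c("x", "effort_hours"), small_settings(), seed = 1)
  expect_equal(fit3$n_trees, fit$n_trees)
  expect_equal(climsens:::predict_model(fit3, probe), p)

  expect_error(fit_brt(train, c("x", "nope"), small_settings()), "nope")
  few <- train[c(which(train$presence == 1)[1:3],
                 which(train$presence == 0)[1:50]), ]
  expect_error(fit_brt(few, "x", small_settings()),
               class = "climsens_insufficient_data")
})

test_that("permuted labels give chance-level cross-validated AUC", {
  set.seed(3)
  train <- toy_frame(n = 300, seed = 3, noise = 0.3)
  aucs <- sapply(1:10, function(k) {
    perm <- train
    set.seed(1000 + k)
    perm$presence <- sample(perm$presence)
    half <- seq_len(150)
    fit <- fit_brt(perm[half, ], c("x", "effort_hours"),
                   model_settings(n_folds = 3, min_trees = 50,
                                  max_trees = 100, min_class_n = 5),
                   seed = k)
    evaluate(fit, perm[-half, ])$auc
  })
  expect_gt(mean(aucs), 0.40)
  expect_lt(mean(aucs), 0.60)
})

test_that("grid prediction uses constants and is traversal-invariant", {
  l <- tiny_landscape()
  cl <- tiny_climate(l)
  b <- compute_bioclim(cl)
  sp <- make_species(1, archetype_mix = c(shrinker = 0, shifter = 0,
                                          stable = 1),
                     bioclim = b, seed = 2)[[1]]
  sp$season <- "nonbreeding"
  design <- make_survey_design(l, 120, 2000:2004, seed = 3)
  occ <- sample_occurrences(true_suitability(sp, b), design, seed = 4)
  sb <- extract_at_points(b, cbind(design$sites,
                                   data.frame(site_id = design$sites$site_id)),
                          l$cell_size)
  rownames(sb) <- design$sites$site_id
  frame <- cbind(occ, sb[occ$site_id, , drop = FALSE])
  covs <- c(sprintf("bio%02d", 1:19), "effort_hours")
  fit <- fit_brt(frame, covs, small_settings(), seed = 5)
  s <- predict_suitability(fit, b, list(effort_hours = 8))
  expect_true(all(s$values >= 0 & s$values <= 1))
  expect_equal(s$period, "base")
  # missing constant is named
  expect_error(predict_suitability(fit, b, list()), "effort_hours")
  # effort constant shifts predictions in the learned direction
  lo <- predict_suitability(fit, b, list(effort_hours = 1))
  hi <- predict_suitability(fit, b, list(effort_hours = 30))
  expect_gt(mean(hi$values), mean(lo$values))
})

test_that("evaluation metrics behave at the extremes", {
  train <- toy_frame(n = 200, seed = 9, noise = 0.2)
  fit <- fit_brt(train, c("x", "effort_hours"), small_settings(), seed = 1)
  test <- toy_frame(n = 200, seed = 10, noise = 0.2)
  ev <- evaluate(fit, test)
  expect_gt(ev$auc, 0.9)
  expect_gt(ev$deviance_explained, 0)
  expect_true(ev$tpr >= 0 && ev$tpr <= 1)
  expect_true(ev$kappa_max >= -1 && ev$kappa_max <= 1)
  one_class <- test[test$presence == 1, ]
  expect_error(evaluate(fit, one_class), "single class")
})

test_that("QC filter drops only models far below the mean", {
  base <- data.frame(species_id = sprintf("s%d", 1:10),
                     auc = rep(0.9, 10), deviance_explained = rep(0.5, 10))
  # identical metrics: SD = 0 edge, keep all
  expect_true(all(model_qc_filter(base)$keep))
  # one far-below outlier on AUC is dropped (> 2 SD below the mean of
  # nine tightly clustered good models plus itself)
  set.seed(8)
  out <- base
  out$auc <- c(0.9 + rnorm(9, 0, 0.01), 0.3)
  expect_lt(out$auc[10], mean(out$auc) - 2 * sd(out$auc))
  got <- model_qc_filter(out)
  expect_false(got$keep[10])
  expect_true(all(got$keep[1:9]))
  # flags invariant to row order
  perm <- sample(nrow(out))
  got2 <- model_qc_filter(out[perm, ])
  expect_equal(got2$keep, got$keep[perm])
  expect_error(model_qc_filter(base[1:2, ]), "at least 3")
})
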