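bio_fixture <- function() compute_bioclim(tiny_climate())

test_that("species generation is reproducible and respects the mix", {
  b <- bio_fixture()
  s1 <- make_species(12, bioclim = b, seed = 4)
  s2 <- make_species(12, bioclim = b, seed = 4)
  expect_identical(s1, s2)
  expect_equal(table(vapply(s1, `[[`, "", "archetype")),
               table(rep(c("shrinker", "shifter", "stable"), 4)))

  # all-stable mix -> every species has the broad configured breadth
  st <- make_species(6, archetype_mix = c(shrinker = 0, shifter = 0,
                                          stable = 1),
                     bioclim = b, seed = 4, sigma_stable = c(5, 7))
  expect_true(all(vapply(st, function(x) x$sigma[["bio01"]] >= 5, TRUE)))

  expect_error(make_species(0, bioclim = b), "n_species")
  expect_error(make_species(5, archetype_mix = c(shrinker = 0.7, shifter = 0.7,
                                                 stable = 0),
                            bioclim = b), "sum to 1")
})

test_that("true suitability is the product-Gaussian closed form", {
  b <- bio_fixture()
  sp <- make_species(1, bioclim = b, seed = 4)[[1]]
  # single-variable hand evaluation at 3 probe cells
  s <- true_suitability(sp, b)
  x <- b[, , "bio01"]
  for (cell in list(c(1, 1), c(10, 5), c(20, 20))) {
    expected <- sp$p_max *
      exp(-(x[cell[1], cell[2]] - sp$mu[["bio01"]])^2 /
            (2 * sp$sigma[["bio01"]]^2))
    expect_equal(s$values[cell[1], cell[2]], expected, tolerance = 1e-12)
  }
  # peak equals p_max where x = mu; far from mu suitability vanishes
  niche_flat <- sp; niche_flat$mu[["bio01"]] <- x[3, 3]
  expect_equal(true_suitability(niche_flat, b)$values[3, 3], sp$p_max)
  niche_far <- sp; niche_far$mu[["bio01"]] <- 1e6
  expect_true(all(true_suitability(niche_far, b)$values < 1e-10))

  # missing niche variable is named
  niche_bad <- sp; names(niche_bad$mu) <- names(niche_bad$sigma) <- "bio99"
  expect_error(true_suitability(niche_bad, b), "bio99")
})

test_that("shrinker truth ranges lose most cells under 2050 warming", {
  b <- bio_fixture()
  sh <- make_species(6, archetype_mix = c(shrinker = 1, shifter = 0,
                                          stable = 0),
                     bioclim = b, seed = 8)
  cl <- tiny_climate()
  for (sc in c("A2", "A1B", "B2")) {
    fb <- compute_bioclim(make_future_climate(cl, sc, "2050",
                                              gcm_jitter_sd = 0))
    for (niche in sh) {
      thr <- niche$p_max / 2
      cur <- binarize(true_suitability(niche, b), thr)
      fut <- binarize(true_suitability(niche, fb), thr)
      expect_gt(1 - stability(cur, fut), 0.5)
    }
  }
})

test_that("occurrence sampling follows the detection model", {
  l <- tiny_landscape()
  b <- compute_bioclim(tiny_climate(l))
  design <- make_survey_design(l, n_sites = 50, years = 2000:2001, seed = 5)

  zero <- suitability_surface(matrix(0, l$ny, l$nx), "spZ", "nonbreeding")
  occ0 <- sample_occurrences(zero, design, seed = 1)
  expect_true(all(occ0$presence == 0))

  one <- suitability_surface(matrix(1, l$ny, l$nx), "spO", "nonbreeding")
  occ_nodetect <- sample_occurrences(one, design, detect_beta = 0, seed = 1)
  expect_true(all(occ_nodetect$presence == 0))

  # seasons carry the applicable covariate only
  expect_true(all(!is.na(occ0$effort_hours)) && all(is.na(occ0$ordinal_date)))
  breed <- suitability_surface(matrix(0.5, l$ny, l$nx), "spB", "breeding")
  occb <- sample_occurrences(breed, design, seed = 1)
  expect_true(all(is.na(occb$effort_hours)) && all(!is.na(occb$ordinal_date)))

  expect_error(sample_occurrences(one, design, detect_beta = -1), "detect_beta")
})

test_that("empirical detection matches the saturating closed form", {
  l <- tiny_landscape()
  beta <- 0.25; h <- 6
  design <- make_survey_design(l, n_sites = 100, years = 2000:2001, seed = 5)
  design$visits$effort_hours <- h
  one <- suitability_surface(matrix(1, l$ny, l$nx), "spO", "nonbreeding")
  draws <- unlist(lapply(1:50, function(k)
    sample_occurrences(one, design, detect_beta = beta, seed = k)$presence))
  p_true <- 1 - exp(-beta * h)
  se <- sqrt(p_true * (1 - p_true) / length(draws))
  expect_lt(abs(mean(draws) - p_true), 3 * se)
  expect_gt(length(draws), 9999)
})

test_that("expected detection is monotone in effort", {
  for (beta in c(0.05, 0.25, 1)) {
    h <- seq(0.5, 40, length.out = 50)
    p <- 1 - exp(-beta * h)
    expect_true(all(diff(p) >= 0))
  }
})

test_that("truth table is self-consistent with the classifier", {
  l <- tiny_landscape()
  cl <- tiny_climate(l)
  b <- compute_bioclim(cl)
  sp <- make_species(9, bioclim = b, seed = 6, n_introduced = 1,
                     n_marginal = 1)
  futs <- list()
  for (sc in c("A2", "A1B", "B2")) for (pd in c("2050", "2080"))
    futs[[paste(sc, pd)]] <- compute_bioclim(
      make_future_climate(cl, sc, pd, gcm_jitter_sd = 0))
  tt <- truth_table(sp, b, futs)
  # reclassifying the truth metrics reproduces the recorded categories
  for (i in seq_along(sp)) {
    niche <- sp[[i]]
    m <- tt$metrics[tt$metrics$species_id == niche$species_id, ]
    rec <- sensitivity_record(niche$species_id, niche$season, m,
                              introduced = niche$introduced,
                              marginal = niche$marginal)
    expect_identical(classify(rec),
                     tt$categories$category[tt$categories$species_id ==
                                              niche$species_id])
  }
  # flags force the "other" category
  expect_true(all(tt$categories$category[tt$categories$introduced |
                                           tt$categories$marginal] == "other"))
})
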