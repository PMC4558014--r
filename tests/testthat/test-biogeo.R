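test_that("weighted centroids match the explicit weighted-sum oracle", {
  l <- tiny_landscape()
  # single-cell range -> that cell's attributes
  m <- matrix(0L, l$ny, l$nx); m[7, 9] <- 1L
  c1 <- weighted_centroid(range_map(m), l)
  expect_equal(c1$latitude, l$latitude[7])
  expect_equal(c1$elevation, l$elevation[7, 9])
  expect_equal(c1$dist_coast, l$dist_coast[7, 9])

  # two equal cells at two latitudes -> midpoint
  m2 <- matrix(0L, l$ny, l$nx); m2[3, 5] <- 1L; m2[11, 5] <- 1L
  expect_equal(weighted_centroid(range_map(m2), l)$latitude,
               mean(l$latitude[c(3, 11)]))

  # random 50-cell range vs naive sum(w_i x_i) loop
  set.seed(23)
  m3 <- matrix(0L, l$ny, l$nx); m3[sample(length(m3), 50)] <- 1L
  got <- weighted_centroid(range_map(m3), l)
  idx <- which(m3 == 1, arr.ind = TRUE)
  w <- 1 / nrow(idx)
  expect_equal(got$latitude, sum(w * l$latitude[idx[, 1]]), tolerance = 1e-12)
  expect_equal(got$elevation, sum(w * l$elevation[idx]), tolerance = 1e-12)
  expect_equal(got$dist_coast, sum(w * l$dist_coast[idx]), tolerance = 1e-12)

  # attribute bounds
  expect_true(got$latitude >= min(l$latitude) && got$latitude <= max(l$latitude))
  expect_error(weighted_centroid(range_map(matrix(0L, l$ny, l$nx)), l),
               "empty distribution")
})

test_that("suitability-weighted centroids lean toward high suitability", {
  l <- tiny_landscape()
  m <- matrix(0L, l$ny, l$nx); m[2, 3] <- 1L; m[18, 3] <- 1L
  s <- matrix(0.1, l$ny, l$nx); s[18, 3] <- 0.9
  w <- suitability_surface(s)
  got <- weighted_centroid(range_map(m), l, weights = w)
  expect_equal(got$latitude, (0.1 * l$latitude[2] + 0.9 * l$latitude[18]) / 1.0)
})

test_that("centroid shifts convert latitude to km at 111.32 km/deg", {
  a <- structure(list(latitude = 40, elevation = 100, dist_coast = 50),
                 class = "cs_centroid")
  b <- structure(list(latitude = 41, elevation = 130, dist_coast = 45),
                 class = "cs_centroid")
  d <- centroid_shift(a, b)
  expect_equal(d$dlat_km, 111.32)
  expect_equal(d$delev_m, 30)
  expect_equal(d$dcoast_km, -5)
  z <- centroid_shift(a, a)
  expect_equal(unlist(z), c(dlat_km = 0, delev_m = 0, dcoast_km = 0))
})

test_that("an engineered poleward cohort shows the expected mean shift", {
  l <- make_landscape(20, 40, cell_size = 10, seed = 2)
  shift_rows <- round(2 * 111.32 / l$cell_size)  # +2 degrees north
  set.seed(31)
  shifts <- sapply(1:12, function(k) {
    cur <- matrix(0L, l$ny, l$nx)
    r0 <- sample(3:8, 1); c0 <- sample(1:15, 1)
    cur[r0:(r0 + 3), c0:(c0 + 3)] <- 1L
    fut <- matrix(0L, l$ny, l$nx)
    fut[(r0 + shift_rows):(r0 + 3 + shift_rows), c0:(c0 + 3)] <- 1L
    centroid_shift(weighted_centroid(range_map(cur), l),
                   weighted_centroid(range_map(fut), l))$dlat_km
  })
  # each shift is exactly shift_rows cells; the mean is ~222.6 km up to
  # grid quantization (22 rows x 10 km = 220 km)
  expect_equal(mean(shifts), shift_rows * l$cell_size, tolerance = 1e-9)
  expect_lt(abs(mean(shifts) - 2 * 111.32), 5)
})

test_that("richness change satisfies the conservation identity", {
  set.seed(7)
  for (k in 1:20) {
    cur <- lapply(1:6, function(i) random_range(8, 8, runif(1, 0.2, 0.6),
                                                seed = k * 100 + i))
    fut <- lapply(1:6, function(i) random_range(8, 8, runif(1, 0.2, 0.6),
                                                seed = k * 100 + i + 50))
    cg <- richness_change(cur, fut)
    expect_true(all(cg$gain >= 0) && all(cg$loss >= 0))
    expect_equal(cg$richness_current - cg$loss + cg$gain, cg$richness_future)
  }
  # no change -> zero gain/loss; one species vacating one cell -> loss 1
  r <- random_range(5, 5, 0.5, seed = 1)
  same <- richness_change(list(r), list(r))
  expect_true(all(same$gain == 0) && all(same$loss == 0))
  r2 <- r; i <- which(r2$cells == 1)[1]; r2$cells[i] <- 0L
  one <- richness_change(list(r), list(r2))
  expect_equal(sum(one$loss), 1)
})

test_that("binary Bray-Curtis matches closed forms and vegan", {
  expect_equal(bray_curtis_cell(c("A", "B"), c("A", "B")), 0)
  expect_equal(bray_curtis_cell(c("A"), c("B")), 1)
  expect_equal(bray_curtis_cell(c("A", "B", "C"), c("B", "C", "D")), 1 / 3)
  expect_equal(bray_curtis_cell(character(0), character(0)), 0)
  # symmetry and bounds on random sets
  set.seed(11)
  for (k in 1:25) {
    a <- sample(letters, sample(0:10, 1))
    b <- sample(letters, sample(0:10, 1))
    d1 <- bray_curtis_cell(a, b); d2 <- bray_curtis_cell(b, a)
    expect_equal(d1, d2)
    expect_true(d1 >= 0 && d1 <= 1)
    # 1 - Sorensen identity via an independent implementation
    if (length(a) + length(b) > 0) {
      sor <- 2 * length(intersect(a, b)) / (length(unique(a)) +
                                              length(unique(b)))
      expect_equal(d1, 1 - sor)
    }
  }
  skip_if_not_installed("vegan")
  pool <- letters[1:12]
  for (k in 1:10) {
    set.seed(k)
    a <- sample(pool, sample(1:10, 1)); b <- sample(pool, sample(1:10, 1))
    mat <- rbind(as.integer(pool %in% a), as.integer(pool %in% b))
    expect_equal(bray_curtis_cell(a, b),
                 as.numeric(vegan::vegdist(mat, "bray", binary = TRUE)))
  }
})

test_that("dissimilarity maps match the per-cell loop oracle", {
  set.seed(9)
  cur <- lapply(1:5, function(i) random_range(6, 7, 0.4, seed = i))
  fut <- lapply(1:5, function(i) random_range(6, 7, 0.4, seed = i + 10))
  got <- dissimilarity_map(cur, fut)
  ids <- sprintf("sp%d", 1:5)
  for (i in 1:6) for (j in 1:7) {
    a <- ids[sapply(cur, function(r) r$cells[i, j] == 1)]
    b <- ids[sapply(fut, function(r) r$cells[i, j] == 1)]
    expect_equal(got$dissimilarity[i, j], bray_curtis_cell(a, b))
  }
  # no change anywhere -> mean 0; complete turnover -> mean 1
  expect_equal(dissimilarity_map(cur, cur)$mean, 0)
  inv <- lapply(cur, function(r) range_map(1L - r$cells))
  expect_equal(dissimilarity_map(cur, inv)$mean, 1)
})
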