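# Shared small fixtures, built once per test run.

tiny_landscape <- function(nx = 20, ny = 20, seed = 11) {
  make_landscape(nx, ny, cell_size = 10, seed = seed)
}

tiny_climate <- function(landscape = tiny_landscape(), seed = 12, ...) {
  make_baseline_climate(landscape, seed = seed, ...)
}

# constant-climate monthly stack for closed-form bioclim identities
constant_climate <- function(ny = 5, nx = 5, tmin = 10, tmax = 10, prec = 10) {
  monthly_climate(array(tmin, c(ny, nx, 12)),
                  array(tmax, c(ny, nx, 12)),
                  array(prec, c(ny, nx, 12)))
}

# brute-force bioclim for one cell: naive loops over months and quarters
bioclim_oracle_cell <- function(tmin, tmax, prec) {
  tavg <- (tmin + tmax) / 2
  quarters <- lapply(1:12, function(q) ((q - 1):(q + 1)) %% 12 + 1)
  qt <- sapply(quarters, function(m) mean(tavg[m]))
  qp <- sapply(quarters, function(m) sum(prec[m]))
  out <- numeric(19)
  out[1] <- mean(tavg)
  out[2] <- mean(tmax - tmin)
  out[4] <- sd(tavg) * 100
  out[5] <- max(tmax)
  out[6] <- min(tmin)
  out[7] <- out[5] - out[6]
  out[3] <- if (out[7] > 0) out[2] / out[7] * 100 else 0
  out[8] <- qt[which.max(qp)]
  out[9] <- qt[which.min(qp)]
  out[10] <- max(qt)
  out[11] <- min(qt)
  out[12] <- sum(prec)
  out[13] <- max(prec)
  out[14] <- min(prec)
  out[15] <- sd(prec) / (mean(prec) + 1) * 100
  out[16] <- max(qp)
  out[17] <- min(qp)
  out[18] <- qp[which.max(qt)]
  out[19] <- qp[which.min(qt)]
  out
}

# small random binary range on a given grid
random_range <- function(ny, nx, p = 0.3, seed = 1) {
  set.seed(seed)
  range_map(matrix(rbinom(ny * nx, 1, p), ny, nx))
}

# quick sensitivity record from per-scenario loss/expansion vectors
rec_from <- function(l2050, e2050, l2080, e2080 = rep(0.1, 3),
                     introduced = FALSE, marginal = FALSE,
                     species = "spX", season = "breeding") {
  m <- rbind(
    data.frame(scenario = c("A2", "A1B", "B2"), period = "2050",
               loss = l2050, expansion = e2050),
    data.frame(scenario = c("A2", "A1B", "B2"), period = "2080",
               loss = l2080, expansion = e2080))
  sensitivity_record(species, season, m, introduced = introduced,
                     marginal = marginal)
}

# a separable toy model frame with a monotone response in one covariate
toy_frame <- function(n = 300, seed = 42, noise = 0) {
  set.seed(seed)
  x <- runif(n, -2, 2)
  p <- plogis(3 * x + rnorm(n, 0, noise))
  data.frame(species_id = "toy", season = "nonbreeding", year = 2000,
             site_id = sprintf("s%d", seq_len(n)),
             presence = rbinom(n, 1, p), x = x,
             effort_hours = rep(8, n))
}
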