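# Internal helpers shared across modules.

# Smooth mean-zero Gaussian random field on an ny x nx grid.
# White noise convolved with a separable Gaussian kernel (reflection
# padding), then rescaled to the requested marginal sd. range_cells is
# the kernel sd in cell units and controls spatial autocorrelation.
gaussian_field <- function(ny, nx, range_cells = 8, sd = 1) {
  stopifnot(ny >= 1, nx >= 1, range_cells > 0)
  half <- max(1L, as.integer(ceiling(3 * range_cells)))
  k <- stats::dnorm(seq(-half, half), sd = range_cells)
  k <- k / sum(k)
  z <- matrix(stats::rnorm(ny * nx), ny, nx)
  z <- apply(z, 2, smooth_1d, kernel = k)              # along rows (y)
  z <- t(apply(z, 1, smooth_1d, kernel = k))           # along cols (x)
  z <- z - mean(z)
  s <- stats::sd(z)
  if (s > 0) z <- z * (sd / s)
  z
}

smooth_1d <- function(x, kernel) {
  half <- (length(kernel) - 1L) / 2L
  # reflect-pad so edges keep comparable variance
  xp <- c(rev(x[seq_len(min(half, length(x)))]),
          x,
          rev(x[seq.int(max(1L, length(x) - half + 1L), length(x))]))
  # pad further with edge values if the series is shorter than the kernel
  while (length(xp) < length(x) + 2L * half) xp <- c(xp[1L], xp, xp[length(xp)])
  out <- stats::filter(xp, kernel, sides = 2)
  as.numeric(out[(half + 1L):(half + length(x))])
}

# Map point coordinates (km) to cell row/col indices; cells are
# cell_size x cell_size with cell (1,1) covering [0, cs) x [0, cs).
point_to_cell <- function(x, y, nx, ny, cell_size) {
  col <- pmin(pmax(ceiling(x / cell_size), 1L), nx)
  row <- pmin(pmax(ceiling(y / cell_size), 1L), ny)
  ok <- x >= 0 & x <= nx * cell_size & y >= 0 & y <= ny * cell_size
  list(row = as.integer(row), col = as.integer(col), inside = ok)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_climsens <- function(fmt, ..., class = "climsens_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "climsens_error",
                                                   "error", "condition")))
}

# Run an expression with a locally scoped RNG seed, restoring the
# caller's RNG state afterwards (keeps module seeding independent).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}
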