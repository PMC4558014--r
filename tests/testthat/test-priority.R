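test_that("rank assignment follows the published rank rules", {
  st <- data.frame(species_id = c("a", "b", "c", "d"),
                   climate_category = c("endangered", "threatened", "stable",
                                        "other"),
                   fed_bcc = c("FED", "BCC", "none", "none"),
                   iucn = c("EN", "VU", "LC", "least_concern"),
                   pif = c(18, 12, 7, NA))
  r <- assign_ranks(st)
  expect_equal(r$climate_rank, c(1, 2, 3, NA))  # stable gets the highest rank
  expect_equal(r$fed_bcc_rank, c(1, 2, 3, 3))   # federally listed = 1
  expect_equal(r$iucn_rank, c(1, 2, 3, 3))      # least concern = 3
  # PIF scores are negated so low rank = high threat in every scheme
  expect_equal(order(r$pif_rank[1:3]), order(-st$pif[1:3]))
  expect_true(is.na(r$pif_rank[4]))
  bad <- data.frame(species_id = "x", iucn = "mystery")
  expect_error(assign_ranks(bad), "mystery")
})

test_that("kendall tau matches the exhaustive pair-counting oracle", {
  tau_oracle <- function(x, y) {
    n <- length(x); C <- 0; D <- 0; tx <- 0; ty <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      sx <- sign(x[j] - x[i]); sy <- sign(y[j] - y[i])
      if (sx == 0 && sy == 0) next
      if (sx == 0) tx <- tx + 1
      else if (sy == 0) ty <- ty + 1
      else if (sx == sy) C <- C + 1
      else D <- D + 1
    }
    n0 <- n * (n - 1) / 2
    tie <- function(v) { t <- table(v); sum(t * (t - 1) / 2) }
    (C - D) / sqrt((n0 - tie(x)) * (n0 - tie(y)))
  }
  expect_equal(kendall_tau(1:4, 1:4)$tau, 1)
  expect_equal(kendall_tau(1:4, 4:1)$tau, -1)
  x <- c(1, 1, 2, 3); y <- c(1, 2, 2, 3)
  expect_equal(kendall_tau(x, y)$tau, tau_oracle(x, y))
  set.seed(15)
  for (k in 1:10) {
    n <- sample(10:200, 1)
    x <- sample(1:3, n, TRUE)  # heavily tied 3-level ordinals
    y <- sample(1:5, n, TRUE)
    got <- kendall_tau(x, y)
    expect_equal(got$tau, tau_oracle(x, y), tolerance = 1e-12)
    # independent cross-check against the base-R implementation
    expect_equal(got$tau, unname(cor(x, y, method = "kendall")),
                 tolerance = 1e-12)
    ct <- suppressWarnings(cor.test(x, y, method = "kendall"))
    expect_equal(got$p_value, ct$p.value, tolerance = 1e-9)
  }
  # pairwise-complete handling and degenerate input
  expect_equal(kendall_tau(c(1, 2, 3, NA, 5), c(2, 1, 3, 4, NA))$n, 3)
  expect_error(kendall_tau(rep(1, 5), 1:5), "tied")
  expect_error(kendall_tau(1:2, 1:2), "at least 3")
})

test_that("variance components recover simulated ground truth", {
  # one factor, sigma2_factor = sigma2_residual = 1 -> 0.5 / 0.5
  set.seed(19)
  g <- 200; m <- 50
  eff <- rnorm(g)
  y <- rep(eff, each = m) + rnorm(g * m)
  vc <- variance_components(y, data.frame(grp = rep(seq_len(g), each = m)))
  expect_lt(abs(vc$proportion[vc$term == "grp"] - 0.5), 0.05)
  expect_lt(abs(vc$proportion[vc$term == "residual"] - 0.5), 0.05)
  expect_equal(sum(vc$proportion), 1, tolerance = 1e-9)

  # two crossed factors with variance ratio 4:1 and tiny residual
  set.seed(20)
  a <- rnorm(60, 0, 2); b <- rnorm(60, 0, 1)
  d <- expand.grid(a = seq_len(60), b = seq_len(60))
  y2 <- a[d$a] + b[d$b] + rnorm(nrow(d), 0, 0.05)
  vc2 <- variance_components(y2, data.frame(fa = d$a, fb = d$b))
  expect_lt(abs(vc2$proportion[vc2$term == "fa"] - 0.8), 0.05)
  expect_lt(abs(vc2$proportion[vc2$term == "fb"] - 0.2), 0.05)
})

test_that("variance components handle degenerate inputs", {
  # constant response -> all zero, residual 1
  vc <- variance_components(rep(3, 40), data.frame(g = rep(1:4, 10)))
  expect_true(all(vc$proportion[vc$term != "residual"] == 0))
  expect_equal(vc$proportion[vc$term == "residual"], 1)
  # single-level factor dropped with a warning
  expect_warning(
    vc2 <- variance_components(rnorm(40),
                               data.frame(g = rep(1:4, 10), flat = 1)),
    "flat")
  expect_false("flat" %in% vc2$term)
  # proportions sum to 1 and are invariant to observation order
  set.seed(2)
  y <- rnorm(120); f <- data.frame(g = rep(1:6, 20))
  vcA <- variance_components(y, f)
  perm <- sample(120)
  vcB <- variance_components(y[perm], data.frame(g = f$g[perm]))
  expect_equal(vcA$proportion, vcB$proportion, tolerance = 1e-6)
  expect_equal(sum(vcA$proportion), 1, tolerance = 1e-9)
})

test_that("REML matches the ANOVA estimator on a balanced one-factor design", {
  set.seed(27)
  g <- 30; m <- 8
  sig_a <- 1.3; sig_e <- 0.7
  y <- rep(rnorm(g, 0, sig_a), each = m) + rnorm(g * m, 0, sig_e)
  f <- rep(seq_len(g), each = m)
  vc <- variance_components(y, data.frame(grp = f))
  # closed-form method-of-moments (expected mean squares)
  fit <- stats::aov(y ~ Error(factor(f)))
  ms <- sapply(summary(fit), function(s) s[[1]]$`Mean Sq`[1])
  msa <- ms[[1]]; mse <- ms[[2]]
  sa2 <- max((msa - mse) / m, 0)
  # balanced design: REML equals the ANOVA estimator
  expect_equal(vc$variance[vc$term == "grp"], sa2, tolerance = 1e-6)
  expect_equal(vc$variance[vc$term == "residual"], mse, tolerance = 1e-6)
})

test_that("relative change in range size is exact arithmetic", {
  expect_equal(relative_change(100, 100), 0)
  expect_equal(relative_change(100, 0), -1)
  expect_equal(relative_change(100, 150), 0.5)
  expect_error(relative_change(0, 10), "positive")
})
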