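exp_points <- function(A, lam, d = seq(25, 375, by = 50))
  data.frame(d_um = d, density = A * exp(-lam * d),
             band_lo_um = d - 25, band_hi_um = d + 25)

test_that("exponential fit recovers exact model points to 1e-6 relative", {
  pts <- exp_points(100, 0.01)
  f <- fit_exponential_decay(pts)
  expect_lt(abs(f$estimates["A"] - 100) / 100, 1e-6)
  expect_lt(abs(f$estimates["lambda"] - 0.01) / 0.01, 1e-6)
  expect_lt(f$rss, 1e-8)
  expect_error(fit_exponential_decay(pts[1:2, ]), ">= 3 points")
})

test_that("constant densities give a boundary (flat) exponential fit", {
  pts <- data.frame(d_um = seq(25, 225, 50), density = rep(50, 5))
  f <- fit_exponential_decay(pts)
  expect_lt(abs(f$estimates["lambda"]), 1e-8)
  expect_true(f$boundary_flat)
})

test_that("linear fit: exact line, closed-form normal equations, input contracts", {
  d <- seq(25, 225, 50)
  pts <- data.frame(d_um = d, density = 5 - 0.02 * d)
  f <- suppressWarnings(fit_linear(pts))
  expect_equal(unname(f$estimates["a"]), 5)
  expect_equal(unname(f$estimates["b"]), -0.02)
  expect_lt(f$rss, 1e-20)

  set.seed(3)
  for (k in 1:5) {
    x <- runif(7) * 100; y <- rnorm(7, 10 - 0.05 * x, 2)
    fk <- fit_linear(data.frame(d_um = x, density = y))
    X <- cbind(1, x)
    beta <- solve(t(X) %*% X, t(X) %*% y)   # closed-form normal equations
    expect_equal(unname(fk$estimates), as.numeric(beta), tolerance = 1e-10)
  }
  expect_error(fit_linear(pts[1:2, ]), ">= 3")
  expect_error(fit_linear(data.frame(d_um = rep(1, 4), density = 1:4)),
               "zero variance")
})

test_that("exponential and log-linear fits agree exactly on noiseless model points", {
  pts <- exp_points(2000, 0.008)
  fe <- fit_exponential_decay(pts)
  lg <- log_transform_profile(pts, depth_um = 400)
  slope <- coef(lm(log_density ~ d_um, data = lg))[2]
  expect_equal(unname(fe$estimates["lambda"]), -unname(slope), tolerance = 1e-7)
})

test_that("log transform: ln values, capsule restriction, zero-band exclusion", {
  pts <- data.frame(d_um = c(25, 75, 125), density = c(exp(-2), 1, 0),
                    band_lo_um = c(0, 50, 100), band_hi_um = c(50, 100, 150))
  lt <- suppressMessages(log_transform_profile(pts, depth_um = 150))
  expect_equal(lt$log_density[1], -2)
  expect_equal(nrow(lt), 2)                 # zero-density band excluded
  expect_equal(attr(lt, "n_dropped"), 1L)

  # D = 250 with w = 50 keeps exactly the 5 capsule bands
  pts2 <- exp_points(100, 0.01)             # bands up to 400 um
  lt2 <- log_transform_profile(pts2, depth_um = 250)
  expect_equal(nrow(lt2), 5)
  expect_error(log_transform_profile(
    data.frame(d_um = c(25, 75, 125), density = 0,
               band_lo_um = c(0, 50, 100), band_hi_um = c(50, 100, 150)), 150),
    "zero or absent")
})

test_that("compare_slopes: identical groups null, interaction = slope difference", {
  set.seed(11)
  base <- data.frame(d_um = seq(25, 225, 50),
                     log_density = 5 - 0.01 * seq(25, 225, 50) + rnorm(5, 0, 0.1))
  cmp0 <- compare_slopes(base, base)
  expect_equal(cmp0$delta, 0, tolerance = 1e-12)
  expect_equal(cmp0$p_interaction, 1, tolerance = 1e-9)

  for (k in 1:5) {
    a <- data.frame(d_um = seq(25, 225, 50), log_density = rnorm(5))
    b <- data.frame(d_um = seq(25, 225, 50), log_density = rnorm(5))
    cmp <- compare_slopes(a, b)
    sa <- coef(lm(log_density ~ d_um, a))[2]
    sb <- coef(lm(log_density ~ d_um, b))[2]
    expect_equal(cmp$delta, unname(sb - sa), tolerance = 1e-10)
    expect_identical(unname(cmp$slopes), unname(c(sa, sb)))
  }
  expect_error(compare_slopes(base[1:2, ], base), ">= 3")
})

test_that("pooled-interaction p is close to the Welch-style two-fit comparison", {
  # balanced design, equal noise: the two test constructions should agree
  # closely (documented tolerance 0.05 on the p scale)
  set.seed(23)
  d <- seq(25, 225, 50)
  a <- data.frame(d_um = d, log_density = 6 - 0.012 * d + rnorm(5, 0, 0.15))
  b <- data.frame(d_um = d, log_density = 6 - 0.002 * d + rnorm(5, 0, 0.15))
  cmp <- compare_slopes(a, b)
  se_a <- summary(lm(log_density ~ d_um, a))$coefficients[2, 2]
  se_b <- summary(lm(log_density ~ d_um, b))$coefficients[2, 2]
  tw <- cmp$delta / sqrt(se_a^2 + se_b^2)
  df_w <- (se_a^2 + se_b^2)^2 / (se_a^4 / 3 + se_b^4 / 3)
  p_welch <- 2 * pt(-abs(tw), df_w)
  expect_lt(abs(cmp$p_interaction - p_welch), 0.05)
})

test_that("grubbs screen: constant data, single outlier, two-sided double outliers", {
  const <- suppressMessages(grubbs_screen(rep(5, 8)))
  expect_equal(length(const$removed_idx), 0)

  x <- c(1, 1, 1, 1, 1, 1, 1, 100)
  g <- grubbs_screen(x, alpha = 0.05)
  # independent evaluation of G and the critical-value formula
  G_oracle <- max(abs(x - mean(x))) / sd(x)
  n <- 8; t <- qt(1 - 0.05 / (2 * n), n - 2)
  Gc_oracle <- (n - 1) / sqrt(n) * sqrt(t^2 / (n - 2 + t^2))
  expect_gt(G_oracle, Gc_oracle)
  expect_equal(g$iterations$G[1], G_oracle)
  expect_equal(g$iterations$G_crit[1], Gc_oracle)
  expect_equal(g$removed_idx, 8)
  expect_equal(g$retained, rep(1, 7))

  # planted extremes on opposite tails, removed in order of |x - mean|
  y <- c(10.1, 9.9, 10.0, 10.2, 9.8, 10.1, 9.9, 10.0, 50, -40)
  g2 <- grubbs_screen(y, alpha = 0.05)
  expect_setequal(g2$removed_idx, c(9, 10))
  # step-by-step hand run: mean(y) = 8.0 -> |-40 - 8| > |50 - 8|: -40 first
  expect_equal(g2$iterations$index[1:2], c(10, 9))
  expect_error(grubbs_screen(c(1, 2)), "N >= 3")
  expect_error(grubbs_screen(1:10, alpha = 0.7), "alpha")
})

test_that("grubbs removal set is permutation invariant", {
  set.seed(77)
  y <- c(rnorm(12), 9, -8)
  base <- sort(grubbs_screen(y)$retained)
  for (k in 1:5) {
    p <- sample(length(y))
    expect_equal(sort(grubbs_screen(y[p])$retained), base)
  }
})

test_that("flat-line test and slope comparison hold their nominal level (quick check)", {
  # smaller companion to the acceptance-grade 500-sim calibration run
  areas_mm2 <- pi * ((1000 - seq(0, 350, 50))^2 - (1000 - seq(50, 400, 50))^2) / 1e6
  mids <- seq(25, 375, 50)
  set.seed(301)
  n_sim <- 150; rej <- 0
  for (s in seq_len(n_sim)) {
    dens <- rpois(8, 500 * areas_mm2 * 8) / (areas_mm2 * 8)
    f <- fit_linear(data.frame(d_um = mids, density = dens))
    rej <- rej + (f$p_slope_zero < 0.05)
  }
  expect_gt(rej / n_sim, 0.01)
  expect_lt(rej / n_sim, 0.11)
})
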