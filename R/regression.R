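#' Fit an exponential-decay model to a radial density profile
#'
#' Nonlinear least squares of `density = A * exp(-lambda * d)`, initialized
#' from the log-linear OLS fit of the positive-density points. A
#' non-converging fit is an explicit failure (error), never a silent
#' fallback. When the data carry no decay (lambda indistinguishable from 0)
#' the fit is flagged as a boundary/flat fit rather than rejected.
#'
#' @param points data.frame with columns `d_um` (band midpoint, um) and
#'   `density` (cells/mm^2); >= 3 points required
#' @return a `DecayFit` with model `"exponential"`: estimates A (cells/mm^2)
#'   and lambda (per um), SEs, 95% CIs, df, RSS, R2, convergence info and
#'   `boundary_flat` flag
#' @export
fit_exponential_decay <- function(points) {
  points <- points[is.finite(points$density), ]
  n <- nrow(points)
  if (n < 3) stopf("exponential fit needs >= 3 points, got %d", n)
  pos <- points[points$density > 0, ]
  if (nrow(pos) < 2) stopf("exponential fit needs >= 2 positive densities")
  init <- coef(lm(log(density) ~ d_um, data = pos))
  start <- list(A = exp(unname(init[1])), lambda = max(0, -unname(init[2])))
  df <- n - 2L
  tcrit <- qt(0.975, df)
  tss <- sum((points$density - mean(points$density))^2)
  # nls cannot iterate on zero-residual data; when the log-linear start
  # already fits to machine precision (noiseless model points, constant
  # profiles) the start IS the least-squares solution
  rss0 <- sum((points$density - start$A * exp(-start$lambda * points$d_um))^2)
  if (rss0 <= 1e-16 * max(1, sum(points$density^2))) {
    est <- c(A = start$A, lambda = start$lambda)
    se <- c(A = 0, lambda = 0)
    rss <- rss0
  } else {
    fit <- tryCatch(
      nls(density ~ A * exp(-lambda * d_um), data = points, start = start,
          control = list(maxiter = 200, warnOnly = FALSE)),
      error = function(e) stopf("exponential fit did not converge: %s",
                                conditionMessage(e)))
    est <- coef(fit)
    se <- summary(fit)$coefficients[, "Std. Error"]
    rss <- sum(residuals(fit)^2)
  }
  lam_ci <- est["lambda"] + c(-1, 1) * tcrit * se["lambda"]
  structure(list(model = "exponential",
                 estimates = c(A = unname(est["A"]), lambda = unname(est["lambda"])),
                 se = c(A = unname(se["A"]), lambda = unname(se["lambda"])),
                 ci = list(A = unname(est["A"] + c(-1, 1) * tcrit * se["A"]),
                           lambda = unname(lam_ci)),
                 df = df, rss = rss,
                 r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
                 converged = TRUE,
                 boundary_flat = unname(lam_ci[1] <= 1e-10),
                 n = n), class = "DecayFit")
}

#' Fit a linear model to a radial density profile (flat-line test)
#'
#' Ordinary least squares `density = a + b * d`; `p_slope_zero` is the
#' two-sided t-test of b = 0 - the "is the profile different from a flat
#' line" test. Unweighted by design (band-area weighting is an explicit
#' option of the pipeline layer, logged when used).
#'
#' @param points data.frame with `d_um`, `density`; >= 3 points
#' @return a `DecayFit` with model `"linear"`: a (intercept), b (slope),
#'   SEs, CIs, `p_slope_zero`, df, RSS, R2
#' @export
fit_linear <- function(points) {
  points <- points[is.finite(points$density), ]
  n <- nrow(points)
  if (n < 3) stopf("linear fit needs >= 3 points, got %d", n)
  if (length(unique(points$d_um)) < 2) stopf("zero variance in d: cannot fit a slope")
  fit <- lm(density ~ d_um, data = points)
  sm <- summary(fit)
  est <- coef(fit)
  se <- sm$coefficients[, "Std. Error"]
  df <- fit$df.residual
  tcrit <- qt(0.975, df)
  structure(list(model = "linear",
                 estimates = c(a = unname(est[1]), b = unname(est[2])),
                 se = c(a = unname(se[1]), b = unname(se[2])),
                 ci = list(a = unname(est[1] + c(-1, 1) * tcrit * se[1]),
                           b = unname(est[2] + c(-1, 1) * tcrit * se[2])),
                 df = df,
                 p_slope_zero = unname(sm$coefficients[2, "Pr(>|t|)"]),
                 rss = sum(residuals(fit)^2),
                 r_squared = sm$r.squared,
                 converged = TRUE, n = n), class = "DecayFit")
}

#' @export
print.DecayFit <- function(x, ...) {
  cat(sprintf("DecayFit [%s], n = %d, df = %d\n", x$model, x$n, x$df))
  for (nm in names(x$estimates))
    cat(sprintf("  %s = %.6g (SE %.3g, 95%% CI %.6g..%.6g)\n", nm,
                x$estimates[nm], x$se[nm], x$ci[[nm]][1], x$ci[[nm]][2]))
  if (!is.null(x$p_slope_zero))
    cat(sprintf("  p(slope = 0) = %.4g\n", x$p_slope_zero))
  if (isTRUE(x$boundary_flat))
    cat("  boundary fit: decay rate indistinguishable from 0 (flat)\n")
  invisible(x)
}

#' Natural-log transform of a profile restricted to the capsule depth
#'
#' Keeps the bands lying wholly inside `[0, D)` um from the outer border
#' (with band width w and D = 250 um that is exactly the first D/w bands),
#' drops zero/absent densities with a logged count (no pseudo-count: an
#' offset would change the slope under test), and returns `y = ln(density)`.
#'
#' @param points data.frame with `d_um`, `density` and band extents
#'   `band_lo_um`/`band_hi_um` (falls back to `d_um` < D when absent)
#' @param depth_um restriction depth D (default 250 um, the capsule width)
#' @return data.frame with `d_um`, `log_density`; attribute `n_dropped`
#' @export
log_transform_profile <- function(points, depth_um = 250) {
  if (depth_um <= 0) stopf("depth_um must be > 0")
  keep <- if (!is.null(points$band_hi_um)) points$band_hi_um <= depth_um
          else points$d_um < depth_um
  pts <- points[keep, ]
  ok <- is.finite(pts$density) & pts$density > 0
  n_dropped <- sum(!ok)
  if (n_dropped)
    tg_log("log_transform_profile: %d zero/absent density band(s) excluded", n_dropped)
  if (!any(ok)) stopf("all densities in [0, %g) um are zero or absent", depth_um)
  out <- data.frame(d_um = pts$d_um[ok], log_density = log(pts$density[ok]))
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Compare log-linear infiltration slopes between two groups
#'
#' Pooled OLS of `log density ~ distance * group`: the group-by-distance
#' interaction estimates the slope difference, and its t-test p-value is the
#' reported comparison. Per-group slopes from separate fits are also
#' returned; the interaction estimate equals their difference algebraically.
#'
#' @param points_a,points_b data.frames with `d_um` and `log_density`
#'   (output of [log_transform_profile()]); >= 3 points each
#' @param labels length-2 character vector naming the groups
#' @return a `SlopeComparison`: per-group slopes with SE, `delta` (slope
#'   difference) with SE, t, df, `p_interaction`
#' @export
compare_slopes <- function(points_a, points_b, labels = c("A", "B")) {
  if (nrow(points_a) < 3 || nrow(points_b) < 3)
    stopf("slope comparison needs >= 3 transformed points per group (got %d, %d)",
          nrow(points_a), nrow(points_b))
  dat <- rbind(data.frame(d = points_a$d_um, y = points_a$log_density, g = 0),
               data.frame(d = points_b$d_um, y = points_b$log_density, g = 1))
  fit <- lm(y ~ d * g, data = dat)
  sm <- summary(fit)$coefficients
  slope_a <- coef(lm(log_density ~ d_um, data = points_a))[2]
  slope_b <- coef(lm(log_density ~ d_um, data = points_b))[2]
  se_a <- summary(lm(log_density ~ d_um, data = points_a))$coefficients[2, 2]
  se_b <- summary(lm(log_density ~ d_um, data = points_b))$coefficients[2, 2]
  structure(list(labels = labels,
                 slopes = setNames(c(unname(slope_a), unname(slope_b)), labels),
                 slope_se = setNames(c(se_a, se_b), labels),
                 delta = unname(sm["d:g", "Estimate"]),
                 delta_se = sm["d:g", "Std. Error"],
                 t = sm["d:g", "t value"],
                 df = fit$df.residual,
                 p_interaction = sm["d:g", "Pr(>|t|)"]),
            class = "SlopeComparison")
}

#' @export
print.SlopeComparison <- function(x, ...) {
  cat(sprintf("SlopeComparison: %s slope %.5g (SE %.3g) vs %s slope %.5g (SE %.3g)\n",
              x$labels[1], x$slopes[1], x$slope_se[1],
              x$labels[2], x$slopes[2], x$slope_se[2]))
  cat(sprintf("  delta = %.5g (SE %.3g), t = %.3f, df = %d, p = %.4g\n",
              x$delta, x$delta_se, x$t, x$df, x$p_interaction))
  invisible(x)
}

# Two-sided Grubbs critical value for sample size N at level alpha.
grubbs_critical <- function(alpha, n) {
  t <- qt(1 - alpha / (2 * n), n - 2)
  (n - 1) / sqrt(n) * sqrt(t^2 / (n - 2 + t^2))
}

#' Iterative two-sided Grubbs outlier screen
#'
#' Repeatedly tests the most extreme point: while
#' `G = max|x - mean| / sd` exceeds the critical value
#' `G_crit = ((N-1)/sqrt(N)) * sqrt(t^2 / (N-2+t^2))` (t the upper
#' `alpha/(2N)` Student-t quantile with N-2 df), the extreme point is
#' removed and the test repeated on the remainder. Constant data (zero SD)
#' admits no declarable outlier.
#'
#' @param values numeric vector, N >= 3
#' @param alpha significance level in (0, 0.5); default 0.05 two-sided
#' @return a `GrubbsResult`: per-iteration table (index into the original
#'   vector, value, G, G_crit, removed), `retained` values, `removed_idx`
#' @export
grubbs_screen <- function(values, alpha = 0.05) {
  n0 <- length(values)
  if (n0 < 3) stopf("Grubbs screen needs N >= 3, got %d", n0)
  if (alpha <= 0 || alpha >= 0.5) stopf("alpha must be in (0, 0.5)")
  idx <- seq_len(n0)
  iterations <- data.frame(index = integer(0), value = numeric(0),
                           G = numeric(0), G_crit = numeric(0),
                           removed = logical(0))
  repeat {
    n <- length(idx)
    if (n < 3) break
    x <- values[idx]
    s <- sd(x)
    if (s == 0) {
      tg_log("grubbs_screen: zero sample SD, no outlier declarable")
      break
    }
    dev <- abs(x - mean(x))
    i_ext <- which.max(dev)
    G <- dev[i_ext] / s
    Gc <- grubbs_critical(alpha, n)
    rm <- G > Gc
    iterations <- rbind(iterations,
                        data.frame(index = idx[i_ext], value = x[i_ext],
                                   G = G, G_crit = Gc, removed = rm))
    if (!rm) break
    idx <- idx[-i_ext]
  }
  structure(list(iterations = iterations,
                 retained = values[idx],
                 retained_idx = idx,
                 removed_idx = setdiff(seq_len(n0), idx),
                 alpha = alpha), class = "GrubbsResult")
}

#' @export
print.GrubbsResult <- function(x, ...) {
  cat(sprintf("GrubbsResult (alpha = %g): %d removed, %d retained\n",
              x$alpha, length(x$removed_idx), length(x$retained)))
  if (nrow(x$iterations)) print(x$iterations)
  invisible(x)
}

#' @importFrom stats residuals
NULL
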