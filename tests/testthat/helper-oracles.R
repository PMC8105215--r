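# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Weighted least squares via stats::lm (independent of the package's
# normal-equation solver).
lm_wls_oracle <- function(x, y, w) {
  fit <- stats::lm(y ~ x, weights = w)
  list(m = unname(stats::coef(fit)[2]), b = unname(stats::coef(fit)[1]))
}

# Brute-force minimiser of the weighted SSE, started from a perturbed
# point; converges to the same optimum for a convex quadratic.
optim_wls_oracle <- function(x, y, w) {
  sse <- function(p) sum(w * (y - p[1] * x - p[2])^2)
  p0 <- c(stats::cov(x, y) / stats::var(x) + 0.3, mean(y) + 0.5)
  fit <- stats::optim(p0, sse, method = "BFGS",
                      control = list(reltol = 1e-15, maxit = 5000))
  list(m = fit$par[1], b = fit$par[2])
}

# AUC of the piecewise-linear interpolant by dense-grid trapezoid
# integration via stats::approx.
fine_grid_auc_oracle <- function(times, conc, t_start, t_end,
                                 n_grid = 200001L) {
  g <- seq(t_start, t_end, length.out = n_grid)
  # include the knots: trapezoids across a kink of the interpolant would
  # otherwise leave O(h^2) error
  g <- sort(unique(c(g, times[times >= t_start & times <= t_end])))
  cg <- stats::approx(times, conc, xout = g)$y
  sum(diff(g) * (head(cg, -1) + tail(cg, -1)) / 2)
}

# Closed-form OLS slope on (t, log c) for a hand check of the terminal fit.
hand_loglinear_slope <- function(t, c) {
  lc <- log(c)
  sum((t - mean(t)) * (lc - mean(lc))) / sum((t - mean(t))^2)
}

# A small synthetic profile builder for NCA tests.
profile_from <- function(time, conc) {
  build_profile(data.frame(time = time, conc = conc))
}
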