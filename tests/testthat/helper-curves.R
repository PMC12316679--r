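# Shared fixtures built in code.

# A 4D array wrapping a single signal curve.
curve_series <- function(signal, contrast = "GE", params = vai_acquisition()) {
  vai_series(array(signal, dim = c(1, 1, 1, length(signal))), contrast, params)
}

# Acquisition with a short series for curve-level unit tests.
short_acq <- function(n = 20L, injection = 9L) {
  vai_acquisition(n_dynamics = n, injection_dynamic = injection)
}

# Forward GE/SE tissue curve pair on the acquisition grid: gamma-variate AIF
# convolved with an exponential residue, SE from the 2/3-power law with lag.
make_tissue_curves <- function(params = vai_acquisition(), q = 0.39,
                               rcbv = 0.032, mtt = 5.5, tau = 0,
                               aif = gamma_variate_params(1, 14.4, 3, 2.5),
                               peak_dr2s = 10) {
  tg <- acquisition_times(params)
  dtf <- params$dt / 16
  tf <- seq(0, max(tg), by = dtf)
  ca <- gamma_variate(tf, aif$k, aif$t0, aif$alpha, aif$beta)
  ct <- (rcbv / mtt) *
    stats::convolve(ca, rev(exp(-tf / mtt)), type = "open")[seq_along(tf)] * dtf
  x_f <- pmax(ct, 0) / max(ct) * peak_dr2s
  x <- stats::approx(tf, x_f, xout = tg)$y
  xlag <- stats::approx(tf, x_f, xout = tg - tau, yleft = 0,
                        yright = x_f[length(x_f)])$y
  list(t = tg, dr2s = x, dr2 = q * xlag^(2 / 3))
}

# Default-phantom cache: generating once per test file is cheap (~1 s) but
# several files need it, so memoize within a session.
default_phantom_cached <- local({
  ph <- NULL
  function() {
    if (is.null(ph)) ph <<- generate_phantom(phantom_config())
    ph
  }
})

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual / expected - 1), tol)
}
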