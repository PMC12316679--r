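test_that("gamma-variate integral matches the closed form", {
  expect_equal(gamma_variate_integral(gamma_variate_params(1, 0, 0, 1)), 1)
  expect_equal(gamma_variate_integral(gamma_variate_params(1, 0, 1, 2)), 4)
  expect_equal(gamma_variate_integral(gamma_variate_params(1, 0, 2, 1)), 2)
  # oracle: numeric quadrature of the model on a fine grid
  p <- gamma_variate_params(2.3, 5, 2.7, 1.9)
  num <- stats::integrate(function(t) gamma_variate(t, p$k, p$t0, p$alpha, p$beta),
                          lower = p$t0, upper = Inf)$value
  expect_equal(gamma_variate_integral(p), num, tolerance = 1e-6)
})

test_that("gamma-variate fit recovers generating parameters", {
  tg <- seq(0, 158.4, by = 1.6)
  y <- gamma_variate(tg, k = 1, t0 = 8, alpha = 3, beta = 1.5)
  fit <- fit_gamma_variate(tg, y)
  expect_true(fit$converged)
  p <- fit$params
  expect_rel(p$k, 1, 0.01)
  expect_rel(p$t0, 8, 0.01)
  expect_rel(p$alpha, 3, 0.01)
  expect_rel(p$beta, 1.5, 0.01)

  expect_error(fit_gamma_variate(tg, rep(0, length(tg))), "no bolus")

  set.seed(3)
  yn <- y + stats::rnorm(length(y), 0, 0.01 * max(y))
  fitn <- fit_gamma_variate(tg, yn)
  expect_lt(fitn$sse, length(tg) * (0.03 * max(y))^2)
  expect_rel(fitn$params$alpha, 3, 0.05)
  expect_rel(fitn$params$beta, 1.5, 0.05)
})

test_that("AIF selection averages top-ranked arterial curves", {
  p <- vai_acquisition()
  tg <- acquisition_times(p)
  good <- gamma_variate(tg, 1, 14.4, 3, 1.5)
  late <- gamma_variate(tg, 1, 22.4, 3, 1.5)
  # single-voxel mask returns that curve
  arr1 <- array(good, dim = c(1, 1, 1, p$n_dynamics))
  a1 <- select_aif(arr1, array(TRUE, c(1, 1, 1)), p, n_aif = 1)
  expect_equal(a1$conc, good)
  # two identical curves average to themselves
  arr2 <- array(rep(good, each = 2), dim = c(2, 1, 1, p$n_dynamics))
  a2 <- select_aif(arr2, array(TRUE, c(2, 1, 1)), p, n_aif = 2)
  expect_equal(a2$conc, good)
  # 20 candidates, 5 delayed: ranking drops the late arrivals
  curves <- rbind(matrix(rep(good, each = 15), 15),
                  matrix(rep(late, each = 5), 5))
  arr20 <- array(curves, dim = c(20, 1, 1, p$n_dynamics))
  a20 <- select_aif(arr20, array(TRUE, c(20, 1, 1)), p, n_aif = 10)
  expect_true(all(a20$voxels <= 15))
  expect_error(select_aif(arr20, array(FALSE, c(20, 1, 1)), p), "empty")
  expect_warning(select_aif(arr2, array(TRUE, c(2, 1, 1)), p, n_aif = 5),
                 "candidates")
})

test_that("rCBV is the analytic integral ratio of tissue to AIF", {
  p <- vai_acquisition()
  tg <- acquisition_times(p)
  aif_curve <- gamma_variate(tg, 1, 14.4, 3, 1.5)
  arr <- array(aif_curve, dim = c(1, 1, 1, p$n_dynamics))
  aif <- select_aif(arr, array(TRUE, c(1, 1, 1)), p, n_aif = 1)
  # tissue identical to the AIF -> rCBV 1; half amplitude -> 0.5
  tis <- array(c(rbind(aif_curve, 0.5 * aif_curve)),
               dim = c(2, 1, 1, p$n_dynamics))
  r <- rcbv_map(tis, array(TRUE, c(2, 1, 1)), aif, p)
  expect_equal(as.vector(r), c(1, 0.5), tolerance = 1e-6)
})

test_that("NAWM anchoring rescales exactly and respects the sensitivity mode", {
  raw <- array(c(0.06, 0.07, 0.05, 0.01), c(4, 1, 1))
  nawm <- array(c(TRUE, TRUE, TRUE, FALSE), c(4, 1, 1))
  sc <- scale_aif_to_nawm(raw, nawm)
  expect_equal(sc$factor, 0.06 / 0.032)
  expect_equal(mean(sc$rcbv[nawm]), 0.032, tolerance = 1e-15)
  # raw mean already on target -> identity
  sc2 <- scale_aif_to_nawm(raw / sc$factor, nawm)
  expect_equal(sc2$factor, 1)
  # sensitivity mode leaves the map untouched
  off <- scale_aif_to_nawm(raw, nawm, enabled = FALSE)
  expect_identical(off$rcbv, raw)
  expect_error(scale_aif_to_nawm(raw, nawm & FALSE), "NAWM")
})

test_that("anchored rCBV is invariant to raw AIF amplitude", {
  p <- vai_acquisition()
  tg <- acquisition_times(p)
  base <- gamma_variate(tg, 1, 14.4, 3, 1.5)
  tis <- array(c(rbind(0.032 * base, 0.05 * base)),
               dim = c(2, 1, 1, p$n_dynamics))
  mask <- array(TRUE, c(2, 1, 1))
  nawm <- array(c(TRUE, FALSE), c(2, 1, 1))
  maps <- lapply(c(1, 7), function(amp) {
    arr <- array(amp * base, dim = c(1, 1, 1, p$n_dynamics))
    aif <- select_aif(arr, array(TRUE, c(1, 1, 1)), p, n_aif = 1)
    scale_aif_to_nawm(rcbv_map(tis, mask, aif, p), nawm)$rcbv
  })
  expect_equal(maps[[1]], maps[[2]], tolerance = 1e-6)
})

test_that("high-rCBV exclusion follows the 90th-percentile rule", {
  set.seed(5)
  vals <- sample(seq(0.001, 1, length.out = 1000))  # 1000 distinct values
  rc <- array(vals, c(1000, 1, 1))
  mask <- array(TRUE, c(1000, 1, 1))
  keep <- exclude_top_rcbv(rc, mask)
  expect_equal(sum(keep), 900L)
  expect_true(all(rc[!keep & mask] > rc[keep]))
  # all-equal values: nothing strictly above the percentile
  expect_equal(sum(exclude_top_rcbv(array(0.3, c(50, 1, 1)),
                                    array(TRUE, c(50, 1, 1)))), 50L)
  # values 1..10: only the top voxel leaves
  k10 <- exclude_top_rcbv(array(1:10, c(10, 1, 1)), array(TRUE, c(10, 1, 1)))
  expect_equal(which(!k10), 10L)
})

test_that("exclusion count is bounded for arbitrary inputs", {
  set.seed(9)
  for (r in 1:20) {
    n <- sample(5:400, 1)
    vals <- round(stats::runif(n), sample(1:3, 1))  # ties likely
    keep <- exclude_top_rcbv(array(vals, c(n, 1, 1)),
                             array(TRUE, c(n, 1, 1)))
    removed <- n - sum(keep)
    expect_gte(removed, 0)
    expect_lte(removed, ceiling(0.10 * n))
  }
})

test_that("oSVD deconvolution recovers flow and scales linearly", {
  dt <- 0.1
  tg <- seq(0, 50, by = dt)
  aif <- gamma_variate(tg, 1, 10, 3, 1.5)
  cbf_true <- 0.008; mtt <- 4
  tis <- cbf_true *
    stats::convolve(aif, rev(exp(-tg / mtt)), type = "open")[seq_along(tg)] * dt
  dec <- cbf_deconvolution(tis, aif, dt)
  expect_rel(dec$cbf, cbf_true, 0.10)
  # linearity: doubling the tissue curve doubles CBF
  dec2 <- cbf_deconvolution(2 * tis, aif, dt)
  expect_equal(dec2$cbf, 2 * dec$cbf, tolerance = 1e-8)
  # inverse scaling with AIF amplitude
  dec3 <- cbf_deconvolution(tis, 2 * aif, dt)
  expect_equal(dec3$cbf, dec$cbf / 2, tolerance = 1e-6)
  expect_equal(cbf_deconvolution(0 * tis, aif, dt)$cbf, 0)
  expect_error(cbf_deconvolution(tis, 0 * aif, dt), "degenerate")
})

test_that("SE-derived CBF stays below GE-derived CBF on the default phantom", {
  ph <- default_phantom_cached()
  res <- run_subject(ph, vai_config(compute_cbf = TRUE))
  ok <- res$maps$valid & is.finite(res$maps$cbf_ge) & is.finite(res$maps$cbf_se)
  expect_gt(sum(ok), 100)
  expect_true(all(res$maps$cbf_se[ok] <= res$maps$cbf_ge[ok] + 1e-12))
})
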