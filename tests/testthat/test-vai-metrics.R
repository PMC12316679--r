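test_that("Q follows dR2/(dR2*)^(2/3) on window means", {
  expect_equal(vessel_density_q(rep(1, 5), rep(1, 5)), 1)
  expect_equal(vessel_density_q(rep(2, 5), rep(8, 5)), 0.5)  # 2 / 8^(2/3)
  # exact whenever dR2 = c * (dR2*)^(2/3) and dR2* is constant
  x <- rep(6.5, 13)
  expect_equal(vessel_density_q(0.39 * x^(2 / 3), x), 0.39, tolerance = 1e-12)
  # invalid voxels: nonpositive means or missing values flag, not clip
  expect_true(is.na(vessel_density_q(c(1, NA, 1), c(1, 1, 1))))
  expect_true(is.na(vessel_density_q(rep(-1, 3), rep(1, 3))))
  expect_true(is.na(vessel_density_q(rep(1, 3), rep(-1, 3))))
})

test_that("Q estimator stays within 5% when dR2* varies by up to factor 2", {
  set.seed(7)
  for (r in 1:50) {
    lo <- stats::runif(1, 1, 5)
    x <- stats::runif(13, lo, 2 * lo)   # window variation <= factor 2
    q <- stats::runif(1, 0.2, 0.6)
    qhat <- vessel_density_q(q * x^(2 / 3), x)
    expect_lt(abs(qhat / q - 1), 0.05)
  }
})

test_that("alternative Q estimators agree on proportional curves", {
  x <- c(2, 4, 8, 6, 3)
  y <- 0.4 * x^(2 / 3)
  expect_equal(vessel_density_q(y, x, method = "pointwise"), 0.4,
               tolerance = 1e-12)
  expect_equal(vessel_density_q(y, x, method = "regression"), 0.4,
               tolerance = 1e-12)
})

test_that("VSI formula constant, worked value and power-law scaling", {
  expect_equal(vessel_size_index(1, 1, 1), 0.867)
  expect_equal(vessel_size_index(800, 0.032, 0.39),
               0.867 * sqrt(800 * 0.032) * 0.39^(-1.5))
  expect_equal(vessel_size_index(800, 0.032, 0.39), 18.0, tolerance = 0.005)
  # q -> 4q scales VSI by 1/8; d -> c^2 d scales VSI by c
  v1 <- vessel_size_index(500, 0.04, 0.3)
  expect_equal(vessel_size_index(500, 0.04, 4 * 0.3), v1 / 8)
  expect_equal(vessel_size_index(9 * 500, 0.04, 0.3), 3 * v1)
  expect_true(is.na(vessel_size_index(-1, 0.04, 0.3)))
  expect_true(is.na(vessel_size_index(500, 0, 0.3)))
})

test_that("MTI is the negated shoelace area with clockwise positive", {
  # unit square traversed (0,0)->(0,1)->(1,1)->(1,0) is clockwise in the
  # (dR2, dR2*) plane: MTI = +1
  x <- c(0, 0, 1, 1); y <- c(0, 1, 1, 0)
  expect_equal(mti_loop_area(x, y), 1)
  expect_equal(mti_loop_area(rev(x), rev(y)), -1)  # antisymmetry
  # collinear curves carry no hysteresis
  x2 <- c(1, 2, 3, 4, 3, 2)
  expect_equal(mti_loop_area(x2, 2 * x2), 0)
  expect_true(is.na(mti_loop_area(c(1, 2), c(1, 2))))
  expect_true(is.na(mti_loop_area(c(1, NA, 2), c(1, 2, 3))))
})

test_that("MTI is invariant under cyclic rotation and negates under reversal", {
  set.seed(11)
  for (r in 1:20) {
    n <- sample(5:13, 1)
    x <- stats::rnorm(n); y <- stats::rnorm(n)
    a <- mti_loop_area(x, y)
    k <- sample(n - 1, 1)
    rot <- c((k + 1):n, 1:k)
    expect_equal(mti_loop_area(x[rot], y[rot]), a, tolerance = 1e-12)
    expect_equal(mti_loop_area(rev(x), rev(y)), -a, tolerance = 1e-12)
  }
})

test_that("loop sign flips with the sign of the SE lag on bolus curves", {
  p <- vai_acquisition()
  for (tau in c(0.4, 0.8, 1.6)) {
    cp <- make_tissue_curves(p, tau = tau)
    cm <- make_tissue_curves(p, tau = -tau)
    pk <- find_bolus_peak(cp$dr2s, p$injection_dynamic)
    w <- first_pass_window(pk, p$n_dynamics)
    wi <- w$start:w$end
    expect_gt(mti_loop_area(cp$dr2[wi], cp$dr2s[wi]), 0)
    expect_lt(mti_loop_area(cm$dr2[wi], cm$dr2s[wi]), 0)
  }
  # zero lag: the curve is retraced without hysteresis, so the loop area sits
  # at the discretization floor (chord error of the curved power-law path),
  # far below any real loop
  c0 <- make_tissue_curves(p, tau = 0)
  ct <- make_tissue_curves(p, tau = 0.4)
  pk <- find_bolus_peak(c0$dr2s, p$injection_dynamic)
  wi <- first_pass_window(pk, p$n_dynamics)$start:first_pass_window(pk, p$n_dynamics)$end
  expect_lt(abs(mti_loop_area(c0$dr2[wi], c0$dr2s[wi])),
            0.05 * abs(mti_loop_area(ct$dr2[wi], ct$dr2s[wi])))
})

test_that("voxelwise maps equal the scalar operations elementwise", {
  p <- vai_acquisition()
  c1 <- make_tissue_curves(p, q = 0.39, tau = -0.8)
  c2 <- make_tissue_curves(p, q = 0.29, mtt = 6, tau = 0.8)
  dr2s <- array(c(rbind(c1$dr2s, c2$dr2s)), dim = c(2, 1, 1, p$n_dynamics))
  dr2 <- array(c(rbind(c1$dr2, c2$dr2)), dim = c(2, 1, 1, p$n_dynamics))
  d <- array(800, c(2, 1, 1)); rcbv <- array(0.032, c(2, 1, 1))
  maps <- voxelwise_vai(dr2s, dr2, p, d, rcbv)
  for (i in 1:2) {
    cc <- list(c1, c2)[[i]]
    pk <- find_bolus_peak(cc$dr2s, p$injection_dynamic)
    wi <- first_pass_window(pk, p$n_dynamics)$start:
      first_pass_window(pk, p$n_dynamics)$end
    expect_equal(maps$q[i, 1, 1], vessel_density_q(cc$dr2[wi], cc$dr2s[wi]))
    expect_equal(maps$mti[i, 1, 1], mti_loop_area(cc$dr2[wi], cc$dr2s[wi]))
    expect_equal(maps$vsi[i, 1, 1],
                 vessel_size_index(800, 0.032, maps$q[i, 1, 1]))
  }
  expect_error(voxelwise_vai(dr2s, dr2[1, , , , drop = FALSE], p, d, rcbv),
               "grid mismatch")
  flat <- array(0, dim = dim(dr2s))
  expect_warning(voxelwise_vai(flat, flat, p, d, rcbv), "invalid")
})

test_that("percent contrast reproduces lesion-vs-normal arithmetic", {
  expect_equal(percent_contrast(10, 15), 50)
  expect_equal(percent_contrast(10, 5), -50)
  expect_error(percent_contrast(0, 5))
})
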