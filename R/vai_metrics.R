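#' Vessel density index Q
#'
#' `Q = dR2 / (dR2*)^(2/3)` evaluated over the first-pass bolus window.
#' The default estimator is the ratio of window means, the most noise-robust
#' single-number summary that uses all window points symmetrically; the mean
#' of pointwise ratios and the regression slope of dR2 on (dR2*)^(2/3) are
#' available as alternatives.
#'
#' @param dr2_window dR2 values restricted to the first-pass window (1/s).
#' @param dr2s_window dR2* values over the same window (1/s).
#' @param method `"means"` (default), `"pointwise"` or `"regression"`.
#' @return Q in s^(-1/3), or `NA` for an invalid voxel (missing window values,
#'   nonpositive mean dR2*, or negative mean dR2).
#' @export
vessel_density_q <- function(dr2_window, dr2s_window,
                             method = c("means", "pointwise", "regression")) {
  method <- match.arg(method)
  if (length(dr2_window) != length(dr2s_window))
    stop("window series must have equal length")
  if (anyNA(dr2_window) || anyNA(dr2s_window)) return(NA_real_)
  m2 <- mean(dr2_window); m2s <- mean(dr2s_window)
  if (m2s <= 0 || m2 < 0) return(NA_real_)
  switch(method,
    means = m2 / m2s^(2 / 3),
    pointwise = {
      ok <- dr2s_window > 0
      if (!any(ok)) return(NA_real_)
      mean(dr2_window[ok] / dr2s_window[ok]^(2 / 3))
    },
    regression = {
      x <- dr2s_window^(2 / 3)
      if (stats::var(x) == 0) return(m2 / m2s^(2 / 3))
      unname(stats::cov(x, dr2_window) / stats::var(x))
    })
}

#' Vessel size index VSI
#'
#' `VSI = 0.867 * sqrt(D * rCBV) * Q^(-3/2)`, the weighted-average microvessel
#' radius. Unit contract: with `d` in um^2/s and `q` in s^(-1/3) the result is
#' in um (sqrt(um^2/s) * s^(1/2) = um). Vectorized; nonpositive inputs yield
#' `NA` (invalid voxel).
#'
#' @param d Parenchymal diffusion coefficient, um^2/s.
#' @param rcbv Relative cerebral blood volume as a fraction (e.g. 0.032).
#' @param q Vessel density index, s^(-1/3).
#' @return VSI in um.
#' @export
vessel_size_index <- function(d, rcbv, q) {
  ok <- d > 0 & rcbv > 0 & q > 0
  out <- 0.867 * sqrt(pmax(d * rcbv, 0)) * pmax(q, 0)^(-3 / 2)
  out[!ok] <- NA_real_
  out
}

#' Microvessel type indicator MTI (signed vortex-loop area)
#'
#' The vortex curve plots dR2*(t) against dR2(t) over the first-pass window;
#' inter-compartment bolus delays open the curve into a loop. MTI is the
#' signed area of the polygon with vertices `(x_i, y_i) = (dR2(t_i),
#' dR2*(t_i))` in window order, closed last-to-first. The shoelace sum is
#' negated so that a clockwise loop — arteriole-dominated, where the bolus
#' reaches arterioles (driving dR2*) before capillaries (driving dR2) — is
#' positive, and a venule-dominated counter-clockwise loop is negative.
#'
#' @param dr2_window,dr2s_window dR2 and dR2* over the first-pass window.
#' @return Signed loop area (product of two rates, 1/s^2), or `NA` for an
#'   invalid voxel (missing values or fewer than 3 points).
#' @export
mti_loop_area <- function(dr2_window, dr2s_window) {
  if (length(dr2_window) != length(dr2s_window))
    stop("window series must have equal length")
  if (length(dr2_window) < 3L) return(NA_real_)
  if (anyNA(dr2_window) || anyNA(dr2s_window)) return(NA_real_)
  x <- dr2_window; y <- dr2s_window
  j <- c(seq_along(x)[-1], 1L)
  -0.5 * sum(x * y[j] - x[j] * y)
}

#' Voxel-wise VAI maps
#'
#' Applies the scalar Q, VSI and MTI operations per voxel. The first-pass
#' window is found per voxel on the GE (dR2*) curve, searching from the
#' injection dynamic, and the same window indices are applied to the SE
#' curve. Voxels whose window contains missing values, or that were removed
#' by the high-rCBV filter, are marked invalid.
#'
#' @param dr2s 4D dR2* array (from the GE series).
#' @param dr2 4D dR2 array (from the SE series), same grid.
#' @param params A [vai_acquisition()] object.
#' @param d Diffusion coefficient map, um^2/s (3D array).
#' @param rcbv rCBV fraction map (3D array).
#' @param mask Logical 3D array of voxels to analyse (after ROI and high-rCBV
#'   filtering).
#' @param q_method Passed to [vessel_density_q()].
#' @return Object of class `vai_maps`: list of 3D arrays `q`, `vsi`, `mti`,
#'   `rcbv`, `d` and logical `valid`.
#' @export
voxelwise_vai <- function(dr2s, dr2, params, d, rcbv, mask = NULL,
                          q_method = "means") {
  if (!identical(dim(dr2s), dim(dr2)))
    stop(sprintf("grid mismatch: dR2* %s vs dR2 %s",
                 paste(dim(dr2s), collapse = "x"),
                 paste(dim(dr2), collapse = "x")))
  d3 <- dim(dr2s)[1:3]
  if (!identical(dim(d)[1:3], d3) || !identical(dim(rcbv)[1:3], d3))
    stop("d/rcbv maps must share the dynamic series' spatial grid")
  if (is.null(mask)) mask <- array(TRUE, dim = d3)
  nvox <- prod(d3)
  ms <- matrix(dr2s, nrow = nvox)
  m2 <- matrix(dr2, nrow = nvox)
  qv <- vsiv <- mtiv <- rep(NA_real_, nvox)
  idx <- which(as.vector(mask))
  n_dyn <- params$n_dynamics
  sfrom <- params$injection_dynamic
  dv <- as.vector(d); rv <- as.vector(rcbv)
  for (i in idx) {
    cs <- ms[i, ]
    if (!any(is.finite(cs[sfrom:n_dyn])) || max(cs[sfrom:n_dyn], na.rm = TRUE) <= 0)
      next
    pk <- which.max(replace(cs, seq_len(sfrom - 1L), -Inf))
    w <- first_pass_window(pk, n_dyn)
    wi <- window_idx(w)
    qv[i] <- vessel_density_q(m2[i, wi], cs[wi], method = q_method)
    mtiv[i] <- mti_loop_area(m2[i, wi], cs[wi])
    if (is.finite(qv[i]))
      vsiv[i] <- vessel_size_index(dv[i], rv[i], qv[i])
  }
  valid <- is.finite(qv) & is.finite(vsiv)
  n_excl <- length(idx) - sum(valid[idx])
  if (length(idx) > 0 && all(!valid[idx]))
    warning(sprintf("all %d masked voxels invalid", length(idx)))
  structure(list(q = array(qv, d3), vsi = array(vsiv, d3),
                 mti = array(mtiv, d3), rcbv = array(rv, d3),
                 d = array(dv, d3), valid = array(valid, d3),
                 n_excluded = n_excl),
            class = "vai_maps")
}

#' Percent contrast between two group or ROI means
#'
#' Reports the relative difference of `value` versus `ref` in percent,
#' `100 * (value - ref) / ref`; e.g. lesion-versus-normal-tissue contrasts of
#' the VAI measures. Negative values indicate a reduction relative to the
#' reference.
#'
#' @param ref Reference mean (e.g. NAWM).
#' @param value Comparison mean (e.g. WMH).
#' @return Percent difference (signed).
#' @export
percent_contrast <- function(ref, value) {
  stopifnot(is.finite(ref), ref != 0)
  100 * (value - ref) / ref
}

#' @export
print.vai_maps <- function(x, ...) {
  cat(sprintf("VAI maps on a %s grid; %d valid voxels\n",
              paste(dim(x$q), collapse = "x"), sum(x$valid)))
  for (nm in c("q", "vsi", "mti")) {
    v <- x[[nm]][x$valid]
    if (length(v))
      cat(sprintf("  %-4s mean %.4g (sd %.3g)\n", toupper(nm), mean(v), stats::sd(v)))
  }
  invisible(x)
}
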