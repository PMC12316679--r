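#' Dynamic GE or SE signal series
#'
#' Wraps a 4D signal array (x, y, z, dynamic) together with its acquisition
#' parameters and contrast mechanism.
#'
#' @param data 4D numeric array; the fourth dimension must have length
#'   `params$n_dynamics`. A plain vector or voxels-by-time matrix is also
#'   accepted for curve-level work and is stored as a 1 x 1 x nvox x t array
#'   equivalent.
#' @param contrast `"GE"` or `"SE"`.
#' @param params A [vai_acquisition()] object.
#' @return Object of class `vai_series`.
#' @export
vai_series <- function(data, contrast = c("GE", "SE"), params = vai_acquisition()) {
  contrast <- match.arg(contrast)
  stopifnot(inherits(params, "vai_acquisition"))
  if (is.vector(data)) data <- array(data, dim = c(1, 1, 1, length(data)))
  if (is.matrix(data)) data <- array(data, dim = c(nrow(data), 1, 1, ncol(data)))
  if (length(dim(data)) != 4L)
    stop("`data` must be a 4D array (x, y, z, dynamic)")
  if (dim(data)[4] != params$n_dynamics)
    stop(sprintf("fourth dimension (%d) does not match n_dynamics (%d)",
                 dim(data)[4], params$n_dynamics))
  if (!all(is.finite(data)))
    stop("signal values must be finite")
  structure(list(data = data, contrast = contrast, params = params),
            class = "vai_series")
}

# voxels-by-time view of a 4D array
vox_mat <- function(a) {
  d <- dim(a)
  matrix(a, nrow = prod(d[1:3]), ncol = d[4])
}

#' Per-voxel baseline signal S0
#'
#' Arithmetic mean of the pre-contrast dynamics in `params$baseline_range`.
#' Voxels with any nonpositive baseline sample are flagged invalid (their
#' log-ratio relaxation rates would be undefined) and excluded downstream.
#'
#' @param series A [vai_series()] object.
#' @return List with `s0` (3D array) and `valid` (3D logical array).
#' @export
estimate_baseline <- function(series) {
  stopifnot(inherits(series, "vai_series"))
  p <- series$params
  rng <- p$baseline_range
  if (rng[2] < rng[1]) stop("empty baseline range")
  m <- vox_mat(series$data)[, rng[1]:rng[2], drop = FALSE]
  s0 <- rowMeans(m)
  valid <- apply(m > 0, 1L, all)
  if (!any(valid))
    stop(sprintf("all %d voxels have nonpositive baseline signal", length(valid)))
  d3 <- dim(series$data)[1:3]
  list(s0 = array(s0, dim = d3), valid = array(valid, dim = d3))
}

#' Relaxation-rate change time series
#'
#' Computes the contrast-induced change in transverse relaxation rate from a
#' dynamic signal series: `dR(t) = -log(S(t)/S0)/TE`, using TE_GE for GE
#' series (giving dR2*) and TE_SE for SE series (giving dR2). Nonpositive
#' signal samples propagate as `NA` at that voxel-timepoint rather than being
#' zeroed; any first-pass window containing `NA` later invalidates the voxel.
#'
#' @param series A [vai_series()] object.
#' @param baseline Result of [estimate_baseline()] on the same series (or a
#'   compatible list with `s0` and `valid`).
#' @return 4D array of relaxation-rate changes in 1/s, `NA` where undefined.
#' @export
delta_r2_series <- function(series, baseline = estimate_baseline(series)) {
  stopifnot(inherits(series, "vai_series"))
  te <- if (series$contrast == "GE") series$params$te_ge else series$params$te_se
  m <- vox_mat(series$data)
  s0 <- as.vector(baseline$s0)
  ok <- as.vector(baseline$valid) & s0 > 0
  dr <- -log(sweep(m, 1L, s0, "/")) / te
  dr[m <= 0] <- NA_real_
  dr[!ok, ] <- NA_real_
  array(dr, dim = dim(series$data))
}

#' Locate the first-pass bolus peak on a dR2* curve
#'
#' Returns the 1-based index of the maximum value at or after `search_from`
#' (ties broken by the earliest index). Peak detection is defined on the GE
#' (dR2*) curve, which carries the larger susceptibility effect; the same
#' window indices are then applied to the SE curve.
#'
#' @param dr2s Numeric vector (one voxel's dR2* series), `NA` allowed.
#' @param search_from 1-based index from which to search (default: start of
#'   the series; pipelines pass the injection dynamic).
#' @return Integer peak index (1-based).
#' @export
find_bolus_peak <- function(dr2s, search_from = 1L) {
  stopifnot(search_from >= 1L, search_from <= length(dr2s))
  seg <- dr2s[search_from:length(dr2s)]
  if (!any(is.finite(seg))) stop("no bolus detected: no finite values in search range")
  if (max(seg, na.rm = TRUE) <= 0) stop("no bolus detected: curve never rises above zero")
  pk <- which.max(seg) + search_from - 1L  # which.max takes the earliest tie
  if (pk == length(dr2s))
    warning("bolus peak at the last dynamic; first pass is truncated")
  as.integer(pk)
}

#' First-pass bolus window around a peak
#'
#' The window spans `pre` timepoints before and `post` timepoints after the
#' peak (defaults 4 and 8; 6.4 s and 12.8 s at a 1.6 s dynamic interval),
#' clamped to the acquisition. The nominal window length is 13 timepoints.
#'
#' @param peak 1-based peak index.
#' @param n_dynamics Series length.
#' @param pre,post Timepoints before/after the peak.
#' @return Object of class `first_pass_window` with fields `peak`, `start`,
#'   `end` (1-based, inclusive) and `clamped`.
#' @export
first_pass_window <- function(peak, n_dynamics, pre = 4L, post = 8L) {
  stopifnot(peak >= 1L, peak <= n_dynamics)
  start <- max(1L, as.integer(peak - pre))
  end <- min(as.integer(n_dynamics), as.integer(peak + post))
  structure(list(peak = as.integer(peak), start = start, end = end,
                 clamped = (start > peak - pre) || (end < peak + post)),
            class = "first_pass_window")
}

#' @export
print.first_pass_window <- function(x, ...) {
  cat(sprintf("first-pass window: dynamics %d-%d (peak %d)%s\n",
              x$start, x$end, x$peak, if (x$clamped) ", clamped" else ""))
  invisible(x)
}

#' Paired relaxation-rate curves with their first-pass window
#'
#' @param dr2s,dr2 dR2*(t) and dR2(t) series (equal length, same time grid).
#' @param window A [first_pass_window()] object.
#' @return Object of class `relaxation_curves`.
#' @export
relaxation_curves <- function(dr2s, dr2, window) {
  if (length(dr2s) != length(dr2))
    stop("dr2s and dr2 must have equal length")
  stopifnot(inherits(window, "first_pass_window"))
  if (window$end > length(dr2s)) stop("window extends beyond the series")
  structure(list(dr2s = dr2s, dr2 = dr2, window = window),
            class = "relaxation_curves")
}

# window slice helpers used by the metric operations
window_idx <- function(window) window$start:window$end
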