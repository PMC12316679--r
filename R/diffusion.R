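#' Diffusion acquisition protocol
#'
#' @param bvalues b-values in s/mm^2, nonnegative and strictly increasing.
#'   Default: 0, 200, 300, 400, 500, 600, 800, 1000.
#' @param n_directions Number of orthogonal diffusion directions (default 3).
#' @param fit_bmin Smallest b-value entering the mono-exponential fit
#'   (default 200 s/mm^2, which removes perfusion-sensitive low-b points).
#' @return Object of class `diffusion_protocol`.
#' @export
diffusion_protocol <- function(bvalues = c(0, 200, 300, 400, 500, 600, 800, 1000),
                               n_directions = 3L, fit_bmin = 200) {
  stopifnot(all(bvalues >= 0), !is.unsorted(bvalues, strictly = TRUE))
  if (sum(bvalues >= fit_bmin) < 2L)
    stop("need at least 2 b-values at or above `fit_bmin`")
  structure(list(bvalues = bvalues, n_directions = as.integer(n_directions),
                 fit_bmin = fit_bmin), class = "diffusion_protocol")
}

#' Read an FSL-style bval table
#'
#' Accepts a plain-text file with b-values either on one whitespace-separated
#' line (FSL bval layout, one entry per volume) or as a two-column
#' (volume, b) table. Returns the per-volume b-value vector.
#'
#' @param path Path to the text file.
#' @return Numeric vector of b-values per volume.
#' @export
read_bvals <- function(path) {
  tab <- utils::read.table(path, header = FALSE)
  if (nrow(tab) == 1L) as.numeric(tab[1, ]) else as.numeric(tab[[ncol(tab)]])
}

#' Parenchymal diffusion coefficient from multi-b signals
#'
#' For each voxel the three orthogonal-direction signals at each b-value are
#' combined by their geometric mean (equivalently, log-signals are averaged),
#' so the fitted decay constant equals the mean of the per-direction ADCs —
#' the trace-mean diffusion coefficient. D is then the negative slope of the
#' least-squares line of log(signal) versus b over `b >= fit_bmin`
#' (mono-exponential model). An arithmetic-mean direction combination and a
#' signal-squared-weighted fit are available for noisy data.
#'
#' @param signals 4D array (x, y, z, volume) with volumes ordered as in
#'   `bvol` / `dirvol`, or a voxels-by-volume matrix.
#' @param protocol A [diffusion_protocol()] object.
#' @param bvol Per-volume b-values (default: protocol b-values repeated for
#'   each direction, direction-major order
#'   `b1 d1, b2 d1, ..., b1 d2, ...`).
#' @param combine `"geometric"` (default) or `"arithmetic"` direction
#'   averaging.
#' @param weighted Use weights proportional to squared signal in the
#'   log-linear fit.
#' @return List with `d_mm2` (D map, mm^2/s), `d_um2` (same in um^2/s),
#'   `valid`, and `implausible` (voxels with fitted D < 0).
#' @export
fit_adc <- function(signals, protocol = diffusion_protocol(), bvol = NULL,
                    combine = c("geometric", "arithmetic"), weighted = FALSE) {
  combine <- match.arg(combine)
  d4 <- if (is.matrix(signals)) c(nrow(signals), 1L, 1L, ncol(signals)) else dim(signals)
  m <- matrix(signals, nrow = prod(d4[1:3]), ncol = d4[4])
  if (is.null(bvol))
    bvol <- rep(protocol$bvalues, times = protocol$n_directions)
  if (length(bvol) != ncol(m))
    stop(sprintf("%d volumes but %d b-value entries", ncol(m), length(bvol)))
  ub <- sort(unique(bvol))
  # direction-combined signal per unique b
  comb <- matrix(NA_real_, nrow(m), length(ub))
  for (j in seq_along(ub)) {
    cols <- which(bvol == ub[j])
    block <- m[, cols, drop = FALSE]
    comb[, j] <- if (combine == "geometric") {
      out <- exp(rowMeans(log(block)))
      out[apply(block <= 0, 1L, any)] <- NA_real_
      out
    } else rowMeans(block)
  }
  usefit <- ub >= protocol$fit_bmin
  if (sum(usefit) < 2L) stop("fewer than 2 b-values at or above fit_bmin")
  b <- ub[usefit]
  y <- comb[, usefit, drop = FALSE]
  valid <- apply(is.finite(y) & y > 0, 1L, all)
  slope <- rep(NA_real_, nrow(m))
  ly <- log(y)
  if (!weighted) {
    bc <- b - mean(b)
    slope[valid] <- (ly[valid, , drop = FALSE] %*% bc) / sum(bc^2)
  } else {
    for (i in which(valid)) {
      w <- y[i, ]^2
      fitc <- stats::lm.wfit(cbind(1, b), ly[i, ], w = w)$coefficients
      slope[i] <- fitc[2]
    }
  }
  d <- -slope
  implausible <- valid & d < 0
  d3 <- d4[1:3]
  list(d_mm2 = array(d, d3), d_um2 = array(d * 1e6, d3),
       valid = array(valid, d3), implausible = array(implausible, d3))
}
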