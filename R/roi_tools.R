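#' ROI mask set
#'
#' Binary masks for the analysis regions on one voxel grid. Recognised
#' labels: `CGM`, `DGM`, `NAWM`, `WMH`, `VENTRICLES`, `ARTERIES`,
#' `EXCLUDE_LESION`.
#'
#' @param labels Named list of logical 3D arrays.
#' @param voxel_size Voxel dimensions in mm (length-3 numeric).
#' @return Object of class `vai_roi_set`.
#' @export
vai_roi_set <- function(labels, voxel_size) {
  stopifnot(is.list(labels), length(voxel_size) == 3L, all(voxel_size > 0))
  dims <- lapply(labels, dim)
  if (length(unique(lapply(dims, paste, collapse = "x"))) > 1L)
    stop("all masks must share one grid")
  labels <- lapply(labels, function(m) array(as.logical(m), dim = dim(m)))
  structure(list(labels = labels, voxel_size = as.numeric(voxel_size)),
            class = "vai_roi_set")
}

analysis_rois <- c("CGM", "DGM", "NAWM", "WMH")

#' Anisotropy-aware 3D Euclidean distance transform
#'
#' Exact squared Euclidean distance (in mm) from every voxel to the nearest
#' `TRUE` voxel of `mask`, measured center-to-center with per-axis voxel
#' spacing. Separable lower-envelope (Felzenszwalb-Huttenlocher) algorithm,
#' applied along each axis in turn.
#'
#' @param mask Logical 3D array of source voxels.
#' @param voxel_size Voxel dimensions in mm.
#' @return 3D numeric array of distances in mm (`Inf` if the mask is empty).
#' @export
distance_transform_mm <- function(mask, voxel_size) {
  d <- dim(mask)
  stopifnot(length(d) == 3L, length(voxel_size) == 3L)
  f <- array(ifelse(mask, 0, Inf), dim = d)
  # pass along x
  for (k in seq_len(d[3])) for (j in seq_len(d[2]))
    f[, j, k] <- dt_1d(f[, j, k], voxel_size[1])
  for (k in seq_len(d[3])) for (i in seq_len(d[1]))
    f[i, , k] <- dt_1d(f[i, , k], voxel_size[2])
  for (j in seq_len(d[2])) for (i in seq_len(d[1]))
    f[i, j, ] <- dt_1d(f[i, j, ], voxel_size[3])
  sqrt(f)
}

# 1D squared-distance transform (lower envelope of parabolas) of sampled
# function f on a grid with spacing h; Inf entries contribute no parabola.
dt_1d <- function(f, h) {
  n <- length(f)
  fin <- which(is.finite(f))
  if (length(fin) == 0L) return(f)
  x <- (seq_len(n) - 1) * h
  v <- integer(length(fin)); z <- numeric(length(fin) + 1L)
  k <- 1L; v[1] <- fin[1]; z[1] <- -Inf; z[2] <- Inf
  for (q in fin[-1]) {
    repeat {
      p <- v[k]
      s <- ((f[q] + x[q]^2) - (f[p] + x[p]^2)) / (2 * (x[q] - x[p]))
      if (s > z[k]) break
      k <- k - 1L
      if (k == 0L) { k <- 1L; v[1] <- q; s <- -Inf; break }
    }
    if (v[k] != q) { k <- k + 1L; v[k] <- q }
    z[k] <- if (is.finite(s)) s else -Inf
    z[k + 1L] <- Inf
  }
  out <- numeric(n); j <- 1L
  for (q in seq_len(n)) {
    while (z[j + 1L] < x[q]) j <- j + 1L
    out[q] <- (x[q] - x[v[j]])^2 + f[v[j]]
  }
  out
}

#' Periventricular exclusion zone
#'
#' Removes from the NAWM mask every voxel within `distance_mm` (default
#' 10 mm, boundary inclusive) of the ventricle mask, measured as 3D Euclidean
#' distance in mm with anisotropic voxel spacing. This suppresses
#' location-dependent differences in NAWM composition between groups whose
#' periventricular white matter is differentially lesioned.
#'
#' @param nawm_mask,ventricle_mask Logical 3D arrays on one grid.
#' @param distance_mm Exclusion radius in mm.
#' @param voxel_size Voxel dimensions in mm.
#' @return Reduced NAWM mask.
#' @export
periventricular_exclusion <- function(nawm_mask, ventricle_mask,
                                      distance_mm = 10, voxel_size) {
  if (!identical(dim(nawm_mask), dim(ventricle_mask)))
    stop("masks must share one grid")
  if (!any(ventricle_mask)) {
    warning("empty ventricle mask; NAWM returned unchanged")
    return(nawm_mask)
  }
  if (distance_mm <= 0) return(nawm_mask)
  dist <- distance_transform_mm(ventricle_mask, voxel_size)
  nawm_mask & !(dist <= distance_mm)
}

#' Apply lesion exclusions to every analysis ROI
#'
#' Subtracts the `EXCLUDE_LESION` mask (manually segmented infarcts,
#' hemorrhages, venous anomalies, cavernomas) from each analysis ROI, and
#' enforces disjointness of NAWM and WMH (NAWM minus WMH). Removed voxel
#' counts are recorded in the `removed` attribute.
#'
#' @param roi_set A [vai_roi_set()] object containing an `EXCLUDE_LESION`
#'   mask (which may be empty).
#' @return The updated `vai_roi_set`.
#' @export
apply_lesion_exclusions <- function(roi_set) {
  stopifnot(inherits(roi_set, "vai_roi_set"))
  excl <- roi_set$labels$EXCLUDE_LESION
  if (is.null(excl)) stop("EXCLUDE_LESION mask is required (may be all-FALSE)")
  removed <- integer(0)
  if (!is.null(roi_set$labels$NAWM) && !is.null(roi_set$labels$WMH))
    roi_set$labels$NAWM <- roi_set$labels$NAWM & !roi_set$labels$WMH
  for (nm in intersect(analysis_rois, names(roi_set$labels))) {
    before <- sum(roi_set$labels[[nm]])
    roi_set$labels[[nm]] <- roi_set$labels[[nm]] & !excl
    removed[nm] <- before - sum(roi_set$labels[[nm]])
  }
  attr(roi_set, "removed") <- removed
  roi_set
}

#' Summary statistics of a map over an ROI
#'
#' Mean, SD (n-1 denominator), median, IQR (Q3 - Q1 with the
#' linear-interpolation quantile rule) and voxel count of the valid map
#' values inside the mask.
#'
#' @param map 3D numeric array.
#' @param mask Logical 3D array.
#' @param roi,metric Labels carried into the output row.
#' @return One-row data.frame (`roi`, `metric`, `mean`, `sd`, `median`,
#'   `iqr`, `n_voxels`), or a zero-row frame with a warning when no valid
#'   voxels exist.
#' @export
roi_summary <- function(map, mask, roi = "", metric = "") {
  v <- map[mask]
  v <- v[is.finite(v)]
  if (length(v) == 0L) {
    warning(sprintf("no valid voxels for %s in %s", metric, roi))
    return(data.frame(roi = character(), metric = character(), mean = numeric(),
                      sd = numeric(), median = numeric(), iqr = numeric(),
                      n_voxels = integer()))
  }
  qs <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  data.frame(roi = roi, metric = metric, mean = mean(v),
             sd = if (length(v) > 1) stats::sd(v) else 0,
             median = qs[2], iqr = qs[3] - qs[1], n_voxels = length(v))
}

#' Per-ROI summary table for a set of maps
#'
#' @param maps Named list of 3D arrays (e.g. `q`, `vsi`, `mti`, `rcbv`, ...).
#' @param roi_set A [vai_roi_set()].
#' @param valid Optional logical 3D array intersected with every ROI.
#' @param subject Subject identifier column value.
#' @return Long data.frame, one row per ROI x metric.
#' @export
roi_summary_table <- function(maps, roi_set, valid = NULL, subject = "subject") {
  rows <- list()
  for (roi in intersect(analysis_rois, names(roi_set$labels))) {
    mk <- roi_set$labels[[roi]]
    if (!is.null(valid)) mk <- mk & valid
    for (metric in names(maps)) {
      if (!any(mk)) next
      r <- suppressWarnings(roi_summary(maps[[metric]], mk, roi, metric))
      if (nrow(r)) rows[[length(rows) + 1L]] <- r
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  cbind(subject = subject, out, row.names = NULL)
}
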