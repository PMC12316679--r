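#' Pipeline configuration
#'
#' Validated option set for a single-subject analysis. Paths may be `NULL`
#' when the subject is supplied in memory (a [generate_phantom()] result).
#'
#' @param ge,se,dwi,labels,bvals Input file paths (4D GE NIfTI, 4D SE NIfTI,
#'   4D diffusion NIfTI, integer label NIfTI, bval table).
#' @param acquisition A [vai_acquisition()] object or path to a YAML/JSON
#'   acquisition config.
#' @param q_method Q estimator mode (see [vessel_density_q()]).
#' @param oi_threshold oSVD oscillation-index threshold.
#' @param rcbv_scaling Anchor NAWM rCBV at `rcbv_target` (`FALSE` selects the
#'   no-scaling sensitivity mode).
#' @param rcbv_target NAWM anchor value as a fraction.
#' @param exclusion_scope `"global"` applies the high-rCBV filter over the
#'   union of analysis ROIs; `"per_roi"` applies it within each ROI.
#' @param exclude_fraction Fraction of highest-rCBV voxels removed.
#' @param periventricular_mm Periventricular exclusion radius in mm.
#' @param n_aif Number of arterial voxels averaged into the AIF.
#' @param compute_cbf Run the oSVD CBF stage (the slowest stage).
#' @param seed Integer seed recorded in provenance.
#' @return Object of class `vai_config`.
#' @export
vai_config <- function(ge = NULL, se = NULL, dwi = NULL, labels = NULL,
                       bvals = NULL, acquisition = vai_acquisition(),
                       q_method = "means", oi_threshold = 0.095,
                       rcbv_scaling = TRUE, rcbv_target = 0.032,
                       exclusion_scope = c("global", "per_roi"),
                       exclude_fraction = 0.10, periventricular_mm = 10,
                       n_aif = 10L, compute_cbf = TRUE, seed = 1L) {
  exclusion_scope <- match.arg(exclusion_scope)
  if (is.character(acquisition))
    acquisition <- read_acquisition_config(acquisition)
  for (p in c(ge, se, dwi, labels, bvals))
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  structure(list(ge = ge, se = se, dwi = dwi, labels = labels, bvals = bvals,
                 acquisition = acquisition, q_method = q_method,
                 oi_threshold = oi_threshold, rcbv_scaling = rcbv_scaling,
                 rcbv_target = rcbv_target, exclusion_scope = exclusion_scope,
                 exclude_fraction = exclude_fraction,
                 periventricular_mm = periventricular_mm,
                 n_aif = as.integer(n_aif), compute_cbf = compute_cbf,
                 seed = as.integer(seed)),
            class = "vai_config")
}

label_codes <- c(CGM = 1L, DGM = 2L, NAWM = 3L, WMH = 4L, VENTRICLES = 5L,
                 ARTERIES = 6L, EXCLUDE_LESION = 7L)

read_subject_inputs <- function(config) {
  for (nm in c("ge", "se", "dwi", "labels", "bvals"))
    if (is.null(config[[nm]])) stop("missing input: ", nm)
  acq <- config$acquisition
  ge_img <- RNifti::readNifti(config$ge)
  se_img <- RNifti::readNifti(config$se)
  lab_img <- RNifti::readNifti(config$labels)
  vs <- RNifti::pixdim(lab_img)[1:3]
  masks <- lapply(label_codes, function(code)
    array(lab_img == code, dim = dim(lab_img)))
  dwi_img <- RNifti::readNifti(config$dwi)
  list(ge = vai_series(array(as.numeric(ge_img), dim = dim(ge_img)), "GE", acq),
       se = vai_series(array(as.numeric(se_img), dim = dim(se_img)), "SE", acq),
       dwi = array(as.numeric(dwi_img), dim = dim(dwi_img)),
       bvol = read_bvals(config$bvals),
       roi_set = vai_roi_set(masks, vs))
}

#' Run the full VAI analysis for one subject
#'
#' Ordered stages: relaxometry (baseline, dR2*/dR2) -> AIF selection and
#' gamma-variate rCBV with NAWM anchoring and high-rCBV exclusion ->
#' diffusion fit -> voxel-wise Q/VSI/MTI -> ROI construction
#' (periventricular zone, lesion removal) -> per-ROI summaries -> optional
#' GE/SE CBF deconvolution. Outputs NIfTI maps, a per-ROI CSV, VSI histogram
#' bins and a provenance JSON into `outdir` when given.
#'
#' @param subject A [generate_phantom()] result, or `NULL` to read the files
#'   named in `config`.
#' @param config A [vai_config()] object.
#' @param outdir Optional output directory.
#' @return Object of class `vai_subject`: `maps` ([voxelwise_vai()] result
#'   augmented with `cbf_ge`/`cbf_se`), `summary` (per-ROI data.frame),
#'   `aif`, `scale_factor`, `roi_set`, `provenance`.
#' @export
run_subject <- function(subject = NULL, config = vai_config(), outdir = NULL) {
  stopifnot(inherits(config, "vai_config"))
  acq <- config$acquisition
  if (is.null(subject)) {
    inp <- read_subject_inputs(config)
  } else {
    stopifnot(inherits(subject, "vai_phantom"))
    inp <- subject
    inp$bvol <- rep(subject$protocol$bvalues,
                    times = subject$protocol$n_directions)
    acq <- subject$ge$params
  }
  # stage 1: relaxometry
  base_ge <- estimate_baseline(inp$ge)
  base_se <- estimate_baseline(inp$se)
  dr2s <- delta_r2_series(inp$ge, base_ge)
  dr2 <- delta_r2_series(inp$se, base_se)
  # stage 2: ROI construction
  roi <- inp$roi_set
  roi$labels$NAWM <- periventricular_exclusion(
    roi$labels$NAWM, roi$labels$VENTRICLES,
    distance_mm = config$periventricular_mm, voxel_size = roi$voxel_size)
  roi <- apply_lesion_exclusions(roi)
  analysis_mask <- Reduce(`|`, roi$labels[intersect(analysis_rois,
                                                    names(roi$labels))])
  # stage 3: AIF and rCBV
  aif <- select_aif(dr2s, roi$labels$ARTERIES, acq, n_aif = config$n_aif)
  rcbv_raw <- rcbv_map(dr2s, analysis_mask, aif, acq)
  sc <- scale_aif_to_nawm(rcbv_raw, roi$labels$NAWM,
                          target = config$rcbv_target,
                          enabled = config$rcbv_scaling)
  if (config$exclusion_scope == "global") {
    keep <- exclude_top_rcbv(sc$rcbv, analysis_mask,
                             fraction = config$exclude_fraction)
  } else {
    keep <- analysis_mask & FALSE
    for (nm in intersect(analysis_rois, names(roi$labels)))
      if (any(roi$labels[[nm]]))
        keep <- keep | exclude_top_rcbv(sc$rcbv, roi$labels[[nm]],
                                        fraction = config$exclude_fraction)
  }
  # stage 4: diffusion
  adc <- fit_adc(inp$dwi, if (!is.null(inp$protocol)) inp$protocol
                 else diffusion_protocol(), bvol = inp$bvol)
  # stage 5: voxel-wise VAI maps
  maps <- voxelwise_vai(dr2s, dr2, acq, adc$d_um2, sc$rcbv, mask = keep,
                        q_method = config$q_method)
  # stage 6: GE and SE CBF by oSVD against the GE-derived AIF
  if (config$compute_cbf) {
    nvox <- prod(dim(maps$q))
    ms <- matrix(dr2s, nrow = nvox); m2 <- matrix(dr2, nrow = nvox)
    idx <- which(as.vector(keep))
    cbf_ge <- cbf_se <- rep(NA_real_, nvox)
    if (length(idx)) {
      ge_curves <- ms[idx, , drop = FALSE]; ge_curves[!is.finite(ge_curves)] <- 0
      se_curves <- m2[idx, , drop = FALSE]; se_curves[!is.finite(se_curves)] <- 0
      cbf_ge[idx] <- cbf_deconvolution(ge_curves, aif, acq$dt,
                                       config$oi_threshold)$cbf
      cbf_se[idx] <- cbf_deconvolution(se_curves, aif, acq$dt,
                                       config$oi_threshold)$cbf
    }
    maps$cbf_ge <- array(cbf_ge, dim = dim(maps$q))
    maps$cbf_se <- array(cbf_se, dim = dim(maps$q))
  }
  # stage 7: summaries
  map_list <- list(q = maps$q, vsi = maps$vsi, mti = maps$mti,
                   rcbv = maps$rcbv * 100, d = maps$d)
  if (config$compute_cbf) {
    map_list$cbf_ge <- maps$cbf_ge
    map_list$cbf_se <- maps$cbf_se
  }
  summary <- roi_summary_table(map_list, roi, valid = maps$valid)
  hist_bins <- vsi_histogram(maps$vsi, maps$valid & analysis_mask)
  prov <- list(
    package_version = as.character(utils::packageVersion("vaimri")),
    seed = config$seed, q_method = config$q_method,
    rcbv_scaling = config$rcbv_scaling, rcbv_target = config$rcbv_target,
    scale_factor = sc$factor, oi_threshold = config$oi_threshold,
    exclusion_scope = config$exclusion_scope,
    exclude_fraction = config$exclude_fraction,
    periventricular_mm = config$periventricular_mm,
    n_voxels_analysed = sum(keep), n_voxels_valid = sum(maps$valid),
    config_hash = config_hash(config))
  out <- structure(list(maps = maps, summary = summary, aif = aif,
                        scale_factor = sc$factor, roi_set = roi,
                        vsi_histogram = hist_bins, provenance = prov),
                   class = "vai_subject")
  if (!is.null(outdir)) write_subject_bundle(out, outdir,
                                             voxel_size = roi$voxel_size)
  out
}

# deterministic hash of the configuration (provenance, not cryptographic)
config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(
    config[setdiff(names(config), "acquisition")])), collapse = "\n")
  sprintf("%08x", sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% .Machine$integer.max)
}

#' VSI histogram bins
#'
#' Fixed 2-um bins from 0 to 50 um; voxels above 50 um are counted in the
#' `n_above_50` attribute and excluded from the bins (mirroring how the
#' vessel-size distribution is usually displayed).
#'
#' @param vsi VSI map (um).
#' @param mask Logical 3D array.
#' @return data.frame with `bin_low`, `bin_high`, `count`.
#' @export
vsi_histogram <- function(vsi, mask) {
  v <- vsi[mask]
  v <- v[is.finite(v)]
  breaks <- seq(0, 50, by = 2)
  cnt <- table(cut(v[v <= 50 & v >= 0], breaks = breaks,
                   include.lowest = TRUE))
  out <- data.frame(bin_low = breaks[-length(breaks)], bin_high = breaks[-1],
                    count = as.integer(cnt))
  attr(out, "n_above_50") <- sum(v > 50)
  out
}

write_subject_bundle <- function(res, outdir, voxel_size = c(3, 3.3, 5)) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  maps <- res$maps
  nm_map <- c(q = "q", vsi = "vsi", mti = "mti", rcbv = "rcbv",
              d = "d", cbf_ge = "cbf_ge", cbf_se = "cbf_se")
  for (nm in names(nm_map)) {
    if (is.null(maps[[nm]])) next
    img <- maps[[nm]]
    storage.mode(img) <- "double"
    RNifti::writeNifti(RNifti::asNifti(img, pixdim = voxel_size),
                       file.path(outdir, paste0(nm, ".nii.gz")),
                       datatype = "float")
  }
  utils::write.csv(format(res$summary, digits = 6),
                   file.path(outdir, "roi_summary.csv"), row.names = FALSE)
  utils::write.csv(res$vsi_histogram, file.path(outdir, "vsi_histogram.csv"),
                   row.names = FALSE)
  jsonlite::write_json(res$provenance, file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' Run the cohort-level statistical analysis
#'
#' Aggregates a per-subject wide table (e.g. from [make_cohort()] or from
#' stacked [run_subject()] summaries) and runs the group statistical layer.
#' Writes a long-format results CSV and a markdown report when `outdir` is
#' given.
#'
#' @param subjects Wide per-subject data.frame (see [cohort_analysis()]).
#' @param outdir Optional output directory.
#' @param ... Passed to [cohort_analysis()].
#' @return The [cohort_analysis()] result list, with a `report` attribute.
#' @export
run_cohort <- function(subjects, outdir = NULL, ...) {
  res <- cohort_analysis(subjects, ...)
  report <- c("# Cohort vessel-architecture analysis", "",
              sprintf("%d patients, %d controls", sum(subjects$group == 1),
                      sum(subjects$group == 0)), "",
              "## Multivariable models (group + age + sex)", "",
              format_regression_report(res$multivariable))
  if (!is.null(res$nawm_vs_wmh)) {
    report <- c(report, "", "## NAWM versus WMH (paired, patients only)", "")
    for (i in seq_len(nrow(res$nawm_vs_wmh))) {
      row <- res$nawm_vs_wmh[i, ]
      report <- c(report, sprintf(
        "- %s: NAWM %.3g vs WMH %.3g (%+.0f%%), t = %.2f, df = %d, p = %.3g",
        row$metric, row$mean_a, row$mean_b, row$pct_contrast, row$t,
        row$df, row$p_value))
    }
  }
  attr(res, "report") <- report
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    long <- rbind_rows(lapply(c("univariable", "multivariable", "interaction"),
                              function(nm) cbind(model = nm, res[[nm]])))
    utils::write.csv(format(long, digits = 6),
                     file.path(outdir, "cohort_results.csv"),
                     row.names = FALSE)
    writeLines(report, file.path(outdir, "cohort_report.md"))
  }
  res
}
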