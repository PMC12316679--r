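#' Digital phantom configuration
#'
#' Defines the ground truth of a synthetic GE/SE perfusion + diffusion
#' subject. Per-tissue parameters: vessel density index `q` (s^(-1/3)),
#' blood-volume fraction `rcbv`, diffusion coefficient `d` (mm^2/s), mean
#' transit time `mtt` (s), and the SE-versus-GE bolus lag `tau_se` (s) whose
#' sign encodes the dominant vessel type (positive: SE lags GE,
#' arteriole-dominated; negative: venule-dominated). Defaults reflect a
#' normal-appearing-white-matter anchor of Q = 0.39 s^(-1/3) and
#' rCBV = 3.2%, a hyperintense-lesion compartment with lower density, higher
#' diffusivity and prolonged transit, and an arterial bolus with a ~10 s
#' first-pass width arriving one dynamic after injection.
#'
#' @param dims Grid size (default 32 x 32 x 8).
#' @param voxel_size_mm Voxel dimensions in mm (default 3 x 3.3 x 5).
#' @param tissues data.frame with columns `tissue`, `q`, `rcbv`, `d`, `mtt`,
#'   `tau_se`, `s0_ge`, `s0_se`; rows CGM, DGM, NAWM, WMH.
#' @param aif A [gamma_variate_params()] object for the arterial
#'   concentration curve (arbitrary concentration units).
#' @param artery_amplitude Peak arterial dR2* in 1/s.
#' @param k_ge Susceptibility calibration (dR2* per concentration unit);
#'   `NULL` auto-calibrates so the NAWM tissue curve peaks at
#'   `peak_dr2s_nawm`.
#' @param peak_dr2s_nawm Target NAWM peak dR2* for auto-calibration (1/s).
#' @param snr Baseline signal-to-noise ratio of the Rician noise; `Inf`
#'   (default) is noise-free.
#' @param seed Integer seed controlling the noise realization.
#' @param acquisition A [vai_acquisition()] object.
#' @return Object of class `phantom_config`.
#' @export
phantom_config <- function(dims = c(32L, 32L, 8L),
                           voxel_size_mm = c(3, 3.3, 5),
                           tissues = default_phantom_tissues(),
                           aif = gamma_variate_params(k = 1, t0 = 14.4,
                                                      alpha = 3, beta = 2.5),
                           artery_amplitude = 60,
                           k_ge = NULL, peak_dr2s_nawm = 10,
                           snr = Inf, seed = 1L,
                           acquisition = vai_acquisition()) {
  stopifnot(length(dims) == 3L, all(dims >= 8L),
            all(c("tissue", "q", "rcbv", "d", "mtt", "tau_se",
                  "s0_ge", "s0_se") %in% names(tissues)),
            all(tissues$q > 0), all(tissues$rcbv > 0), all(tissues$d > 0),
            all(tissues$mtt > 0), all(tissues$s0_ge > 0),
            all(tissues$s0_se > 0), snr > 0,
            inherits(aif, "gamma_variate_params"),
            inherits(acquisition, "vai_acquisition"))
  span <- (4 + 8) * acquisition$dt
  if (any(abs(tissues$tau_se) >= span))
    stop(sprintf("tau_se magnitude must be below the window span (%.1f s)", span))
  structure(list(dims = as.integer(dims), voxel_size_mm = voxel_size_mm,
                 tissues = tissues, aif = aif,
                 artery_amplitude = artery_amplitude,
                 k_ge = k_ge, peak_dr2s_nawm = peak_dr2s_nawm,
                 snr = snr, seed = as.integer(seed),
                 acquisition = acquisition),
            class = "phantom_config")
}

#' Default per-tissue ground-truth parameters
#'
#' @return data.frame of tissue parameters used by [phantom_config()].
#' @export
default_phantom_tissues <- function() {
  data.frame(
    tissue = c("CGM", "DGM", "NAWM", "WMH"),
    q      = c(0.44, 0.45, 0.39, 0.29),
    rcbv   = c(0.055, 0.050, 0.032, 0.030),
    d      = c(8.5e-4, 7.5e-4, 8.0e-4, 1.1e-3),  # mm^2/s
    mtt    = c(4.5, 4.5, 5.5, 6.0),              # s
    tau_se = c(-0.8, -0.8, -0.8, -0.9),          # s (venule-dominated)
    s0_ge  = 1000, s0_se = 1000)
}

# deterministic block layout of the tissue labels on the phantom grid
phantom_labels <- function(dims) {
  lab <- array("", dim = dims)
  cx <- round(dims[1] / 2); cy <- round(dims[2] / 2); cz <- round(dims[3] / 2)
  within <- function(i, lo, hi) i >= lo & i <= hi
  ii <- slice.index(lab, 1); jj <- slice.index(lab, 2); kk <- slice.index(lab, 3)
  # outer cortical rim
  rim <- (within(ii, 4, dims[1] - 3) & within(jj, 4, dims[2] - 3) &
            within(kk, 2, dims[3] - 1)) &
    !(within(ii, 6, dims[1] - 5) & within(jj, 6, dims[2] - 5) &
        within(kk, 3, dims[3] - 2))
  lab[rim] <- "CGM"
  # white matter interior
  wm <- within(ii, 7, dims[1] - 6) & within(jj, 7, dims[2] - 6) &
    within(kk, 3, dims[3] - 2)
  lab[wm] <- "NAWM"
  # central ventricles
  vent <- within(ii, cx - 2, cx + 2) & within(jj, cy - 2, cy + 2) &
    within(kk, cz, cz + 1)
  lab[vent] <- "VENTRICLES"
  # deep gray flanking the ventricles
  dgm <- (within(ii, cx - 6, cx - 4) | within(ii, cx + 4, cx + 6)) &
    within(jj, cy - 3, cy + 3) & within(kk, cz, cz + 1)
  lab[dgm & !vent] <- "DGM"
  # lesion block in anterior white matter, clear of the periventricular zone
  wmh <- within(ii, 8, 11) & within(jj, 8, 11) & within(kk, 3, 4)
  lab[wmh] <- "WMH"
  # arterial voxels along the inferior edge
  art <- within(ii, 5, 14) & jj == 2 & kk == 2
  lab[art] <- "ARTERIES"
  lab
}

#' Generate a synthetic GE/SE perfusion + diffusion phantom
#'
#' Forward model, per labeled tissue: (1) arterial concentration `C_a(t)`
#' from the configured gamma-variate; (2) tissue concentration
#' `C_t(t) = (rcbv/mtt) * (C_a (*) exp(-t/mtt))`, evaluated by convolution on
#' a 16-fold refined grid so the continuous integral ratio of tissue to
#' arterial curve equals `rcbv` analytically; (3) `dR2*(t) = k_ge * C_t(t)`;
#' (4) `dR2(t) = q * [k_ge * C_t(t - tau_se)]^(2/3)` (lag applied by linear
#' interpolation), so the vessel-density relation and the vortex-loop sign
#' are both encoded exactly; (5) signals `S = s0 * exp(-dR * TE)` per
#' contrast; (6) diffusion volumes `S(b, dir) = s0 * exp(-b * d)`, identical
#' across the three orthogonal directions; (7) optional Rician noise at the
#' configured baseline SNR; (8) label masks and per-voxel ground-truth maps.
#'
#' @param config A [phantom_config()] object.
#' @return Object of class `vai_phantom`: `ge`, `se` ([vai_series()]), `dwi`
#'   (4D array), `protocol` ([diffusion_protocol()]), `roi_set`
#'   ([vai_roi_set()]), `truth` (list of per-voxel maps and per-tissue
#'   table), `config`.
#' @export
generate_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  acq <- config$acquisition
  tgrid <- acquisition_times(acq)
  dims <- config$dims
  lab <- phantom_labels(dims)
  aif_p <- config$aif
  # refined grid for the convolution (continuous-model accuracy)
  dtf <- acq$dt / 16
  tf <- seq(0, max(tgrid), by = dtf)
  ca_f <- gamma_variate(tf, aif_p$k, aif_p$t0, aif_p$alpha, aif_p$beta)
  tissue_curve <- function(rcbv, mtt) {
    resid <- exp(-tf / mtt)
    ct_f <- (rcbv / mtt) *
      stats::convolve(ca_f, rev(resid), type = "open")[seq_along(tf)] * dtf
    pmax(stats::approx(tf, ct_f, xout = tgrid)$y, 0)  # FFT rounding can dip below 0
  }
  tis <- config$tissues
  curves <- lapply(seq_len(nrow(tis)),
                   function(i) tissue_curve(tis$rcbv[i], tis$mtt[i]))
  names(curves) <- tis$tissue
  k_ge <- config$k_ge
  if (is.null(k_ge)) k_ge <- config$peak_dr2s_nawm / max(curves[["NAWM"]])
  ca <- gamma_variate(tgrid, aif_p$k, aif_p$t0, aif_p$alpha, aif_p$beta)
  art_dr2s <- config$artery_amplitude * ca / max(ca)
  art_q <- mean(tis$q)
  nvox <- prod(dims)
  n_dyn <- acq$n_dynamics
  ge_sig <- matrix(config$tissues$s0_ge[1], nvox, n_dyn)
  se_sig <- matrix(config$tissues$s0_se[1], nvox, n_dyn)
  truth <- list(q = rep(NA_real_, nvox), rcbv = rep(NA_real_, nvox),
                d = rep(NA_real_, nvox), mtt = rep(NA_real_, nvox),
                cbf = rep(NA_real_, nvox), tau_se = rep(NA_real_, nvox))
  lagged <- function(x, tau) stats::approx(tgrid, x, xout = tgrid - tau,
                                           yleft = 0, yright = x[n_dyn])$y
  for (i in seq_len(nrow(tis))) {
    nm <- tis$tissue[i]
    idx <- which(lab == nm)
    if (!length(idx)) next
    dr2s <- k_ge * curves[[nm]]
    dr2 <- tis$q[i] * lagged(dr2s, tis$tau_se[i])^(2 / 3)
    ge_sig[idx, ] <- matrix(tis$s0_ge[i] * exp(-dr2s * acq$te_ge),
                            length(idx), n_dyn, byrow = TRUE)
    se_sig[idx, ] <- matrix(tis$s0_se[i] * exp(-dr2 * acq$te_se),
                            length(idx), n_dyn, byrow = TRUE)
    truth$q[idx] <- tis$q[i]; truth$rcbv[idx] <- tis$rcbv[i]
    truth$d[idx] <- tis$d[i]; truth$mtt[idx] <- tis$mtt[i]
    truth$cbf[idx] <- tis$rcbv[i] / tis$mtt[i]
    truth$tau_se[idx] <- tis$tau_se[i]
  }
  # arterial voxels: strong GE effect, SE via the same power law
  aidx <- which(lab == "ARTERIES")
  art_dr2 <- art_q * art_dr2s^(2 / 3)
  ge_sig[aidx, ] <- matrix(tis$s0_ge[1] * exp(-art_dr2s * acq$te_ge),
                           length(aidx), n_dyn, byrow = TRUE)
  se_sig[aidx, ] <- matrix(tis$s0_se[1] * exp(-art_dr2 * acq$te_se),
                           length(aidx), n_dyn, byrow = TRUE)
  # diffusion volumes (direction-major ordering)
  protocol <- diffusion_protocol()
  bvol <- rep(protocol$bvalues, times = protocol$n_directions)
  dmap <- truth$d
  dmap[is.na(dmap)] <- 7e-4  # unlabeled background parenchyma
  dwi <- vapply(bvol, function(b) 1000 * exp(-b * dmap), numeric(nvox))
  if (is.finite(config$snr)) {
    set.seed(config$seed)
    ge_sig <- rician(ge_sig, tis$s0_ge[1] / config$snr)
    se_sig <- rician(se_sig, tis$s0_se[1] / config$snr)
    dwi <- rician(dwi, 1000 / config$snr)
  }
  masks <- lapply(c(CGM = "CGM", DGM = "DGM", NAWM = "NAWM", WMH = "WMH",
                    VENTRICLES = "VENTRICLES", ARTERIES = "ARTERIES"),
                  function(nm) array(lab == nm, dim = dims))
  masks$EXCLUDE_LESION <- array(FALSE, dim = dims)
  structure(list(
    ge = vai_series(array(ge_sig, c(dims, n_dyn)), "GE", acq),
    se = vai_series(array(se_sig, c(dims, n_dyn)), "SE", acq),
    dwi = array(dwi, c(dims, length(bvol))),
    protocol = protocol,
    roi_set = vai_roi_set(masks, config$voxel_size_mm),
    truth = c(lapply(truth, array, dim = dims),
              list(tissues = tis, k_ge = k_ge, aif = config$aif,
                   labels = lab)),
    config = config), class = "vai_phantom")
}

# Rician noise: magnitude of a complex Gaussian perturbation
rician <- function(s, sigma) {
  if (sigma <= 0) return(s)
  n <- length(s)
  sqrt((s + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
}

#' Write a phantom subject to disk in the pipeline's input layout
#'
#' Emits NIfTI volumes (GE, SE, DWI, integer label mask), an FSL-style bval
#' table, an acquisition YAML config and a ground-truth JSON.
#'
#' @param phantom A [generate_phantom()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named list of file paths.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  acq <- phantom$ge$params
  vs <- phantom$roi_set$voxel_size
  wr <- function(x, nm) {
    p <- file.path(dir, nm)
    RNifti::writeNifti(RNifti::asNifti(x, pixdim = vs), p)
    p
  }
  paths <- list(
    ge = wr(phantom$ge$data, "ge_dynamic.nii.gz"),
    se = wr(phantom$se$data, "se_dynamic.nii.gz"),
    dwi = wr(phantom$dwi, "dwi.nii.gz"))
  lab <- phantom$truth$labels
  code <- array(0L, dim = dim(lab))
  keys <- c(CGM = 1L, DGM = 2L, NAWM = 3L, WMH = 4L, VENTRICLES = 5L,
            ARTERIES = 6L, EXCLUDE_LESION = 7L)
  for (nm in names(keys)) code[lab == nm] <- keys[[nm]]
  paths$labels <- wr(code, "labels.nii.gz")
  paths$bvals <- file.path(dir, "dwi.bval")
  writeLines(paste(rep(phantom$protocol$bvalues,
                       times = phantom$protocol$n_directions),
                   collapse = " "), paths$bvals)
  paths$config <- file.path(dir, "acquisition.yaml")
  yaml::write_yaml(list(te_ge_s = acq$te_ge, te_se_s = acq$te_se,
                        dt_s = acq$dt, n_dynamics = acq$n_dynamics,
                        injection_dynamic = acq$injection_dynamic,
                        baseline_range = acq$baseline_range),
                   paths$config)
  paths$truth <- file.path(dir, "truth.json")
  jsonlite::write_json(list(tissues = phantom$truth$tissues,
                            k_ge = phantom$truth$k_ge,
                            label_codes = as.list(keys)),
                       paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Simulate a cohort of subject-level ROI summaries
#'
#' Draws per-subject ROI means of the VAI measures from configured group
#' distributions with additive age and sex effects, producing the wide table
#' consumed by [cohort_analysis()]. Default control means and group effects
#' follow the direction of the cohort findings this package models: lower Q,
#' higher VSI and higher (less negative) MTI in patients.
#'
#' @param n_patients,n_controls Group sizes (each >= 2).
#' @param effects data.frame with columns `metric`, `roi`, `control_mean`,
#'   `sd`, `group_effect`, `age_effect`, `sex_effect`; default
#'   [default_cohort_effects()].
#' @param seed Integer seed.
#' @return data.frame with columns `subject_id`, `group`, `age`, `sex`,
#'   cardiovascular covariates, and `<metric>_<roi>` columns.
#' @export
make_cohort <- function(n_patients = 40L, n_controls = 21L,
                        effects = default_cohort_effects(), seed = 1L) {
  if (n_patients < 2L || n_controls < 2L)
    stop("need at least 2 subjects per group")
  if (any(effects$sd <= 0)) stop("effect SDs must be positive")
  set.seed(seed)
  n <- n_patients + n_controls
  group <- rep(c(1L, 0L), c(n_patients, n_controls))
  age <- round(stats::rnorm(n, mean = ifelse(group == 1, 70.1, 67.0),
                            sd = ifelse(group == 1, 9.3, 6.5)), 1)
  sex <- stats::rbinom(n, 1L, 0.69)  # 1 = male
  out <- data.frame(subject_id = sprintf("sub-%03d", seq_len(n)),
                    group = group, age = age, sex = sex,
                    hypertension = stats::rbinom(n, 1L, ifelse(group == 1, 0.80, 0.62)),
                    diabetes = stats::rbinom(n, 1L, 0.15),
                    hypercholesterolemia = stats::rbinom(n, 1L, ifelse(group == 1, 0.90, 0.57)),
                    smoking = stats::rbinom(n, 1L, 0.15),
                    alcohol = stats::rbinom(n, 1L, 0.04),
                    bmi = round(stats::rnorm(n, 27, 3.8), 1))
  ac <- age - mean(age)
  for (i in seq_len(nrow(effects))) {
    e <- effects[i, ]
    col <- paste0(e$metric, "_", e$roi)
    out[[col]] <- e$control_mean + e$group_effect * group +
      e$age_effect * ac + e$sex_effect * sex + stats::rnorm(n, 0, e$sd)
  }
  out
}

#' Default cohort effect configuration
#'
#' Control-group means and SDs on the scale of the printed cohort tables,
#' with group/age/sex effects matching the multivariable regression
#' coefficients reported for these measures.
#'
#' @return data.frame consumed by [make_cohort()].
#' @export
default_cohort_effects <- function() {
  rbind(
    data.frame(metric = "q", roi = c("NAWM", "DGM", "CGM"),
               control_mean = c(0.40, 0.46, 0.45), sd = c(0.03, 0.05, 0.03),
               group_effect = c(-0.009, -0.026, -0.019),
               age_effect = c(-0.001, -0.002, -0.002),
               sex_effect = c(-0.027, -0.041, -0.039)),
    data.frame(metric = "q", roi = "WMH", control_mean = 0.30, sd = 0.04,
               group_effect = -0.01, age_effect = -0.001, sex_effect = -0.02),
    data.frame(metric = "vsi", roi = c("NAWM", "DGM", "CGM"),
               control_mean = c(16.8, 18.5, 18.9), sd = c(2.3, 5.5, 2.6),
               group_effect = c(1.144, 3.994, 2.339),
               age_effect = c(0.079, 0.213, 0.177),
               sex_effect = c(1.722, 4.624, 1.646)),
    data.frame(metric = "vsi", roi = "WMH", control_mean = 26.5, sd = 9.7,
               group_effect = 2.0, age_effect = 0.1, sex_effect = 1.5),
    data.frame(metric = "mti", roi = c("NAWM", "DGM", "CGM"),
               control_mean = c(-1.2, -1.5, -1.6), sd = c(0.7, 2.2, 1.6),
               group_effect = c(0.572, 0.038, 1.256),
               age_effect = c(0.023, 0.129, 0.066),
               sex_effect = c(0.655, 2.799, 1.646)),
    data.frame(metric = "mti", roi = "WMH", control_mean = -1.3, sd = 1.1,
               group_effect = 0.2, age_effect = 0.02, sex_effect = 0.5),
    data.frame(metric = "vsi_iqr", roi = c("NAWM", "DGM", "CGM"),
               control_mean = c(7.9, 10.8, 12.6), sd = c(1.2, 2.5, 2.4),
               group_effect = c(1.2, 2.8, 2.5),
               age_effect = 0.05, sex_effect = 0.5))
}
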