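#' Ordinary least squares with named terms
#'
#' OLS fit of `y` on a design matrix, with normal-theory two-sided p-values
#' and 95% confidence intervals from the t distribution on n - k degrees of
#' freedom. An intercept column is added unless the design already contains a
#' constant column named `(Intercept)`.
#'
#' @param y Response vector.
#' @param design Numeric matrix with named columns (terms).
#' @return data.frame with one row per term: `term`, `beta`, `ci95_low`,
#'   `ci95_high`, `p_value`.
#' @export
ols_fit <- function(y, design) {
  design <- as.matrix(design)
  if (is.null(colnames(design)))
    colnames(design) <- paste0("x", seq_len(ncol(design)))
  if (!"(Intercept)" %in% colnames(design))
    design <- cbind(`(Intercept)` = 1, design)
  n <- length(y); k <- ncol(design)
  if (n <= k) stop("need more observations than terms")
  qrx <- qr(design)
  if (qrx$rank < k) {
    bad <- colnames(design)[qrx$pivot[(qrx$rank + 1):k]]
    stop("rank-deficient design; collinear term(s): ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::lm.fit(design, y)
  beta <- fit$coefficients
  df <- n - k
  sigma2 <- sum(fit$residuals^2) / df
  se <- sqrt(sigma2 * diag(chol2inv(chol(crossprod(design)))))
  tval <- beta / se
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  tq <- stats::qt(0.975, df)
  data.frame(term = colnames(design), beta = unname(beta),
             ci95_low = unname(beta - tq * se),
             ci95_high = unname(beta + tq * se),
             p_value = unname(p), row.names = NULL)
}

#' Group-by-age effect-modification model
#'
#' Fits `y ~ group + age + sex + group:age`. Age is mean-centered before the
#' interaction product is formed (default), which keeps the group main
#' effect interpretable at the cohort mean age; set `center_age = FALSE` for
#' the raw product.
#'
#' @param y Response vector.
#' @param group 0 = control, 1 = patient.
#' @param age Years.
#' @param sex 0 = female, 1 = male.
#' @param center_age Mean-center age before forming the product.
#' @return [ols_fit()] result including the `group:age` term.
#' @export
interaction_model <- function(y, group, age, sex, center_age = TRUE) {
  a <- if (center_age) age - mean(age) else age
  X <- cbind(group = group, age = a, sex = sex, `group:age` = group * a)
  ols_fit(y, X)
}

#' Paired t-test
#'
#' Two-sided paired t-test (e.g. NAWM versus WMH within patients). A zero
#' variance of the paired differences is an error, not a zero p-value.
#'
#' @param a,b Paired measurement vectors of equal length >= 2.
#' @return List with `t`, `df`, `p`.
#' @export
paired_ttest <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  d <- a - b
  if (stats::var(d) == 0) stop("zero variance of paired differences")
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Independent-samples t-test
#'
#' Two-sided independent t-test, pooled-variance (classical Student) by
#' default; set `var_equal = FALSE` for the Welch form.
#'
#' @param a,b Group measurement vectors (each length >= 2).
#' @param var_equal Pool the variances (default `TRUE`).
#' @return List with `t`, `df`, `p`.
#' @export
independent_ttest <- function(a, b, var_equal = TRUE) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop("zero variance in both groups")
  tt <- stats::t.test(a, b, var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Group-level analysis of a per-subject VAI summary table
#'
#' Reproduces the cohort statistical layer on a wide per-subject table:
#' univariable regression of each ROI metric on group, multivariable
#' regression adding age and sex, the group-by-age interaction model, paired
#' NAWM-versus-WMH tests within patients, and independent-group comparison
#' of the voxel-wise VSI IQR. Optional cardiovascular covariates are added
#' one at a time to the multivariable model.
#'
#' @param subjects data.frame with columns `subject_id`, `group`
#'   (0 = control, 1 = patient), `age`, `sex` (0 = female, 1 = male), metric
#'   columns named `<metric>_<roi>` (e.g. `q_NAWM`, `vsi_CGM`), optional
#'   `vsi_iqr_<roi>` columns, and optional covariate columns.
#' @param metrics Metric prefixes analysed (default `q`, `vsi`, `mti`).
#' @param rois ROIs analysed between groups (default NAWM, DGM, CGM).
#' @param covariates Optional covariate column names added one at a time.
#' @return List of data.frames: `univariable`, `multivariable`,
#'   `interaction`, `covariate_adjusted`, `nawm_vs_wmh`, `vsi_iqr`.
#' @export
cohort_analysis <- function(subjects, metrics = c("q", "vsi", "mti"),
                            rois = c("NAWM", "DGM", "CGM"),
                            covariates = NULL) {
  stopifnot(all(c("group", "age", "sex") %in% names(subjects)))
  if (length(unique(subjects$group)) < 2L)
    stop("need both groups (controls and patients)")
  uni <- multi <- inter <- covadj <- list()
  for (m in metrics) for (r in rois) {
    col <- paste0(m, "_", r)
    if (!col %in% names(subjects)) next
    y <- subjects[[col]]
    ok <- is.finite(y)
    tag <- data.frame(metric = m, roi = r)
    uni[[col]] <- cbind(tag, ols_fit(y[ok], cbind(group = subjects$group[ok])))
    multi[[col]] <- cbind(tag, ols_fit(y[ok], cbind(group = subjects$group[ok],
                                                    age = subjects$age[ok],
                                                    sex = subjects$sex[ok])))
    inter[[col]] <- cbind(tag, interaction_model(y[ok], subjects$group[ok],
                                                 subjects$age[ok],
                                                 subjects$sex[ok]))
    for (cv in covariates) {
      X <- cbind(group = subjects$group[ok], age = subjects$age[ok],
                 sex = subjects$sex[ok])
      X <- cbind(X, stats::setNames(data.frame(subjects[[cv]][ok]), cv))
      covadj[[paste(col, cv)]] <- cbind(tag, covariate = cv,
                                        ols_fit(y[ok], as.matrix(X)))
    }
  }
  # paired NAWM vs WMH within patients
  paired <- list()
  pat <- subjects$group == 1
  for (m in metrics) {
    ca <- paste0(m, "_NAWM"); cb <- paste0(m, "_WMH")
    if (!all(c(ca, cb) %in% names(subjects))) next
    a <- subjects[[ca]][pat]; b <- subjects[[cb]][pat]
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 2L) next
    tt <- paired_ttest(a[ok], b[ok])
    paired[[m]] <- data.frame(metric = m, roi_a = "NAWM", roi_b = "WMH",
                              mean_a = mean(a[ok]), mean_b = mean(b[ok]),
                              pct_contrast = percent_contrast(mean(a[ok]),
                                                              mean(b[ok])),
                              t = tt$t, df = tt$df, p_value = tt$p)
  }
  # independent tests on the per-subject voxel-wise VSI IQR
  iqrres <- list()
  for (r in rois) {
    col <- paste0("vsi_iqr_", r)
    if (!col %in% names(subjects)) next
    a <- subjects[[col]][pat]; b <- subjects[[col]][!pat]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < 2L || length(b) < 2L) next
    tt <- independent_ttest(a, b)
    iqrres[[r]] <- data.frame(roi = r, mean_patients = mean(a),
                              mean_controls = mean(b), t = tt$t, df = tt$df,
                              p_value = tt$p)
  }
  list(univariable = rbind_rows(uni), multivariable = rbind_rows(multi),
       interaction = rbind_rows(inter), covariate_adjusted = rbind_rows(covadj),
       nawm_vs_wmh = rbind_rows(paired), vsi_iqr = rbind_rows(iqrres))
}

rbind_rows <- function(l) {
  if (!length(l)) return(NULL)
  do.call(rbind, c(l, list(make.row.names = FALSE)))
}

#' Format a regression table as markdown
#'
#' One row per ROI, with beta (95% CI) and p-value per term, in the layout
#' used for multivariable cohort reports.
#'
#' @param res A `multivariable` data.frame from [cohort_analysis()].
#' @return Character vector of markdown lines.
#' @export
format_regression_report <- function(res) {
  terms <- setdiff(unique(res$term), "(Intercept)")
  lines <- c(paste0("| metric | roi | ",
                    paste(sprintf("%s beta (95%% CI) | p ", terms),
                          collapse = "| "), "|"),
             paste0("|", paste(rep("---|", 2 + 2 * length(terms)),
                               collapse = "")))
  for (key in unique(paste(res$metric, res$roi))) {
    sub <- res[paste(res$metric, res$roi) == key, ]
    cells <- vapply(terms, function(tm) {
      row <- sub[sub$term == tm, ]
      sprintf("%.3f (%.3f to %.3f) | %.3g ", row$beta, row$ci95_low,
              row$ci95_high, row$p_value)
    }, character(1))
    lines <- c(lines, paste0("| ", sub$metric[1], " | ", sub$roi[1], " | ",
                             paste(cells, collapse = "| "), "|"))
  }
  lines
}
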