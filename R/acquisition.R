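#' Acquisition parameters for a dynamic GE/SE perfusion series
#'
#' Bundles the echo times, dynamic scan interval and bolus-injection timing of
#' a hybrid gradient-echo (GE) / spin-echo (SE) dynamic susceptibility contrast
#' acquisition. Defaults correspond to a combined GE-SE echo-planar protocol
#' with TE_GE/TE_SE = 25/78 ms, 100 dynamics at 1.6 s, and contrast injection
#' at the beginning of the 9th dynamic volume.
#'
#' All dynamic indices in this package are 1-based: `injection_dynamic = 9`
#' means dynamics 1..8 are pre-contrast, and `baseline_range = c(1, 8)` is the
#' default baseline.
#'
#' @param te_ge GE echo time in seconds.
#' @param te_se SE echo time in seconds.
#' @param dt Dynamic scan interval in seconds.
#' @param n_dynamics Number of dynamic volumes.
#' @param injection_dynamic 1-based index of the first post-injection dynamic.
#' @param baseline_range Inclusive 1-based index range of pre-contrast
#'   dynamics used for the baseline signal S0.
#' @return An object of class `vai_acquisition`.
#' @export
vai_acquisition <- function(te_ge = 0.025, te_se = 0.078, dt = 1.6,
                            n_dynamics = 100L, injection_dynamic = 9L,
                            baseline_range = c(1L, 8L)) {
  stopifnot(is.numeric(te_ge), te_ge > 0, is.numeric(te_se), te_se > 0,
            is.numeric(dt), dt > 0)
  n_dynamics <- as.integer(n_dynamics)
  injection_dynamic <- as.integer(injection_dynamic)
  baseline_range <- as.integer(baseline_range)
  if (length(baseline_range) != 2L || baseline_range[1] < 1L ||
      baseline_range[2] < baseline_range[1])
    stop("`baseline_range` must be an increasing pair of 1-based indices")
  if (baseline_range[2] >= injection_dynamic)
    stop("baseline range must end before the injection dynamic")
  if (n_dynamics < injection_dynamic)
    stop("`n_dynamics` must be at least `injection_dynamic`")
  structure(list(te_ge = te_ge, te_se = te_se, dt = dt,
                 n_dynamics = n_dynamics,
                 injection_dynamic = injection_dynamic,
                 baseline_range = baseline_range),
            class = "vai_acquisition")
}

#' @export
print.vai_acquisition <- function(x, ...) {
  cat(sprintf(
    "GE/SE acquisition: TE_GE %.0f ms, TE_SE %.0f ms, %d dynamics at %.2g s,\n",
    x$te_ge * 1000, x$te_se * 1000, x$n_dynamics, x$dt))
  cat(sprintf("  injection at dynamic %d, baseline dynamics %d-%d\n",
              x$injection_dynamic, x$baseline_range[1], x$baseline_range[2]))
  invisible(x)
}

#' Time grid of an acquisition
#'
#' @param params A `vai_acquisition` object.
#' @return Numeric vector of acquisition times in seconds, starting at 0.
#' @export
acquisition_times <- function(params) {
  (seq_len(params$n_dynamics) - 1) * params$dt
}

#' Read acquisition parameters from a YAML or JSON config file
#'
#' Recognised keys: `te_ge_s`, `te_se_s`, `dt_s`, `n_dynamics`,
#' `injection_dynamic`, `baseline_range` (pair of 1-based indices). Unknown
#' keys are rejected so typos do not silently fall back to defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `vai_acquisition` object.
#' @export
read_acquisition_config <- function(path) {
  cfg <- read_config_file(path)
  known <- c("te_ge_s", "te_se_s", "dt_s", "n_dynamics",
             "injection_dynamic", "baseline_range")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown acquisition config keys: ", paste(extra, collapse = ", "))
  defaults <- list(te_ge_s = 0.025, te_se_s = 0.078, dt_s = 1.6,
                   n_dynamics = 100L, injection_dynamic = 9L,
                   baseline_range = c(1L, 8L))
  cfg <- utils::modifyList(defaults, cfg)
  vai_acquisition(te_ge = cfg$te_ge_s, te_se = cfg$te_se_s, dt = cfg$dt_s,
                  n_dynamics = cfg$n_dynamics,
                  injection_dynamic = cfg$injection_dynamic,
                  baseline_range = unlist(cfg$baseline_range))
}

# Dispatch on file extension; YAML parses JSON-ish too but keep it explicit.
read_config_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config format: .", ext, " (use YAML or JSON)")
  }
}
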