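#' Pipeline configuration
#'
#' Collects every tunable processing constant in one overridable list. The
#' defaults are the operating point of the pipeline: 200 Hz sampling, a
#' 30 Hz fourth-order zero-phase low-pass for denoising, accelerometer filter
#' gain 1e-4 in the orientation filter, a drift-removal high-pass at 2/3 of
#' the stride frequency, the 1e-3 (deg/s)^2 / 10-sample variance exclusion
#' gate for alignment, and 1.96-standard-deviation limits of agreement.
#' `trim_strides` upper-body strides at each end of a trial are excluded from
#' the symmetry tables (the stride-frequency-tuned high-pass needs about one
#' stride to settle at each edge).
#'
#' @param ... Named overrides of the defaults (nested lists are merged).
#' @return A nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    sample_rate = 200,
    lowpass = list(cutoff = 30, order = 4),
    ahrs = list(accel_gain = 1e-4, gravity = 9.81),
    events = list(omega_threshold = 20, min_stance = 0.08,
                  lowpass_cutoff = 15, refine_window = 0.2,
                  acc_prominence = 3),
    highpass = list(stride_freq_fraction = 2 / 3, order = 4),
    sync = list(max_lag = 30),
    alignment = list(variance_threshold = 1e-3, variance_window = 10),
    agreement = list(loa_mult = 1.96, conf = 0.95),
    trim_strides = 1,
    ref_limb = "LF",
    upper_locations = c("withers", "sacrum", "sternum"),
    stride_freq_location = "sacrum"
  )
  over <- list(...)
  if (length(over)) cfg <- utils::modifyList(cfg, over)
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path File path.
#' @return `read_pipeline_config` returns a [pipeline_config()];
#'   `write_pipeline_config` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  over <- yaml::read_yaml(path)
  do.call(pipeline_config, over)
}

#' @rdname read_pipeline_config
#' @param cfg A [pipeline_config()].
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
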