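#' Read a study configuration from a YAML file
#'
#' Nested key-value configuration holding the global seed, cohort size,
#' loading protocol, per-exercise trajectory settings and per-device error
#' profiles. Any omitted field falls back to the package default, so a
#' minimal file may set only what it varies.
#'
#' @param path Path to a YAML file.
#' @return A [study_config()].
#' @export
#' @examples
#' cfg_file <- tempfile(fileext = ".yml")
#' writeLines(c("seed: 7", "n_subjects: 10", "devices:",
#'              "  lt_ref: {alpha: 0.005, beta: 1.0, sigma: 0.015}"),
#'            cfg_file)
#' if (requireNamespace("yaml", quietly = TRUE)) read_study_config(cfg_file)
read_study_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read configuration files",
         call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  protocol <- if (is.null(raw$protocol)) {
    protocol_spec()
  } else {
    do.call(protocol_spec, raw$protocol)
  }
  trajectories <- lapply(stats::setNames(EXERCISES, EXERCISES), function(ex) {
    args <- raw$trajectories[[ex]] %||% list()
    do.call(trajectory_config, c(list(exercise = ex), args))
  })
  devices <- if (is.null(raw$devices)) {
    default_devices()
  } else {
    lapply(names(raw$devices), function(id) {
      do.call(device_profile, c(list(device_id = id), raw$devices[[id]]))
    })
  }
  sampler <- if (is.null(raw$sampler)) {
    sampler_spec()
  } else {
    do.call(sampler_spec, raw$sampler)
  }
  study_config(
    seed = raw$seed %||% 1L,
    n_subjects = raw$n_subjects %||% 20L,
    protocol = protocol,
    trajectories = trajectories,
    devices = devices,
    criterion_id = raw$criterion_id %||% "vicon",
    reference_id = raw$reference_id %||% "lt_ref",
    sampler = sampler,
    rope_mass = raw$rope_mass %||% 0.95,
    statistics = raw$statistics %||% c("intercept", "slope", "r2", "rmse",
                                       "smb")
  )
}
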