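# Run configuration: one flat list of the pipeline parameters, round-
# trippable through YAML so every run can write its resolved settings.

#' Pipeline run configuration
#'
#' Collects every tunable parameter of the pipeline with its default. The
#' result serializes to YAML ([write_timex_config()]) and back.
#'
#' @param ... Overrides of the defaults (unknown names error).
#' @return A named `timex_config` list.
#' @export
timex_config <- function(...) {
  defaults <- list(
    bin_width = 500, sigma = 1e5, scale_factor = 1.4,
    hires_bin_width = 1000, hires_sigma = 2e4, hires_outlier_cut = 2.4,
    ard_threshold = 0.02, ard_max_gap = 250000, ard_min_size = 50000,
    core_threshold = 0.1, core_max_gap = 50000, core_min_size = 50000,
    fdr = 0.05, s_length_min = 480, range_factor = 1.2,
    mean_depth = 25, snp_spacing_min = 500, snp_spacing_max = 5000,
    timing_domain_scale = 1e6,
    sigma_fine = 2e4, sigma_coarse = 1e5, top_fraction = 0.1,
    peak_width = 400, top_n_peaks = 100000, bootstrap_iters = 100,
    sv_sub = 5000, sv_window = 5e5, sv_step = 1e5, sv_n_rand = 1000,
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("unknown config fields: %s", paste(unknown, collapse = ", ")))
  }
  defaults[names(over)] <- over
  structure(defaults, class = "timex_config")
}

#' @rdname timex_config
#' @param config A `timex_config`.
#' @param path YAML file path.
#' @export
write_timex_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname timex_config
#' @export
read_timex_config <- function(path) {
  do.call(timex_config, yaml::read_yaml(path))
}
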