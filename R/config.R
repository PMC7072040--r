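#' Pipeline configuration
#'
#' Loads the default processing profile shipped with the package (a fully
#' documented YAML file; see
#' `system.file("extdata", "default_config.yaml", package = "dxascol")`),
#' optionally merged with a user YAML file and with named overrides.
#' Overrides use `$`-nested names, e.g.
#' `dsm_config(preprocessing = list(target_height_px = 256))`.
#'
#' @param file optional path to a YAML file whose keys override the defaults.
#' @param ... named lists merged on top (deepest wins).
#' @return A nested list of class `dsm_config`.
#' @examples
#' cfg <- dsm_config()
#' cfg$classification$cutoff
#' @export
dsm_config <- function(file = NULL, ...) {
  cfg <- yaml::read_yaml(system.file("extdata", "default_config.yaml",
                                     package = "dxascol"))
  if (!is.null(file)) cfg <- modifyList(cfg, yaml::read_yaml(file))
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop_dxascol("invalid_input", "config overrides must be named")
    cfg <- modifyList(cfg, dots)
  }
  validate_config(cfg)
  structure(cfg, class = c("dsm_config", "list"))
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$preprocessing$target_height_px >= 2,
    cfg$midspine$sigma_px > 0,
    cfg$midline$df >= 3,
    cfg$suspiciousness$midpoint_deg > 0,
    cfg$suspiciousness$steepness_per_deg > 0,
    cfg$positioning$tilt_max_deg > 0,
    cfg$positioning$offset_max_frac > 0,
    cfg$positioning$asym_max > 0,
    cfg$positioning$exclusion_threshold >= 0,
    cfg$positioning$exclusion_threshold <= 1,
    cfg$classification$cutoff >= 0, cfg$classification$cutoff <= 1,
    !is.unsorted(cfg$classification$cutoff_sweep, strictly = TRUE),
    cfg$projection$prevalence > 0, cfg$projection$prevalence < 1,
    cfg$projection$n_population >= 1
  )
  invisible(cfg)
}

#' @export
print.dsm_config <- function(x, ...) {
  cat("<dsm_config>\n")
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}
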