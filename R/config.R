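# Plain-text (YAML) parameter files. Dimensioned keys declare their unit
# explicitly and are normalised to the canonical internal units (mm, ms)
# on load. Unknown keys are rejected rather than ignored.

CONFIG_LENGTH_KEYS <- c("sigma_v", "sigma_p", "mu_x", "sigma_x")
CONFIG_TIME_KEYS <- c("sigma_tv", "sigma_tt", "mu_t", "sigma_t")
CONFIG_PLAIN_KEYS <- c("p_common", "include_temporal")
CONFIG_META_KEYS <- c("provenance")

read_dimensioned <- function(entry, key, kind) {
  if (is.numeric(entry) && length(entry) == 1L)
    stop_param("config key '", key, "' must declare a unit, e.g. ",
               "{value: ", entry, ", unit: ",
               if (kind == "length") "mm" else "ms", "}")
  if (!is.list(entry) || !all(c("value", "unit") %in% names(entry)))
    stop_param("config key '", key, "' must be a {value, unit} pair")
  if (kind == "length") as_mm(entry$value, entry$unit)
  else as_ms(entry$value, entry$unit)
}

#' Read model parameters from a YAML configuration file
#'
#' Keys mirror the [rhi_params()] fields. Every dimensioned key (`sigma_v`,
#' `sigma_p`, `mu_x`, `sigma_x` in mm/cm/m; `sigma_tv`, `sigma_tt`, `mu_t`,
#' `sigma_t` in ms/s) is written as a `{value, unit}` pair and converted to
#' mm/ms on load; `p_common` and `include_temporal` are plain scalars. A
#' free-text `provenance` key is allowed and attached as an attribute.
#' Unknown keys, missing units and invalid values (e.g. a non-positive SD)
#' are rejected with the offending key named.
#'
#' @param path YAML file; defaults to the calibrated configuration shipped
#'   with the package.
#' @return An [rhi_params()] object with attribute `provenance`.
#' @export
load_config <- function(path = default_config_path()) {
  if (!file.exists(path)) stop_input("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  known <- c(CONFIG_LENGTH_KEYS, CONFIG_TIME_KEYS, CONFIG_PLAIN_KEYS,
             CONFIG_META_KEYS)
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop_param("unknown config key(s): ", paste(unknown, collapse = ", "))
  vals <- list()
  for (key in intersect(CONFIG_LENGTH_KEYS, names(raw)))
    vals[[key]] <- read_dimensioned(raw[[key]], key, "length")
  for (key in intersect(CONFIG_TIME_KEYS, names(raw)))
    vals[[key]] <- read_dimensioned(raw[[key]], key, "time")
  for (key in intersect(CONFIG_PLAIN_KEYS, names(raw)))
    vals[[key]] <- raw[[key]]
  defaults <- rhi_priors()
  priors <- rhi_priors(
    mu_x = vals$mu_x %||% defaults$mu_x,
    sigma_x = vals$sigma_x %||% defaults$sigma_x,
    mu_t = vals$mu_t %||% defaults$mu_t,
    sigma_t = vals$sigma_t %||% defaults$sigma_t,
    p_common = vals$p_common %||% defaults$p_common
  )
  params <- rhi_params(
    sigma_v = vals$sigma_v %||% 1,
    sigma_p = vals$sigma_p %||% 15,
    sigma_tv = vals$sigma_tv %||% 20,
    sigma_tt = vals$sigma_tt %||% 20,
    priors = priors,
    include_temporal = vals$include_temporal %||% TRUE
  )
  attr(params, "provenance") <- raw$provenance
  params
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write model parameters to a YAML configuration file
#'
#' Inverse of [load_config()]: emits all parameters in canonical units
#' (mm/ms) with explicit unit declarations.
#'
#' @param params An [rhi_params()] object.
#' @param path Output file.
#' @param provenance Optional free-text note recording how the parameters
#'   were obtained (e.g. the calibration call).
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path, provenance = NULL) {
  if (!inherits(params, "rhi_params")) stop_param("params must be an rhi_params")
  pr <- params$priors
  dim_entry <- function(v, u) list(value = v, unit = u)
  out <- list(
    sigma_v = dim_entry(params$sigma_v, "mm"),
    sigma_p = dim_entry(params$sigma_p, "mm"),
    sigma_tv = dim_entry(params$sigma_tv, "ms"),
    sigma_tt = dim_entry(params$sigma_tt, "ms"),
    mu_x = dim_entry(pr$mu_x, "mm"),
    sigma_x = dim_entry(pr$sigma_x, "mm"),
    mu_t = dim_entry(pr$mu_t, "ms"),
    sigma_t = dim_entry(pr$sigma_t, "ms"),
    p_common = pr$p_common,
    include_temporal = params$include_temporal
  )
  if (!is.null(provenance)) out$provenance <- provenance
  yaml::write_yaml(out, path, precision = 17)
  invisible(path)
}

#' Path of the shipped default configuration
#'
#' The calibrated default parameters recorded as a YAML file; see
#' [default_params()] and [calibrate_prior_width()].
#'
#' @return File path.
#' @export
default_config_path <- function() {
  system.file("extdata", "default_params.yaml", package = "rhibayes",
              mustWork = TRUE)
}
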