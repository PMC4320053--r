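# Parameter containers and validation. Canonical internal units are
# millimetres (space) and milliseconds (time); conversion from cm/s happens
# at the interfaces (see as_mm(), as_ms(), load_config()).

#' Convert lengths and times to canonical internal units
#'
#' All model arithmetic is carried out in millimetres and milliseconds.
#' These helpers convert values declared in other units at package
#' boundaries (configuration files, command-line flags).
#'
#' @param x Numeric vector.
#' @param unit Unit the values are expressed in: `"mm"`, `"cm"` or `"m"` for
#'   lengths; `"ms"` or `"s"` for times.
#' @return Numeric vector in mm (`as_mm`) or ms (`as_ms`).
#' @examples
#' as_mm(16, "cm")  # 160
#' as_ms(0.75, "s") # 750
#' @export
as_mm <- function(x, unit = c("mm", "cm", "m")) {
  unit <- match.arg(unit)
  x * switch(unit, mm = 1, cm = 10, m = 1000)
}

#' @rdname as_mm
#' @export
as_ms <- function(x, unit = c("ms", "s")) {
  unit <- match.arg(unit)
  x * switch(unit, ms = 1, s = 1000)
}

stop_param <- function(...) {
  stop(errorCondition(paste0(...), class = c("rhi_param_error", "error")))
}

stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("rhi_input_error", "error")))
}

check_scalar <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_param(name, " must be a single non-missing number")
  if (finite && !is.finite(x))
    stop_param(name, " must be finite")
  if (positive && x <= 0)
    stop_param(name, " must be strictly positive (got ", x, ")")
  as.numeric(x)
}

#' Priors over the latent spatial and temporal stimulus variables
#'
#' The latent hand position X (mm from the body midline, increasing toward
#' the occluded hand) and latent event time T (ms from trial start) carry
#' Gaussian priors N(mu_x, sigma_x) and N(mu_t, sigma_t). `p_common` is the
#' prior probability that all sensory signals share one environmental cause.
#'
#' The prior widths act through the Occam factor of the marginal
#' likelihoods: a wider prior penalises the independent-causes structure
#' relative to the common-cause structure, so the common-cause posterior at
#' a given cue discrepancy depends directly on `sigma_x` and `sigma_t`.
#' They are therefore explicit configuration; shipped defaults come from
#' [calibrate_prior_width()]. A "flat" prior is represented by a proper,
#' very wide Gaussian rather than an improper uniform, which would make the
#' marginal-likelihood ratio ill-defined.
#'
#' @param mu_x,sigma_x Mean and SD of the spatial prior, mm. `sigma_x > 0`.
#' @param mu_t,sigma_t Mean and SD of the temporal prior, ms. `sigma_t > 0`.
#' @param p_common Prior probability of a common cause, in `[0, 1]`.
#' @return An object of class `rhi_priors`.
#' @seealso [rhi_params()], [calibrate_prior_width()]
#' @export
rhi_priors <- function(mu_x = 0, sigma_x = 1e4, mu_t = 0, sigma_t = 1e4,
                       p_common = 0.5) {
  mu_x <- check_scalar(mu_x, "mu_x")
  sigma_x <- check_scalar(sigma_x, "sigma_x", positive = TRUE)
  mu_t <- check_scalar(mu_t, "mu_t")
  sigma_t <- check_scalar(sigma_t, "sigma_t", positive = TRUE)
  p_common <- check_scalar(p_common, "p_common")
  if (p_common < 0 || p_common > 1)
    stop_param("p_common must lie in [0, 1] (got ", p_common, ")")
  structure(list(mu_x = mu_x, sigma_x = sigma_x, mu_t = mu_t,
                 sigma_t = sigma_t, p_common = p_common),
            class = "rhi_priors")
}

#' Observer model parameters
#'
#' Sensory noise standard deviations for the four cues, the latent-variable
#' priors, and whether the temporal dimension participates at all (it does
#' not when no stroking is delivered, so the inference is purely spatial).
#'
#' Default sensory noise values are the ones used throughout the package's
#' simulations: proprioceptive spatial SD 15 mm, visual spatial SD 1 mm,
#' and 20 ms temporal SDs for both the visual and tactile timing cues.
#'
#' @param sigma_v Visual spatial SD, mm.
#' @param sigma_p Proprioceptive spatial SD, mm.
#' @param sigma_tv Visual temporal SD, ms.
#' @param sigma_tt Tactile temporal SD, ms.
#' @param priors An [rhi_priors()] object.
#' @param include_temporal Logical; when `FALSE` every operation ignores the
#'   temporal cues and priors (spatial-only model).
#' @return An object of class `rhi_params`.
#' @seealso [default_params()] for the calibrated defaults.
#' @export
rhi_params <- function(sigma_v = 1, sigma_p = 15, sigma_tv = 20,
                       sigma_tt = 20, priors = rhi_priors(),
                       include_temporal = TRUE) {
  if (!inherits(priors, "rhi_priors"))
    stop_param("priors must be an rhi_priors object")
  if (!is.logical(include_temporal) || length(include_temporal) != 1L ||
      is.na(include_temporal))
    stop_param("include_temporal must be TRUE or FALSE")
  structure(list(
    sigma_v = check_scalar(sigma_v, "sigma_v", positive = TRUE),
    sigma_p = check_scalar(sigma_p, "sigma_p", positive = TRUE),
    sigma_tv = check_scalar(sigma_tv, "sigma_tv", positive = TRUE),
    sigma_tt = check_scalar(sigma_tt, "sigma_tt", positive = TRUE),
    priors = priors,
    include_temporal = include_temporal
  ), class = "rhi_params")
}

#' Default calibrated model parameters
#'
#' Returns the package's default observer: sigma_p = 15 mm, sigma_v = 1 mm,
#' temporal SDs 20 ms, p(C = 1) = 0.5, and prior widths calibrated by
#' [calibrate_prior_width()] so that, with noise-free cues and synchronous
#' timing, the common-cause posterior equals 0.5 at a 300 mm hand
#' separation. The calibration is deterministic (closed-form root search),
#' so this function always returns the same object.
#'
#' @param include_temporal Logical; drop the temporal dimension for
#'   spatial-only (no-stroking) analyses.
#' @return An `rhi_params` object.
#' @export
default_params <- function(include_temporal = TRUE) {
  p <- calibrate_prior_width()$params
  p$include_temporal <- include_temporal
  p
}

#' One (or many) trials' noisy sensory cues
#'
#' A sensory sample holds the four internal signals on which the causal
#' inference operates: visual and proprioceptive position cues (mm from the
#' body midline, increasing toward the occluded-hand side) and visual and
#' tactile timing cues (ms from trial start). All fields are vectorised, so
#' one object can hold a whole Monte Carlo batch. Temporal cues may be
#' omitted only for spatial-only analyses (models with
#' `include_temporal = FALSE`); a temporal model presented with a sample
#' lacking timing cues raises an input error rather than silently falling
#' back to spatial-only inference.
#'
#' @param chi_v Visual position cue(s), mm.
#' @param chi_p Proprioceptive position cue(s), mm.
#' @param tau_v Visual timing cue(s), ms, or `NULL`.
#' @param tau_t Tactile timing cue(s), ms, or `NULL`.
#' @return An object of class `rhi_sample`.
#' @export
sensory_sample <- function(chi_v, chi_p, tau_v = NULL, tau_t = NULL) {
  check_vec <- function(x, name) {
    if (!is.numeric(x) || length(x) == 0L || !all(is.finite(x)))
      stop_input(name, " must be a non-empty finite numeric vector")
    as.numeric(x)
  }
  chi_v <- check_vec(chi_v, "chi_v")
  chi_p <- check_vec(chi_p, "chi_p")
  if (length(chi_v) != length(chi_p))
    stop_input("chi_v and chi_p must have equal length")
  if (xor(is.null(tau_v), is.null(tau_t)))
    stop_input("tau_v and tau_t must be supplied together or both omitted")
  if (!is.null(tau_v)) {
    tau_v <- check_vec(tau_v, "tau_v")
    tau_t <- check_vec(tau_t, "tau_t")
    if (length(tau_v) != length(chi_v) || length(tau_t) != length(chi_v))
      stop_input("temporal cues must match the length of the spatial cues")
  }
  structure(list(chi_v = chi_v, chi_p = chi_p, tau_v = tau_v, tau_t = tau_t),
            class = "rhi_sample")
}

has_temporal <- function(sample) !is.null(sample$tau_v)

# Shared precondition for every likelihood/estimate operation.
check_model_inputs <- function(sample, params) {
  if (!inherits(sample, "rhi_sample")) stop_input("sample must be an rhi_sample")
  if (!inherits(params, "rhi_params")) stop_param("params must be an rhi_params")
  if (params$include_temporal && !has_temporal(sample))
    stop_input("model includes the temporal dimension but the sample has no ",
               "timing cues; build a spatial-only model explicitly with ",
               "include_temporal = FALSE")
  invisible(TRUE)
}

#' @export
print.rhi_priors <- function(x, ...) {
  cat("Latent-variable priors:\n")
  cat(sprintf("  X ~ N(%g, %g) mm   T ~ N(%g, %g) ms\n",
              x$mu_x, x$sigma_x, x$mu_t, x$sigma_t))
  cat(sprintf("  p(C = 1) = %g\n", x$p_common))
  invisible(x)
}

#' @export
print.rhi_params <- function(x, ...) {
  cat("Causal-inference observer parameters\n")
  cat(sprintf("  spatial noise:  sigma_v = %g mm, sigma_p = %g mm\n",
              x$sigma_v, x$sigma_p))
  if (x$include_temporal)
    cat(sprintf("  temporal noise: sigma_tv = %g ms, sigma_tt = %g ms\n",
                x$sigma_tv, x$sigma_tt))
  else
    cat("  temporal dimension disabled (spatial-only)\n")
  print(x$priors)
  invisible(x)
}
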