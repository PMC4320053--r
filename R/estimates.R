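# Optimal stimulus estimates. Under squared-error loss on both the spatial
# and the temporal estimate, the optimal readout is the posterior mean, so
# the final estimate is the model average: the common-cause (fused) and
# independent-causes (segregated) conditional means mixed by the posterior
# probability of each structure.

precision_weighted_mean <- function(values, sds) {
  w <- lapply(sds, function(s) 1 / s^2)
  num <- 0
  for (i in seq_along(values)) num <- num + values[[i]] * w[[i]]
  num / Reduce(`+`, w)
}

#' Fused (common-cause) spatial estimate
#'
#' Under C = 1 the best estimate of hand position is the same for both
#' modalities: the precision-weighted mean of the visual cue, the
#' proprioceptive cue, and the prior mean.
#'
#' @inheritParams likelihood_common
#' @return Numeric vector, mm.
#' @export
fused_spatial_estimate <- function(sample, params) {
  check_model_inputs(sample, params)
  pr <- params$priors
  precision_weighted_mean(list(sample$chi_v, sample$chi_p, pr$mu_x),
                          list(params$sigma_v, params$sigma_p, pr$sigma_x))
}

#' Segregated (independent-causes) spatial estimates
#'
#' Under C = 2 each modality combines only its own cue with the prior.
#'
#' @inheritParams likelihood_common
#' @return A list with numeric components `visual` and `proprioceptive`, mm.
#' @export
segregated_estimates <- function(sample, params) {
  check_model_inputs(sample, params)
  pr <- params$priors
  list(
    visual = precision_weighted_mean(list(sample$chi_v, pr$mu_x),
                                     list(params$sigma_v, pr$sigma_x)),
    proprioceptive = precision_weighted_mean(list(sample$chi_p, pr$mu_x),
                                             list(params$sigma_p, pr$sigma_x))
  )
}

#' Model-averaged spatial and temporal estimates
#'
#' Evaluates the full inference for each trial in `sample`: the posterior
#' probability of a common cause, the fused and segregated conditional
#' estimates, and their posterior-weighted mixture (the squared-error
#' optimal readout). Temporal estimates are computed with identical algebra
#' on the timing cues whenever the temporal dimension is enabled.
#'
#' Both the averaged values and the per-structure components are returned:
#' every averaged estimate is a convex combination of its fused and
#' segregated components, so either readout can be inspected.
#'
#' @inheritParams likelihood_common
#' @return A data frame of class `rhi_estimates` with one row per trial and
#'   columns `p_c1`, `x_hat_p`, `x_hat_v`, `x_fused`, `x_seg_v`, `x_seg_p`
#'   (mm) plus, for temporal models, `t_hat_v`, `t_hat_t`, `t_fused`,
#'   `t_seg_v`, `t_seg_t` (ms).
#' @examples
#' p <- default_params()
#' s <- sensory_sample(160, 320, 1000, 1000)
#' model_averaged_estimates(s, p)
#' @export
model_averaged_estimates <- function(sample, params) {
  check_model_inputs(sample, params)
  p1 <- posterior_common_cause(sample, params)
  fused <- fused_spatial_estimate(sample, params)
  seg <- segregated_estimates(sample, params)
  out <- data.frame(
    p_c1 = p1,
    x_hat_p = p1 * fused + (1 - p1) * seg$proprioceptive,
    x_hat_v = p1 * fused + (1 - p1) * seg$visual,
    x_fused = fused,
    x_seg_v = seg$visual,
    x_seg_p = seg$proprioceptive
  )
  if (params$include_temporal) {
    pr <- params$priors
    t_fused <- precision_weighted_mean(
      list(sample$tau_v, sample$tau_t, pr$mu_t),
      list(params$sigma_tv, params$sigma_tt, pr$sigma_t))
    t_seg_v <- precision_weighted_mean(list(sample$tau_v, pr$mu_t),
                                       list(params$sigma_tv, pr$sigma_t))
    t_seg_t <- precision_weighted_mean(list(sample$tau_t, pr$mu_t),
                                       list(params$sigma_tt, pr$sigma_t))
    out$t_hat_v <- p1 * t_fused + (1 - p1) * t_seg_v
    out$t_hat_t <- p1 * t_fused + (1 - p1) * t_seg_t
    out$t_fused <- t_fused
    out$t_seg_v <- t_seg_v
    out$t_seg_t <- t_seg_t
  }
  class(out) <- c("rhi_estimates", "data.frame")
  out
}
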