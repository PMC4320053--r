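# Closed-form marginal likelihoods of the two causal structures and the
# common-cause posterior. Spatial and temporal factors are independent, so
# each marginal is a product of one-dimensional Gaussian integrals that have
# analytic solutions. Everything is computed in log space: at the default
# geometry the cue discrepancy is ~10 proprioceptive SDs, where the raw
# densities underflow double precision.

# log of integral over X of N(x1; X, s1) N(x2; X, s2) N(X; m, s0):
# a Gaussian marginal with covariance [[s1^2+s0^2, s0^2], [s0^2, s2^2+s0^2]].
log_marg_common_1d <- function(x1, x2, s1, s2, m, s0) {
  V <- s1^2 * s2^2 + s1^2 * s0^2 + s2^2 * s0^2
  -log(2 * pi) - 0.5 * log(V) -
    0.5 * ((x1 - x2)^2 * s0^2 + (x1 - m)^2 * s2^2 + (x2 - m)^2 * s1^2) / V
}

# log of [int N(x1; X1, s1) N(X1; m, s0) dX1] * [same for x2]: each cue has
# its own latent cause drawn from the prior.
log_marg_indep_1d <- function(x1, x2, s1, s2, m, s0) {
  stats::dnorm(x1, m, sqrt(s1^2 + s0^2), log = TRUE) +
    stats::dnorm(x2, m, sqrt(s2^2 + s0^2), log = TRUE)
}

#' Marginal likelihood of a sensory sample under each causal structure
#'
#' Under a common cause (C = 1) one latent position X generates both spatial
#' cues and one latent time T generates both timing cues, and the latents
#' are integrated out against their Gaussian priors. Under independent
#' causes (C = 2) each cue gets its own latent draw from the prior. Because
#' spatial and temporal signals are assumed statistically independent, both
#' marginals factor into a spatial and (when the temporal dimension is
#' enabled) a temporal term, each available in closed form.
#'
#' `log_likelihood_common()` / `log_likelihood_independent()` return the log
#' density and are what the rest of the package uses; the non-log versions
#' exponentiate and will underflow to 0 for widely discrepant cues.
#'
#' @param sample An [sensory_sample()] object (vectorised).
#' @param params An [rhi_params()] object.
#' @return Numeric vector of (log) densities, one per trial in `sample`.
#' @examples
#' p <- rhi_params(priors = rhi_priors(sigma_x = 100, sigma_t = 100))
#' s <- sensory_sample(0, 0, 0, 0)
#' likelihood_common(s, p) > likelihood_independent(s, p)  # identical cues
#' @export
likelihood_common <- function(sample, params) {
  exp(log_likelihood_common(sample, params))
}

#' @rdname likelihood_common
#' @export
likelihood_independent <- function(sample, params) {
  exp(log_likelihood_independent(sample, params))
}

#' @rdname likelihood_common
#' @export
log_likelihood_common <- function(sample, params) {
  check_model_inputs(sample, params)
  pr <- params$priors
  ll <- log_marg_common_1d(sample$chi_v, sample$chi_p, params$sigma_v,
                           params$sigma_p, pr$mu_x, pr$sigma_x)
  if (params$include_temporal)
    ll <- ll + log_marg_common_1d(sample$tau_v, sample$tau_t, params$sigma_tv,
                                  params$sigma_tt, pr$mu_t, pr$sigma_t)
  ll
}

#' @rdname likelihood_common
#' @export
log_likelihood_independent <- function(sample, params) {
  check_model_inputs(sample, params)
  pr <- params$priors
  ll <- log_marg_indep_1d(sample$chi_v, sample$chi_p, params$sigma_v,
                          params$sigma_p, pr$mu_x, pr$sigma_x)
  if (params$include_temporal)
    ll <- ll + log_marg_indep_1d(sample$tau_v, sample$tau_t, params$sigma_tv,
                                 params$sigma_tt, pr$mu_t, pr$sigma_t)
  ll
}

#' Posterior probability that the sensory signals share a common cause
#'
#' Bayes' rule over the two causal structures: the common-cause marginal
#' likelihood weighted by the prior `p_common` against the
#' independent-causes marginal weighted by `1 - p_common`. Computed from the
#' log-likelihood difference, so it remains exact when both raw densities
#' underflow.
#'
#' The posterior is non-increasing in the spatial discrepancy |chi_v -
#' chi_p| and the temporal discrepancy |tau_v - tau_t|, and non-decreasing
#' in `p_common`.
#'
#' @inheritParams likelihood_common
#' @return Numeric vector of probabilities in `[0, 1]`, one per trial.
#' @export
posterior_common_cause <- function(sample, params) {
  check_model_inputs(sample, params)
  pc <- params$priors$p_common
  if (pc == 0) return(rep(0, length(sample$chi_v)))
  if (pc == 1) return(rep(1, length(sample$chi_v)))
  dl <- (log1p(-pc) + log_likelihood_independent(sample, params)) -
        (log(pc)    + log_likelihood_common(sample, params))
  stats::plogis(-dl)
}
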