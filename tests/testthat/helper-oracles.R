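# Independent numerical oracles and fixture builders used across the
# suite. The quadrature oracles integrate the generative joint density
# directly (nested adaptive quadrature over the latent position and time),
# without reusing any closed form from the package.

# Adaptive quadrature over the union of every factor's +-12 sigma support,
# split at the factors' boundaries so narrow spikes are never missed.
quad_piecewise <- function(f, centers, scales) {
  knots <- sort(unique(c(centers - 12 * scales, centers + 12 * scales)))
  total <- 0
  for (i in seq_len(length(knots) - 1L)) {
    a <- knots[i]; b <- knots[i + 1L]
    fmax <- max(f(seq(a, b, length.out = 17)))
    if (fmax <= 1e-280) next  # numerically empty tail segment
    total <- total + stats::integrate(f, a, b, rel.tol = 1e-12,
                                      abs.tol = fmax * (b - a) * 1e-13,
                                      subdivisions = 500L)$value
  }
  total
}

# marginal density of (chi_v, chi_p, tau_v, tau_t) under a common cause:
# one latent X generates both position cues, one latent T both timing cues
quad_lik_common <- function(s, p) {
  pr <- p$priors
  inner_t <- function(X) {
    if (!p$include_temporal) return(1)
    quad_piecewise(function(T_)
      dnorm(s$tau_v, T_, p$sigma_tv) * dnorm(s$tau_t, T_, p$sigma_tt) *
        dnorm(T_, pr$mu_t, pr$sigma_t),
      centers = c(s$tau_v, s$tau_t, pr$mu_t),
      scales = c(p$sigma_tv, p$sigma_tt, pr$sigma_t))
  }
  quad_piecewise(function(X) {
    fx <- dnorm(s$chi_v, X, p$sigma_v) * dnorm(s$chi_p, X, p$sigma_p) *
      dnorm(X, pr$mu_x, pr$sigma_x)
    fx * vapply(X, inner_t, numeric(1))
  }, centers = c(s$chi_v, s$chi_p, pr$mu_x),
     scales = c(p$sigma_v, p$sigma_p, pr$sigma_x))
}

# marginal under independent causes: each cue gets its own latent draw
quad_lik_independent <- function(s, p) {
  pr <- p$priors
  one <- function(x, sn, m, s0)
    quad_piecewise(function(z) dnorm(x, z, sn) * dnorm(z, m, s0),
                   centers = c(x, m), scales = c(sn, s0))
  out <- one(s$chi_v, p$sigma_v, pr$mu_x, pr$sigma_x) *
    one(s$chi_p, p$sigma_p, pr$mu_x, pr$sigma_x)
  if (p$include_temporal)
    out <- out * one(s$tau_v, p$sigma_tv, pr$mu_t, pr$sigma_t) *
      one(s$tau_t, p$sigma_tt, pr$mu_t, pr$sigma_t)
  out
}

# random parameter/sample draw in a regime where quadrature is reliable
# (densities far from underflow)
random_model_case <- function(temporal = TRUE) {
  pr <- rhi_priors(mu_x = runif(1, -200, 200),
                   sigma_x = runif(1, 50, 3000),
                   mu_t = runif(1, -200, 200),
                   sigma_t = runif(1, 50, 3000),
                   p_common = runif(1, 0.05, 0.95))
  params <- rhi_params(sigma_v = runif(1, 0.5, 30),
                       sigma_p = runif(1, 0.5, 30),
                       sigma_tv = runif(1, 0.5, 30),
                       sigma_tt = runif(1, 0.5, 30),
                       priors = pr, include_temporal = temporal)
  sample <- if (temporal)
    sensory_sample(runif(1, -300, 300), runif(1, -300, 300),
                   runif(1, -300, 300), runif(1, -300, 300))
  else sensory_sample(runif(1, -300, 300), runif(1, -300, 300))
  list(sample = sample, params = params)
}

# small hand-built Experiment 1 record set: `n` subjects cycled over the
# four groups, localization matrices supplied or defaulting to zeros
make_exp1 <- function(pre, post, groups = NULL, ownership_pre = NULL,
                      ownership_post = NULL, true_x = NA_real_) {
  n <- nrow(pre)
  if (is.null(groups))
    groups <- rep(c("sync", "async", "no_stroke", "no_hand"), length.out = n)
  subjects <- data.frame(
    subject = sprintf("s%02d", seq_len(n)), group = groups,
    ownership_pre = ownership_pre %||% rep(1L, n),
    ownership_post = ownership_post %||% rep(1L, n),
    true_x = true_x, stringsAsFactors = FALSE)
  suppressWarnings(exp1_records(subjects, pre, post))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 99% two-sided Monte Carlo band half-width for a binomial proportion
mc_band <- function(p, n) qnorm(0.995) * sqrt(pmax(p * (1 - p), 1e-12) / n)
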