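# Closed-form marginal likelihoods and the common-cause posterior.

test_that("closed-form marginals match nested adaptive quadrature", {
  set.seed(101)
  for (i in 1:30) {
    case <- random_model_case(temporal = TRUE)
    expect_equal(likelihood_common(case$sample, case$params),
                 quad_lik_common(case$sample, case$params),
                 tolerance = 1e-8)
    expect_equal(likelihood_independent(case$sample, case$params),
                 quad_lik_independent(case$sample, case$params),
                 tolerance = 1e-8)
  }
  for (i in 1:10) {
    case <- random_model_case(temporal = FALSE)
    expect_equal(likelihood_common(case$sample, case$params),
                 quad_lik_common(case$sample, case$params),
                 tolerance = 1e-8)
    expect_equal(likelihood_independent(case$sample, case$params),
                 quad_lik_independent(case$sample, case$params),
                 tolerance = 1e-8)
  }
})

test_that("wide-prior limit: common-cause marginal tends to the cue-difference density", {
  p <- rhi_params(priors = rhi_priors(sigma_x = 1e7),
                  include_temporal = FALSE)
  s <- sensory_sample(12, -30)
  # N(chi_v - chi_p; 0, sqrt(sv^2 + sp^2)) spread over the prior width
  approx <- dnorm(12 - (-30), 0, sqrt(p$sigma_v^2 + p$sigma_p^2)) /
    (sqrt(2 * pi) * p$priors$sigma_x)
  expect_equal(likelihood_common(s, p), approx, tolerance = 1e-6)
})

test_that("marginals are symmetric under exchanging cues with their noise SDs", {
  p1 <- rhi_params(sigma_v = 3, sigma_p = 17, sigma_tv = 8, sigma_tt = 25,
                   priors = rhi_priors(sigma_x = 500, sigma_t = 700))
  p2 <- rhi_params(sigma_v = 17, sigma_p = 3, sigma_tv = 25, sigma_tt = 8,
                   priors = p1$priors)
  s1 <- sensory_sample(40, -90, 120, 350)
  s2 <- sensory_sample(-90, 40, 350, 120)
  expect_identical(log_likelihood_common(s1, p1), log_likelihood_common(s2, p2))
  expect_identical(log_likelihood_independent(s1, p1),
                   log_likelihood_independent(s2, p2))
  expect_identical(posterior_common_cause(s1, p1),
                   posterior_common_cause(s2, p2))
})

test_that("identical cue parameters factorize the independent marginal", {
  p <- rhi_params(sigma_v = 10, sigma_p = 10,
                  priors = rhi_priors(sigma_x = 300), include_temporal = FALSE)
  s <- sensory_sample(55, 55)
  one <- dnorm(55, 0, sqrt(100 + 300^2))
  expect_equal(likelihood_independent(s, p), one^2, tolerance = 1e-12)
})

test_that("disabling the temporal dimension drops the temporal factor", {
  p_t <- rhi_params(priors = rhi_priors(sigma_x = 400, sigma_t = 400))
  p_s <- rhi_params(priors = p_t$priors, include_temporal = FALSE)
  s <- sensory_sample(10, 60, 100, 180)
  s_sp <- sensory_sample(10, 60)
  ratio <- log_likelihood_common(s, p_t) - log_likelihood_common(s_sp, p_s)
  # the difference is exactly the temporal common-cause factor
  tcase <- sensory_sample(0, 0, 100, 180)
  p_only_t <- rhi_params(sigma_v = 1, sigma_p = 1, priors = p_t$priors)
  p_only_s <- rhi_params(sigma_v = 1, sigma_p = 1, priors = p_t$priors,
                         include_temporal = FALSE)
  expect_equal(ratio,
               log_likelihood_common(tcase, p_only_t) -
                 log_likelihood_common(sensory_sample(0, 0), p_only_s),
               tolerance = 1e-10)
  # and a temporal model refuses a spatial-only sample
  expect_error(log_likelihood_common(s_sp, p_t), class = "rhi_input_error")
})

test_that("posterior respects degenerate priors and zero-discrepancy evidence", {
  s <- sensory_sample(80, 230, 900, 1400)
  p1 <- rhi_params(priors = rhi_priors(p_common = 1))
  p0 <- rhi_params(priors = rhi_priors(p_common = 0))
  expect_identical(posterior_common_cause(s, p1), 1)
  expect_identical(posterior_common_cause(s, p0), 0)
  # congruent cues with wide priors favor the common cause
  pw <- rhi_params(priors = rhi_priors(sigma_x = 5e3, sigma_t = 5e3))
  s0 <- sensory_sample(100, 100, 500, 500)
  expect_gt(posterior_common_cause(s0, pw), 0.5)
  # cross-check against the quadrature oracle
  l1 <- quad_lik_common(s0, pw); l2 <- quad_lik_independent(s0, pw)
  expect_equal(posterior_common_cause(s0, pw),
               0.5 * l1 / (0.5 * l1 + 0.5 * l2), tolerance = 1e-8)
})

test_that("posterior is stable far beyond density underflow", {
  p <- default_params()
  s <- sensory_sample(160, 320, 1000, 50000)  # enormous temporal conflict
  expect_identical(likelihood_common(s, p), 0)  # raw density underflows
  post <- posterior_common_cause(s, p)
  expect_true(is.finite(post))
  expect_gte(post, 0)
  expect_lt(post, 1e-6)
})

test_that("posterior is monotone in cue discrepancies and the prior", {
  p <- rhi_params(priors = rhi_priors(sigma_x = 2000, sigma_t = 2000))
  base <- 40
  dx <- seq(0, 300, by = 25)
  post_x <- posterior_common_cause(
    sensory_sample(base + dx, rep(base, length(dx)),
                   rep(1000, length(dx)), rep(1000, length(dx))), p)
  expect_true(all(diff(post_x) <= 1e-12))
  dt <- seq(0, 900, by = 75)
  post_t <- posterior_common_cause(
    sensory_sample(rep(base, length(dt)), rep(base, length(dt)),
                   1000 + dt, rep(1000, length(dt))), p)
  expect_true(all(diff(post_t) <= 1e-12))
  s <- sensory_sample(100, 250, 1000, 1300)
  post_pc <- vapply(seq(0.05, 0.95, by = 0.1), function(pc)
    posterior_common_cause(s, rhi_params(priors = rhi_priors(
      sigma_x = 2000, sigma_t = 2000, p_common = pc))), numeric(1))
  expect_true(all(diff(post_pc) >= -1e-12))
})

test_that("invalid parameters and inputs are rejected", {
  expect_error(rhi_params(sigma_v = -1), class = "rhi_param_error")
  expect_error(rhi_params(sigma_p = 0), class = "rhi_param_error")
  expect_error(rhi_priors(sigma_x = Inf), class = "rhi_param_error")
  expect_error(rhi_priors(p_common = 1.2), class = "rhi_param_error")
  expect_error(sensory_sample(1, c(1, 2)), class = "rhi_input_error")
  expect_error(sensory_sample(1, 1, tau_v = 5), class = "rhi_input_error")
  expect_error(sensory_sample(NaN, 1), class = "rhi_input_error")
})
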