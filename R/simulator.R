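# Seeded Monte Carlo simulation of the rubber hand illusion: per-trial
# sensory noise, causal inference, and aggregation into illusion
# frequencies; the rubber-hand distance sweep; and the deterministic
# calibration of the latent-prior widths.

# Evaluate expr with R's RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so simulations never perturb user code.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# Documented seed-derivation scheme: stage i of a run seeded with s uses
# child_seed(s, i). Keeps every derived seed a valid 32-bit integer.
child_seed <- function(seed, stage) {
  as.integer((as.double(seed) + 7919 * as.double(stage)) %% 2147483647)
}

#' Specify a stimulation condition
#'
#' The three simulated conditions: `sync` (stroking with congruent timing),
#' `async` (stroking with a visual-tactile lag, by default 750 ms, the
#' midpoint of the 0.5-1 s range typically used), and `no_stroke` (no
#' tactile stimulation, hence a spatial-only inference). The default
#' geometry places the rubber hand 160 mm and the real hand 320 mm from the
#' body midline.
#'
#' @param name `"sync"`, `"async"` or `"no_stroke"`.
#' @param true_x_v Rubber-hand azimuth, mm from midline.
#' @param true_x_p Real-hand azimuth, mm from midline.
#' @param temporal_offset |tau_v - tau_t| lag, ms. Forced to 0 for `sync`;
#'   defaults to 750 for `async` and must then lie in `[500, 1000]` unless
#'   `allow_any_offset = TRUE`. Ignored for `no_stroke`.
#' @param allow_any_offset Permit asynchronous offsets outside the standard
#'   500-1000 ms range.
#' @return An object of class `rhi_condition`.
#' @export
condition_spec <- function(name = c("sync", "async", "no_stroke"),
                           true_x_v = 160, true_x_p = 320,
                           temporal_offset = NULL,
                           allow_any_offset = FALSE) {
  name <- match.arg(name)
  true_x_v <- check_scalar(true_x_v, "true_x_v")
  true_x_p <- check_scalar(true_x_p, "true_x_p")
  offset <- switch(name,
    sync = 0,
    async = if (is.null(temporal_offset)) 750
            else check_scalar(temporal_offset, "temporal_offset"),
    no_stroke = NA_real_)
  if (name == "sync" && !is.null(temporal_offset) && temporal_offset != 0)
    stop_input("sync condition requires temporal_offset = 0")
  if (name == "async" && !allow_any_offset &&
      (offset < 500 || offset > 1000))
    stop_input("async temporal_offset must lie in [500, 1000] ms ",
               "(or set allow_any_offset = TRUE)")
  structure(list(name = name, true_x_v = true_x_v, true_x_p = true_x_p,
                 temporal_offset = offset,
                 include_temporal = name != "no_stroke"),
            class = "rhi_condition")
}

#' Draw noisy sensory samples for a condition
#'
#' Generates the internal signals for `n` trials: position cues are the true
#' hand positions corrupted by the observer's sensory noise, and (for
#' stroking conditions) timing cues are a stroke at `t0` seen immediately
#' and felt after the condition's lag, each corrupted by temporal noise.
#' With a translation-invariant wide temporal prior the value of `t0` is
#' immaterial.
#'
#' @param spec An [condition_spec()] object.
#' @param params An [rhi_params()] object.
#' @param n Number of trials.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @param t0 Stroke time, ms from trial start.
#' @return An [sensory_sample()] of length `n`.
#' @export
sample_sensations <- function(spec, params, n = 1, seed = NULL, t0 = 1000) {
  if (!inherits(spec, "rhi_condition")) stop_input("spec must be an rhi_condition")
  if (!inherits(params, "rhi_params")) stop_param("params must be an rhi_params")
  n <- check_scalar(n, "n")
  if (n < 1 || n != round(n)) stop_input("n must be a positive integer")
  with_seed(seed, {
    chi_v <- stats::rnorm(n, spec$true_x_v, params$sigma_v)
    chi_p <- stats::rnorm(n, spec$true_x_p, params$sigma_p)
    if (spec$include_temporal) {
      tau_v <- stats::rnorm(n, t0, params$sigma_tv)
      tau_t <- stats::rnorm(n, t0 + spec$temporal_offset, params$sigma_tt)
      sensory_sample(chi_v, chi_p, tau_v, tau_t)
    } else {
      sensory_sample(chi_v, chi_p)
    }
  })
}

#' Run a Monte Carlo simulation of one condition
#'
#' For each trial, sensory cues are sampled, the causal inference is
#' evaluated, and the trial is counted as producing the illusion when the
#' posterior probability of a common cause exceeds `illusion_threshold`.
#' Results are bit-reproducible for a fixed seed.
#'
#' @inheritParams sample_sensations
#' @param n_trials Number of Monte Carlo trials (the headline simulations
#'   use 1e5).
#' @param illusion_threshold Posterior cut-off defining an illusion trial.
#' @param seed Integer seed.
#' @return An object of class `rhi_sim`: a list with `p_illusion`,
#'   `mean_p_c1`, mean model-averaged estimates, `n_trials`, `seed`, the
#'   condition and a parameter snapshot.
#' @examples
#' run_condition(condition_spec("sync"), default_params(),
#'               n_trials = 1000, seed = 1)
#' @export
run_condition <- function(spec, params, n_trials = 1e5,
                          illusion_threshold = 0.5, seed = 1, t0 = 1000) {
  n_trials <- check_scalar(n_trials, "n_trials")
  if (n_trials < 1) stop_input("n_trials must be >= 1")
  use_params <- params
  if (!spec$include_temporal) use_params$include_temporal <- FALSE
  smp <- sample_sensations(spec, use_params, n = n_trials, seed = seed, t0 = t0)
  est <- model_averaged_estimates(smp, use_params)
  means <- colMeans(as.data.frame(est))
  structure(list(
    condition = spec,
    n_trials = as.integer(n_trials),
    illusion_threshold = illusion_threshold,
    p_illusion = mean(est$p_c1 > illusion_threshold),
    mean_p_c1 = unname(means[["p_c1"]]),
    mean_estimates = as.list(means[setdiff(names(means), "p_c1")]),
    seed = seed,
    params = use_params
  ), class = "rhi_sim")
}

#' @export
print.rhi_sim <- function(x, ...) {
  cat(sprintf("Condition '%s': %d trials (seed %s)\n", x$condition$name,
              x$n_trials, format(x$seed)))
  cat(sprintf("  p(illusion)  = %.4f  (p_c1 > %g)\n", x$p_illusion,
              x$illusion_threshold))
  cat(sprintf("  mean p(C=1)  = %.4f\n", x$mean_p_c1))
  cat(sprintf("  mean x_hat_p = %.1f mm, mean x_hat_v = %.1f mm\n",
              x$mean_estimates$x_hat_p, x$mean_estimates$x_hat_v))
  invisible(x)
}

#' Sweep the rubber-hand distance
#'
#' Moves the simulated rubber hand away from the real hand over a grid of
#' separations (default 160-360 mm in 20 mm steps, i.e. 16-36 cm in 2 cm
#' steps), holding all other parameters constant, and records the fraction
#' of trials in which a common cause is inferred at each separation. By
#' default the timing input is synchronous. Each grid point runs on a child
#' seed derived from `seed`, so results are reproducible and independent of
#' the grid order.
#'
#' @param params An [rhi_params()] object.
#' @param n_trials Monte Carlo trials per grid point.
#' @param seed Integer seed.
#' @param d_min,d_max,step Separation grid, mm.
#' @param sync Use synchronous timing input (`FALSE` runs spatial-only).
#' @param true_x_p Real-hand azimuth, mm; the rubber hand is placed at
#'   `true_x_p - d`.
#' @param illusion_threshold Posterior cut-off defining an illusion trial.
#' @return An object of class `rhi_sweep`: a list with a data frame `grid`
#'   (`distance_mm`, `p_illusion`), `vanish_distance_mm` (smallest tabulated
#'   separation with `p_illusion < 0.5`) and `vanish_interp_mm` (linear
#'   interpolation of the 0.5 crossing between adjacent grid points).
#' @export
distance_sweep <- function(params, n_trials = 1e4, seed = 1,
                           d_min = 160, d_max = 360, step = 20,
                           sync = TRUE, true_x_p = 320,
                           illusion_threshold = 0.5) {
  if (d_min >= d_max) stop_input("d_min must be smaller than d_max")
  if (step <= 0) stop_input("step must be positive")
  distances <- seq(d_min, d_max, by = step)
  if (length(distances) < 2L) stop_input("separation grid is empty")
  p <- vapply(seq_along(distances), function(i) {
    d <- distances[i]
    spec <- if (sync) condition_spec("sync", true_x_v = true_x_p - d,
                                     true_x_p = true_x_p)
            else condition_spec("no_stroke", true_x_v = true_x_p - d,
                                true_x_p = true_x_p)
    run_condition(spec, params, n_trials = n_trials,
                  illusion_threshold = illusion_threshold,
                  seed = child_seed(seed, i))$p_illusion
  }, numeric(1))
  below <- which(p < 0.5)
  vanish <- if (length(below)) distances[min(below)] else NA_real_
  interp <- NA_real_
  if (length(below) && min(below) > 1L) {
    i <- min(below)
    interp <- distances[i - 1] + (0.5 - p[i - 1]) * step / (p[i] - p[i - 1])
  } else if (length(below) && min(below) == 1L) {
    interp <- distances[1]
  }
  structure(list(grid = data.frame(distance_mm = distances, p_illusion = p),
                 vanish_distance_mm = vanish, vanish_interp_mm = interp,
                 n_trials = as.integer(n_trials), seed = seed, sync = sync,
                 params = params),
            class = "rhi_sweep")
}

#' @export
print.rhi_sweep <- function(x, ...) {
  cat(sprintf("Distance sweep (%d trials/point, seed %s, %s input)\n",
              x$n_trials, format(x$seed),
              if (x$sync) "synchronous" else "spatial-only"))
  print(x$grid, row.names = FALSE)
  cat(sprintf("Illusion vanishes at %s mm (interpolated %.1f mm)\n",
              format(x$vanish_distance_mm), x$vanish_interp_mm))
  invisible(x)
}

#' Calibrate the latent-prior widths
#'
#' The prior widths sigma_x and sigma_t are meant to approximate
#' uninformative priors, but the common-cause posterior depends on them
#' through the Occam factor, so "large" is not a free choice: it fixes the
#' separation at which the illusion vanishes. This routine resolves them by
#' a monotone root search on log sigma_x such that, with noise-free cues
#' (each cue at its true value) and synchronous timing, the common-cause
#' posterior at a hand separation of `target_mm` equals exactly 0.5.
#' `sigma_t` is scaled by the same log-factor relative to the template, so
#' both priors stay equally diffuse. The computation is closed-form and
#' deterministic.
#'
#' @param target_mm Separation (mm) at which the noise-free posterior
#'   should equal 0.5; the default 300 mm is where the simulated illusion
#'   starts to vanish.
#' @param params_template An [rhi_params()] object providing the sensory
#'   SDs, `p_common`, prior means and the template `sigma_x`/`sigma_t`
#'   ratio.
#' @param true_x_p Real-hand azimuth, mm.
#' @param t0 Stroke time, ms.
#' @param bracket Search interval for log(sigma_x).
#' @return A list with `params` (template with calibrated priors),
#'   `sigma_x`, `sigma_t`, `target_mm` and `residual` (the posterior minus
#'   0.5 at the root, ~0).
#' @export
calibrate_prior_width <- function(target_mm = 300,
                                  params_template = rhi_params(),
                                  true_x_p = 320, t0 = 1000,
                                  bracket = log(c(1e2, 1e80))) {
  if (!inherits(params_template, "rhi_params"))
    stop_param("params_template must be an rhi_params")
  target_mm <- check_scalar(target_mm, "target_mm", positive = TRUE)
  tmpl <- params_template
  ratio_t <- tmpl$priors$sigma_t / tmpl$priors$sigma_x

  params_at <- function(log_sx) {
    sx <- exp(log_sx)
    pr <- tmpl$priors
    pr$sigma_x <- sx
    pr$sigma_t <- sx * ratio_t
    tmpl$priors <- pr
    tmpl
  }
  # log posterior-odds of C=1 at the noise-free target configuration
  objective <- function(log_sx) {
    p <- params_at(log_sx)
    s <- sensory_sample(true_x_p - target_mm, true_x_p, t0, t0)
    (log(p$priors$p_common) + log_likelihood_common(s, p)) -
      (log1p(-p$priors$p_common) + log_likelihood_independent(s, p))
  }
  lo <- objective(bracket[1]); hi <- objective(bracket[2])
  if (is.na(lo) || is.na(hi) || sign(lo) == sign(hi)) {
    grid <- seq(bracket[1], bracket[2], length.out = 25)
    diag <- data.frame(log_sigma_x = grid,
                       log_odds = vapply(grid, objective, numeric(1)))
    cond <- errorCondition(
      paste0("no 0.5 crossing for the common-cause posterior inside the ",
             "bracket; see the attached diagnostic curve"),
      class = c("rhi_calibration_error", "error"))
    cond$diagnostic <- diag
    stop(cond)
  }
  root <- stats::uniroot(objective, interval = bracket, tol = 1e-13)$root
  out <- params_at(root)
  s <- sensory_sample(true_x_p - target_mm, true_x_p, t0, t0)
  list(params = out,
       sigma_x = out$priors$sigma_x,
       sigma_t = out$priors$sigma_t,
       target_mm = target_mm,
       residual = posterior_common_cause(s, out) - 0.5)
}
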