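---
title: "A Bayesian causal-inference model of the rubber hand illusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Bayesian causal-inference model of the rubber hand illusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhibayes)
```

## The model

In the rubber hand illusion (RHI) an observer sees a dummy hand near their
occluded real hand; with congruent stimulation many observers come to feel
the dummy hand is their own, and their felt hand position drifts toward it.
`rhibayes` treats the illusion as perceptual causal inference: the brain
receives a visual position cue $\chi_v$ (the rubber hand), a proprioceptive
position cue $\chi_p$ (the real hand), and — when stroking is delivered —
a visual timing cue $\tau_v$ and a tactile timing cue $\tau_t$, and asks
whether one environmental cause ($C = 1$) or two independent causes
($C = 2$) produced them.

Cues are modeled as Gaussian-corrupted readings of latent stimulus
attributes: a position $X$ (mm along the azimuth, zero at the body midline)
and a time $T$ (ms from trial start), with priors
$X \sim \mathcal{N}(\mu_X, \sigma_X)$ and
$T \sim \mathcal{N}(\mu_T, \sigma_T)$. Spatial and temporal signals are
assumed statistically independent, so each causal structure's marginal
likelihood factors into a spatial and a temporal term, each a
one-dimensional Gaussian integral with a closed form. Under a common cause
both position cues share one draw of $X$ and both timing cues one draw of
$T$; under independent causes every cue gets its own latent draw. Bayes'
rule then gives the posterior probability of a common cause from the two
marginals and the prior $p(C=1)$.

Assuming the observer minimizes squared error jointly on the spatial and
temporal estimates, the optimal readout is the posterior mean — *model
averaging*: the final estimate of, say, hand position is the fused
(common-cause) estimate and the segregated (proprioception-only) estimate
mixed by the posterior probabilities of the two structures. The fused
estimate is the precision-weighted mean of $\chi_v$, $\chi_p$ and the prior
mean; segregated estimates combine each cue with the prior alone.
`model_averaged_estimates()` returns the posterior, the averaged estimates,
and all per-structure components, so either the averaged readout or the
components can be inspected (e.g. to display the conditional estimates that
simulation figures typically mark).

All likelihood and posterior arithmetic is done in log space with the
logistic form of the posterior odds. This is not cosmetic: at the standard
geometry the hands are 160 mm apart, about 10.6 proprioceptive standard
deviations, and the raw marginal densities underflow double precision while
the posterior is still perfectly well defined.

## Parameters, units and the prior-width calibration

Canonical internal units are millimetres and milliseconds; configuration
files declare a unit per key and other units (cm, m, s) are converted at
the boundary. The default observer uses:

* $\sigma_p = 15$ mm — proprioceptive spatial noise;
* $\sigma_v = 1$ mm — visual spatial noise (results are robust to this
  value);
* $\sigma_{tv} = \sigma_{tt} = 20$ ms — visual and tactile temporal noise;
* $p(C=1) = 0.5$ — indifferent prior over causal structures;
* $\mu_X = 0$ mm, $\mu_T = 0$ ms — prior means.

The prior widths $\sigma_X$, $\sigma_T$ are conceptually "large numbers
approximating uniform priors", but they cannot be an arbitrary choice: the
marginal likelihood of the independent-causes structure integrates each cue
against the prior, so widening the prior penalizes $C = 2$ through the
Occam factor and pushes the posterior toward a common cause. Concretely, at
cue discrepancy $\Delta$ the spatial posterior odds grow like
$\sigma_X \exp(-\Delta^2 / 2(\sigma_v^2 + \sigma_p^2))$, so the width fixes
the separation at which the illusion vanishes. We also deliberately use a
proper wide Gaussian rather than an improper uniform: in the improper limit
the odds diverge and the posterior is ill-defined.

`calibrate_prior_width()` therefore resolves the widths by a deterministic
root search on $\log \sigma_X$ (with $\sigma_T$ tied by the template's
log-offset, so both priors stay equally diffuse): it finds the width at
which the *noise-free* common-cause posterior with synchronous timing
equals exactly 0.5 at a target hand separation of 300 mm — the separation
where the simulated illusion should start to vanish. The calibrated value,
$\sigma_X \approx 3.6\times10^{44}$ mm, is astronomically large precisely
because a 300 mm separation is ~20 noise SDs; it is recorded with its
provenance in the shipped configuration (`default_config_path()`) and is
what `default_params()` returns. Because the Gaussian prior is effectively
flat across any realistic workspace, its absurd nominal width has no other
observable consequence; it acts only through the Occam factor.

## The Monte Carlo simulator

`run_condition()` simulates the three stimulation conditions. Per trial,
cues are drawn around the true stimulus values with the observer's sensory
noise ($\chi_v$ around the rubber hand at 160 mm, $\chi_p$ around the real
hand at 320 mm; timing cues around a stroke at $t_0 = 1$ s, the tactile cue
lagging by the condition's offset), the inference is evaluated, and a trial
counts as "illusion" when the common-cause posterior exceeds 0.5 — the
model-averaging posterior against an even threshold, matching the
frequency-of-common-cause readout of the simulation literature; the
threshold is configurable. The headline simulations use $10^5$ trials;
tests and the sweep default to $10^4$ with correspondingly widened binomial
tolerances. With the wide translation-invariant temporal prior the value of
$t_0$ is immaterial (asserted by a test).

Design choices worth stating explicitly:

* **Asynchronous offset.** Typical asynchronous stroking lags the felt
  touch by 0.5–1 s; the default is the fixed midpoint, 750 ms, for
  reproducibility. Offsets outside that range require an explicit override.
* **The distance sweep** (`distance_sweep()`) moves the rubber hand from
  160 to 360 mm away from the real hand in 20 mm steps with synchronous
  timing — since all other parameters are held constant at the synchronous
  baseline — and reports both the first tabulated separation at which
  `p_illusion` drops below 0.5 and the linear interpolation between the
  bracketing grid points. Cues are sampled per trial (the readout is a
  frequency over simulation runs, not a noise-free curve).
* **No-stroke condition.** Without stroking there is no temporal signal at
  all, so the inference is purely spatial (`include_temporal = FALSE`).
  This is an explicit modeling choice, not a fallback: a temporal model fed
  a sample without timing cues raises an error rather than silently
  degrading.
* **Seeding.** Every stochastic stage takes one integer seed; multi-stage
  commands (the sweep, the CLI) derive documented per-stage child seeds, so
  results are bit-reproducible and independent of evaluation order, and the
  simulator restores the caller's RNG state.

With the calibrated defaults the simulator reproduces the qualitative
pattern that motivates the model: synchronous stroking yields a
common-cause posterior near 1 at the standard geometry (the illusion),
asynchronous stroking abolishes it, the purely spatial no-stroke model
still yields the illusion at 160 mm, and the sweep's 0.5 crossing lands at
300 mm — close to the ~275 mm spatial limit reported empirically for the
illusion.

## The experiment analysis pipeline

The package also analyses the two kinds of experimental data the model
speaks to, from CSV files whose column layout is configuration (the
deposited files' schema is not fixed by the package).

**Localization / ownership (Experiment 1 design).** Four groups (sync,
async, no-stroke, no-hand), each subject giving 40 pre-test and 40
post-test localization responses and an ownership rating (−3..+3) at each
phase. Subjects whose mean pre-test localization deviates more than 3
sample SDs from the sample mean are excluded, with screening statistics
computed once (no re-screening). Proprioceptive drift is the mean post-test
minus mean pre-test localization; since localization is stored as mm from
the midline and the rubber hand sits midline-ward of the real hand,
inference functions flip the sign (`toward_rubber_sign = -1`) so reported
drifts are positive toward the rubber hand. `drift_inference()` runs
per-group one-sample t-tests (Cohen's d = mean/SD), the omnibus one-way
ANOVA, planned one-tailed pooled-variance t-tests of sync against each
other group (pooled-SD d), and a first-15 vs last-15 post-test stability
check. `ownership_inference()` pools pre-test ratings over the three
rubber-hand groups ("owning" the hand is a rating > 0, the agreement side
of the scale), sign-tests the median against zero (zeros dropped, exact
binomial — the standard definition), and compares post-minus-pre change
scores across groups with Kruskal-Wallis. For the planned pairwise
change-score comparisons the groups are independent, so a paired sign test
is undefined; we use the exact Wilcoxon rank-sum test as the two-sample
analog. Baseline accuracy (`baseline_bias()`) needs the true hand position
and degrades to an explicit "unavailable" result when the data lack it.
Planned comparisons are reported unadjusted, as is conventional for a small
set of a-priori contrasts; a Holm adjustment can be applied downstream from
the returned p-values.

**Skin conductance (Experiment 2 design).** Three groups (plausible-arm,
hanging-arm, no-arm), each subject contributing a 10 Hz conductance trace
with two events: eye opening and threat. The SCR to an event is
$\max - \min$ conductance over the closed window 1–5 s after the event,
transformed as $\log_{10}(\mathrm{SCR}+1)$ (window endpoints and log base
configurable; base 10 follows the electrodermal literature the transform
comes from). The statistic is invariant to additive baseline shifts and to
integer upsampling. `exp2_inference()` runs per-time-point one-way ANOVAs,
planned two-tailed t-tests of plausible-arm against each control, ownership
summaries with exact sign tests for the two rated groups, and Pearson
correlations of ownership with each time-point's transformed SCR.

## The synthetic cohort generators

`generate_exp1()` / `generate_exp2()` produce seeded cohorts with exactly
the structure the analyses assume, so the full pipeline is testable without
any data download. Their defaults are the package's statement of the study
conditions:

* Experiment 1: 21 subjects per group; latent localization mean = true
  position (320 mm) − 31.5 mm midline bias + between-subject noise (SD 20
  mm); 40 draws per phase with 13 mm within-subject noise; injected drifts
  (mm toward the rubber hand) of 10, 5.5, 4.5 and 2.5 for sync, async,
  no-stroke and no-hand, with 9 mm between-subject drift SD — magnitudes
  chosen so the sync standardized effect is near 1 and the controls grade
  down, echoing the behavioral literature. Ownership ratings discretize a
  latent Gaussian (baseline 1.2 for rubber-hand groups, −2.5 for no-hand,
  slope 0.08 per mm of drift, noise SD 2.0) by rounding and clipping to
  −3..3 — the simplest mechanism producing ordinal ratings with a tunable
  drift correlation; the implied large-sample ownership–drift correlation
  is ≈ 0.31.
* Experiment 2: 17 subjects per group; 420 s traces at 10 Hz (tonic level 5
  µS, slow linear drift, 0.01 µS noise); events at 240 s and 300 s;
  event-locked responses with a 0.5 s linear rise and 2 s exponential decay
  — a qualitatively standard SCR morphology, though only the amplitude
  matters to the max−min statistic — with mean eye-opening amplitudes 0.8
  µS (plausible-arm) vs 0.25 µS (both controls) and threat amplitudes
  scaled by 0.8; ownership latents coupled to amplitude for the two rated
  groups.

What the generators emulate is the *statistical* structure: Gaussian
localization noise, additive group effects, latent-variable ordinal
ratings, event-locked conductance changes. They do not emulate serial
dependence in localization responses, non-Gaussian proprioceptive error,
habituating or overlapping SCRs, tonic-phasic decomposition, or item-level
questionnaire structure. Tests passing on synthetic cohorts therefore
validate the pipeline's arithmetic and calibration, not the empirical
claims themselves, which require the deposited datasets.

## Numerical and testing choices

* Closed-form marginals are validated against nested adaptive quadrature of
  the generative integrals to 1e-8 relative tolerance over randomized
  parameter draws (in regimes where quadrature itself is reliable;
  log-space evaluation is exact far beyond that).
* The calibration root search brackets $\log \sigma_X$ in
  $[\log 10^2, \log 10^{80}]$ and reports a diagnostic curve if no crossing
  exists in the bracket.
* Statistical calibration of the pipeline is tested at the study's own
  scale: across 1000 synthetic null cohorts (no drift, no coupling,
  centered ratings) every reported test — one-sample t, ANOVA, planned
  one-tailed t, Kruskal-Wallis, Pearson correlation, exact sign test,
  post-test stability t — rejects at a rate within [0.03, 0.07] at
  α = 0.05. Note the exact sign test is discrete and conservative by
  construction; at these sample sizes its size stays within the band.
* Parameter recovery is tested as *coverage*: across 100 seeded cohorts,
  95% confidence intervals for the injected sync drift, midline bias,
  within-subject SD (against its small-sample expectation $c_4\sigma$) and
  ownership–drift correlation (against the generator's large-sample value)
  cover the truth at ≥ 88% — the statistically correct reading of
  "recovered within the CI", robust to any single seed's luck.
* Monte Carlo ordering claims (sync > async; monotone distance sweep;
  halving $\sigma_p$ never strengthening the illusion) are asserted against
  99% binomial bands at the simulated trial counts.
* Test problem sizes — $10^4$-trial conditions, $2\times10^3$-trial sweep
  points, 1000 null replicates, 100 recovery replicates — are the package's
  chosen balance of statistical resolution against a test suite that runs
  in a couple of minutes on one core.

## Known limitations

The model is a trial-less, static account: it does not capture the 5–10 s
onset dynamics of the illusion, stroking kinematics, or temporal
correlation structure between the visual and tactile streams (which can
sustain an illusion even under a constant lag). Hand posture and appearance
congruence are outside the model's variables. The analysis pipeline
implements one documented convention where the field has several (sign-test
zeros, Cohen's d flavors, log base for the SCR transform); alternatives are
exposed as arguments rather than guessed silently. The deposited
experimental datasets are not redistributable with the package, so the
reproduction of the published statistics runs only when the user supplies
those files; everything else is validated on synthetic cohorts.
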