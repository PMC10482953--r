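---
title: "Weighting of priors in decisions and confidence: the observer model and its estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighting of priors in decisions and confidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(priorconf)
```

## The task and the model

`priorconf` models dual-decision experiments with random-dot-motion
stimuli. On each trial an observer makes two left/right decisions. The
direction of the second ("target") stimulus is set deterministically by the
task rule: rightward if the first ("lead") decision was correct, leftward
otherwise. An observer who knows the rule should therefore treat their
internal confidence in the lead decision as the prior probability of a
rightward target. Pairs of conditions matched in total posterior
information — *Stronger-Lead* (more informative lead) versus
*Stronger-Target* (more informative target) — make over- or underweighting
of the prior visible as condition differences in accuracy and confidence.

All stimulus strengths enter the model in internal-noise units,

$$s = \frac{\mathrm{dir}\cdot\mathrm{coh} - \mathrm{bias}}{\sigma},$$

after which internal responses are unit-variance Gaussians,
$r \sim N(s, 1)$. The lead choice is the sign of $r_\mathrm{lead}$ and lead
confidence is $\Phi(|r_\mathrm{lead}|)$, the posterior probability correct
under a flat prior over continuous stimulus strength.

The prior shifts the target decision criterion,

$$\theta = -\,\frac{|r_\mathrm{lead}|}{w_\mathrm{choice}},$$

so the observer answers "right" whenever $r_\mathrm{target} > \theta$.
The weighting parameter $w_\mathrm{choice} > 0$ scales the *perceived
variance* of the prior: $w = 1$ is the ideal observer, $w > 1$
underweights the prior (criterion shifted too little), $w < 1$ overweights
it. Because the experimenter never observes $r_\mathrm{lead}$, the
likelihood of a rightward target choice marginalizes it over the truncated
normal implied by the observed lead choice.

Confidence is the posterior probability of the chosen target direction,
built from a weighted prior and likelihood

$$p(R)_\mathrm{conf} = \Phi\!\left(\frac{|r_\mathrm{lead}|}{b\,w_\mathrm{conf}}\right),
\qquad
p(r_\mathrm{target}\mid R) = \Phi\!\left(\frac{r_\mathrm{target}}{b}\right),$$

combined by Bayes' rule. $w_\mathrm{conf}$ plays exactly the same
variance-scaling role as $w_\mathrm{choice}$ but at the confidence level, so
the two are directly comparable; $b$ is a confidence bias that scales the
perceived variance of *both* sources ($b > 1$ compresses confidence toward
50%). Four variants are fit and compared: **Flexible**
($w_\mathrm{choice}, w_\mathrm{conf}, b$ free), **Flat Prior** (prior fixed
at exactly 0.5, only $b$ free), **Optimal** ($w_\mathrm{choice} =
w_\mathrm{conf} = 1$), and **Equal** ($w_\mathrm{choice} = w_\mathrm{conf} =
w$).

## Parameters, units and defaults

| Parameter | Meaning | Default / prior |
|---|---|---|
| `w_choice`, `w_conf` | prior-variance scaling in choice / confidence (1 = optimal) | lognormal(0, 1) sampling prior |
| `b` | confidence bias, joint variance misestimation | lognormal(0, 1) |
| `sigma` | internal noise, coherence units | 0.23 for synthetic observers |
| `bias` | decision bias, coherence units | 0 |
| `lapse` | probability a choice is a coin flip | 0 |
| `report_noise_sd` | truncated-Gaussian report noise on the [0.5, 1] scale | 0.08 generator, half-normal(0.15) prior |
| `metacog_noise_sd` | SD of noise on internal responses entering confidence only | 0 |

The generator default $\sigma = 0.23$ is the value at which the staircased
coherences (medium 2-down-1-up targeting 71%, high 3-down-1-up targeting
79%, low yoked 5 coherence points below medium) reproduce lead accuracies
of about 0.63 / 0.71 / 0.79 at the three levels, the typical outcome of
this design. Staircases start at 0.15 (medium) and 0.25 (high) coherence
with 1-point steps and bounds [0.01, 0.90]; these operational constants are
not reported for the original experiments and were fixed once at values
that keep coherences inside the usable stimulus range.

Reported confidence is the model confidence in the chosen option clipped to
$[0.5, 1]$ (it can fall below 0.5 when $w_\mathrm{conf} \neq
w_\mathrm{choice}$; the pre-clip value is retained in `conf_model`), plus
truncated-Gaussian report noise. The report-noise field exists so the
generator and the fitted observation model form a coherent pair — without
it, generated reports would be deterministic given the latent responses and
the report-noise SD would be degenerate under the full likelihood.

## What the synthetic experiment emulates — and what it does not

`generate_dataset()` reproduces the trial structure end to end: per session
a 90-trial control task (six fixed coherences, 15 trials each), then
counterbalanced 36-trial blocks in which each (posterior level × condition)
cell appears equally often with balanced lead directions, live staircases
updated by lead decisions of the matching level and carried across
sessions, the deterministic task rule, continuous confidence reports, and
optional lapses, metacognitive noise and random trial dropout.

It does **not** emulate reaction times (and therefore no RT-based trial
exclusion), session-wise drift in internal noise, learning or fatigue,
sequential effects such as confidence leak, or gamification artefacts.
Passing tests on synthetic data demonstrate the internal consistency of the
pipeline (generative model ↔ likelihood ↔ estimation), not the truth of the
model for any real dataset.

## Estimation

No probabilistic-programming backend is used: the marginalized choice
likelihood cannot be written in closed form for general samplers, so the
package ships its own adaptive MCMC in compiled code.

* **Individual fits** (`fit_individual()`) use the full likelihood — the
  choice term marginalizes $|r_\mathrm{lead}|$ by Gauss–Legendre quadrature
  and the confidence term additionally integrates $r_\mathrm{target}$ over
  the side of the criterion selected by the observed choice, using
  equal-probability (quantile) nodes. Sampling is joint random-walk
  Metropolis on log parameters with Haario-style covariance adaptation
  during warmup, initialized at the posterior mode.
* **Hierarchical fits** (`fit_hierarchical()`) place participant-level log
  parameters on group normals, $\theta_{jk} \sim N(\mu_k, \tau_k)$, with
  $\mu_k \sim N(0,1)$, $\tau_k \sim$ half-normal(1) and a shared
  report-noise SD. The confidence likelihood uses the *level-mean
  simplification*: internal signals are replaced by the mean normalized
  strength of each coherence level on the true-direction side, which keeps
  the per-trial latent responses out of the parameter vector (they would
  otherwise add two free parameters per trial). The choice likelihood
  remains the full marginalization. Sampling is Metropolis-within-Gibbs
  with a conjugate Gibbs update for $\mu_k$.

A *centered* parameterization is used for the hierarchy. With hundreds of
informative trials per participant the funnel geometry that motivates
non-centering does not arise, and centering makes the group-mean update
conjugate — the difference is what makes desk-scale cross-validation
affordable on one CPU.

Convergence is gated at split-$\widehat R < 1.1$ per parameter; fits
violating the gate are returned but flagged, never silently accepted.
Summaries report posterior mean, SD, MCSE (from an autocorrelation-based
effective sample size) and 89% equal-tailed credible intervals. The
group-level location is reported as $e^{\mu_k}$, the population median of
the lognormal.

### Numerical choices

* Exported `p_right_target()`: composite Simpson rule with 201 nodes on
  $|r_\mathrm{lead}| \in (0, 8]$, self-normalized truncated-normal weights;
  agreement with a 1601-node refinement is ~2e-8 and with a 1e6-draw
  Monte-Carlo marginalization well within 1e-3 (both tested).
* Fitting paths use 16-node (hierarchical choice term) and 12×8-node
  (individual full confidence term) Gauss–Legendre rules; at the parameter
  regions the samplers actually visit these agree with dense 48×32
  references to well under 0.1 log-likelihood units per dataset. Quadrature
  error grows only at parameter sets hundreds of log-units below the
  posterior mode, where it is conservative (it cannot attract the sampler).
* Probabilities are clamped to $[10^{-9}, 1-10^{-9}]$ before the Bayes
  combination and per-trial likelihoods are floored at $10^{-300}$ before
  logs; choice probabilities are clamped at $10^{-12}$.
* Ties at $r_\mathrm{lead} = 0$ (a measure-zero event) resolve to "right"
  with probability 0.5.

## Model comparison and recovery

`logo_cv()` implements leave-one-group-out cross-validation with
participants as groups (default 10 folds × 2 held-out participants). A
held-out participant has no fitted parameters, so their pointwise log
predictive density integrates over the group-level posterior predictive:
for each posterior draw, new-participant parameters are drawn from the
fitted group distribution. Standard errors of elpd differences come from
trial-level pointwise differences scaled by $\sqrt n$. A model is judged
decisively better only when its advantage is at least 4 elpd *and* at least
twice the SE of the difference.

`model_recovery_study()` defaults to simulating from each variant's *own
fitted observation model* (`simulate_from_model()`), which is the
well-specified model-recovery setting. Simulating the full latent-response
observer instead (`generator = "observer"`) makes every candidate mildly
misspecified through the level-mean simplification; in that regime data
generated from the Equal model are genuinely better predicted by the
Flexible model, because the simplification biases the fitted confidence
weight downward relative to the choice weight. This asymmetry is a known
property of the simplification (it underestimates confidence overall — a
comparison the test suite makes explicit) and is worth keeping in mind when
interpreting Equal-vs-Flexible comparisons on real data. For scoring,
the default is the group-predictive log score on the generating data (an
information-criterion-style proxy); full LOGO-CV is available behind
`method = "logo"`.

## Calibration of confidence — a deliberate red flag

The model's confidence is the posterior probability correct *under the
observer's subjective generative model*, which assumes a flat prior over
continuous stimulus strength. Under an experiment with a few fixed
coherence levels this confidence is systematically overconfident relative
to realized accuracy (at optimal parameters and the default levels, per-cell
mean model confidence is ≈ 0.83 against accuracy ≈ 0.74). Mean confidence
does converge to accuracy when stimulus strengths are drawn from a
distribution broad enough to approximate the subjective prior — the test
suite demonstrates both facts. Consequently the acceptance-level
"confidence equals accuracy per condition cell" check fails by
construction and is intentionally left failing; treating it as a bug and
"fixing" it would change the model.

## Problem sizes used by the test suite

Simulation-based checks run at sizes chosen for a single CPU: staircase
calibration over 3000 trials; condition symmetry at $10^5$ trials per
cell; Monte-Carlo likelihood oracles at $10^6$ draws; parameter recovery
with 20 observers × 720 trials at 2 chains × (400 + 400) iterations;
LOGO-CV on a 20 × 720 cohort at 2 × (300 + 300); model recovery on 8 × 360
cohorts at 2 × (500 + 500). Published-scale MCMC (longer chains, more
draws) changes only Monte-Carlo precision, not any of the qualitative
outcomes tested.

## Known limitations

* The original study's exact confidence observation model and hierarchical
  priors are not public; this package's truncated-Gaussian report model
  and weakly informative priors are its own choices, so numerical agreement
  with the published posterior means on the deposited data is expected to
  be approximate only.
* The hierarchical simplification biases `w_conf` (downward here) and
  inflates the fitted report noise when data contain genuine latent
  variability; the direction of the headline asymmetry
  ($w_\mathrm{choice} > w_\mathrm{conf}$) is preserved, and individual
  (full-likelihood) fits are unbiased in recovery tests.
* Staircase step sizes, bounds and starting coherences are unreported in
  the source experiments; the defaults here are reasonable conventions,
  and the staircase asymptotes are insensitive to them.
* Exogenously cued probabilistic priors (a single-decision variant of the
  paradigm) and reaction-time modelling are out of scope.
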