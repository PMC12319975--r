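---
title: "Models and methods behind confdcm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind confdcm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`confdcm` implements an effective-connectivity analysis of perceptual
decision confidence and speed: a canonical-microcircuit (CMC) neural mass
forward model for event-related potentials (ERPs), variational-Laplace model
inversion with a free-energy model evidence, group-level Bayesian model
comparison and hierarchical (parametric empirical Bayes, PEB) inference,
behavioral stratification of reaction times (RTs) and confidence ratings,
and a trial-by-trial nonlinear encoding analysis of the fitted latent
population activity. A synthetic cohort generator stands in for the
experimental data, so every stage has a recovery-based test surface.

This vignette records the models, the defaults and their units, the
numerical choices, and the places where the design was genuinely open.

## The forward model

Each cortical region is a canonical microcircuit of four neural
populations: spiny stellate cells (SS), superficial pyramidal cells (SP),
inhibitory interneurons (II), and deep pyramidal cells (DP). Every
population has two states, a voltage $v$ (mV) and a current $i$ (mV/s),
obeying the damped second-order dynamics

$$\dot v = i, \qquad
  \dot i = \kappa\,u \;-\; 2\kappa\,i \;-\; \kappa^2 v,$$

where $\kappa$ is the population's rate constant (1/s) and $u$ the
presynaptic drive: a signed, gain-weighted sum of the firing of afferent
populations, $S(v) = 1/(1+e^{-r v}) - 1/2$, with slope $r$ (1/mV). The
centred sigmoid makes the zero state an exact fixed point, so a zero-input
simulation stays identically zero.

The intrinsic wiring is the conventional CMC connection set: ten
connections whose signs are fixed by the circuit (the gains $g \ge 0$ carry
only magnitudes):

SS→SS(−), SP→SS(−), II→SS(−), II→II(−), SS→II(+),
DP→II(+), SP→SP(−), SS→SP(+), II→DP(−), DP→DP(−).

Between regions, *forward* connections project from SP of the source onto
SS and DP of the target; *backward* connections from DP of the source onto
SP and II of the target. The exogenous input drives SS of designated input
regions. All extrinsic and input gains are parameterized as log-scalings of
canonical base values, so a parameter value of 0 means "canonical
strength" and gains are positive by construction — the usual convention for
connectivity parameters in this model family.

Defaults: $\kappa = (256, 128, 16, 32)$ 1/s for (SS, SP, II, DP);
$r = 2/3$ per mV; intrinsic gain magnitudes of order 1–8 scaled by a common
factor of 200; forward/backward/input base gains 800/200/256. These were
chosen once so that a unit-amplitude input produces damped, bounded,
millivolt-scale responses; they are conventions of this model class, not
values recovered from data, and every one is overridable through
`cmc_region_params()` and `network_spec()`.

The stimulus is a cumulative-Gaussian ramp
$A\,\Phi((t-\mu)/\sigma)$ with $\mu = \text{onset} + 2.326\,\sigma$, so the
input carries about 1% of its final amplitude at the nominal onset: "onset
at 200 ms" is read as the time the input *begins*, not half-peaks.

Integration is fixed-step classical Runge–Kutta (RK4) from the zero state,
default step 1 ms (matching a 1000 Hz recording grid). The integrator is
compiled; fits typically run on a 4 ms grid (`fit_step = 0.004`), which is well
inside the stability region of the default parameters. Trajectories that
leave the finite range abort with the first offending time.

## Observation model

The scalp signal is linear in the latent voltages:
$y_{c}(t) = \sum_r L_{cr} \sum_p J_p\, v_{rp}(t)$, with a channels × regions
lead field $L$ and population contribution weights
$J = (0.2, 0.8, 0, 0.2)$ for (SS, SP, II, DP). SP dominates because
superficial pyramidal apical dendrites generate most of the scalp EEG; II
contributes nothing and the deep populations contribute weakly — which is
precisely why deep-layer findings of the trial-wise analysis are invisible
to scalp-level analysis. Synthetic lead fields are unit-norm random
columns; no head modelling is implied or attempted.

Epochs run from −50 ms to 1.2 s around stimulus onset; baseline correction
subtracts the per-trial, per-channel mean over the 100 ms pre-stimulus
interval and is idempotent. Condition ERPs are plain arithmetic means of
baseline-corrected epochs. Model–data agreement is summarized by the mean
squared error over channel–time samples, computed on amplitude-normalized
data (below).

## Inversion

A network is fitted to an observed ERP by maximizing a variational
free-energy bound with a Gaussian (Laplace) posterior. The generative model
is $y = G(\theta) + \varepsilon$ with iid Gaussian noise at precision
$e^{\lambda}$, shrinkage priors $\theta \sim N(0, 1/16)$ on every
log-scaling parameter, and $\lambda \sim N(4, 1)$. A prior variance of 0
fixes a parameter.

The scheme is Gauss–Newton with Levenberg–Marquardt damping (×8 on
rejection, ÷2 on acceptance, initial 1) on $\theta$, interleaved with
noise-precision updates: the stationarity condition for $\lambda$ is
monotone, so it is solved by a bracketed root search — plain Newton
overflows when residuals become very small. Jacobians are forward finite
differences with step $10^{-3}$ on the log scale. A step is accepted only
if it increases $F$, so the accepted-step trace is nondecreasing by
construction; convergence is declared after three consecutive proposals
changing $F$ by less than 0.01 nats, or at 64 iterations.

The reported free energy is
$F = \text{accuracy} - \text{complexity}$, where accuracy is the
*expected* log likelihood under the posterior in its Gauss–Newton
approximation (it includes the $-\tfrac12 e^{\lambda}\,
\mathrm{tr}(J^\top J \Sigma)$ term) and complexity is the KL divergence of
the posterior from the prior (parameters and noise log-precision). With
that convention $F$ reproduces the analytic log evidence of linear-Gaussian
models to well under 0.1 nats, and complexity is exactly zero when the
posterior equals the prior. Averaged-ERP fits use the −50…800 ms window;
single-trial fits use −50…1200 ms. Before fitting, the data are rescaled
to unit median absolute amplitude; the scale is stored, and the predicted
response is returned on the original scale.

There is no internal randomness anywhere in the inversion: identical
inputs give bit-identical results.

## Group-level inference

*Fixed effects* model comparison sums free energies over subjects and
applies a stable softmax. *Random effects* comparison uses the variational
Dirichlet scheme over per-subject model frequencies (concentration prior
$\alpha_0 = 1$, convergence at $\max|\Delta\alpha| < 10^{-4}$); exceedance
probabilities use the exact Beta marginal for two models and seeded
Dirichlet Monte Carlo (default $10^5$ draws) otherwise.

Bayesian model averaging moment-matches the mixture of model-specific
Gaussian posteriors. Bayesian model reduction evaluates, in closed form,
the evidence change and posterior under a more constrained prior; removing
a parameter means sending its reduced prior variance to zero (implemented
with a large finite precision, which cancels in the evidence ratio), and
reductions compose additively.

PEB is a two-level Gaussian model: subject parameters are design-matrix
combinations of group effects plus an iid random effect. The random-effect
precision is a single scalar chosen by maximizing the exact two-level
marginal likelihood on a 16-point log grid spanning $10^{-2}$–$10^{2}$
times the mean subject precision — a deliberate simplification that avoids
a second variational scheme. The "probability of occurrence" of a
connection is the BMR-based posterior probability that its group effect is
nonzero; the reporting filter retains parameters strictly above 0.75, a
literal reading of "more than 75%".

## Behavioral stratification

Confidence ratings band into high (≥ 7), medium (5–6), and low (≤ 4). RTs
cluster per participant by 1-D k-means with $k = 4$: one deterministic
start at the 12.5/37.5/62.5/87.5 percentiles plus nine seeded random
restarts, best within-cluster sum of squares wins. Trials below the second
sorted centre are fast, above the third slow, and *between the centres —
inclusive at both boundaries —* medium. Participants enter the analysis
only if their trial-level Spearman correlation between confidence and RT is
significant (two-sided, $p < 0.05$); constant columns exclude a participant
as degenerate. The fast-versus-slow accuracy contrast is a paired Wilcoxon
signed-rank test across participants, reported one-sided (fast > slow) and
two-sided.

## Trial-by-trial encoding

Single trials are inverted with priors centred on the winning averaged
model's posterior means and variances tightened to a quarter of the
averaged-fit prior variances (the initialization is informed); failed
trials are flagged and excluded. Latents are integrated at each trial's
posterior mean. The analysis consumes the *reported* population signal:
voltage for SS, SP and DP, but current for II — the CMC convention for
inhibitory interneurons.

Feature matrices sample a region/population signal on a 0–800 ms, 4 ms
grid by default and z-score each column across trials. Support vector
regression (libsvm via `e1071`; $C = 1$, $\epsilon = 0.1$, Gaussian
bandwidth $1/(p \cdot \overline{\mathrm{var}})$, 5-fold cross-validation)
predicts RT or confidence. Per timepoint the analysis reports:

* **importance** — the mean drop in held-out $R^2$ over $R$ permutations of
  that column (default $R = 50$);
* **sensitivity sign** — the sign of the mean prediction change under a
  +0.1 SD perturbation of that column;
* **bootstrap pass fraction** — over $B$ resamples of trials (default
  $B = 500$), the fraction in which the out-of-bag mean drop exceeds the
  95th-percentile bound of its own permutation null *and* the resample's
  sensitivity sign matches the full-data sign. Two aspects of this
  composition deserve note. First, the null for the mean drop is its
  standard error across the $R$ single-permutation drops (they are centred
  under irrelevance), recentred by the resample's median drop across
  timepoints — an overfit model loses held-out accuracy when *any* used
  column is permuted, and the median absorbs that shared bias. Second, a
  resample only counts if its out-of-bag $R^2$ is positive: performance
  drops of a model with no held-out skill do not measure encoding.

Group inference gates each participant's timepoints at pass fraction
> 0.7, then tests the gated signed importances against zero across
participants with a Wilcoxon signed-rank test at $p < 0.05$; the exact
two-sided test needs at least six agreeing participants to reach that
level, which sets the minimum useful cohort size. Significant timepoints
are reported only as *sustained windows*: maximal runs whose duration
$(\text{run length} - 1)\cdot dt$ strictly exceeds 25 ms. A linear-kernel
screen across conditions decides whether Gaussian-kernel findings are
reported as nonlinear.

Two structural caveats. First, the pipeline *decodes*: it predicts
behavior from latent activity. If the generative coupling runs the other
way as a non-monotone function (latent $= g(\text{behavior})$ with $g$
two-to-one), the decoding problem is ill-posed and no kernel can solve it;
non-monotone couplings are only detectable when the latent cause itself
drives the target. Second, by Stein's identity a coupling with exactly
zero linear component also has zero mean derivative, so its sensitivity
sign is undefined in expectation and the sign-consistency group test
cannot flag a perfectly symmetric U-shaped relation; asymmetric
non-monotone couplings are detectable.

## The synthetic cohort generator

The generator emulates the *statistics* of a two-alternative motion
discrimination protocol with confidence ratings — 24 participants, 2 blocks
of 160 trials, responses capped at 1.2 s, delay uniform on 1.5–4 s and
independent of confidence, ratings 1–9 — not any particular participant's
mechanism. Choices and RTs come from a symmetric two-boundary diffusion
(Euler–Maruyama, 1 ms steps) whose drift magnitude is a two-level
lognormal mixture (85% hard trials; easy trials 20× stronger, within-level
spread 0.15 log units), with a bound that collapses linearly from 1.1 to
55% of its initial value over 1 s of decision time. The mixture emulates
the hard/easy trial mix of a coherence-titrated task; the collapsing bound
makes late decisions less reliable. Both are needed: with a fixed bound and
unimodal drift, the mean accuracies of k-means fast and slow bands cannot
be separated far enough at an overall accuracy of 75% — the configuration
reaches fast ≈ 0.84 and slow ≈ 0.66 around the targets of 0.87 and 0.69.
The hard-level median drift is calibrated to the protocol's overall
accuracy target by root-solving on a fixed-internal-seed pilot cohort
(common random numbers make the pilot accuracy monotone in the drift
scale); the result is cached. Confidence is
$\text{round}(9.5 - 7\,\text{RT} + \varepsilon)$ clipped to 1–9, with
participant-level intercept jitter — a negative, per-participant
significant Spearman relation without asserting any particular functional
form.

Scalp cohorts are produced by integrating a ground-truth network per
trial, optionally modulating named parameters through bounded link
functions of the trial's (z-scored) behavioral variables, optionally adding
time-localized raised-cosine bumps to a population's reported signal
(the mechanism for planting encoding windows), projecting through a lead
field, and adding iid Gaussian noise at a stated signal-to-noise power
ratio.

What the generator does *not* emulate: real electrode topographies, trial
history and learning effects, non-stationary noise, artifacts, or the
empirical coupling between connectivity and behavior. Passing recovery
tests on this cohort therefore demonstrates the correctness and calibration
of the machinery, not the reproducibility of the original study's fitted
connectivity values.

The two condition model spaces ship as structural fixtures: a
seven-region confidence space (lPreCUN, lIPL, lSPL, l/rMFG, l/rSFG) and a
five-region RT space (rSPL, lPreCUN, rSMG, lPreCG, lMeFG), sharing only
the left precuneus; in both, model 2 extends model 1 with direct
parietal-to-frontal forward edges (lIPL/lSPL→lSFG, and rSPL→lPreCG/lMeFG).

## Problem sizes in the test suite

The suite exercises every stage at desk scale: two-region networks with
6–8 channels for inversion and model-comparison properties (20 noisy
repeats for the Occam ordering; 10 cohorts of 6 subjects for the PEB
occurrence filter), 24-participant cohorts for the behavioral calibration,
and encoding runs of 50–200 trials × 20–80 timepoints with 10–20
permutations and 30–100 bootstrap resamples (the analysis defaults,
$R = 50$ and $B = 500$, remain the reporting configuration). The planted
40 ms encoding window is localized from generator ground-truth latents
through the full encode→group→window path in cohorts of 7 participants;
the single-trial DCM stage is validated separately by a 20-trial
gain-recovery simulation at SNR 10.

## Known limitations

* The inversion uses a single noise-precision component and no temporal
  confound modelling; heavily colored noise will bias $\lambda$.
* PEB's scalar random-effect precision cannot express parameter-specific
  between-subject variability.
* Permutation importance is diluted by strongly redundant (near-collinear)
  timepoints; sustained windows mitigate but do not remove this.
* The generator's censoring of non-responses slightly couples miss rate to
  difficulty; responded-trial accuracy is calibrated, miss rate (~10%) is
  an emergent property.
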