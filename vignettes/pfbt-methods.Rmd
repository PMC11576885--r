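---
title: "Modelling self–other belief updating on the probabilistic false-belief task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling self–other belief updating on the probabilistic false-belief task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The task

The probabilistic false-belief task (p-FBT) asks a participant to track a
gradually drifting Bernoulli outcome probability (will the next customer buy a
pink umbrella or a yellow sunshade?) while simultaneously predicting what a
second agent — who receives partial or misleading information — believes about
that probability. Two latent probabilities evolve as independent bounded
random walks: \(P^{Self}\), governing what the participant observes, and
\(P^{Other}\), governing what the other agent observes. Each of the 360
sampling trials is one of three types:

* **shared** — both agents see the same sample, drawn from either walk with
  equal probability (the walk used is recorded);
* **privileged** — only the participant sees the sample, drawn from
  \(P^{Self}\);
* **decoy** — the other agent sees a sample drawn from \(P^{Other}\); the
  participant knows it is uninformative about the real outcome stream.

Every 4–9 sampling trials a probe asks the participant to report, on a
continuous \([0,1]\) scale, either their own predicted probability (Self
probe) or the probability they believe the other agent would report (Other
probe).

### Generator defaults

`task_config()` fixes the walk step at 0.025 with reflecting bounds at 0 and
1, equal-probability up/down steps (a Gaussian-step variant is available),
both walks starting at 0.5, probe gaps uniform on \(\{4,\dots,9\}\), and
probes assigned to Self or Other with equal probability (strict alternation
available).

Trial-type proportions default to 5% shared and 47.5% each privileged and
decoy. The proportion matters: shared samples are the only input common to
the two belief streams, and because they are drawn from either walk, each
agent's belief then partially tracks the *other* agent's walk. With, say,
equal thirds of each type, this mechanically correlates the two belief
trajectories at about \(r \approx 0.5\) even under fully agent-specific
updating — which would destroy the task's defining property that leakage, and
only leakage, induces belief correlation. Keeping shared trials rare
preserves that property (mean \(|r| < 0.1\) at \(\lambda = 0\) across
sequences) while retaining all three trial types. The proportions are
configurable for users who want to study this trade-off.

## The learning model

The participant maintains two beliefs, \(B^{Self}\) (their own) and
\(B^{Other}\) (the belief they attribute to the other agent), both starting
at chance (0.5). On each sampling trial with binary outcome \(o_t\):

\[
\begin{aligned}
PE^{Self}_t &= o_t - B^{Self}_{t-1}, \quad &&\text{but } 0 \text{ on decoy trials},\\
PE^{Other}_t &= o_t - B^{Other}_{t-1}, \quad &&\text{but } 0 \text{ on privileged trials},
\end{aligned}
\]

\[
\begin{aligned}
B^{Self}_t &= B^{Self}_{t-1} + \alpha\,(PE^{Self}_t + \lambda^{Other} PE^{Other}_t) + \delta\,(0.5 - B^{Self}_{t-1}),\\
B^{Other}_t &= B^{Other}_{t-1} + \alpha\,(PE^{Other}_t + \lambda^{Self} PE^{Self}_t) + \delta\,(0.5 - B^{Other}_{t-1}).
\end{aligned}
\]

* \(\alpha \in (0,1)\): learning rate (sensitivity to new information).
* \(\delta \in [0,1)\): memory decay — beliefs drift towards chance.
* \(\lambda^{Self} \in (-1,1)\): *idiocentric* leakage — the participant's own
  prediction errors update the belief attributed to the Other.
* \(\lambda^{Other} \in (-1,1)\): *allocentric* leakage — the Other's
  prediction errors update the participant's own belief.
* \(\tau \in [0.001, 0.08]\): response variance (below).

\(\lambda = 0\) is fully agent-specific updating; \(\lambda \to 1\) collapses
the two representations (self–other mergence); negative \(\lambda\)
anti-correlates them. Six variants cross three leakage patterns
(unrestricted, symmetric, zero) with shared or per-agent learning rates
(`model_set()`); in the per-agent variant \(\alpha^{Self}\) scales the Self
update and \(\alpha^{Other}\) the Other update.

Three readings of the update equations were genuinely open and are resolved
as follows. The decay term pulls each agent's belief towards 0.5 using that
agent's own previous belief — the only reading that keeps the two equations
symmetric. Decay applies on every sampling trial, including trials on which
an agent's prediction error is zeroed, because drift towards chance describes
passive forgetting, not outcome processing. Beliefs are clipped into
\([0,1]\) after each update (an alternative would be a squashing transform;
clipping keeps the update linear in its interior, where the model virtually
always operates).

## The response model

Probe responses are modelled with a Beta likelihood whose **mode** is the
probed agent's current model belief and whose **variance** is \(\tau\).
Solving for shapes with a given mode \(m\) and variance \(v\) uses the
parametrisation \(a = 1 + mk\), \(b = 1 + (1-m)k\), \(k \ge 0\), which pins
the mode at \(m\) for every \(k\) while the variance falls monotonically from
\(1/12\) (the uniform, \(k = 0\)) towards 0 — so any \(v < 1/12\) has a
unique solution, found by bisection to machine precision, with shapes
\(\ge 1\) guaranteeing an interior mode. Variances at or above \(1/12\)
cannot be achieved by any unimodal Beta with interior mode; they are shrunk
to the feasible maximum and flagged. The admissible \(\tau\) range
\([0.001, 0.08]\) never triggers this: \(\tau = 0.08\) gives the
near-uniform Beta(1.0625, 1.0625) — effectively random responding — and
\(\tau = 0.001\) concentrates responses tightly (SD \(\approx 0.032\)) around
the belief. Modes and responses are clamped into
\([\varepsilon, 1-\varepsilon]\), \(\varepsilon = 10^{-4}\), so reports of
exactly 0 or 1 keep finite density.

## Fitting, evidence, model comparison

Fitting is maximum a posteriori on an unconstrained scale: \(\alpha\),
\(\delta\) map through the logistic, \(\tau\) through an affine-scaled
logistic onto \((0.001, 0.08)\), \(\lambda\) through \(2\,\text{logistic}-1\)
onto \((-1,1)\). Priors are independent N(0, 1) on each unconstrained
parameter — weakly informative, centring \(\alpha, \delta\) at 0.5, \(\tau\)
mid-range, and \(\lambda\) at 0 so that agent-specific updating is the prior
expectation. Optimisation is multi-start BFGS with numerical gradients
(default 10 restarts drawn from the prior, relative tolerance \(10^{-8}\)),
deterministic given the seed.

Per-participant log model evidence uses the Laplace approximation at the MAP,
\(\log p(y) \approx \log p(y,\hat\theta) + \tfrac{d}{2}\log 2\pi -
\tfrac12 \log\det H\); it is exact for Gaussian posteriors (verified against
the conjugate toy) and penalises the extra parameters of the richer variants.
If the curvature at the optimum is not positive definite the fit falls back
to a BIC-style evidence with a warning.

Fixed-effects comparison sums log evidences over participants
(`fixed_effects_compare()`); random-effects comparison
(`random_effects_bms()`) treats model identity as a random effect with a
Dirichlet prior over model frequencies, estimated by variational Bayes.
Exceedance probabilities are computed by Monte Carlo over the posterior
Dirichlet (default \(10^6\) draws, seeded, accurate to about \(10^{-3}\));
the Bayes omnibus risk (BOR) compares the free energy of the fitted
frequency model against the null of equal frequencies, exactly computable
for the null; the protected exceedance probability is
\(PXP = EP\,(1-BOR) + BOR/K\). Best-model counts break ties towards the
variant with fewer free parameters, since the variants are nested.

## Model-free metrics

Task performance is measured without the model by correlating probe
responses with an exponential recency-weighted average \(O\) of the outcomes
pertinent to the probed agent (Self: shared + privileged; Other: shared +
decoy), updated as \(O \leftarrow O + w\,(o - O)\). The recency weight
defaults to \(w = 0.1\), matching the learning rate used in the reference
simulations, and is configurable; \(O\) rather than the true generating
\(P\) absorbs sampling error in the observed outcomes. \(O\) starts at 0.5
and probes arriving before any pertinent outcome are flagged.

The per-participant performance statistic pools Self- and Other-probe pairs
into a single Pearson correlation. It is referenced to a null distribution
obtained by re-computing the statistic for 1000 sets of uniform random
responses on the same sequence: the reported score is the raw correlation
minus the null mean (mean-subtraction, not z-scoring — chance level fixes
only the location), and a participant counts as above chance only if the raw
statistic strictly exceeds the null's 95th percentile. By construction about
5% of genuinely random responders are flagged, which the test suite verifies.
Direction-specific metrics use the across-agent pairings: *idiocentric* =
corr(\(O^{Self}\), responses on Other probes), *allocentric* =
corr(\(O^{Other}\), responses on Self probes).

A caution on single-participant metrics: each correlation compares two
smooth, autocorrelated series at ~25–30 probes, so its sampling variability
is large (SD ≈ 0.4 under the null). Group or replicate averaging is
essential; the consistency analyses below therefore work on replicate means
over matched sequences.

## Simulation experiments

`simulate_cohort()` draws generative parameters (by default resampling a
packaged *synthetic* table of plausible values — a stand-in for an empirical
MAP table — with uniform and fixed samplers as alternatives), generates a
fresh sequence per participant (a shared-sequence policy is available), and
simulates responses; everything derives from one base seed.

`parameter_recovery()` fits every participant and reports the full
generative-by-fitted correlation matrix, stratified by quartile of
generative \(\tau\). Under low choice noise (\(\tau = 0.005\), \(\lambda\)
uniform on \((-0.8, 0.8)\), 100 participants) the leakage parameters recover
at \(r \gtrsim 0.9\) with cross-correlations near zero — the two leakage
directions are separately identifiable — while near the upper \(\tau\) bound
recovery degrades markedly, as expected when responding approaches uniform.
`model_recovery()` runs the companion confusion analysis: data simulated from
the zero-leakage variant are assigned to it by summed evidence (the
complexity penalty works), and data with strong asymmetric leakage at low
noise select the unrestricted variant.

Problem sizes used by the packaged checks (`tests/testthat/test-acceptance.R`
and `scripts/acceptance.R`) are chosen to give stable Monte-Carlo estimates
on a single CPU: 50 sequences for the belief-correlation signature, cohorts
of 60–100 for recovery, 500 random responders (against 1000-draw nulls) for
the calibration check, and 25–40 matched replicates per \(\lambda\) for the
model-free consistency grid. The two-group contrast in the acceptance script
is a *power-style* simulation of the design (groups of 38 and 74, generative
idiocentric leakage centred at 0.14 vs −0.01, SD 0.235): it checks that the
pipeline detects a group difference of that order, not a reproduction of any
empirical estimate.

## What the synthetic data do and do not show

The generator reproduces the task's generative structure: bounded walks,
trial-type provenance, probe schedule, and Beta-distributed responses around
model beliefs. It does not emulate human non-idealities — lapses, anchoring
on the response scale, drifting attention, learning-to-learn across the
session, or any relationship between parameters and clinical status. Passing
recovery and calibration checks therefore shows the *pipeline* is correct
and the design identifiable under its own assumptions; it cannot certify
parameter estimates from real participants, for which the model-free
metrics and the random-responding null provide complementary, assumption-light
checks.

Other known limitations: the likelihood treats probes as conditionally
independent given the trajectory (no response autocorrelation); evidence is
a Laplace approximation, which can be optimistic for strongly non-Gaussian
posteriors (the BIC fallback is cruder still); and exceedance probabilities
are Monte-Carlo estimates, so comparisons between nearly-tied models inherit
\(\sim 10^{-3}\) noise.
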