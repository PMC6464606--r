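---
title: "Separating value and movement-direction coding in photometry signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating value and movement-direction coding in photometry signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Dopamine neurons projecting to dorsomedial striatum (DMS) respond more
strongly when a mouse chooses the lever contralateral to the recorded
hemisphere. Is that a movement-direction signal, or could it be an
action-specific reward-prediction error (RPE) in disguise? Because animals
preferentially choose the action they value more, a signal proportional to
the *value of the contralateral action* is, on average, larger on
contralateral choices — it can masquerade as choice selectivity. The
package implements the analysis that separates these accounts on a
trial-by-trial basis, together with a fully synthetic test bed, so every
stage can be validated against data whose ground truth is known.

Three generative hypotheses are distinguished, all expressed as modulations
of the event-locked transient at lever presentation:

* **contralateral value** — amplitude proportional to
  $Q_\text{contra} - Q_\text{ipsi}$, whichever side is chosen;
* **chosen value** — amplitude proportional to
  $Q_\text{chosen} - Q_\text{unchosen}$, the classic "critic" RPE
  orientation, identical for both choices;
* **chosen value + movement** — chosen value plus a fixed bonus on
  contralateral-choice trials.

## Behavioral model

Choices come from a Q-learning agent with a choice-repetition ("stay")
bias. The chosen action's value is updated by the delta rule
$Q_{t+1}(c_t) = Q_t(c_t) + \alpha\,(r_t - Q_t(c_t))$ and choice follows a
softmax $P(c_t = c) \propto \exp\{\beta\,Q_t(c) + \text{stay}\cdot
I(c, c_{t-1})\}$, with $\alpha \in [0,1]$, $\beta \ge 0$, and stay
unconstrained. `agent_params_default()` carries the group-median estimates
from mice on this task ($\alpha = 0.612$, $\beta = 0.990$,
stay $= 0.945$); an agent at these parameters repeats its previous choice
on roughly three quarters of trials, which is what makes value and choice
so correlated in the first place.

The task simulator reproduces the reversal structure these estimates came
from: 70%/10% reward levers, the high side reversing after at least 10
rewarded trials plus a Geometric($p=0.4$) number of extra trials. The
geometric convention is support $\{1, 2, \dots\}$, i.e. mean $1/p = 2.5$
extra trials — the convention that matches the task's stated mean. Event
times use jittered 0–1 s delays on a 0.1 s grid; the grid excludes 0 so
that nose poke, lever presentation, press, and outcome are strictly
ordered. Press latencies are log-normal (median 0.5 s, log-SD 0.6,
consistent with the depicted average latency); draws beyond the 10 s
deadline mark the trial abandoned, which at these settings is essentially
never, matching the <2% rate reported for the animals. Q values are
initialised once per subject's concatenated record (sessions are analysed
concatenated); per-session resetting is available via
`task_config(q_reset_per_session = TRUE)`.

## Hierarchical fitting

Subject-level parameters live on unconstrained scales (logit $\alpha$,
log $\beta$, identity stay) and are modelled as Gaussian draws from
group-level distributions, with weakly-informative priors: Normal(0, 1.5)
on group means, half-Normal(0, 1) on group SDs. Three backends share one
interface:

* `per_subject_mle` — independent L-BFGS fits from multiple starts;
* `hierarchical_map` — MAP-EM with Laplace variance propagation;
* `hierarchical_mcmc` — the default schedule is 4 chains of 1000
  iterations, 250 discarded as warmup. The sampler is slice-within-Gibbs:
  subject parameters are updated by slice sampling along per-subject
  eigen-directions of the warmup covariance (plain component-wise slice
  sampling mixes poorly because $\alpha$ and $\beta$ trade off in the
  likelihood), group means by conjugate Gibbs, group SDs by slice on the
  log scale, plus interleaved non-centred (ASIS) translation and rescale
  moves that break the usual funnel between group scale and subject
  effects. Each stored iteration comprises five full sweeps of these
  updates, so the retained draws are close to independent. Convergence is
  monitored by split-Rhat; the package flags anything above 1.1, and at
  the study scale (17 subjects, 1000 trials each) all parameters reach
  split-Rhat below 1.003.

Two readings of "group percentiles" are reported: posterior percentiles of
the transformed group-mean parameters (`group_percentiles`, the
table-style summary) and percentiles of the implied subject-level
distribution (`subject_dist_percentiles`). Downstream Q trajectories use
per-subject posterior medians, giving one value trajectory per subject.

Synthetic cohorts (`cohort_params()`) draw subject effects with SDs
(0.20, 0.15, 0.15) on the unconstrained scales around the group medians —
modest heterogeneity comparable to the spread of the fitted subject
estimates.

## Photometry generator

There is no ground-truth generative model for GCaMP6f photometry, so the
generator is deliberately simple and is documented as such: a unit-peak
double-exponential transient (rise 0.1 s, decay 0.6 s) placed at lever
presentation with amplitude given by the hypothesis; for the movement
variant the movement component is re-expressed at the lever press, with
the side flipped when `movement_reversal` is set (emulating the post-press
reversal of side selectivity that accompanies the animal's change of
movement direction). Signals are synthesized in raw fluorescence — a
baseline of 100 units times (1 + drift + events + noise), with a slow
filtered-random-walk drift (SD 10% of baseline, 60 s timescale) and white
noise (SD 5% of baseline) — so the preprocessing chain does real work.
Default gains are 0.05 fractional dF/F per unit value difference and 0.05
for the movement bonus; the real data pin neither amplitudes nor SNR, so
recovery-style checks, not absolute amplitudes, are what the test bed
asserts. What the generator does **not** emulate: photon/shot noise,
hemodynamic or motion artifacts, an isosbestic channel, nonlinear
indicator dynamics, or site-to-site gain heterogeneity — passing tests
demonstrate the analysis logic, not robustness to every artifact of real
recordings.

## Preprocessing

The chain mirrors standard photometry practice: a linear-phase high-pass
FIR filter (passband 0.375 Hz, stopband 0.075 Hz, at least 10 dB stopband
attenuation, 15 Hz sampling), dF/F as the filtered signal divided by the
mean raw signal of the site's full record, then z-scoring per site over
the full record. The design is a Hamming-window type-I filter whose order
starts at the 3.3/Δf transition-width estimate and grows until the spec is
met; the printed band spec, not a particular tap vector, is the contract.
Filtering is zero-phase (forward-backward with odd-reflection padding),
applied per session segment so filtering commutes with concatenation; a
causal mode exists behind a flag. The z-score uses the site's standard
deviation (z-scoring by a standard *error* would produce values orders of
magnitude larger than the ±1-ish range the signals occupy).

Epochs are 45 samples — 15 before the event and 30 from it onward, i.e.
$[-1\,\text{s}, +2\,\text{s})$ — with nearest-sample alignment and no
sub-sample interpolation. Events whose window would leave the trace or
cross a session boundary are dropped and logged, never padded.

## Regression machinery

At each of the 45 timepoints the z-scored signal is regressed on choice
(contra = 1), the standardised value difference in a declared frame
(chosen − unchosen, or contra − ipsi), their interaction, an intercept,
and optionally log press latency, with random effects by recording site.
The default structure is random intercept plus choice and value slopes,
falling back to random intercepts when the fuller model fails. P-values
use Satterthwaite degrees of freedom by default; a Wald option exists for
replicated simulation studies where, at thousands of trials, the two are
indistinguishable. For the random-intercept/Wald combination the package
solves the profiled REML problem in closed form per timepoint (per-site
sufficient statistics make the 45 fits essentially free); the estimator is
identical to lme4's and the equality is part of the test suite. P-values
are Benjamini–Hochberg corrected per regressor across the 45 timepoints,
and significance tiers (0.05 / 0.01 / 0.001) are assigned on the adjusted
values.

The multi-event kernel regression models the continuous z-scored trace as
a sum of lagged-indicator kernels (45 lags spanning −1 s to +2 s) for
three events (nose poke, lever presentation, lever press) × four
conditions (choice × previous-trial outcome) plus a global intercept,
solved by sparse least squares with cluster-robust (CR1 sandwich)
standard errors grouped by site. Jittered inter-event delays are what
keep the three events' columns linearly independent; a rank-deficient
design raises an error naming the offending columns.

## The discrimination logic

Writing $g$ for the value gain and $c \in \{0,1\}$ for contra choice, the
identity $dq_\text{contra} = (2c-1)\,dq_\text{chosen}$ means a generator
linear in one frame is, in the other frame, a pure choice × value
interaction. The decision rule therefore runs the pointwise regression in
*both* frames and asks where a sustained interaction lives, using the
0.25–1 s post-presentation window in which action and value coding are
most prominent. "Sustained" is operationalised as at least 4 consecutive
BH-significant timepoints at adjusted $p < 0.05$ (≈ 0.27 s at 15 Hz;
configurable):

* interaction in the chosen frame only → **contralateral value**;
* interaction in the contra frame only, with a sustained choice main
  effect → **chosen value + movement**;
* interaction in the contra frame only, without one → **chosen value**;
* anything else → **indeterminate**.

Degrading the gains moves outcomes toward *indeterminate* rather than
toward a wrong label, since all three labels require a detected
interaction asymmetry.

The press-locked reversal check computes the across-site contra − ipsi
difference trace on press-aligned epochs and reports the first post-press
sign change sustained for ≥ 3 samples. The flipped excursion must also
exceed half the peak absolute difference: a zero-phase high-pass filter
leaves rebound lobes (roughly 30% of peak at these band edges) around any
decayed transient, and without the magnitude guard that rebound registers
as a spurious reversal even on noise-free traces, whereas a genuine side
reversal flips by close to the full selectivity magnitude. The same function applied to the previously-rewarded −
unrewarded contrast verifies that value modulation does *not* reverse.

## Problem sizes and numerical choices

The test suite exercises the full pipeline at the study's scales: the
posterior-predictive stay-fraction and parameter-recovery checks use 17
subjects × 1000 trials; the discrimination study uses 50 replicates of 17
subjects × 800 trials at the default gains, cycling the three generators.
Module-level tests use smaller cohorts (4–8 subjects, 150–400 trials)
chosen so each property is tested at the smallest size where it is
meaningful. Other numerical choices: optimiser bounds ±8 on logit-alpha
and log-beta (±10 for stay) guard separable choice sequences; the MAP-EM
group-SD update carries a small (0.02) regulariser against collapse;
quantile bin edges for the value-binned averages are computed within
site; ties in nearest-sample event alignment follow `round()`.

## Known limitations

The MCMC backend is a purpose-built Gibbs/slice sampler, not a
general-purpose HMC engine; it is tuned for this 3-parameter-per-subject
hierarchy and validated by recovery and split-Rhat, but new model variants
would need their own mixing checks. The mixed-model random-slope
structure falls back silently (with a logged note) to random intercepts
on convergence failure. The generator's linearity means interaction
effects are exact algebraic consequences of the frame change; real data
can of course contain partial mixtures of the three hypotheses, for which
the discrimination returns *indeterminate* rather than a graded weight.
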