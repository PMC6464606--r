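# photoval

Does an event-locked dopamine photometry signal encode the *value* of an
action (an anticipatory reward-prediction error, RPE) or the *direction of
movement*? The two are easy to confuse: animals preferentially choose the
action they value more, so a signal proportional to the value of the
contralateral action is larger, on average, on contralateral choices — and
can masquerade as movement selectivity. `photoval` implements the
trial-by-trial analysis that separates the two accounts, along with a
synthetic task/photometry test bed in which the ground truth is known, so
every stage of the analysis can be validated by recovery.

It is aimed at systems-neuroscience analysts working with fiber photometry
from choice tasks — in particular recordings from dopamine neurons
projecting to dorsomedial striatum during a probabilistic reversal-learning
task — and at methodologists who want a reproducible reference
implementation of the frame-discrimination logic.

## The model and the analysis

Behavior is fit with a Q-learning model with a choice-repetition bias:

    Q_{t+1}(c_t) = Q_t(c_t) + α (r_t − Q_t(c_t))
    P(c_t = c) ∝ exp{ β Q_t(c) + stay · I(c, c_{t−1}) }

estimated per subject and hierarchically across subjects (slice-within-Gibbs
MCMC with split-Rhat diagnostics, or MAP-EM, or per-subject MLE).

Photometry preprocessing follows standard practice: high-pass FIR filter
(0.375 Hz passband, 0.075 Hz stopband, ≥ 10 dB attenuation at 15 Hz
sampling), dF/F as filtered signal over the raw mean, per-site z-scoring,
and 45-sample event-locked epochs (−1 s to +2 s).

The statistical core is a per-timepoint linear mixed-effects regression of
the z-scored signal on choice, the standardised value difference ΔQ in a
declared reference frame — chosen − unchosen, or contralateral −
ipsilateral — their interaction, and an intercept, with random effects by
recording site and Benjamini–Hochberg correction across timepoints. The key
identity `ΔQ_contra = (2·choice − 1) · ΔQ_chosen` means a signal linear in
one frame appears in the other frame as a pure choice × value interaction,
so running the regression in both frames and asking where a *sustained*
interaction lives (≥ 4 consecutive significant timepoints in the 0.25–1 s
window) identifies the generative hypothesis: contralateral value, chosen
value, or chosen value plus movement. A multi-event kernel regression
(lagged indicators for nose poke, lever presentation and lever press ×
choice × previous outcome, cluster-robust covariance by animal) verifies
the conclusions are not tied to a single alignment event.

## Worked example

```r
library(photoval)
set.seed(7)

tc  <- task_config(trials_per_session = 200, sessions_per_site = 4)
trials <- simulate_cohort(cohort_params(17), tc)
round(100 * stay_fraction(trials), 1)
#> [1] 75.1

fit   <- fit_hierarchical(trials, fit_config(method = "per_subject_mle"))
qtraj <- compute_q_trajectories(fit$subject_params, trials)

sig <- prepare_cohort_signals(trials, qtraj,
                              photometry_config(hypothesis = "chosen_value"))
rep <- discriminate_frame(trials, qtraj, sig)
rep$inferred
#> [1] "chosen_value"
unlist(rep$evidence[1:4])
#> interaction_chosen_frame interaction_contra_frame
#>                    FALSE                     TRUE
#>       choice_main_effect        value_main_effect
#>                    FALSE                     TRUE
```

The cohort repeats its previous choice on ~75% of trials (the stay bias at
the fitted group medians). Data generated under chosen-value coding show a
significant value effect with *no* sustained interaction when analysed in
the chosen frame, while re-orienting the same data to the contralateral
frame produces a sustained interaction — exactly the asymmetry the
discrimination rule keys on, and the report correctly labels the generator.
`run_full_pipeline()` wraps the whole chain (simulation, fitting,
preprocessing, both-frame regressions at three alignment events, kernel
regression, condition-binned averages, press-locked reversal check,
discrimination) behind a single seeded call.

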