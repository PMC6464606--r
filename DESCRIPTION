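Package: photoval
Title: Separating Value and Movement-Direction Coding in Fiber Photometry Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking whether event-locked dopamine photometry signals
    reflect action value (an anticipatory reward-prediction error) or movement
    direction. Provides a simulator for a probabilistic reversal-learning task
    and a Q-learning agent with a choice-repetition (stay) bias; a synthetic
    GCaMP6f-like photometry generator embodying three competing generative
    hypotheses (contralateral value, chosen value, chosen value plus movement);
    hierarchical model fitting by MCMC or MAP-EM with split-Rhat diagnostics;
    photometry preprocessing (high-pass FIR filtering, dF/F, per-site
    z-scoring, event-locked epoching at 15 Hz); per-timepoint mixed-effects
    regression with Benjamini-Hochberg correction; multi-event kernel
    regression with cluster-robust covariance; and an end-to-end pipeline that
    discriminates the generating hypothesis from the pattern of interaction
    effects across value reference frames.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    data.table,
    jsonlite,
    lme4,
    lmerTest,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    sandwich,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
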