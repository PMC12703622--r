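Package: planxai
Title: Explainable Analysis of a Reinforcement-Learning Treatment-Planning Agent
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale testbed for interpreting a deep-reinforcement-learning
    agent that tunes treatment planning parameters (TPPs) for intensity-modulated
    radiotherapy inverse planning. Provides a synthetic 2-D phantom environment
    with a DVH-constrained fluence-map optimizer, ProKnow-style plan scoring, a
    two-head LSTM actor-critic agent over DVH inputs with an 18-action TPP-tuning
    policy, integrated-gradients attribution from DVH and LSTM memory inputs to
    tuning decisions with a completeness audit, and a quantitative interpretation
    suite: attribution-reward cosine similarity, policy entropy, ideal planning
    steps, final-TPP-space summaries, LSTM memory probing, and baseline-offset
    sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    cluster,
    lme4,
    lmerTest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
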