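# planxai

Explainable analysis of a deep-reinforcement-learning agent that tunes
treatment planning parameters (TPPs) for IMRT inverse planning.

## What this is for

In inverse planning, a treatment planning system optimizes beamlet fluences
`x ≥ 0` so the dose `d = Mx` covers the planning target volume (PTV) at the
prescription dose `d_p` while sparing the bladder and rectum. The trade-offs
are steered by nine TPPs — weights `λ_PTV, λ_BLA, λ_REC`, dose thresholds
`t_PTV, t_BLA, t_REC` and volume fractions `V_PTV, V_BLA, V_REC` in the
objective

```
F(x) = λ_PTV [ Σ_{v∈PTV} (d_v − d_p)_−² + Σ_{v∈S_PTV} (d_v − t_PTV d_p)_+² ]
     + Σ_{i∈{BLA,REC}} λ_i Σ_{v∈S_i} (d_v − t_i d_p)_+²
```

— and an LSTM actor-critic agent learns to tune them, observing only the
plan's dose-volume histograms (300 values: PTV, bladder, rectum curves) and
choosing among 18 actions (±one fixed step on one TPP). `planxai` asks *why*
the agent's tuning works, using integrated gradients (IG):

```
IG_ij(x, x') = (x_i − x'_i) ∫₀¹ ∂F_j(x' + α(x − x'))/∂x_i dα
```

attributing each action's policy probability `F_j` to the DVH observation
and the LSTM memory vectors `c` and `h` against a zero baseline, with the
completeness identity `Σ_i IG_ij = F_j(x) − F_j(x')` audited on every
record. On top of the attributions the package computes the interpretation
metrics that connect them to planning behaviour: the probability-weighted
attribution–reward cosine similarity `(1/N) Σ_i Σ_j p_ij cos(A_ij, R_ij)`,
normalized policy entropy `−(1/N) Σ_i Σ_j p_ij ln p_ij`, ideal (shortest
lattice path) planning steps, final-TPP-space summaries, an LSTM memory
probe under synthetic dose-violation scenarios, and baseline-offset
sensitivity of the attribution heatmaps.

Everything runs at desk scale on synthetic 2-D phantom cases; no clinical
data, no GPU, no deep-learning framework (the two-head LSTM network and its
gradients are implemented in the package, because the network itself is the
object under analysis).

## Worked example

```r
library(planxai)

case <- generate_case(seed = 1, overlap_level = 0.25)   # 400-voxel phantom
agent <- agent_init(seed = 1)                            # untrained network
trace <- run_episode(case, agent, max_steps = 5, mode = "stochastic", seed = 3)
trace
#> <episode_trace case-1-small-025> stochastic, 5 steps, score 4 -> 5 (max_steps)

st <- trace$steps[[1]]
recs <- attribute_all_actions(agent, st$dvh_input, st$memory_in,
                              baseline_spec(0), path_steps = 256)
leading_action(recs)
#> dvh   c   h
#>   1   1   1
organ_attribution(recs[[1]])
#>           PTV           BLA           REC
#>  0.0023224784 -0.0006912456  0.0010065478
policy_entropy(trace)$entropy
#> [1] 2.889046
```

The trace starts at score 4 of 9 (untuned plans are deliberately mediocre)
and ends at 5. For the first step, action 1 ("increase λ_PTV") receives the
highest total attribution from all three inputs; its organ-wise DVH
attribution says the PTV curve pushed the action's probability up by
~0.0023 while the bladder curve pulled it down — tiny numbers, because an
untrained policy is nearly uniform, which the entropy confirms
(2.889 ≈ ln 18 = 2.890). Training
(`train_checkpoints()`) produces checkpoint agents whose entropy drops and
whose attributions align with dose-violation reduction; the numbered
scripts under `analysis/` walk the full pipeline (cohort simulation,
training, planning archives, attribution analysis, interpretation metrics)
and write their tables under `results/`.

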