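---
title: "Interpreting a reinforcement-learning treatment-planning agent with integrated gradients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpreting a reinforcement-learning treatment-planning agent with integrated gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In intensity-modulated radiotherapy (IMRT) inverse planning, a treatment
planning system (TPS) optimizes beamlet fluences $x \ge 0$ so that the dose
$d = Mx$ covers the planning target volume (PTV) at the prescription dose
$d_p$ while sparing organs at risk (OARs — here bladder and rectum). How the
competing goals trade off is set by nine treatment planning parameters
(TPPs): importance weights $\lambda_{PTV}, \lambda_{BLA}, \lambda_{REC}$,
upper dose thresholds $t_{PTV}, t_{BLA}, t_{REC}$ (fractions of $d_p$), and
allowed volume fractions $V_{PTV}, V_{BLA}, V_{REC}$. Human planners tune
these by trial and error; a reinforcement-learning agent can automate the
tuning, observing the plan's dose-volume histograms (DVHs) and choosing one
of 18 discrete actions (raise or lower one TPP by a fixed step) per
iteration.

`planxai` is a desk-scale testbed for *interpreting* such an agent. It
provides every stage in one package: a synthetic planning environment, a
two-head LSTM actor-critic agent, integrated-gradients (IG) attribution from
the agent's inputs to its tuning decisions, and a quantitative
interpretation suite connecting attributions to planning behaviour.

## The planning environment

The objective minimized by `optimize_fluence()` is the standard
quadratic-penalty DVH-constrained form

$$F(x) = \lambda_{PTV}\Big[\sum_{v\in PTV}(d_v-d_p)_-^2 +
  \sum_{v\in S_{PTV}}(d_v-t_{PTV}d_p)_+^2\Big] +
  \sum_{i\in\{BLA,REC\}}\lambda_i\sum_{v\in S_i}(d_v-t_id_p)_+^2$$

with $d = Mx$, $x \ge 0$. The volume constraints enter through the penalised
sets $S_i$: among voxels exceeding the threshold, the $\lfloor V_i
n_i\rfloor$ highest-dose violators are tolerated and the remaining
(lowest-dose excess) violators are penalised — the classic DVH-constraint
heuristic. Selections are recomputed every outer round (20 by default) and
frozen during inner projected-gradient steps (50 per round, backtracking
line search, relative-change tolerance $10^{-6}$), which makes the inner
objective provably non-increasing. Convergence is declared on the projected
gradient sup-norm ($\le 10^{-4}(1+F)$). Raw voxel sums are used (no
per-voxel averaging); only relative $\lambda$ values matter, which the test
suite verifies by rescaling all three weights jointly.

The phantom (`generate_case()`) is a 2-D stand-in for the clinical TPS: a
20×20 (or 30×30) voxel grid with a roughly circular PTV, a bladder-like OAR
above and a rectum-like OAR below, irradiated by three beams of parallel
pencil beamlets with Gaussian lateral profile (σ = 0.6 voxel) and
exponential depth attenuation (μ = 0.04/voxel). The geometry knob that
matters clinically is PTV–OAR overlap: `overlap_level` sets the fraction of
each OAR's voxels within one voxel of the PTV, built constructively from the
PTV's adjacency ring so the achieved fraction tracks the request (saturating
when the ring is exhausted; the achieved value is stored in the case
metadata). The cohort default of 0.25 was chosen so that untuned plans score
well below the maximum (typically 2–5 of 9) while careful tuning can reach
the maximum on most cases — the regime in which tuning is both necessary and
possible. At overlap 0.5 the rectum criteria become geometrically
unsatisfiable (half the organ sits at the PTV boundary), which is a feature
for robustness experiments, not a bug.

What the phantom does *not* emulate: 3-D scatter, realistic beam models,
anatomical shape variation, DICOM geometry. Tests passing here show the
analysis machinery is correct and that the agent-environment loop has the
intended structure; they do not certify behaviour on clinical data.

## Scoring

`score_plan()` awards points per satisfied dose-volume criterion, maximum 9,
in the style of criterion-based plan-quality scoring: PTV $V(0.95) \ge 0.95$
(2 pts) and $V(1.07) \le 0.10$ (1 pt); bladder $V(0.6) \le 0.50$, $V(0.8)
\le 0.30$, $V(0.9) \le 0.15$; rectum $V(0.6) \le 0.45$, $V(0.8) \le 0.25$,
$V(0.9) \le 0.10$ (1 pt each). The exact clinical criteria behind the
published scoring system are proprietary, so this table is a plausible
stand-in with the right total; it is fully overridable through the config.
A criterion's *violation* is the volume-fraction excess beyond its limit
(`max(0, observed - limit)` for upper bounds), summed per organ — the
quantity the mode-2 reward tracks. DVH curves are sampled at 100 uniform
points on $[0, 1.2] \cdot d_p$ (the upper end covers hot spots past the
1.07 criterion); criteria are evaluated by linear interpolation on that
grid. Violations are per-criterion, not per-DVH-point.

## The agent

The network is deliberately the analyzed object, so the cell is implemented
exactly:

$$f = \sigma(W_f a + U_f h + b_f),\quad i = \sigma(W_i a + U_i h + b_i),$$
$$g = \tanh(W_g a + U_g h + b_g),\quad o = \sigma(W_o a + U_o h + b_o),$$
$$c' = f \odot c + i \odot g,\qquad h' = o \odot \tanh(c'),$$

where $a = \tanh(W_d\,\mathrm{dvh} + b_d)$ encodes the 300-value DVH
observation (PTV, bladder, rectum curves, 100 points each) through a
64-unit dense layer, the LSTM has 32 units, and $h'$ feeds an 18-way
softmax policy head and an 18-way linear Q head. Because the agent sees
only the DVH — never the current TPPs — the task is partially observed and
the memory $(c, h)$ is a genuine input in its own right, which is exactly
why the attribution engine treats it as one.

Training (`train_checkpoints()`) is plain on-policy advantage actor-critic
with entropy regularization, a deliberate simplification of the
experience-replay actor-critic family used at full scale: the analysis
consumes a *graded progression of checkpoints*, not a state-of-the-art
agent. Immediate reward is the change in total plan score *plus twice the
reduction in total dose violation*, minus a 0.05 per-step penalty, with a
terminal bonus of 1 at the maximum score. The violation-reduction term is
the dense component of criterion-based scoring: with the sparse score
delta alone, a desk-scale agent discovers "ratchet" strategies that grind
one parameter until a criterion flips — strategies whose single-step
effects are *anti*-aligned with violation mitigation even though they
eventually gain points. Folding the evaluation criteria's violation
magnitudes into the immediate reward (as full-scale criterion-driven
reward designs do) removes that pathology. Updates are episodic with
discounted Monte-Carlo returns (discount 0.9 — a short effective horizon
matching the 10–30-step episodes and favouring immediate mitigation):
each episode contributes one batched gradient — the policy head weighted
by the advantage $G_t - \sum_j \pi_{tj} q_{tj}$ with a 0.003 entropy
bonus, the Q head regressed on $G_t$ — applied with Adam at learning rate
$3\times10^{-3}$. Monte-Carlo returns were preferred over one-step
temporal-difference bootstrapping because score changes are sparse within
an episode and the desk-scale budget allows only a few hundred episodes;
the entropy bonus is kept small because the attribution–reward similarity
is probability-weighted, and an over-regularized (near-uniform) policy
dilutes the aligned dominant actions with noise from the 17 others.
Backpropagation is truncated at single steps (the incoming memory is
treated as a constant), consistent with the attribution view of $(c, h)$
as inputs. The desk-scale
study conditions are 5000 environment steps on one small case with
checkpoints every 1250 steps; greedy evaluation runs on 20 independently
generated cases, mirroring the train-on-one-case / test-across-cases
protocol of the full-scale system.

TPP grid defaults: $\lambda \in [0.05, 5]$ step 0.15, $t \in [0.5, 1.2]$
step 0.05, $V \in [0.05, 0.95]$ step 0.05. Initial values sit near
mid-range and are *lattice-aligned* (2.45, 0.85, 0.50): every bound is a
whole number of steps from the initial value, so clipping at a bound never
takes a trajectory off the step lattice — which keeps the ideal-step count
well-defined for every reachable configuration.

## Integrated gradients

For action $j$, the attribution of input coordinate $i$ is

$$\mathrm{IG}_{ij}(x, x') = (x_i - x'_i)\int_0^1
  \frac{\partial F_j(x' + \alpha(x - x'))}{\partial x_i}\,d\alpha,$$

where $F_j$ is the *post-softmax probability* of action $j$ (a function
into $[0,1]$, matching the attribution framing) and the path scales all
three inputs (DVH, $c$, $h$) jointly from their baselines. A joint path is
essential: per-input paths would break the completeness identity
$\sum_i \mathrm{IG}_{ij} = F_j(x) - F_j(x')$, which the analysis leans on to
decompose each action's probability into baseline + DVH + $c$ + $h$
contributions.

The integral is approximated by trapezoid quadrature (default 256 nodes;
exact for linear $F$ at any node count $\ge 2$). Published descriptions of
IG rarely state the quadrature rule or node count, so rather than guessing
and hiding the choice, every `attribution_record` carries its completeness
residual — quadrature adequacy is observable, and `validate_archive()`
flags any record whose residual exceeds the configured tolerance. At 1024
nodes the residual stays below $10^{-4}$ across random networks (an
acceptance-tested property).

The default baseline is all-zero (absence of planning signal). The
sensitivity analysis offsets the OAR part of the DVH baseline by 0.005 and
0.01 while keeping the 100 PTV entries at zero (a nonzero PTV baseline
would itself violate target-coverage criteria) and reports the cosine
similarity between offset and zero-baseline DVH heatmaps grouped by leading
action; at offset 0 the similarity is exactly 1 by construction, and zero-norm
heatmaps are assigned similarity 0 by convention.

## Interpretation metrics

* **Attribution–reward similarity.** Per step $i$ and action $j$, the
  organ-wise attribution $\vec A_{ij}$ (DVH attributions summed per organ
  block) is compared with an organ-wise reward $\vec R_{ij}$ from a
  counterfactual rollout: apply action $j$ to the step's pre-action TPPs,
  re-optimize (warm-started), and take per-organ score change (mode 1) or
  violation *reduction* (mode 2, so mitigation is positive — the sign
  convention that makes "high similarity = attributions align with
  violation mitigation" read correctly). The plan-level index is
  $\frac{1}{N}\sum_i\sum_j p_{ij}\cos(\vec A_{ij},\vec R_{ij}) \in [-1,1]$,
  with $\cos$ of a zero vector defined as 0. All 18 counterfactuals per
  step make this the most expensive metric; warm starts keep it desk-scale,
  and a cold-start oracle cross-checks the warm-started values in the tests.
* **Policy entropy.** $-\frac{1}{N}\sum_i\sum_j p_{ij}\ln p_{ij} \in
  [0, \ln 18]$, with $0\ln 0 = 0$; lower = more decisive.
* **Ideal planning steps.** The minimal number of monotonic one-directional
  lattice moves from initial to final TPPs,
  $\sum_p \mathrm{round}(|f_p - i_p|/\delta_p)$, which the tests verify
  equals a BFS shortest path on the (product) action graph. Actual minus
  ideal measures back-and-forth tuning. `ideal_steps()` is *not* asserted
  to be $\le$ actual steps: clipping at bounds can make a wandering
  trajectory end nearer its start than the path it walked.
* **Memory probe.** Eight synthetic DVH scenarios (each organ block all
  ones = "violation" or all zeros = "conserved") are each processed ten
  times with memory carried across repetitions (reset only between
  scenarios), yielding 80 $c$ and 80 $h$ states. States are L2-normalized;
  cluster structure is quantified by within- vs between-scenario cosine
  distance and (in the analysis driver) a classical-MDS embedding with
  silhouette widths. The conventional nonlinear-embedding defaults
  (perplexity 8, cosine metric, PCA init, learning rate 50) are recorded as
  metadata for use with an external t-SNE implementation.
* **Cohort report.** Per checkpoint: initial/final score, full-score
  counts, actual and ideal steps over full-score plans, entropy and
  similarity distributions, the final-TPP-space multiset, and the
  across-checkpoint Pearson and Spearman correlations between mean
  similarity and mean steps (the expected direction is negative:
  better-aligned agents plan faster). Mixed-model comparisons of step
  counts between checkpoints are delegated to the off-the-shelf
  `lmerTest::lmer` behind `step_comparison_test()`.

## Numerical and design choices

* Randomness flows from one root seed through named substreams
  (`derive_seed()`), so case generation, training, and per-episode action
  sampling are independently reproducible; greedy episodes are
  deterministic end-to-end, and ties in `which.max` resolve to the lowest
  action index everywhere.
* Archives are JSON-lines with no timestamps; a rerun under the same config
  and seed is byte-identical. Checkpoints are flat whitespace-separated
  text matrices plus a JSON manifest.
* Problem sizes in the tests and the acceptance script are the package's
  scaled-down study conditions: 400-voxel cases, 5000 training steps with
  four checkpoints (three training seeds in the acceptance suite), 20-case
  greedy evaluation panels, attribution at 32–64 path nodes where only
  aggregate similarity matters and 256–1024 where the quadrature itself is
  under test.
* The forward/backward passes are batched over matrix columns; one IG
  record costs a single batched forward plus one batched backward per
  action.

## Known limitations

The trainer is a simplification (no replay correction, no trust region,
single-step backprop), so checkpoint progressions are noisier than
full-scale training; the acceptance suite therefore pools greedy
evaluations over three training seeds and asserts only first-to-last
non-degradation plus positive mode-2 similarity of the best checkpoint.
Absolute similarity and entropy levels from the full-scale clinical study
depend on the authors' trained agents and patient cohort and are not
reproduction targets here. The scoring table is a stand-in for a
proprietary criteria set. The phantom's DVH behaviour is realistic at the
curve level, not anatomically.
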