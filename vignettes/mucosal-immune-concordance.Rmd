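---
title: "Ternary steady states of the mucosal-immune network and cytokine cohort concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ternary steady states of the mucosal-immune network and cytokine cohort concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ternimmune)
```

## The model

`ternimmune` treats the ocular/otolaryngological mucosal-immune system as a
discrete dynamical system. Each of the 27 nodes — immune cell types, signaling
molecules, the epithelial compartment, and a clamped `Infection` input — holds
one of three values: −1 (suppressed relative to homeostatic baseline), 0
(normal), +1 (increased). Edges are signed (stimulation or inhibition) and may
carry a *condition*: the edge only counts as a regulator while a designated
condition node occupies one of a listed set of states. This captures
context-dependent biology such as T-helper differentiation, which requires an
expanded naive T-cell pool.

### The update rule

Let `A` be the sign of the sum of the states of a node's condition-satisfied
activators and `I` the same for its inhibitors. The node's target value is

| situation | target |
|---|---|
| clamped node | current value |
| no satisfied regulators | 0 |
| activators only | `A` |
| inhibitors only | `−I` |
| both, `A = I ≠ 0` | current value |
| both, otherwise | `sign(A − I)` |

Four conventions deserve comment, because the verbal description of this
class of models leaves them open:

* **Aggregation is sum-then-sign.** Multiple regulators are combined by
  summing their states and taking the sign. This is symmetric in the
  regulators, reduces exactly to the single-regulator case, and makes a
  majority of increased activators behave like one increased activator.
  A max-based aggregation would behave differently only in mixed-sign
  regulator configurations; we document sum-then-sign as the package's
  choice.
* **Conflict retention.** When activators and inhibitors push with equal,
  nonzero strength (`A = I ≠ 0`), the node keeps its current value. We apply
  this symmetrically to the simultaneous-decrease case `A = I = −1`.
* **Inhibition semantics.** Inhibitor-only nodes move opposite to their
  inhibitors (`target = −I`): increased inhibitors suppress the node,
  decreased inhibitors release it. This is the standard reading of
  inhibition in signed regulatory logic.
* **Baseline decay.** An unclamped node with no satisfied regulators decays
  to 0: the levels ±1 are deviations from homeostasis and are not
  self-sustaining without input.

Updates are asynchronous: exactly one node changes per step, by default one
level at a time (−1 ↔ 0 ↔ +1; `stepwise = FALSE` switches to jump-to-target).
The two step conventions have identical fixed points; only trajectories
differ. Steady states are assignments where every node's target equals its
current value — the sinks of the asynchronous transition graph.

### Exact enumeration

`enumerateSteadyStates()` finds *all* fixed points. For small models a
vectorized exhaustive scan over all `3^n` free-node assignments is available
(`method = "brute_force"`) and serves as the oracle in the test suite. The
default constraint search backtracks over node assignments with propagation:
whenever all regulators (and condition nodes) of a node are assigned, the
node's fixed-point constraint either forces its value, prunes the branch, or
— in the retention case, where any value is self-consistent — leaves it for
branching. In practice only the genuine feedback nodes are branched on, so
the 27-node fixture enumerates in well under a second despite `3^27 ≈ 7.6
trillion` raw states. The suite checks set-equality of the two methods on
200 seeded random networks of 3–10 nodes at edge densities 0.2–0.5.

## The shipped fixture and its curation

The package ships a curated 27-node network (`loadMucosalFixture()`), three
labeled reference states, and the map from the 12 assayed cytokines to model
nodes (identity except IL12p70 → IL12). The connectivity of the published
system is available only as a drawing, so the edge list here is a **de novo
curation**, constrained to:

1. every edge is a canonical, literature-standard mucosal-immune interaction
   (macrophages secrete IL1β/IL6/IL12/IL23/TNFα; IL12 drives Th1; IFNγ
   activates macrophages and antagonizes Th2/Th17; IL6 blocks Treg
   induction; IL8/GM-CSF recruit neutrophils; Tregs secrete TGFβ and IL10;
   the epithelium sources IL6/IL8/CCL2/GM-CSF; and so on — each edge in
   `inst/extdata/mucosal_network.yaml` carries a one-line rationale);
2. all three reference states are fixed points with `Infection` clamped at
   0; and
3. they are the *only* fixed points under that clamp.

### Why some conditions must sit on effector nodes

T-helper differentiation edges are conditional on `NaiveTcell` being at +1.
One might wish *all* conditions to live there, but a small symmetry argument
shows that cannot yield exactly three steady states of the shipped form.
SS1 and SS2 agree on the entire "A block" of nodes (both +1) and on
`NaiveTcell`; they differ only on the cytokine/regulatory block that sits at
0 in SS1 and −1 in SS2. For that block to be 0 in SS1, none of its nodes can
receive a net unconditional push from the A block; with naive-T-cell
conditions satisfied identically in SS1 and SS2, the remaining within-block
update map is odd (pure sums and signs of block values). Hence if the all-−1
block configuration is a fixed point, so is its all-+1 mirror — a fourth
steady state. Breaking the mirror requires condition gates whose truth value
*differs* between the candidate states. The fixture therefore gates a small
number of edges on effector levels: `Macrophage → TNFα` is licensed only
while `Treg` is at 0, and the suppressive edges `IFNγ ⊣ Th2`, `IFNγ ⊣ Th17`,
`IL6 ⊣ Treg` act only while `TNFα` is at 0 (the "resolved acute
inflammation" context). These gates are fixture conventions, documented in
the YAML header; they are biologically interpretable (regulatory licensing
and suppression that engage as acute mediators resolve) but are the
curation's choice, not transcription.

Mucus-layer protection is encoded as a boolean variant rather than a 28th
node: the deficient-mucus fixture (default) contains the pathogen-contact
edges `Infection → SubmucosalDC` and `Infection ⊣ EpithelialCell`; the
protected variant (`mucusProtected = TRUE`) drops them. Under the
`Infection = 0` clamp used for all steady-state claims the two variants have
identical fixed points; the variant matters for scenario runs with pathogen
influx (`Infection` clamped at +1).

`verifyReferenceStates()` re-checks the three printed columns against the
rule and lists any violating node; the acceptance suite asserts that
enumeration returns exactly the three reference states.

## The statistical stage

### Welch tests and the direction mapping

Per sex stratum (analyzed independently), each marker is compared case vs
control with a Welch heteroscedastic t-test (Satterthwaite df, via
`stats::t.test`). Degenerate zero-variance-in-both-groups cases return
`p = 1` for equal means by convention. The t statistic (case − control) is
mapped onto a concordance p-value against a state's predicted level:

* predicted +1 → upper-tail one-sided p (small when cases exceed controls);
* predicted −1 → lower-tail one-sided p;
* predicted 0 → `1 − p_two` (small when the group means coincide).

This makes "small p = concordant with the state" uniform across all three
predicted levels, so the combined P behaves as a distance with 0 meaning
complete overlap. p-values are clipped to `[1e−15, 1]` before logs so the
Fisher statistic stays finite. The mapping — in particular the treatment of
predicted-0 markers — is a documented package convention; see *Limitations*
for its consequences.

### Brown's combination for dependent tests

Cytokines co-express, so the 12 per-marker p-values are not independent.
Fisher's statistic `X = −2Σ ln pᵢ` is therefore referred to a rescaled
chi-square: with `E = 2k` and `Var = 4k + 2Σ_{i<j} cov_ij`, the scale is
`c = Var/(2E)`, the effective degrees of freedom `f = 2E²/Var`, and
`P = Pr(χ²_f > X/c)`. The pairwise covariances of the `−2 ln p` terms are
approximated from the marker correlation `r` by the Kost–McDermott cubic
`3.263 r + 0.710 r² + 0.027 r³` (default), or by a two-branch quadratic fit
to the original tabulated values (`method = "brown-table"`). Two exact
checks pin the implementation: an identity correlation matrix reproduces
Fisher's method to machine precision (for `k = 2`, `p = (0.05, 0.05)` gives
`P = p₁p₂(1 − ln p₁p₂) ≈ 0.01748`), and duplicated tests at `r = 1` collapse
to the single-test p exactly, because the cubic evaluates to 4.000 there,
giving `c = 2`, `f = 2`.

Marker correlations are estimated from the cohort after centering each
marker *within its group*, so the case/control mean shift does not inflate
the dependence estimate; a non-positive Brown variance (only reachable with
pathological negative correlation inputs) falls back to independence with a
warning.

### Dissimilarities and the 2-D map

The case group's dissimilarity to each state is its aggregate P. To place
SS0/SS1/SS2 jointly in one map, model–model dissimilarities use the
normalized L1 distance `mean(|vᵢ − wᵢ|)/2` over the 12 mapped markers — a
construction isolated in one internal function, since nothing in the
measured data pins it down. Controls are by default only the t-test
reference, not a plotted point (`includeControls = TRUE` adds them against
all-normal predictions).

`embedMDS()` minimizes metric stress by SMACOF majorization (the Guttman
transform), under which the raw stress is non-increasing within a run. Eight
seeded random starts are used by default and the best final configuration
wins, ties to the first found. The reported stress is Kruskal's normalized
form `sqrt(Σ(d − δ)²/Σ δ²)`. Degenerate inputs are handled directly: an
all-zero dissimilarity matrix returns all points at the origin with stress
0; coincident rows yield coincident points. The returned configuration is
gauge-fixed (centroid at origin, principal axis on x, signs fixed by the
first points) so plots are reproducible. Any 3-point metric embeds exactly
in the plane; the tests require stress ≤ 1e−6 there and ≤ 1e−5 for
Euclidean-embeddable 4-point inputs with 8 restarts, and the reported stress
must match recomputation from the coordinates to 1e−10.

## The synthetic cohort generator

`generateCohort()` draws subjects on the log2 scale from a multivariate
normal with exchangeable correlation ρ (default 0.3) and common baseline
(mean 4.0, SD 1.0 log2 units per marker — deliberately arbitrary, clearly
synthetic values; no attempt is made to imitate plotted concentrations).
Default strata mirror the study sizes: 29 cases / 36 controls (female), 25 /
28 (male). When an effect state is named, case means shift by
`effectSize × SD × predicted level` per mapped marker (default 0.8 SD), e.g.
SS1 raises IL1β, IL2, IL6, IL12p70, IL17, IL23, IFNγ and TNFα. Generation is
deterministic given the seed, down to CSV bytes.

The generator emulates: study-sized strata, log-scale analysis, exchangeable
inter-marker dependence (which makes Brown's correction consequential), and
state-aligned mean shifts. It does **not** emulate: heavy-tailed or skewed
concentration distributions, assay floor/ceiling effects, missing data,
covariates (age, BMI, illness duration), or the real — unpublished —
correlation structure of the panel; ρ = 0.3 is a placeholder swept in tests.
Passing recovery tests therefore demonstrates that the pipeline detects the
structure it assumes, not that real cohorts satisfy those assumptions.

Generator self-validation uses Cohen's-d-style recovery
(`estimateEffects()`): at 10⁴ subjects per group, injected effects are
recovered within ±0.05 SD and generated correlations within ±0.05 of ρ.

## Problem sizes used by the test and acceptance suites

Enumeration oracle-equivalence uses 200 random networks of 3–10 nodes;
Brown-vs-Fisher uses 100 random p-vectors with k ≤ 10; recovery uses 20
replicates per arm at the female stratum sizes; Welch calibration uses 2000
null simulations at n = 29/36 with the type-I band [0.035, 0.065] at
α = 0.05. These sizes keep the full suite under half a minute while leaving
the sampling error of each check well inside its asserted tolerance.

## Limitations

* **The fixture is a curation, not a transcription.** Another edge list
  satisfying the same three constraints could differ; all claims about the
  shipped network are claims about this curation.
* **Null cohorts do not concentrate on the healthy state.** Under a
  zero-effect cohort every directional p-value — one-sided for predicted ±1,
  `1 − p_two` for predicted 0 — is marginally Uniform(0, 1), because a
  frequentist p cannot pile up near 0 under a point null of "no
  difference". The three aggregate Ps are then nearly exchangeable and SS0
  is ranked nearest only ~35–45% of the time at the study sizes (the
  acceptance suite computes this rate). The ranking is informative when a
  real directional signal exists (SS1-aligned cohorts recover SS1 in
  ≥ 90–95% of seeded replicates); it is *not* a calibrated test of
  healthiness. An equivalence-testing formulation for predicted-0 markers
  would be needed for that, and is out of scope here.
* **Aggregate P is a heuristic distance.** Brown's calibration assumes the
  `−2 ln p` covariances follow the cubic in the *signed-statistic*
  correlation; for predicted-0 markers the effective dependence of
  `1 − p_two` terms is weaker, making the healthy-state P mildly
  conservative.
* **Steady states only.** Cyclic attractors of the asynchronous dynamics are
  not classified; the transition graph is exposed for small models if such
  analysis is wanted.
* **No real patient data.** The measured-cohort analysis this package
  operationalizes can only be reproduced in distributional structure, not in
  its patient-level numbers.
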