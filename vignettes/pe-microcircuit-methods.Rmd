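---
title: "Modelling feature-selective prediction-error circuits with pecircuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling feature-selective prediction-error circuits with pecircuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`pecircuit` simulates a layer-2/3-like cortical microcircuit in which
prediction-error (PE) neurons emerge through inhibitory synaptic
plasticity. The network contains 280 excitatory pyramidal cells (PCs) and
three interneuron classes (40 PV, 40 SOM, 40 VIP). PCs are two-compartment
units: a somatic compartment and one apical dendritic branch per stimulus
feature dimension (one branch for 1-D features, two for 2-D). SOM cells
split 7:3 into Martinotti cells, which inhibit PC dendrites, and
non-Martinotti cells, which inhibit PC somata.

The somatic activation variable of PC $i$ follows

$$\tau_E \dot h_i^E = -h_i^E + (I_i - \Theta), \qquad r_i^E = [h_i^E]_+,$$

with rate time constant $\tau_E = 60$ ms and rheobase $\Theta = 14\,
\mathrm{s}^{-1}$. The total somatic current couples the compartments
through leak fractions $\lambda_E = 0.31$ and $\lambda_D = 0.27$:

$$I_i = (1-\lambda_E)\, I^{syn}_{E,i} +
  \sum_k \lambda_D \left[ I^{syn}_{D_k,i} + c_{i,k} \right]_+ ,$$

where the rectification limits how much dendritic input can reach the
soma. Each branch can fire a calcium event $c_{i,k} = c\,H(I^0_{D_k,i} -
\Theta_c)$ with amplitude $c = 7\,\mathrm{s}^{-1}$ and threshold $\Theta_c
= 28\,\mathrm{s}^{-1}$ on the within-dendrite current $I^0_{D_k} =
\lambda_E I^{syn}_E + (1-\lambda_D) I^{syn}_{D_k}$. Interneurons are point
neurons with the analogous single-compartment dynamics and a fast time
constant $\tau_I$ (not constrained by the circuit data; we default to 2 ms
and expose it in `model_params()`; the steady states the analyses use are
independent of its exact value).

Stimuli are abstract feature values. Every PC and SOM cell carries a
Gaussian tuning curve with peak rate 30 Hz; PCs are narrowly tuned
($\sigma_{PC} = 0.8$), SOM cells broadly ($\sigma_{SOM} = 1.0$). The
feature space is $\{0,1,2,3\}$ in 1-D and $\{(0,2),(0,3),(1,2),(1,3)\}$ in
2-D, with preferred values evenly assigned (70 PCs and 10 SOM cells per
value). Bottom-up sensory input $S$ drives PC somata and SOM cells through
their tuning curves and PV cells untuned; top-down predictions $P$ drive
each dendritic branch through the 1-D tuning curve of its feature
dimension and VIP cells untuned. Background inputs ($x_E = 28$, $x_P = x_S
= x_V = 2$, $x_D = 0$ Hz) hold the baseline PC rate near $\rho_E = 1.25$
Hz once the circuit is balanced. An entry of $-1$ in $P$ or $S$ marks an
absent feature dimension: that dimension contributes no tuning term and
the pathway carrying only that dimension receives no drive, which is what
lets the 2-D circuit fall back to 1-D operation.

All training and testing stimuli are jittered by additive Gaussian feature
noise. The source describes the noise scale as
"$\sigma_{noise} = 0.35$" while calling it a variance; because the symbol
convention ($\sigma$) and the magnitude both point to a standard
deviation, the package treats 0.35 as the SD of the feature jitter and
offers `noise_as_variance = TRUE` for the other reading. Noise perturbs
the stimulus value once per phase (it is stimulus noise, not per-neuron
noise).

## Connectivity

Connection probabilities and mean total strengths per pathway are shipped
as editable 5x5 tables (`default_connection_probs()`,
`default_mean_weights()`), indexed by postsynaptic compartment (E soma, D
dendrite, P, S, V) and presynaptic type. The printed source tables are
typographically run together; the parse used here reproduces the printed
digit string exactly and its absent entries coincide with the
zero-probability entries, with one special case: the unit probability
between dendrite and soma describes the within-cell coupling already
expressed by the leak fractions, not a synapse. Each postsynaptic unit
draws its afferents independently with the pathway probability, and each
synapse weight from $U(0.5\bar w, 1.5\bar w)/N_w$ with $N_w$ the realized
afferent count, so expected total input equals $\bar w$ exactly.
Soma-targeting SOM input comes from non-Martinotti cells, dendrite-targeting
input from Martinotti cells; PV and VIP draw SOM input from the whole SOM
population. `perturb_connectivity()` implements the robustness check of
multiplying every weight by $U(1-\delta, 1+\delta)$.

The untuned drive amplitudes to PV (with $S$) and VIP (with $P$) are not
constrained by the circuit tables; both default to the tuned-input peak
(30 Hz) and are exposed as `untuned_amp_pv` / `untuned_amp_vip` in
`assign_preferred_stimuli()`. The consequences of the VIP amplitude for
prediction-phase disinhibition are discussed under "Limitations".

## Steady states: integrator and direct solver

`run_to_steady_state()` integrates the equations with explicit Euler
(default `dt` = 0.1 ms, an order of magnitude below $\tau_I$; the event
order per step is currents, calcium, activation update, rectification,
fixed so runs are bit-reproducible). Convergence is declared when
$\max |\Delta r|/dt$ stays below `steady_tol` ($10^{-4}\,\mathrm{s}^{-2}$)
over a 1 ms window.

Because every analysis and every plasticity update consumes only the
steady state, the package also provides a direct solver
(`method = "newton"`): for a fixed rectification pattern — which units are
above threshold, which dendritic brackets are open, which branches carry a
calcium event — the fixed-point equations are linear, so the solver
alternates between solving that linear system and recomputing the pattern,
and verifies the full nonlinear residual (`newton_tol`, $10^{-8}$ Hz) on
exit. If the pattern iteration does not settle (rare; rectification
boundaries can cycle), the call falls back to Euler integration. The test
suite asserts that both routes agree on the default network to within the
Euler tolerance. The training loop runs entirely in compiled code and
reuses the LU factorization of the pattern system across presentations
(weights drift slowly), with iterative refinement correcting for the
drift.

## Plasticity

Five inhibitory pathways are plastic: PV→soma, non-Martinotti-SOM→soma,
Martinotti-SOM→dendrite (per branch), SOM→PV and VIP→PV, with default
learning rates $10^{-4}$, $10^{-4}$, $10^{-6}$, $10^{-6}$, $10^{-6}$.
The derived error terms are:

* soma: $(r_i^E - \rho_i)\, r_j^{pre}$ — homeostatic inhibitory
  plasticity towards the target rate;
* dendrite: $\big(\lambda_D (r_i^E - \rho_i) + (A^{D_k}_i - \epsilon_i)\big)
  r_j^M$, where $A^{D_k} = I^{syn}_{D_k} + c_k$ is the dendritic activity
  and $\epsilon$ its target;
* PV afferents: $-\big[\sum_k (r_k^E-\rho_k) W^{EP}_{ki}\big] r_j^{pre}$ —
  the PC error backpropagated through the PV→soma weights.

Weights are kept nonnegative through the softplus reparameterization $w =
s^+(v) = \ln(1+e^v)$; `softplus()`/`softplus_inverse()` round-trip to
$10^{-10}$ and $v$ is maintained for every plastic synapse.

**Gradient parameterization.** The update can be applied in two
parameterizations, controlled by `plasticity_params(gradient = ...)`. The
literal gradient-descent form updates $v$ and therefore carries the factor
$\partial w/\partial v = \sigma(v)$. At the network's initialization the
per-synapse weights are $\bar w / N_w \approx 0.01$–$0.07$, where
$\sigma(v) \approx w$, so the literal form multiplies the effective
weight-space step by $w^2 \approx 10^{-4}$–$10^{-2}$: the four SOM- and
VIP-related pathways then move by well under 1% over ten thousand
presentations and the circuit converges to a degenerate state in which
only PV→soma inhibition has adapted, the baseline drifts, and no
prediction-driven suppression appears (we verified this with 3,000- and
15,000-presentation runs). The default, `gradient = "weight"`, therefore
applies the same derived error terms directly to the weight magnitudes
with non-negativity enforced — exactly the form of classic homeostatic
inhibitory plasticity, which is also the biological analog this rule
family descends from. Under this parameterization the stated learning
rates give coherent co-adaptation timescales: the circuit balances within
a few thousand presentations. The literal form remains available as
`gradient = "softplus"` for studying the reparameterized dynamics.

**Why both somatic pathways share a learning rate.** Joint balance at
stimulus and baseline phases is only reachable if some soma-targeting
channel can carry a *feature-tuned, phase-dependent* difference in
inhibition. Every inhibitory channel fires more during a match phase
than at baseline, so the untuned PV pathway alone faces incompatible
demands (we verified that baseline-only and match-only training each
converge to machine precision while joint training stalls at a seesaw
equilibrium around 2 Hz baseline). The tuned non-Martinotti pathway
resolves the conflict, but only if it adapts on a timescale comparable
to the PV pathway — hence `eta_ES = eta_EP = 1e-4` by default. With
`eta_ES` several orders smaller the pathway is effectively frozen and
the circuit never balances; that value remains available as an argument
for studying the degenerate regime.

**Dendritic target $\epsilon$.** The dendritic activity target is measured
once on the untrained network as the rectified dendritic input during a
baseline phase (per neuron and branch); a scalar override (including 0) is
accepted. This anchors "balanced" dendrites at their resting drive.

**Training loop.** One presentation is a noisy match phase ($P = S$ = the
trained feature: 0 in 1-D, (0,2) in 2-D) followed by a baseline phase;
all updates are computed from the frozen steady state of each phase and
applied synchronously (both phases update by default; `update_baseline =
FALSE` restricts updates to stimulus phases). Training runs for
`n_presentations` pairs (default 8000) with early stopping once the mean
somatic error stays below 5% of $\rho$ for 100 consecutive
presentations. The default length is set by the slowest co-adapting
mode: quieting the PV response to matched stimuli through its SOM and
VIP afferents (learning rates $10^{-6}$) takes several thousand pairs;
the baseline rate settles within 10% of $\rho$ from roughly 8,000 pairs
onward and keeps tightening slowly thereafter.

# The measurement layer

* **PE classification** (`classify_pe()`): a PC is a PE neuron when
  $\Delta R/R = (r - r_{BL})/r_{BL}$ exceeds 20% in its corresponding
  mismatch phase and stays within 10% of baseline in the match phase. The
  corresponding mismatch phase is the one whose actual stimulus equals the
  neuron's preferred feature; for neurons preferring the predicted feature
  itself that phase would be the match phase, so the mismatch phase with
  the nearest actual stimulus is used instead.
* **Selectivity coefficient** (`selectivity_coefficient()`): the
  skewness-style statistic
  $\gamma = \langle (m_s - \bar m)^3 \rangle_s / \langle (m_s - \bar m)^2
  \rangle_s^{3/2}$ over the group-mean responses $m_s$ under a given
  prediction, with $|\gamma| > 0.5$ deemed significant; degenerate
  profiles (variance $< 10^{-12}$) return exactly 0. Groups are averaged
  unweighted by default (they are equally sized in the default network);
  count-weighting is available.
* **Similarity** (`similarity()`): in 1-D the tuning-curve ratio
  $f(s_{max}, s_0)/f_{max}$; in 2-D $1 - \mu\!\left((s_{max} -
  s_0)/(\|s_{max}\| + \|s_0\|)\right)$ with $\mu$ the mean absolute
  component and Euclidean norms (the norm is not pinned down by the
  defining text; L1 is available via the obvious one-line change and
  changes none of the qualitative orderings on the default feature
  spaces).
* **Tuning refits** (`fit_tuning_curves()`): per-group nonlinear
  least-squares Gaussian fits across a stimulus sweep, used to verify that
  training does not shift tuning peaks.
* **Mismatch scaling** (`mismatch_scaling()`): feature distance $|S-P|$
  against the mean response of the $S$-preferring group, with a Spearman
  monotonicity verdict.
* **Pathway decomposition** (`grouped_weight_matrix()`,
  `pathway_decomposition()`): the connectivity is collapsed onto the
  homogeneous selectivity groups with inhibitory signs applied, somatic
  leak factors included, and a $-1$ self term per row, so that the linear
  steady state is $r = -W^{-1} S$. The inverse $M$ is split by sign
  (Hadamard masks) and applied to the compartment's input slice, giving
  per-compartment excitatory and inhibitory path sums whose difference
  equals $M_X S_X$ exactly. Dendritic rows enter as algebraic constraints
  (the dendrite is not a dynamical unit), which is what makes the grouped
  matrix invertible and equal to the simulator's fixed point in the linear
  regime — the package tests this equivalence on fully connected
  homogenized networks where group homogeneity is exact.
* **Condition comparison** (`compare_conditions()`): two-sample t and
  Mann-Whitney U tests, both raw (no multiple-comparison correction, as
  in the original two-test report).

# Choices made where the sources are open

* $\tau_I$: unprinted; 2 ms (fast interneuron kinetics), configurable.
* Interneuron drive carries no rheobase (the printed interneuron equation
  has none).
* $H(0) = 0$: a within-dendrite current exactly at $\Theta_c$ does not
  trigger a calcium event.
* Calcium events are per branch; a config flag shares one event across
  branches.
* The somatic drive $(I - \Theta)$ is not rectified inside the dynamics
  (only rates are), matching the printed equation literally.
* Attention acts by scaling the attended dimension's difference term by
  1.2 before the tuning curves of the PC pathways are evaluated,
  narrowing tuning without changing the peak; interneuron drives are not
  gain-modulated.
* Untuned drive amplitudes to PV and VIP default to the tuned peak
  (30 Hz); see "Limitations" for the VIP case.
* Training length is not constrained by the circuit data; the default is
  8000 match/baseline pairs with early stopping.

# Problem sizes used by the test suite

The suite trains the default 280-PC network once per dimensionality
(8000-pair default, about four minutes each with the compiled loop)
and shares the trained fixtures across test files; solver-equivalence
oracles run on 16-PC fully connected toy networks where the linear regime
can be enforced exactly. Property-style tests loop over seeded random
cases.

# Limitations

* The steady-state solver assumes the dynamics settle to a fixed point;
  oscillatory regimes are flagged by the Euler convergence check rather
  than resolved.
* Prediction-only probes are outside the training distribution (training
  only ever pairs `P` with `S`), and the only channels driven by `P`
  alone — the dendritic drive and VIP disinhibition — are net excitatory.
  VIP silences SOM during such probes at any VIP amplitude that still
  lets the VIP→PV pathway learn, so the learned feature-specific
  inhibition is only partially expressed and prediction-only responses
  are dominated by broad disinhibition. Users probing prediction-driven
  suppression should treat `untuned_amp_vip` as a key sensitivity.
* After training, the network is silent under sensory-only probes
  (`P` absent): PV's untuned sensory drive is then uncompensated by the
  VIP activity that accompanied every training stimulus. Tuning curves
  should therefore be measured under the test condition (fixed `P`,
  varying `S`); prediction-driven suppression around the trained feature
  can shift the fitted peaks of those curves.
* The pyramidal cells preferring the predicted feature are suppressed in
  every mismatch phase of a fixed-`P` test set, so the PE classifier's
  fallback (nearest mismatch phase) can never label them PE when the
  trained circuit suppresses them below baseline; the published
  all-cells-PE outcome is not reproduced at the package defaults.
* The synthetic stimuli are abstract scalar features with Gaussian
  tuning; none of the receptive-field structure, adaptation or
  correlated noise of real V1 responses is represented, so passing tests
  demonstrate internal consistency of the circuit mechanism, not fidelity
  to recorded data.
* Training presents a single match feature (0 or (0,2)); generalization
  claims concern the tuning-curve geometry, not a trained repertoire of
  predictions.
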