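---
title: "Personalized brain-network models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalized brain-network models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`conndyn` links individual differences in structural brain connectivity to
individual differences in behavior through a dynamical network model. This
vignette explains the model, the derived features, the statistical layer,
the synthetic cohort generator, and the design decisions that were genuinely
open — with the reasoning behind each.

## The dynamical model

Each brain region `i` of a parcellation carries a Wilson–Cowan neural-mass
unit: a fraction of active excitatory neurons $E_i(t)$ and of inhibitory
neurons $I_i(t)$,

$$\tau \dot E_i = -E_i + (S_E^{max} - E_i)\, S_E\!\big(c_1 E_i - c_2 I_i +
c_5 \textstyle\sum_j A_{ij} E_j(t - \tau_{ij}) + P_i(t)\big) + \sigma w_i(t),$$

$$\tau \dot I_i = -I_i + (S_I^{max} - I_i)\, S_I\!\big(c_3 E_i - c_4 I_i +
c_6 \textstyle\sum_j A_{ij} I_j(t - \tau_{ij})\big) + \sigma v_i(t),$$

with the shifted sigmoid
$S(x) = 1/(1+e^{-a(x-\theta)}) - 1/(1+e^{a\theta})$, which satisfies
$S(0)=0$ so that the origin is an equilibrium of the uncoupled system.
$A$ is the subject's weighted structural connectome (symmetric, zero
diagonal, nonnegative), $c_5$ the global excitatory coupling with
$c_6 = c_5/4$, and $\tau_{ij} = d_{ij}/t_d$ the conduction delay over the
Euclidean centroid distance $d_{ij}$ at $t_d = 10$ mm/ms. The constants are
the standard biologically derived set: $c_1=16$, $c_2=12$, $c_3=15$,
$c_4=3$, $a_E=1.3$, $a_I=2$, $\theta_E=4$, $\theta_I=3.7$, $\tau=8$ ms,
$\sigma=10^{-5}$.

Because every unit is identical, all subject differences in simulated
dynamics are caused by the subject's $A$ (and the geometry entering the
delays). That is the core logic of the personalization.

### Time units and integration

The equations are integrated with a stochastic midpoint (second-order
Runge–Kutta) scheme at step $h = 0.1$ ms from $E_i(0)=I_i(0)=0.1$, with the
first second discarded as stabilization. Milliseconds are the only unit
consistent with $\tau = 8$ and delays in mm over mm/ms, so $h=0.1$ is read
as 0.1 ms. Numerical choices:

* **Delay discretization.** Delays are rounded to integer steps
  ($\mathrm{round}(\tau_{ij}/h)$); delays under half a step become
  zero-lag coupling. The midpoint stage evaluates delayed state by linear
  interpolation between stored grid points, and uses the midpoint state
  itself for zero-delay edges; the scheme shows observed order ≥ 1.8 on
  smooth trajectories (tested).
* **Noise.** The model writes additive noise inside the differential
  equation without an SDE discretization; we add one $\sigma\,N(0,1)$
  increment per state variable per step after the deterministic update.
  At $\sigma=10^{-5}$ the distinction between this and a stage-wise or
  $\sqrt{h}$-scaled scheme is far below every tolerance used anywhere in
  the package; the choice is recorded here rather than hidden.
* **Histories.** The pre-$t=0$ history required by the delays is filled
  with the initial condition.
* **Guard.** States beyond $|x|>10$ abort with the offending step; the
  sigmoid bounds make this unreachable except under pathological inputs.

## Excitability: the transition value c5T

Sweeping $c_5$ upward (conventionally 0.05–0.25 in steps of 0.001; tests
and examples use 0.005 to trade resolution for runtime) with $P=0$, the
time- and region-averaged excitatory activity stays near zero until, at a
subject-specific coupling, the network jumps to a high-amplitude
oscillatory state. `detect_transition()` reads the curve's largest forward
difference, requires it to exceed `jump_factor` (default 5) times the
median absolute forward difference, and reports the grid value at the
*left edge* of the jump — the largest coupling before the excited state.
Ties break toward smaller $c_5$, and detection is invariant to affine
rescaling of the activity axis. Two open points were decided as follows:

* Whether c5T is the last sub-threshold or first supra-threshold grid
  point is not determined by the phenomenon; we use the left edge so that
  "just below c5T" (the stimulation operating point, one grid step lower)
  is guaranteed quiescent.
* In networks containing a planted, strongly coupled subcircuit the sweep
  can show *two* jumps — the circuit igniting before the bulk. For the
  global excitability feature the largest jump is the transition
  (`rule = "largest"`); for positioning the stimulation experiment the
  package offers `rule = "first"`, the onset of any ignition, because the
  protocol requires the whole network to be quiescent at the stimulation
  coupling. For homogeneous networks the two rules coincide.

## Stimulation, functional connectivity, functional effect

The in-silico stimulation protocol fixes $c_5$ one sweep-grid step below
c5T (maximal sensitivity without crossing), stabilizes for 1 s, runs 1 s
with no input, then applies a constant $P_i = 1.15$ — enough to push a
unit into a limit cycle — to the 4-region target set for 1 s. Functional
connectivity within each 1 s segment is the *signed maximum* over integer
lags within ±250 ms of the Pearson correlation between two regions'
excitatory traces, computed on overlapping samples without padding.
The change ΔFC = FC(during) − FC(pre) is summarized as the functional
effect: its mean over all unordered off-diagonal pairs (global), pairs
with both endpoints in a task circuit (within), or both outside
(outside). Decisions:

* "Maximum normalized cross-correlation" is taken as the signed maximum,
  not the maximum absolute value; anticorrelation only wins when no
  positive-lag correlation exceeds it.
* Cross pairs (one endpoint in the circuit, one outside) enter neither
  restricted scope, because the protocol assigns them to neither.
* FC is sampled at a 1 ms stride (configurable, recorded in the output):
  the integration grid oversamples the ~tens-of-ms oscillation by two
  orders of magnitude, and the stride reduces the lag scan cost by 100×
  with no measurable change in the matrix.
* Constant signals make a correlation undefined; such pairs are `NA` and
  are excluded from effects rather than zero-filled.

## Network statistics

Weighted degree $k_i = \sum_j A_{ij}$, spectral radius
$\lambda_{max}(A)$ (with its inverse), and synchronizability
$\lambda_2(L)/\lambda_{max}(L)$ for $L = D - A$, all via the dense
symmetric eigensolver — connectomes here are a few hundred regions at
most. A disconnected graph has $\lambda_2 = 0$ and synchronizability 0.

## Statistical layer

Associations between any per-subject feature and median response times are
Pearson correlations with a two-sided p-value from the standard t
reference (the protocol does not state the reference distribution; the t
test is the conventional choice at small n), a 90% CI from the 0.05/0.95
quantiles of 5000 pair-resampling bootstrap replicates (degenerate
resamples are redrawn), and Benjamini–Hochberg FDR across the task family
within each feature and condition. Randomization controls:

* **Edge-weight shuffling** permutes the full upper triangle (zeros
  included) — the connectivity distribution is preserved exactly,
  topology is not.
* **Random subnetworks** re-average the already computed ΔFC matrices
  over uniformly drawn region subsets of the circuit's size (22 for the
  number-reading circuit) and count draws meeting r > 0.5, p < 0.05.
* **Alternate stimulation sites** are spatially contiguous 4-region
  groups inside the circuit, contiguity defined by a symmetric
  3-nearest-neighbor graph on centroids (the protocol gives no adjacency
  definition; k-NN is scale-free in the centroid units), enumerated
  exhaustively and run through the full stimulation pipeline.

## The synthetic cohort generator

No imaging or behavioral data ship with the package; a generator produces
cohorts with the statistical structure the analysis assumes, and it is the
basis of every end-to-end test. What it emulates, and what it does not:

* **Weights** are log-normal (heavy-tailed, nonnegative), qualitatively
  matching volume-normalized streamline densities; no attempt is made to
  match an empirical DSI weight distribution quantitatively.
* **Geometry**: two Gaussian centroid clouds separated along one axis by
  half the 140 mm extent give hemisphere-like structure and heterogeneous
  conduction delays; region volumes are uniform on 500–8000 mm³. The
  atlas (labels, centroids, volumes) is shared across subjects.
* **Sparsity and normalization.** Background density defaults to 0.08,
  and every subject's matrix is rescaled to a common mean weighted degree
  (85). The fixed total strength mirrors deterministic tractography that
  reconstructs a fixed streamline count per subject: individuals differ
  in how connectivity is *organized*, not in how much they have. This is
  also what makes the shuffling control meaningful. In this model the
  ignition transition is mean-field dominated: c5T tracks total coupling,
  which shuffling conserves; in a dense homogeneous ensemble shuffled
  c5T would correlate ≈ 0.99 with the original and no randomization
  control could ever "destroy" an association. Sparse, heavy-tailed,
  hemispherically modular networks place the dynamics in a regime where
  edge placement matters, so c5T is stable under simulation noise yet
  re-randomizes under weight shuffling — the behavior the control logic
  presumes of real brains.
* **Scale calibration.** The mean weighted degree of 85 places the
  transition near $c_5 \approx 0.1$, inside the conventional 0.05–0.25
  sweep window (empirical matrices carry their own scale from the data; a
  synthetic ensemble must choose one).
* **Planted circuit**: an optional label set whose internal pairs get a
  higher edge density (e.g. 0.5) and a weight bonus (e.g. 3), planting a
  densely connected, strongly coupled subnetwork for circuit-specificity
  experiments.
* **Behavior**: response times are affine in the z-scored driving feature
  (600 ms intercept, 50 ms/SD slope, 15 ms noise — a plausible
  language-task scale), or independent noise for null cohorts. Z-scoring
  keeps the slope's units stable across feature types.

Passing tests on these cohorts demonstrate that the pipeline recovers
planted structure under the stated noise — not that real DSI cohorts
satisfy the generator's assumptions (iid log-normal weights, shared
atlas, two clean hemispheres, a single planted circuit).

## Problem sizes in the shipped tests

The test suite and the acceptance script use 50-region networks, sweeps at
grid step 0.005 with 1 s windows, cohorts of 10–12 subjects, 500–5000
bootstrap resamples, and 500 subnetwork draws — sizes chosen so a full run
completes in minutes on one core while every phenomenon (abrupt
transition, noise-stable c5T, planted-signal recovery, shuffle
destruction, circuit specificity, near-nominal CI coverage) is exercised
end to end at the conventional parcellation scale the defaults emulate.

## Known limitations

* The integrator is fixed-step; no adaptive error control. With the
  bounded sigmoid dynamics and $h = 0.1$ ms this is comfortably inside
  the stability region, but stiff parameter variants are untested.
* c5T is quantized to the sweep grid; features inherit that granularity.
* The generator does not model cortical geometry, distance-dependent
  connection probability, or measurement noise in tractography.
* FC is defined on the model's excitatory traces; it is not an estimator
  for empirical BOLD/EEG functional connectivity.
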