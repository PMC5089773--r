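---
title: "Laminar neural mass modelling and information-theoretic cross-frequency coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Laminar neural mass modelling and information-theoretic cross-frequency coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(laminarpac)
```

## The model

`laminarpac` simulates a cortical column as a network of neural mass
oscillators. Each of 14 neuronal populations (regular-spiking RS and
intrinsically bursting IB excitatory cells, low-threshold-spiking LTS and
fast-spiking FS interneurons, distributed over layers 2/3, 4, 5, 6; layer 1
has no somata and is omitted) is described by its mean postsynaptic
potential (PSP) $x_m$ (mV). Two operations define the dynamics:

* a static sigmoid converts PSP into mean firing rate,
  $S(x) = e_0 / (1 + e^{r (v_0 - x)})$, with maximal rate $e_0$ (1/s),
  half-maximum PSP $v_0$ (mV) and steepness $r$ (1/mV);
* a linear synaptic kernel $h(t) = G\,g\,t\,e^{-g t}$ converts presynaptic
  rate into PSP, with gain $G$ (mV) and reciprocal lumped time constant $g$
  (1/s).

Converting the convolution into a differential operator and adding a
dimensionless damping parameter $b_m$ gives, per population,

$$\ddot x_m = -2 g_m b_m \dot x_m - g_m^2 x_m +
  G_m g_m \Big(p_m + \sum_n \Gamma_{nm} S(x_n)\Big),$$

a system of 14 second-order (28 first-order) random differential equations.
$\Gamma_{nm}$ is the signed effective connectivity from population $n$ to
$m$ (inhibitory sources have non-positive rows), and $p_m$ is the external
input rate, nonzero only for the layer-4 RS and FS populations. With
$b_m < 1$ an isolated population is an underdamped resonator ringing at
$g_m \sqrt{1 - b_m^2} / 2\pi$ Hz; $b_m = 1$ recovers the classical
critically damped population model in which only network loops oscillate.
The only nonlinearity is the sigmoid, so every cross-frequency interaction
in the simulated signals is attributable to it.

### Default parameters

The canonical parameter tables for this architecture are not part of the
distributed text, so the shipped defaults are approximate reconstructions,
clearly overridable through the model-file interface
(`read_model_file()`, a JSON/YAML record plus an optional connectivity
CSV). The choices, made once and documented here:

* **Natural frequencies.** Reciprocal time constants are solved so every
  isolated population rings at the published natural frequency (L2RS
  8.25 Hz ... L6FS 44.76 Hz), which also fixes the class ordering of time
  constants (FS fastest, then IB, RS, LTS). Shared damping $b = 0.2$.
* **Sigmoid.** $e_0 = 5$ 1/s, $v_0 = 6$ mV, $r = 0.56$ 1/mV for every
  population (the standard neural-mass values), with per-population
  override available.
* **Connectivity.** Within-layer RS→FS/LTS excitation with FS/LTS→RS
  feedback inhibition, IB participation in L2/3 and L5, the canonical
  interlaminar chain L4→L2/3→L5→L6→L4, and a single anatomical FS
  self-connection in L4. The global weight scale is set just above the
  network's oscillation threshold: strong enough that rhythms are
  sustained, weak enough that PSP excursions stay inside the sigmoid's
  sensitive range.
* **Inputs.** Mean drive 60 / 80 1/s with noise SD 10 1/s to L4RS / L4FS;
  all other populations are driven only through the network, as the
  architecture prescribes.

### The three-population chain

The control experiment uses three generic excitatory populations:
population 2 oscillates in the theta band and drives populations 1 and 3,
which ring in the gamma band; there is no 1–3 connection. Designing this
chain exposed a mechanism worth recording: a noise-driven resonator's
envelope can only follow a modulating drive if its linewidth ($\approx 2 g
b$) exceeds the drive frequency, while its oscillation amplitude grows with
the compensated self-feedback gain. The shipped chain therefore gives the
slow population compensated positive self-feedback (design frequency 3 Hz,
effective peak near 4.4 Hz once the feedback softening is accounted for)
and places the fast populations below the sigmoid inflection
($x_{op} = 3.5$ mV) with moderate self-feedback, so the strong slow drive
sweeps their operating point through the curved region of the sigmoid and
modulates their effective gain — a parametric route from slow phase to fast
amplitude. External inputs are solved so the prescribed operating points
are exact fixed points. For this parameter set, noise SD 5 1/s is the
moderate regime, 10 the elevated regime of the noisy control, and by
~100 1/s the slow rhythm disintegrates and every coupling measure loses
significance (the destructive level quoted in the original control is not
transferable because the remaining parameters differ).

In the linear control variant the sigmoid is replaced by a linear function;
the connection weights are then rescaled by the sigmoid slope at each
source's operating point so that the linearized system keeps the same
resonances. Without the nonlinearity the simulated spectra contain no
sidebands and no coupling measure reaches significance.

## Numerical integration

The 28-equation system is integrated at a fixed step (default
$10^{-4}$ s) with noise held constant within each step — the
random-differential-equation convention for band-limited physiological
input, not an Itô interpretation. The default scheme is local
linearization: each step propagates the drift linearized at the current
state exactly, via the exponential of the augmented Jacobian matrix
$[[J, f], [0, 0]]$. The scheme is exact on linear systems (verified to
machine precision against the closed-form matrix exponential) and shows
second-order self-convergence on nonlinear ones; an explicit Euler variant
is provided as an independent cross-check, and the two agree to
correlation > 0.999 at the default step. Initial conditions default to the
noise-free uncoupled fixed point; a burn-in span (default 2 s) is
discarded. Ill-conditioned linearizations fall back to an Euler update with
a warning; divergence beyond a configurable PSP bound aborts with a
diagnostic.

## Signal analysis

Simulated PSPs are filtered into delta (0.1–4 Hz), theta (4–8), alpha
(8–12), beta (12–30) and gamma (30–120) bands with linear-phase FIR filters
applied forward and backward (zero net phase shift). The filter is a
windowed design with default order six cycles of the band's low edge —
long enough that the transition band stays well inside the band — capped so
the series remains longer than three filter orders; filter-order samples
are discarded at each end. Instantaneous amplitude and phase come from the
FFT-based analytic signal; amplitudes are z-normalized per band and
channel so bands are comparable. The 0.1 Hz delta edge requires
impractically long filters on short desk-scale runs, so the experiment
drivers raise it to 0.5 Hz; full-scale analyses keep 0.1 Hz. Because
content below 120 Hz is heavily oversampled at the native $10^4$ Hz rate,
the decomposition can decimate first (`downsample_to`; the desk presets use
1000 Hz). Layer local field potentials are the sums of each layer's
excitatory PSPs.

## Coupling estimators

The modulation index $\mathrm{Midx} = |\sum_t a(t) e^{i\varphi(t)}|$ and
envelope-to-signal correlation
$\mathrm{ESC} = \mathrm{corr}(\cos\varphi, a)$ are the pairwise references
(the un-normalized Midx sum is the default; a length-normalized variant is
available but off). The central estimators are discrete, histogram-based:
phases are binned uniformly on $[-\pi, \pi)$ (circular), amplitudes and
instantaneous frequencies into equiprobable rank bins (robust to heavy
tails), default 8 bins (4 in the desk presets, where series are shorter).
Conditional mutual information is computed through the chain rule
$I(X; Y \mid M) = I(X; (Y, M)) - I(X; M)$, so identities between sums of
MI terms hold exactly for the plug-in estimates. The conditional transfer
entropy averages the cMI between the source now and the target shifted
$\delta$ samples into the future over $\delta = s \cdot (1 \dots N)$,
conditioned on the target's own series and any exogenous conditioning
series.

Two numerical choices deserve emphasis:

* **Lag stride.** Band-limited signals at 1000 Hz are smooth: one sample
  ahead, a narrowband phase is almost deterministic given its binned past,
  and the residual within-bin information lets *any* contemporaneously
  correlated series masquerade as a driver. Stretching the lag unit (desk
  default 20 ms, horizon $10 \times 20$ ms = 200 ms) pushes the prediction
  horizon beyond the target's deterministic continuation, restoring
  directionality: on planted-coupling fixtures the genuine direction stays
  strongly significant while the reverse direction drops to chance. At the
  native $10^{-4}$ s step with $N = 100$ single-sample lags the horizon is
  10 ms (the `paper` preset).
* **Conditioning.** Conditioning on *all* phases and amplitudes of all
  populations (the full multivariate intent) is infeasible for histogram
  estimators — the joint alphabet dwarfs any realistic sample count, and
  every estimate collapses toward zero. The implemented policies are
  `none`, `target_past` (default), `others` (target past plus the other
  channels' source-band series), `custom`, a user function, and `all`
  (available, with an undersampling warning). A Frenzel–Pompe
  nearest-neighbour cMI estimator (`knn_cmi()`) is provided as the
  continuous-backend alternative for low-dimensional conditioning.

Surrogate significance applies an independent random circular offset —
uniform over the middle 10–90% of the series — to the *target* series and
recomputes the statistic (1000 surrogates at full scale, 200 desk). Offsetting
the target rather than the source preserves both the source–conditioning
dependence and the target's own autostructure in the null, so the surrogate
distribution shares the plug-in estimator's finite-sample bias; offsetting
the source instead produces strongly negative z-scores whenever source and
conditioning are dependent. z-scores use the surrogate mean and SD,
p-values are two-sided Gaussian, $|Z| > 1.96$ marks 5% significance, and a
Benjamini–Hochberg mask over all simultaneously tested entries controls the
false discovery rate. Negative plug-in values are clipped to zero in the
reported matrices with a count, never silently. Calibration on independent
white-noise pairs reproduces the nominal level provided the series are long
relative to the bands' coherence times (the acceptance computation uses
25 s pairs; much shorter series leave the circular-shift null slightly
narrower than the observed statistic's sampling spread and the test runs
anticonservative by a few points).

### A structural limitation of the chain control

In the three-population chain the theta content of populations 1 and 3 is
the filtered common drive: with white external noise, their theta phases
are nearly noiseless copies of the driver's phase (cosine-phase correlation
> 0.95 across the tested regimes whenever the modulation is detectable at
all). An estimator conditioned on the remaining populations therefore faces
copies of the same information: at coarse conditioning resolution the
spurious 1→3 link survives (the copy carries the driver's within-bin
detail), and at fine resolution the genuine 2→1 and 2→3 links are explained
away along with it. Separating the two would need conditioning resolution
on the order of the copy noise (hundreds of phase bins), far beyond what
the sample sizes support. The package therefore documents both regimes; the
acceptance suite asserts the architecture-recovery property as specified
and reports its outcome honestly. The pairwise measures behave exactly as
expected: Midx and ESC report the spurious symmetric 1↔3 coupling, and at
destructive noise every measure goes silent.

## Indirect couplings and cascades

For a chain $y_1 \to y_2 \to y_3$ the lag-averaged conditional transfer
entropy of the indirect link decomposes exactly:
$\mathrm{cTE}(y_1 \rightsquigarrow y_3) = \mathrm{cTE}(y_1 \to y_2) +
\mathrm{cTE}(y_2 \to y_3) + \tilde I$, with $\tilde I$ a combination of six
MI terms. Because all terms are plug-in estimates on a shared
discretization and common per-lag windows, the identity holds to machine
precision for *any* inputs — it is the module's primary regression test.
The cascade study sweeps the two connection strengths of a
theta→(delta|beta)→gamma chain, computes 16 surrogate-masked coupling
predictors (PAC/APC/AAC/PPC and same-frequency terms through the relay),
and fits ten regression models for the indirect response
(`cascade_models()`), reporting $R^2$ per slice of the second connection
strength — free coefficients with intercept, matching a linear-regression
reading of the model sums. Phase→frequency (PFC) couplings are computable
but excluded from the default model set, which mirrors their reported
weakness as predictors.

The nonlinear correlation $r_{nl}$ fits a $K = 10$-term Fourier series
$\hat Y(X) = a_0 + \sum_k a_k \sin(b_k X + c_k)$ by profiled least squares
(the amplitudes/phases solved linearly for each candidate frequency
vector, the frequencies optimized by multi-start Nelder–Mead, 20 seeded
restarts) and reports $|\mathrm{corr}(Y, \hat Y)|$ with shuffle-surrogate
significance at matched fitting effort.

## Topology

Local weighted-digraph measures operate on $W = |\Gamma|$ with self-loops
removed: the directed weighted clustering coefficient (one-third-power
weights, binary total degree and reciprocated-pair correction), local
efficiency (mean inverse shortest weighted out-path length), and
betweenness centrality (fraction of shortest paths through the node,
normalized by $(N-1)(N-2)$). Shortest path lengths use the standard
connectivity-toolbox mapping length $= 1/$weight; tied path multiplicities
are counted exactly with ties merged at $10^{-12}$ relative tolerance. All
three implementations are validated against exhaustive path-enumeration
oracles on a thousand random digraphs with up to six nodes. Significant
coupling entries are classified direct (backed by a nonzero anatomical
entry) or indirect, and role statistics aggregate the endpoint nodes'
metrics with two-sample t-tests.

## Problem sizes and what the synthetic tests show

The desk presets (22 s simulations analysed at 1000 Hz, 200 surrogates,
10 lags of 20 ms, 4 bins) keep each experiment in minutes; the `paper`
presets restore 1000 surrogates, 100 single-sample lags and the native
rate. The generators emulate narrowband stochastic rhythms with planted,
optionally delayed, phase–amplitude modulation and exactly-sampled discrete
joints; they do not emulate measurement artifacts, nonstationarity,
volume conduction, or 1/f backgrounds, so passing tests demonstrate
estimator correctness and calibration on stationary band-limited signals,
not robustness to the full pathology of recorded electrophysiology.

## Known limitations

* Parameter values are approximate reconstructions; analyses that depend on
  the exact canonical tables require supplying them via the model-file
  interface.
* Histogram cMI with high-dimensional conditioning is undersampled; the
  k-NN backend is quadratic in series length.
* The chain-control copy problem above: phase-based conditioning cannot
  separate a perfect copy from its source at feasible resolutions.
* Circular-shift surrogates assume approximate stationarity and series
  much longer than the slowest band's coherence time.
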