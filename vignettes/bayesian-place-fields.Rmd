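---
title: "Predicting place-field sizes by Bayesian cue integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting place-field sizes by Bayesian cue integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(placefuse)
```

## The model

A navigating animal must estimate its own position from noisy evidence.
`placefuse` treats a hippocampal place field as the read-out of that
estimate: the field's centre is the animal's best-guess location and the
field's size is the uncertainty attached to it. The estimate itself is the
Bayesian combination of

* a **prior** from path integration (grid-cell input), a Gaussian with
  precision `alpha` (cm^-2^), and
* one **observation per boundary or object** (border-cell input): a Gaussian
  along the direction of that cue whose standard deviation grows linearly
  with the distance `d` being judged, `sigma_o = gamma * d` (Weber's law).
  `gamma` is dimensionless; its reciprocal square `beta = 1 / gamma^2` is the
  observation precision factor, and the two are stored together and kept
  consistent (`cue_params()`).

Under Gaussian assumptions the posterior is again Gaussian: precisions add,
and the mean is the precision-weighted mean of the inputs (`fuse_1d()`). In
one dimension the posterior standard deviation given distances `d_j` and a
subset indicator `delta_j` is

    sigma = (alpha + beta * sum_j delta_j / d_j^2)^(-1/2)

(`posterior_sigma()`). In two dimensions each directed observation
contributes `n_j n_j^T / (gamma d_j)^2` to the precision matrix
(`posterior_covariance_2d()`); for the rectangular boxes used here the wall
normals are orthogonal, so the 2D result is exactly two independent 1D
fusions, which is how `rect_track_size()` computes its per-axis sigmas.

`alpha` defaults to 0 throughout: the recordings these analyses emulate come
from distal CA1, which receives predominantly sensory (lateral
entorhinal/subicular) rather than path-integration input, so the prior term
is taken as negligible and `gamma` is the model's single fitted parameter.

## Environments and size dialects

Three geometries cover the emulated experiments:

* **Rectangular track / open boxes** (`rect_env()`): origin at the
  south-west corner, x eastward, y northward, all units cm. The four walls
  are the observations. On the narrow track, field size is an *area-like*
  quantity, the product `sigma_x * sigma_y`, matching sizes measured as
  suprathreshold bin counts (`segment_fields()` uses a 20 %-of-peak
  criterion; the threshold is configurable because the original area
  criterion is not recorded). The linear-track dimensions are package
  defaults (180 x 10 cm), chosen as a typical narrow track; they are not
  values taken from the source recordings.
* **Circular track with objects** (`circular_track()`): arc-length
  coordinate measured counter-clockwise from the barrier along the track
  midline (the printed 106.7 cm diameter is treated as the midline diameter
  of the 15 cm-wide annulus). The barrier blocks passage, so all distances
  are path lengths that never wrap across it, and the barrier's own distance
  is the minimum over its two faces. Here field size is the *standard
  deviation of spike positions* (`field_from_spikes()`, population
  estimator), directly comparable to the model sigma. The two size dialects
  are never mixed in one table.
* Observation order for masks is always: objects in their stored order, then
  the barrier last.

## Fitting

`fit_gamma()` minimizes the sum of squared differences between predicted and
observed sizes. Because the model has a single scalar parameter, coordinate
descent degenerates to a line search: we use golden-section search (with
parabolic refinement, via `stats::optimize`) on `gamma` in `[1e-4, 10]` with
tolerance 1e-8, which is deterministic and recovers noiseless synthetic data
to better than one part in 10^6^. With `alpha = 0` the track prediction is
proportional to `gamma`, so the objective is convex in the search range.

For the rectangular track, `fit_gamma_rect()` additionally reports the two
bound curves — the model evaluated along a trajectory hugging a side wall
(default offset one 1.9 cm bin) and along the track midline — and the
fraction of observed sizes falling between them, the coverage summary used
for that dataset. The near-wall offset is configurable; coverage grows
monotonically as the bounds separate, which the tests check.

`fit_subset()` implements the subset-extended model: each of the `N`
observations (8 objects + barrier = 9 on the standard track) carries a
binary indicator, and all `2^N - 1` non-empty masks are scored
exhaustively (guarded at `N <= 20`). Both the predicted profile and the
observed sizes are z-scored before comparison; with `alpha = 0` the z-scored
profile shape does not depend on `gamma`, so the enumeration needs no inner
optimization. The score is `R^2 = 1 - SS_err / SS_tot`; the adjusted value
uses `p = N + 1` parameters (the indicators plus the Weber factor).

Rate maps are fitted with a separable 2D Gaussian by Levenberg–Marquardt
least squares (`fit_gaussian_ratemap()`, via `minpack.lm`), started from
rate-weighted moments, optionally with a uniform baseline term.
`cross_env_predict()` runs the transfer analysis: per-field Gaussians are
fitted in two source boxes; a per-field `gamma` is derived from each fitted
sigma and its wall distances (`alpha = 0`) and averaged; the centroid is
relocated to the target box by preserving its relative position (x/L, y/W) —
the natural reading of "appropriately scaled distance relations"; target
sigmas follow from the target walls; and the rendered Gaussian's amplitude
is set by least squares against the observed map, since amplitude reflects
non-spatial factors (running speed, excitability) outside the model. The
per-field prediction R^2^ is compared with the best achievable Gaussian fit
of the observed map by a paired t-test. Fields whose rate-weighted marginal
skewness exceeds 1.0 on either axis are excluded as asymmetric before
Gaussian fitting (threshold configurable).

`residual_tests()` computes the statistic set reported for the track
analyses: Pearson correlation between model and data with its p-value, and
chi-square goodness-of-fit tests of the data and of the residuals against a
fitted normal. The GOF test uses equal-probability bins,
`k = max(8, floor(n/5))`, with `k - 3` degrees of freedom because two normal
parameters are estimated from the data; `stats::chisq.test` does not make
that correction, which is why the binning is implemented here.

## The spiking implementation

The same inference is demonstrated in a spiking network: a current-based
leaky integrate-and-fire place cell (`simulate_place_cell()`, Euler
integration in compiled code) receives Gaussian-tuned non-homogeneous
Poisson inputs — a wide "grid-cell" prior and a narrow "border-cell"
observation — while the animal sweeps a 100 cm track at 20 cm/s. Because
multiplication of firing-rate profiles is what Bayes' rule requires, the
cell must fire only on *coincident* input spikes. The coincidence window is
approximated from the membrane fluctuation, membrane time constant and PSP
amplitude as `delta_t = sigma_V * tau_m / A` (`temporal_resolution()`);
with in-vivo-like CA1 values (sigma_V ~2 mV, tau_m ~20-30 ms, A just under
the ~16 mV rest-to-threshold gap) this gives a few milliseconds, the same
order as the 5–10 ms window measured in vitro.

Whether an integrate-and-fire neuron actually detects coincidences rather
than integrating is a quantitative matter, and the package's defaults are
chosen to satisfy two explicit inequalities:

1. a single PSP peaks several noise-sd below threshold
   (`v_thresh - v_rest - A >= 6 sigma_V`), so one input alone almost never
   fires the cell;
2. the steady-state summation ceiling of one input train,
   `A / (1 - exp(-R / tau_m))` for inter-spike intervals at least `R`, stays
   at least 3.5 noise-sd below threshold, so a lone input cannot climb to
   threshold by temporal summation either.

The second inequality is why input trains carry an absolute refractory
period (default `R` = 15 ms) — it also matches the binary per-window
semantics of the coincidence rule, under which an input cannot register
twice within one window. The resulting defaults are `tau_m` = 10 ms (the
effective in-vivo membrane constant under synaptic bombardment is shorter
than the in-vitro one), threshold −56 mV, PSP amplitude 8 mV, noise sd 1 mV.
Without these constraints the neuron drifts into the addition regime: the
output field centres on the amplitude-weighted average of the inputs instead
of the precision-weighted product mean. That failure mode is exactly what
`error_surface()` maps over membrane time constants and thresholds, and what
the near-rest-threshold comparison in the tests exhibits.

The output field is read out by mapping output spikes to trajectory
positions and taking the mean and standard deviation of the noise-filtered
positions — iterative trimming of points beyond 3 standard deviations, at
most 5 passes (`posterior_from_spikes()`); the trimming rule is this
package's concrete choice for "noise-filtered". With the default inputs
(narrow field at 40 cm, sigma 5, peak 50 Hz; wide field at 60 cm, sigma 10,
peak 25 Hz — equal total mass, so the narrow field is the taller, as a
probability-like population code implies) the exact product mean is 44 cm;
the simulated cell lands within a couple of cm of it, strictly between the
input centres and nearer the narrow input, with a field no wider than the
narrower input — Gaussian-product shrinkage expressed in spikes. Its peak
rate (~2.5 Hz) falls inside the 1–10 Hz range reported for CA1 place cells.
`path_probability()` turns the same spike train into interval probabilities
by treating spike-bearing coincidence windows as posterior samples; by
construction these probabilities are additive and sum to one over a
partition.

## Synthetic data

No recordings are deposited for the three emulated experiments, so
`gen_linear_track()`, `gen_circular_track()` and `gen_openfield()` generate
datasets with the statistical structure the analyses assume: centroids
uniform over the environment, sizes on the model surface, multiplicative
lognormal size noise (sizes are positive and their spread grows with
magnitude; the cv is the `noise_cv` parameter), Gaussian spike positions
around each centroid, Poisson count noise on rate maps under uniform
occupancy, and optional two-field cells (`multi_field_prob`). The eight
object positions on the synthetic circular track are fixed constants
(`default_object_arcs()`) so every dataset is reproducible; all generators
are byte-identical across runs with the same seed.

Default study conditions: `gamma_true = 0.1` on the tracks (giving
field sizes of a few cm, comparable to the spike-position-std sizes
reported there) and 0.3 in the open boxes (fields tens of cm across, well
resolved by 1.9 cm bins); 100 cells; `noise_cv = 0.1` for noisy runs.

What passing tests on these data do show: the estimator recovers the
generating parameters (gamma exactly at zero noise; within 10 % in at least
95 % of 100 replicates at cv 0.1, n = 100 fields; the generating mask
exactly at zero noise), and every pipeline stage closes end to end. What
they do not show: anything about deviations of real place fields from the
model — theta modulation, speed-dependent rates, asymmetric fields,
non-uniform occupancy and behavioural sampling bias are all absent from the
generators, deliberately. Printed in-vivo fit statistics are therefore not
reproduced here.

## Numerical choices and degenerate inputs

* Positions exactly at an object have zero predicted uncertainty;
  `posterior_sigma()` returns 0 with a `degenerate` flag rather than
  erroring, and profile code clips at a floor of 1e-6 cm so curves can be
  z-scored. The floor is why z-scored profile shapes are gamma-invariant
  only to ~1e-6 at object-adjacent grid points.
* `moving_average()` centres its window, extending `floor((w-1)/2)` left and
  `ceiling((w-1)/2)` right (even windows lean right); circular series wrap,
  linear series shrink the window at the edges.
* Standard deviations use the population (divide-by-n) estimator throughout,
  both in `field_from_spikes()` and in `zscore()`.
* LIF integration uses dt = 0.1 ms (rejected above `tau_s / 2`); spike
  reset is to `v_reset` with an absolute refractory of one coincidence
  window, so a window yields at most one output spike.
* Per-repetition seeds are derived deterministically from a master seed and
  kept below 2^31.

Problem sizes used by the test-suite and the acceptance script — 100
replicates of 100 fields for recovery, 30 repetitions of 60 s simulations
for the spiking read-outs, 511-mask enumerations — were chosen so the whole
suite runs in a few minutes on one CPU while keeping Monte-Carlo standard
errors well inside the asserted tolerances.

## Known limitations

* Gaussian fields only; skewed fields are excluded, not modelled.
* The 2D covariance machinery is exercised with axis-aligned and oblique
  normals, but no environment type with non-orthogonal walls is provided.
* The subset search is exhaustive and intentionally capped at 20
  observations.
* The spiking model is a single output neuron with two inputs; populations,
  learning, conductance-based synapses and theta dynamics are out of scope.
* The linear-track box dimensions and several spiking constants are package
  configuration defaults, not measured values; conclusions that depend on
  them are conditional on that configuration.
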