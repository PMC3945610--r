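# placefuse

Predicting hippocampal place-field sizes from environment geometry by
Bayesian cue integration — and demonstrating the same computation in a
spiking neuron.

## The problem

Place cells fire where the animal is; how *large* their firing fields are is
treated here as a read-out of the animal's location uncertainty. The model
fuses a path-integration prior with one Gaussian observation per boundary or
object, where the noise of a distance judgement grows linearly with the
distance judged (Weber's law, `sigma_o = gamma * d`). Precisions add, means
are precision-weighted, and the posterior standard deviation

    sigma = (alpha + (1 / gamma^2) * sum_j delta_j / d_j^2)^(-1/2)

predicts field size at any location from the distances `d_j` to the cues,
with a single fitted parameter `gamma` (the prior precision `alpha` is
negligible for the sensory-driven distal-CA1 cells modelled; the binary
`delta_j` optionally restrict the cell to a subset of cues). The package is
for computational neuroscientists who want to fit this model to field-size
data, run its cross-environment predictions, or reproduce its
coincidence-detection spiking implementation, where a leaky
integrate-and-fire place cell multiplies its inputs' firing-rate profiles by
firing only on coincident spikes.

Everything runs on seeded synthetic data with the structure of the three
emulated in-vivo paradigms (narrow rectangular track; 106.7 cm circular
track with 8 objects and a barrier; four open boxes of 61/122 cm sides), so
the full pipeline is testable without recordings.

## Worked example

Fit the model to a synthetic circular-track dataset whose fields were driven
by a *subset* of the objects, then recover that subset:

```r
library(placefuse)

track <- circular_track(106.7, 15, object_arcs_cm = default_object_arcs())
spec  <- synthetic_spec(track, gamma_true = 0.1,
                        mask_true = subset_mask(c(1,0,1,1,0,1,0,1,1)),
                        n_cells = 100, noise_cv = 0.1, seed = 42)
data  <- gen_circular_track(spec)

fit_gamma_track(data$fields$arc_cm, data$fields$size_value, track)
#> <placefuse fit>
#>   gamma = 0.165967 (beta = 36.3041, alpha = 0)
#>   R^2 = -0.2126  adj R^2 = -0.2250  r = 0.2802

fit_subset(data$fields$arc_cm, data$fields$size_value, track)
#> <placefuse fit>
#>   gamma = 1 (beta = 1, alpha = 0)
#>   mask  = 101101011
#>   R^2 = 0.9709  adj R^2 = 0.9676  r = 0.9855
```

The base model, which assumes every object drives every cell, fits these
data worse than their mean (negative R²). Exhaustively scoring all 511
observation subsets recovers the generating mask `101101011` exactly and
explains 97 % of the variance; the adjusted R² (p = 10 parameters) stays at
0.97. The `gamma = 1` line reflects that z-scoring makes the subset score
shape-only — `gamma` rescales amplitude and is not refit per mask.

The spiking counterpart — a wide "grid-cell" prior (centre 60 cm, sd 10)
and a narrow "border-cell" observation (centre 40 cm, sd 5) driving one LIF
place cell:

```r
lif  <- lif_params()
temporal_resolution(lif)          # coincidence window, ms
#> [1] 1.25
traj <- gen_trajectory(rect_env(100, 10), speed_cm_s = 20, duration_s = 60)
sim  <- simulate_place_cell(lif, list(gaussian_rate_field(60, 10, 25),
                                      gaussian_rate_field(40, 5, 50)),
                            traj, seed = 42)
posterior_from_spikes(sim$spikes_s, traj)
#> simulated field: mu = 45.1 cm, sigma = 3.97 cm (17 spikes)
```

The exact Gaussian-product posterior mean is 44 cm; the spiking estimate
(45.1 cm) lies between the two input centres, closer to the narrower
(more reliable) input, and its field is *narrower than either input* —
Gaussian-product shrinkage expressed in spikes. The peak output rate
(3.1 Hz here) sits in the 1–10 Hz range observed for CA1 place cells.

A thin CLI over the same functions ships in
`inst/scripts/placefuse-cli.R` (subcommands `generate`, `fit-gamma`,
`fit-subset`, `predict-crossenv`, `simulate-spiking`, `sweep-error`,
`report`; JSON/YAML configs; one seed governs all randomness). The methods
vignette (`vignettes/bayesian-place-fields.Rmd`) documents the model,
parameter choices and limitations.

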