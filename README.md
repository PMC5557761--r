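# arcomp

Decomposition of the posterior EEG alpha rhythm into frequency-, space-,
and time-resolved components.

## What it does

The 7–13 Hz alpha rhythm of resting eyes-closed EEG usually superimposes
at least two distinct oscillatory components: a higher-frequency
occipito-parietal component (ARC1, peak ≈ 10.4 Hz) and a lower-frequency
occipito-temporal one (ARC2, ≈ 9.4 Hz), each with its own amplitude
dynamics. `arcomp` separates them by modeling the three-way EEG
amplitude-spectrum tensor (space × frequency × time) as a sum of K
non-negative rank-one components,

```
ASD[s, f, t] = Σₖ a[f,k] · b[s,k] · c[t,k] + ε,
```

a PARAFAC (canonical polyadic) model fitted by non-negativity-constrained
alternating least squares. The pipeline is two-staged: a sensor-space fit
determines the frequency loadings `a_k` and temporal loadings `c_k`
(model order K chosen as the largest whose CORCONDIA core consistency is
≥ 90 %), noise components (flat spectra, non-posterior topographies) are
rejected, and a second fit on LORETA-imaged source spectra — with `a_k`
and `c_k` held fixed — recovers each component's cortical distribution
`b'_k`. Group-level spatial contrasts between components use a one-sided
paired cluster-based permutation test on the source grid; replicability
is quantified with Tucker congruence coefficients (TCC > 0.85 = highly
similar, > 0.95 = nearly identical).

A synthetic EEG generator with known ground truth (oscillatory cortical
patches with independently fluctuating envelopes, 1/f background, sensor
noise, analytic three-shell spherical forward model) makes the whole
chain testable end to end. It is first-class, tested code.

Intended users: EEG methodologists and clinical neuroscientists who need
a data-driven segmentation of the alpha band instead of fixed sub-band
boundaries.

## Worked example

```r
library(arcomp)

leadfield <- build_leadfield(sensor_layout(62)$positions)  # 62 ch, 387 sources
sim <- simulate_recording(default_two_arc_scenario(seed = 1), leadfield)
dec <- decompose_subject(sim$recording, arc_config(seed = 3),
                         leadfield = leadfield)
component_table(dec)
#>   label peak_frequency spectral_flatness posterior_fraction
#> 1  ARC1           10.4      3.174479e-92          0.8205264
#> 2  ARC2            9.4      7.210203e-50          0.7313889
recovery_congruence(dec, sim$ground_truth)
#>       patch matched_label tcc_frequency tcc_source tcc_channel
#> 1 ARC1-like          ARC1     0.9964917  0.9571096   0.9996611
#> 2 ARC2-like          ARC2     0.9976717  0.9510913   0.9987798
```

The simulated recording contains two posterior alpha patches at 10.4 and
9.4 Hz. The pipeline selects K = 2 by core consistency, labels the
higher-frequency component ARC1 (peaked, posterior, as the table shows),
and the recovered frequency and source loadings match the generating
ground truth with Tucker congruence well above the 0.85
high-similarity threshold.

For the model, its assumptions, all tunable parameters, and the design
choices behind the head model and the generator, see the vignette source
in `vignettes/arc-decomposition.Rmd`.

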