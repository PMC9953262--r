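# vfasense

Signal modeling and discrimination for nanomechanical sensor-array
(membrane-type surface stress sensor, MSS) measurements of volatile fatty
acid (VFA) odors — the odor fingerprint used to judge silage fermentation
quality. The package is aimed at e-nose / volatilomics practitioners who
need a tested, reproducible version of the full computational chain:
forward response model → kinetic parameter extraction → time-anchored
features → PCA discrimination, plus a seeded synthetic-data generator so
everything runs without instrument data.

## The model

An MSS channel is a polymer film whose sorption of vapor produces surface
stress. Two first-order processes set the transient: sorption with
diffusion time constant τ_s, and viscoelastic stress relaxation with time
constant τ_r (standard-linear-solid modulus E(t) = E_R + (E_U − E_R)
e^(−t/τ_r)). A single valve switch gives

    σ(t) = σ_sat · [1 − α·e^(−t/τ_s) − (1−α)·e^(−t/τ_r)],
    α = 1 + (E_U/E_R − 1)·τ_r/(τ_r − τ_s),

and an injection/purge protocol is the alternating superposition of this
basis at the switch times (evaluated in time-shifted form — all exponents
≤ 0 — which is the only numerically stable and continuous form).
Five anchored differences per channel, S_i = S(t0+Δ_i) − S(t0) with
Δ = (2, 10, 120, 122, 130) s, feed a standardized PCA; slow-desorbing
acids (τ_s above water's, further delayed by dissociation in a hydrated
film) make the decay-curve anchors the discriminating ones.

## Worked example

```r
library(vfasense)

# group contrast in the embedded headspace concentration table
group_ratio_summary()
#>         vfa    mean_s1  mean_s2    ratio ratio_2sf flagged
#> 1    acetic 24.4333333 103.2667 4.226467       4.2   FALSE
#> 2 propionic  5.1466667   7.7900 1.513601       1.5   FALSE
#> 3   butyric  9.2966667  15.8000 1.699534       1.7   FALSE
#> 4   valeric  0.6733333   1.7700 2.628713       2.6   FALSE
#> 5   caproic  0.0000000   0.0000       NA        NA    TRUE
```

The bottom-of-silo group (S2) runs 4.2× higher in acetic acid and 1.7× in
butyric acid — the contrast the pipeline must recover from sensor curves.

```r
# simulate the default study (6 panels x 3 replicates + 3 water blanks,
# 2 min sampling / 8 min purge, 100 Hz) and analyze it
ds  <- generate_dataset(generator_config(seed = 1))
res <- cli_analyze(ds$measurements, quiet = TRUE)
round(res$scree[1:3], 3)                    # 0.982 0.010 0.005
round(res$separation$mean_silhouette, 3)    # 0.853  (groups on PCs 1,3)
round(100 * res$replicate_deviation$max_deviation, 2)  # 0.6 (%)
```

PC1 carries the VFA-concentration axis, PC2 drift, and the (PC1, PC3)
plane separates S1 / S2 / water with silhouette 0.85; replicate
reproducibility stays under the 1% bound.

```r
# recover kinetic parameters from a 4-cycle 20 Hz curve
sc <- switching_schedule(t0 = 5, half_period_T = 10, n_cycles = 4)
cu <- sample_model_curve(sorption_params(1, 1.3, 8, 60, 5), sc, 20, 0, 125)
fit_response(cu, sc)
#> fit_result: sigma_sat=1 alpha=1.3 tau_s=8 tau_r=60 t0=5
#>   rms=2.15e-16 converged=TRUE bounds_active=none
```

A command-line driver lives at `inst/cli/vfasense.R`
(`simulate | fit | analyze | all`).

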