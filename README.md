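# patlakpet

Patlak parametric imaging and framing-protocol evaluation for dynamic PET,
in R.

## The problem

Total-body PET scanners make 60-minute dynamic ¹⁸F-FDG scans with very fine
temporal framing practical, and with them voxelwise kinetic modeling. The
standard oncological estimator is Patlak graphical analysis: for an
irreversible tracer, past an equilibration time *t\**,

```
C_T(t) / C_p(t)  =  K_i · ∫₀ᵗ C_p(τ) dτ / C_p(t)  +  V
```

so plotting the tissue-to-plasma ratio against "normalized time" gives a
line whose slope **K_i** (mL/min/cm³; reported in μL/min/cm³) is the net
influx rate and whose intercept **V** is the combined blood volume and
reversible-compartment distribution volume. The practical question this
package addresses is *protocol choice*: how many temporal frames does a
60-min scan actually need before the image-derived input function (IDIF)
and the parametric maps degrade? It provides, for researchers working on
dynamic-PET protocol design and kinetic-modeling software validation:

- the six standard 60-min framing protocols (P-100f … P-12f) and arbitrary
  frame schedules;
- rebinning of dynamic images / time-activity curves between protocols
  (overlap-duration-weighted, exact on aligned boundaries);
- IDIF extraction from a 4-mm-radius cylindrical descending-aorta ROI;
- ROI-level and vectorized voxelwise Patlak fits (Ki, intercept, SSE maps);
- the comparison machinery: relative differences vs a reference protocol,
  Bland–Altman, correlation, paired t-test, variance F-test, AUC errors;
- a synthetic dynamic-PET phantom (tri-exponential arterial bolus,
  two-tissue irreversible tissue kinetics, count-like noise) so the whole
  workflow runs and is tested without patient data.

## Worked example

```r
library(patlakpet)

# a noisy synthetic phantom on the 29-frame protocol
ph   <- build_phantom(phantom_spec(seed = 42), preset_protocol("P-29f"))
idif <- extract_idif(ph$image, ph$centerline, radius_mm = 4)

# ROI-level Patlak fit of the lesion (label 2)
fit <- roi_patlak(ph$image, idif, t_star = 10,
                  label_mask = ph$label_map, label = 2L)
print(fit)
#> Patlak fit (t* = 10 min, 14 frames)
#>   Ki        = 0.0221449 mL/min/cm^3  (22.14 uL/min/cm^3)
#>   intercept = 0.235614 mL/cm^3
#>   SSE       = 0.000134

# voxelwise parametric maps
maps <- patlak_voxelwise(ph$image, idif, t_star = 10)
roi_mean(maps$Ki, ph$label_map, 2L) * 1000
#> [1] 22.14486
```

The lesion is simulated with K1 = 0.094, k2 = 0.3, k3 = 0.1 /min and a 5%
blood volume fraction, so its tissue-level Ki is 23.5 μL/min/cm³ and the
measured-curve Patlak slope approaches (1 − Vb)·Ki ≈ 22.3 — the printed
22.14 is that value plus residual transient and noise. The ROI mean of the
voxelwise map equals the ROI-level fit because the regression design is
shared across voxels.

A shell interface covering the same pipeline (subcommands `simulate`,
`rebin`, `idif`, `patlak`, `evaluate`, `full-study`) is installed at
`inst/cli/patlakpet.R`:

```sh
Rscript $(Rscript -e 'cat(system.file("cli","patlakpet.R",package="patlakpet"))') \
    full-study --out-dir run/ --seed 7
```

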