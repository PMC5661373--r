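# gabedit

Simulation, reconstruction and quantification of J-difference edited
GABA magnetic resonance spectroscopy at ultra-high field (7 T), with
the test–retest reproducibility statistics used to validate automated
voxel prescription.

## Who this is for

MRS methods developers and students who want a fully simulatable,
testable model of a GABA-editing protocol: BASING/MEGA-style editing
pulses inserted into PRESS, the macromolecule-suppressing
symmetric-about-1.7-ppm pulse placement, multi-coil single-voxel and
8×8×1 phase-encoded acquisitions, and the downstream processing chain.
Everything is generated by the package's own density-matrix simulator;
no scanner data are required.

## The method in brief

GABA's 3.01 ppm multiplet couples (J ≈ 7.3 Hz) to its 1.89 ppm
methylene. Two interleaved cycles are acquired at TE = 68 ms ≈ 1/(2J):
in the *edited* cycle a frequency-selective inversion at 2.0 ppm
refocuses the J evolution of the 3.01 ppm partner; in the *non-edited*
cycle the pulse sits at 1.4 ppm and the coupling evolves freely, so
the in-phase amplitude is cos(πJ·TE) ≈ 0. The difference

DIFF = edited − non-edited

cancels uncoupled resonances (creatine at 3.03 ppm) and reveals GABA.
Macromolecules at 3.0 ppm couple to 1.7 ppm spins; because 2.0 and
1.4 ppm are symmetric about 1.7, the MM partners are perturbed
identically in both cycles and MM cancels in the difference — unlike
the water-symmetric placement (2.0/7.4 ppm), which co-edits MM and
inflates GABA into "GABA+".

The simulator propagates the full isotropic-coupling Hamiltonian

H/ħ = Σᵢ 2π νᵢ Iᵢz + Σᵢ<ⱼ 2π Jᵢⱼ Iᵢ·Iⱼ

through an idealised PRESS double echo with echo-pathway coherence
selection (emulating crushers) and an instantaneous Gaussian-profile
editing rotation. Downstream: k-space reconstruction with half-voxel
shift, per-coil/per-average spectral registration,
sensitivity-weighted coil combination, linear-combination fitting with
Cramér–Rao bounds and a CRLB < 20% inclusion rule, and the
repositioning statistics (two-point CV, dice overlap of oriented
prescription boxes, centre shift, tissue fractions, paired t tests).

## Worked example

Simulate a basis, generate a noisy drifting single-voxel acquisition,
reconstruct with corrections, and fit the difference spectrum:

```r
library(gabedit)

basis   <- makeBasis(sequenceParams(n_points = 1024L))   # TE 68 ms, 2.0/1.4 ppm editing
phantom <- phantomConfig(residual_water_amp = 2)         # brain-like concentrations
coils   <- makeSensitivities(8, c(1, 1, 1), seed = 11)
raw <- generateAcquisition(basis, phantom, coils,
                           encoding = list(matrix = c(1, 1, 1), averages = 64),
                           noise_sd = 0.02, drift_hz_per_avg = 0.1,
                           phase_sd_deg = 3, seed = 7)
rec <- reconstructVoxel(raw)          # registration, combination, difference
fitLinearCombination(rec$difference, basis)
#> QuantResult:
#>      amplitude crlb_pct included  ratio
#> NAA     0.9992      0.1     TRUE 1.0000
#> Glu     0.9044      0.4     TRUE 0.9051
#> Gln     0.3014      1.9     TRUE 0.3017
#> GABA    0.2002      0.7     TRUE 0.2004
#> GSH     0.2365      1.5     TRUE 0.2367
#> NAAG    0.1470      0.7     TRUE 0.1471
#>   noise sd 0.5592, zero-order phase -1.8 deg
```

The phantom's true GABA level (0.2 relative to NAA) is recovered as a
GABA/NAA ratio of 0.2004 despite drift, phase jitter and noise, with a
0.7% Cramér–Rao bound — comfortably inside the 20% inclusion rule.

Reproducibility statistics over the bundled 7 T test–retest reference
table (five subjects, two scans, three regions):

```r
reproducibilityStats()$averaged
#>       ACC     RCaud      LSTG
#>  3.300799 16.917083  6.004621
overestimationFactor(0.58, 0.21)   # GABA+ vs GABA, relative to NAA
#> [1] 1.761905
```

The averaged CVs per region and the 1.76-fold GABA+ overestimation
factor match the published summaries of the experiment the package
models (the ACC average computed from the printed per-subject CVs,
which include one internally inconsistent row, is 3.6).

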