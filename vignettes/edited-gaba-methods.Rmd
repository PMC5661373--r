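---
title: "Simulating and quantifying J-difference edited GABA spectroscopy at 7 T"
author: "gabedit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and quantifying J-difference edited GABA spectroscopy at 7 T}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gabedit)
```

## The problem

γ-aminobutyric acid (GABA) is the main inhibitory neurotransmitter of
the adult brain, present at roughly a fifth of the NAA concentration.
Its 3.01 ppm methylene resonance is buried under creatine (3.03 ppm),
so it is measured by J-difference editing: a frequency-selective
inversion pulse applied to the coupled 1.89 ppm GABA methylene in one
of two interleaved cycles refocuses the scalar-coupling evolution of
the 3.01 ppm partner. Subtracting the two cycles cancels everything
that does not couple to the inverted band and reveals the GABA
multiplet. At an echo time TE near 1/(2J) (68 ms for J ≈ 7.3 Hz) the
contrast between the refocused and freely evolving multiplet is
maximal.

Two practical complications drive the design choices modelled here:

* **Macromolecule (MM) co-editing.** Broad macromolecular resonances
  at 3.0 ppm couple to spins at 1.7 ppm. An editing pulse placed at
  1.9–2.0 ppm with its control far away (mirrored about the water
  frequency) partially inverts the 1.7 ppm partners in one cycle only,
  so MM signal survives the subtraction and inflates the apparent
  GABA — the quantity is then called GABA+. Placing the two pulses at
  2.0 and 1.4 ppm, *symmetric about 1.7 ppm*, perturbs the MM partners
  identically in both cycles and the MM contribution cancels in the
  difference, while the GABA editing (driven by the 1.89 ppm partner,
  asymmetric between 2.0 and 1.4 ppm) is essentially unchanged.
* **Instability between cycles.** The difference is vulnerable to
  frequency drift and phase fluctuations between the interleaved
  cycles, which leave a creatine subtraction artifact exactly where
  the GABA multiplet is read.

The package simulates the whole chain — spin physics, multi-coil
acquisition, reconstruction, quantification — and computes the
test–retest statistics used to assess such protocols.

## Spin simulation

Each metabolite is a set of coupled spin-1/2 nuclei with chemical
shifts δ (ppm) and scalar couplings J (Hz). One pseudo-spin represents
each group of equivalent protons, with a `proton_scale` weight
carrying the multiplicity (the creatine methyl is one spin with weight
3); this keeps every Hilbert space at ≤ 2^8 and reproduces the group
amplitudes and the vicinal-coupling editing behaviour, at the cost of
intra-group multiplet fine structure that is irrelevant at the 8–25 Hz
in vivo linewidths. Shifts and couplings follow the standard
literature compilations for brain metabolites and are recorded as the
table of record in `R/spin-systems.R`. The macromolecule pseudo-system
is deliberately minimal — a 3.0 ppm group J-coupled (7 Hz) to a
1.7 ppm group — which is exactly the topology that produces
co-editing.

The rotating-frame Hamiltonian is

H/ħ = Σᵢ 2π νᵢ Iᵢz + Σᵢ<ⱼ 2π Jᵢⱼ (Iᵢ·Iⱼ),   νᵢ = (δᵢ − δ_carrier)·f₀,

with f₀ = 297.2 MHz (7 T) and the carrier on water at 4.7 ppm. The
full isotropic coupling term is used (strong coupling); a secular
(IzSz-only) mode exists solely so the propagation machinery can be
validated against analytic weak-coupling product-operator formulas,
which are exact only in that approximation.

PRESS localisation is idealised as a hard-pulse double spin echo:
90°x, refocusing pulses at TE/4 and 3TE/4, acquisition from the echo
top. Crusher gradients are not simulated explicitly; instead the
density matrix is projected onto the echo coherence pathway
(−1 → +1 → −1) after each refocusing pulse. This matters: without the
projection an ideal-unitary simulation retains anti-echo pathways that
real crushers dephase. The editing pulse is an instantaneous per-spin
rotation by arccos(λ) about x, where λ is the Gaussian inversion
profile 1 − 2·exp(−4 ln2 · Δν²/fwhm²); it is applied immediately after
each refocusing pulse, which separates the two editing inversions by
TE/2 symmetrically about the echo — the placement that refocuses the
J-evolution of partners of the inverted spins. The scanner's exact
BASING timing is not public; this choice is configurable in principle
and documented rather than asserted. The profile width default of
60 Hz is likewise a stand-in for an unpublished pulse bandwidth,
exposed as `edit_fwhm_hz`.

A consequence of the pathway projection worth knowing: spins *inside*
the inverted band have their transverse coherence dephased (their
coherence order flips under the inversion and is discarded), so the
edited cycle loses the 2.0 ppm NAA acetyl singlet. The difference
spectrum therefore contains a large inverted NAA resonance at 2.0 ppm
alongside GABA — as in vivo edited spectra do.

### Strong-coupling accuracy

For a two-spin system at separations |Δν| ≥ 10 J the simulated echo in
secular mode matches the hand-derived closed forms
s(t) = Σ w·cos(πJ(TE+t))·e^{iωt} (non-edited) and cos(πJt)·e^{iωt}
(edited, refocused partner only) at machine precision. With the full
isotropic Hamiltonian the echo additionally carries a first-order
(J/Δν) modulation anomaly — oscillatory in Δν·TE, a few percent of the
full signal at the GABA 3.01/1.89 separation at 7 T, and *not*
removable by crusher pathway selection (verified against an
independent implementation). This is genuine spin physics of strongly
coupled echoes, so the closed forms serve as oracles for the secular
mode only; a separate test pins the size of the strong-coupling
deviation.

### Difference-spectrum sign

The pipeline difference is **edited − non-edited**, which displays the
refocused GABA multiplet with positive absorption — the convention of
the consensus processing chain for edited MRS and of the published
difference spectra this package emulates. `differenceSpectrum(a, b)`
itself is the plain pointwise `a − b`.

## Synthetic acquisitions

`generateAcquisition()` builds each average as the spatially
phase-encoded sum over a grid of concentration-weighted,
Lorentzian-damped basis FIDs multiplied by smooth complex coil maps,
then applies per-average errors and adds i.i.d. circular Gaussian
noise. The defaults encode the protocol under study: TE/TR
68/2000 ms, editing at 2.0/1.4 ppm, either 8×8×1 phase encoding with
two averages per cycle or a 1×1×1 single-voxel acquisition with 64
averages per cycle, interleaved cycle ordering (edited₁, non-edited₁,
edited₂, …), and a 32-channel-style coil array (tests use fewer coils
purely to keep runtimes short — coil count enters linearly and no
tested property depends on it).

Deliberate simplifications, hence what passing tests do *not* show
about real data: noise is uncorrelated across coils (no noise
covariance was available to model), drift is linear in the acquisition
index by default, lineshapes are pure Lorentzian (no eddy currents or
B0 distribution), there is no motion, and out-of-volume contamination
("unspoiled coherence" residues) is phenomenological — spectral
components pinned to grid cells, which localise exactly on the
discrete grid rather than through a continuous point-spread function.
The outer-volume suppression of the single-voxel mode is a scalar
attenuation (default 95% suppression) applied to contamination only,
mirroring the six-band vs two-band saturation difference between the
single-voxel and phase-encoded protocols.

Residual water after CHESS suppression is modelled as a water basis
signal of amplitude `residual_water_amp` per cell. The pipeline
default is 2 (twice NAA) — moderate suppression, typical at 7 T — and
it doubles as the natural phase reference for the correction stage
below.

## Reconstruction

The 8×8×1 data are reconstructed by an inverse 2-D DFT over (kx, ky)
with a half-voxel in-plane shift implemented as a k-space linear phase
ramp (verified against a direct DFT oracle, not interpolation); 1×1×1
data pass through. Coils are combined with conjugate-sensitivity
weights normalised by Σ|C|², which preserves amplitude for uniform
sensitivities.

Frequency and phase correction is the numerically delicate stage:

* **Within a cycle**, every average is registered to the cycle's first
  average by windowed nonlinear least squares: the *reference* is
  frequency-shifted in the time domain and only then band-limited
  (masking the shifted signal with a fixed window destroys the
  phase-ramp model — a 0.3 Hz shift was estimated as 0.02 Hz that
  way), with the zero-order phase solved analytically at each
  candidate shift and a full-band cross-correlation peak as the coarse
  start. A second pass against the aligned mean removes the error
  floor contributed by the reference average's own noise. The default
  window is the creatine region (2.9–3.1 ppm); with data at a creatine
  peak SNR of 20 that narrow window is information-limited near
  0.4 Hz, so the drift studies register on the full 1.8–5.0 ppm band.
  Because scanner drift is smooth in time, the per-average frequency
  series can additionally be smoothed with a local-linear
  (Savitzky–Golay) window (`smooth_averages`, default 9 in the voxel
  pipeline), taking the recovery error well below the single-average
  information limit; phases are never smoothed (phase jitter is not
  smooth).
* **Between cycles**, direct spectral registration is biased by the
  genuine editing differences, whose dispersive tails reach every
  window. The frequency offset is instead taken from the interleaving
  structure — a non-edited average sits midway in time between two
  edited ones, so the offset is the mean midpoint discrepancy of the
  two within-cycle series — and the zero-order phase from closed-form
  minimisation of the subtraction residual over windows whose content
  is identical in both cycles (residual water, creatine methylene, NAA
  aspartyl). The residual creatine subtraction artifact is measured as
  the excess over an error-free reconstruction after removing one
  global frequency/phase (which is unobservable; quantification
  re-phases anyway).

## Quantification

Difference spectra are fitted in the frequency domain as a linear
combination of the simulated basis shapes (the six standard basis
metabolites NAA, Glu, Gln, GABA, GSH, NAAG by default), broadened to a
target linewidth, over 1.8–4.1 ppm, on the real part after an
automatic zero-order phase search, with a polynomial baseline (order 2
by default) and non-negative metabolite amplitudes via bounded least
squares (baseline columns stay unconstrained as ± pairs). The
reference implementation of edited-MRS quantification uses a spline
baseline and lineshape model; the polynomial baseline is a documented
fidelity gap, acceptable here because the synthetic data share the
basis lineshape exactly.

Cramér–Rao lower bounds come from the Fisher information of the
design at the residual-based noise estimate, reported as percent of
each amplitude, with the conventional 999% sentinel at zero amplitude.
Metabolites are included when their CRLB is strictly below 20%.
Because MM is *not* in the fit basis (matching the published basis
set), any co-edited MM signal is attributed largely to GABA — which is
precisely the GABA+ overestimation mechanism, and the package
reproduces its direction end to end: fitting water-symmetric
difference spectra of an MM-containing phantom yields a strictly
larger GABA amplitude than fitting the symmetric-1.7 spectra of the
same phantom. The *magnitude* of the published in vivo overestimation
(GABA+/NAA = 0.58 vs GABA/NAA = 0.21, a 1.76-fold excess) is an
empirical property of tissue MM content and pulse profiles; the
package computes that factor from the published ratios rather than
claiming to predict it from the pseudo-system.

The test–retest CVs in the reference table were evidently computed on
all pairs — the caudate pair whose first scan has CRLB 21% (above the
inclusion threshold) still contributes a printed CV — so
`reproducibilityStats()` likewise computes CVs on all pairs and
reports the inclusion flags alongside.

## Reproducibility and geometry statistics

* The two-measurement CV uses the n−1 standard deviation,
  100·(|a−b|/√2)/mean — the only convention that reproduces the
  published per-subject values (14 of 15 pairs to ±0.1 point; the
  remaining pair, ACC subject 3, is internally inconsistent in the
  source itself: ratios 0.098/0.102 give 2.8%, printed 4.5%). ROI
  averages are arithmetic means; the published ACC average (3.6%)
  traces to the printed per-subject CVs including that row.
* Dice overlap of prescribed voxels rasterises both oriented boxes on
  a common 0.5 mm grid; this handles arbitrary orientations with a
  bounded, testable error, unlike analytic polytope intersection.
* Affine transport of a prescription uses the polar decomposition:
  the centre maps exactly, the orientation composes with the rotation
  factor, and half-lengths scale isotropically; anisotropic stretch or
  shear beyond 10⁻³ warns, since a box is then only approximate (the
  registration pipelines this models are near-rigid).
* Tissue fractions are probability-weighted means over the rasterised
  box, normalised to sum to 100 across gray matter, white matter and
  CSF; masks are nearest-neighbour sampled in 0-based voxel
  coordinates through the NIfTI voxel-to-mm affine.
* The paired between-session test is the standard paired t with a
  two-sided p on n−1 degrees of freedom; identical sessions return
  t = 0, p = 1, and no multiple-testing correction is applied (a
  single test family is reported).
* Chemical-shift displacement is (Δδ·f₀)/bandwidth as a fraction of
  the selected dimension; the protocol's over-excitation factor is
  1.9.

## Numerical choices and problem sizes

Simulated basis sets use 2048 points over 4000 Hz where spectral
detail matters and 1024 points in the statistical studies; both
resolve the 8 Hz in vivo linewidth comfortably. The test suite runs
the drift studies with 64 averages and 2–4 coils, the parameter
recovery on 100 noisy spectra spanning GABA-peak SNR 5–50 plus 200
Monte-Carlo repeats at SNR 10, and full-grid 8×8 reconstructions
against brute-force DFT oracles; these sizes were chosen so the full
chain, including two independent editing schemes, completes in a few
minutes while keeping every estimate's sampling error far from its
test threshold. All randomness is seeded explicitly; identical seeds
give bit-identical synthetic datasets and pipeline outputs
(checksummed in the run manifest).

## Known limitations

Shaped RF pulses, gradient waveforms, relaxation during pulses,
realistic B0 maps, coil noise correlation, motion, spline baselines
and lineshape deconvolution are out of scope; the geometry module
takes registration transforms as inputs rather than estimating them.
The strong-coupling echo anomaly discussed above means weak-coupling
closed forms should not be used as tight references for the full
Hamiltonian at small shift separations — the package's own secular
mode exists for that purpose.
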