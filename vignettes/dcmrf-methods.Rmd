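---
title: "Dual-contrast MRF: models, simulators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-contrast MRF: models, simulators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcmrf)
```

## The problem

Paramagnetic MRI contrast agents shorten both the longitudinal (T1) and
transverse (T2) relaxation times of the water they are dissolved in, in
proportion to their concentration. Because a conventional contrast-enhanced
scan is sensitive to a single weighted signal, two agents administered
together cannot be told apart. Magnetic resonance fingerprinting (MRF)
changes the arithmetic: it measures T1 and T2 *simultaneously and
co-registered*, giving two equations per voxel — enough to solve for two
agent concentrations. `dcmrf` implements this dual-contrast MRF (DC-MRF)
scheme end to end in simulation: relaxivity calibration, reference
relaxometry, FISP-MRF dictionary generation and matching, digital phantoms,
and the analytic two-agent inversion.

## The dual-agent relaxation model

For agents A (Gd role) and B (Mn role) with relaxivities $r_{1A}, r_{2A},
r_{1B}, r_{2B}$ (mM$^{-1}$ms$^{-1}$) in a solvent with pre-contrast times
$T1_0, T2_0$:

$$1/T1 = 1/T1_0 + r_{1A}[A] + r_{1B}[B], \qquad
  1/T2 = 1/T2_0 + r_{2A}[A] + r_{2B}[B].$$

Given measured $(T1, T2)$ the system is linear in $([A], [B])$ and solved in
closed form (`invertDualAgent`), with
$\Delta R_i$ the rate changes relative to baseline:

$$[A] = \frac{\Delta R2\, r_{1B} - \Delta R1\, r_{2B}}
             {r_{2A} r_{1B} - r_{1A} r_{2B}}, \qquad
  [B] = \frac{\Delta R2 - r_{2A}[A]}{r_{2B}}.$$

**Assumptions.** The two agents act independently (no competition for water
coordination — valid at moderate concentrations) and relaxation stays
mono-exponential. The model degrades when the relaxivity determinant
$r_{2A} r_{1B} - r_{1A} r_{2B}$ is small: two agents with proportional
relaxivity pairs are inseparable. `invertDualAgent` guards this with a
configurable singularity threshold (`det_tol`, default $10^{-12}$
mM$^{-2}$ms$^{-2}$ — an exact-degeneracy guard, deliberately permissive so
that sensitivity studies near degeneracy remain possible). The propagated
concentration error for a fixed rate-measurement error scales with the
inverse determinant; the test suite asserts this ordering.

**Units.** All times are ms, rates ms$^{-1}$, relaxivities
mM$^{-1}$ms$^{-1}$, concentrations mM. Literature relaxivities quoted in
s$^{-1}$mM$^{-1}$ divide by 1000.

**Negative concentrations.** Noisy measurements can produce slightly
negative estimates. The inversion returns them untouched: clamping is a
separate map-level option (`concentrationMaps(clamp = TRUE)`), kept off for
statistics (unbiased ROI means) and on for map export. Whether published
concentration maps of this kind are clamped is generally not stated; both
modes are first-class here.

## Reference parameters

`referenceRelaxivities()` and `referenceBaseline()` carry the
gadobenate-dimeglumine / MnCl$_2$ parameter sets the default phantoms use:
60 MHz at 37°C (Gd 0.0040/0.0048, Mn 0.0054/0.0652; water 4250/2760 ms) and
3 T at room temperature measured by spin echo (Gd 0.0051/0.0060, Mn
0.0068/0.1079) and by MRF (Gd 0.0056/0.0076, Mn 0.0067/0.1144; water
2897/946 ms). Temperature is handled as different parameter sets, not as
simulated physics.

## Relaxometry simulators

The reference arm mimics a benchtop relaxometer: inversion-recovery
spin-echo for T1 (signed model $S = M_0(1 - 2\beta e^{-TI/T1})$ with
inversion efficiency $\beta$) and a CPMG echo train for T2
($S_k = M_0 e^{-k\Delta t/T2}$). Fitting uses a coarse-grid profile over T1
(linear parameters solved exactly) refined by Levenberg–Marquardt
(`minpack.lm`); T2 uses log-linear least squares, falling back to nonlinear
fitting when noisy amplitudes cross zero. Signed (not magnitude) IR signals
are simulated and fitted, avoiding the sign ambiguity of magnitude fitting.
Noise is additive zero-mean Gaussian on amplitudes — the standard
NMR thermal-noise model.

The instrument's exact protocol values are not public, so the defaults are
declared, not inferred: 7 inversion times log-spaced from 50 ms to
3× the largest expected T1, and 1000 CPMG echoes at 1 ms spacing; all
configurable. Per-sample averaging follows the study design the package
emulates: 2 T1 repeats and 3 T2 repeats, averaged.

## The FISP-MRF engine

`simulateFISP` is an extended-phase-graph (EPG) recursion over configuration
states $(F^+_k, F^-_k, Z_k)$: ideal (efficiency-configurable) inversion,
relaxation during the inversion delay (default 21 ms), then per TR an RF
rotation about a fixed axis (constant phase — FISP has no RF spoiling),
relaxation split before and after the echo (default TE 2 ms), the sample
taken as $F_0$ at TE, and one unit of gradient dephasing per TR (unbalanced
gradient). The inner loops are compiled (Rcpp). Truncation keeps 50
configuration orders by default; against untruncated runs the deviation is
below $10^{-3}$ relative RMS for these schedules, and the suite checks the
full engine against an independent isochromat Bloch simulator (2001 spins
uniformly spanning one dephasing cycle) to < 1% relative RMS.

**Acquisition schedule.** The published 3000-image FISP-MRF waveform is not
recoverable from its description, so `makeDefaultSchedule` defines a
documented default with the same character: half-sinusoid flip-angle lobes
(250 excitations per lobe, pseudo-random peaks ≤ 75° with alternating
high/low lobes) and TR = 12 ms baseline plus a smooth positive pseudo-random
perturbation ≤ 3 ms, fully determined by a seed. The 3000-point default
lasts ≈ 40 s, consistent with a sub-minute single-slice acquisition. Any
published waveform can be supplied via `readSchedule()` (JSON).

**Dictionary.** The default grid is the piecewise-uniform T1/T2 lattice used
for matching (105 × 100 axis values; segments documented in
`defaultDictionaryGrid`). "All logical combinations" is interpreted as the
Cartesian product with pairs T2 > T1 removed (flag-controlled, since such
pairs are unphysical for aqueous solutions; the unfiltered grid remains
available), leaving 8542 atoms. Atoms are unit-normalized and ordered by T1
then T2; that ordering is the deterministic tie-break of `matchFingerprints`
(bit-reproducible maps). Matching maximizes the magnitude of the complex
inner product; magnitude-only signals work identically since matching is
invariant to global phase and positive scaling. Dictionaries persist as RDS
with a JSON provenance sidecar.

## The digital phantom

`defaultPhantomTable()` is a representative 17-vial design: 5 Gd-only vials
(0.05, 0.1, 0.2, 0.35, 0.5 mM — a dilution-style series), 5 Mn-only vials
(0.0125 to 0.2 mM in two-fold steps), 6 mixtures evenly spanning Gd
0.025–0.355 mM and Mn 0.00625–0.15 mM, and one water vial. The exact
mixture compositions of the physical phantom it emulates are not published;
the endpoints of each stated range are hit exactly and the table is
explicitly a representative stand-in (user tables load via
`readPhantomSpec`). The layout mirrors the four-row arrangement of the
physical phantom (bottom row Gd-only, third row Mn-only, mixtures on top).
The default image is 128 × 128 pixels with radius-9 vials — a desk-scale
choice; full scan-matrix sizes are a config away.

`simulateMRFSeries` renders per-vial fingerprints through
`forwardRelaxation` + `simulateFISP` and adds stationary complex Gaussian
noise, per-channel sd = `noise_sd` × the maximum noise-free amplitude
(default 0.01, a realistic in-vitro level). Background pixels carry no
signal and are skipped by default (a memory choice, flag-controlled);
matching flags them as no-signal rather than erroring. `repeatStudy` models
repositioning between repeats as a small global integer translation
(default ±2 px).

**What the phantom does *not* emulate:** coil sensitivity profiles, B0/B1
inhomogeneity, spiral k-space undersampling and reconstruction aliasing,
partial-volume edges, temperature drift, or agent–agent chemical
interaction. Passing tests therefore demonstrate correctness of the
modelling and quantification chain, not robustness to those physical
confounds.

## Quantification pipeline

`runPipeline` chains the stages and fixes two conventions worth stating:

* **Baseline from the matched water vial.** $T1_0/T2_0$ for the inversion
  are taken from the matched (dictionary-quantized) water-vial ROI of the
  *same modality and repeat*, never mixed across modalities. This mirrors
  how a no-agent sample defines the baseline in practice, and it cancels
  most of the grid-quantization bias: the water vial then inverts to
  exactly zero.
* **Per-repeat quantification.** Concentrations are computed per repeat and
  then averaged — not computed from averaged T1/T2 maps — matching the
  repeated-scan design; `compareVials` then applies an unpaired two-tailed
  Student's t-test (equal-variance by default, Welch behind a flag) to
  per-repeat ROI means.

## Numerical behaviour and known limitations

* The analytic round trip (forward model → inversion) is exact to
  $10^{-10}$ relative tolerance over randomized systems; an absent agent
  yields exactly 0.
* End-to-end accuracy through matching is quantization-limited: on the
  noise-free 17-vial replication the estimated-vs-true slopes are ≈ 0.993
  (Gd) and ≈ 0.997 (Mn) with $R^2 > 0.999$ — within the 0.95–1.05 band the
  test suite asserts — and stay within 0.05 of unity under 1% noise. These
  are properties of the synthetic replication, not reproductions of any
  measured dataset.
* For truths sampled uniformly inside the grid hull, ≥ 95% of noise-free
  matches land within one local grid step on both axes. The exception
  region is the short-T1 corner (T1 ≲ 100 ms): there the 10 ms T1 step is
  coarse relative to T2, and the match can trade several fine T2 steps
  along the well-known T1–T2 inner-product ridge while the inner product
  changes by only ~$10^{-5}$. Log-uniform sampling, which concentrates on
  that corner, drops the within-one-step rate to ≈ 0.74.
* Matching cost is one complex matrix product per pixel block; the full
  default dictionary (8542 × 3000) builds in ~15 s and matches itself in
  ~1–2 minutes on one CPU. Tests and examples use coarse grids
  (`defaultDictionaryGrid(scale = ...)`), shorter schedules and smaller
  phantoms where full scale adds nothing; the problem sizes used are stated
  in each test.
* Three or more agents make the linear system underdetermined and are out
  of scope, as are multi-exponential relaxation models.

## Open choices made here

Where the emulated study leaves details unstated, the package picks one
default and documents it: free intercepts in relaxivity fits (standard
practice; the intercept then estimates the solvent rate, and the fitted
baseline is reported alongside), complex inner products with magnitude
maximization for matching (magnitude-only supported), signed IR fitting,
CPMG echo count 1000 (the stated range's lower, typo-safe end), and the
schedule construction above. Each sits behind a parameter so the choice is
reversible.
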