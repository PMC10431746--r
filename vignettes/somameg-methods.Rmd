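---
title: "Methods: source-level somatosensory MEG analysis with planted ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: source-level somatosensory MEG analysis with planted ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

somameg implements a complete source-level analysis chain for somatosensory
MEG experiments — forward modeling, LCMV beamforming, seed-based
orthogonalized amplitude-envelope connectivity, paired-pulse gating of
evoked fields, psychometric thresholding, and vertex-wise group statistics
with TFCE permutation inference — together with a synthetic cohort generator
that plants recoverable ground truth at every one of those levels. This
vignette documents the models, the numerical choices, and what the
validation on synthetic cohorts does and does not establish about real data.

## The forward model

Source currents are equivalent current dipoles on a closed triangulated
"cortical" surface; the conductor is a homogeneous sphere. The external
magnetic field of a dipole in a spherically symmetric conductor has a closed
form (the classical spherical-conductor solution), implemented in
`sphere_forward()`. Two of its exact properties anchor the test suite: the
field is linear in the dipole moment, and a radially oriented dipole
produces no external field at all. The analysis therefore only ever sees the
tangential component of cortical currents — which is why the synthetic
surface is a *radially perturbed* sphere: its folding tilts the outward
normals away from the radius so that normal-constrained sources remain
visible. Gradiometers are modeled as differenced point magnetometers.

The forward code is validated against an independent numerical route: the
Geselowitz boundary-integral form of the volume-current contribution, i.e. a
Biot–Savart quadrature of the secondary currents over the conductor surface
using the classical Legendre-series surface potential of a dipole in a
homogeneous sphere (`field_quadrature_oracle()`). The two routes share no
algebra; they agree to well below 0.1% at the quadrature resolutions used,
and the test suite requires 1%.

A single shared sphere is used for all sensors. A per-sensor sphere center
(the "overlapping spheres" refinement) changes the geometry passed to the
same closed form, not the algorithmics, and is omitted; `sphere_forward()`
takes the center as an argument, so the refinement is a loop away if ever
needed.

## LCMV beamforming

For vertex $v$ with free-orientation lead field $L_v$ (channels × 3) and
data covariance $C$, the minimum-variance spatial filter is
$W_v = (L_v^\top C^{-1} L_v)^{-1} L_v^\top C^{-1}$, projected onto the
outward surface normal $n_v$ to give the constrained filter
$w_v = n_v^\top W_v$. Both this weight-projection convention (the default)
and the alternative — constraining the lead field first,
$l_v = L_v n_v$, then forming the scalar filter — are implemented
(`lcmv_weights(orientation=)`); they satisfy the same unit-gain constraint
$w_v^\top l_v = 1$.

Two numerical points matter in a spherical conductor:

* $L_v^\top C^{-1} L_v$ is *always* rank-deficient, because the radial
  orientation is silent. The 3×3 system is therefore inverted on its
  numerical range (eigenvalue pseudo-inverse, relative threshold $10^{-10}$)
  and the projected weight is renormalized so the unit-gain constraint holds
  exactly. A fully degenerate vertex is flagged and zeroed.
* The data covariance (per-epoch sample covariance averaged across epochs,
  `compute_data_covariance()`) is regularized by replacing every eigenvalue
  below its median with the median (`regularize_median_eig()`), with
  eigenvectors untouched. The spectrum floor bounds the condition number by
  $\lambda_{\max}/\lambda_{\mathrm{med}}$ and never decreases an eigenvalue.

Unit-gain minimum-variance maps inflate amplitude at vertices with weak
lead fields (the filter amplifies noise there). Wherever a map is scanned
for a *location* — localization tests and evoked ROI-scout placement — the
per-vertex noise gain $\lVert w_v\rVert$ divides the map first
(`beamformer_nai()`, the Van Veen neural activity index, and
`define_roi_scout(norm=)`). Amplitudes and ratios are always read off the
unit-gain maps themselves.

Covariance windows: resting weights use the full 2,000-ms segments; evoked
weights use the full epoch (−1,500 to 2,500 ms), which spans the prestimulus
and poststimulus periods that define the evoked covariance.

## Seed-based orthogonalized AEC

Connectivity is amplitude-envelope correlation in the alpha (8–12 Hz) and
beta (15–29 Hz) bands. Per 2,000-ms epoch: the seed series is the mean of
the 10 scout vertices' source time courses (averaged *before* any
connectivity computation); seed and every target are band-filtered with an
even-order linear-phase FIR (single pass, group delay compensated); the
Hilbert envelope is taken; the first and last 200 ms are discarded (FIR and
Hilbert edge transients; the value is a package default, not from the study
description); and the Pearson correlation of the envelopes is computed after
time-resolved pairwise orthogonalization,
$y_{\perp}(t) = \mathrm{Im}\!\left[y(t)\,\overline{s(t)}/|s(t)|\right]$,
which removes the component of the target instantaneously in phase with the
seed — exactly the zero-lag signal that inverse-operator leakage produces.
The correlation is computed in both directions (target orthogonalized to
seed and vice versa) and averaged, making the measure symmetric; per-epoch
values are averaged into one map (Fisher-z averaging is available behind a
flag, plain averaging is the default). Epoch averaging sums values in sorted
order so the map is bit-identical under epoch relabeling.

The study-scale design computes the correlation per epoch and then averages
over epochs; correlating concatenated epochs is the other reading of
"averaged across epochs and time points" and is not implemented as a
default because per-epoch correlation with epoch averaging is the common
AEC convention for segmented resting data.

Only the pairwise orthogonalization scheme is implemented. The symmetric
multivariate alternative (projecting the whole source matrix onto the
nearest orthonormal set) answers a different question — a single global
leakage correction across all vertices — and has no consumer in a
seed-based vertex-wise analysis, where each seed–target pair must be
corrected on its own terms; adding it as a mode would advertise an
untested code path.

Orthogonalized AEC is a conservative measure: even for perfectly correlated
envelopes it is attenuated well below 1, because orthogonalization discards
amplitude shared at zero lag and the residual envelope carries the
fluctuating phase geometry of the pair. The recovery tests therefore check
*order*, not identity: planted envelope correlations {0, 0.3, 0.6, 0.9} must
come out strictly increasing through the full simulate → mix → beamform →
orthogonalized-AEC chain, and a one-source (pure leakage) world must be
indistinguishable from an epoch-permutation null.

## Evoked responses and somatosensory gating

Evoked analysis averages epochs per condition (single-pulse SP, paired-pulse
PP; PP epochs locked to the first pulse), inverts the averages, and
quantifies the three successive components N20m / P35m / P60m in their
windows 20–26 / 27–40 / 45–71 ms. Scouts of 10 vertices are placed on the
noise-gain-normalized SP map peak per component (deterministic replacement
for interactive scout drawing: center = normalized argmax, plus nearest
neighbors by mesh hop distance, ties to the lower vertex index). The PP/SP
gating analysis subtracts the SP average from the PP average (removing the
first-pulse response under linear superposition), shifts the residual by
−100 ms so the second pulse aligns with the SP trigger, re-baselines
(−100 to −5 ms), extracts the scout-mean waveform, rectifies, and reads the
windowed peak. The ratio of PP to SP peaks is the gating measure;
values below 1 indicate inhibition.

Order of operations: baseline correction precedes rectification, and the
scout waveform is averaged across the scout *before* the absolute value is
taken, so uncorrelated vertex noise cancels in the average rather than
rectifying into a positive floor. The same order is applied to SP and PP
paths, which is what the ratio requires for comparability.

## Psychometrics

The two-point discrimination task is modeled as binomial logistic
regression of the "two points" response on pin distance (0–5 mm, 16 trials
per distance); "uncertain" responses are pooled with "one point" as the task
button mapping dictates. The threshold is the 50% point,
$-\beta_0/\beta_1$. Perfect separation has no finite MLE; such fits are
flagged and the slope clamped (default 25 /mm) with the intercept refitted
at the clamped slope — small per-subject trial counts make this path
reachable in practice. Trial-level and proportion-level fitting are
identical at the MLE; the counts interface exists so idealized (fractional)
proportions can be fitted in validation.

## Group statistics

The brain–behavior analysis regresses per-subject connectivity maps on the
behavioral covariate vertex-wise (single regressor; the t statistic is the
correlation t). Spatial inference uses threshold-free cluster enhancement,
$\mathrm{TFCE}(v) = \sum_h e(v,h)^{E} h^{H} \, dh$ with $E = 0.5$, $H = 2$,
over a ladder of 100 equal steps per sign up to the map maximum
($dh = \max/100$; a 10× finer ladder changes scores by under 2%, which
bounds the discretization error). Positive and negative tails are enhanced
separately and recombined with sign — the two-tailed design. Family-wise
error is controlled by the max-statistic permutation scheme: the covariate
is shuffled across subjects (the only exchangeable unit in a
single-regressor design), the full t → TFCE map is recomputed per
permutation, and null maxima are pooled over both tails;
$p(v) = (1 + \#\{\max \ge \mathrm{TFCE}(v)\})/(1 + B)$, never exactly zero.
When $n! \le B$ all permutations are enumerated instead. Surviving vertices
are grouped by first-order mesh adjacency and clusters with extent
$k_E \le 50$ are dropped (configurable; small demo meshes use a smaller
floor). Peak-vertex associations are Spearman correlations (exact
enumeration p for $n \le 9$ without ties, t approximation otherwise) and
SP-vs-PP amplitude comparisons are Wilcoxon signed-rank tests (exact for
$n \le 25$ without ties), both Bonferroni-corrected over the three
components ($\alpha = 0.05/3$).

The TFCE inner loop (incremental union-find over a descending threshold
ladder) is implemented in C++; one permutation of a ~600-vertex map costs
well under a millisecond, which is what makes the permutation calibration
tests affordable.

## The synthetic cohort generator

The generator is first-class, tested code; its defaults are the acquisition
conditions of the emulated study design: 1,000 Hz sampling, 5 minutes of
resting recording segmented every 2,000 ms, ~300 single-pulse and ~300
paired-pulse stimulations at 3.5–4.5 s spacing with 100 ms within a pair,
and 10 distances × 16 trials of behavior. Ground truth is drawn and recorded
before any mixing or noise and never recomputed from data.

**Resting oscillators.** Each active vertex carries, per band, a
constant-modulus band-limited carrier multiplied by a log-normal envelope
$\exp(\sigma z)$, with $z$ a unit-variance Gaussian process smoothed over
100 ms and $\sigma = 0.5$. A target's process mixes the seed's with an
independent one, $z = a\,z_{\text{seed}} + \sqrt{1-a^2}\,z_{\text{own}}$,
and the log-normal identity
$\mathrm{corr}(e^{\sigma z_1}, e^{\sigma z_2}) =
(e^{\rho\sigma^2}-1)/(e^{\sigma^2}-1)$ gives the closed-form mixing weight
that makes the planted envelope correlation exact. The carrier is a
frequency-wandering oscillator, $\cos(2\pi\!\int\! f)$ with $f$ centred in
the band and wandering by 15% of the half-bandwidth: its Hilbert envelope
is identically 1, so the planted envelope survives band-pass filtering and
envelope extraction without attenuation. (A carrier made of band-filtered
noise would multiply in its own Rayleigh-like envelope and the planted
correlation would be destroyed — with a shared envelope and independent
noise carriers, the measured envelope correlation saturates near 0.75
rather than 1.) Monte-Carlo calibration over seeds confirms the planted
values are recovered at the source level to within ±0.1 at 40 s of data
({0, 0.3, 0.6, 0.9} → means 0.02, 0.31, 0.61, 0.90 over 20 seeds).

**Source extent.** Sources are single vertices by default
(`source_patch_size = 1`). On the coarse synthetic meshes used for testing,
an extended *perfectly coherent* patch occupies a visibly distinguishable
topography and the minimum-variance filter partially cancels it (weights
can satisfy unit gain at the center lead field while nulling the patch
sum); point sources avoid planting that pathology while the 10-vertex
analysis scouts still capture them through the inverse operator's point
spread. Background activity — independent band-limited oscillators — is
placed on a configurable number of inactive vertices (default 64) rather
than all of them, bounding memory at study-scale durations; remaining
vertices are silent and sensor noise is white (a colored-noise option is
deliberately deferred to keep covariance behavior analyzable).

**Evoked responses.** Each stimulus evokes three signed Gaussian
deflections at the seed vertex, nominally 22 / 33 / 58 ms (inside the
component windows), widths 2.5 / 3.5 / 8 ms and amplitudes 35 / 45 / 40 nAm.
Widths were calibrated so the components remain separable within their
analysis windows — the property real SEF components have that makes the
windowed-peak analysis meaningful at all; with substantially broader
deflections the P35m tail bleeds into the 20–26 ms window and imposes a
floor of ~0.4 on the measurable N20m gating ratio. Paired-pulse trials add
a second response at +100 ms with each component scaled by the planted
per-component gating factor.

**Noise levels.** Sensor noise is specified as SNR and converted to an
absolute level per recording: resting SNR 5 (clean-signal RMS over noise
SD) and evoked single-trial SNR 1 (clean peak over noise SD) — the latter
reflecting that median-nerve SEFs are among the strongest evoked MEG
responses. With 300 trials per condition the averaged evoked SNR is ~17,
and the full-chain Monte-Carlo recovery of a planted N20m gating factor of
0.5 is 0.51 ± 0.07 across seeds.

**Cohort coupling.** Per subject, the planted envelope correlation is drawn
uniformly from [0.15, 0.85] and the true discrimination threshold is
$3.58 - 2 \cdot \mathrm{corr} + \mathcal{N}(0, 0.3)$ mm — mean ≈ 2.58 mm
and between-subject SD ≈ 0.5 mm, the scale of the emulated study, with the
negative slope encoding "stronger connectivity, better performance".
Gating factors are held at their configured values across subjects by
default; coupling them to behavior is a one-line config change. A
lightweight map-level cohort generator (`simulate_fc_cohort()`) plants the
same kind of coupling directly in connectivity maps (effect patch of 3 mesh
rings, amplitude 0.35 per unit latent strength, map noise SD 0.03) and is
used for the permutation-calibration experiments, where thousands of
sensor-level simulations would be pointless — FWE control depends only on
exchangeability, which the generator preserves exactly under the null.

## Problem sizes used in validation

The test-suite and acceptance-script experiments run at desk scale with
every *analysis* parameter at its standard value; only problem sizes are
scaled: meshes of 162–2,562 vertices instead of 15,000; 24–102
magnetometers instead of 306 channels; 30–40 s of rest instead of 5
minutes; inter-trial intervals of 1–1.5 s (trial counts, epoch windows, and
component windows unchanged) instead of 3.5–4.5 s; 100–1,000 permutations
instead of 10,000 (the study-scale value remains the documented setting for
real use). Determinism is exact: every random draw descends from one master
seed through a fixed splitting rule
(`subject_seed()`), and two pipeline runs with the same configuration are
bit-identical, including on-disk artifacts (no timestamps are written).

## What the synthetic validation does and does not show

Passing recovery tests establishes that the implementation does what the
models claim: the forward solution is the spherical-conductor field, the
beamformer has unit gain and localizes at the stated SNR, orthogonalization
cancels leakage exactly in a one-source world, planted effects of known
size come back in the right order and magnitude, the permutation machinery
controls family-wise error at its nominal level, and the whole chain is
reproducible bit-for-bit. It does *not* establish performance on real MEG:
the generator contains no head movement, no cardiac/ocular artifacts, no
environmental noise fields (their removal — SSS, ICA — is outside this
package's scope), no 1/f background spectrum, no inter-subject anatomical
variability, and its conductor is a sphere rather than a realistic head.
Claims about real-data sensitivity must come from real data; the synthetic
cohort is a correctness instrument, not a benchmark.

## Known limitations

* The spherical forward model is the analysis model *and* the generator
  model; model-mismatch robustness (e.g. BEM-generated data inverted with a
  sphere) is untested.
* Orthogonalized AEC values are attenuated relative to planted envelope
  correlations by design; the package reports the measure as defined, not a
  de-attenuated estimate.
* Extended coherent patches are partially cancelled by the LCMV filter on
  coarse meshes (see above); `source_patch_size > 1` exists but is not the
  validated default.
* The automated peak-to-peak trial rejection stands in for visual artifact
  review; with the default 7×median threshold on clean synthetic data it
  rejects essentially nothing, and the threshold is a convention, not a
  reconstruction of any published criterion.
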