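---
title: "Methods: microstate and network rhythm-energy estimation in restate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microstate and network rhythm-energy estimation in restate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(restate)
```

`restate` implements two estimators for resting-state EEG — polarity-
invariant microstate segmentation and empirical-Bayes network rhythm-energy
estimation — together with the synthetic data needed to validate them and
the within-subject statistics used to compare experimental conditions. This
vignette explains the models, the assumptions behind them, the tunable
parameters, and the design decisions taken where the methodology is
genuinely open.

## 1. The microstate model

The scalp potential field of resting EEG does not drift continuously:
band-passed to 2–20 Hz and referenced to the common average, its topography
at the local maxima of global field power (GFP, the spatial standard
deviation over channels) stays quasi-stable for tens of milliseconds and
then switches abruptly to another configuration. The handful of recurring
configurations are the *microstate classes*, conventionally labelled A–D.

### Estimation pipeline

1. **GFP peaks** (`extract_gfp_peaks`): samples with `GFP(t) > GFP(t±1)`
   (strict local maxima). Only these high signal-to-noise maps enter the
   clustering.
2. **Polarity-invariant k-means** (`microstate_fit`): maps are assigned to
   the prototype with the largest *absolute* spatial correlation — map
   polarity is physiologically uninformative because it flips with the
   oscillatory phase of the generators — and each prototype is re-estimated
   as the dominant eigenvector of the cross-product matrix of its assigned
   maps, the polarity-blind analogue of the cluster mean. Each iterate is
   scored as a complete model (partition eigenvectors plus best
   assignment) by GFP-weighted global explained variance (GEV), and the
   best-scoring iterate of the best of `n_restarts` (default 50) random
   starts is returned, so the reported GEV never degrades a warm start.
   Ties in the assignment go to the lowest class index.
3. **Number of classes** (`optimal_k_metacriterion`): seven cluster-validity
   criteria — Krzanowski–Lai, silhouette, Davies–Bouldin (inverted),
   point-biserial, Dunn, Calinski–Harabasz, and a cross-validation
   criterion — are evaluated under the polarity-invariant dissimilarity
   `1 − |r|`; each votes for a k and the lower median vote wins (ties
   resolve to the smaller, more parsimonious k). The identity of such
   criterion batteries varies between software packages; ours is
   configurable and the default is documented here. Pairwise criteria
   (silhouette, point-biserial, Dunn) run on a seeded subsample of at most
   400 maps for tractability.
4. **Group maps** (`group_maps_two_stage`): subject-level prototypes are
   pooled and re-clustered with the same algorithm; output classes are
   ordered by best match to a reference set of class topographies when one
   is supplied. How population maps are derived from subject maps is rarely
   reported in detail; two-stage re-clustering is the assumption made here.
5. **Backfitting** (`backfit`): every GFP-peak sample takes the label of the
   prototype with greatest `|r|`; every other sample inherits the label of
   the nearest peak in time (midpoint rule, ties to the earlier peak). No
   correlation floor and no minimum-duration smoothing are applied by
   default — assignment is unconditional, and temporal smoothing is left as
   an explicit opt-in rather than a hidden default.
6. **Parameters** (`microstate_stats`, `transition_probabilities`): mean
   run duration (ms), occurrences per second, coverage, per-class GEV, and
   the K×K matrix of switch fractions (switches i→j over all switches).

### What the synthetic generator emulates

`msgen_spec` / `simulate_microstate_eeg` generate EEG whose microstate
structure is known exactly:

- **Templates** are scalp fields of random dipoles in a homogeneous sphere
  (smooth, dipolar, like real topographies), redrawn until all pairwise
  `|r|` < 0.9.
- **Dwell structure** is semi-Markov: state dwells are gamma-distributed
  (shape 4) with a configurable mean (default 120 ms, the upper end of the
  50–120 ms range typical of eyes-closed rest), and successive states
  follow an embedded transition chain. The gamma default reflects the
  peaked, non-memoryless dwell histograms of real microstate sequences; a
  memoryless (geometric) law is available but places so much mass on
  sub-20-ms dwells that no peak-based segmentation could resolve them —
  such dwells are merged by any backfitting scheme, which inflates
  recovered durations for reasons unrelated to the estimator under test.
- **Amplitude dynamics**: each dwell's topography rides a band-limited
  alpha-band carrier (9–13 Hz, the rhythm that dominates resting GFP),
  tapered to zero at the dwell boundaries — transitions between microstates
  occur at troughs of the global field power, as observed in real EEG. GFP
  therefore shows realistic peaks inside dwells and troughs at switches.
- **Band-limited rendering**: the per-state gated signals are band-limited
  to 2–20 Hz at render time, because microstate structure is a phenomenon
  of that band; instantaneous broadband switching is not physically
  realizable in-band. As a consequence the dominant state near a boundary
  can shift by a few samples relative to the nominal gating; the ground
  truth recorded with each recording is the rendered dominant state (the
  argmax of the per-state signal power smoothed over ~20 ms), with the
  nominal planted sequence kept alongside.
- **Polarity**: the carrier is signed and each dwell additionally flips
  sign with probability 0.5, exercising the polarity-invariance path
  everywhere.
- **Noise**: white Gaussian sensor noise; the default
  `gfp_scale / noise_sd = 10/2` corresponds to the signal-to-noise ratio 5
  used throughout the validation suite.

What passing the recovery tests does **not** show about real data: the
generator has no artifacts (ocular, muscular, line noise beyond what the
notch stage would remove), no inter-subject topography variability, no
non-stationarity of the dwell process, and rank-1 within-state activity.
Recovery rates on real EEG will be lower, and the 2-s epoch/±100 µV
rejection stage stands in for the manual independent-component pruning used
in practice on human recordings.

### Analytic ledger

`expected_state_stats` converts generator parameters into the implied
stationary quantities: with embedded-chain stationary distribution ν and
mean dwells μ, coverage is νμ/Σνμ, occurrence is ν/Σνμ, and the expected
switch fraction i→j is ν·P (normalized). Planted cohort effects use these
forms exactly; in particular the "state D coverage ×m" effect rescales D's
mean dwell by the closed form `f = c*(T − c_D)/(c_D(1 − c*))` — with `T`
the mean dwell per run, `c_D` state D's coverage contribution and `c*` the
target coverage — solved on the fully updated post chain, so the planted
post/pre coverage ratio is exact,
and the A↔C / B↔D effects scale the corresponding chain entries with row
renormalization. Because switch fractions sum to one, scaling four of the
twelve ordered pairs necessarily shifts the remaining eight slightly
(by ×~0.95 under the default multipliers); this is a property of the
quantity, not an artifact of the generator.

## 2. The network rhythm-energy model

### Forward model

`build_sphere_leadfield` solves the potential of a current dipole inside
three concentric conducting shells (brain/skull/scalp; default radii
0.87/0.92/1.0, conductivities 0.33/0.0042/0.33 S/m). For each Legendre
order the five layer coefficients are found from a 5×5 interface system
with radius-normalized unknowns (numerically stable to high order), and the
series is truncated at `n_terms = 100`: at the default mesh radius 0.8 the
n-th term decays like 0.8ⁿ, so the truncation tail is ~2·10⁻⁸ relative —
series truncated at 60 terms would leave ~10⁻⁵ residuals, which is why the
default is higher. The equal-conductivity case reduces analytically to the
homogeneous sphere, for which `leadfield_homogeneous` implements the exact
closed form (obtained by summing the series): this is the oracle used in
the validation suite, agreeing with the layered solver to ~10⁻⁹ relative in
Frobenius norm. Lead-field columns are re-referenced to the common average,
matching the preprocessing of the data they will be inverted against.

The source space is a deterministic icosphere (`cortical_mesh`; the test
scale uses 162–2,562 vertices) with radial dipoles — a synthetic stand-in
for an MRI-derived cortical surface, at a scale where every validation runs
in seconds. The eight-network atlas (`synthetic_atlas`) partitions the
sphere by nearest seed direction with anatomically oriented seeds: visual
occipital, somatomotor at the vertex, deep at the inferior cap. The deep
patch is deliberately placed where scalp electrodes barely see it,
mimicking the genuinely poor visibility of thalamus/striatum sources in
EEG; its energy estimates are accordingly the least reliable, which is the
expected behavior, not a defect.

### Priors, ReML, and band energies

Each network contributes one covariance component `V_i`: the Green function
`exp(σ·W)` of the row-normalized adjacency `W` (default smoothness σ = 0.6)
restricted to the network's vertices, zero elsewhere, symmetrized and
eigenvalue-floored at zero. σ = 0 gives identity (uncorrelated-source)
priors; larger σ encodes smooth local coherence along the mesh.

`reml_estimate` fits the sensor-covariance model
`C(λ) = exp(λ₀)·I + Σᵢ exp(λᵢ)·L·Vᵢ·Lᵀ` by maximizing the restricted log
likelihood (free energy) with Fisher scoring and step halving, so the
recorded evidence trajectory is non-decreasing. Numerical choices: the
sensor projections of the priors are trace-normalized so the λᵢ are
comparable; log-parameterization enforces positivity with a floor of −32
*relative to the log mean sensor variance*; convergence is declared when
the evidence change per effective sample falls below 10⁻⁴; both the floor
and the convergence rule are functions of evidence *differences* and
data-relative scales, which makes the whole fit — and therefore every
energy — exactly equivariant under rescaling the data by c (energies scale
by c²). With a single identity prior the posterior-mean operator reduces to
the closed-form regularized minimum-norm (ridge) inverse, which the test
suite checks to 10⁻⁶.

`band_energies` estimates one operator from the broadband epoch-averaged
covariance and applies it to each band-passed copy of the data (bands:
δ 0.5–4, θ 4–8, α1 8–10.5, α2 10.5–13, β1 13–20, β2 20–30, γ 30–45 Hz —
conventional splits of a 0.5–45 Hz analysis band; configurable). Whether
the original methodology inverted per-band covariances or a broadband one
is not documented; the broadband choice follows from the linearity of the
operator and keeps the cost of a 56-cell table at one inversion. Energies
are mean squared current density per vertex, averaged over each network's
vertices and over epochs, in arbitrary (relative) units — absolute source
units are not identifiable from scalp data without a calibrated forward
model, so only ratios and condition contrasts are meaningful.

## 3. Preprocessing

FIR filters are Hamming windowed-sinc designs (`signal::fir1`) applied by
FFT convolution with exact group-delay compensation, so they are zero-delay
and linear-phase; the transition bandwidth is 25% of the lower band edge,
floored at 0.5 Hz, and the band-stop notch uses a 5-Hz-wide stop band.
Epoching cuts consecutive non-overlapping windows and discards the trailing
remainder; amplitude-based rejection marks (but does not delete) epochs
containing any sample beyond ±100 µV. This rejection stage replaces manual
independent-component artifact removal, which is neither reproducible nor
meaningful on artifact-free synthetic data.

## 4. The statistical layer

`rm_anova_two_way` computes the classical within-subject partition (each
effect tested against its subject-interaction error term) from cell means —
validated against the `aov` error-strata decomposition to 10⁻⁹ — plus, per
effect, Mauchly's W on orthonormal contrast scores (interaction contrasts
are Kronecker products), the chi-square p with the standard second-order
correction, and the Greenhouse–Geisser ε in eigenvalue form. Following
standard practice, the corrected p replaces the uncorrected one only when
Mauchly's test rejects at 0.05 and the effect has more than one numerator
df. Partial eta squared uses the F-statistic identity
`η²p = F·df1/(F·df1 + df2)`.

Post hoc families: after a significant interaction, each level (4 classes,
12 ordered transition pairs, or 8 networks) is compared pre vs post by a
paired t-test with Bonferroni correction over the levels of that family
(m = 4, 12, or 8). The family definition is a convention choice — original
reports rarely state theirs — and is configurable.

## 5. Validation scales and limitations

The validation suite runs at deliberately desk-sized problem scales, chosen
once as part of the study design: 32 channels at 250 Hz; 180 s single-
subject recordings for parameter recovery; 60 s recordings for the
20-run meta-criterion sweep; a 600-s sequence for transition recovery; a
2,562-vertex icosphere for the forward-model oracle and a 162-vertex mesh
for inversion studies; and 25 simulated cohorts of 20 subjects (40-s
microstate and 16-s network recordings per condition) for the planted-
effect power check. Under these conditions the suite verifies: prototype
recovery |r| ≥ 0.95 and ≥ 90% label agreement at SNR 5 with temporal
parameters within 10% of the ledger; ≥ 80% recovery of planted K ∈ {3,4,5};
switch-fraction recovery within 0.02; forward-model agreement within 10⁻⁶;
ReML ridge agreement within 10⁻⁶ with ≥ 90% planted-network identification;
detection of all five planted cohort effects in ≥ 80% of cohorts; and
type-I error within 0.05 ± 0.01 for the paired t and Mauchly tests.

Known limitations: spherical geometry only (no realistic BEM/FEM head
models and no MRI mesh import); microstate sequence analyses beyond the
five standard parameters (entropy, syntax) are out of scope; the energy
table is relative, not absolute; and all recovery figures are properties
of the synthetic generator's assumptions listed above, not guarantees on
human data.
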