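---
title: "Tract-specific anisotropy: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tract-specific anisotropy: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`tractsa` post-processes probabilistic-tractography visitation maps into
a per-pair tract trajectory, a per-participant tract-specific anisotropy
(TSA) map, and distance-wise covariate statistics. This vignette is the
package's account of the underlying models, the tunable parameters and
the choices made where the design was genuinely open.

## 1. From visitation counts to a tract probability

The input per participant and ROI pair is a pair of directed visitation
count volumes (seed in `R_a` terminating in `R_b`, and the reverse) and
a mean streamline-orientation volume, all on one common voxel grid —
the method assumes spatial normalisation has already happened upstream,
and a registration hook defaulting to the identity is the only
concession to native-space data.

Each directed map is divided by the total number of streamlines that
reached the target. A way-point voxel can be visited by more streamlines
than reach the target, so the ratio can exceed 1; we clip at 1. All
downstream operations (minimum across directions, averaging, maxima) are
order-preserving, so clipping only enforces the probability contract
without reordering candidates. A zero total marks the pair unconnectable.

The per-voxel **minimum** across the two directions suppresses
direction-specific artefacts (a voxel that only one seeding direction
reaches is not credible tract core); the minima are averaged over
participants, Gaussian-smoothed, and divided by the global maximum,
giving `P_ab` with values in [0, 1]. The smoothing kernel width for this
population average is not prescribed by the method; we default to a
FWHM of 2 mm — one voxel on the 2 mm isotropic grids the method targets
— as minimal regularisation at grid scale, and expose it
(`smoothing_fwhm`).

Thresholding keeps voxels with `P_ab >= alpha` (inclusive at equality,
the literal reading of "set values below alpha to zero"), with
`alpha = 0.07` as the working default; both ROIs are morphologically
dilated by 3 iterations and unioned in, because visitation probability
dips near grey matter and the ROIs must stay connected to the tract
body. Rejection of a pair is then purely topological: if the flood fill
cannot walk from the dilated seed to the dilated target through the
member set, there is no unambiguous trajectory.

### Flood fill and the core polyline

Distances are breadth-first labels over the member set: member
neighbours of the seed ROI get `d = 1`, their unlabelled member
neighbours `d = 2`, and so on; seed voxels carry no label and
disconnected members stay unassigned. The neighbourhood defaults to
26-connectivity (faces, edges, corners): the segment-length bound of
4 mm on a 2 mm grid already admits diagonal steps, so the permissive
neighbourhood is the consistent choice; 6 and 18 are available
(`connectivity`).

The polyline takes, at each distance, the highest-`P_ab` voxel whose
centre is less than 4 mm from the previous vertex and turns by less
than 60 degrees (the turning angle is measured between the incoming and
outgoing segment directions, 0 = straight). Candidates are scanned in
descending probability with ties broken by lowest linear voxel index,
for exact reproducibility. When no candidate satisfies the constraints
the maximal voxel is still appended but flagged for inspection — a
deliberate "keep going, but tell the user" rule. The walk terminates as
accepted as soon as a vertex's voxel is inside or 26-adjacent to the
dilated target (the dilation exists precisely to preserve that
encounter), and as rejected when the strata run out first. The maximal
distance is whatever the flood fill produced; there is no extrapolation.

### Uncertainty field and per-stratum normalisation

Per-vertex orientations are the normalised sum of the two adjacent
segment vectors (single segment at the endpoints). Around each vertex an
anisotropic Gaussian kernel is evaluated at voxel centres within 8 mm:
the offset is split into its component along the vertex orientation
(axial, `sigma_a = 10` mm) and the perpendicular remainder (radial,
`sigma_r = 4` mm), and the field takes the maximum over vertices.
Kernels are peak-normalised (value 1 at the vertex) rather than
density-normalised: the subsequent per-stratum rescaling makes any
constant factor irrelevant. The final tract probability is
`Phi_ab * P_ab` rescaled to a maximum of 1 within each distance stratum
(all-zero strata stay zero), so every stratum contributes a full-weight
core voxel regardless of its absolute visitation probability.

## 2. The TSA regression

At voxel `j` with unit mean orientation `v_j`, gradients `r_i` (rows of
`R`), b-value `b` and diffusivity `delta`,

    s_ij / s0_j = beta_j * exp(-b * delta * (r_i . v_j)^2) + c_j + noise.

Ordinary least squares on the M gradient rows gives the TSA `beta_j`
and intercept `c_j`. Three reading decisions deserve note:

* `R^T v` is taken as the vector of per-gradient dot products — the
  only dimensionally consistent reading of the exponent.
* The regression is linear only because `delta` is supplied, not
  estimated. Its source is left to the user: a per-voxel diffusivity
  map (for real data, a tensor-fit mean-diffusivity map is the
  documented choice) or a scalar; the default scalar is
  `1e-3 mm^2/s`, typical white matter. The phantom supplies its own
  known `delta`.
* b = 0 rows are excluded from the fit (the response is already defined
  relative to `s0`), and no non-negativity constraint is placed on
  `beta` — it is a plain regression coefficient, and negative estimates
  carry information for the statistics stage.

The regressor is antipodally symmetric (the dot product is squared), so
orientation sign conventions cannot affect results. Voxels with no
orientation, non-positive `s0`, or a constant regressor (orientation
orthogonal to every gradient never happens with realistic schemes, but
degenerate inputs do) are flagged unfitted rather than erroring; the
covariate model later excludes, listwise, any voxel unfitted in any
participant, keeping the per-voxel design balanced.

Fitted maps are smoothed with a masked Gaussian kernel
(`fwhm = 1.5` mm): unfitted voxels contribute neither signal nor kernel
normalisation, so constants are preserved on the support and nothing
bleeds across the tract boundary. `fwhm = 0` is the exact identity.

## 3. Distance-wise statistics

Per voxel, `TSA ~ 1 + Age + Sex + Age:Sex` with sex coded 1 = male /
2 = female exactly as read from the cohort (not re-centred) and the
interaction as the literal product; `nu = n - 4`. Each distance stratum
is summarised through the weighted statistic
`t' = t * P_tract^lambda` (`lambda = 1` by default; `lambda = 0`
recovers the plain extremum). The method's reference description keeps
only "the t of the maximal t'", yet reports negative clusters, which a
single signed maximum cannot produce; we therefore summarise each
stratum twice — the voxel maximising `t'` for the positive tail and the
voxel minimising it for the negative tail — and test each tail at the
nominal level. This per-tail reading is recorded as our implementation
choice, not as the original authors' procedure.

Residual smoothness along the tract is estimated from the GLM residuals
at each stratum's maximal-`P_tract` voxel (the core voxel — a
contrast-independent choice): residual fields are standardised per
stratum, differentiated along the distance axis with central
differences, and the mean per-node resel density inverted into a FWHM
in stratum units (inter-stratum spacing = 1; millimetres are a display
conversion only). Constant residuals return an `Inf` sentinel and
tracts with fewer than 2 strata are excluded from the cross-tract
average.

The critical value `t*` solves `P(max > t*) = alpha` under the
expected-Euler-characteristic approximation for a 1D field with
`(Q - 1) / FWHM` resels. The reference description says "Gaussian
field" while the statistics are t's with modest degrees of freedom; we
default to the t-field form with `nu = n - 4` for correct small-sample
behaviour and expose `model = "gaussian"` to match the Gaussian wording
exactly. Monte-Carlo validation (5000 simulated smooth t-fields,
FWHM 10, length 100, `nu = 126`) places `t*` within 3% of the empirical
95th percentile, and the resel-free limit reproduces the point-wise
quantile.

Runs of at least 3 consecutive supra-threshold strata become clusters;
each receives `p = 1 - exp(-E[N] * exp(-extent / E[S]))`, the
expected-extent exponential approximation for supra-threshold runs in a
stationary 1D field (`E[N]` expected upcrossings at `t*`, `E[S]`
expected run extent). The approximation's contract is agreement with
simulation, which the type-I experiment below checks end to end.
Cluster p-values across all tracts enter the two-stage non-negative FDR
step-up at `q = 0.05`: stage one estimates the number of true nulls at
level `q / (1 + q)`, stage two inflates the threshold by `m / m0`.
Adjusted p-values are monotone in raw p-values but can drop below them
— a property of the adaptive procedure itself, which we preserve
because matching its decisions exactly matters more than a cosmetic
ordering constraint. Finally, summarised t-values of surviving clusters
are summed per tract, separately by sign, as a compact effect-extent
measure.

## 4. What the phantom emulates — and what it does not

The phantom builds a Gaussian tube of visitation probability
(`exp(-r^2 / 2 sigma^2)`, `tube_sigma = 4` mm) around a smooth
ground-truth curve on a 2 mm isotropic grid, with spherical 4 mm ROIs
at its endpoints, unit tangents as the orientation field wherever the
noiseless probability exceeds `1e-3`, optional competing routes at
relative amplitudes below 1, multiplicative log-normal jitter
(sd 0.1) per seeding direction — mimicking the seed-direction asymmetry
the bidirectional minimum is designed to suppress — and participant
level jitter (sd 0.05) on top of the shared population field. DWI
signals follow the forward model above with additive Gaussian noise on
the signal scale by default (a Rician option exists; the Gaussian
default keeps the OLS fit's bias behaviour analytically inspectable).
The b0 volume is noise-free so that signal normalisation is exact.

What passing tests on this phantom demonstrate: geometric recovery of
the core under realistic visitation noise, exact and noisy recovery of
the anisotropy fraction, calibration of the random-field threshold, and
type-I/power behaviour of the full statistical chain. What they do not
demonstrate: behaviour under streamline-level tractography biases
(distance bias beyond the upstream correction, gyral seeding bias),
crossing-fibre orientation ambiguity, registration error, or
multi-shell acquisitions — all explicitly upstream of this package's
scope.

## 5. Numerical choices and problem sizes

* Gaussian smoothing uses separable shift-and-add convolution truncated
  at 4 sigma with weights renormalised to sum 1; masked smoothing
  divides by the smoothed mask.
* Ties in candidate selection, stratum maxima and FDR ordering are
  broken by index order; every stochastic component consumes an
  explicit seed (participant p of a signal specification uses
  `seed + 7919 p`), so identical configurations reproduce outputs byte
  for byte.
* The validation suite uses a 32^3 reference phantom (2 mm voxels,
  24 distance strata, ~2600 tract voxels). Exact-recovery runs use 130
  synthetic participants with 137 gradients at b = 1500 s/mm^2; the
  type-I experiment runs 500 null cohorts of 12 participants and the
  power experiment 200 cohorts with an age slope of 0.0025 per year
  injected into the middle third of the strata — calibrated so the
  within-region summarised t averages well above 4. The acceptance
  script repeats these computations at moderately reduced replicate
  counts.

## 6. Known limitations

The per-stratum extremum of weighted t-statistics is an extreme-value
summary; its null distribution is not exactly the stationary-field null
that calibrates `t*`, and the minimum-extent rule plus FDR stage absorb
the difference in practice (the measured type-I rate sits well below
the nominal level — conservative, not inflated). The cluster-extent
p-value is an exponential approximation validated by simulation, not an
exact law. One core per ROI pair is a design commitment: genuinely
bimodal route distributions are rejected rather than split. Sex enters
as a 1/2 numeric code for fidelity to the cohort encoding; users
wanting centred or factor codings should recode upstream of
`tract_stats()`.
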