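---
title: "Methods: track analysis, directionality testing and random-walk modelling"
author: "trackmotility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: track analysis, directionality testing and random-walk modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models, statistics and design decisions behind
`trackmotility`: what each method assumes, which tunable parameters matter
and why their defaults were chosen, what the synthetic-data generator does
and does not emulate, and the numerical conventions used throughout. It
states no empirical result beyond what the package's test suite and
`scripts/acceptance.R` themselves compute.

## The data model

A **track** is the time-ordered sequence of observations of one cell: a
numeric matrix with a time column (minutes, by convention) and 2 or 3
coordinate columns (micrometers, by convention). A **tracks object** is a
named list of such matrices sharing one dimensionality. Units are metadata
only — nothing is ever converted — and all outputs are in (space unit,
time unit) terms.

Three invariants are enforced at construction and therefore hold
everywhere downstream:

* at least one observation per track, and strictly increasing times.
  Duplicate timestamps within a track are an *error*, not something to
  average away: they almost always indicate a tracking fault, and silently
  merging them would hide exactly the kind of artifact the QC tools exist
  to find;
* one dimensionality per dataset;
* tracks are held in lexicographic id order, so every statistic that
  iterates over a dataset is deterministic.

On disk, tracks are delimited text with columns `id, t, x, y[, z]`.
Because every tracking tool names its columns differently, `read_tracks()`
accepts a *dialect*: a named list or a plain-text `key: value` file
remapping the delimiter and column names. Dimensionality is inferred from
the presence of a mapped z column — a z column of zeros still yields a 3D
dataset, since "flat" 3D data and 2D data are semantically different
inputs that a user may want to distinguish.

### Analysis scales

`subtracks(x, L, overlap)` decomposes tracks into contiguous subtracks of
`L` steps; a "length" always counts *steps* (observations minus one), and
subtrack index ranges are 0-based and inclusive. With maximal overlap
(`L - 1`, the default) a track with n steps yields `n - L + 1` subtracks;
with overlap 0, `floor(n / L)`; in general
`floor((n - L)/(L - overlap)) + 1`. `staggered_subtracks()` enumerates all
`n(n + 1)/2` contiguous slices, which any measure turns into a triangular
matrix (`apply_staggered()`).

These decompositions implement the three analysis scales: *cell-based*
(one value per track), *step-based* (pooled over fixed-length subtracks)
and *staggered*. Cell-based summaries give every cell equal weight
regardless of how long it was tracked and are therefore sensitive to
tracking duration artifacts; step-based pooling weights by observed steps.
Both are provided because the comparison between them is itself
informative.

## Motility measures

All measures are functions `track matrix -> scalar`, so user-defined
statistics are first-class citizens everywhere (`apply_measure()`,
`aggregate()`, `feature_matrix()`, `select_tracks()`, the pipeline's
measure registry by name).

Where a measure is undefined — speed of a zero-duration track,
straightness of a zero-length track, a turning angle at a zero-length step
— the result is `NA`, never 0 and never a silent omission: undefined
values propagate into result tables and are excluded from
embedding/clustering only with an explicit message. Silent NA-dropping is
a classic source of bias in track statistics.

Numerical conventions:

* angles are reported in **degrees** and computed internally via
  `atan2(‖v_perp‖, u·v)` rather than `acos` of a cosine; near 0° and 180°
  the arccosine form loses ~6 significant digits, the arctangent form does
  not;
* the asphericity uses the gyration tensor of the *observed positions*,
  unweighted by time spacing (the literature convention), and equals
  Σ_{i<j}(λ_i − λ_j)² / ((d−1)(Σλ)²): 1 for collinear configurations, 0
  for isotropic ones;
* `overall_angle`/`overall_dot` relate the *first and last step* of a
  (sub)track, which makes `aggregate()` with these measures the angle
  autocorrelation and displacement autocovariance versus lag.

`aggregate()` (and its vectorized special case `msd()`, verified in the
tests to agree with the generic path to 1e-12) reports the lag axis both
in steps and in time units. This requires a uniform step duration, so
datasets with gaps must be repaired first; mixing step durations is an
error rather than a warning because a silently mixed lag axis invalidates
the whole curve. Maximally overlapping subtracks are the default — they
use all the data — and the per-lag count `n` is always reported so that
the dependence between overlapping subtracks can be taken into account;
non-overlapping decomposition is available where independence matters.

## Quality control

**Double tracking.** When a segmentation error makes one cell two tracks,
the two tracks stay close at shared timepoints *and* move in near-parallel
directions. `pair_diagnostics()` reports, per unordered pair with temporal
overlap, the minimum inter-cell distance over shared timepoints and the
angle between overall displacement vectors. Timestamps are matched with a
tolerance of 1e-6 times the median step duration; pairs without temporal
overlap are omitted (and counted) because positions at different times
carry no co-tracking signal. The package deliberately does not pick an
automatic distance/angle threshold — the distance–angle plot is designed
for visual inspection — but `rank_pairs()` orders pairs by the rank
product of the two columns, which the validation suite uses to check that
injected duplicates surface at the top.

**Gaps.** Steps whose duration deviates from the per-track median by more
than 50% (i.e., outside [0.5, 1.5]× the median, tolerance configurable)
are flagged; the median reference is robust to one-off dropouts. Repair
strategies: `drop` whole tracks, `split` at flagged steps (ids suffixed
`.1`, `.2`, … in temporal order, collision-checked; total observation
count conserved), or `interpolate` onto the uniform median-interval grid.

**Drift.** Stage or tissue drift is estimated *globally* as the sum of all
step displacement vectors divided by the total step duration, and
subtracted as `v·(t − t_first)` per track. A per-track drift estimate is
deliberately not offered: per-track directed displacement is
indistinguishable from genuine directed motion, and "correcting" it would
erase biology. The estimator choice (duration-weighted mean step velocity)
is this package's own; it makes the corrected dataset have exactly zero
re-estimated drift.

## The directionality test

`hotellings_test()` pools the step displacement vectors of all tracks and
computes Hotelling's one-sample T² = n x̄ᵀS⁻¹x̄ against H₀: E[step] = 0,
with F = T²(n − p)/(p(n − 1)) referred to F(p, n − p). The (1 − α)
confidence region of the mean step vector has axes along the eigenvectors
of S with half-lengths `sqrt(λ_i · p(n−1)/(n(n−p)) · F_crit)`; in 2D a
91-point polyline is returned for plotting.

Two caveats are built into the interface:

* consecutive steps of one cell are autocorrelated (cells persist in
  direction over several frames), which inflates the type-I error of the
  pooled test. `step_spacing = k` keeps every (k+1)-th step per track; the
  default is 0 (all steps) with this documented warning, and
  `per_track = TRUE` offers the fully conservative variant that tests one
  mean step vector per cell;
* thin 3D imaging volumes make the z component of steps uninformative or
  the covariance ill-conditioned; `dim_select` tests a coordinate subset
  (for instance the xy projection). A singular covariance is an error
  advising exactly this.

`step_normal_angles()` tabulates per-step angles against a reference
direction, point or plane together with the distance of the step's start
to that reference. Under unbiased motion the expected angle is flat in
distance: 90° to a direction or point, and 180/π·(π/2 − 1) ≈ 32.70° to a
plane in 3D (the mean elevation of an isotropic direction). Localized
deviations expose drift, chemotaxis, or reflection at the imaging-volume
border.

## Feature maps and clustering

`feature_matrix()` evaluates a list of measures cell-based over a dataset.
Because motility features have incommensurate units (µm/min, degrees,
µm²), columns are standardized to mean 0/sd 1 *by default*; constant
columns are centered with a recorded zero scale, and the centering/scale
vectors are stored so the transform is reproducible. The unscaled mode is
retained for parity checks — the tests assert that changing one feature's
unit by 10³ leaves scaled PCA embeddings unchanged (up to sign) but does
change unscaled ones.

PCA is computed by `stats::prcomp` with a fixed sign convention (largest
loading per component is positive), making embeddings bit-reproducible;
MDS uses classical scaling on Euclidean distances. Clustering is average-
linkage hierarchical (fully deterministic; ties broken by the id-sorted
input order) or k-means with a recorded seed and restart count.
Nonlinear, stochastic embeddings (UMAP, t-SNE) are deliberately out of the
core: the exported feature matrix makes them trivial to apply externally
without tying the package to nondeterministic heavy dependencies.

## Simulators

All simulators are bit-reproducible given a seed, and
`simulate_tracks()` expands one root seed into per-track substreams (drawn
up front), so replicate sets are reproducible regardless of evaluation
order.

**Brownian.** Positions accumulate iid N(0, σ²I) increments plus an
optional deterministic drift per step; MSD(L) = dσ²L plus the drift's
quadratic term, so the per-axis diffusion coefficient is D = σ²/(2Δt).

**Bootstrap.** Step lengths and turning angles are drawn independently
with replacement from a reference dataset's empirical distributions and
chained: each new step keeps the previous heading rotated by the sampled
turning angle — about a uniformly random axis orthogonal to the heading in
3D, with a random sign in 2D — and scaled to the sampled length. This
preserves speed and turning statistics while destroying longer-range
correlations, which is exactly what makes it a useful null model.

**Stop-and-go (Beauchemin-type).** The cell alternates straight free runs
(speed `v_free`, duration `t_free`, direction uniform on the sphere) with
stationary pauses (`t_pause`), re-orienting at the end of each pause. The
defaults v_free = 18.8 µm/min, t_free = 2 min, t_pause = 0.5 min are the
model's published parameterization for T cells in lymph nodes; they are
defaults, not constants. Design choices that the model family leaves open,
resolved here as follows:

* *Pause behavior*: the cell is exactly stationary during pauses; turning
  happens at pause end. Observations sample the continuous piecewise-
  linear path exactly at multiples of `delta_t` (no snapping to phase
  boundaries).
* *Initialization*: by default the process starts time-stationary — the
  initial phase is free with probability t_free/(t_free + t_pause) and its
  remaining duration is uniform. (Drawing only the first phase's duration
  uniformly, without weighting the phase choice by duration, would leave a
  small non-stationary transient.) `stationary_start = FALSE` instead
  starts exactly at the beginning of a free run, which aligns phase
  boundaries with observations when `delta_t` divides the phase durations
  — useful for exact structural checks.
* *Directional bias*: a new direction is `normalize(u + p_bias·b)` with u
  uniform on the sphere and b the unit bias direction — exactly uniform at
  `p_bias = 0` and monotonically more aligned as it grows. This is one
  concrete, simple mechanism among several plausible ones; it is the
  package's choice, not a canonical definition.

Over times long against the cycle, displacements of successive cycles are
iid with magnitude v_free·t_free, so the MSD slope per unit time
approaches v_free²·t_free²/(t_free + t_pause) in any dimension
(equivalently M = v_free²t_free²/(6(t_free + t_pause)) in 3D). The
validation suite estimates this slope from non-overlapping 250-minute
windows (100-cycle windows make the finite-window bias ≈1%, while many
windows keep the Monte-Carlo error a few percent).

## MSD model fitting

`fit_msd()` least-squares fits a model MSD to an empirical curve over lags
up to `max_fit_lag`. Long lags should be excluded: within a finite imaging
window, long-lag MSD means are computed preferentially from cells that
stayed in view, biasing the curve downward. All fitted lags are weighted
equally by default; inverse-variance weighting (`n/var`) is available
because long-lag means rest on few subtracks, but it concentrates the fit
almost entirely on the shortest lags, which is not always wanted.

The Brownian model is linear through the origin (one parameter; the
reported D is slope/(2d), in closed form). The stop-and-go model has no
convenient closed form at lags comparable to t_free, so its MSD is
evaluated by forward simulation with *common random numbers* — the same
seed for every parameter evaluation, making the objective a deterministic,
smooth-enough function that `stats::optimize` (one free parameter) or
Nelder-Mead (several) can minimize; the asymptotic linear form is
available as a cheap alternative for long-lag fits. Free parameters
default to `v_free` only, the best-identified parameter of the three from
an MSD curve; t_free and t_pause trade off against each other and against
v_free near the asymptotic regime, so fitting all three from an MSD alone
is ill-posed and is left to the user's discretion.

## The synthetic-data generator

`generate_fixture()` emulates a typical two-photon migration experiment
with three labeled populations, chosen to echo lymph-node T cells
(stop-and-go defaults), B cells (slower: v_free = 6.5 µm/min, t_free = 1
min, t_pause = 1 min — lower speed and more turning per unit path), and
infection-recruited neutrophils (fast, v_free = 16 µm/min, and biased
toward the xy direction (1, −1) with `p_bias = 0.5` — detectable at 70
tracks per class without being trivial). Defaults: 3D, 70 tracks per
class, 40 frames at 0.4 min (24 s), starting positions uniform over a
400 × 400 × 60 µm volume (laterally wide, axially thin, as in two-photon
stacks), and iid Gaussian localization noise of 0.3 µm per coordinate.
The spec and seed are echoed with the dataset, and generation is fully
deterministic.

What the generator does *not* emulate — and therefore what passing tests
do not certify about real data: anisotropic z localization error,
fluorophore blinking and detection dropouts, track fragmentation and
identity switches from the tracker, cell–cell collisions and contact
interactions, confinement by tissue structures, cells entering/leaving the
imaging volume (no boundary effects at all), and heterogeneity of motility
parameters within a class. Methods validated here on clean synthetic
conditions still require the QC tools on real data — that is precisely why
the QC module exists.

`inject_duplicate()` reproduces the double-tracking artifact by appending
a Gaussian-noised copy of one track (same timestamps, fresh id), recording
the ground truth in attributes.

## Validation problem sizes

The test suite and the acceptance script size their simulations so the
whole run stays in the minutes range on one CPU: 10⁴ pooled steps for
isotropy calibration; 150–300 tracks for the MSD laws (stop-and-go slope
from 2400 independent 250-min windows); 1000 unbiased replicates for
type-I calibration of the directionality test and 200 replicates for
power at drift 0.5σ, n = 500 steps; 100 seeded fixture datasets for
duplicate recovery; the default 70-track-per-class fixture for the bias
and PCA class-separation checks; 100–200 tracks for fit recovery. Where a
statistic pools autocorrelated steps (fixture classes emit runs of
correlated steps), standard errors in the tests are computed across
tracks, the independent sampling units, not across pooled steps.

## Known limitations

* `pair_diagnostics()` is O(n²) in the number of tracks with an O(T)
  scan per pair; datasets of a few thousand tracks are fine, tens of
  thousands are not its design point.
* The Hotelling test assumes an approximately elliptical step
  distribution; heavy-tailed step distributions call for `per_track = TRUE`
  or heavier thinning.
* `fit_msd()` fits means only; it does not propagate the empirical
  curve's covariance between overlapping lags into parameter uncertainty,
  and reports no standard errors.
* Gap repair by interpolation assumes motion is well approximated as
  linear across the gap; for long gaps `split` is the safer default.
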