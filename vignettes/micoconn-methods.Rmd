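---
title: "Methods: microstructure-informed connectomes at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microstructure-informed connectomes at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, estimation choices and simulation
design behind `micoconn` — the assumptions each stage makes, the defaults
and why they were chosen, and what the synthetic-data tests do and do not
establish about real data.

## 1. The signal model

Each voxel's diffusion-weighted signal, normalized to the b = 0 intensity,
is a nonnegative mixture of three Gaussian compartments evaluated against
an acquisition scheme of b-values and unit gradient directions:

* **stick** (intra-axonal, fully restricted perpendicular to the axon):
  `S = exp(-b * d_par * (g·u)^2)`;
* **zeppelin** (hindered extra-axonal, axially symmetric tensor):
  `S = exp(-b * (d_perp + (d_par_zep - d_perp)(g·u)^2))`;
* **ball** (free/isotropic water): `S = exp(-b * d_iso)`.

Diffusivities are fixed, not estimated: `d_par = d_par_zep = 1.7e-3`
mm²/s, `d_perp = 0.61e-3` mm²/s, and two balls at `d_iso = 1.7e-3` and
`3.0e-3` mm²/s. The single printed perpendicular diffusivity belongs to
the zeppelin (a stick has none — the only consistent reading of the
stick-zeppelin-ball parameterization). The diffusivity *interval* for the
isotropic compartment is realized as two ball compartments, one at each
endpoint (hindered-isotropic and CSF-like), matching common usage of
multi-compartment deconvolution frameworks; an interval admits other
discretizations, so this is a package choice, stated here once.

The default acquisition scheme mirrors a strong-gradient multi-shell
protocol: b = 500, 1200, 2400, 4000, 6000 s/mm² with 30, 30, 60, 60, 60
directions plus 14 b = 0 volumes (254 volumes), at 2 mm isotropic voxels.
Directions are laid out on a golden-angle (Fibonacci) spiral per shell and
given a seeded random rotation: deterministic, approximately uniform, and
different per seed.

## 2. Phantom geometry and conditioning

Coordinates are continuous millimetres; voxel `(i, j, k)` (1-based) spans
the half-open box `[(i-1)v, iv) × …`. Streamlines are resampled at step
`v/10` and a segment belongs to the voxel containing its midpoint; the
approximation error of all length integrals is controlled by that step.

`make_crossing_phantom()` builds one streamline per discrete *lane*
(a distinct transverse voxel row), with bundles along orthogonal axes
sharing z-planes so that every covered voxel is a genuine crossing voxel.
This layout is deliberate: streamlines within a coherent bundle that share
their entire voxel support produce (near-)collinear operator columns and
an unidentifiable inverse problem — the known degeneracy of
streamline-level deconvolution. One-streamline-per-lane keeps each column's
support distinct (two crossing streamlines share exactly one voxel), so
the noiseless inverse problem has a unique solution and recovery error
measures solver correctness rather than phantom degeneracy. A gentle
sinusoidal bow (amplitude 0.25 voxel) keeps segment directions varying
without leaving the lane.

Ground-truth streamline fractions are drawn uniformly from [0.2, 0.7].
Each traversed voxel's remaining signal budget is filled with a ball
fraction (default 0.2, reduced if intra-axonal signal already approaches
1) and zeppelins taking 80% of what remains, oriented along each bundle's
length-weighted mean direction in the voxel and split across bundles by
their intra-axonal length shares. The b = 0 signal therefore equals the
voxel's total compartment fraction exactly — an invariant asserted to
1e-9 in the tests.

The optional *decoy* streamline runs through otherwise empty voxels with
true weight 0; it exercises implausible-streamline filtering (its
recovered weight must be numerically zero).

Noise: Gaussian, or Rician as the magnitude of a complex Gaussian
perturbation. Unit tests run noiseless (the oracle regime); integration
tests use Rician sigma = 0.02. The phantom noise level is a package
default chosen to resemble magnitude MR data, not a claim about any
particular acquisition's SNR.

## 3. The deconvolution operator and solver

Rows of the linear operator index (traversed voxel, acquisition volume)
pairs; columns are stick (one per streamline), zeppelin (per voxel, per
local bundle orientation, at most 3 per voxel by length share) and ball
(per voxel, per d_iso). A streamline's column accumulates per-segment
stick attenuations weighted by `segment length / total in-grid length`, so
a unit coefficient contributes unit b = 0 signal distributed along the
path and the recovered coefficient is a dimensionless signal fraction.
This column normalization is a stated contract of this package (reference
implementations differ in this convention, so the package pins its own). Zeppelin orientations come from the tractogram itself
(mean bundle direction per voxel) rather than from spherical-deconvolution
peaks, which are out of scope; this preserves the structure of the model
while keeping the stage self-contained.

Both the analytic phantom synthesis and the operator assembly integrate
per-segment stick kernels over the same segment table, but through
separate accumulation code paths — the round-trip test is a check of the
two syntheses against each other, not of code against itself.

The inverse problem `min ||Ax − y||², x ≥ 0` is solved on the normal
equations by block principal pivoting (Portugal–Júdice–Vicente): whole
blocks of primal/dual-infeasible variables are exchanged between active
and passive sets, with a single-index fallback when the infeasible count
stops shrinking, guaranteeing finite exact termination. The solver is
deterministic — no stochastic initialization — so identical inputs give
bit-identical weights. Tiny Cholesky ridge (1e-10 of the mean diagonal)
handles numerically singular passive blocks. Tests cross-check the
solution objective against an exhaustive passive-set enumeration oracle
(≤ 10 columns) and an independent reference implementation, and assert
noiseless phantom recovery to a relative error below 1e-3 (measured:
~1e-13). The filtering threshold defaults to 1e-10 — numerical zero for
double-precision NNLS — and is exposed for sensitivity analyses.

Problem sizes: the package targets desk-scale instances (≤ 10⁴
streamlines, ≤ 10³ voxels, a few thousand columns). The acceptance
phantom uses 2 bundles × 20 streamlines on a 10³-voxel grid with the full
254-volume scheme (~65k rows, ~950 columns), solving in seconds.

## 4. Connectomes and the atlas merge

Kept streamlines (weight above threshold, both endpoints assigned to
distinct ROIs) form bundles per unordered ROI pair, with edge weight

    a_ij = Σ_k x_k l_k / (Σ_k l_k / N_ij)

— the length-weighted total IASF normalized by mean bundle length. For
equal weights c this is exactly c·N_ij, which links the IASF weighting to
the conventional NOS weighting (also provided). Intra-ROI streamlines are
excluded (zero-diagonal invariant). Endpoints falling in background take
the nearest labelled voxel within 2 mm (one voxel) — tractography
termination relative to cortical labels always needs such a tolerance and
it is stated explicitly rather than left implicit.

The atlas merge assigns each fine parcel to the candidate network with
maximal voxel overlap within each subject, then retains a parcel only if
its modal assignment holds in ≥ 80% of subjects *and* its contralateral
homolog shares the same modal assignment; parcels overlapping no network
count as disagreeing. Overlap ties break to the smallest network id
(deterministic). The acceptance fixture reproduces a hand-computed
retain/discard list covering every rule.

## 5. Weighted network measures

* **Strength**: row sums of the weight matrix; mean strength averages
  nodes.
* **Global efficiency**: mean inverse shortest-path length over pairs,
  with lengths = 1/weight (the reference-toolbox convention; the source
  analyses do not state the transform, so it is pinned here).
  Disconnected pairs contribute 0, not exclusion.
* **Local efficiency**: global efficiency of the neighbour-induced
  subgraph (node excluded); 0 below 2 neighbours.
* **Clustering**: Onnela's geometric-mean triangle intensity with weights
  normalized by the graph's own maximum — per graph and per subnetwork,
  which makes the coefficient scale-free but subject-relative; stated
  because it affects cross-subject comparisons.
* **Modularity**: Newman spectral bisection of the generalized modularity
  matrix at resolution γ = 1, each split refined by Kernighan–Lin-style
  single-node sweeps until no move improves Q, recursing while a split
  increases Q. Eigenvector sign is fixed deterministically and zero
  entries join the positive block. On fixtures small enough for exhaustive
  partition enumeration (two disconnected triangles, rings of cliques) the
  algorithm attains the global optimum; in general spectral bisection is a
  heuristic and only local optimality is guaranteed.

Efficiency and clustering are validated against Floyd–Warshall and
triangle-enumeration brute force on 200 random ≤ 6-node graphs to 1e-10.
Scale behaviour (efficiency scales with weights; clustering does not) and
node-permutation invariance are asserted as properties.

## 6. Cohort simulation

`simulate_cohort()` generates subject records (age, sex, ICV, connectome)
whose within-network edge weights follow

    w = baseline + slope·(age − age_min) + sex_offset·[M]
        + age_sex_slope·(age − age_min)·[M] + subject_offset + N(0, sd),

truncated at zero, symmetrized, with a per-subject shared random offset.
Between-network edges carry a common baseline and noise but no programmed
effects. Age enters as `(age − age_min)` in *generation* so baselines are
interpretable at the youngest age; the statistical stage models raw age —
the slope is unaffected, and this asymmetry is documented to avoid
double-centering confusion.

Defaults emulate a developmental cohort design: n = 88, ages uniform on
8–19, 46 female, eight canonical cortical networks. Quantities that
design leaves open were fixed once as plausible for this kind of data and
never tuned: baseline
edge weight 0.3 within networks and 0.15 between, edge noise SD 0.05,
subject offset SD 0.02, edge presence probability 0.85 (so connection
density is a non-degenerate covariate), ICV lognormal around 1.45e6 mm³
(sdlog 0.1) with a male offset giving r ≈ 0.3 with sex — enough variance
for the covariate adjustments to be testable. Edge truncation at zero
(rather than resampling) is monotone and preserves the rank order of
programmed effects.

What the simulator does *not* emulate: empirical effect sizes of any
real cohort (those depend on data the package does not ship and are not
simulation targets), spatial autocorrelation of edges, heavy-tailed edge
noise, and any age–density coupling. Passing calibration and recovery
tests therefore establishes correctness of the statistical machinery under
the programmed generative model, not agreement with the developmental
cohort.

## 7. Statistical stage

**Mixed models.** For each network measure, four nested fixed-effect
structures — main effects (age + sex + network + ICV), + age:network,
+ age:sex, and the full age×network×sex — with a subject-level random
intercept, fitted by maximum likelihood so AICs are comparable; the
lowest AIC wins, ties to fewer parameters. The subject random intercept
is this package's choice: each subject contributes one row per network,
so independence across rows is implausible, and a subject intercept is
the minimal structure that acknowledges it. Interaction evidence is
reported by
likelihood-ratio tests against the base model (coefficient tables carry
Wald normal intervals); the p-value method is recorded in the fit
metadata. Singular (boundary) random-effect fits are treated as converged
— they occur by construction when the generative subject variance is
zero. ICV is standardized inside the fitting functions for numerical
hygiene.

**Per-network models.** OLS of the measure on age + sex + ICV within each
network, reporting adjusted R², the age p-value and a significance flag
at α = 0.005. No multiplicity correction beyond that fixed threshold, by
design. The density-covariate replication refits with connection density
added and reports flag changes; zero-variance covariates are dropped with
a warning.

**Calibration and power.** Under the null simulator the per-network age
test's type-I error rate across 8 networks × 1000 cohorts must lie in the
exact binomial 95% interval around 0.005. The 8 tests within a cohort
share the subject offset, but under the chosen defaults that offset
contributes ~10% of the metric variance, so the binomial reference is
adequate. The power harness programs a visual-network slope of 0.02/yr on
edge weights with edge noise SD 0.01 — a large, low-noise effect chosen a
priori as the "detectable regime" — and requires ≥ 95% detection of the
age×network interaction and ≥ 90% AIC selection of an
interaction-containing model over 200 replicates at n = 88.

**Elastic net.** Features (per-node local efficiency of one network) are
split 80:20 — stratified by age tertile by default so an 18-subject
validation set spans the age range; a plain random split is a flag —
z-scaled with training statistics only (the leakage-free default), and
fitted over the L1-ratio
grid {0.1, 0.5, 0.7, 0.9, 0.95, 0.99, 1} × 50 log-spaced penalties
spanning [1e-4, 10]·max|Xᵀy|/n, chosen by mean fivefold CV R². The
objective is `(1/2n)||y − β0 − Xβ||² + λ(ρ||β||₁ + (1−ρ)/2||β||₂²)`.
glmnet is the solver, but it internally standardizes the response by its
population SD, which silently rescales the ridge term relative to this
objective; the package therefore reparameterizes each call (fits y/s with
adjusted internal alpha and lambda and back-transforms) so the returned
coefficients are exact minimizers of the stated objective — verified by a
solver-independent subgradient (KKT) certificate required to be below
1e-6. Feature importance is the ranking by |β| with cumulative
absolute-weight shares.

## 8. Pipeline and reproducibility

`run_all()` chains every stage, writes each artifact (TCK tractogram,
NIfTI volumes, gradient tables, weights/connectome/metric/fit CSVs) and
emits a manifest of MD5 checksums, seeds and the package version. Every
stochastic stage takes an explicit seed, validated before any stage runs;
rerunning a config reproduces the artifacts byte-for-byte (the wall-clock
run log is excluded from the manifest). Stage failures abort with the
stage name, keeping partial outputs.

Problem sizes throughout the test suite (10³-voxel phantoms, 32-node
cohort connectomes, 1000/200/20-replicate harnesses) were chosen as the
smallest instances that still exercise every rule meaningfully.

## 9. Known limitations

* No whole-brain scale: the solver works on dense normal equations and is
  intended for ≤ 10⁴ streamlines, not 3-million-streamline tractograms.
* No tractography or spherical deconvolution; tractograms are consumed or
  synthesized, never reconstructed from signals.
* Spectral modularity guarantees only local optimality in general.
* The simulator's independence assumptions (edges, subjects) are idealized;
  calibration results transfer to real data only insofar as those hold.
* The lane-based phantom makes the inverse problem well-conditioned by
  construction; recovery accuracy on degenerate, densely overlapping real
  bundles is a property of the data, not certified by these tests.
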