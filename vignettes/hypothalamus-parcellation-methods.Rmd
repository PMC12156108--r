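---
title: "Methods: consensus-Louvain parcellation of hypothalamic connectivity"
author: "hypoparc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus-Louvain parcellation of hypothalamic connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`hypoparc` implements a data-driven functional parcellation of the human
hypothalamus from voxel-wise resting-state functional connectivity (FC),
together with its downstream cortical-coupling analysis.  The pipeline has
five scientific stages:

1. **Analysis voxel set.**  A probabilistic hypothalamus atlas is binarized
   at a probability threshold (default 20%, inclusive) after resampling to
   the functional resolution.  Within each functional run, voxels with
   excessive temporal variance — the signature of the adjacent third
   ventricle's pulsatile signal — are excluded *for that run only*.  The
   exclusion threshold is found automatically with the kneedle knee-point
   detector on the descending sorted-variance curve.  Per-run availability
   is tracked so that a voxel filtered from one run still contributes its
   other runs.
2. **Connectivity.**  Each run is residualised against an intercept,
   fmriprep-style nuisance regressors and a discrete-cosine basis
   implementing a high-pass filter (120 s cutoff: all cosines with period
   longer than the cutoff, `floor(2 * T * TR / cutoff)` regressors).
   Subject-level voxel-by-voxel Pearson correlations are computed on the
   concatenation of the runs in which *both* voxels of a pair are
   available, Fisher z-transformed (`atanh`), and averaged entrywise over
   subjects to a group FC matrix.
3. **Consensus parcellation.**  Louvain modularity optimisation is run 100
   times on the group FC graph (negative edges zeroed by default), each
   iteration with a different seeded node sweep order.  The proportion of
   iterations in which each voxel pair shares a community forms the
   co-assignment matrix; Louvain applied once to that matrix yields the
   final partition.  Per-community mean and 25th/75th-percentile
   co-assignment summarise the stability of the solution.
4. **Cortical coupling.**  Community-mean timeseries (availability
   respecting) are appended to the cortical parcel timeseries, giving a
   subject-level (360 + K)-node Fisher-z matrix.  The group-averaged
   cortical-by-community block (360 × K profile matrix) is clustered with
   seeded multi-restart k-means for k = 2..40; the Calinski–Harabasz (CH)
   index scores each k and the number of networks is selected from the
   CH-versus-k curve.
5. **Group statistics.**  Per subject and (network, community) cell, the
   mean Fisher z over the network's ROIs enters a 2 × K within-subject
   ANOVA with Greenhouse–Geisser-corrected degrees of freedom, LSD
   (uncorrected) post-hoc paired comparisons, and t-based 95% confidence
   intervals.

# The modularity objective and the Louvain implementation

The partition objective is Newman–Girvan weighted modularity
$$Q = \frac{1}{2m}\sum_{ij}\left[w_{ij} - \gamma\frac{k_i k_j}{2m}\right]
\delta(c_i, c_j),$$
with $2m$ the total weight, $k_i$ weighted degrees and resolution
$\gamma = 1$ by default (no resolution parameter is part of the study
design; the option is exposed).  The optimiser is the classical two-phase
Louvain heuristic, written from scratch: local moves visit nodes in a
seeded uniform random permutation per sweep and accept only strictly
positive gains (this guarantees termination); when a sweep makes no move
the graph is aggregated (community internal weight becomes a self-loop,
preserving degrees and $Q$) and the process repeats.  The returned
partition's `modularity` always equals `graph_modularity()` of its
assignment, and on small graphs the implementation is tested against an
exhaustive enumeration of all set partitions.

Standard modularity is undefined for signed graphs.  Negative Fisher-z
edges are zeroed before clustering (`negative_policy = "zero"`, the
dominant convention in FC parcellation); an absolute-value policy is
exposed for sensitivity analyses.  Entries that are missing after group
averaging (e.g. artifact voxels excluded from every run) are treated as
absent edges, and voxels with no usable edge at all are dropped from the
partition rather than being assigned arbitrarily.

Consensus seeds are derived as `rng_seed + iteration`, which is what makes
the 100 iterations non-degenerate while keeping the whole procedure
deterministic.  Final community labels are canonicalised by decreasing
size with ties broken by the smallest member node, so outputs are stable
across runs and platforms.

# Kneedle

`find_knee()` implements the kneedle detector: min–max normalise the
curve, transform it to a concave increasing curve (vertical flip for
convex curves, index reversal for the remaining decreasing cases), form
the difference curve $d = y_n - x_n$, and declare a knee at the first
local maximum of $d$ whose following values drop below
$d_{max} - S\,\overline{\Delta x}$ before the next local maximum.  The
sensitivity default is $S = 1$, the usual offline recommendation.
Detection is invariant to affine rescaling of either axis, and the set of
knees at larger $S$ is a subset of the candidates at smaller $S$.

Two uses differ in orientation:

* **Variance filtering** sorts voxel variances in descending order; the
  curve is decreasing and convex (a cliff of artifact variances followed
  by a long flat tail), and the knee lands on the first "clean" voxel.
  Voxels *strictly above* the knee are excluded.  If no knee qualifies —
  e.g. a constant-variance run — no voxel is excluded; that conservative
  default preserves data.
* **Cluster-number selection** treats the CH-versus-k curve as
  decreasing-concave (direction auto-detected).  This choice is
  deliberate: a profile matrix with well-separated planted clusters
  produces a CH curve that peaks at the first scanned k and decays
  roughly hyperbolically, and on such a curve a convex-decreasing kneedle
  can never return the first point (its normalised difference value is 0
  by construction — the geometric elbow of a hyperbola lies several k
  later).  Under the concave treatment such a curve has no qualifying
  knee, and the selection falls back to the maximum-index rule, which is
  the other selection convention in circulation for this analysis.  The
  two rules therefore agree whenever the index peaks at the scan start,
  and the one actually applied is recorded in `selection_method`.  Curves
  that genuinely flatten before dropping (concave decreasing) yield a
  real knee.

# The synthetic-data generator

High-field resting-state scans of the kind this analysis targets cannot be
bundled with a package, so the generator is a first-class module that
emulates the study conditions with known ground truth.  Defaults (`default_study_config()`):

| parameter | default | rationale |
|---|---|---|
| subjects | 104 | study sample size |
| run pattern | 91×3, 9×2, 4×1 runs | study missing-run pattern (295 runs) |
| timepoints/run | 300 | desk-scale while keeping correlation estimates stable |
| TR | 2.34 s | acquisition repetition time |
| voxel communities | 295/234/291/199 (1019 voxels) | the four community sizes of the reference parcellation |
| cortical ROIs | 360 in 2 networks of 180 | cortical atlas size; two-network solution |
| within / between community r | 0.40 / 0.15 | not reported for real data; chosen as realistic voxel-scale resting FC inside a small structure vs. across subregions |
| coupling z (network 1) | (.08, .16, .12, .12), mean .12 | network-1 marginal .12; "anterior" community strongest, "anteroventral-tuberal" weakest |
| coupling z (network 2) | (.00, .07, .02, .03), mean .03 | network-2 marginal .03, same ordering |
| subject coupling SD | 0.04 | between-subject SD of the planted coupling; yields network-marginal SDs near the reported .05/.03 |
| artifact voxels | 20 at 20× median variance | ventricle-like pulsation the variance filter targets |
| noise_sd | 1 | calibrated: empirical correlations equal the targets |

**Signal model.**  A voxel in community $c$ is
$x_v = \sqrt{b}\,g + \sqrt{w - b}\,f_c + \texttt{noise\_sd}\sqrt{1-w}\,e_v$
with global factor $g$, community factor $f_c$ and idiosyncratic noise
$e_v$, all i.i.d. standard normal per timepoint — the simplest
exchangeable block-covariance model consistent with a Pearson/Fisher-z
analysis (population correlation exactly $w$ within and $b$ between
communities at `noise_sd = 1`).  Artifact voxels are replaced by
independent noise at `artifact_variance_factor` times the clean variance:
high variance without structured signal, which is what the kneedle filter
targets.  Cortical ROI signals mix the standardised community mean signals
with weights $w_n = S^{-1}\rho_n$ (where $S$ is the closed-form
correlation matrix of the community means and $\rho_n = \tanh z_n$), so
the expected ROI–community Fisher z equals the planted target; a valid
construction requires $1 - \rho_n^\top S^{-1}\rho_n > 0$, and
configurations violating it are rejected.  A per-subject normal shift of
the coupling targets (SD `subject_coupling_sd`) models stable individual
differences, giving the coupling table realistic between-subject variance
for the ANOVA.  Confound tables (motion-like random walks and their
derivatives) are emitted for interface realism but are not mixed into the
signals; the regression stage therefore only spends degrees of freedom on
them.

**What the generator does not emulate** — and hence what passing tests do
*not* show about real data: hemodynamic autocorrelation, spatial smoothness
within communities, scanner drifts or physiology coupled to the signal,
non-Gaussian artifacts, registration error, and any uncertainty about the
*true* number of communities.  Tests against the generator establish that
the implementation recovers known structure under its stated model, not
that four communities exist in any particular brain.

# Numerical choices

* **Inclusive atlas threshold** (`>=`): "binarized at 20%" does not state
  strictness; inclusive matches common practice and is documented.
* **Pairwise-complete concatenation** for voxel pairs under per-run
  availability: maximises data use when a voxel is filtered from some runs
  only; equals plain `atanh(cor())` on availability-complete data (tested
  as an oracle equivalence).
* **Fisher clipping** at $|r| = 1 - 10^{-7}$ with a warning keeps
  degenerate pairs (identical series) finite; matrix diagonals are set to
  0, not $\operatorname{atanh}(1)$, because downstream graph algorithms
  need finite self-weights.
* **ROI extraction** uses the unweighted mean of available member voxels
  (field convention; median and count-weighted variants were considered
  and rejected for opacity).
* **k-means**: `stats::kmeans` with 50 seeded restarts per k, keeping the
  best within-cluster sum of squares.  Restarts are drawn sequentially
  from one RNG stream, so increasing the restart count can never worsen
  the kept solution.  (A k-means++ seeding rule was considered; with 50
  restarts on 360 × K profiles the standard sampler is equally stable and
  keeps the dependency surface to base R.)
* **Sphericity**: the reported corrected dfs in this design are non-integer
  with no correction named; Greenhouse–Geisser is the default (its
  epsilon, computed from the covariance of orthonormal within-subject
  contrasts, reproduces `car::Anova` to machine precision in the tests)
  and Huynh–Feldt is exposed.  A two-level factor has epsilon exactly 1.
  Fully degenerate effects (zero effect and zero error variance) report
  F = 0 rather than NaN.
* **Confidence intervals** are per-cell t-intervals on across-subject
  means, not within-subject (Loftus–Masson) intervals; the choice is
  documented because the design is within-subject.
* **Coordinates**: voxel ids encode 1-based grid indices; writers document
  0-based conventions where they apply; world coordinates go through the
  NIfTI affine.

# Problem sizes used by the test suite and acceptance script

Group-averaged FC stabilises quickly with subjects, so the voxel-level
stage (1019 voxels, planted sizes 295/234/291/199, 20 artifact voxels,
100-iteration consensus) is exercised with 6–8 subjects; the
cortical-coupling stage, which is cheap at ROI resolution, uses the full
104 subjects and 295 runs.  Unit tests use miniature studies (tens of
voxels, a handful of subjects).  These sizes are the package's own
desk-scale choices; all stage parameters (threshold 0.20, sensitivity 1,
high-pass 120 s, 100 iterations, resolution 1, k = 2..40) are the study
defaults.

# Known limitations

* Real-data mode performs the voxel-level parcellation stages from NIfTI
  runs and confound TSVs on a common grid; it does not do registration,
  motion correction or aCompCor extraction (it consumes already-extracted
  confounds), and it ends after the parcellation stage unless cortical ROI
  timeseries are supplied.
* Louvain is a greedy heuristic: on small unstructured graphs it can stop
  short of the global modularity optimum (the test suite requires the
  exhaustive-partition optimum on at least 18 of 20 random small graphs,
  never exceeding it).
* Signed-graph community detection is reduced to a negative-weight policy
  (zero or absolute value); no signed-null modularity is implemented.
* The consensus procedure re-clusters the raw co-assignment proportions
  without thresholding; strongly unstable solutions may merge under
  re-clustering.
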