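# hypoparc

Data-driven functional parcellation of the human hypothalamus from
voxel-wise resting-state functional connectivity, with the downstream
analysis of how the resulting subregions couple to cortical networks.

The hypothalamus is a small, heterogeneous subcortical structure whose
nuclei serve distinct regulatory functions, yet most fMRI work treats it as
a single blob. High-resolution resting-state data make it possible to ask,
voxel by voxel, whether its intrinsic connectivity splits it into
functional subregions — and how those subregions relate to the cortex.
`hypoparc` packages that analysis for anyone who wants to run it, stress
it, or re-use its pieces: methods researchers, and groups with co-registered
BOLD runs plus a probabilistic mask of a small structure.

## The method

1. **Voxel set** — binarize a probabilistic atlas at a threshold
   (default 20%), then exclude high-variance (ventricle-like) voxels *per
   run* using the kneedle knee-point of the sorted variance curve,
   tracking per-run voxel availability.
2. **Connectivity** — residualise each run against nuisance regressors and
   a discrete-cosine high-pass (120 s), compute subject-level voxel-wise
   Pearson correlations on pairwise-available concatenated runs, Fisher
   z-transform (`z = atanh(r)`), and average across subjects.
3. **Parcellation** — maximise Newman–Girvan modularity
   `Q = (1/2m) Σ_ij [w_ij − γ k_i k_j / 2m] δ(c_i, c_j)`
   with a from-scratch Louvain implementation, run 100 times with
   different seeded sweep orders; re-cluster the matrix of pairwise
   co-assignment proportions to obtain the consensus partition, with
   per-community stability summaries.
4. **Cortical coupling** — append community-mean timeseries to the 360
   cortical parcel timeseries, build subject 364×364 Fisher-z matrices,
   cluster cortical ROIs on their 360×4 coupling profiles with k-means
   scanning k = 2..40 under the Calinski–Harabasz index, and average
   Fisher z within (network, community) cells per subject.
5. **Statistics** — 2 (network) × 4 (community) repeated-measures ANOVA
   with Greenhouse–Geisser correction, LSD post-hoc paired tests and 95%
   confidence intervals.

A synthetic-data generator (`simulate_study()`) emulates the study design —
104 subjects with a 91×3/9×2/4×1 missing-run pattern (295 runs), 1019
mask voxels in four planted communities of 295/234/291/199, 360 cortical
ROIs in two networks with planted mean coupling z of .12 and .03, and
injected high-variance artifact voxels — so every stage is testable with
known ground truth and no scanner data.

## Worked example

A miniature study (10 subjects, 100 voxels in four planted communities,
40 cortical ROIs in two networks) through the whole pipeline:

```r
library(hypoparc)

sim <- simulation_config(
  n_subjects = 10, runs_per_subject = cbind(c(3, 2, 1), c(8, 1, 1)),
  n_timepoints_per_run = 120, community_sizes = c(30, 25, 20, 25),
  network_sizes = c(20, 20),
  network_coupling_z = rbind(c(0.08, 0.16, 0.12, 0.12),
                             c(0.00, 0.07, 0.02, 0.03)),
  subject_coupling_sd = 0.02, n_artifact_voxels = 5, rng_seed = 61)

res <- run_pipeline(pipeline_config(simulation = sim, out_dir = tempfile(),
                                    n_iterations = 25, k_max = 10,
                                    rng_seed = 61))
res$partition
#> <partition> 98 nodes in 4 communities, Q = 0.7300
res$stability
#>   community n_voxels mean_coassignment p25 p75 singleton
#> 1         1       29                 1   1   1     FALSE
#> 2         2       25                 1   1   1     FALSE
#> 3         3       25                 1   1   1     FALSE
#> 4         4       19                 1   1   1     FALSE
res$anova
#> Repeated-measures ANOVA (gg correction)
#>             effect      F df1_corr df2_corr epsilon        p
#>            network  40.70     1.00     9.00   1.000 1.28e-04
#>          community 137.13     1.82    16.34   0.605 1.01e-10
#>  network:community   6.64     2.15    19.31   0.715 5.61e-03
subset(res$summary, scope == "network")
#>      scope network community  n       mean         sd   ci_lower   ci_upper
#> 9  network      N1      <NA> 10 0.10947839 0.02210024 0.09366883 0.12528795
#> 10 network      N2      <NA> 10 0.03283901 0.02732650 0.01329080 0.05238721
```

Reading the output: the consensus partition finds exactly the four planted
communities (two artifact voxels were excluded from every run and are
dropped; the rest land with their block, co-assignment 1.0 across all 25
Louvain iterations). The profile clustering picks k = 2, and the coupling
table shows network 1 coupling to the communities around z ≈ .11 versus
z ≈ .03 for network 2 — the planted .12/.03 marginals attenuated slightly
by extraction noise at this miniature scale — with an overwhelming network
main effect, F(1, 9) = 40.7, p < .001.

Every stage also writes its artifacts (TSV matrices and tables, JSON
ground truth, a provenance manifest with md5 sums) under `out_dir`.
A thin command-line wrapper lives at `inst/cli/hypoparc.R`:

```sh
Rscript inst/cli/hypoparc.R run --out myrun --seed 7 --subjects 8 --iterations 100
```

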