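---
title: "Quantifying higher-order coordination in two-group methylomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying higher-order coordination in two-group methylomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epicoord)
```

## Why hypergraphs

A differential methylation analysis ranks CpG probes one at a time; a
network analysis models pairwise correlations. Neither captures the
situation this package targets: a *group* of differentially methylated
probes (DMPs) whose methylation co-varies with a much larger set of
background CpGs, i.e. a higher-order interaction. A hypergraph represents
this directly. DMPs are vertices; each background CpG that correlates
strongly with several DMPs defines a hyperedge joining them; the number of
CpGs two DMPs share (the *edge dimension*) measures how strongly the pair
is embedded in the coordinated structure.

The pipeline builds one hypergraph per group from the same DMP vertex list,
so case and control models differ only in which samples the correlations
are estimated from. Differences in the topology of the two hypergraphs —
summarized by the Shannon entropy of the edge-dimension distribution — are
then differences in how the *same* probes are coordinated, not in which
probes were selected.

## The pipeline and its parameters

| Stage | Parameter | Default | Meaning |
|---|---|---|---|
| DMP test | `alpha` | 1e-4 | BH FDR threshold for the significant set |
| DMR | `max_gap` | 300 bp | maximum gap between member probes |
| DMR | `min_probes` | 8 | "more than seven" probes per region, read strictly |
| DMR | `n_perm` | ≥ 100 | group-label permutations |
| Hypergraph | — | SD of pooled \|r\| | incidence cut-off, recomputed per matrix |
| Cluster | `min_size`, `k_max`, `trim` | 10, 10, 0.9 | central-cluster extraction (below) |
| Peripheral | `fraction` | 0.95 | strict: a CpG tied to exactly 95% is excluded |
| Entropy null | `subset_size`, `n_iter` | 100, 1000 | random-CpG pseudo-DMP draws |
| Pathway | `n_graphs`, `n_resample`, `ci` | 100, 10000, 0.89 | bootstrap hypergraphs, posterior resamples, credible level |
| Silencing | `z_threshold` | 2 | \|Z\| cut for a direct edge |
| cis/trans | `window` | 1 Mb | strict: exactly 1,000,000 bp is trans |

All sample standard deviations use the n−1 denominator, one convention
throughout (z-scoring, the incidence cut-off, Z-scores of silenced scores).

### Differential stages

The per-probe test is the two-group ordinary least-squares fit, identical to
a pooled-variance t-test; effects are case minus control, and `hyper` means
a positive effect. `bh_adjust()` implements the Benjamini–Hochberg step-up
closed form directly and is verified in the tests against both a brute-force
definitional oracle and `stats::p.adjust`.

The DMR statistic is the sum of member effects, which rewards both run
length and magnitude. Permutation p-values pool all candidate regions found
under label permutations and use +1 smoothing in numerator and denominator,
so no region can receive p = 0 at finite `n_perm`; the FWER compares each
observed region against the per-permutation maximum statistic. Two
properties of this estimator are worth knowing. First, when a permutation
yields no candidate region it contributes a maximum statistic of 0 (this is
what makes a strongly planted region's FWER small). Second, if the
permutations yield very few regions in total, the pooled p-value estimate
degrades toward 1 while the FWER stays informative — so the FWER, not p, is
the primary decision statistic, and the uniformity of p is only guaranteed
in regimes where permuted regions are plentiful. Candidate selection can be
switched from BH q-values to raw p-values (`select_by = "p"`) for
calibration studies, because under a global null BH admits no probes at all
and no candidate regions exist to calibrate against.

### Central-cluster extraction

The clustering rule is deliberately simple and seed-free so that reruns are
identical: average-linkage hierarchical clustering of Euclidean distances
between adjacency rows, cut at the *smallest* k (scanning k = 2 … `k_max`)
at which any cluster reaches `min_size`; among qualifying clusters at that
cut the one with the largest mean internal edge dimension is selected.
Stopping at the shallowest qualifying cut matters: scanning all cuts for a
global score maximum instead tends to return ever-tighter sub-blocks of the
coordinated cluster, because the mean internal dimension of a subset of a
saturated block is always at least that of the block. On simulated data
with a planted 100-DMP block the shallow-cut rule recovers the block with
Jaccard ≥ 0.94 across conditions, where the global-maximum rule collapses
to ~20-member sub-blocks in a substantial fraction of runs.

The selected cluster is then trimmed: members whose mean edge dimension to
the rest of the cluster is below `trim` (default 0.9) of the cluster's mean
internal dimension are dropped iteratively, never below `min_size`. This
enforces the cluster's defining property — vertices connected by a large
number of hyperedges — and prevents a fringe of weakly attached DMPs
(common when correlations are estimated from few samples) from diluting the
edge-dimension distribution that the entropy stage consumes.

If every off-diagonal entry of the adjacency is equal there is no structure
to refine, and the full vertex set is returned rather than an arbitrary
subset.

### Entropy and its nulls

Entropy is computed on the empirical distribution over the *distinct
integer* edge dimensions of the cluster's pairs, with no binning:
dimensions are counts, and binning would introduce a tuning parameter the
statistic does not need. The random-CpG null rebuilds the entire
construction — correlation, SD-of-|r| cut, adjacency — per iteration with
`subset_size` randomly drawn background CpGs as pseudo-vertices. The
empirical p is one-sided toward low entropy (the direction that indicates
more ordered coordination), +1-smoothed; a two-sided variant is a flag.
The null draws from the non-DMP background only, since drawing DMPs into
their own null would contaminate it with planted signal.

The pathway comparison builds `n_graphs` hypergraphs per group from
bootstrap subsets (80% of the pathway's mapped CpGs, drawn without
replacement) and forms the posterior difference as differences of means of
`n_resample` bootstrap resamples of each group's entropy list; a pathway is
significant when the equal-tailed 89% credible interval excludes zero. A
limitation is inherited from the procedure itself: the interval reflects
hypergraph-iteration variability only. All graphs of a group share that
group's sample draw, so group-level sampling noise shifts a group's whole
entropy list coherently and is invisible to the interval; with small,
disjoint sample sets the comparison is therefore anti-conservative. The
package's calibration test constructs the null so that both entropy lists
come from the same samples, which isolates the part of the procedure the
interval can honestly claim to calibrate; pathway flags on real two-group
data should be read as descriptive rankings rather than error-controlled
tests.

### Silencing

`silence_network()` implements the global silencing closed form
S = (G − I + D((G − I)·G))·G⁻¹, where D(·) zeroes off-diagonal entries.
The matrix silenced is the per-group Pearson correlation among
central-cluster DMPs — a unit-diagonal, correlation-like G, which is what
the transform assumes; normalizing the integer adjacency by its diagonal is
available as an alternative input but is not the default. For 2×2 inputs
the transform returns G's off-diagonal exactly and the suppression of
indirect chain associations is checked numerically in the tests. The
diagonal of S is exactly zero only in the 2×2 case; it is never interpreted
— Z-scores are computed from off-diagonal entries alone, after symmetrizing
S by averaging with its transpose. When G is near-singular (always true
when cluster size exceeds the group's sample count), the Moore–Penrose
generalized inverse is used and the event logged; this is deterministic and
parameter-free, unlike ridge damping.

## The synthetic methylome generator

`simulate_methylome()` draws, for sample *i* and probe *j*,

m_ij = μ_j + δ_j·g_i + s_g(i) · Σ_k λ_jk f_ik + ε_ij

with baseline μ_j ~ N(0, 2), δ_j = ±`dmp_effect` at planted DMPs, shared
latent factors f ~ N(0, 1), binary loadings λ linking the coordinated DMP
block and the hyperedge CpGs to the factors, per-group strength s_g, and
noise ε ~ N(0, `noise_sd`). Beta values are logistic(m·ln 2), making the
base-2 logit transform the exact inverse — transform round-trips are tested
to 1e-9. One master seed drives separate annotation, methylome and
downstream streams, so the annotation is reproducible without replaying the
value draws.

The default study conditions are 22 cases vs 138 controls; 3,000 probes of
which 200 are DMPs (two of them realized as 8-probe runs at 250 bp spacing,
the planted DMRs); a coordinated block of 100 DMPs sharing one dominant
latent factor with 1,500 hyperedge CpGs; effect 2 M-units; unit noise;
loading 2 in cases vs 0.6 in controls.

Two of these choices deserve their rationale spelled out:

* **One dominant factor, hyperedge CpGs a majority of the background.** The
  method refines a single primary cluster, so the generator plants one; and
  real methylomes are pervasively correlated — a background dominated by
  independent probes is the unrealistic extreme. Multi-factor structure is
  available (`n_factors`, used by the NMF validation tests to plant two
  blocks) but is not the default.
* **Asymmetric loadings (2 vs 0.6) rather than proportional ones.** The
  generator's purpose includes reproducing the direction of the group
  differences in entropy and |r| under the *unbalanced* 22/138 design. With
  22 samples the null sampling distribution of |r| is wide
  (SD ≈ 1/√21 ≈ 0.22), so the case incidence matrix unavoidably retains a
  substantial fraction of noise entries, and the dispersion they add to the
  edge dimensions would dominate any proportional increase in loading —
  scanning case loadings up to 3 at a noise-dominated background never
  flips the direction. The regime in which the stated mechanism operates is
  the one planted: case correlations saturate the SD-of-|r| cut-off
  (retention ≈ 1, concentrated dimensions, low entropy) while control
  correlations sit near their own cut-off (partial, variable retention,
  dispersed dimensions, higher entropy). This is a statement about where
  the method's observable lives, and it is the main caveat for interpreting
  the simulation: passing tests show the pipeline recovers planted
  structure and directions in this regime, not that real methylomes are in
  it.

Other things the generator does not emulate: array chemistry (dye bias,
probe-type effects), detection-p masking (accepted as precomputed masks),
realistic per-chromosome probe densities, and correlated baseline noise.

## Numerical and degenerate-input choices

* Beta clipping at ε = 1e-6 before the logit keeps boundary values finite
  without moving interior points.
* Covariate adjustment centers covariates and drops columns constant after
  centering (they are the intercept); rank deficiency among the remaining
  columns is an error, not a silent pseudo-inverse.
* Constant probe rows: dropped with a report at z-scoring; correlations of
  constant rows are set to 0 with a logged count rather than propagating
  NA.
* `binarize_incidence` errors when the SD of |r| is zero — a degenerate
  correlation structure the method cannot binarize meaningfully.
* Permutation p-values and entropy null p-values are +1-smoothed; fully
  empty contingency tables report Fisher p = 1 with a warning.
* The NMF uses |r| (not a minimum shift) so magnitude semantics match the
  hypergraph's use of |r|; rank defaults to 2 (coordinated vs not),
  multiplicative updates stop at a relative objective change below 1e-6 or
  500 iterations, and the objective trace is returned so non-monotonicity
  would be visible.

## Problem sizes used by the tests

The test suite and the acceptance script run entirely on simulated data at
desk scale: 300–3,000 probes, 40–160 samples, 200 permutations, 50
calibration replicates, 100 bootstrap hypergraphs per group with a
capped correlation background (the cap is a documented argument,
`max_background`). These sizes were chosen so the full suite completes in a
few minutes while every statistical check retains its discriminating power;
the algorithms themselves have no scale-specific branches, and the
correlation stages are plain matrix products that scale to array-sized
data.

## Interfaces

Every module works on plain R objects (matrices, data.frames) with TSV /
CSV / GMT / JSON / YAML serialization helpers, and `run_full_analysis()`
orchestrates the stages from a single `run_config()` whose resolved values
are echoed into the run manifest for audit. The package is driven from R
(or `Rscript` one-liners over these functions); `scripts/acceptance.R` is a
worked example of scripting the full pipeline.

## Known limitations

* The incidence cut-off (SD of |r|) adapts to the matrix at hand; two
  groups with different sample sizes get different cut-offs, which is part
  of the method, but it means incidence densities are not directly
  comparable across groups — only derived, within-group quantities are.
* The pathway credible interval calibrates hypergraph-iteration noise only
  (see above).
* Entropy on distinct integer dimensions grows with cluster size and
  background size; compare entropies only between hypergraphs built over
  the same vertex list and background pool.
* The silencing transform assumes the observed matrix is well approximated
  by direct effects plus first-order indirect paths; for clusters larger
  than the group's sample count the correlation matrix is rank-deficient
  and the generalized-inverse scores should be read comparatively, not as
  calibrated effect sizes.
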