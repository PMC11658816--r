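# epicoord

Higher-order coordination analysis of DNA methylation with hypergraph
models.

Differential analysis treats every CpG probe independently, and region
calling only rescues probes that happen to sit next to each other; in a
typical two-group methylation study most significant probes belong to
neither category. `epicoord` is for epigenomics researchers who want to ask
the complementary question: *how are the differentially methylated probes
coordinated with each other and with the rest of the methylome, and does
that coordination differ between groups?*

## The model

Starting from a probes × samples matrix of beta values with case/control
labels, the pipeline is:

1. **Preprocessing** — probe harmonization across arrays, exclusion-flag and
   sex-chromosome filtering, the base-2 logit transform
   *M* = log₂(β / (1 − β)), optional covariate regression (e.g. cell-type
   proportions), and per-probe z-scoring.
2. **Differential methylation** — per-probe two-group linear models
   (pooled-variance t) with Benjamini–Hochberg control; DMPs at FDR < 10⁻⁴.
   DMRs are maximal runs of ≥ 8 DMPs with inter-probe gaps ≤ 300 bp, scored
   by the sum of member effects against a group-label permutation null
   (smoothed permutation p and family-wise error rate from the per-permutation
   maximum).
3. **Hypergraph construction** — per group, the correlation matrix **R**
   between DMPs and all remaining CpGs is binarized at a cut-off equal to
   the standard deviation of |r|, giving the incidence matrix **M** of a
   hypergraph whose vertices are DMPs and whose hyperedges are the CpGs
   they share. **A** = **M**·**Mᵗ** counts the shared correlations of every
   DMP pair (the *edge dimension*). Hierarchical clustering of **A** refines
   the *central cluster* of coordinated DMPs, and CpGs connected to > 95% of
   the cluster are its *peripheral* (indirectly co-regulated) CpGs.
4. **Coordination** — Shannon entropy of the central cluster's
   edge-dimension distribution, H = −Σ p·log₂ p, compared against 1,000
   hypergraphs of randomly drawn CpGs, and, per pathway, a Bayesian
   bootstrap comparison (100 hypergraphs per group, 10,000 resamples, 89%
   credible interval) of entropy between groups.
5. **Network silencing** — direct associations are separated from indirect
   ones with the global silencing transform
   S = (G − I + D((G − I)·G))·G⁻¹ (Barzel–Barabási); off-diagonal scores
   are z-scored, edges with |Z| > 2 are kept, and classified *cis*
   (< 1 Mb, same chromosome) or *trans*.
6. **Validation** — NMF clustering of |R| (multiplicative updates) as an
   independent check of the central cluster, and a hypergeometric gene-set
   over-representation test over GMT collections.

A latent-factor simulator (`simulation_config()`, `simulate_methylome()`)
generates two-group methylomes with planted DMPs, DMR runs, and a
coordinated DMP block sharing hyperedge CpGs, returning full ground truth,
so the whole pipeline is testable end to end without external data.

## Worked example

```r
library(epicoord)

cfg <- simulation_config(seed = 42)     # 22 cases vs 138 controls
sim <- simulate_methylome(generate_probe_annotation(cfg), cfg)
sim$dataset
#> MethylationDataset: 3000 probes x 160 samples (22 case / 138 control), scale = beta

ds   <- zscore_normalize(beta_to_m(filter_probes(sim$dataset)))
dmps <- test_dmps(ds, alpha = 1e-4)
sum(dmps$significant)
#> [1] 196

regions <- find_candidate_regions(dmps, ds$annotation)
dmrs <- permutation_region_test(ds, regions, n_perm = 200, seed = 42)
dmrs[, c("chromosome", "start", "end", "n_probes", "value", "fwer")]
#>   chromosome start    end n_probes     value        fwer
#> 2       chr2 2e+05 201750        8 -13.77552 0.004975124
#> 1       chr1 1e+05 101750        8  12.55951 0.004975124

verts <- dmps$probe_id[dmps$significant]
for (g in c("case", "control")) {
  R  <- bipartite_correlation(ds, verts, group = g)
  M  <- binarize_incidence(R)
  A  <- adjacency_from_incidence(M)
  cl <- extract_central_cluster(A, min_size = 10)
  H  <- shannon_entropy(edge_dimension_distribution(A, cl$members))
  cat(sprintf("%s: cluster of %d DMPs, %d peripheral CpGs, entropy %.2f bits\n",
              g, length(cl$members), length(refine_peripheral_cpgs(M, cl)), H))
}
#> case: cluster of 98 DMPs, 1528 peripheral CpGs, entropy 5.82 bits
#> control: cluster of 95 DMPs, 1460 peripheral CpGs, entropy 6.55 bits
```

Both planted DMR runs are recovered at FWER < 0.01. The hypergraphs of the
two groups contain nearly the same central cluster, but the case group —
simulated with stronger coordination — shows more peripheral CpGs and a
lower edge-dimension entropy: a more ordered coordination structure, despite
its correlations being estimated from far fewer samples.

`run_full_analysis(run_config(seed = 1), out_dir = "run1")` executes every
stage with one configuration and writes stage outputs plus a JSON manifest
echoing every threshold applied. YAML configurations are read with
`read_run_config()`.

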