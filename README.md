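# ssrclust

SSR genotype analysis for germplasm collections.

Curators of clonally propagated crop collections (apple, grape, olive, …)
genotype thousands of accessions with a shared panel of co-dominant
microsatellite (SSR) markers and then face the same sequence of questions:
which accessions are the same cultivar under different names, which profiles
are triploid, how much allelic diversity the unique genotypes hold, how the
material is structured into genepools, how differentiated those genepools
are, and which accessions form parent-pair/offspring trios. `ssrclust`
implements that entire workflow as composable, tested R functions, together
with a synthetic-collection generator so every stage can be verified against
a known truth.

## The statistics at the core

* **Duplicate resolution** — two diploid profiles are the same genotype if
  they are identical or differ by one allele copy at ≤ 2 loci (no locus
  fully disjoint); duplicate groups are transitive closures of that
  relation. Match confidence is qualified by the probability of identity
  \(P_{ID} = \sum_i p_i^4 + \sum_{i<j}(2p_ip_j)^2\), multiplied over loci.
* **Diversity** — allele counts, rare alleles (< 5 % and < 1 %), effective
  alleles \(N_E = 1/\sum p_i^2\), observed and Nei-corrected expected
  heterozygosity, private/unique alleles, and hypergeometric rarefied
  allelic richness \(A_R(g)=\sum_i[1-\binom{N-N_i}{g}/\binom{N}{g}]\).
* **Structure** — a from-scratch MCMC sampler for the Bayesian admixture
  model with correlated allele frequencies (F-model), replicate-run
  alignment, Evanno
  \(\Delta K = |L(K{+}1)-2L(K)+L(K{-}1)|/\mathrm{sd}(L(K))\) model choice,
  \(q_I \ge 0.80\) / \(< 0.55\) assignment thresholds, and nested
  substructure analysis within each genepool.
* **Differentiation** — multi-allelic Weir–Cockerham θ (ratio of summed
  variance components) and a two-level AMOVA on the 0/1 allelic distance,
  both with individual-level permutation tests.
* **Ordination/trees** — simple-matching dissimilarity, principal
  coordinate analysis, and a neighbor-joining tree with Newick export.
* **Parentage** — trio-only LOD scores with a genotyping-error model,
  Delta (best-vs-second LOD gap), simulation-calibrated 95 % confidence,
  and a ≤ 1 locus mismatch cap.

## Worked example

```r
library(ssrclust)

# a synthetic collection: 3 genepools x 40 accessions, clones, triploids
cfg <- sim_config(n_groups = 3, n_per_group = 40, drift = 0.07,
                  clone_groups = 5, triploid_fraction = 0.05, seed = 7)
sim <- simulate_germplasm(cfg)

res <- run_full_analysis(sim$table, k_range = 1:4, profile = "desk", seed = 7)
#> dedup: 134 input, 6 triploid excluded, 14 redundant removed,
#>        114 unique diploid genotypes
#> structure: selected K = 3; 103/114 strongly assigned

res$structure$delta_k
#>       k n_runs mean_lnpd sd_lnpd lprime lsecond delta_k
#>   1     1      3    -6852.   0.243   NA      NA     NA
#>   2     2      3    -6639.   7.42   213.     40.7    5.49
#>   3     3      3    -6467.   8.09   172.    218.    26.9
#>   4     4      3    -6513.   6.03   -45.5    NA     NA
#> selected K (max delta-K): 3

res$fst
#>   group1 group2    fst fst_clamped p_value    n1    n2
#> 1 K1     K2     0.0660      0.0660   0.005    35    40
#> 2 K1     K3     0.0516      0.0516   0.005    35    39
#> 3 K2     K3     0.0593      0.0593   0.005    40    39

res$cumulative_pid
#> [1] 5.01e-20
```

Reading those numbers: the collection of 134 accessions reduces to 114
unique diploid genotypes after removing 6 putative triploids and 14 clonal
redundancies; the ΔK profile peaks unambiguously at K = 3, matching the
three simulated genepools, with 103 genotypes strongly assigned
(qI ≥ 0.80); pairwise F_ST between the inferred groups is 0.05–0.07 with
permutation p = 0.005 (199 permutations); and a cumulative probability of
identity of 5×10⁻²⁰ means two unrelated genotypes essentially never share a
full 16-locus profile, so the duplicate groups are trustworthy.

Each stage is also available on its own (`find_duplicate_groups()`,
`diversity_stats()`, `structure_sweep()` + `delta_k()` + `assign_groups()`,
`nested_structure()`, `amova()`, `pairwise_fst()`, `pcoa()`,
`neighbor_joining()`, `calibrate_confidence()` + `infer_trios()`), returns
tibbles or objects with `tidy()`/`glance()` methods, and plots via
`autoplot()`.

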