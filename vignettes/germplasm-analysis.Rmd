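---
title: "Methods: SSR germplasm analysis with ssrclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SSR germplasm analysis with ssrclust}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrclust)
```

`ssrclust` implements the statistical workflow used to characterize large,
multi-collection plant germplasm panels genotyped with co-dominant
microsatellite (SSR) markers: resolving clonal redundancy, describing
diversity, inferring genepool structure with a Bayesian admixture model,
quantifying differentiation, and reconstructing parent-pair/offspring trios.
This vignette explains the models, the tunable parameters, the numerical
choices, and what the synthetic-data generator does and does not emulate.

## Data model

A `genotype_tbl` is a tibble with one row per accession and one list-column
per locus holding 0–3 sorted integer allele sizes (base pairs). An empty
vector is a missing call; homozygotes carry two identical copies so diploid
calls always contain exactly two gene copies, which keeps all frequency
arithmetic uniform. Profiles with triallelic calls are retained in the
container but excluded from strictly diploid computations.

Because fragment sizes scored in different laboratories are typically offset
by a constant number of base pairs per locus, `harmonize_allele_sizes()`
estimates one integer offset per locus as the **mode** of the pairwise size
differences over reference accessions genotyped in both collections. The
mode, not the mean, is used because inter-platform offsets are integer and
constant; loci whose differences are not constant are flagged as unresolved
in the report while the modal shift is still applied, which makes the
procedure idempotent. The exact mechanics of cross-laboratory adjustment are
not standardized in practice; this modal-offset rule is this package's
documented procedure.

## Duplicate and ploidy resolution

Two diploid profiles are the same genotype when, over loci scored in both,
they are identical or differ by a single allele copy at no more than two
loci with no locus fully disjoint — a tolerance that absorbs occasional
scoring slips and spontaneous SSR mutations. "One allelic difference" is
defined as a multiset intersection of size one at that locus; a locus where
the two genotypes share no copy disqualifies the pair outright. Duplicate
groups are the connected components of the pairwise-duplicate graph, so
membership is transitive even when two distant members exceed the pairwise
tolerance; this matches the partition semantics of duplicate group codes
used in germplasm curation. The lexicographically smallest accession id is
the group representative, for determinism. Pairs sharing fewer than 12 of 16
loci (75 %) are deemed incomparable — collections discard profiles with
excessive missing data without a universal threshold, and 75 % is this
package's default. Accessions with three distinct alleles at three or more
loci are flagged putative triploids and excluded before grouping by default.

The probability of identity
$P_{ID} = \sum_i p_i^4 + \sum_{i<j} (2 p_i p_j)^2$, multiplied across
independent loci, qualifies the confidence of duplicate matches: with ~16
informative SSRs it is typically below $10^{-15}$, so identical profiles are
essentially never coincidental.

## Diversity statistics

Per locus and group the package reports allele counts ($N_A$), rare alleles
(frequency strictly below 5 %, with a 1 % column as well), effective alleles
($N_E = 1/\sum p_i^2$), observed heterozygosity, and expected heterozygosity
with Nei's small-sample correction $\frac{N}{N-1}(1-\sum p_i^2)$ — the
convention of the SPAGeDi/FSTAT family of programs; the uncorrected gene
diversity is exposed alongside since either convention may be wanted.
Allelic richness is hypergeometric rarefaction on gene copies (not
individuals), $A_R(g) = \sum_i [1 - \binom{N-N_i}{g}/\binom{N}{g}]$, scaled
by default to the smallest group-by-locus copy count so group comparisons
are size-unbiased. Ties at exactly the 5 % threshold are classified as
non-rare (strictly-below rule).

Frequent-allele composition is compared across groups per locus with a
Pearson chi-square test; alleles at or below the frequency threshold are
pooled into one column to stabilize expected counts, and if any expected
cell still falls below 1 a Monte-Carlo p-value (10,000 table simulations)
replaces the asymptotic one.

## The admixture model

`run_admixture_mcmc()` is a from-scratch Gibbs/Metropolis sampler for the
Bayesian admixture model with **correlated allele frequencies**. Each
individual $i$ has ancestry proportions $q_i$ on the $K$-simplex with a
symmetric Dirichlet($\alpha$) prior; each allele copy carries a latent
cluster of origin $z$; cluster $k$'s allele frequencies at each locus follow
an F-model, Dirichlet centred on inferred ancestral frequencies with
variance controlled by a cluster-specific drift $F_k$:
$p_{k\ell} \sim \mathrm{Dir}\!\big(p^A_\ell (1-F_k)/F_k\big)$.
Updates: $z$ by exact Gibbs; $q_i \sim \mathrm{Dir}(\alpha + n_{ik})$;
$p_{k\ell}$ by its conjugate Dirichlet posterior; the ancestral frequencies
by a Metropolis move that transfers mass between two random alleles
(uniform step, width 0.05); $F_k$ by a Gaussian random walk (step 0.01,
prior $\mathcal N(0.01, 0.05^2)$ truncated to $(0,1)$); and $\alpha$ by a
uniform-window Metropolis step of half-width 0.025 with $\lambda = 1$ for
the ancestral prior. Missing alleles are skipped in the likelihood. All
randomness flows through R's RNG, so a run is bit-reproducible given its
seed; replicate-run and nested-analysis seeds are derived deterministically
from one master seed.

The model evidence proxy is the familiar
$\ln \hat P(D) = \overline{\ln L} - \mathrm{Var}(\ln L)/2$ over post-burn-in
samples. The log-likelihood is evaluated at **every** post-burn-in
iteration, not only at thinned samples: the variance penalty is the noisiest
ingredient of $\ln \hat P(D)$, and a full-resolution variance markedly
stabilizes the run-to-run spread that the ΔK denominator depends on.

Two chain profiles are named: `desk` (2,000 burn-in, 10,000 iterations,
3 replicate runs) for interactive work and the test suite, and `paper`
(200,000/500,000, 10 runs) matching the chain lengths customary in
full-scale germplasm surveys. Tests never run the paper profile.

### Model choice and assignment

`delta_k()` implements the Evanno second-difference statistic
$\Delta K = |L(K{+}1) - 2L(K) + L(K{-}1)| / \mathrm{sd}(L(K))$ over
replicate runs, defined for interior K; the selected K is its argmax. The
full table is exposed rather than any automatic secondary-peak rule —
secondary peaks are a judgement call best left to the analyst. With only a
few replicate runs ΔK is intrinsically noisy; more runs sharpen the sd
estimates.

Replicate runs are aligned before averaging because cluster labels are
arbitrary per run: `align_runs()` searches permutations (exhaustive up to
$K = 8$, greedy beyond) maximizing similarity to the first run. Individuals
are assigned to their argmax cluster (ties broken toward the lowest index);
an assignment is *strong* at $q_I \ge 0.80$ and *unambiguously admixed*
below 0.55, the conventional thresholds. `nested_structure()` re-runs the
sweep inside each top-level group — including admixed members, placed with
their argmax group, so the nested level re-analyzes every genotype — and
skips groups below 25 members, where a further split is rarely supported.

## Differentiation

`wc_theta()` is the multi-allelic Weir–Cockerham (1984) θ with the
among-population, between-individual and within-individual components
summed over alleles and loci before taking the ratio (a ratio of sums, not
a mean of per-locus ratios). `amova()` performs a two-level analysis of
molecular variance on allele copies under the infinite-allele 0/1 distance
(fragment-size differences carry no weight, the non-stepwise treatment
appropriate for SSR panels scored across labs). Significance comes from
permuting individuals — both allele copies move together — with the +1
correction, 999 permutations by default. Negative variance components are
reported as computed with the percentage clamped at zero, mirroring common
AMOVA practice. The haploid-copy AMOVA Φ and the diploid θ estimate the
same quantity and agree to $O(1/n)$; they differ in finite samples because
one weighs individuals and the other gene copies.

## Ordination and trees

The simple-matching dissimilarity between two profiles is one minus the
mean per-locus fraction of shared allele copies (multiset overlap over
ploidy 2), computed over loci scored in both — the Darwin convention for
co-dominant data. PCoA is classical double-centred scaling; negative
eigenvalues are reported, not silently corrected (a Cailliez option
exists), and axes are returned for positive eigenvalues only. The
neighbor-joining tree uses the standard Saitou–Nei agglomeration (via
`ape`); negative branch lengths are clamped to zero for Newick
serialization with raw values retained.

## Trio parentage

Only two-parent (trio) relationships are scored: single-parent inference is
deliberately excluded because the unconstrained second parent makes
assignments speculative with a 16-locus panel. The per-locus likelihood
ratio compares Mendelian transmission from a candidate pair against a
random Hardy–Weinberg draw, with a genotyping-error mixture: with
probability $E = 1-(1-e)^2$ the offspring genotype is treated as a random
population draw ($e$ is the per-allele error rate, default 0.01). At
$e = 0$ a Mendelian-impossible locus drives the LOD to $-\infty$; the
mismatch count is always the number of loci impossible at $e = 0$, and
accepted trios tolerate at most one such locus. Parent pairs are unordered
— co-dominant markers cannot tell seed from pollen parent.

Confidence is calibrated by simulation, in the manner of likelihood
parentage software: offspring are simulated from random parent pairs drawn
from the observed pool (each true parent sampled into the candidate set
with probability 0.9 by default), the trio search is run, and the Delta
threshold (LOD gap between best and second-best pair) is set to the
smallest value at which at least 95 % of accepted assignments are correct.
A sharing pre-filter — a candidate parent must share an allele with the
offspring at all but at most one co-scored locus — prunes the cubic pair
enumeration to near-relatives before any likelihood is computed; with
heterozygosity near 0.8 across 16 loci, unrelated pairs essentially never
survive it.

## The synthetic-data generator

`simulate_germplasm()` produces collections with known truth at every
level, emulating the statistical structure of a large European apple
germplasm panel: 16 SSR loci with 8–30 alleles on a 2-bp fragment ladder
and Dirichlet(0.3) ancestral frequencies (expected heterozygosity around
0.8 with a long tail of rare alleles); three weakly differentiated
genepools built by the Balding–Nichols construction
$p_k \sim \mathrm{Dir}(p_{anc}(1-F)/F)$, optionally split into nested
subgroups by the same construction; per-individual ancestry
$q_i \sim \mathrm{Dir}(\alpha + w\,e_g)$ with $\alpha = 0.3$ and own-group
weight $w = 5$, giving mostly strongly assigned individuals plus a
realistic admixed tail; clonal duplicate groups of 2–9 members whose copies
mutate at most two loci by one ladder step each (guaranteeing the planted
group stays inside the duplicate-detection tolerance); ~8 % triploid
profiles with a third distinct allele at 3–6 loci; and planted trios built
by Mendelian segregation with per-allele genotyping error applied as a
random population draw — the same error model the parentage likelihood
assumes, for coherence.

Because admixture mixes genepools, the realized F_ST of a simulated panel
sits below the nominal Balding–Nichols drift: with the default admixture
profile, drift 0.07 realizes a Weir–Cockerham θ near 0.05. The
admixture-recovery analyses in the test suite and acceptance script use
that calibrated value so the simulated differentiation matches the weakly
structured regime the workflow targets.

What the generator does **not** emulate: linkage between loci (real panels
spread markers across linkage groups precisely so independence is
defensible), null alleles and allele-specific dropout, coalescent mutation
history, isolation-by-distance gradients, and pedigree depth beyond single
trios. Passing tests therefore demonstrate correctness of the estimators
under the stated generative model, not robustness to every artefact of real
fragment data.

## Problem sizes and numerical choices

The test suite and `scripts/acceptance.R` run at desk scale, chosen so the
full battery completes in minutes on one core: duplicate detection checked
against a brute-force union-find oracle at ~200 accessions; admixture
recovery on 150 individuals × 16 loci with the desk profile over K = 1–6;
θ calibration with 20 replicates of 100 individuals per population at 20
loci; AMOVA null uniformity over 200 replicates at 199 permutations; and
parentage with 50 planted trios among 500 candidates, 300 calibration
simulations, and 20 null replicates. Dirichlet draws use gamma variates
floored at $10^{-300}$ to avoid degenerate zero simplex coordinates;
rarefaction uses log-binomials for stability; permutation p-values always
carry the +1 correction; argmax ties break toward the lowest index and are
deterministic.

## Known limitations

Within-run label switching is not corrected (only across-run alignment);
with very weak structure and long chains a single run could mix modes and
smear its posterior means. ΔK cannot, by construction, support $K = 1$ and
inherits the known tendency to flag the uppermost hierarchical level. The
AMOVA is two-level only. F_ST replication of any specific published matrix
is not claimed: estimator conventions differ across programs, and raw
genotype matrices of the motivating surveys are generally not deposited.
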