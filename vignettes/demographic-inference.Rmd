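---
title: "Coalescent demographic inference for a two-cluster SNP dataset"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coalescent demographic inference for a two-cluster SNP dataset}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`karstdemog` re-implements, as a tested and reusable pipeline, a
demographic-inference workflow for an endangered shrub genotyped by a
reduced-representation method (MIG-seq-style stacks of ~138 bp loci) in two
genetic clusters: SNP filtering, diversity and differentiation statistics,
construction of a folded two-dimensional minor-allele site frequency
spectrum (2D-mSFS), coalescent simulation under four two-population
divergence models, maximum composite-likelihood fitting with AIC model
selection, and parametric-bootstrap confidence intervals. This vignette is
the package's account of the science: the models, the estimators, the
numerical choices, and what the synthetic-data tests do and do not show.

## The model family

All four demographic models describe two demes — cluster I and cluster II —
with piecewise-constant diploid effective sizes over three epochs
(backwards in time):

* `[0, T1)`: sizes `N_CLI_0`, `N_CLII_0` (present-day sizes);
* `[T1, T2)`: sizes `N_CLI_1`, `N_CLII_1`;
* before `T2`: the demes merge into a single ancestral deme of size `N_ANC`.

The models differ only in when gene flow occurs. `Nm_i-j` denotes the
forward-in-time number of migrant gene copies per generation into deme i
from deme j:

| model | migration window | free parameters |
|---|---|---|
| 1 (no migration) | none | 7 |
| 2 (isolation with migration) | present to `T2` | 9 |
| 3 (ancient migration) | `T1` to `T2` | 9 |
| 4 (secondary contact) | present to `T1` | 9 |

Two conventions deserve emphasis because simulators disagree on them:

* **Sizes are diploid.** A deme of diploid size `N` holds `2N` gene copies,
  and `k` lineages coalesce at rate `choose(k,2)/(2N)` per generation.
* **Migration is converted with the recipient-deme size.** Backwards in
  time a lineage currently in deme i jumps to deme j at rate
  `Nm_ij / (2 N_i(t))`: the forward flow j→i is the backward flow i→j. When
  the deme size changes across epochs inside the migration window, the
  backward rate is recomputed with the epoch's size, which keeps the
  forward migrant *count* (not the rate) constant — the quantity the models
  parameterize.

Time is continuous in generations, size changes are instantaneous, and
there is no recombination within a locus, no selection, and no growth
within an epoch. Mutations follow the infinite-sites model within a locus;
at the default locus length (138 bp) and mutation rate the probability of
recurrent hits is negligible.

## Default rates and the study geometry

The default mutation rate is `5.39e-8` per site per generation, the value
adopted by the reference analysis (estimated in a related woody shrub).
The source that rate was taken from quotes `7.7e-8` per site per year and
7 years per generation, whose product is actually `5.39e-7`; we deliberately
adopt the *stated per-generation value* `5.39e-8`, since all reported
parameter estimates were obtained under it, and flag the internal
inconsistency here rather than silently "fixing" it.

The default generation time for converting generations to calendar time is
20 years. Default data geometry mirrors the reference dataset: 14
populations in two clusters of 106 and 81 diploids, 1753 loci of 138 bp
(242,107 total sites, ~4.2k SNPs at the reference parameters), with 10%
per-genotype missingness in the synthetic generator — a typical value for
reduced-representation data, chosen once; the reference study does not
publish its per-genotype rate.

## Filtering

`filter_snps()` mirrors the Stacks `populations` filters used to produce
such datasets: presence (`-p` populations at `-r` fraction of samples each),
pooled minor-allele frequency (`--min-maf`), pooled observed-heterozygosity
ceiling (`--max-obs-het`), and first-SNP-per-stack thinning
(`--write-single-snp`). Order is fixed as presence → single-SNP → MAF →
heterozygosity and is recorded in the returned report. The reference
toolchain applies per-SNP filters after locus-level presence; the relative
order of MAF and heterozygosity does not matter (both are per-SNP and
independent), which the test suite asserts as a commutation property. MAF
is computed on the pooled sample, matching the `populations` default, and
presence ties at exactly `r` are retained (≥).

## Diversity statistics

The per-population/per-cluster table follows the conventions of the common
desktop tools:

* `H_O`: fraction of heterozygous genotypes among non-missing calls per
  SNP; reported mean ± SE, with SE = sd over SNPs / √(#SNPs).
* `H_E = 2p(1-p)` from pooled group allele frequencies (no small-sample
  correction, GenAlEx-style).
* `F_IS = mean((H_E - H_O)/H_E)` over SNPs with `H_E > 0`. Published
  tables computed with other per-locus weighting conventions will not
  reproduce exactly; the convention here is fixed and documented rather
  than reverse-engineered.
* Allelic richness by hypergeometric rarefaction to `g` gene copies
  (FSTAT-style); `g` defaults to the smallest per-group non-missing gene
  count so every group is comparable.
* Nucleotide diversity per variant site as `n/(n-1) * (1 - Σp²)` — the
  unbiased average pairwise difference — averaged over variant sites.
* Weir–Cockerham θ from the standard variance components (a, b, c),
  multilocus as a ratio of sums; pairwise F_ST matrices use the same
  estimator restricted to each pair. Slightly negative estimates are an
  expected estimator property near zero differentiation.
* Nei's (1972) standard distance from identity sums over all loci.
* The Mantel test uses the squared Pearson correlation of lower-triangle
  entries, with joint row/column permutations and
  `p = (1 + #{perm ≥ obs}) / (n_perm + 1)`; the seed is a required
  argument so published p-values can be reproduced exactly.

## The folded 2D-mSFS and missing data

The spectrum counts SNPs by minor-allele copy number jointly in the two
clusters. Folding uses the *global* minor allele: alternate-allele counts
`(i, j)` with `i + j` above half the total gene count reflect to
`(2n1 - i, 2n2 - j)`; exact-half ties contribute 1/2 to each complementary
cell, so counts are conserved (cells may hold half-integers). Cell `(0,0)`
stores the monomorphic-site count when the total site count is known,
which the likelihood can use as an invariant-site term.

Missing genotypes are imputed by a bootstrap *within the cluster*: each
missing gene copy is drawn i.i.d. with replacement from the cluster's
observed gene copies at that SNP. The bootstrap unit is the gene copy, not
the diploid genotype — the SFS is defined on allele counts, and resampling
genes keeps the expected imputed frequency exactly equal to the observed
cluster frequency (a property the tests verify by simulation). One
imputation replicate feeds one analysis by default; averaging spectra over
several imputation seeds is available but not the default, matching the
single-imputation character of the reference workflow. Both choices are
exposed because the reference description ("bootstrapping within the
cluster") does not specify either knob.

## Composite likelihood

Expected spectra are estimated from simulated genealogies by classifying
*branch lengths* by the joint descendant counts of each branch, rather
than by dropping Poisson mutations: the expected number of SNPs per site
in cell `(i,j)` is `mu × E[length subtending (i,j)]`. This is the standard
variance-reduction used by SFS-based likelihood engines, and it makes one
likelihood evaluation cost one set of genealogies.

With the invariant-site term (the default whenever the observed spectrum
carries a monomorphic count), cell probabilities are absolute
(`mu`-scaled) and the monomorphic probability is `1 - mu × E[total
length]`; the likelihood is then informative about the absolute time/size
scale, exactly as when a simulator is given "all sites" input. Without it,
probabilities are normalized over polymorphic cells, and only relative
parameters are identified. The composite log-likelihood is
`Σ m_cell log10 p_cell` (log10, matching how such analyses report LL).
Cells observed in the data but unvisited (or under-visited) by the finite
simulation are floored at `p_poly / (n_branches × n_sims)`, with `p_poly`
the total polymorphic probability and `n_branches` the number of branches
in one genealogy — the expected mass of a cell that a single typical
branch in one simulated genealogy would have contributed. The floor's
form matters more than one might expect. A floor that shrinks faster than
`1/n_sims` (for example, "one tenth of the smallest positive simulated
probability") punishes unvisited cells ever more harshly as precision
grows, making likelihoods evaluated at different simulation counts
incomparable and biasing low-precision evaluations *against* models with
fine-grained spectra — which steers the optimizer toward diffuse
migration-equilibrium ridges. A floor much larger than the single-visit
scale errs the other way, subsidizing models that miss observed cells.
The single-visit scale keeps the penalty commensurate with the
simulation's own resolution, and in the package's recovery experiments it
preserves the likelihood ordering of competing parameter regions across
two orders of magnitude of simulation count.

## Optimization

The likelihood is maximized by cyclic conditional maximization: one pass
over all parameters is one ECM cycle, and each conditional step maximizes
one parameter over its *full* log10 range — a coarse grid followed by
bisection refinement around the grid winner — holding the others fixed.
The full-range grid matters: this likelihood surface contains a broad
migration-equilibrium plateau (any sufficiently old divergence with
`Nm ≳ 1` fits almost as well as the true history), and purely local
steps tend to walk onto it and stay; full-range conditional search lets
a parameter jump several decades in one step when the conditional slice
rewards it. `T2` is reparameterized as `T1 + dT` so the epoch-order
constraint can never be violated. Within a cycle every evaluation uses
one common random seed, making the likelihood a deterministic surface for
the line search; across cycles the seed changes so the optimizer does not
overfit one simulation realization. Because desk-scale simulation counts
leave appreciable Monte-Carlo spread, the per-evaluation simulation count
is annealed — doubling in the middle third of the cycles and quadrupling
in the final third — and the winner among all late-cycle candidate optima
from every start is chosen by a two-stage common-random-number
evaluation: all candidates screened at `n_sims_final`, the leaders
separated at four times that. Default search ranges are `1e2–1e6`
(sizes), `1e2–1e7` generations (`T1`, `dT`), and `1e-2–1e2` (Nm), sampled
log-uniformly for starting values.

Model selection uses `AIC = 2·NP - 2·ln(10)·LL` (the log10-scale form of
the usual definition) with NP = 7 for model 1 and 9 for models 2–4.
Confidence intervals come from a parametric bootstrap: datasets simulated
at the MLE with the observed geometry, refit from the MLE as the starting
value with 15 ECM cycles, and summarized as 2.5/97.5 percentile intervals.
Derived quantities (size-change ratios, times in ka at 20 y/generation,
migrant counts) are computed per replicate and flagged significant when
their interval excludes 1.0.

## Problem sizes used by the tests

The test-suite and acceptance runs use deliberately scaled problem sizes,
chosen once as the package's desk-scale defaults: Monte-Carlo closed-form
checks use 2×10⁴ genealogies (10⁵ loci for mutational expectations); the
equilibrium-differentiation fixture uses 2×20 diploids, 500 loci and an
elevated mutation rate (1e-6) so a few thousand SNPs carry the F_ST
estimate; and parameter-recovery runs use 300 loci at the reference MLEs
(~700–800 SNPs) with 2 random starts, 9 annealed ECM cycles and 1000
base simulations per evaluation. At those sizes a full model fit takes
several minutes on one CPU; a reference-scale configuration (tens of
starts, tens of cycles, 10⁵ simulations, 1753 loci) is expressible
through the same `fit_config()` interface.

## What the synthetic data does and does not show

The generator reproduces the *geometry* of the reference dataset
(population sizes, cluster totals, locus count and length, missingness
rate) and its generating process is exactly the model family being fitted.
Passing recovery tests therefore demonstrate the correctness and
calibration of the estimator under its own assumptions — they do not
demonstrate that real data satisfy those assumptions. Known departures in
real reduced-representation data that the generator deliberately omits:
within-cluster population substructure (population labels are random
partitions of a cluster's diploids; real tables show mild among-population
structure), linkage between SNPs of the same stack when more than one SNP
per locus is retained, sequencing error and allele dropout, and
non-random missingness. The isolation-by-distance fixture places
populations on a 1D transect so the Mantel test has signal by
construction; it validates the test's mechanics, not any biological claim.

## Numerical notes and limitations

* Exact-half folds are split half-and-half; spectra may contain
  half-integer counts, and all conservation properties hold exactly.
* Half-missing genotypes (`0/.`) in VCF input are treated as missing — the
  upstream toolchains do not document a consistent convention.
* Multi-allelic records are skipped (with a warning), not split; the
  target datasets are biallelic-SNP-only.
* More than two clusters are accepted by all diversity statistics but
  rejected by the SFS and demography modules, which model exactly two
  demes.
* The composite likelihood treats sites as independent; SNPs within a
  stack are linked in reality, so composite-likelihood confidence regions
  are optimistic unless bootstrapped, which is why interval estimation is
  parametric-bootstrap-only.
* At 300-locus scale the model-2 likelihood surface has a known soft ridge
  trading divergence time against ancestral size and late-epoch sizes;
  accurate final-candidate comparison (large common simulation counts) is
  what resolves it, and the annealing defaults were chosen with that in
  mind.
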