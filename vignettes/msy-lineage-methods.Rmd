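---
title: "Methods: MSY haplotype backbones, hierarchical calling and clock dating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MSY haplotype backbones, hierarchical calling and clock dating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msylineage)
```

## The problem

The male-specific region of the Y chromosome (MSY) is strictly paternally
inherited and does not recombine, so the MSY haplotypes of a set of males
form a tree: every derived variant marks one branch, and every male sits at
one node. In stallion-centred breeding this tree is a direct record of sire
lines. Most modern horse breeds fall into a young haplogroup (the "Crown",
rooted at a node conventionally called `daC`, with a most recent common
ancestor around 1,500 years ago), and diagnostic panels of a few dozen to a
few hundred key variants are used to place each animal on a published
backbone topology.

`msylineage` implements that workflow end to end:

1. **backbone** — model, import (labelled Newick + variant panel), build
   (perfect phylogeny from a 0/1 matrix), condense (sHGs) and validate the
   haplotype tree;
2. **htcaller** — call each sample's haplotype by hierarchical descent over
   its tested variants, with inner-node `"*HT"` allocation, frequency-aware
   test planning, imputation, and 0/1 encoding;
3. **popstats** — haplotype-frequency spectra and Nei haplotype diversity by
   breed group;
4. **ancestry** — haplotype-to-ancestry predictor signatures and cohort
   composition summaries;
5. **clockdating** — strict-clock TMRCA estimation via the rho statistic
   with Poisson intervals;
6. **synthdata** — a genealogy simulator with full ground truth, so every
   stage is testable without external data;
7. a thin orchestration layer (`validate_config()`, `run_pipeline()`, and
   the `exec/msylineage` script).

## Perfect phylogeny and the compatibility test

`build_tree_from_matrix()` assumes infinite sites: each variant arose once,
so the samples carrying its derived allele form one clade. With the
ancestral state known (alleles are coded Ref/Alt as 0/1, ancestral = 0), the
all-ancestral root haplotype is implicitly present, and two variant columns
are tree-compatible if and only if the gametes 01, 10 and 11 do not all
occur. This is the rooted form of the classical four-gamete test: the 00
gamete is supplied by the implicit root, so only three gametes need
checking. The builder collapses identical columns onto one edge, sorts
distinct columns by decreasing derived count, attaches each cluster to the
smallest strictly containing cluster, and hangs each sample under its
smallest containing cluster. Internal nodes are named `N<k>` in
deterministic preorder; imported backbones keep their published labels.

Recurrent mutation or assay error violates compatibility. By default the
builder aborts and lists the offending pairs; with `drop_recurrent = TRUE`
it greedily removes the column involved in the most conflicts (ties broken
lexicographically by variant id) and reports what it dropped. There is no
general parsimony search over incompatible data: that is a different
problem, and off-the-shelf phylogenetics tools solve it.

## Hierarchical calling and the `"*HT"` convention

Real genotyping is successive: a sample is tested for the Crown-defining
variant first, then down the hierarchy, skipping assays that the breed's
known haplotype frequencies make uninformative. `call_haplotype()`
reproduces the logic on any subset of tested variants:

* The call is the deepest node whose root path is supported. An untested
  variant *bracketed* by a tested-derived variant deeper on the same path is
  treated as derived — this is what makes a skip-ahead series (Crown variant
  plus one deep terminal variant) yield a terminal call. A tested-ancestral
  edge blocks descent.
* Terminal node: status `terminal`. Internal node: `inner_confirmed` when
  every child edge was tested ancestral, `inner_unresolved` when at least
  one child edge is untested. Both display as the node name plus `"*"`,
  matching the field's reporting convention; the status distinction is kept
  because published `*HT` labels do not say which of the two situations
  produced them.
* Conflicts: one off-path tested-derived variant is tolerated — the
  maximal-support path (most tested-derived variants) is kept and the
  conflict recorded with a warning. Two or more off-path derived variants,
  or a support tie between disjoint paths, raise an ambiguous-call error
  carrying the candidate paths. This guards against recurrent mutation or
  assay error silently misplacing samples; the choice of "one" as the
  tolerance is a design decision, made once, erring on the side of loud
  failure.
* A sample with no tested variant is a no-call. `batch_call()` never aborts
  a cohort; failures become flagged rows.

`plan_tests()` returns the untested variants below the current node,
depth-first, branches ordered by descending prior subtree mass (ties by
variant id). Subtrees with zero prior mass are omitted, so a prior
concentrated on one haplotype yields exactly the path to it; pass a uniform
prior to enumerate everything. In simulations against a breadth-first
baseline the greedy plan needs no more assays on average.

`impute_alleles()` completes a called sample to a full 0/1 vector: path
variants 1, off-path 0, tested states never overwritten (off-path derived
calls stay 1 and are flagged, never silently zeroed). Imputation is
idempotent, and `encode_matrix()` followed by `batch_call()` reproduces the
assignments.

## Frequency spectra and Nei diversity

`ht_frequencies()` counts labels directly; terminal HTs and `*HT` labels are
distinct rows (inner-node groupings are real haplotype classes in this
setting and are counted as such). `haplotype_diversity()` implements the
Nei (1987) unbiased estimator

$$\widehat{H}_d = \frac{n}{n-1}\Big(1 - \sum_i p_i^2\Big),$$

the probability that two samples drawn without replacement carry different
haplotypes, with sampling variance

$$V = \frac{2}{n(n-1)}\Big\{2(n-2)\Big[\sum_i p_i^3 - \big(\sum_i p_i^2\big)^2\Big] + \sum_i p_i^2 - \big(\sum_i p_i^2\big)^2\Big\},$$

and SD $=\sqrt{V}$. The variance choice is a documented assumption: field
reports typically cite the estimator without printing the variance formula,
and this is the standard one (compatible with common population-genetics
packages). Diversity is undefined for $n < 2$ and the function says so
rather than returning a number. The estimator is verified in the tests
against exhaustive pair counting up to $n = 200$.

`group_summary()` produces the descriptive table used for breed-group
comparisons (sample counts and haplotype counts inside/outside the Crown,
diversity of the Crown subset and of all samples, plus a Total row);
`crown_fraction()` reports the headline percentages (Crown membership,
terminal vs inner-node resolution), rounded to integers as such figures are
conventionally printed.

## Ancestry predictors

`derive_predictors()` turns reference-group frequencies into signatures: a
haplotype observed at least `min_count` times in exactly one reference group
predicts that ancestry; in several, a `varied` signature joining the groups
with `"/"`; in none, `unexplained`. The default `min_count = 2` treats a
single observation as too weak to define a predictor. Raising `min_count`
can only demote predictors toward `unexplained`, never flip one unique
signature to another. Expert-curated override files are applied last and
logged — published predictor lists mix frequency evidence with narrative
breed history, and overrides are the mechanism to reproduce them exactly.
`classify_samples()` adds the historical basis (recent breeding for
Arabian/Thoroughbred/Coldblood signatures, early dissemination for
Spanish/West Asian, plus varied, unexplained and non-Crown), and
`summarize_composition()` reports counts and one-decimal percentages per
group.

## Strict-clock dating

Full Bayesian tip-dating (BEAST-style MCMC) is off-the-shelf machinery and
is deliberately not reimplemented. Instead `rho_statistic()` and
`tmrca_estimate()` provide the classical founder-analysis clock: rho is the
mean number of derived variants from a clade's founding node to its sampled
tips, and

$$\widehat{T} = \frac{\rho}{\mu L}$$

with $\mu$ the per-site per-year rate and $L$ the effective callable length.
The default rate in the simulator is the published horse MSY rate
($1.69\times10^{-9}$ substitutions/site/year, bounds $1.41$–$2.11\times10^{-9}$).
$L$ is a required configuration value with no default: the callable length
behind any per-site rate is assay-specific and is not recoverable from
summary reports, so published clade ages cannot be recomputed without it.
Fixtures use $L = 5\times10^6$ sites, a synthetic placeholder chosen to give
a realistic mutation input ($\mu L T \approx 13$ derived variants per lineage
over 1,500 years).

The confidence interval combines the exact Poisson interval on the total
tip-to-node mutation count $S$ (bounds `qgamma(0.025, S)` and
`qgamma(0.975, S + 1)`) with the rate envelope $[\mu_{low}, \mu_{high}]$. A
zero-mutation clade gets age 0 with a finite upper bound. The interval
treats tip counts as independent Poisson draws, which is exact for a star
genealogy and approximate otherwise: shared internal branches make tip
counts positively correlated, so on strongly nested genealogies the
intervals are somewhat anti-conservative. For the intended use case — a
star-like founder expansion — simulation shows ~92–95% empirical coverage of
nominal 95% intervals (checked across TMRCA 500–5,000 years and expected
counts 3–50 in the test suite), and the package's acceptance criterion is
parameter recovery (≥ 90% coverage), not agreement with any particular
Bayesian posterior.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, not
horse biology in detail:

* **Genealogy** (`simulate_genealogy()`): rooted binary ultrametric trees
  with root age exactly `tmrca_years` (default 1,500). `star_burst`
  (default) compresses all coalescences into the oldest 5% of the depth —
  the Crown-like founder expansion; `kingman` and `yule` give nested
  alternatives.
* **Mutations** (`drop_mutations()`): Poisson(μ·L·t) per edge, infinite
  sites, abstract 0/1 alleles. Matrices are perfect-phylogeny compatible by
  construction; recurrent mutation enters only through the masking stage's
  error rate.
* **Breeds** (`assign_breeds()`): each breed draws Dirichlet(α) weights over
  the root-child patrilines and recruits tips accordingly. Small α (default
  0.3) concentrates breeds on few sire lines — the line-breeding skew that
  produces low within-breed diversity; α → ∞ approaches panmixia. Because
  infinite sites makes every tip a private haplotype, the line-breeding
  diversity contrast is defined at the patriline (clade) level.
* **Masking** (`mask_panel()`): i.i.d. missingness plus optional state
  flips, with ground truth retained.

What the generator does *not* emulate: recurrent mutation as a mutational
process, microsatellite stepwise evolution, pedigree-correlated (non-random)
missingness, and population-size dynamics. Passing tests therefore
demonstrate correctness of the algorithms under the stated model, not
robustness to every artefact of real assay data.

A note on truth: a tip whose terminal edges carry no mutation is
genotypically identical to its ancestor, so the generator's `true_nodes()`
reports the deepest *identifiable* node. Clean full genotyping recovers
exactly that node for 100% of samples; under missingness with zero error the
call never leaves the true node's root path (ancestor safety) — both are
enforced in the test suite, the latter over 10,000 masked calls.

## Numerical and design choices

* Percentages: headline fractions to the nearest integer, composition and
  realized rates to one decimal; diversity to three decimals in printed
  output (full precision is always returned).
* Determinism: every stochastic function takes a mandatory seed; a whole
  truth bundle is a pure function of its parameters, and identical seeds
  give byte-identical bundle files. Batch outputs are independent of input
  order.
* Junction nodes (edges with no defining variant) are permitted — published
  topologies sometimes branch where no key variant was genotyped — but they
  are flagged by `validate_backbone()` and can never be confirmed by
  testing.
* Ties everywhere (test planning, conflict columns, candidate paths) break
  lexicographically, never randomly.
* Problem sizes in the shipped tests (cohorts of 100–300 simulated lineages,
  500-replicate coverage runs, 10,000-call masking sweeps) were chosen as
  the smallest sizes at which the statistical checks have useful power; all
  scale linearly if users want more.

## Limitations

* The caller trusts hard genotype calls; there is no likelihood model for
  assay quality.
* The clock interval's independence approximation is only exact for
  star-like clades (see above).
* sHG condensation requires non-overlapping subtree roots; overlapping
  reporting schemes must be resolved by the user.
* Published per-sample datasets (supplementary spreadsheets of specific
  studies) are not bundled; benchmark comparisons against them require the
  user to supply the files in the package's CSV/TSV formats.
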