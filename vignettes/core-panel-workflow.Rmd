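---
title: "Methods: SNP core panels and variety identification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SNP core panels and variety identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model behind `corepanel`, the
conventions and numerical choices the implementation commits to, and what
the simulation-based tests do and do not establish.

## Data model

A `genotype_matrix` holds accessions × biallelic loci with calls coded as
ALT-allele dosages (0 = REF homozygote, 1 = heterozygote, 2 = ALT
homozygote, `NA` = missing) and, when the source VCF carries per-sample
`DP`, a parallel depth matrix. Coordinates are 1-based, chromosome labels
are normalised by stripping a `chr`/`Chr` prefix, and (chromosome,
position) pairs must be unique. Allele orientation is taken from the input
file; a two-letter Fluidigm-style call containing an allele outside the
marker's {REF, ALT} is an error, never silently recoded — silent strand
flipping is exactly the kind of corruption that wrecks identification
panels downstream. When genotypes for the same markers arrive from two
platforms, they are merged on marker id with an allele-consistency check.

## The synthetic collection

No individual-level genotypes for the motivating germplasm collection are
public, so the package generates its own under the Balding–Nichols model:
each locus draws an ancestral ALT frequency $p$ (minor-allele frequency
uniform on $[0.1, 0.5]$, mirrored to $1-p$ with probability $1/2$ so
REF/ALT orientation carries no signal); population $k$ with drift
parameter $F_k$ draws its frequency from
$\mathrm{Beta}\!\left(p\tfrac{1-F_k}{F_k},\,(1-p)\tfrac{1-F_k}{F_k}\right)$,
which has mean $p$ and variance $p(1-p)F_k$; each diploid genotype is
$\mathrm{Binomial}(2, q_k)$. For a population pair this yields a known
Hudson-style target Fst close to the mean of the two $F$ values, which is
what makes quantitative parameter-recovery tests possible; the recorded
true frequencies also give every population's expected heterozygosity in
closed form as $\overline{2q(1-q)}$.

The default configuration emulates a realistic cultivated-pear
collection: five populations of 86/27/19/26/26 accessions (four
species-like groups and an interspecific-hybrid-like group), 288 loci
placed uniformly on 17 chromosomes with chromosome lengths of 19–40 Mb,
drift $F = (0.04, 0.12, 0.14, 0.80, 0.05)$ — chosen once so that pairwise
Fst spans roughly 0.02–0.5 and within-population He spans roughly
0.08–0.45, i.e. three closely related Asian-type populations, one strongly
bottlenecked European-type population, and a hybrid-like group near the
largest population — a 3% missing-call rate (most accessions end up with
>90% call rates), and four zero-mutation clone pairs standing in for bud
mutants. A config flag can instead build a hybrid population by averaging
two parents' per-locus frequencies (off by default).

What the simulator deliberately does **not** reproduce: linkage
disequilibrium (loci are independent), genotyping error, null alleles,
platform-specific cluster-calling artifacts, and real pedigree structure
(sibling or parent–offspring pairs that are similar but not identical).
Passing tests therefore establish correctness of the statistics and the
panel/identification logic under idealised population structure, not
robustness to assay artifacts.

## Marker statistics and filters

Allele frequencies come from allele counting over non-missing diploid
calls. For frequencies $p_1,\dots,p_n$,

$$\mathrm{PIC} = 1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2,$$

which for a biallelic locus is maximal (0.375) at MAF 0.5 and strictly
increasing in MAF. Expected heterozygosity uses Nei's unbiased form
$\frac{2n}{2n-1}(1 - \sum p_i^2)$; the unbiased estimator is used
throughout (including inside Nei's distance) because the workflow
explicitly corrects for unequal population sizes. Allelic richness uses
El Mousadik & Petit rarefaction,
$A = \sum_i \left[1 - \binom{2N - N_i}{g}\big/\binom{2N}{g}\right]$,
evaluated on the log-choose scale; the rarefaction size $g$ defaults to
the smallest per-population per-locus called-copy count so that no locus
is skipped, and is reported alongside the table. The pooled "Total" row
treats all assigned accessions as one sample (a choice, since pooling
versus averaging is ambiguous in this kind of report table; it is labelled
as pooled).

`filter_loci` applies the gates in a fixed order: depth masking first
(calls with depth < 3 become missing; a no-op with a warning when depths
are absent), then missing rate, then MAF, with each dropped locus
attributed to the first failing rule. Thresholds are strict inequalities
(MAF exactly 0.05 fails); the missing-rate default is 0.15, exposed as a
parameter because reduced-representation pipelines commonly run the same
gate anywhere between 0.15 and 0.30. The filter is idempotent, which the
tests assert.

## Differentiation statistics

Pairwise Fst is Weir & Cockerham's (1984) θ with the two-population
variance components $a$ (between populations), $b$ (between individuals
within populations) and $c$ (within individuals), combined across loci as
a ratio of sums $\theta = \sum_\ell a_\ell / \sum_\ell (a_\ell + b_\ell +
c_\ell)$. The estimator choice is recorded in the output because the
original analyses in this field often come from tools that do not name
theirs. Slightly negative multi-locus θ is reported as computed — clipping
would bias comparisons near zero. One estimator subtlety worth knowing:
for two *literally duplicated* samples θ is not exactly zero but slightly
negative, because the observed between-sample variance (zero) falls below
its sampling expectation; θ is exactly zero only when
$\bar p(1-\bar p) = \bar h/4$ at every locus. The tests cover both cases.

Nei's distance uses the 1978 unbiased within-population identities
$\hat J_X = (2n\sum x_i^2 - 1)/(2n - 1)$, identities averaged over loci
before the ratio, $D = -\ln\!\left(J_{XY}/\sqrt{J_X J_Y}\right)$, clipped
at 0 (the unbiased correction can push the argument above 1 for very
similar populations) and reported as `Inf` when the populations share no
alleles at any locus.

The permutation test reassigns whole multilocus genotypes — the accession
is the exchangeable unit — to two groups of the original sizes,
recomputing θ each time, with the add-one p-value
$p = (1 + \#\{\theta^* \ge \theta_{obs}\})/(1 + B)$ so $p$ is never zero,
and a Bonferroni factor equal to the number of population pairs in the
full analysis (10 for five populations). Under the null this p-value is
uniform up to discreteness, which the calibration test checks empirically
(rejection rate at $\alpha = 0.05$ across replicate null datasets).

## Clustering

PCA encodes calls as dosages, imputes missing calls to the locus mean,
centres columns and eigendecomposes; no allele-frequency scaling is
applied, matching the plain genotype-PCA convention. Euclidean distances
use pairwise-complete loci with the squared sum rescaled by
$L/L_{shared}$, so that missingness does not shrink distances; a pair must
share at least half the loci (configurable) or the computation errors
rather than returning noise. Pre-imputation is deliberately *not* used
for distances so that clone detection is driven only by observed
disagreements. UPGMA is average-linkage agglomeration (`stats::hclust`);
tie handling follows `hclust`'s deterministic convention given the input
order. Trees serialise to Newick with branch lengths equal to height
differences, so leaf-to-root path lengths equal half the cophenetic merge
distance.

## Panel selection

Candidates must pass the gate PIC > 0.25 and heterozygosity rate < 35%
(strict, as such gates are conventionally printed; the heterozygosity cap
guards against paralog-collapse artifacts that masquerade as
hyper-informative markers). The genome-distribution criterion is then
enforced by apportionment: per-chromosome quotas proportional to the
physical span of that chromosome's candidates, rounded by largest
remainder, with a floor of one marker per candidate-bearing chromosome
whenever the target allows; within a chromosome, greedy selection by
descending PIC (marker id breaks ties) subject to a minimum same-chromosome
spacing, 500 kb by default. Quota that a chromosome cannot fill moves to
chromosomes that can; if spacing alone blocks completion it is relaxed for
the remainder and the panel is flagged. The procedure is fully
deterministic. No published allocation algorithm exists for this step, so
a transparent quota-greedy rule with exposed parameters was chosen over
combinatorial optimisation — panels of this kind are meant to be auditable.

Nested subsets re-run the same rule restricted to the parent panel's
markers, so the chain is nested by construction and subsets of size ≥ 17
retain full chromosome coverage whenever feasible. Nesting is a design
choice (it simplifies deployment and guarantees the monotone behaviour of
identification rates); an independent, non-nested selection is available
by calling `select_core_panel` directly with a different target.

## Identification

Two accessions are indistinguishable when they agree at every panel locus
called in both, provided they share at least `min_shared` such loci —
default half the panel, which prevents spurious matches between
low-call-rate accessions. A missing-versus-called locus never counts as a
difference (conservative for variety protection: absence of evidence is
not distinctness). Because missing-data patterns can make the relation
non-transitive, groups are its connected components; pairs below the
overlap threshold with no observed disagreement are reported separately as
uncallable rather than merged. On complete data, shrinking a nested panel
can only merge groups, never split them, so identification rates are
non-increasing along a nested chain — asserted over replicate simulations.

## Problem sizes and numerical choices in the tests

The test suite runs the calibration study at 200 replicate null datasets
of 50 accessions × 300 loci with 499 permutations each; parameter recovery
at two populations of 80 with 1000 loci ($F = 0.1$ each, 25% relative
tolerance against the true-frequency oracle); and the structural pipeline
properties over 50 replicate collections of 40 accessions × 150 loci —
sizes chosen to keep Monte-Carlo error well inside the asserted bounds
while the whole suite stays fast. Exact formula checks (PIC, unbiased He,
rarefaction by exhaustive hypergeometric enumeration, θ against an
independently coded variance-component loop, UPGMA against a naive
$O(n^3)$ reference) are at tolerances 1e-10 to 1e-12.

## Known limitations

- Imputation is limited to PCA's locus-mean fill; no haplotype-based
  imputation is provided (upstream pipelines typically handle that before
  export).
- Model-based admixture clustering and its cluster-number diagnostics are
  out of scope; PCA and UPGMA are the provided structure views.
- The Fst estimator is fixed to Weir–Cockerham; other estimators
  (Hudson, Nei G_st variants) would give systematically different values
  on strongly diverged pairs.
- Identification uses exact profile matching, not a genotyping-error-aware
  likelihood; with error-prone assays the zero-difference rule
  understates true duplication.
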