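---
title: "Methods: parentage assignment and genetic monitoring of mass crosses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: parentage assignment and genetic monitoring of mass crosses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(masscross)
```

## The problem

In a full-factorial mass cross, all candidate sires and dams of a
broodstock spawn together, so any of the `n_sires * n_dams` families may
have produced a given offspring. `masscross` reconstructs the pedigree
from codominant marker genotypes (microsatellite-style integer allele
sizes), then quantifies what the reconstruction reveals: reproductive
skew among brooders, the effective size of the offspring cohort, and the
loss of allelic and gene diversity between the parental and offspring
generations.

## Assignment model and its assumptions

The likelihood is pure Mendelian transmission. At one locus, a parent
transmits each of its two alleles with probability 1/2 independently of
the other parent, so each of the four gamete combinations has weight
1/4 and

$$P(g_o \mid g_s, g_d) \in \{0, 1/4, 1/2, 1\}.$$

The multilocus pair log-likelihood sums the log probabilities over loci
where all three genotypes are present. This model assumes:

* **No genotyping error.** A single incompatible locus excludes a pair
  outright. The simulator's `error_rate` exists precisely to probe this
  fragility: substituted alleles can only push offspring toward
  *unassigned* or (rarely) an incorrect family, never crash the method.
* **No mutation, no null alleles.** Transmission is exact.
* **Sexed parents, full-factorial candidates.** The candidate set is the
  design's sire list crossed with its dam list; single-parent assignment
  and sibship reconstruction are out of scope.
* **No allele-frequency weighting.** With a closed candidate set and an
  error-free model, Mendelian transmission products suffice; population
  allele frequencies matter only for the diversity statistics. CERVUS
  style likelihood ratios with error rates are deliberately not
  implemented.

An offspring is *assigned* when exactly one compatible pair attains the
maximal log-likelihood, *ambiguous* when two or more compatible pairs lie
within `tie_tol` of the maximum, and *unassigned* when no pair is
compatible (or too few loci are usable). Ambiguity is reported with the
tied pairs — ties are never broken silently, because downstream
contribution counts must only contain confident assignments.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_loci` | 5 | minimum fully genotyped loci per trio; 5 of a 9-locus panel keeps exclusion power while tolerating moderate missingness |
| `tie_tol` | 1e-9 | relative log-likelihood tolerance for declaring a tie; at this scale only exact likelihood ties (identical compatible genotype configurations) are ambiguous |
| Ne variance | population (divisor *k*) | see below |

The population-variance convention makes $K + V/K = \sum x_i^2 / \sum
x_i$, so `effective_size()` is exactly invariant to appending
zero-contributing candidates — the estimate depends only on who actually
contributed, while the chi-square test deliberately keeps all candidates
(expected counts $N/k$ over the full candidate list, d.f. $= k-1$),
because "this brooder produced nothing" is itself the finding of
interest. The same convention reproduces published per-cross effective
sizes computed from family matrices of this design, which the sample
(\(k-1\)) divisor does not.

Percentages are reported at one decimal, rounded half away from zero,
next to the exact fraction; mean allele counts print at one decimal and
heterozygosities at two, the conventional resolution for these tables.

## Diversity estimators

Gene diversity uses Nei's unbiased small-sample correction,
$\hat H_e = \frac{2n}{2n-1}(1 - \sum_i p_i^2)$, with $n$ the individuals
genotyped at the locus. This equals the probability that two gene copies
drawn without replacement from the sample differ — the identity the test
suite checks against an enumerated pairwise oracle. The fixation index is
$f = 1 - H_o/H_e$ per locus, undefined (reported `NA`) at monomorphic
loci and averaged over polymorphic loci only; note that multilocus
estimators (Weir & Cockerham style) weight loci differently, so per-locus
averages are comparable between sets analysed the same way but not
necessarily with other software's multilocus *f*.

Allelic loss between a parental set and its offspring is
$(A_p - A_o)/A_p$, both per locus and on the mean over loci; gene
diversity loss analogously on $H_e$. On error-free data offspring allele
sets are necessarily subsets of their contributing parents' — the
mechanism by which skewed contributions destroy low-frequency alleles.

## The simulator: what it emulates, and what it does not

`sim_config()` defaults encode the monitored-hatchery setting: 9 loci,
7 alleles per locus, 10 sires × 10 dams, 810 offspring. Per-locus allele
frequencies are drawn once from a flat Dirichlet (expected gene diversity
≈ 0.75, matching microsatellite panels of this polymorphism), with allele
sizes on a dinucleotide ladder so the 3-digit Genepop coding stays
realistic. Parents are drawn under Hardy–Weinberg proportions. Spawning
weights follow a symmetric Dirichlet per sex (`alpha` = 1 by default;
smaller values give stronger skew), with an optional forced non-spawner
fraction; family probabilities are the product $w_s w_d$ (independent
mating), or an explicit dam × sire weight matrix when specific pairings
must be reproduced — real crosses show both regimes. `scenario_presets()`
packages a screened-broodstock scenario (`cross1_like`: all sires, ~9/10
dams, mild skew) and an unscreened one (`cross3_like`: 5 sires, 2 dams,
one dam near 99.7% of the weight).

A single random stream is seeded once per run from `config$seed`, so
whole pipelines re-run byte-identically.

What the simulator does **not** model: genotype-dependent survival,
gamete competition dynamics, mutation, null alleles, linkage, or
family-correlated genotyping failure. Passing tests on simulated data
therefore demonstrate the correctness of the algorithms under the stated
transmission model — not that real mass-cross data are free of the
genotyping artefacts the no-error model is sensitive to.

## Numerical and degenerate-input choices

* Genotypes are canonicalised to smaller/larger allele on construction,
  giving bit-stable round trips through CSV and Genepop.
* Half-called genotypes (one known allele) are treated as missing — the
  error-free likelihood has no use for them.
* A locus missing in any trio member contributes factor 1 (is skipped)
  and decrements the usable-locus count for that trio only.
* `chi_square_uniform()` requires a positive total and at least two
  candidates; an all-zero family matrix is a valid object whose
  contributing-parent and family counts are zero.
* `effective_size()` rejects $N \le 2$ and mismatched sire/dam totals;
  with a single contributing pair it converges to the formula's limit of
  2 as $N \to \infty$, and with $k$ balanced contributors per sex it
  approaches $2k$ per-sex-combined from above.
* Genepop files carry no sex, so parent sex is decoded from the id's
  first letter (M/S male, F/D female); files written by this package
  (S01/D01 ids) round-trip exactly.

## Reported discrepancies in the published family tables

The matrix-only entry point (`run_cross_report()` on a
`family_matrix`) exists because published family tables are often the
only available artefact of a cross. For the packaged matrices the
marginals are always recomputed from the cells; a few of the originally
printed marginals and derived statistics are internally inconsistent
with their own cells (one dam total printed as 0 where the cells sum
to 2; three shifted row totals; two chi-square values and two effective
sizes not recoverable from the printed counts under any convention
tried; a pair-share percentage that actually equals the sire's column
marginal). The package reports what the cells imply.

## Problem sizes used by the test suite

The suite validates assignment recovery on 300–500 offspring crosses
(10 × 10 parents, 9 loci), the chi-square and Ne identities on 100
random vectors each, the null chi-square p-value uniformity on 1,000
multinomial replicates at $N = 500$, and Hardy–Weinberg *f* recovery on
500 simulated individuals — sizes chosen to match the real cohorts the
method targets while keeping each property check well inside a minute.

## Known limitations

* Assignment power depends on panel polymorphism; with few alleles per
  locus ambiguous ties become common, and the package reports rather than
  resolves them.
* Absolute diversity values from other software may differ through
  estimator conventions (He correction, multilocus *f*); ratios between
  sets analysed by this package are internally consistent.
* The Ne formula ignores overlapping generations, sex-ratio corrections
  beyond its own terms, and inbreeding/variance effective-size
  distinctions.
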