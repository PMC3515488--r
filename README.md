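# masscross

Molecular parentage analysis and genetic monitoring of **full-factorial
mass crosses** from multilocus codominant marker genotypes.

In hatchery breeding of fish such as Asian seabass (*Lates calcarifer*),
candidate sires and dams are spawned together in one tank, so every
sire × dam pair is a possible family and the pedigree must be
reconstructed afterwards from marker genotypes (typically a panel of
~9 microsatellites). `masscross` is for geneticists and breeding-program
managers who need to answer, for each cross: who are each offspring's
parents, how evenly did the brooders contribute, and how much allelic and
gene diversity survived into the offspring generation?

## The methods

**Parent-pair assignment.** Under an error-free Mendelian model each
parent transmits one of its two alleles with probability 1/2, so the
single-locus transmission probability is

    P(g_o | g_s, g_d) = (1/4) · #{gamete combinations producing g_o}

and the pair log-likelihood is the sum of log transmission probabilities
over the loci genotyped in all three individuals. Each offspring is
assigned to the unique compatible maximum-likelihood pair; ties within a
relative tolerance are reported as *ambiguous*, incompatibility with
every pair as *unassigned*.

**Contribution analysis.** Assigned offspring are tabulated in a
dam × sire family matrix. Equality of contribution within a sex is
tested by X² = Σᵢ(Oᵢ − N/k)²/(N/k) over all k candidates (zero
contributors included), d.f. = k − 1.

**Effective population size** from family-size means and variances
(population-variance convention):

    Ne = 4(N − 2) / ((Ks + Vs/Ks) + (Kd + Vd/Kd) − 2)

**Diversity monitoring.** Per-locus allele counts A, allele frequencies,
observed heterozygosity Ho, unbiased gene diversity
He = 2n/(2n−1)·(1 − Σp²), fixation index f = 1 − Ho/He, and
parent→offspring allelic / gene-diversity loss (Aₚ − Aₒ)/Aₚ,
(Heₚ − Heₒ)/Heₚ.

A synthetic mass-spawning simulator (`simulate_mass_cross()`) generates
full crosses with known pedigree truth — Hardy–Weinberg parents,
Dirichlet-skewed or explicit spawning weights, non-spawner fractions,
missing-data and genotyping-error rates — so every stage is testable
without real genotypes.

## Worked example

Matrix-only mode: the packaged family matrix of cross 3 (a cross whose
brooders were not screened for spawning readiness) drives the
contribution and Ne analyses directly:

```r
library(masscross)
run_cross_report(mass_cross_fixture(3))
```

```
=== Mass-cross monitoring report ===
Parental contribution summary (N = 566 assigned offspring)
  contributing: 5 sires, 2 dams; 6 families
  sires: Equal-contribution chi-square: X^2 = 2993.6, d.f. = 9, P < 0.0001
  dams:  Equal-contribution chi-square: X^2 = 5054.1, d.f. = 9, P < 0.0001
  dominant sire 2: 75.8%; dominant dam 8: 99.6%

Effective population size (family-size variance method)
  N = 566 offspring; Ks = 56.60 (Vs = 16944.0), Kd = 56.60 (Vd = 28606.4)
  Ne = 2.46
```

Only 7 of 20 brooders reproduced, one dam produced ~99.6% of the cohort,
and the effective size collapsed to 2.5 against a census of 20.

End-to-end on simulated data with known truth:

```r
sim <- simulate_mass_cross(scenario_presets("cross1_like", seed = 42))
fit <- assign_parentage(sim$dataset, sim$design)
summary(fit)
```

```
Parentage assignment summary
  offspring: 810
  assigned     808 (99.8%)
  ambiguous      2 (0.2%)
  unassigned     0 (0.0%)
  assignment rate: 0.998
```

99.5% of offspring are recovered to their true pair;
`effective_size(family_matrix(fit))` gives Ne = 11.09 for this
moderately skewed cross, and `allele_retention(sim$dataset)` shows the
mild diversity loss (mean A 5.8 → 5.6) expected when most brooders
contribute.

A thin command-line wrapper with `simulate`, `assign`, `contrib`, `ne`
and `report` subcommands is installed at `inst/cli/masscross.R`.

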