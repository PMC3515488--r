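Package: masscross
Title: Parentage Assignment and Genetic Monitoring of Full-Factorial Mass Crosses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for molecular parentage analysis of full-factorial
    mass-spawning crosses genotyped with codominant markers such as
    microsatellites. Assigns each offspring to its maximum-likelihood
    sire-dam pair under an error-free Mendelian transmission model,
    tabulates dam-by-sire family matrices, tests equality of parental
    contributions by chi-square, estimates the effective population size
    from the means and variances of per-parent family sizes, and tracks
    the change in allelic and gene diversity between parents and
    offspring. Includes readers and writers for genotype tables in CSV
    and Genepop formats and a synthetic mass-cross simulator with known
    pedigree truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
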