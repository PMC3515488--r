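# Build a genotype_dataset from genotype strings ("a/b" or "" = missing),
# one row per individual, for readable hand-constructed fixtures.
make_dataset <- function(ids, sexes, roles, geno, loci) {
  n <- length(ids)
  a1 <- a2 <- matrix(NA_integer_, n, length(loci))
  for (i in seq_len(n)) for (j in seq_along(loci)) {
    cell <- geno[[i]][j]
    if (nzchar(cell)) {
      p <- as.integer(strsplit(cell, "/", fixed = TRUE)[[1]])
      a1[i, j] <- p[1]; a2[i, j] <- p[2]
    }
  }
  genotype_dataset(data.frame(id = ids, sex = sexes, role = roles,
                              stringsAsFactors = FALSE),
                   a1, a2, loci)
}

# A minimal trio dataset: one sire, one dam, one offspring over `loci`.
make_trio <- function(sire, dam, off, loci = paste0("L", seq_along(sire))) {
  make_dataset(c("S1", "D1", "O1"),
               c("male", "female", "unknown"),
               c("parent", "parent", "offspring"),
               list(sire, dam, off), loci)
}

expect_dataset_equal <- function(a, b) {
  expect_equal(a$loci, b$loci)
  expect_equal(a$meta$id, b$meta$id)
  expect_equal(a$meta$sex, b$meta$sex)
  expect_equal(a$meta$role, b$meta$role)
  expect_equal(unname(a$a1), unname(b$a1))
  expect_equal(unname(a$a2), unname(b$a2))
}

# independent brute-force chi-square oracle
chisq_oracle <- function(x) {
  E <- sum(x) / length(x)
  s <- 0
  for (o in x) s <- s + (o - E)^2 / E
  s
}

.rand_p <- function(k) { p <- stats::runif(k); p / sum(p) }

# independent evaluation of the Ne formula with population variance
ne_oracle <- function(s, d) {
  pvar <- function(x) sum((x - mean(x))^2) / length(x)
  N <- sum(s)
  4 * (N - 2) / ((mean(s) + pvar(s) / mean(s)) +
                 (mean(d) + pvar(d) / mean(d)) - 2)
}

# enumerate all unordered genotypes over an allele set
all_genotypes <- function(alleles) {
  gs <- list()
  for (i in seq_along(alleles)) for (j in i:length(alleles))
    gs[[length(gs) + 1L]] <- c(alleles[i], alleles[j])
  gs
}
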