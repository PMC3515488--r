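test_that("allele frequencies count gene copies over non-missing genotypes", {
  ds <- make_dataset(c("A", "B", "C"), rep("unknown", 3), rep("offspring", 3),
                     list(c("1/1"), c("1/2"), c("")), "L1")
  af <- allele_frequencies(ds, "L1")
  expect_equal(unname(af$freq), c(0.75, 0.25))
  expect_equal(names(af$freq), c("1", "2"))
  expect_equal(af$n_individuals, 2L)
  expect_equal(af$n_gene_copies, 4L)
  expect_equal(sum(af$freq), 1)
  af1 <- allele_frequencies(ds, "L1", ids = "A")
  expect_equal(unname(af1$freq), 1)
  ds_all_missing <- make_dataset("A", "unknown", "offspring",
                                 list(c("", "1/2")), c("L1", "L2"))
  expect_error(allele_frequencies(ds_all_missing, "L1"), "missing")
})

test_that("estimated frequencies recover the generating spectrum", {
  freqs <- replicate(3, {
    f <- c(0.5, 0.3, 0.2); names(f) <- c(200, 202, 204); f
  }, simplify = FALSE)
  cfg <- sim_config(n_loci = 3L, allele_freqs = freqs, n_sires = 250L,
                    n_dams = 250L, n_offspring = 1L, seed = 31L)
  par <- sample_parents(cfg)
  af <- allele_frequencies(par$dataset, "loc1")
  # binomial standard error on 1000 gene copies ~ 0.016
  expect_true(all(abs(af$freq - c(0.5, 0.3, 0.2)) < 3 * 0.016))
})

test_that("two He routes agree: corrected 1-sum(p^2) vs pairwise difference", {
  # oracle: probability two gene copies drawn without replacement differ
  he_pairwise <- function(copies) {
    n2 <- length(copies); diff <- 0
    for (i in seq_len(n2 - 1)) for (j in (i + 1):n2)
      diff <- diff + (copies[i] != copies[j])
    as.numeric(diff / choose(n2, 2))
  }
  cases <- list(c("1/1", "1/2", "2/2"),
                c("1/2", "3/4", "1/1", "2/3"),
                c("5/5", "5/5", "5/6"))
  for (gs in cases) {
    ds <- make_dataset(sprintf("I%d", seq_along(gs)),
                       rep("unknown", length(gs)),
                       rep("offspring", length(gs)),
                       as.list(gs), "L1")
    st <- diversity_stats(ds)
    copies <- c(ds$a1[, 1], ds$a2[, 1])
    expect_equal(st$per_locus$He, he_pairwise(copies), tolerance = 1e-12)
  }
})

test_that("diversity statistics honour their invariants", {
  ds <- make_dataset(c("A", "B"), rep("unknown", 2), rep("offspring", 2),
                     list(c("1/1", "1/2"), c("1/1", "1/2")), c("L1", "L2"))
  st <- diversity_stats(ds)
  # monomorphic locus: A = 1, Ho = He = 0, f undefined
  expect_equal(st$per_locus$A[1], 1L)
  expect_equal(st$per_locus$Ho[1], 0)
  expect_equal(st$per_locus$He[1], 0)
  expect_true(is.na(st$per_locus$f[1]))
  expect_true(all(st$per_locus$Ho >= 0 & st$per_locus$Ho <= 1))
  expect_true(all(st$per_locus$He >= 0 & st$per_locus$He <= 1))
  # mean f averages polymorphic loci only
  expect_equal(st$means[["f"]], st$per_locus$f[2])
  expect_error(diversity_stats(ds, ids = "A"), "at least 2")
})

test_that("He approaches 0.5 for a balanced two-allele locus and f recovers 0", {
  freqs <- replicate(9, { f <- c(0.5, 0.5); names(f) <- c(200, 202); f },
                     simplify = FALSE)
  cfg <- sim_config(n_loci = 9L, allele_freqs = freqs, n_sires = 250L,
                    n_dams = 250L, n_offspring = 1L, seed = 77L)
  par <- sample_parents(cfg)
  st <- diversity_stats(par$dataset)
  expect_equal(st$means[["He"]], 0.5, tolerance = 0.02)
  # Hardy-Weinberg draw: fixation index centred on 0
  expect_lt(abs(st$means[["f"]]), 0.05)
})

test_that("offspring alleles are conserved subsets of parental alleles", {
  sim <- simulate_mass_cross(sim_config(n_offspring = 250L,
                                        alpha_sire = 0.3, alpha_dam = 0.3,
                                        seed = 13L))
  ds <- sim$dataset
  par_ids <- ds$meta$id[ds$meta$role == "parent"]
  off_ids <- ds$meta$id[ds$meta$role == "offspring"]
  reg_p <- allele_registry(ds, par_ids)
  reg_o <- allele_registry(ds, off_ids)
  ret <- allele_retention(ds)
  for (j in seq_along(ds$loci)) {
    expect_true(all(reg_o[[j]] %in% reg_p[[j]]))
    expect_lte(ret$per_locus$A_offspring[j], ret$per_locus$A_parent[j])
  }
  expect_true(all(ret$per_locus$allelic_loss >= 0))
  # identical sets lose nothing
  ret0 <- allele_retention(ds, parent_ids = par_ids, offspring_ids = par_ids)
  expect_true(all(ret0$per_locus$allelic_loss == 0))
  expect_true(all(abs(ret0$per_locus$gene_loss) < 1e-12))
  expect_equal(sum(ret0$per_locus$n_lost_alleles), 0L)
})

test_that("diversity-loss ratios reproduce the published cohort declines", {
  # published per-cross means (A and He) for parents vs offspring
  tab <- utils::read.csv(system.file("extdata", "table2_diversity_means.csv",
                                     package = "masscross"))
  a_p <- tab$A[tab$cross == 4 & tab$set == "parent"]
  a_o <- tab$A[tab$cross == 4 & tab$set == "offspring"]
  expect_equal(round(100 * diversity_loss(a_p, a_o), 1), 34.3)
  he_p <- tab$He[tab$cross == 4 & tab$set == "parent"]
  he_o <- tab$He[tab$cross == 4 & tab$set == "offspring"]
  expect_equal(round(100 * diversity_loss(he_p, he_o), 1), 25.7)
  # cross 2 retained most diversity
  expect_lt(100 * diversity_loss(tab$A[tab$cross == 2 & tab$set == "parent"],
                                 tab$A[tab$cross == 2 & tab$set == "offspring"]),
            5)
})
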