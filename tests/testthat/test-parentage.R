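test_that("single-locus transmission probabilities match Mendelian enumeration", {
  expect_equal(transmission_probability(c(1, 2), c(3, 4), c(1, 3)), 0.25)
  expect_equal(transmission_probability(c(1, 1), c(1, 1), c(1, 1)), 1.0)
  expect_equal(transmission_probability(c(1, 2), c(1, 2), c(1, 2)), 0.5)
  expect_equal(transmission_probability(c(1, 2), c(1, 2), c(1, 1)), 0.25)
  expect_equal(transmission_probability(c(1, 1), c(1, 1), c(1, 2)), 0.0)
  # unordered arguments
  expect_equal(transmission_probability(c(2, 1), c(4, 3), c(3, 1)), 0.25)
})

test_that("transmission probabilities form a distribution over offspring space", {
  alleles <- 1:4
  gts <- all_genotypes(alleles)
  for (gs in gts) for (gd in gts) {
    tot <- sum(vapply(gts, function(go)
      transmission_probability(gs, gd, go), 1.0))
    expect_equal(tot, 1.0, tolerance = 1e-12)
  }
})

test_that("pair log-likelihood sums per-locus logs and flags exclusions", {
  # 9 loci, each sire {1,2} x dam {3,4} -> offspring {1,3}: p = 0.25 each
  ds <- make_trio(rep("1/2", 9), rep("3/4", 9), rep("1/3", 9))
  res <- pair_loglikelihood(ds, "O1", "S1", "D1")
  expect_equal(res$loglik, 9 * log(0.25))
  expect_equal(res$n_loci_used, 9L)
  expect_true(res$compatible)

  # one incompatible locus disqualifies the pair
  ds2 <- make_trio(rep("1/1", 9), rep("1/1", 9),
                   c(rep("1/1", 8), "1/2"))
  res2 <- pair_loglikelihood(ds2, "O1", "S1", "D1")
  expect_false(res2$compatible)
  expect_identical(res2$loglik, -Inf)
  expect_equal(res2$reason, "incompatible locus")
})

test_that("loci missing in any trio member are skipped", {
  geno_s <- c("1/2", "", "1/2", "1/2", "1/2", "1/2")
  geno_d <- c("3/4", "3/4", "", "3/4", "3/4", "3/4")
  geno_o <- c("1/3", "1/3", "1/3", "", "1/3", "1/3")
  ds <- make_trio(geno_s, geno_d, geno_o)
  res <- pair_loglikelihood(ds, "O1", "S1", "D1", min_loci = 3L)
  # brute-force recomputation on the fully genotyped locus subset (1,5,6)
  expect_equal(res$n_loci_used, 3L)
  expect_equal(res$loglik, 3 * log(0.25))
  # below min_loci -> insufficient
  res2 <- pair_loglikelihood(ds, "O1", "S1", "D1", min_loci = 5L)
  expect_false(res2$compatible)
  expect_equal(res2$reason, "insufficient loci")
})

test_that("assignment recovers the true pedigree on error-free simulations", {
  cfg <- sim_config(n_offspring = 300L, contribution = "equal", seed = 303L)
  sim <- simulate_mass_cross(cfg)
  fit <- assign_parentage(sim$dataset, sim$design)
  rec <- fit$records
  expect_equal(nrow(rec), 300L)
  expect_equal(sum(table(rec$status)), 300L)
  hit <- rec$status == "assigned" &
    rec$sire_id == sim$pedigree$sire_id & rec$dam_id == sim$pedigree$dam_id
  expect_gte(mean(hit), 0.95)
  # error-free data: the true pair is never excluded, so a wrong winner is
  # only possible when a false pair is compatible everywhere and strictly
  # more likely than the truth
  true_col <- match(paste(sim$pedigree$dam_id, sim$pedigree$sire_id, sep = ":"),
                    colnames(fit$loglik_matrix))
  true_ll <- fit$loglik_matrix[cbind(seq_len(nrow(rec)), true_col)]
  expect_true(all(is.finite(true_ll)))
  wrong <- which(rec$status == "assigned" & !hit)
  expect_true(all(rec$loglik[wrong] > true_ll[wrong]))
  # consistency with the scalar likelihood path on a few offspring
  for (i in c(1L, 150L, 300L)) {
    r <- rec[i, ]
    if (r$status != "assigned") next
    res <- pair_loglikelihood(sim$dataset, r$offspring_id, r$sire_id, r$dam_id)
    expect_equal(res$loglik, r$loglik)
  }
})

test_that("assignment is invariant to parent and locus ordering", {
  cfg <- sim_config(n_offspring = 80L, seed = 17L)
  sim <- simulate_mass_cross(cfg)
  fit1 <- assign_parentage(sim$dataset, sim$design)
  perm_design <- cross_design(rev(sim$design$sire_ids),
                              sample(sim$design$dam_ids))
  fit2 <- assign_parentage(sim$dataset, perm_design)
  ds_perm <- sim$dataset
  jj <- rev(seq_along(ds_perm$loci))
  ds_perm$a1 <- ds_perm$a1[, jj]; ds_perm$a2 <- ds_perm$a2[, jj]
  ds_perm$loci <- ds_perm$loci[jj]
  fit3 <- assign_parentage(ds_perm, sim$design)
  for (f in list(fit2, fit3)) {
    expect_equal(f$records$status, fit1$records$status)
    expect_equal(f$records$sire_id, fit1$records$sire_id)
    expect_equal(f$records$dam_id, fit1$records$dam_id)
    expect_equal(f$records$loglik, fit1$records$loglik)
  }
})

test_that("thresholds and degenerate offspring produce unassigned, not errors", {
  # offspring genotyped at only 3 loci with min_loci = 5 -> unassigned
  geno_o <- c("1/3", "1/3", "1/3", rep("", 6))
  ds <- make_trio(rep("1/2", 9), rep("3/4", 9), geno_o)
  design <- cross_design("S1", "D1", ds)
  fit <- assign_parentage(ds, design, min_loci = 5L)
  expect_equal(fit$records$status, "unassigned")
  # with a permissive threshold the single compatible pair is assigned
  fit2 <- assign_parentage(ds, design, min_loci = 3L)
  expect_equal(fit2$records$status, "assigned")
  expect_equal(fit2$records$sire_id, "S1")
  expect_equal(fit2$records$dam_id, "D1")
  expect_equal(assignment_rate(fit2), 1.0)
  # all loci missing
  ds3 <- make_trio(rep("1/2", 9), rep("3/4", 9), rep("", 9))
  fit3 <- assign_parentage(ds3, cross_design("S1", "D1", ds3))
  expect_equal(fit3$records$status, "unassigned")
  expect_equal(assignment_rate(fit3), 0.0)
})

test_that("genotyping errors degrade assignments gracefully", {
  cfg <- sim_config(n_offspring = 150L, contribution = "equal",
                    error_rate = 0.05, seed = 99L)
  sim <- simulate_mass_cross(cfg)
  expect_no_error(fit <- assign_parentage(sim$dataset, sim$design))
  rec <- fit$records
  hit <- rec$status == "assigned" &
    rec$sire_id == sim$pedigree$sire_id & rec$dam_id == sim$pedigree$dam_id
  cfg0 <- sim_config(n_offspring = 150L, contribution = "equal", seed = 99L)
  sim0 <- simulate_mass_cross(cfg0)
  fit0 <- assign_parentage(sim0$dataset, sim0$design)
  rec0 <- fit0$records
  hit0 <- rec0$status == "assigned" &
    rec0$sire_id == sim0$pedigree$sire_id & rec0$dam_id == sim0$pedigree$dam_id
  # errors can only lose correct assignments, never gain them
  expect_lte(mean(hit), mean(hit0))
  expect_gt(sum(rec$status == "unassigned"), 0L)
})

test_that("assignment rate matches the bookkeeping fractions", {
  fake <- structure(list(records = data.frame(
    offspring_id = sprintf("O%03d", 1:810),
    status = rep(c("assigned", "unassigned"), c(784, 26)))),
    class = "parentage")
  expect_equal(assignment_rate(fake), 784 / 810)
  expect_equal(round(100 * assignment_rate(fake), 1), 96.8)
  fake$records$status <- rep(c("assigned", "unassigned"), c(563, 810 - 563))
  fake$records <- fake$records[1:570, ]
  expect_equal(round(100 * assignment_rate(fake), 1), 98.8)
})
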