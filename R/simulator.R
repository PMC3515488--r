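#' Configure a synthetic mass-cross simulation
#'
#' Parameters of a full-factorial mass-spawning simulation with known
#' pedigree truth. The defaults emulate the monitored hatchery crosses:
#' a 9-locus microsatellite panel with 7 alleles per locus (allele
#' frequencies drawn from a flat Dirichlet, giving expected gene diversity
#' around 0.75), 10 candidate sires x 10 dams, 810 offspring, and
#' Dirichlet-distributed spawning weights producing the uneven parental
#' contributions mass spawning shows in practice.
#'
#' @param n_loci number of loci (default 9).
#' @param n_alleles alleles per locus (default 7); ignored when
#'   \code{allele_freqs} is supplied.
#' @param allele_freqs optional list (one element per locus) of named
#'   frequency vectors (names = integer allele sizes, values sum to 1).
#' @param n_sires,n_dams candidate parents per sex (default 10 each).
#' @param n_offspring offspring sampled from the cross (default 810).
#' @param contribution \code{"dirichlet"} (default), \code{"equal"}, or
#'   \code{"matrix"} (explicit family weights for non-independent mating).
#' @param alpha_sire,alpha_dam symmetric Dirichlet concentration of the
#'   spawning weights (default 1; smaller = more skew).
#' @param weight_sire,weight_dam optional explicit per-parent weights
#'   (override the Dirichlet draw).
#' @param weight_matrix dams x sires family weight matrix for
#'   \code{contribution = "matrix"}.
#' @param nonspawner_sire,nonspawner_dam fraction of candidates per sex
#'   forced to weight 0 (default 0).
#' @param missing_rate per-genotype missing probability (default 0).
#' @param error_rate per-allele-copy substitution probability (default 0).
#' @param seed mandatory integer seed; the whole run uses one stream.
#' @return Object of class \code{sim_config}.
#' @seealso [scenario_presets()], [simulate_mass_cross()]
#' @export
sim_config <- function(n_loci = 9L, n_alleles = 7L, allele_freqs = NULL,
                       n_sires = 10L, n_dams = 10L, n_offspring = 810L,
                       contribution = c("dirichlet", "equal", "matrix"),
                       alpha_sire = 1, alpha_dam = 1,
                       weight_sire = NULL, weight_dam = NULL,
                       weight_matrix = NULL,
                       nonspawner_sire = 0, nonspawner_dam = 0,
                       missing_rate = 0, error_rate = 0, seed) {
  contribution <- match.arg(contribution)
  if (missing(seed) || is.null(seed))
    stop("a seed is mandatory for reproducible simulation")
  stopifnot(n_loci >= 1L, n_sires >= 1L, n_dams >= 1L, n_offspring >= 1L,
            missing_rate >= 0, missing_rate <= 1,
            error_rate >= 0, error_rate <= 1,
            nonspawner_sire >= 0, nonspawner_sire < 1,
            nonspawner_dam >= 0, nonspawner_dam < 1)
  if (!is.null(allele_freqs)) {
    stopifnot(length(allele_freqs) == n_loci)
    for (f in allele_freqs) {
      if (is.null(names(f)) || any(f < 0) || abs(sum(f) - 1) > 1e-8)
        stop("each allele frequency vector must be named and sum to 1")
      if (sum(f > 0) < 1) stop("degenerate allele frequency vector")
    }
  } else stopifnot(n_alleles >= 1L)
  if (contribution == "matrix") {
    if (is.null(weight_matrix) ||
        !all(dim(weight_matrix) == c(n_dams, n_sires)))
      stop("contribution = 'matrix' needs a dams x sires weight_matrix")
    if (any(weight_matrix < 0) || sum(weight_matrix) <= 0)
      stop("weight_matrix must be non-negative with positive sum")
  }
  structure(list(n_loci = as.integer(n_loci), n_alleles = as.integer(n_alleles),
                 allele_freqs = allele_freqs, n_sires = as.integer(n_sires),
                 n_dams = as.integer(n_dams),
                 n_offspring = as.integer(n_offspring),
                 contribution = contribution, alpha_sire = alpha_sire,
                 alpha_dam = alpha_dam, weight_sire = weight_sire,
                 weight_dam = weight_dam, weight_matrix = weight_matrix,
                 nonspawner_sire = nonspawner_sire,
                 nonspawner_dam = nonspawner_dam,
                 missing_rate = missing_rate, error_rate = error_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Preset simulation scenarios
#'
#' \code{"cross1_like"}: brooders screened for spawning readiness — all
#' sires and ~9 of 10 dams spawn, mild-to-moderate skew, 810 offspring.
#' \code{"cross3_like"}: unscreened brooders — 5 spawning sires, 2 spawning
#' dams with one dam carrying ~99\% of the weight, 570 offspring.
#'
#' @param name preset name.
#' @param seed integer seed.
#' @return A [sim_config()].
#' @export
scenario_presets <- function(name = c("cross1_like", "cross3_like"), seed) {
  name <- match.arg(name)
  switch(name,
    cross1_like = sim_config(n_offspring = 810L, contribution = "dirichlet",
                             alpha_sire = 1, alpha_dam = 1,
                             nonspawner_dam = 0.1, seed = seed),
    cross3_like = {
      ws <- c(0, 0.76, 0.23, 0, 0, 0.003, 0, 0, 0.003, 0.004)
      wd <- c(0.003, 0, 0, 0, 0, 0, 0, 0.997, 0, 0)
      sim_config(n_offspring = 570L, contribution = "dirichlet",
                 weight_sire = ws / sum(ws), weight_dam = wd / sum(wd),
                 seed = seed)
    })
}

# allele sizes on a dinucleotide ladder per locus, 3-digit friendly
.sim_allele_sizes <- function(locus_index, k) {
  base <- 100L + 30L * ((locus_index - 1L) %% 25L)
  base + 2L * (seq_len(k) - 1L)
}

.rdirichlet1 <- function(k, alpha) {
  g <- stats::rgamma(k, shape = alpha)
  if (sum(g) <= 0) g <- rep(1, k)
  g / sum(g)
}

.sim_freqs <- function(config) {
  if (!is.null(config$allele_freqs)) {
    lapply(config$allele_freqs, function(f) {
      out <- as.numeric(f); names(out) <- names(f); out
    })
  } else {
    lapply(seq_len(config$n_loci), function(j) {
      f <- .rdirichlet1(config$n_alleles, 1)
      names(f) <- .sim_allele_sizes(j, config$n_alleles)
      f
    })
  }
}

#' Draw candidate parents under Hardy-Weinberg proportions
#'
#' Samples each parental genotype by drawing two alleles independently from
#' the per-locus frequencies (supplied in the config, or drawn once from a
#' flat Dirichlet). Sires are named \code{S01...}, dams \code{D01...}.
#'
#' @param config a [sim_config()].
#' @param .seed set the stream from \code{config$seed} before drawing
#'   (default TRUE; [simulate_mass_cross()] seeds once and disables this).
#' @return List: \code{dataset} (parents-only \code{genotype_dataset}) and
#'   \code{allele_freqs} (the frequencies used).
#' @export
sample_parents <- function(config, .seed = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (.seed) set.seed(config$seed)
  freqs <- .sim_freqs(config)
  n_par <- config$n_sires + config$n_dams
  ids <- c(sprintf("S%02d", seq_len(config$n_sires)),
           sprintf("D%02d", seq_len(config$n_dams)))
  sexes <- rep(c("male", "female"), c(config$n_sires, config$n_dams))
  a1 <- a2 <- matrix(NA_integer_, n_par, config$n_loci)
  for (j in seq_len(config$n_loci)) {
    sizes <- as.integer(names(freqs[[j]]))
    x1 <- sizes[sample.int(length(sizes), n_par, replace = TRUE,
                           prob = freqs[[j]])]
    x2 <- sizes[sample.int(length(sizes), n_par, replace = TRUE,
                           prob = freqs[[j]])]
    a1[, j] <- pmin(x1, x2); a2[, j] <- pmax(x1, x2)
  }
  ds <- genotype_dataset(
    data.frame(id = ids, sex = sexes, role = "parent",
               stringsAsFactors = FALSE),
    a1, a2, sprintf("loc%d", seq_len(config$n_loci)))
  list(dataset = ds, allele_freqs = freqs)
}

.spawning_weights <- function(k, alpha, explicit, nonspawner_frac) {
  if (!is.null(explicit)) {
    w <- as.numeric(explicit)
    stopifnot(length(w) == k, all(w >= 0), sum(w) > 0)
    return(w / sum(w))
  }
  w <- if (is.finite(alpha)) .rdirichlet1(k, alpha) else rep(1 / k, k)
  n_out <- floor(nonspawner_frac * k)
  if (n_out > 0) {
    w[sample.int(k, n_out)] <- 0
    if (sum(w) <= 0) stop("all spawning weights are zero")
    w <- w / sum(w)
  }
  w
}

#' Simulate the offspring of one mass cross
#'
#' Draws per-parent spawning weights under the configured contribution
#' model (equal, Dirichlet, or an explicit family weight matrix), forces
#' the configured fraction of non-spawners to weight zero, samples each
#' offspring's family with probability proportional to w_sire x w_dam
#' (or the explicit matrix), and transmits one uniformly random allele
#' from each parent per locus. Genotyping noise is then applied:
#' \code{missing_rate} masks whole genotypes and \code{error_rate}
#' substitutes single allele copies with a uniformly chosen other
#' registry allele.
#'
#' @param parents result of [sample_parents()] (or a parents-only
#'   \code{genotype_dataset}).
#' @param config a [sim_config()].
#' @param .seed set the stream from \code{config$seed + 1} before drawing
#'   (default TRUE; disabled inside [simulate_mass_cross()]).
#' @return Object of class \code{mass_cross_sim}: \code{dataset} (parents
#'   plus offspring), \code{pedigree} (data.frame offspring_id, sire_id,
#'   dam_id — the truth), \code{design} ([cross_design()]), and the
#'   realised \code{weights}.
#' @export
simulate_cross <- function(parents, config, .seed = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (.seed) set.seed(config$seed + 1L)
  pds <- if (inherits(parents, "genotype_dataset")) parents else parents$dataset
  design <- design_from_dataset(pds)
  ns <- length(design$sire_ids); nd <- length(design$dam_ids)
  stopifnot(ns == config$n_sires, nd == config$n_dams)
  if (config$contribution == "matrix") {
    W <- config$weight_matrix / sum(config$weight_matrix)
    ws <- colSums(W); wd <- rowSums(W)
  } else {
    ws <- .spawning_weights(ns, if (config$contribution == "equal") Inf
                                else config$alpha_sire,
                            config$weight_sire, config$nonspawner_sire)
    wd <- .spawning_weights(nd, if (config$contribution == "equal") Inf
                                else config$alpha_dam,
                            config$weight_dam, config$nonspawner_dam)
    W <- outer(wd, ws)   # independent mating: P(family) = w_d * w_s
  }
  n <- config$n_offspring
  fam <- sample.int(ns * nd, n, replace = TRUE, prob = as.vector(t(W)))
  dam_idx <- (fam - 1L) %/% ns + 1L
  sire_idx <- (fam - 1L) %% ns + 1L
  sire_rows <- match(design$sire_ids, pds$meta$id)[sire_idx]
  dam_rows <- match(design$dam_ids, pds$meta$id)[dam_idx]
  L <- config$n_loci
  a1 <- a2 <- matrix(NA_integer_, n, L)
  for (j in seq_len(L)) {
    from_sire <- ifelse(stats::runif(n) < 0.5,
                        pds$a1[sire_rows, j], pds$a2[sire_rows, j])
    from_dam <- ifelse(stats::runif(n) < 0.5,
                       pds$a1[dam_rows, j], pds$a2[dam_rows, j])
    a1[, j] <- pmin(from_sire, from_dam)
    a2[, j] <- pmax(from_sire, from_dam)
  }
  if (config$error_rate > 0) {
    reg <- allele_registry(pds)
    for (j in seq_len(L)) {
      sizes <- reg[[j]]
      if (length(sizes) < 2L) next
      for (mat in c("a1", "a2")) {
        hit <- which(stats::runif(n) < config$error_rate)
        if (!length(hit)) next
        cur <- get(mat)[hit, j]
        sub <- vapply(cur, function(a)
          sample(setdiff(sizes, a), 1L), integer(1))
        if (mat == "a1") a1[hit, j] <- sub else a2[hit, j] <- sub
      }
    }
    swap <- a1 > a2
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  }
  if (config$missing_rate > 0) {
    mask <- matrix(stats::runif(n * L) < config$missing_rate, n, L)
    a1[mask] <- NA_integer_; a2[mask] <- NA_integer_
  }
  off_ids <- sprintf("O%04d", seq_len(n))
  meta <- rbind(pds$meta,
                data.frame(id = off_ids, sex = "unknown", role = "offspring",
                           stringsAsFactors = FALSE))
  ds <- genotype_dataset(meta, rbind(pds$a1, a1), rbind(pds$a2, a2), pds$loci)
  pedigree <- data.frame(offspring_id = off_ids,
                         sire_id = design$sire_ids[sire_idx],
                         dam_id = design$dam_ids[dam_idx],
                         stringsAsFactors = FALSE)
  structure(list(dataset = ds, pedigree = pedigree, design = design,
                 weights = list(sire = ws, dam = wd, family = W),
                 config = config),
            class = "mass_cross_sim")
}

#' Simulate a complete mass cross (parents + offspring) in one stream
#'
#' Seeds the random stream once from \code{config$seed}, draws the parents,
#' then the offspring — the reproducibility entry point.
#'
#' @param config a [sim_config()].
#' @return A \code{mass_cross_sim} (see [simulate_cross()]) with the
#'   parental allele frequencies attached as \code{allele_freqs}.
#' @export
simulate_mass_cross <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  parents <- sample_parents(config, .seed = FALSE)
  sim <- simulate_cross(parents$dataset, config, .seed = FALSE)
  sim$allele_freqs <- parents$allele_freqs
  sim
}

#' @export
print.mass_cross_sim <- function(x, ...) {
  cat("Simulated full-factorial mass cross\n")
  cat(sprintf("  %d sires x %d dams, %d offspring, %d loci (seed %d)\n",
              length(x$design$sire_ids), length(x$design$dam_ids),
              nrow(x$pedigree), length(x$dataset$loci), x$config$seed))
  cat(sprintf("  realised families: %d\n",
              nrow(unique(x$pedigree[, c("sire_id", "dam_id")]))))
  invisible(x)
}

#' True family matrix of a simulation
#'
#' @param sim a \code{mass_cross_sim}.
#' @return The dam x sire \code{family_matrix} of the true pedigree.
#' @export
true_family_matrix <- function(sim) {
  stopifnot(inherits(sim, "mass_cross_sim"))
  counts <- table(factor(sim$pedigree$dam_id, levels = sim$design$dam_ids),
                  factor(sim$pedigree$sire_id, levels = sim$design$sire_ids))
  m <- matrix(as.integer(counts), nrow = length(sim$design$dam_ids),
              dimnames = list(dam = sim$design$dam_ids,
                              sire = sim$design$sire_ids))
  family_matrix(m)
}

#' Fast family-count simulation (no genotypes)
#'
#' Draws spawning weights and the multinomial family counts of one cross
#' without simulating genotypes — useful for null-distribution replicates
#' of the contribution chi-square.
#'
#' @param config a [sim_config()].
#' @param .seed seed the stream from \code{config$seed} (default TRUE; set
#'   FALSE inside replicate loops sharing one stream).
#' @return A \code{family_matrix} of simulated counts.
#' @export
sim_family_counts <- function(config, .seed = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (.seed) set.seed(config$seed)
  ns <- config$n_sires; nd <- config$n_dams
  if (config$contribution == "matrix") {
    W <- config$weight_matrix / sum(config$weight_matrix)
  } else {
    ws <- .spawning_weights(ns, if (config$contribution == "equal") Inf
                                else config$alpha_sire,
                            config$weight_sire, config$nonspawner_sire)
    wd <- .spawning_weights(nd, if (config$contribution == "equal") Inf
                                else config$alpha_dam,
                            config$weight_dam, config$nonspawner_dam)
    W <- outer(wd, ws)
  }
  counts <- stats::rmultinom(1, config$n_offspring, as.vector(W))
  m <- matrix(as.integer(counts), nrow = nd,
              dimnames = list(dam = sprintf("D%02d", seq_len(nd)),
                              sire = sprintf("S%02d", seq_len(ns))))
  family_matrix(m)
}
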