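#' Allele frequencies at one locus
#'
#' Counts each allele over the non-missing gene copies (two per genotyped
#' individual) of the chosen individuals and normalises.
#'
#' @param dataset a \code{genotype_dataset}.
#' @param locus locus name.
#' @param ids optional subset of individual ids (default: all).
#' @return List with \code{freq} (named numeric, sums to 1),
#'   \code{n_individuals} (non-missing at this locus) and
#'   \code{n_gene_copies}.
#' @export
allele_frequencies <- function(dataset, locus, ids = NULL) {
  j <- match(locus, dataset$loci)
  if (is.na(j)) stop("unknown locus: ", locus)
  rows <- .resolve_ids(dataset, ids)
  x1 <- dataset$a1[rows, j]; x2 <- dataset$a2[rows, j]
  keep <- !is.na(x1)
  if (!any(keep))
    stop("all genotypes missing at locus ", locus)
  copies <- c(x1[keep], x2[keep])
  tab <- table(copies)
  freq <- as.numeric(tab) / length(copies)
  names(freq) <- names(tab)
  list(freq = freq, n_individuals = sum(keep),
       n_gene_copies = length(copies))
}

#' Per-locus and mean genetic diversity
#'
#' For each locus: A = number of distinct alleles; Ho = fraction of
#' non-missing genotypes that are heterozygous; He = unbiased gene
#' diversity \eqn{\frac{2n}{2n-1}(1 - \sum p_i^2)} with n the number of
#' genotyped individuals (Nei's small-sample correction); fixation index
#' f = 1 - Ho/He (undefined, reported NA, at monomorphic loci where
#' He = 0). Means are unweighted over loci; mean f averages the
#' polymorphic loci only.
#'
#' @param dataset a \code{genotype_dataset}.
#' @param ids optional subset of individual ids (>= 2 individuals).
#' @return Object of class \code{diversity_stats}: \code{per_locus}
#'   data.frame (locus, n, A, Ho, He, f), \code{means} (named numeric:
#'   A, Ho, He, f), \code{N} individuals in the set.
#' @export
diversity_stats <- function(dataset, ids = NULL) {
  rows <- .resolve_ids(dataset, ids)
  if (length(rows) < 2L) stop("diversity statistics need at least 2 individuals")
  per <- lapply(seq_along(dataset$loci), function(j) {
    x1 <- dataset$a1[rows, j]; x2 <- dataset$a2[rows, j]
    keep <- !is.na(x1)
    n <- sum(keep)
    if (n == 0L)
      return(data.frame(locus = dataset$loci[j], n = 0L, A = NA_integer_,
                        Ho = NA_real_, He = NA_real_, f = NA_real_))
    alleles <- c(x1[keep], x2[keep])
    p <- as.numeric(table(alleles)) / (2 * n)
    A <- length(p)
    Ho <- mean(x1[keep] != x2[keep])
    He <- (2 * n / (2 * n - 1)) * (1 - sum(p^2))
    f <- if (He > 0) 1 - Ho / He else NA_real_
    data.frame(locus = dataset$loci[j], n = n, A = A, Ho = Ho, He = He, f = f)
  })
  per <- do.call(rbind, per)
  means <- c(A = mean(per$A, na.rm = TRUE),
             Ho = mean(per$Ho, na.rm = TRUE),
             He = mean(per$He, na.rm = TRUE),
             f = mean(per$f, na.rm = TRUE))
  structure(list(per_locus = per, means = means, N = length(rows)),
            class = "diversity_stats")
}

#' @export
print.diversity_stats <- function(x, ...) {
  cat(sprintf("Genetic diversity over %d loci, N = %d individuals\n",
              nrow(x$per_locus), x$N))
  cat(sprintf("  mean A = %.1f, Ho = %.2f, He = %.2f, f = %.2f\n",
              x$means["A"], x$means["Ho"], x$means["He"], x$means["f"]))
  invisible(x)
}

#' Fractional loss of a diversity measure between generations
#'
#' \code{(parent - offspring) / parent}, vectorised; the convention used
#' for allelic and gene-diversity loss between a parental set and its
#' offspring cohort.
#'
#' @param parent,offspring numeric values of the measure in the two sets.
#' @return Fractional loss (negative = gain).
#' @export
diversity_loss <- function(parent, offspring) {
  (parent - offspring) / parent
}

#' Allelic and gene-diversity retention from parents to offspring
#'
#' Compares diversity in a parental set and an offspring set over the same
#' panel: per-locus and mean allelic loss \code{(A_p - A_o)/A_p}, gene
#' diversity loss \code{(He_p - He_o)/He_p}, and the alleles present in
#' parents but absent in offspring.
#'
#' @param dataset a \code{genotype_dataset} holding both sets.
#' @param parent_ids,offspring_ids ids of the two sets; default to the
#'   dataset's \code{parent} and \code{offspring} roles.
#' @return Object of class \code{allele_retention}: \code{per_locus}
#'   data.frame (A and He in both sets, losses, lost allele list-column),
#'   \code{mean} named numerics (losses on mean A and mean He),
#'   \code{lost_alleles} named list per locus.
#' @export
allele_retention <- function(dataset, parent_ids = NULL, offspring_ids = NULL) {
  if (is.null(parent_ids))
    parent_ids <- dataset$meta$id[dataset$meta$role == "parent"]
  if (is.null(offspring_ids))
    offspring_ids <- dataset$meta$id[dataset$meta$role == "offspring"]
  if (!length(parent_ids) || !length(offspring_ids))
    stop("both parental and offspring sets must be non-empty")
  dp <- diversity_stats(dataset, parent_ids)
  do <- diversity_stats(dataset, offspring_ids)
  reg_p <- allele_registry(dataset, parent_ids)
  reg_o <- allele_registry(dataset, offspring_ids)
  lost <- Map(setdiff, reg_p, reg_o)
  per <- data.frame(
    locus = dp$per_locus$locus,
    A_parent = dp$per_locus$A, A_offspring = do$per_locus$A,
    allelic_loss = diversity_loss(dp$per_locus$A, do$per_locus$A),
    He_parent = dp$per_locus$He, He_offspring = do$per_locus$He,
    gene_loss = diversity_loss(dp$per_locus$He, do$per_locus$He),
    n_lost_alleles = vapply(lost, length, 1L),
    stringsAsFactors = FALSE, row.names = NULL)
  means <- c(
    allelic_loss = diversity_loss(dp$means[["A"]], do$means[["A"]]),
    gene_loss = diversity_loss(dp$means[["He"]], do$means[["He"]]))
  structure(list(per_locus = per, mean = means, lost_alleles = lost,
                 parents = dp, offspring = do),
            class = "allele_retention")
}

#' @export
print.allele_retention <- function(x, ...) {
  cat("Parent-to-offspring diversity retention\n")
  cat(sprintf("  mean A: %.1f -> %.1f (loss %.1f%%)\n",
              x$parents$means["A"], x$offspring$means["A"],
              100 * x$mean["allelic_loss"]))
  cat(sprintf("  mean He: %.2f -> %.2f (loss %.1f%%)\n",
              x$parents$means["He"], x$offspring$means["He"],
              100 * x$mean["gene_loss"]))
  n_lost <- sum(x$per_locus$n_lost_alleles)
  cat(sprintf("  parental alleles absent in offspring: %d\n", n_lost))
  invisible(x)
}
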