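#' Mendelian transmission probability at one locus
#'
#' Probability of an offspring genotype given a sire and a dam genotype
#' under error-free Mendelian segregation: each parent transmits one of its
#' two alleles with probability 1/2, so each of the 2 x 2 gamete
#' combinations carries weight 1/4 and the probability is the number of
#' combinations producing the (unordered) offspring genotype divided by 4.
#' Incompatible trios have probability 0.
#'
#' @param sire,dam,offspring length-2 integer vectors, the unordered allele
#'   pairs of the three genotypes (none missing).
#' @return A probability in \{0, 0.25, 0.5, 1\}.
#' @examples
#' transmission_probability(c(1, 2), c(3, 4), c(1, 3))  # 0.25
#' transmission_probability(c(1, 2), c(1, 2), c(1, 2))  # 0.5
#' @export
transmission_probability <- function(sire, dam, offspring) {
  stopifnot(length(sire) == 2L, length(dam) == 2L, length(offspring) == 2L)
  if (anyNA(c(sire, dam, offspring)))
    stop("transmission_probability requires non-missing genotypes")
  o1 <- min(offspring); o2 <- max(offspring)
  hits <- 0L
  for (a in sire) for (b in dam) {
    if (min(a, b) == o1 && max(a, b) == o2) hits <- hits + 1L
  }
  hits / 4
}

#' Multilocus log-likelihood of one parental pair
#'
#' Sums log transmission probabilities over the loci where offspring, sire
#' and dam are all genotyped. A locus with transmission probability 0 makes
#' the pair incompatible (log-likelihood \code{-Inf}); fewer usable loci
#' than \code{min_loci} also disqualifies the pair.
#'
#' @param dataset a \code{genotype_dataset}.
#' @param offspring_id,sire_id,dam_id individual ids.
#' @param min_loci minimum number of fully genotyped loci required (default
#'   5 of a 9-locus panel).
#' @return List with \code{loglik} (\code{-Inf} when incompatible or
#'   under-genotyped), \code{n_loci_used}, \code{compatible} (logical) and
#'   \code{reason} (\code{NA}, \code{"incompatible locus"} or
#'   \code{"insufficient loci"}).
#' @export
pair_loglikelihood <- function(dataset, offspring_id, sire_id, dam_id,
                               min_loci = 5L) {
  ro <- .resolve_ids(dataset, offspring_id)
  rs <- .resolve_ids(dataset, sire_id)
  rd <- .resolve_ids(dataset, dam_id)
  ll <- 0; used <- 0L; excluded <- FALSE
  for (j in seq_along(dataset$loci)) {
    trio <- c(dataset$a1[ro, j], dataset$a2[ro, j],
              dataset$a1[rs, j], dataset$a2[rs, j],
              dataset$a1[rd, j], dataset$a2[rd, j])
    if (anyNA(trio)) next
    p <- transmission_probability(trio[3:4], trio[5:6], trio[1:2])
    used <- used + 1L
    if (p == 0) { excluded <- TRUE; ll <- -Inf } else if (!excluded) {
      ll <- ll + log(p)
    }
  }
  if (excluded)
    return(list(loglik = -Inf, n_loci_used = used, compatible = FALSE,
                reason = "incompatible locus"))
  if (used < min_loci)
    return(list(loglik = -Inf, n_loci_used = used, compatible = FALSE,
                reason = "insufficient loci"))
  list(loglik = ll, n_loci_used = used, compatible = TRUE, reason = NA_character_)
}

#' Assign offspring to maximum-likelihood parental pairs
#'
#' The central fit of the package. For every offspring the multilocus
#' Mendelian log-likelihood of every candidate sire x dam pair in the
#' full-factorial design is evaluated; the offspring is \emph{assigned} to
#' the unique compatible pair of maximal likelihood, \emph{ambiguous} when
#' two or more compatible pairs tie within \code{tie_tol} of the maximum
#' (ties are reported, never silently broken), and \emph{unassigned} when
#' no pair is compatible at the genotyped loci (or too few loci are
#' usable). Loci with a missing genotype in any member of a trio are
#' skipped for that trio.
#'
#' @param dataset a \code{genotype_dataset} holding parents and offspring.
#' @param design a [cross_design()]; defaults to all sexed parents in the
#'   dataset via [design_from_dataset()].
#' @param min_loci minimum usable loci per trio (default 5).
#' @param tie_tol relative log-likelihood tolerance declaring a tie
#'   (default 1e-9).
#' @return An object of class \code{parentage}: list with \code{records}
#'   (one row per offspring: id, status, sire_id, dam_id, loglik,
#'   n_loci_used, n_compatible), \code{ties} (per ambiguous offspring, the
#'   tied pairs), \code{loglik_matrix} (offspring x candidate pairs),
#'   \code{design}, \code{min_loci}, \code{tie_tol}.
#' @seealso [assignment_rate()], [family_matrix()], [summary.parentage()]
#' @export
assign_parentage <- function(dataset, design = design_from_dataset(dataset),
                             min_loci = 5L, tie_tol = 1e-9) {
  stopifnot(inherits(dataset, "genotype_dataset"),
            inherits(design, "cross_design"))
  off_rows <- which(dataset$meta$role == "offspring")
  if (!length(off_rows)) stop("dataset contains no offspring")
  rs <- .resolve_ids(dataset, design$sire_ids)
  rd <- .resolve_ids(dataset, design$dam_ids)
  n_off <- length(off_rows)
  ns <- length(rs); nd <- length(rd)
  n_pair <- ns * nd
  pair_sire <- rep(seq_len(ns), times = nd)   # pair index p = (d-1)*ns + s
  pair_dam <- rep(seq_len(nd), each = ns)
  ll <- matrix(0, n_off, n_pair)
  used <- matrix(0L, n_off, n_pair)
  for (j in seq_along(dataset$loci)) {
    oa1 <- dataset$a1[off_rows, j]; oa2 <- dataset$a2[off_rows, j]
    off_ok <- !is.na(oa1)
    if (!any(off_ok)) next
    for (p in seq_len(n_pair)) {
      s <- rs[pair_sire[p]]; d <- rd[pair_dam[p]]
      sa <- c(dataset$a1[s, j], dataset$a2[s, j])
      da <- c(dataset$a1[d, j], dataset$a2[d, j])
      if (anyNA(sa) || anyNA(da)) next
      # 4 equiprobable gamete combinations, canonicalised
      c1 <- pmin(rep(sa, each = 2L), rep(da, 2L))
      c2 <- pmax(rep(sa, each = 2L), rep(da, 2L))
      cnt <- integer(n_off)
      for (g in 1:4)
        cnt <- cnt + as.integer(off_ok & oa1 == c1[g] & oa2 == c2[g])
      used[, p] <- used[, p] + as.integer(off_ok)
      contrib <- rep(-Inf, n_off)
      contrib[cnt > 0L] <- log(cnt[cnt > 0L] / 4)
      ll[off_ok, p] <- ll[off_ok, p] + contrib[off_ok]
    }
  }
  ll[used < min_loci] <- -Inf
  pair_lab_s <- design$sire_ids[pair_sire]
  pair_lab_d <- design$dam_ids[pair_dam]
  colnames(ll) <- paste(pair_lab_d, pair_lab_s, sep = ":")
  rownames(ll) <- dataset$meta$id[off_rows]
  records <- data.frame(
    offspring_id = dataset$meta$id[off_rows],
    status = character(n_off), sire_id = NA_character_,
    dam_id = NA_character_, loglik = NA_real_,
    n_loci_used = NA_integer_, n_compatible = 0L,
    stringsAsFactors = FALSE)
  ties <- list()
  for (i in seq_len(n_off)) {
    lli <- ll[i, ]
    comp <- which(is.finite(lli))
    records$n_compatible[i] <- length(comp)
    if (!length(comp)) { records$status[i] <- "unassigned"; next }
    mx <- max(lli[comp])
    tol <- tie_tol * max(1, abs(mx))
    top <- comp[lli[comp] >= mx - tol]
    best <- top[1]
    records$loglik[i] <- mx
    records$n_loci_used[i] <- used[i, best]
    if (length(top) >= 2L) {
      records$status[i] <- "ambiguous"
      ties[[records$offspring_id[i]]] <- data.frame(
        sire_id = pair_lab_s[top], dam_id = pair_lab_d[top],
        loglik = lli[top], stringsAsFactors = FALSE)
    } else {
      records$status[i] <- "assigned"
      records$sire_id[i] <- pair_lab_s[best]
      records$dam_id[i] <- pair_lab_d[best]
    }
  }
  structure(list(records = records, ties = ties, loglik_matrix = ll,
                 design = design, min_loci = min_loci, tie_tol = tie_tol),
            class = "parentage")
}

#' Fraction of offspring assigned to a specific parental pair
#'
#' @param fit a \code{parentage} object.
#' @return Assigned / total, a fraction in \[0, 1\].
#' @export
assignment_rate <- function(fit) {
  stopifnot(inherits(fit, "parentage"))
  n <- nrow(fit$records)
  if (!n) stop("empty assignment result")
  sum(fit$records$status == "assigned") / n
}

#' @export
print.parentage <- function(x, ...) {
  n <- nrow(x$records)
  tab <- table(factor(x$records$status,
                      levels = c("assigned", "ambiguous", "unassigned")))
  cat("Mendelian maximum-likelihood parentage assignment\n")
  cat(sprintf("  %d offspring against %d sires x %d dams (min_loci = %d)\n",
              n, length(x$design$sire_ids), length(x$design$dam_ids),
              x$min_loci))
  cat(sprintf("  assigned %d (%.1f%%), ambiguous %d, unassigned %d\n",
              tab[1], 100 * tab[1] / n, tab[2], tab[3]))
  invisible(x)
}

#' Summarise a parentage fit
#'
#' @param object a \code{parentage} object.
#' @param ... unused.
#' @return List of class \code{summary.parentage} with status counts, the
#'   assignment rate, and per-status mean loci used.
#' @export
summary.parentage <- function(object, ...) {
  st <- factor(object$records$status,
               levels = c("assigned", "ambiguous", "unassigned"))
  out <- list(
    n = nrow(object$records),
    counts = table(st),
    rate = assignment_rate(object),
    mean_loci = tapply(object$records$n_loci_used, st, mean),
    n_ties = length(object$ties))
  class(out) <- "summary.parentage"
  out
}

#' @export
print.summary.parentage <- function(x, ...) {
  cat("Parentage assignment summary\n")
  cat(sprintf("  offspring: %d\n", x$n))
  for (s in names(x$counts))
    cat(sprintf("  %-10s %5d (%.1f%%)\n", s, x$counts[[s]],
                100 * x$counts[[s]] / x$n))
  cat(sprintf("  assignment rate: %.3f\n", x$rate))
  invisible(x)
}

#' @export
plot.parentage <- function(x, ...) {
  fm <- family_matrix(x)
  plot(fm, ...)
}
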