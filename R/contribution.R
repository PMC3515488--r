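#' Dam-by-sire family matrix of assigned offspring counts
#'
#' Tabulates, for a parentage fit, how many offspring were assigned to each
#' candidate dam x sire family. Ambiguous and unassigned offspring are
#' excluded (never fractionally allocated). All candidate parents of the
#' design appear, including those with zero offspring.
#'
#' @param x a \code{parentage} fit, or a numeric matrix of counts (dams as
#'   rows, sires as columns) to be validated and classed directly.
#' @param ... passed between methods.
#' @return An integer matrix of class \code{family_matrix} (rows dams,
#'   columns sires) with attribute \code{N} = total assigned offspring.
#' @seealso [percent_contribution()], [chi_square_uniform()],
#'   [effective_size()], [read_family_matrix()]
#' @export
family_matrix <- function(x, ...) UseMethod("family_matrix")

#' @rdname family_matrix
#' @export
family_matrix.parentage <- function(x, ...) {
  rec <- x$records[x$records$status == "assigned", ]
  if (!nrow(rec)) stop("no assigned offspring; cannot build a family matrix")
  counts <- table(factor(rec$dam_id, levels = x$design$dam_ids),
                  factor(rec$sire_id, levels = x$design$sire_ids))
  m <- matrix(as.integer(counts), nrow = length(x$design$dam_ids),
              dimnames = list(dam = x$design$dam_ids,
                              sire = x$design$sire_ids))
  family_matrix(m)
}

#' @rdname family_matrix
#' @export
family_matrix.default <- function(x, ...) {
  m <- as.matrix(x)
  storage.mode(m) <- "integer"
  if (any(m < 0L)) stop("family counts must be non-negative")
  if (is.null(rownames(m))) rownames(m) <- as.character(seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- as.character(seq_len(ncol(m)))
  names(dimnames(m)) <- c("dam", "sire")
  attr(m, "N") <- sum(m)
  class(m) <- "family_matrix"
  m
}

#' Read a family matrix from CSV
#'
#' First column holds dam labels (header \code{dam}), remaining columns are
#' sires. This is the format of the packaged mass-cross fixtures.
#'
#' @param path CSV path.
#' @return A \code{family_matrix}.
#' @export
read_family_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  family_matrix(m)
}

#' Packaged family matrices of the four mass crosses
#'
#' Dam-by-sire offspring counts of four full-factorial (10 sires x 10 dams)
#' mass crosses of Asian seabass broodstock, as recovered by microsatellite
#' parentage assignment. The marginals are always recomputed from the cells
#' (a few printed marginals in the original report are internally
#' inconsistent with the cells).
#'
#' @param cross cross number, 1 to 4.
#' @return A \code{family_matrix} (10 dams x 10 sires).
#' @export
mass_cross_fixture <- function(cross) {
  stopifnot(length(cross) == 1L, cross %in% 1:4)
  path <- system.file("extdata", sprintf("table1_cross%d.csv", cross),
                      package = "masscross", mustWork = TRUE)
  read_family_matrix(path)
}

#' @export
print.family_matrix <- function(x, ...) {
  cat(sprintf("Family matrix: %d dams x %d sires, N = %d assigned offspring\n",
              nrow(x), ncol(x), sum(x)))
  m <- unclass(x); attr(m, "N") <- NULL
  print(m)
  invisible(x)
}

#' @export
plot.family_matrix <- function(x, main = "Assigned offspring per family", ...) {
  m <- unclass(x); attr(m, "N") <- NULL
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m),
                  xlab = "sire", ylab = "dam", axes = FALSE, main = main, ...)
  graphics::axis(1, seq_len(ncol(m)), colnames(m))
  graphics::axis(2, seq_len(nrow(m)), rownames(m))
  graphics::box()
  invisible(x)
}

#' Per-sex family-size marginals
#'
#' @param fm a \code{family_matrix}.
#' @return Named integer vector of offspring counts per candidate sire (or
#'   dam), zero contributors included.
#' @export
sire_totals <- function(fm) {
  stopifnot(inherits(fm, "family_matrix"))
  colSums(unclass(fm))
}

#' @rdname sire_totals
#' @export
dam_totals <- function(fm) {
  stopifnot(inherits(fm, "family_matrix"))
  rowSums(unclass(fm))
}

# paper-style 1-decimal rounding (half away from zero)
round_half_up <- function(x, digits = 1L) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Percent contribution of each candidate parent
#'
#' 100 x marginal / N per candidate of one sex. The exact fraction is kept
#' alongside the conventionally reported 1-decimal (half-up) percentage.
#'
#' @param fm a \code{family_matrix}.
#' @param sex \code{"sire"} or \code{"dam"}.
#' @return data.frame with columns \code{id}, \code{count},
#'   \code{fraction}, \code{percent} (1 dp).
#' @export
percent_contribution <- function(fm, sex = c("sire", "dam")) {
  sex <- match.arg(sex)
  tot <- if (sex == "sire") sire_totals(fm) else dam_totals(fm)
  N <- sum(tot)
  if (N == 0) stop("family matrix has no assigned offspring")
  data.frame(id = names(tot), count = as.integer(tot),
             fraction = as.numeric(tot) / N,
             percent = round_half_up(100 * tot / N, 1L),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Chi-square test of equal parental contribution
#'
#' Tests the observed per-candidate offspring counts of one sex against the
#' equal-contribution expectation E = N/k over \emph{all} k candidates
#' (zero contributors included), giving d.f. = k - 1.
#'
#' @param totals per-candidate offspring counts (length >= 2, sum > 0).
#' @return List of class \code{chisq_contribution}: \code{statistic},
#'   \code{df}, \code{p.value}, \code{expected}, \code{totals}.
#' @export
chi_square_uniform <- function(totals) {
  totals <- as.numeric(totals)
  k <- length(totals)
  if (k < 2L) stop("need at least two candidate parents")
  if (sum(totals) <= 0) stop("no offspring counted; chi-square undefined")
  ht <- suppressWarnings(stats::chisq.test(totals, p = rep(1 / k, k)))
  structure(list(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p.value = ht$p.value,
                 expected = unname(ht$expected),
                 totals = totals),
            class = "chisq_contribution")
}

#' @export
print.chisq_contribution <- function(x, ...) {
  cat(sprintf("Equal-contribution chi-square: X^2 = %.1f, d.f. = %d, P %s\n",
              x$statistic, x$df,
              if (x$p.value < 1e-4) "< 0.0001" else sprintf("= %.4g", x$p.value)))
  invisible(x)
}

#' Count contributing parents and families
#'
#' A parent contributes when its marginal is positive; a family exists when
#' its cell is positive.
#'
#' @param fm a \code{family_matrix}.
#' @param sex \code{"sire"} or \code{"dam"}.
#' @return Integer count.
#' @export
count_contributing <- function(fm, sex = c("sire", "dam")) {
  sex <- match.arg(sex)
  tot <- if (sex == "sire") sire_totals(fm) else dam_totals(fm)
  sum(tot > 0L)
}

#' @rdname count_contributing
#' @export
count_families <- function(fm) {
  stopifnot(inherits(fm, "family_matrix"))
  sum(unclass(fm) > 0L)
}

#' Full contribution summary of one cross
#'
#' Percent contributions, equal-contribution chi-squares, contributing
#' parent counts per sex, and the family count.
#'
#' @param fm a \code{family_matrix}.
#' @return List of class \code{contribution_summary}.
#' @export
contribution_summary <- function(fm) {
  stopifnot(inherits(fm, "family_matrix"))
  out <- list(
    N = sum(fm),
    sire = percent_contribution(fm, "sire"),
    dam = percent_contribution(fm, "dam"),
    chisq_sire = chi_square_uniform(sire_totals(fm)),
    chisq_dam = chi_square_uniform(dam_totals(fm)),
    n_contributing_sires = count_contributing(fm, "sire"),
    n_contributing_dams = count_contributing(fm, "dam"),
    n_families = count_families(fm))
  class(out) <- "contribution_summary"
  out
}

#' @export
print.contribution_summary <- function(x, ...) {
  cat(sprintf("Parental contribution summary (N = %d assigned offspring)\n", x$N))
  cat(sprintf("  contributing: %d sires, %d dams; %d families\n",
              x$n_contributing_sires, x$n_contributing_dams, x$n_families))
  cat("  sires: "); print(x$chisq_sire)
  cat("  dams:  "); print(x$chisq_dam)
  top_s <- x$sire[which.max(x$sire$count), ]
  top_d <- x$dam[which.max(x$dam$count), ]
  cat(sprintf("  dominant sire %s: %.1f%%; dominant dam %s: %.1f%%\n",
              top_s$id, top_s$percent, top_d$id, top_d$percent))
  invisible(x)
}
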