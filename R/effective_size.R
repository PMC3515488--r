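#' Effective population size from family-size variance
#'
#' Estimates the effective size of an offspring cohort from the mean and
#' variance of per-parent family sizes,
#' \deqn{N_e = \frac{4(N-2)}{(K_s + V_s/K_s) + (K_d + V_d/K_d) - 2}}
#' where N is the number of offspring sampled, Ks and Kd the mean number of
#' offspring per candidate sire and dam, and Vs, Vd the variances of the
#' sire and dam family sizes. Variances use the population convention
#' (divisor = number of candidates), under which K + V/K equals
#' \eqn{\sum x_i^2 / \sum x_i}, so the estimate is invariant to appending
#' zero-contributing candidates.
#'
#' @param x a \code{family_matrix}, or a numeric vector of per-sire
#'   offspring counts (then \code{dam_totals} must be given).
#' @param dam_totals per-dam offspring counts (same total as the sire
#'   counts); ignored for the \code{family_matrix} method.
#' @param ... passed between methods.
#' @return List of class \code{ne_result}: \code{N}, \code{Ks}, \code{Kd},
#'   \code{Vs}, \code{Vd}, \code{Ne}.
#' @examples
#' effective_size(rep(10, 10), rep(10, 10))  # balanced: Ne = 4*98/18
#' @export
effective_size <- function(x, ...) UseMethod("effective_size")

#' @rdname effective_size
#' @export
effective_size.family_matrix <- function(x, ...) {
  effective_size(as.numeric(sire_totals(x)), as.numeric(dam_totals(x)))
}

#' @rdname effective_size
#' @export
effective_size.default <- function(x, dam_totals, ...) {
  sire_totals <- as.numeric(x)
  dam_totals <- as.numeric(dam_totals)
  N <- sum(sire_totals)
  if (!isTRUE(all.equal(N, sum(dam_totals))))
    stop("sire and dam family sizes must sum to the same offspring total")
  if (N <= 2) stop("Ne requires more than 2 sampled offspring")
  if (!any(sire_totals > 0) || !any(dam_totals > 0))
    stop("at least one sire and one dam must contribute")
  Ks <- mean(sire_totals); Kd <- mean(dam_totals)
  Vs <- mean((sire_totals - Ks)^2)   # population variance
  Vd <- mean((dam_totals - Kd)^2)
  Ne <- 4 * (N - 2) / ((Ks + Vs / Ks) + (Kd + Vd / Kd) - 2)
  structure(list(N = N, Ks = Ks, Kd = Kd, Vs = Vs, Vd = Vd, Ne = Ne),
            class = "ne_result")
}

#' @export
print.ne_result <- function(x, ...) {
  cat("Effective population size (family-size variance method)\n")
  cat(sprintf("  N = %d offspring; Ks = %.2f (Vs = %.1f), Kd = %.2f (Vd = %.1f)\n",
              as.integer(x$N), x$Ks, x$Vs, x$Kd, x$Vd))
  cat(sprintf("  Ne = %.2f\n", x$Ne))
  invisible(x)
}

#' Effective-size report over several crosses
#'
#' @param matrices list of \code{family_matrix} objects (one per cross).
#' @param census census parent number per cross; defaults to the number of
#'   candidate sires plus dams in each matrix.
#' @return data.frame with one row per cross: N, Ks, Vs, Kd, Vd, Ne,
#'   census, Ne_over_census.
#' @export
ne_report <- function(matrices, census = NULL) {
  if (inherits(matrices, "family_matrix")) matrices <- list(matrices)
  if (is.null(census))
    census <- vapply(matrices, function(m) nrow(m) + ncol(m), 1)
  rows <- lapply(seq_along(matrices), function(i) {
    ne <- effective_size(matrices[[i]])
    data.frame(cross = if (is.null(names(matrices))) i else names(matrices)[i],
               N = ne$N, Ks = ne$Ks, Vs = ne$Vs, Kd = ne$Kd, Vd = ne$Vd,
               Ne = ne$Ne, census = census[i],
               Ne_over_census = ne$Ne / census[i],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
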