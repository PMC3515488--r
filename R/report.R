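#' Run the full per-cross monitoring report
#'
#' Orchestrates the analysis sequence of one mass cross: parentage
#' assignment (when genotypes are supplied), family matrix, contribution
#' summary with equal-contribution chi-squares, effective population size,
#' and — in genotype mode — diversity statistics for parents and offspring
#' plus allele retention. A \code{family_matrix} can be supplied directly
#' ("matrix-only" mode) so that a published family table can drive the
#' contribution and Ne analyses without the underlying genotypes.
#'
#' @param x a \code{genotype_dataset} (with parents and offspring), a
#'   \code{parentage} fit, or a \code{family_matrix}.
#' @param design optional [cross_design()] (genotype mode).
#' @param min_loci,tie_tol assignment parameters (genotype mode).
#' @param ... passed between methods.
#' @return Object of class \code{cross_report}: elements \code{assignment}
#'   (NULL in matrix-only mode), \code{family_matrix}, \code{contribution},
#'   \code{ne}, \code{diversity} (list with \code{parents},
#'   \code{offspring}, \code{retention}; NULL in matrix-only mode).
#' @seealso [write_cross_report()]
#' @export
run_cross_report <- function(x, ...) UseMethod("run_cross_report")

#' @rdname run_cross_report
#' @export
run_cross_report.family_matrix <- function(x, ...) {
  structure(list(assignment = NULL, family_matrix = x,
                 contribution = contribution_summary(x),
                 ne = effective_size(x), diversity = NULL),
            class = "cross_report")
}

#' @rdname run_cross_report
#' @export
run_cross_report.parentage <- function(x, ...) {
  fm <- family_matrix(x)
  structure(list(assignment = x, family_matrix = fm,
                 contribution = contribution_summary(fm),
                 ne = effective_size(fm), diversity = NULL),
            class = "cross_report")
}

#' @rdname run_cross_report
#' @export
run_cross_report.genotype_dataset <- function(x,
                                              design = design_from_dataset(x),
                                              min_loci = 5L, tie_tol = 1e-9,
                                              ...) {
  if (!any(x$meta$role == "offspring"))
    stop("assignment stage: dataset contains no offspring")
  fit <- assign_parentage(x, design, min_loci = min_loci, tie_tol = tie_tol)
  rep <- run_cross_report(fit)
  rep$diversity <- list(
    parents = diversity_stats(x, c(design$sire_ids, design$dam_ids)),
    offspring = diversity_stats(x, x$meta$id[x$meta$role == "offspring"]),
    retention = allele_retention(
      x, parent_ids = c(design$sire_ids, design$dam_ids)))
  rep
}

#' @export
print.cross_report <- function(x, ...) {
  cat("=== Mass-cross monitoring report ===\n")
  if (!is.null(x$assignment)) { print(summary(x$assignment)); cat("\n") }
  print(x$contribution); cat("\n")
  print(x$ne)
  if (!is.null(x$diversity)) {
    cat("\nParents:   "); print(x$diversity$parents)
    cat("Offspring: "); print(x$diversity$offspring)
    print(x$diversity$retention)
  }
  invisible(x)
}

#' Write a cross report to disk
#'
#' Emits the family matrix and (when present) the assignment records as
#' TSV, and the contribution / Ne / diversity summaries as one JSON file.
#'
#' @param report a \code{cross_report}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default \code{"cross"}).
#' @return Invisibly, the paths written.
#' @export
write_cross_report <- function(report, dir, prefix = "cross") {
  stopifnot(inherits(report, "cross_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  fm_path <- file.path(dir, paste0(prefix, "_family_matrix.tsv"))
  fm <- report$family_matrix
  fm_df <- data.frame(dam = rownames(fm), unclass(fm), check.names = FALSE,
                      total = rowSums(unclass(fm)))
  utils::write.table(fm_df, fm_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  paths <- c(paths, fm_path)
  if (!is.null(report$assignment)) {
    as_path <- file.path(dir, paste0(prefix, "_assignments.tsv"))
    utils::write.table(report$assignment$records, as_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    paths <- c(paths, as_path)
  }
  js <- list(
    N = report$contribution$N,
    chisq_sire = unclass(report$contribution$chisq_sire)[c("statistic", "df", "p.value")],
    chisq_dam = unclass(report$contribution$chisq_dam)[c("statistic", "df", "p.value")],
    n_contributing_sires = report$contribution$n_contributing_sires,
    n_contributing_dams = report$contribution$n_contributing_dams,
    n_families = report$contribution$n_families,
    percent_sire = report$contribution$sire,
    percent_dam = report$contribution$dam,
    ne = unclass(report$ne))
  if (!is.null(report$diversity)) {
    js$diversity <- list(
      parents = c(as.list(report$diversity$parents$means),
                  N = report$diversity$parents$N),
      offspring = c(as.list(report$diversity$offspring$means),
                    N = report$diversity$offspring$N),
      mean_allelic_loss = unname(report$diversity$retention$mean["allelic_loss"]),
      mean_gene_loss = unname(report$diversity$retention$mean["gene_loss"]))
  }
  js_path <- file.path(dir, paste0(prefix, "_summary.json"))
  jsonlite::write_json(js, js_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(paths, js_path)
  invisible(paths)
}
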