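#' Construct a multilocus genotype dataset
#'
#' A \code{genotype_dataset} holds codominant (e.g. microsatellite) genotypes
#' for a set of individuals over an ordered marker panel. Each locus genotype
#' is an unordered pair of integer allele sizes (base pairs); missing
#' genotypes carry no alleles. Alleles are compared by exact equality.
#'
#' @param meta data.frame with columns \code{id}, \code{sex}
#'   (\code{"male"}, \code{"female"} or \code{"unknown"}) and \code{role}
#'   (\code{"parent"} or \code{"offspring"}). Ids must be unique.
#' @param a1,a2 integer matrices (individuals x loci) holding the two alleles
#'   of each genotype. The pair is unordered: on construction it is
#'   canonicalised so that \code{a1 <= a2}. A missing genotype has \code{NA}
#'   in both matrices; one-sided \code{NA} is rejected.
#' @param loci character vector of locus names (unique, at least one).
#' @return An object of class \code{genotype_dataset} with elements
#'   \code{meta}, \code{a1}, \code{a2} and \code{loci}.
#' @seealso [read_genotype_table()], [read_genepop()], [allele_registry()]
#' @export
genotype_dataset <- function(meta, a1, a2, loci) {
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "sex", "role") %in% names(meta)))
  meta$id <- as.character(meta$id)
  if (anyDuplicated(meta$id))
    stop("duplicate individual id(s): ",
         paste(unique(meta$id[duplicated(meta$id)]), collapse = ", "))
  bad_sex <- setdiff(unique(meta$sex), c("male", "female", "unknown"))
  if (length(bad_sex))
    stop("unknown sex token(s): ", paste(bad_sex, collapse = ", "))
  bad_role <- setdiff(unique(meta$role), c("parent", "offspring"))
  if (length(bad_role))
    stop("unknown role token(s): ", paste(bad_role, collapse = ", "))
  loci <- as.character(loci)
  if (length(loci) < 1L) stop("at least one locus is required")
  if (anyDuplicated(loci)) stop("locus names must be unique")
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  if (!all(dim(a1) == c(nrow(meta), length(loci))) ||
      !all(dim(a2) == c(nrow(meta), length(loci))))
    stop("allele matrices must be individuals x loci")
  if (any(xor(is.na(a1), is.na(a2))))
    stop("half-missing genotypes are not supported; both alleles must be ",
         "present or both missing")
  if (any(a1 <= 0L, na.rm = TRUE) || any(a2 <= 0L, na.rm = TRUE))
    stop("allele sizes must be positive integers")
  # canonical unordered pair: smaller allele first
  swap <- !is.na(a1) & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  }
  dimnames(a1) <- dimnames(a2) <- list(meta$id, loci)
  structure(list(meta = meta, a1 = a1, a2 = a2, loci = loci),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  n_par <- sum(x$meta$role == "parent")
  n_off <- sum(x$meta$role == "offspring")
  cat("Multilocus genotype dataset\n")
  cat(sprintf("  %d individuals (%d parents, %d offspring), %d loci\n",
              nrow(x$meta), n_par, n_off, length(x$loci)))
  reg <- allele_registry(x)
  cat(sprintf("  alleles per locus: %s\n",
              paste(vapply(reg, length, 1L), collapse = " ")))
  miss <- mean(is.na(x$a1))
  cat(sprintf("  missing genotypes: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' Per-locus allele registry
#'
#' The set of distinct alleles observed at each locus across all (or a
#' subset of) individuals.
#'
#' @param dataset a \code{genotype_dataset}.
#' @param ids optional character vector restricting to these individuals.
#' @return Named list (one element per locus) of sorted integer allele sizes.
#' @export
allele_registry <- function(dataset, ids = NULL) {
  rows <- .resolve_ids(dataset, ids)
  out <- lapply(seq_along(dataset$loci), function(j) {
    sort(unique(c(dataset$a1[rows, j], dataset$a2[rows, j])))
  })
  names(out) <- dataset$loci
  out
}

.resolve_ids <- function(dataset, ids) {
  if (is.null(ids)) return(seq_len(nrow(dataset$meta)))
  rows <- match(ids, dataset$meta$id)
  if (anyNA(rows))
    stop("unknown individual id(s): ", paste(ids[is.na(rows)], collapse = ", "))
  rows
}

#' Read a genotype table from CSV
#'
#' Expects a header \code{id,sex,role,<locus1>,...,<locusK>}. Genotype cells
#' are \code{"a/b"} (or \code{"a/a"} for homozygotes); an empty cell is a
#' missing genotype. The allele pair is unordered, so \code{"276/288"} and
#' \code{"288/276"} load identically.
#'
#' @param path CSV file path (UTF-8).
#' @param loci optional expected locus list; the file's loci must match.
#' @return A [genotype_dataset()].
#' @export
read_genotype_table <- function(path, loci = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        strip.white = TRUE)
  if (ncol(df) < 4L || !identical(names(df)[1:3], c("id", "sex", "role")))
    stop("genotype table must have header id,sex,role,<loci...>: ", path)
  file_loci <- names(df)[-(1:3)]
  if (!is.null(loci) && !identical(as.character(loci), file_loci))
    stop("locus columns in ", path, " do not match the expected panel")
  n <- nrow(df)
  a1 <- a2 <- matrix(NA_integer_, n, length(file_loci))
  for (j in seq_along(file_loci)) {
    cells <- df[[j + 3L]]
    blank <- !nzchar(cells)
    ok <- blank | grepl("^[0-9]+/[0-9]+$", cells)
    if (!all(ok))
      stop(sprintf("malformed genotype cell '%s' at row %d, column '%s'",
                   cells[which(!ok)[1]], which(!ok)[1], file_loci[j]))
    parts <- matrix(NA_integer_, n, 2L)
    if (any(!blank)) {
      sp <- strsplit(cells[!blank], "/", fixed = TRUE)
      parts[!blank, ] <- t(vapply(sp, function(p) as.integer(p), integer(2)))
    }
    a1[, j] <- parts[, 1]; a2[, j] <- parts[, 2]
  }
  genotype_dataset(df[, 1:3], a1, a2, file_loci)
}

#' Write a genotype table to CSV
#'
#' Cells are serialised canonically as \code{"smaller/larger"}; missing
#' genotypes become empty cells, so a written file reads back identically.
#'
#' @param dataset a \code{genotype_dataset}.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_genotype_table <- function(dataset, path) {
  cells <- matrix("", nrow(dataset$meta), length(dataset$loci))
  has <- !is.na(dataset$a1)
  cells[has] <- paste0(dataset$a1[has], "/", dataset$a2[has])
  out <- cbind(dataset$meta[, c("id", "sex", "role")],
               as.data.frame(cells, stringsAsFactors = FALSE))
  names(out) <- c("id", "sex", "role", dataset$loci)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a Genepop file (3-digit allele coding)
#'
#' Supports the common Genepop dialect: a title line, one locus name per
#' line (or a single comma-separated line), and \code{Pop} blocks of
#' individuals \code{"id , 133137 276288 ..."}. Allele code \code{000} is
#' missing; \code{"000000"} is a missing genotype. By convention the first
#' \code{Pop} block holds the candidate parents and subsequent blocks the
#' offspring. Genepop carries no sex field, so parent sex is decoded from
#' the id's first character: \code{M}/\code{S} = male, \code{F}/\code{D} =
#' female, anything else = unknown.
#'
#' @param path Genepop file path.
#' @return A [genotype_dataset()].
#' @export
read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L) stop("truncated Genepop file: ", path)
  is_pop <- toupper(trimws(lines)) == "POP"
  if (!any(is_pop)) stop("missing Pop separator in Genepop file: ", path)
  first_pop <- which(is_pop)[1]
  if (first_pop < 3L) stop("no locus names before first Pop block: ", path)
  header <- lines[2:(first_pop - 1L)]
  loci <- trimws(unlist(strsplit(header, ",", fixed = TRUE)))
  loci <- loci[nzchar(loci)]
  pop_idx <- cumsum(is_pop)
  body <- which(!is_pop & seq_along(lines) > first_pop)
  if (max(pop_idx) < 2L)
    stop("expected at least two Pop blocks (parents, offspring): ", path)
  ids <- character(0); sexes <- character(0); roles <- character(0)
  rows1 <- list(); rows2 <- list()
  for (i in body) {
    ln <- strsplit(lines[i], ",", fixed = TRUE)[[1]]
    if (length(ln) != 2L)
      stop("malformed Genepop individual line ", i, ": ", lines[i])
    id <- trimws(ln[1])
    codes <- strsplit(trimws(ln[2]), "[[:space:]]+")[[1]]
    if (length(codes) != length(loci))
      stop("individual '", id, "' has ", length(codes),
           " genotypes for ", length(loci), " loci")
    nc <- nchar(codes)
    if (any(nc == 4L))
      stop("2-digit allele coding detected for '", id,
           "'; only the 3-digit dialect is supported")
    if (any(nc != 6L))
      stop("malformed 3-digit genotype code for '", id, "': ",
           codes[which(nc != 6L)[1]])
    x1 <- as.integer(substr(codes, 1, 3))
    x2 <- as.integer(substr(codes, 4, 6))
    x1[x1 == 0L] <- NA_integer_; x2[x2 == 0L] <- NA_integer_
    half <- xor(is.na(x1), is.na(x2))
    if (any(half)) { x1[half] <- NA_integer_; x2[half] <- NA_integer_ }
    role <- if (pop_idx[i] == 1L) "parent" else "offspring"
    sex <- if (role == "parent") {
      switch(toupper(substr(id, 1, 1)),
             M = "male", S = "male", F = "female", D = "female", "unknown")
    } else "unknown"
    ids <- c(ids, id); sexes <- c(sexes, sex); roles <- c(roles, role)
    rows1[[length(rows1) + 1L]] <- x1
    rows2[[length(rows2) + 1L]] <- x2
  }
  genotype_dataset(data.frame(id = ids, sex = sexes, role = roles,
                              stringsAsFactors = FALSE),
                   do.call(rbind, rows1), do.call(rbind, rows2), loci)
}

#' Write a Genepop file (3-digit allele coding)
#'
#' Parents form the first \code{Pop} block, offspring the second; missing
#' genotypes are written as \code{000000}. All alleles must be below 1000
#' to fit the 3-digit code.
#'
#' @param dataset a \code{genotype_dataset}.
#' @param path output path.
#' @param title first (comment) line of the file.
#' @return The path, invisibly.
#' @export
write_genepop <- function(dataset, path, title = "masscross genotype export") {
  if (any(dataset$a2 > 999L, na.rm = TRUE))
    stop("allele sizes above 999 cannot be written in 3-digit Genepop coding")
  fmt <- function(rows) {
    vapply(rows, function(i) {
      x1 <- dataset$a1[i, ]; x2 <- dataset$a2[i, ]
      code <- sprintf("%03d%03d", ifelse(is.na(x1), 0L, x1),
                      ifelse(is.na(x2), 0L, x2))
      paste0(dataset$meta$id[i], " , ", paste(code, collapse = " "))
    }, character(1))
  }
  par_rows <- which(dataset$meta$role == "parent")
  off_rows <- which(dataset$meta$role == "offspring")
  lines <- c(title, dataset$loci, "Pop", fmt(par_rows))
  if (length(off_rows)) lines <- c(lines, "Pop", fmt(off_rows))
  writeLines(lines, path)
  invisible(path)
}

#' Define a full-factorial cross design
#'
#' Lists the candidate sires and dams of one mass cross; every sire x dam
#' pair is a candidate family. When a dataset is supplied the parents are
#' checked for presence and matching sex.
#'
#' @param sire_ids,dam_ids ordered character vectors of candidate parent ids
#'   (disjoint, no duplicates).
#' @param dataset optional \code{genotype_dataset} to validate against.
#' @return An object of class \code{cross_design}.
#' @export
cross_design <- function(sire_ids, dam_ids, dataset = NULL) {
  sire_ids <- as.character(sire_ids); dam_ids <- as.character(dam_ids)
  if (!length(sire_ids) || !length(dam_ids))
    stop("a cross design needs at least one sire and one dam")
  if (anyDuplicated(c(sire_ids, dam_ids)))
    stop("sire and dam id lists must be disjoint and duplicate-free")
  if (!is.null(dataset)) {
    rows_s <- .resolve_ids(dataset, sire_ids)
    rows_d <- .resolve_ids(dataset, dam_ids)
    if (any(dataset$meta$sex[rows_s] != "male"))
      stop("candidate sires must have sex 'male'")
    if (any(dataset$meta$sex[rows_d] != "female"))
      stop("candidate dams must have sex 'female'")
  }
  structure(list(sire_ids = sire_ids, dam_ids = dam_ids),
            class = "cross_design")
}

#' Derive the cross design from parent sexes
#'
#' All parents with sex \code{male} become candidate sires, all with sex
#' \code{female} candidate dams, in dataset order.
#'
#' @param dataset a \code{genotype_dataset} containing sexed parents.
#' @return A [cross_design()].
#' @export
design_from_dataset <- function(dataset) {
  par <- dataset$meta[dataset$meta$role == "parent", ]
  cross_design(par$id[par$sex == "male"], par$id[par$sex == "female"],
               dataset = dataset)
}

#' @export
print.cross_design <- function(x, ...) {
  cat(sprintf("Full-factorial cross design: %d sires x %d dams (%d candidate families)\n",
              length(x$sire_ids), length(x$dam_ids),
              length(x$sire_ids) * length(x$dam_ids)))
  invisible(x)
}
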