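#' Construct a diploid microsatellite genotype table
#'
#' The central container of the package: an individuals-by-loci matrix of
#' unordered diploid allele-length genotypes (PCR product sizes in
#' nucleotides), together with per-individual population labels and
#' source-data-set tags. Genotypes are canonicalized so that the first
#' allele is never larger than the second; a genotype is either fully
#' observed or fully missing (`NA` in both allele slots).
#'
#' @param individual_ids character vector of unique individual identifiers.
#'   Identifiers are opaque; when combining data sets, collision-proof
#'   dataset-qualified ids (e.g. `"study2003:IND0042"`) are recommended.
#' @param population_ids character vector, one population label per individual.
#' @param dataset_tags character vector, one source-data-set tag per individual.
#' @param locus_names character vector of unique locus names.
#' @param allele1,allele2 integer matrices (individuals x loci) of allele
#'   lengths in nucleotides; `NA` marks missing data. Both alleles of a
#'   genotype must be observed or both missing; observed lengths must be
#'   strictly positive.
#' @return An object of class `genotype_table` with fields `individual_ids`,
#'   `population_ids`, `dataset_tags`, `locus_names`, `allele1`, `allele2`.
#' @export
genotype_table <- function(individual_ids, population_ids, dataset_tags,
                           locus_names, allele1, allele2) {
  individual_ids <- as.character(individual_ids)
  population_ids <- as.character(population_ids)
  dataset_tags <- as.character(dataset_tags)
  locus_names <- as.character(locus_names)
  allele1 <- .as_allele_matrix(allele1, length(individual_ids), length(locus_names))
  allele2 <- .as_allele_matrix(allele2, length(individual_ids), length(locus_names))

  if (anyDuplicated(individual_ids)) {
    stop("duplicate individual ids: ",
         paste(unique(individual_ids[duplicated(individual_ids)]), collapse = ", "))
  }
  if (anyDuplicated(locus_names)) {
    stop("duplicate locus names: ",
         paste(unique(locus_names[duplicated(locus_names)]), collapse = ", "))
  }
  if (length(population_ids) != length(individual_ids) ||
      length(dataset_tags) != length(individual_ids)) {
    stop("population_ids and dataset_tags must have one entry per individual")
  }
  half_missing <- xor(is.na(allele1), is.na(allele2))
  if (any(half_missing)) {
    stop("genotypes must have both alleles present or both missing (",
         sum(half_missing), " half-missing genotypes)")
  }
  if (any(allele1 <= 0, na.rm = TRUE) || any(allele2 <= 0, na.rm = TRUE)) {
    stop("allele lengths must be strictly positive")
  }

  # unordered genotypes: canonicalize as (min, max)
  lo <- pmin(allele1, allele2)
  hi <- pmax(allele1, allele2)
  dimnames(lo) <- dimnames(hi) <- list(individual_ids, locus_names)

  structure(
    list(individual_ids = individual_ids,
         population_ids = stats::setNames(population_ids, individual_ids),
         dataset_tags = stats::setNames(dataset_tags, individual_ids),
         locus_names = locus_names,
         allele1 = lo,
         allele2 = hi),
    class = "genotype_table")
}

.as_allele_matrix <- function(x, n, l) {
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  if (nrow(x) != n || ncol(x) != l) {
    stop("allele matrix has dimensions ", nrow(x), "x", ncol(x),
         " but expected ", n, "x", l)
  }
  x
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table: ", n_individuals(x), " individuals x ", n_loci(x),
      " loci\n", sep = "")
  cat("  populations: ", length(unique(x$population_ids)),
      "; data sets: ", length(unique(x$dataset_tags)), "\n", sep = "")
  miss <- mean(is.na(x$allele1))
  cat(sprintf("  missing genotypes: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' Number of individuals / loci in a genotype table
#' @param table a `genotype_table`.
#' @return integer count.
#' @export
n_individuals <- function(table) length(table$individual_ids)

#' @rdname n_individuals
#' @export
n_loci <- function(table) length(table$locus_names)

#' Subset a genotype table by individuals and/or loci
#'
#' @param table a `genotype_table`.
#' @param individuals character vector of individual ids to keep (in the given
#'   order), or `NULL` to keep all.
#' @param loci character vector of locus names to keep, or `NULL` to keep all.
#' @return a `genotype_table`.
#' @export
gt_subset <- function(table, individuals = NULL, loci = NULL) {
  ii <- if (is.null(individuals)) table$individual_ids else as.character(individuals)
  ll <- if (is.null(loci)) table$locus_names else as.character(loci)
  bad_i <- setdiff(ii, table$individual_ids)
  if (length(bad_i)) stop("unknown individuals: ", paste(bad_i, collapse = ", "))
  bad_l <- setdiff(ll, table$locus_names)
  if (length(bad_l)) stop("unknown loci: ", paste(bad_l, collapse = ", "))
  genotype_table(ii,
                 unname(table$population_ids[ii]),
                 unname(table$dataset_tags[ii]),
                 ll,
                 table$allele1[ii, ll, drop = FALSE],
                 table$allele2[ii, ll, drop = FALSE])
}

#' Row-bind two genotype tables sharing the same loci
#'
#' @param a,b `genotype_table` objects with identical `locus_names`.
#' @return a `genotype_table` containing the individuals of `a` then `b`.
#' @export
gt_rbind <- function(a, b) {
  if (!identical(a$locus_names, b$locus_names)) {
    stop("tables must share identical locus sets (in the same order) to be combined")
  }
  genotype_table(c(a$individual_ids, b$individual_ids),
                 c(unname(a$population_ids), unname(b$population_ids)),
                 c(unname(a$dataset_tags), unname(b$dataset_tags)),
                 a$locus_names,
                 rbind(a$allele1, b$allele1),
                 rbind(a$allele2, b$allele2))
}

#' Compare two genotype tables for equality
#'
#' Field-for-field equality of ids, labels, loci and genotypes.
#' @param a,b `genotype_table` objects.
#' @return logical scalar.
#' @export
gt_equal <- function(a, b) {
  identical(a$individual_ids, b$individual_ids) &&
    identical(unname(a$population_ids), unname(b$population_ids)) &&
    identical(unname(a$dataset_tags), unname(b$dataset_tags)) &&
    identical(a$locus_names, b$locus_names) &&
    identical(unname(a$allele1), unname(b$allele1)) &&
    identical(unname(a$allele2), unname(b$allele2))
}

#' Per-locus and per-individual missing-data fractions
#'
#' For each locus the fraction `l_m` of individuals with a missing genotype,
#' and for each individual the fraction `i_m` of loci with a missing genotype.
#' Both are exact fractions recomputable from the table, and satisfy
#' `sum(l_m) * n = sum(i_m) * L = total missing genotypes` up to the margin
#' denominators.
#'
#' @param table a nonempty `genotype_table`.
#' @return an object of class `missingness_report`: list with named numeric
#'   vectors `l_m` (per locus) and `i_m` (per individual).
#' @export
missingness_report <- function(table) {
  if (n_individuals(table) == 0L || n_loci(table) == 0L) {
    stop("missingness_report requires a nonempty table")
  }
  miss <- is.na(table$allele1)
  structure(
    list(l_m = colMeans(miss), i_m = rowMeans(miss)),
    class = "missingness_report")
}

#' @export
print.missingness_report <- function(x, ...) {
  cat("missingness_report\n")
  cat(sprintf("  loci: mean l_m = %.4f, max = %.4f\n", mean(x$l_m), max(x$l_m)))
  cat(sprintf("  individuals: mean i_m = %.4f, max = %.4f\n",
              mean(x$i_m), max(x$i_m)))
  invisible(x)
}
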