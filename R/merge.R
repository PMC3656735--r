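#' Merge an incoming genotype table into a reference table
#'
#' Applies the filtering order used when combining genotype panels: loci
#' classified `"mismatch"` are dropped first and not considered further;
#' `"offset"` loci have the inferred translation constant added to the
#' incoming alleles; the members of duplicate pairs belonging to the data
#' set not retained are removed; finally the individuals of both tables are
#' concatenated over the intersection of surviving loci.
#'
#' @param reference_table,incoming_table `genotype_table`s.
#' @param offsets an `offset_table` from [infer_all_offsets()] covering every
#'   shared locus.
#' @param duplicate_pairs data.frame with columns `id_a` (reference member),
#'   `id_b` (incoming member); may have zero rows.
#' @param retain_from which copy of each duplicate pair to keep:
#'   `"reference"` (default, matching alignment of newer panels to an
#'   anchor data set) or `"incoming"`.
#' @return list with elements `table` (merged `genotype_table`) and `report`
#'   (class `merge_report`): loci kept/adjusted/excluded with reasons,
#'   duplicate individuals removed with their retained twin, post-merge
#'   dimensions, and a per-step log.
#' @export
merge_datasets <- function(reference_table, incoming_table, offsets,
                           duplicate_pairs = NULL,
                           retain_from = c("reference", "incoming")) {
  retain_from <- match.arg(retain_from)
  shared <- intersect(reference_table$locus_names, incoming_table$locus_names)
  if (!all(shared %in% offsets$locus)) {
    stop("offsets must cover all shared loci; missing: ",
         paste(setdiff(shared, offsets$locus), collapse = ", "))
  }
  offsets <- offsets[match(shared, offsets$locus), , drop = FALSE]
  log <- character(0)

  mismatch <- offsets$locus[offsets$classification == "mismatch"]
  keep_loci <- setdiff(shared, mismatch)
  log <- c(log, sprintf("%d shared loci; %d mismatch loci excluded",
                        length(shared), length(mismatch)))

  inc <- gt_subset(incoming_table, loci = keep_loci)
  off_rows <- offsets[offsets$classification == "offset", , drop = FALSE]
  adjusted <- intersect(off_rows$locus, keep_loci)
  if (length(adjusted)) {
    shift <- off_rows$c_star[match(adjusted, off_rows$locus)]
    inc$allele1[, adjusted] <- sweep(inc$allele1[, adjusted, drop = FALSE], 2L,
                                     as.integer(shift), `+`)
    inc$allele2[, adjusted] <- sweep(inc$allele2[, adjusted, drop = FALSE], 2L,
                                     as.integer(shift), `+`)
  }
  log <- c(log, sprintf("%d offset loci translated; %d exact loci unchanged",
                        length(adjusted), sum(offsets$classification == "exact")))

  removed <- data.frame(removed = character(0), retained = character(0),
                        stringsAsFactors = FALSE)
  ref <- gt_subset(reference_table, loci = keep_loci)
  if (!is.null(duplicate_pairs) && nrow(duplicate_pairs)) {
    present <- duplicate_pairs$id_a %in% reference_table$individual_ids |
      duplicate_pairs$id_b %in% incoming_table$individual_ids
    if (!all(present)) {
      stop("duplicate pair(s) with both members absent: ",
           paste(which(!present), collapse = ", "))
    }
    if (retain_from == "reference") {
      drop_ids <- unique(duplicate_pairs$id_b)
      inc <- gt_subset(inc, individuals = setdiff(inc$individual_ids, drop_ids))
      removed <- data.frame(removed = duplicate_pairs$id_b,
                            retained = duplicate_pairs$id_a,
                            stringsAsFactors = FALSE)
    } else {
      drop_ids <- unique(duplicate_pairs$id_a)
      ref <- gt_subset(ref, individuals = setdiff(ref$individual_ids, drop_ids))
      removed <- data.frame(removed = duplicate_pairs$id_a,
                            retained = duplicate_pairs$id_b,
                            stringsAsFactors = FALSE)
    }
    log <- c(log, sprintf("%d duplicate individuals removed (retained %s copy)",
                          length(drop_ids), retain_from))
  }

  merged <- gt_rbind(ref, inc)
  log <- c(log, sprintf("merged table: %d individuals x %d loci",
                        n_individuals(merged), n_loci(merged)))
  report <- structure(
    list(loci_kept = keep_loci,
         loci_adjusted = adjusted,
         loci_excluded = data.frame(locus = mismatch,
                                    reason = rep("mismatch", length(mismatch)),
                                    stringsAsFactors = FALSE),
         duplicates_removed = removed,
         dimensions = c(individuals = n_individuals(merged),
                        loci = n_loci(merged)),
         log = log),
    class = "merge_report")
  list(table = merged, report = report)
}

#' @export
print.merge_report <- function(x, ...) {
  cat("merge_report\n")
  for (line in x$log) cat("  -", line, "\n")
  invisible(x)
}

#' Remove loci exceeding a missing-data threshold
#'
#' Removes loci whose missing fraction `l_m` strictly exceeds the threshold;
#' a locus with `l_m` exactly at the threshold is retained.
#'
#' @param table a `genotype_table`.
#' @param l_threshold maximum tolerated per-locus missing fraction
#'   (default 0.146).
#' @return list with `table` (filtered) and `removed` (data.frame of removed
#'   loci and their `l_m`).
#' @export
filter_loci_by_missingness <- function(table, l_threshold = 0.146) {
  stopifnot(l_threshold >= 0, l_threshold <= 1)
  lm <- missingness_report(table)$l_m
  drop <- names(lm)[lm > l_threshold]
  list(table = gt_subset(table, loci = setdiff(table$locus_names, drop)),
       removed = data.frame(locus = drop, l_m = unname(lm[drop]),
                            stringsAsFactors = FALSE))
}

#' Remove individuals exceeding a missing-data threshold
#'
#' Removes individuals whose missing fraction `i_m` strictly exceeds the
#' threshold. Additionally reports whether, after filtering, every pair of
#' remaining individuals shares non-missing genotypes at more than half of
#' the loci — the condition the individual threshold is meant to ensure.
#' The pair-coverage check is a diagnostic, not a filter.
#'
#' @param table a `genotype_table`.
#' @param i_threshold maximum tolerated per-individual missing fraction
#'   (default 0.277).
#' @param check_pair_coverage run the pairwise shared-coverage diagnostic
#'   (quadratic in individuals; default TRUE).
#' @return list with `table`, `removed` (data.frame of individuals and `i_m`),
#'   `pair_coverage_ok` (logical, `NA` if not checked) and
#'   `min_pair_coverage` (smallest pairwise shared non-missing fraction).
#' @export
filter_individuals_by_missingness <- function(table, i_threshold = 0.277,
                                              check_pair_coverage = TRUE) {
  stopifnot(i_threshold >= 0, i_threshold <= 1)
  im <- missingness_report(table)$i_m
  drop <- names(im)[im > i_threshold]
  kept <- gt_subset(table, individuals = setdiff(table$individual_ids, drop))
  cov_ok <- NA
  min_cov <- NA_real_
  if (check_pair_coverage && n_individuals(kept) >= 2L) {
    obs <- !is.na(kept$allele1)
    shared <- tcrossprod(obs * 1L) / n_loci(kept)
    min_cov <- min(shared[upper.tri(shared)])
    cov_ok <- min_cov > 0.5
  }
  list(table = kept,
       removed = data.frame(individual = drop, i_m = unname(im[drop]),
                            stringsAsFactors = FALSE),
       pair_coverage_ok = cov_ok,
       min_pair_coverage = min_cov)
}

#' Flag loci with zero genotype data in at least one population
#'
#' Identifies (locus, population) combinations in which every individual of
#' the population has a missing genotype. Flag-only: the loci are retained in
#' the table, but population-level analyses may reasonably exclude them.
#'
#' @param table a `genotype_table` with nonempty population labels.
#' @return data.frame with columns `locus` and `population` (zero rows when
#'   all populations have data everywhere).
#' @export
flag_population_missing_loci <- function(table) {
  pops <- unique(unname(table$population_ids))
  if (!length(pops)) stop("table has no populations")
  miss <- is.na(table$allele1)
  out <- list()
  for (p in pops) {
    rows <- unname(table$population_ids) == p
    allmiss <- colSums(!miss[rows, , drop = FALSE]) == 0L
    if (any(allmiss)) {
      out[[p]] <- data.frame(locus = table$locus_names[allmiss],
                             population = p, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(locus = character(0), population = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Apply a population label remap
#'
#' Merging population samples that represent the same population under
#' different labels (e.g. the same source population genotyped in two
#' studies) is expressed as an explicit remap instead of ad hoc edits.
#'
#' @param table a `genotype_table`.
#' @param remap named character vector: `old_label = new_label`.
#' @return the relabelled `genotype_table`.
#' @export
remap_populations <- function(table, remap) {
  pops <- unname(table$population_ids)
  hit <- pops %in% names(remap)
  pops[hit] <- unname(remap[pops[hit]])
  genotype_table(table$individual_ids, pops, unname(table$dataset_tags),
                 table$locus_names, table$allele1, table$allele2)
}
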