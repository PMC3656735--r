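# Identity-by-state profiling and allele-size offset inference.
#
# Genotypes are canonical (min, max) pairs, so the number of alleles two
# genotypes share identical by state (the size of the multiset intersection)
# vectorizes: 2 iff the sorted pairs are equal, else 1 iff any allele matches.

.shared_alleles <- function(x1, x2, y1, y2) {
  both <- !is.na(x1) & !is.na(y1)
  eq2 <- both & x1 == y1 & x2 == y2
  eq1 <- both & !eq2 & (x1 == y1 | x1 == y2 | x2 == y1 | x2 == y2)
  out <- rep(NA_integer_, length(x1))
  out[both] <- 0L
  out[eq1] <- 1L
  out[eq2] <- 2L
  out
}

#' Identity-by-state allele-sharing profile of a pair of individuals
#'
#' For one pair of individuals, the proportions of loci at which they share
#' 0, 1 and 2 alleles identical by state (IBS), denoted `p0`, `p1`, `p2`.
#' Only loci at which neither individual has a missing genotype enter the
#' calculation; allele sharing at a locus is the size of the multiset
#' intersection of the two unordered genotypes.
#'
#' @param table a `genotype_table` (or `table_b` below for cross-table pairs).
#' @param individual_i,individual_j individual ids.
#' @param table_b optional second table containing `individual_j`; defaults to
#'   `table`.
#' @return object of class `ibs_profile`: list with `p0`, `p1`, `p2`
#'   (summing to 1) and `n_loci_used`. If the pair shares no usable loci the
#'   proportions are `NA` and `n_loci_used` is 0.
#' @export
ibs_profile <- function(table, individual_i, individual_j, table_b = table) {
  i <- match(individual_i, table$individual_ids)
  j <- match(individual_j, table_b$individual_ids)
  if (is.na(i)) stop("unknown individual: ", individual_i)
  if (is.na(j)) stop("unknown individual: ", individual_j)
  shared_loci <- intersect(table$locus_names, table_b$locus_names)
  if (!length(shared_loci)) stop("tables share no loci")
  s <- .shared_alleles(table$allele1[i, shared_loci], table$allele2[i, shared_loci],
                       table_b$allele1[j, shared_loci], table_b$allele2[j, shared_loci])
  n <- sum(!is.na(s))
  if (n == 0L) {
    prof <- c(p0 = NA_real_, p1 = NA_real_, p2 = NA_real_)
  } else {
    prof <- c(p0 = sum(s == 0L, na.rm = TRUE),
              p1 = sum(s == 1L, na.rm = TRUE),
              p2 = sum(s == 2L, na.rm = TRUE)) / n
  }
  structure(list(p0 = unname(prof[1]), p1 = unname(prof[2]),
                 p2 = unname(prof[3]), n_loci_used = n),
            class = "ibs_profile")
}

# p0/p1/p2 for every pair (rows of a) x (rows of b) over the shared loci.
# Returns list of matrices n_a x n_b. Vectorized one reference row at a time.
.pairwise_ibs <- function(table_a, table_b) {
  shared <- intersect(table_a$locus_names, table_b$locus_names)
  if (!length(shared)) stop("tables share no loci")
  ax1 <- table_a$allele1[, shared, drop = FALSE]
  ax2 <- table_a$allele2[, shared, drop = FALSE]
  bx1 <- table_b$allele1[, shared, drop = FALSE]
  bx2 <- table_b$allele2[, shared, drop = FALSE]
  na <- nrow(ax1); nb <- nrow(bx1)
  n2 <- matrix(0L, na, nb); n1 <- matrix(0L, na, nb); nuse <- matrix(0L, na, nb)
  bmiss <- is.na(bx1)
  for (i in seq_len(na)) {
    x1 <- ax1[i, ]; x2 <- ax2[i, ]
    both <- !is.na(x1)[col(bx1)] & !bmiss
    # recycle reference row across the nb x L matrices of table_b
    e2 <- both & bx1 == rep(x1, each = nb) & bx2 == rep(x2, each = nb)
    e1 <- both & !e2 &
      (bx1 == rep(x1, each = nb) | bx1 == rep(x2, each = nb) |
         bx2 == rep(x1, each = nb) | bx2 == rep(x2, each = nb))
    nuse[i, ] <- rowSums(both)
    n2[i, ] <- rowSums(e2)
    n1[i, ] <- rowSums(e1)
  }
  dn <- list(table_a$individual_ids, table_b$individual_ids)
  dimnames(n2) <- dimnames(n1) <- dimnames(nuse) <- dn
  list(n1 = n1, n2 = n2, n_used = nuse)
}

#' Screen all cross-table pairs for duplicate samples
#'
#' Computes `p2` (the proportion of loci sharing 2 alleles IBS) for every
#' pair with one member in each table and reports the pairs exceeding the
#' duplicate threshold, sorted by descending `p2`. The largest `p2` among
#' sub-threshold pairs is attached as a gap diagnostic, so the bimodality
#' separating true duplicates from mere relatives can be inspected.
#'
#' @param table_a,table_b `genotype_table`s sharing at least one locus.
#' @param p2_threshold duplicate calling threshold on `p2` (strict `>`);
#'   default 0.83.
#' @return data.frame of class `duplicate_pairs` with columns `id_a`, `id_b`,
#'   `p0`, `p1`, `p2`, `n_loci_used`, plus attributes `gap_p2` (largest
#'   sub-threshold `p2`, `NA` if none) and `p2_threshold`.
#' @export
find_duplicates <- function(table_a, table_b, p2_threshold = 0.83) {
  ibs <- .pairwise_ibs(table_a, table_b)
  use <- ibs$n_used
  p2 <- ibs$n2 / ifelse(use > 0L, use, NA_integer_)
  hit <- which(!is.na(p2) & p2 > p2_threshold, arr.ind = TRUE)
  below <- p2[!is.na(p2) & p2 <= p2_threshold]
  res <- data.frame(
    id_a = table_a$individual_ids[hit[, 1]],
    id_b = table_b$individual_ids[hit[, 2]],
    p0 = (use[hit] - ibs$n1[hit] - ibs$n2[hit]) / use[hit],
    p1 = ibs$n1[hit] / use[hit],
    p2 = p2[hit],
    n_loci_used = use[hit],
    stringsAsFactors = FALSE)
  res <- res[order(-res$p2, res$id_a, res$id_b), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "gap_p2") <- if (length(below)) max(below) else NA_real_
  attr(res, "p2_threshold") <- p2_threshold
  class(res) <- c("duplicate_pairs", "data.frame")
  res
}

#' Infer the allele-size translation constant at one locus
#'
#' Given duplicate pairs between a reference and an incoming data set,
#' searches every integer translation constant `c` in the closed range
#' `[a - B, A - b]` (`a`, `A`: smallest/largest reference allele at the
#' locus; `b`, `B`: smallest/largest incoming allele) and evaluates
#' `g_c,2`, the proportion of duplicate pairs with non-missing genotypes in
#' both data sets that share 2 alleles IBS once `c` is added to the incoming
#' alleles. The maximizing constant is `c*`; outside the search range no
#' allele overlap is possible, so the restriction loses nothing.
#'
#' Classification at `c*`: `"exact"` if `c* = 0` and `g2 >=
#' mismatch_threshold`; `"offset"` if `c* != 0` and `g2 >= mismatch_threshold`;
#' otherwise `"mismatch"` (the locus shows no consistent translation, e.g.
#' allele-specific shifts, and should be excluded from a merge).
#'
#' @param reference_table,incoming_table `genotype_table`s.
#' @param duplicate_pairs data.frame with columns `id_a` (reference member)
#'   and `id_b` (incoming member), e.g. from [find_duplicates()].
#' @param locus locus name present in both tables.
#' @param mismatch_threshold minimum `g2` for a locus to be considered
#'   consistently translatable; default 0.75.
#' @param min_pairs minimum usable duplicate pairs; below 5 a warning is
#'   issued, below `min_pairs` the locus is classified `"mismatch"` with
#'   `n_pairs_used` recorded.
#' @return list of class `offset_result`: `locus`, `search_range`, `c_star`,
#'   `g2`, `g12` (share 1 or 2 alleles at `c*`), `n_pairs_used`,
#'   `classification`, `tie` (TRUE if several constants attained the maximum).
#' @export
infer_offset <- function(reference_table, incoming_table, duplicate_pairs,
                         locus, mismatch_threshold = 0.75, min_pairs = 1L) {
  if (!locus %in% reference_table$locus_names ||
      !locus %in% incoming_table$locus_names) {
    stop("locus not present in both tables: ", locus)
  }
  ri <- match(duplicate_pairs$id_a, reference_table$individual_ids)
  ci <- match(duplicate_pairs$id_b, incoming_table$individual_ids)
  if (anyNA(ri) || anyNA(ci)) stop("duplicate pair member absent from table")
  rx1 <- reference_table$allele1[ri, locus]
  rx2 <- reference_table$allele2[ri, locus]
  ix1 <- incoming_table$allele1[ci, locus]
  ix2 <- incoming_table$allele2[ci, locus]
  usable <- !is.na(rx1) & !is.na(ix1)
  n_use <- sum(usable)

  ref_all <- c(reference_table$allele1[, locus], reference_table$allele2[, locus])
  inc_all <- c(incoming_table$allele1[, locus], incoming_table$allele2[, locus])
  if (all(is.na(ref_all)) || all(is.na(inc_all)) || n_use < max(1L, min_pairs)) {
    if (n_use < 5L) {
      warning("locus ", locus, ": only ", n_use,
              " usable duplicate pairs; offset not inferable")
    }
    return(structure(list(locus = locus, search_range = c(NA_integer_, NA_integer_),
                          c_star = NA_integer_, g2 = NA_real_, g12 = NA_real_,
                          n_pairs_used = n_use, classification = "mismatch",
                          tie = FALSE),
                     class = "offset_result"))
  }
  if (n_use < 5L) {
    warning("locus ", locus, ": only ", n_use, " usable duplicate pairs")
  }
  a <- min(ref_all, na.rm = TRUE); A <- max(ref_all, na.rm = TRUE)
  b <- min(inc_all, na.rm = TRUE); B <- max(inc_all, na.rm = TRUE)
  cs <- seq.int(a - B, A - b)
  rx1 <- rx1[usable]; rx2 <- rx2[usable]
  ix1 <- ix1[usable]; ix2 <- ix2[usable]
  g2s <- vapply(cs, function(cc) mean(rx1 == ix1 + cc & rx2 == ix2 + cc), 0)
  best <- max(g2s)
  cand <- cs[g2s == best]
  # ties: smallest |c|, then the negative value
  cand <- cand[order(abs(cand), cand)]
  c_star <- cand[1]
  g12 <- mean(rx1 == ix1 + c_star | rx1 == ix2 + c_star |
                rx2 == ix1 + c_star | rx2 == ix2 + c_star)
  cls <- if (best >= mismatch_threshold) {
    if (c_star == 0L) "exact" else "offset"
  } else "mismatch"
  structure(list(locus = locus, search_range = c(a - B, A - b),
                 c_star = as.integer(c_star), g2 = best, g12 = g12,
                 n_pairs_used = n_use, classification = cls,
                 tie = length(cand) > 1L),
            class = "offset_result")
}

#' Infer translation constants for every shared locus
#'
#' Maps [infer_offset()] over the loci shared by the reference and incoming
#' tables and summarizes the exact / offset / mismatch counts.
#'
#' @inheritParams infer_offset
#' @return data.frame of class `offset_table` with one row per shared locus
#'   (columns `locus`, `range_lo`, `range_hi`, `c_star`, `g2`, `g12`,
#'   `n_pairs`, `classification`, `tie`) and attribute `summary` (named
#'   counts).
#' @export
infer_all_offsets <- function(reference_table, incoming_table, duplicate_pairs,
                              mismatch_threshold = 0.75, min_pairs = 1L) {
  shared <- intersect(reference_table$locus_names, incoming_table$locus_names)
  if (!length(shared)) stop("tables share no loci")
  rows <- lapply(shared, function(loc) {
    r <- infer_offset(reference_table, incoming_table, duplicate_pairs, loc,
                      mismatch_threshold = mismatch_threshold,
                      min_pairs = min_pairs)
    data.frame(locus = r$locus, range_lo = r$search_range[1],
               range_hi = r$search_range[2], c_star = r$c_star, g2 = r$g2,
               g12 = r$g12, n_pairs = r$n_pairs_used,
               classification = r$classification, tie = r$tie,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "summary") <- c(exact = sum(out$classification == "exact"),
                            offset = sum(out$classification == "offset"),
                            mismatch = sum(out$classification == "mismatch"))
  class(out) <- c("offset_table", "data.frame")
  out
}

#' Write inferred offsets as TSV
#'
#' One row per locus: `locus, c_star, g2, g12, n_pairs, classification`.
#' @param offsets an `offset_table` from [infer_all_offsets()].
#' @param path file to write.
#' @export
write_offset_table <- function(offsets, path) {
  utils::write.table(
    offsets[c("locus", "c_star", "g2", "g12", "n_pairs", "classification")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
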