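# Composite-likelihood relationship classification from unlinked loci.
#
# Relationship classes are parameterized by prior IBD-sharing probabilities
# (k0, k1, k2). Half-sib, grandparent-grandchild and avuncular pairs all have
# (1/2, 1/2, 0) and are likelihood-equivalent without linkage information, so
# they are exposed as a single collapsed SECOND_DEGREE class.

.REL_K <- rbind(
  MZ            = c(0,    0,   1),
  PO            = c(0,    1,   0),
  FS            = c(0.25, 0.5, 0.25),
  SECOND_DEGREE = c(0.5,  0.5, 0),
  CO            = c(0.75, 0.25, 0),
  UN            = c(1,    0,   0))
colnames(.REL_K) <- c("k0", "k1", "k2")

#' IBD-sharing coefficients of a relationship class
#'
#' @param relationship one of `"MZ"`, `"PO"`, `"FS"`, `"SECOND_DEGREE"`
#'   (collapsing half-sib, grandparent-grandchild and avuncular), `"CO"`,
#'   `"UN"`.
#' @return named numeric `(k0, k1, k2)`, the prior probabilities that the
#'   pair shares 0, 1 or 2 alleles identical by descent at a locus.
#' @export
ibd_coefficients <- function(relationship) {
  # the specific second-degree pedigrees share (1/2, 1/2, 0)
  if (relationship %in% c("HS", "GG", "AV")) relationship <- "SECOND_DEGREE"
  if (!relationship %in% rownames(.REL_K)) {
    stop("unknown relationship type: ", relationship)
  }
  .REL_K[relationship, ]
}

#' Relationship classes recognized by the classifier
#' @return character vector of class names.
#' @export
relationship_types <- function() rownames(.REL_K)

#' Kinship coefficient implied by a relationship class
#'
#' theta = k1/4 + k2/2: the probability that one allele drawn from each
#' individual is identical by descent.
#' @inheritParams ibd_coefficients
#' @return numeric scalar.
#' @export
kinship_coefficient <- function(relationship) {
  k <- ibd_coefficients(relationship)
  unname(k[2] / 4 + k[3] / 2)
}

# Per-allele replacement error (an allele call is replaced by a random draw
# from the locus frequency vector with probability eps) leaves the marginal
# genotype distribution at HWE and breaks each cross-individual IBD link
# independently with probability 1 - (1-eps)^2, so it folds exactly into the
# IBD-state mixing weights.
.adjust_k_for_error <- function(k, eps) {
  if (eps == 0) return(k)
  s <- (1 - eps)^2
  k2 <- k[3] * s^2
  k1 <- k[2] * s + 2 * k[3] * s * (1 - s)
  c(1 - k1 - k2, k1, k2)
}

#' Classifier settings
#'
#' @param error_rate per-allele genotyping error rate `eps` used in the
#'   likelihoods (default 0.008). Must lie in \[0, 0.1\].
#' @param threshold likelihood-ratio critical value: a pair is accepted as
#'   related when the best non-unrelated likelihood exceeds the unrelated
#'   likelihood by at least this factor (default 100). Must exceed 1.
#' @param exclude_populations populations skipped during intra-population
#'   screening (populations in which relative inference is known to be
#'   unreliable can be opted out).
#' @param loci optional locus subset used for all likelihoods.
#' @return list of class `relatedness_config`.
#' @export
relatedness_config <- function(error_rate = 0.008, threshold = 100,
                               exclude_populations = character(0),
                               loci = NULL) {
  stopifnot(error_rate >= 0, error_rate <= 0.1, threshold > 1)
  structure(list(error_rate = error_rate, threshold = threshold,
                 exclude_populations = exclude_populations, loci = loci),
            class = "relatedness_config")
}

#' Count-estimate allele frequencies
#'
#' Per-locus allele frequencies estimated by counting non-missing gene copies
#' in a group of individuals and normalizing.
#'
#' @param table a `genotype_table`.
#' @param individuals ids forming the frequency group (default: all).
#' @param loci optional locus subset.
#' @return matrix of class `allele_freqs` (allele sizes x loci); rownames are
#'   allele lengths. Columns for loci with zero observed copies are `NA`
#'   (such loci are skipped in likelihoods). Columns sum to 1 otherwise.
#' @export
allele_frequencies <- function(table, individuals = NULL, loci = NULL) {
  if (!is.null(individuals) || !is.null(loci)) {
    table <- gt_subset(table, individuals = individuals, loci = loci)
  }
  if (n_individuals(table) == 0L) stop("frequency group is empty")
  a1 <- table$allele1; a2 <- table$allele2
  ladder <- sort(unique(c(a1[!is.na(a1)], a2[!is.na(a2)])))
  L <- n_loci(table)
  f <- matrix(NA_real_, length(ladder), L,
              dimnames = list(ladder, table$locus_names))
  for (j in seq_len(L)) {
    v <- c(a1[, j], a2[, j])
    v <- v[!is.na(v)]
    if (length(v)) {
      f[, j] <- tabulate(match(v, ladder), nbins = length(ladder)) / length(v)
    }
  }
  attr(f, "ladder") <- ladder
  class(f) <- c("allele_freqs", class(f))
  f
}

# Joint probabilities of an unordered genotype pair conditional on sharing
# 0, 1 or 2 alleles IBD, under HWE with the given allele frequencies.
# x1 <= x2 and y1 <= y2 are canonical genotypes across loci (vectors).
# Returns an L x 3 matrix (P0, P1, P2); NA rows are unusable loci.
.pair_probs <- function(x1, x2, y1, y2, freqs) {
  ladder <- attr(freqs, "ladder")
  L <- length(x1)
  jj <- seq_len(L)
  pa <- freqs[cbind(match(x1, ladder), jj)]
  pb <- freqs[cbind(match(x2, ladder), jj)]
  pc <- freqs[cbind(match(y1, ladder), jj)]
  pd <- freqs[cbind(match(y2, ladder), jj)]
  hom1 <- x1 == x2
  hom2 <- y1 == y2
  pg1 <- ifelse(hom1, pa * pb, 2 * pa * pb)
  pg2 <- ifelse(hom2, pc * pd, 2 * pc * pd)
  p0 <- pg1 * pg2
  p2 <- ifelse(x1 == y1 & x2 == y2, pg1, 0)
  p1 <- ifelse(hom1 & hom2, ifelse(x1 == y1, pa * pa * pc, 0),
        ifelse(hom1 & !hom2,
               ifelse(x1 == y1, pa * pa * pd,
               ifelse(x1 == y2, pa * pa * pc, 0)),
        ifelse(!hom1 & hom2,
               ifelse(y1 == x1, pc * pc * pb,
               ifelse(y1 == x2, pc * pc * pa, 0)),
        ifelse(x1 == y1 & x2 == y2, pa * pb * (pa + pb),
        ifelse(x1 == y1, pa * pb * pd,
        ifelse(x1 == y2, pa * pb * pc,
        ifelse(x2 == y1, pb * pa * pd,
        ifelse(x2 == y2, pb * pa * pc, 0))))))))
  # unusable: missing genotype, undefined frequency column, or an allele
  # carried by the pair but absent from the frequency group
  usable <- !is.na(p0) & p0 > 0
  cbind(P0 = ifelse(usable, p0, NA_real_),
        P1 = ifelse(usable, p1, NA_real_),
        P2 = ifelse(usable, p2, NA_real_))
}

.pair_indices <- function(table, individual_i, individual_j) {
  i <- match(individual_i, table$individual_ids)
  j <- match(individual_j, table$individual_ids)
  if (is.na(i)) stop("unknown individual: ", individual_i)
  if (is.na(j)) stop("unknown individual: ", individual_j)
  c(i, j)
}

#' Composite log-likelihood of a pair under a relationship class
#'
#' Per locus, `P(G1, G2 | R) = k0 P0 + k1 P1 + k2 P2`, where `Pm` is the
#' joint probability of the genotype pair given `m` alleles shared identical
#' by descent under Hardy-Weinberg proportions, and `(k0, k1, k2)` are the
#' class coefficients after folding in the genotyping error rate. The
#' log-likelihood is summed over loci at which both genotypes are non-missing
#' and every carried allele has positive frequency; linkage between loci is
#' ignored (composite likelihood).
#'
#' @param table a `genotype_table`.
#' @param individual_i,individual_j individual ids.
#' @param freqs an `allele_freqs` matrix, typically from the pair's
#'   population or region.
#' @param relationship a class name from [relationship_types()].
#' @param error_rate per-allele replacement error rate (default 0).
#' @return log-likelihood (natural log).
#' @export
pair_likelihood <- function(table, individual_i, individual_j, freqs,
                            relationship, error_rate = 0) {
  ij <- .pair_indices(table, individual_i, individual_j)
  loci <- colnames(freqs)
  probs <- .pair_probs(table$allele1[ij[1], loci], table$allele2[ij[1], loci],
                       table$allele1[ij[2], loci], table$allele2[ij[2], loci],
                       freqs)
  k <- .adjust_k_for_error(ibd_coefficients(relationship), error_rate)
  use <- !is.na(probs[, 1])
  sum(log(probs[use, , drop = FALSE] %*% k))
}

#' Classify a pair of individuals into a relationship class
#'
#' Evaluates the composite log-likelihood of every relationship class and
#' reports the best non-unrelated class together with its likelihood ratio
#' against the unrelated class. A pair is `accepted` when the ratio reaches
#' the critical value and the best class is not first-cousin (CO calls are
#' disregarded as unreliable; they are reported for diagnostics only).
#'
#' @inheritParams pair_likelihood
#' @param config a [relatedness_config()].
#' @return list of class `relationship_call`: `id1`, `id2`, `loglik` (named,
#'   all classes), `best` (best non-UN class), `log10_lr` (log10 likelihood
#'   ratio best vs UN), `accepted`, `n_loci_used`.
#' @export
classify_pair <- function(table, individual_i, individual_j, freqs, config) {
  ij <- .pair_indices(table, individual_i, individual_j)
  loci <- colnames(freqs)
  probs <- .pair_probs(table$allele1[ij[1], loci], table$allele2[ij[1], loci],
                       table$allele1[ij[2], loci], table$allele2[ij[2], loci],
                       freqs)
  .classify_from_probs(probs, individual_i, individual_j, config)
}

.classify_from_probs <- function(probs, id1, id2, config) {
  use <- !is.na(probs[, 1])
  if (!any(use)) stop("pair ", id1, " / ", id2, " shares no usable loci")
  p <- probs[use, , drop = FALSE]
  lls <- vapply(rownames(.REL_K), function(r) {
    k <- .adjust_k_for_error(.REL_K[r, ], config$error_rate)
    sum(log(p %*% k))
  }, 0)
  non_un <- setdiff(names(lls), "UN")
  best <- non_un[which.max(lls[non_un])]
  log10_lr <- (lls[[best]] - lls[["UN"]]) / log(10)
  structure(list(id1 = id1, id2 = id2, loglik = lls, best = best,
                 log10_lr = log10_lr,
                 accepted = log10_lr >= log10(config$threshold) && best != "CO",
                 n_loci_used = sum(use)),
            class = "relationship_call")
}

.rel_degree <- function(type) {
  c(MZ = "mz", PO = "first", FS = "first", SECOND_DEGREE = "second",
    CO = "co", UN = "un")[type]
}

# classify many pairs against one frequency matrix; returns accepted calls
.screen_pairs <- function(table, pairs_idx, freqs, config, scope, group) {
  loci <- colnames(freqs)
  a1 <- table$allele1[, loci, drop = FALSE]
  a2 <- table$allele2[, loci, drop = FALSE]
  out <- vector("list", nrow(pairs_idx))
  for (r in seq_len(nrow(pairs_idx))) {
    i <- pairs_idx[r, 1]; j <- pairs_idx[r, 2]
    probs <- .pair_probs(a1[i, ], a2[i, ], a1[j, ], a2[j, ], freqs)
    if (!any(!is.na(probs[, 1]))) next
    call <- .classify_from_probs(probs, table$individual_ids[i],
                                 table$individual_ids[j], config)
    if (call$accepted) {
      out[[r]] <- data.frame(
        id1 = call$id1, id2 = call$id2, scope = scope, group = group,
        type = call$best, degree = unname(.rel_degree(call$best)),
        log10_lr = unname(call$log10_lr), n_loci = call$n_loci_used,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out[!vapply(out, is.null, TRUE)])
}

.empty_calls <- function() {
  data.frame(id1 = character(0), id2 = character(0), scope = character(0),
             group = character(0), type = character(0), degree = character(0),
             log10_lr = numeric(0), n_loci = integer(0),
             stringsAsFactors = FALSE)
}

#' Screen each population for intra-population relative pairs
#'
#' Separately in each population, classifies every pair of its individuals
#' using count-estimated allele frequencies from that population, and
#' returns the accepted calls. Populations listed in
#' `config$exclude_populations` or with fewer than two individuals are
#' skipped.
#'
#' @param table a `genotype_table`.
#' @param config a [relatedness_config()].
#' @return data.frame of accepted calls: `id1`, `id2`, `scope` (`"intra"`),
#'   `group` (population), `type`, `degree`, `log10_lr`, `n_loci`.
#' @export
screen_intra_population <- function(table, config = relatedness_config()) {
  pops <- setdiff(unique(unname(table$population_ids)),
                  config$exclude_populations)
  res <- list()
  for (p in pops) {
    idx <- which(unname(table$population_ids) == p)
    if (length(idx) < 2L) next
    freqs <- allele_frequencies(table, individuals = table$individual_ids[idx],
                                loci = config$loci)
    pairs_idx <- t(utils::combn(idx, 2L))
    res[[p]] <- .screen_pairs(table, pairs_idx, freqs, config, "intra", p)
  }
  res <- res[!vapply(res, is.null, TRUE)]
  if (!length(res)) return(.empty_calls())
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Screen each geographic region for inter-population relative pairs
#'
#' Separately in each region, classifies pairs of individuals from distinct
#' populations using count-estimated allele frequencies pooled over the
#' region. Within-population pairs are never tested here. Regions with fewer
#' than two populations are skipped.
#'
#' @param table a `genotype_table`.
#' @param region_grouping named character vector mapping population id to
#'   region.
#' @param config a [relatedness_config()].
#' @return data.frame of accepted calls as in [screen_intra_population()],
#'   with `scope = "inter"` and `group` = region.
#' @export
screen_inter_population <- function(table, region_grouping,
                                    config = relatedness_config()) {
  pops <- unname(table$population_ids)
  unknown <- setdiff(unique(pops), names(region_grouping))
  if (length(unknown)) {
    stop("populations without a region: ", paste(unknown, collapse = ", "))
  }
  regions <- unname(region_grouping[pops])
  res <- list()
  for (reg in unique(regions)) {
    idx <- which(regions == reg)
    if (length(unique(pops[idx])) < 2L) next
    freqs <- allele_frequencies(table, individuals = table$individual_ids[idx],
                                loci = config$loci)
    pairs_idx <- t(utils::combn(idx, 2L))
    cross <- pops[pairs_idx[, 1]] != pops[pairs_idx[, 2]]
    if (!any(cross)) next
    res[[reg]] <- .screen_pairs(table, pairs_idx[cross, , drop = FALSE],
                                freqs, config, "inter", reg)
  }
  res <- res[!vapply(res, is.null, TRUE)]
  if (!length(res)) return(.empty_calls())
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Detect parent/parent/offspring trios among parent-offspring calls
#'
#' A trio is an individual with accepted PO calls to two partners who are
#' not themselves called related to each other (two unrelated parents of a
#' shared offspring). Partners with any accepted call between them -- e.g.
#' the grandparent-grandchild pair flanking the middle individual of a
#' three-generation chain -- do not form a trio.
#'
#' @param calls data.frame of accepted relationship calls with columns
#'   `id1`, `id2`, `type` (e.g. from [screen_intra_population()]).
#' @return data.frame with columns `parent1`, `parent2`, `offspring` (zero
#'   rows when no trio exists).
#' @export
find_trios <- function(calls) {
  empty <- data.frame(parent1 = character(0), parent2 = character(0),
                      offspring = character(0), stringsAsFactors = FALSE)
  po <- calls[calls$type == "PO", , drop = FALSE]
  if (!nrow(po)) return(empty)
  closely_related <- paste(pmin(calls$id1, calls$id2),
                           pmax(calls$id1, calls$id2))
  nodes <- unique(c(po$id1, po$id2))
  out <- list()
  for (child in nodes) {
    partners <- sort(unique(c(po$id2[po$id1 == child], po$id1[po$id2 == child])))
    if (length(partners) < 2L) next
    cmb <- utils::combn(partners, 2L)
    for (k in seq_len(ncol(cmb))) {
      m <- cmb[1, k]; f <- cmb[2, k]
      if (!(paste(min(m, f), max(m, f)) %in% closely_related)) {
        out[[length(out) + 1L]] <- data.frame(parent1 = m, parent2 = f,
                                              offspring = child,
                                              stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

# minimum vertex-cover size of an edge list by branch and bound (small
# components only)
.minvc_size <- function(id1, id2) {
  if (!length(id1)) return(0L)
  # branch on the endpoints of the first edge
  u <- id1[1]; v <- id2[1]
  ku <- !(id1 == u | id2 == u)
  kv <- !(id1 == v | id2 == v)
  1L + min(.minvc_size(id1[ku], id2[ku]), .minvc_size(id1[kv], id2[kv]))
}

# Remove one member per target edge, removing as few individuals as possible.
# The removal set has exactly minimum-vertex-cover size on each connected
# component; among minimum covers, individuals covering more remaining target
# edges are preferred, then individuals in more relative pairs overall, then
# higher missingness, then the lexicographically last id. Components too
# large for exact search (not expected in relative graphs, which decompose
# into small families) fall back to the pure greedy preference order.
.min_cover <- function(target, all_edges, i_m, max_exact_nodes = 25L) {
  if (!nrow(target)) return(character(0))
  # connected components of the target graph are independent problems
  comp <- stats::setNames(seq_along(unique(c(target$id1, target$id2))),
                          unique(c(target$id1, target$id2)))
  repeat {
    merged <- pmin(comp[target$id1], comp[target$id2])
    changed <- FALSE
    for (e in seq_len(nrow(target))) {
      if (comp[[target$id1[e]]] != merged[e] ||
          comp[[target$id2[e]]] != merged[e]) {
        old <- c(comp[[target$id1[e]]], comp[[target$id2[e]]])
        comp[comp %in% old] <- merged[e]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  unlist(lapply(unique(comp), function(cid) {
    nodes <- names(comp)[comp == cid]
    sub <- target[target$id1 %in% nodes | target$id2 %in% nodes, ,
                  drop = FALSE]
    .min_cover_component(sub, all_edges, i_m, max_exact_nodes)
  }), use.names = FALSE)
}

.min_cover_component <- function(target, all_edges, i_m, max_exact_nodes) {
  removed <- character(0)
  repeat {
    if (!nrow(target)) break
    cand <- unique(c(target$id1, target$id2))
    tdeg <- vapply(cand, function(v) sum(target$id1 == v) + sum(target$id2 == v),
                   0L)
    fdeg <- vapply(cand, function(v)
      sum(all_edges$id1 == v) + sum(all_edges$id2 == v), 0L)
    miss <- i_m[cand]
    miss[is.na(miss)] <- 0
    ord <- order(-tdeg, -fdeg, -miss, cand, method = "radix",
                 decreasing = c(FALSE, FALSE, FALSE, TRUE))
    pick <- NA_character_
    if (length(cand) <= max_exact_nodes) {
      k <- .minvc_size(target$id1, target$id2)
      for (v in cand[ord]) {
        keep <- !(target$id1 == v | target$id2 == v)
        if (.minvc_size(target$id1[keep], target$id2[keep]) == k - 1L) {
          pick <- v
          break
        }
      }
    }
    if (is.na(pick)) pick <- cand[ord[1]]
    removed <- c(removed, pick)
    keep <- target$id1 != pick & target$id2 != pick
    target <- target[keep, , drop = FALSE]
    all_edges <- all_edges[all_edges$id1 != pick & all_edges$id2 != pick, ,
                           drop = FALSE]
  }
  removed
}

#' Construct three nested standardized subsets of unrelated individuals
#'
#' Level 1 removes both members of every inter-population MZ or first-degree
#' pair (their correct population affiliation cannot be determined) and one
#' member of every intra-population MZ pair. Level 2 additionally removes one
#' member of every intra-population first-degree pair, and level 3 one member
#' of every intra-population second-degree pair. Inter-population
#' second-degree pairs are never excluded (such inferences are unreliable in
#' structured populations). One-member removals remove the minimum number of individuals (exact minimum vertex cover per family component); among minimum covers, individuals
#' participating in the most remaining pairs are removed first, ties broken
#' by membership in more relative pairs overall, then by higher missing-data
#' fraction.
#'
#' @param calls data.frame of accepted calls with columns `id1`, `id2`,
#'   `scope` (`"intra"`/`"inter"`), `degree` (`"mz"`/`"first"`/`"second"`).
#' @param i_m named numeric vector of per-individual missing fractions whose
#'   names enumerate all individuals (see [missingness_report()]).
#' @return list of class `standard_subsets`: `level1`, `level2`, `level3`
#'   (nested character vectors of retained ids) and `removed` (data.frame
#'   with `individual`, `level`, `reason`).
#' @export
build_subsets <- function(calls, i_m) {
  all_ids <- names(i_m)
  if (is.null(all_ids)) stop("i_m must be a named vector over all individuals")
  edges <- calls[c("id1", "id2", "scope", "degree")]

  both_out <- edges$scope == "inter" & edges$degree %in% c("mz", "first")
  mandatory <- unique(c(edges$id1[both_out], edges$id2[both_out]))

  alive_edges <- function(e, alive) {
    e[e$id1 %in% alive & e$id2 %in% alive, , drop = FALSE]
  }
  removed <- data.frame(individual = mandatory,
                        level = rep(1L, length(mandatory)),
                        reason = rep("inter-population MZ/first-degree pair member",
                                     length(mandatory)),
                        stringsAsFactors = FALSE)
  alive <- setdiff(all_ids, mandatory)

  mz_intra <- alive_edges(edges[edges$scope == "intra" & edges$degree == "mz", ,
                                drop = FALSE], alive)
  r1 <- .min_cover(mz_intra, alive_edges(edges, alive), i_m)
  removed <- rbind(removed,
                   data.frame(individual = r1, level = rep(1L, length(r1)),
                              reason = rep("intra-population MZ pair", length(r1)),
                              stringsAsFactors = FALSE))
  level1 <- setdiff(alive, r1)

  fd <- alive_edges(edges[edges$scope == "intra" & edges$degree == "first", ,
                          drop = FALSE], level1)
  r2 <- .min_cover(fd, alive_edges(edges, level1), i_m)
  removed <- rbind(removed,
                   data.frame(individual = r2, level = rep(2L, length(r2)),
                              reason = rep("intra-population first-degree pair", length(r2)),
                              stringsAsFactors = FALSE))
  level2 <- setdiff(level1, r2)

  sd <- alive_edges(edges[edges$scope == "intra" & edges$degree == "second", ,
                          drop = FALSE], level2)
  r3 <- .min_cover(sd, alive_edges(edges, level2), i_m)
  removed <- rbind(removed,
                   data.frame(individual = r3, level = rep(3L, length(r3)),
                              reason = rep("intra-population second-degree pair", length(r3)),
                              stringsAsFactors = FALSE))
  level3 <- setdiff(level2, r3)

  structure(list(level1 = level1, level2 = level2, level3 = level3,
                 removed = removed),
            class = "standard_subsets")
}
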