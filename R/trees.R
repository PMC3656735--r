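# Neighbor-joining, locus bootstrap, and greedy consensus.
#
# NJ and the consensus are implemented here (rather than wrapped) because
# deterministic tie-breaking and negative-branch handling are part of the
# contract: Q-matrix ties are broken by the lowest label-index pair, and
# negative branch lengths are clamped to zero with the deficit moved to the
# sister branch so path lengths are preserved. ape is used for the phylo
# container and Newick serialization.

#' Neighbor-joining tree from a distance matrix
#'
#' Standard agglomerative neighbor joining: repeatedly join the pair
#' minimizing `Q(i,j) = (r - 2) d(i,j) - R_i - R_j`, attach the joined nodes
#' with the usual branch-length formulas, reduce the matrix, and resolve the
#' final three nodes with the three-point formulas. On an additive matrix the
#' generating tree is recovered exactly.
#'
#' @param distance_matrix symmetric matrix with labelled rows/columns
#'   (>= 3 taxa).
#' @param clamp_negative clamp negative branch lengths to zero, transferring
#'   the deficit to the sister branch (default TRUE).
#' @return an unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(distance_matrix, clamp_negative = TRUE) {
  d <- unclass(as.matrix(distance_matrix))
  attr(d, "n_loci") <- NULL
  n <- nrow(d)
  if (n < 3L) stop("neighbor joining requires at least 3 taxa")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  # nodes carry partial Newick strings
  sub <- labels
  repeat {
    r <- nrow(d)
    if (r == 3L) break
    R <- rowSums(d)
    Q <- (r - 2) * d - outer(R, R, `+`)
    diag(Q) <- Inf
    # lowest label-index pair among minima (column-major scan of upper pairs)
    minQ <- min(Q)
    cand <- which(Q - minQ <= abs(minQ) * 1e-12 + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    bi <- d[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    bj <- d[i, j] - bi
    if (clamp_negative) {
      if (bi < 0) { bj <- bj + bi; bi <- 0 }
      if (bj < 0) { bi <- bi + bj; bj <- 0 }
      bi <- max(bi, 0); bj <- max(bj, 0)
    }
    new_sub <- sprintf("(%s:%s,%s:%s)", sub[i], .fmt_bl(bi), sub[j], .fmt_bl(bj))
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]),
               c(du[keep], 0))
    sub <- c(sub[keep], new_sub)
  }
  # final 3 nodes: three-point formulas
  ba <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  bb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  bc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  if (clamp_negative) {
    for (k in 1:3) {
      b <- c(ba, bb, bc)
      if (b[k] < 0) {
        deficit <- b[k]
        b[k] <- 0
        sib <- which.max(b)
        b[sib] <- b[sib] + deficit
        ba <- b[1]; bb <- b[2]; bc <- b[3]
      }
    }
    ba <- max(ba, 0); bb <- max(bb, 0); bc <- max(bc, 0)
  }
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", sub[1], .fmt_bl(ba),
                 sub[2], .fmt_bl(bb), sub[3], .fmt_bl(bc))
  ape::read.tree(text = nwk)
}

.fmt_bl <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)

#' Neighbor-joining trees from locus-bootstrap resamples
#'
#' Each replicate resamples loci with replacement, recomputes the
#' population-level allele-sharing distance matrix, and builds a
#' neighbor-joining tree. A replicate in which some population pair has no
#' usable locus is dropped with a message. Deterministic under `seed`.
#'
#' @param table a `genotype_table` with >= 3 populations.
#' @param n_replicates number of bootstrap replicates (0 gives an empty
#'   list).
#' @param seed integer seed.
#' @return list of `phylo` trees; attribute `n_dropped` counts dropped
#'   replicates.
#' @export
bootstrap_distance_trees <- function(table, n_replicates = 1000L, seed = 1L) {
  S <- .population_locus_sharing(table)
  if (length(attr(S, "populations")) < 3L) stop("need at least 3 populations")
  set.seed(seed)
  L <- ncol(S)
  trees <- vector("list", n_replicates)
  dropped <- 0L
  for (b in seq_len(n_replicates)) {
    w <- tabulate(sample.int(L, L, replace = TRUE), nbins = L)
    tr <- tryCatch(neighbor_joining(.pop_dist_from_sharing(S, w)),
                   error = function(e) NULL)
    if (is.null(tr)) dropped <- dropped + 1L else trees[[b]] <- tr
  }
  if (dropped) message(dropped, " bootstrap replicate(s) dropped ",
                       "(undefined population-pair distance)")
  trees <- trees[!vapply(trees, is.null, TRUE)]
  attr(trees, "n_dropped") <- dropped
  trees
}

# Non-trivial bipartitions of an unrooted tree, canonicalized as the sorted
# block NOT containing the first taxon of `taxa`; returned as "|"-collapsed
# keys.
.tree_bipartitions <- function(tree, taxa) {
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  children <- vector("list", nt + nn)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]
    children[[p]] <- c(children[[p]], tree$edge[e, 2])
  }
  tipsets <- vector("list", nt + nn)
  for (i in seq_len(nt)) tipsets[[i]] <- tree$tip.label[i]
  assemble <- function(node) {
    if (!is.null(tipsets[[node]])) return(tipsets[[node]])
    out <- unlist(lapply(children[[node]], assemble))
    tipsets[[node]] <<- out
    out
  }
  root <- nt + 1L
  assemble(root)
  keys <- character(0)
  for (node in setdiff(unique(tree$edge[, 2]), seq_len(nt))) {
    block <- tipsets[[node]]
    if (taxa[1] %in% block) block <- setdiff(taxa, block)
    if (length(block) >= 2L && length(block) <= length(taxa) - 2L) {
      keys <- c(keys, paste(sort(block), collapse = "|"))
    }
  }
  unique(keys)
}

#' Greedy consensus of a set of trees
#'
#' Bipartitions are ranked by their frequency across the input trees and
#' added in decreasing order whenever compatible with those already
#' accepted; ties at equal frequency are broken by the canonical
#' lexicographic order of the bipartition (logged via the `ties` attribute).
#' Edge support values are the bipartition frequencies.
#'
#' @param trees list of `phylo` trees on an identical taxon set.
#' @return a `phylo` tree whose internal node labels carry the support of
#'   the subtending edge (frequency in \[0, 1\]); attribute `split_support`
#'   is the named frequency vector of accepted splits.
#' @export
greedy_consensus <- function(trees) {
  if (!length(trees)) stop("no trees supplied")
  taxa <- sort(trees[[1]]$tip.label)
  for (tr in trees) {
    if (!identical(sort(tr$tip.label), taxa)) {
      stop("all trees must share an identical taxon set")
    }
  }
  counts <- table(unlist(lapply(trees, .tree_bipartitions, taxa = taxa)))
  freq <- as.numeric(counts) / length(trees)
  names(freq) <- names(counts)
  ord <- order(-freq, names(freq), method = "radix")
  freq <- freq[ord]
  tie <- any(duplicated(freq))

  accepted <- list()
  acc_freq <- numeric(0)
  blocks <- strsplit(names(freq), "|", fixed = TRUE)
  for (k in seq_along(freq)) {
    b <- blocks[[k]]
    compatible <- all(vapply(accepted, function(a) {
      length(intersect(a, b)) == 0L || all(a %in% b) || all(b %in% a)
    }, TRUE))
    if (compatible) {
      accepted[[length(accepted) + 1L]] <- b
      acc_freq <- c(acc_freq, freq[[k]])
    }
  }
  tree <- .tree_from_clusters(taxa, accepted, acc_freq)
  attr(tree, "split_support") <- stats::setNames(acc_freq,
                                                 vapply(accepted, paste,
                                                        "", collapse = "|"))
  attr(tree, "ties") <- tie
  tree
}

# Build a phylo from a laminar family of clusters over taxa[-1] (canonical
# blocks exclude the first taxon), with per-cluster support labels.
.tree_from_clusters <- function(taxa, clusters, supports) {
  nwk_of <- function(members, avail_idx) {
    # children: maximal clusters among avail_idx fully inside `members`,
    # plus leftover leaves
    inside <- avail_idx[vapply(avail_idx,
                               function(k) all(clusters[[k]] %in% members), TRUE)]
    # maximal = not contained in another inside-cluster
    is_max <- vapply(inside, function(k) {
      !any(vapply(setdiff(inside, k), function(m)
        all(clusters[[k]] %in% clusters[[m]]), TRUE))
    }, TRUE)
    tops <- inside[is_max]
    used <- character(0)
    parts <- character(0)
    for (k in tops) {
      sub <- nwk_of(clusters[[k]], setdiff(inside, k))
      parts <- c(parts, sprintf("(%s)%s", sub, .fmt_bl(supports[k])))
      used <- c(used, clusters[[k]])
    }
    leaves <- setdiff(members, used)
    paste(c(parts, leaves), collapse = ",")
  }
  body <- nwk_of(setdiff(taxa, taxa[1]), seq_along(clusters))
  nwk <- sprintf("(%s,%s);", taxa[1], body)
  ape::read.tree(text = nwk)
}

#' Write / read trees in Newick format
#'
#' Thin wrappers over the ape Newick serializer; branch lengths and internal
#' node labels (used for consensus supports) round-trip.
#'
#' @param tree a `phylo` object.
#' @param path file path.
#' @return `read_newick` returns a `phylo`; `write_newick` returns the path
#'   invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("malformed Newick in ", path)
  tr
}
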