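# Shared fixtures and independent brute-force oracles used across tests.

# hand-build a genotype table from per-individual genotype lists:
# genos[[i]] is an L x 2 matrix (or vector pairs); NA for missing
make_table <- function(genos, loci = NULL, pops = NULL, datasets = NULL,
                       ids = NULL) {
  n <- length(genos)
  L <- nrow(genos[[1]])
  if (is.null(loci)) loci <- paste0("L", seq_len(L))
  if (is.null(ids)) ids <- paste0("i", seq_len(n))
  if (is.null(pops)) pops <- rep("A", n)
  if (is.null(datasets)) datasets <- rep("d1", n)
  a1 <- t(vapply(genos, function(g) g[, 1], numeric(L)))
  a2 <- t(vapply(genos, function(g) g[, 2], numeric(L)))
  if (L == 1L) { a1 <- matrix(a1, ncol = 1); a2 <- matrix(a2, ncol = 1) }
  genotype_table(ids, pops, datasets, loci, a1, a2)
}

g_mat <- function(...) {
  v <- c(...)
  matrix(v, ncol = 2, byrow = TRUE)
}

# hand-build an allele_freqs matrix from a named list locus -> named freq vec
freq_mat <- function(freq_list) {
  ladder <- sort(unique(as.integer(unlist(lapply(freq_list, names)))))
  f <- matrix(0, length(ladder), length(freq_list),
              dimnames = list(ladder, names(freq_list)))
  for (j in seq_along(freq_list)) {
    f[as.character(names(freq_list[[j]])), j] <- freq_list[[j]]
  }
  attr(f, "ladder") <- ladder
  class(f) <- c("allele_freqs", class(f))
  f
}

# multiset-intersection size of two unordered genotypes (oracle)
bf_shared <- function(g1, g2) {
  cnt <- 0
  pool <- g2
  for (a in g1) {
    hit <- match(a, pool)
    if (!is.na(hit)) { cnt <- cnt + 1; pool <- pool[-hit] }
  }
  cnt
}

# brute-force offset inference: enumerate every integer c over a padded span,
# same tie rule (smallest |c|, then negative)
bf_offset <- function(ref_pairs, inc_pairs, pad = 30) {
  usable <- !is.na(ref_pairs[, 1]) & !is.na(inc_pairs[, 1])
  rp <- ref_pairs[usable, , drop = FALSE]
  ip <- inc_pairs[usable, , drop = FALSE]
  span <- seq(min(rp) - max(ip) - pad, max(rp) - min(ip) + pad)
  g2 <- vapply(span, function(cc)
    mean(rp[, 1] == ip[, 1] + cc & rp[, 2] == ip[, 2] + cc), 0)
  best <- max(g2)
  cand <- span[g2 == best]
  cand <- cand[order(abs(cand), cand)]
  list(c_star = cand[1], g2 = best)
}

# exhaustive-enumeration likelihood of an unordered genotype pair given k and
# allele frequencies at one locus (oracle for .pair_probs algebra)
bf_pair_lik <- function(g1, g2, p, k) {
  av <- as.integer(names(p))
  key <- function(a, b) paste(min(a, b), max(a, b))
  k1g <- key(g1[1], g1[2]); k2g <- key(g2[1], g2[2])
  P0 <- 0; P1 <- 0; P2 <- 0
  for (a in av) for (b in av) for (c in av) for (d in av) {
    if (key(a, b) == k1g && key(c, d) == k2g) {
      P0 <- P0 + p[[as.character(a)]] * p[[as.character(b)]] *
        p[[as.character(c)]] * p[[as.character(d)]]
    }
  }
  for (s in av) for (u1 in av) for (u2 in av) {
    if (key(s, u1) == k1g && key(s, u2) == k2g) {
      P1 <- P1 + p[[as.character(s)]] * p[[as.character(u1)]] *
        p[[as.character(u2)]]
    }
  }
  for (s1 in av) for (s2 in av) {
    if (key(s1, s2) == k1g && key(s1, s2) == k2g) {
      P2 <- P2 + p[[as.character(s1)]] * p[[as.character(s2)]]
    }
  }
  k[1] * P0 + k[2] * P1 + k[3] * P2
}

# minimum vertex cover size by exhaustive enumeration (nodes <= ~15)
bf_min_cover_size <- function(edges, nodes) {
  if (!nrow(edges)) return(0L)
  n <- length(nodes)
  best <- n
  for (mask in 0:(2^n - 1)) {
    inset <- nodes[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    if (length(inset) >= best) next
    covered <- all(edges$id1 %in% inset | edges$id2 %in% inset)
    if (covered) best <- length(inset)
  }
  best
}

# +/- one-repeat-unit genotyping slips at rate eps, recanonicalized
apply_slips <- function(g, eps, motif = 2) {
  for (m in c("a1", "a2")) {
    x <- g[[m]]
    hit <- stats::runif(length(x)) < eps
    x[hit] <- x[hit] + sample(c(-motif, motif), sum(hit), replace = TRUE)
    g[[m]] <- x
  }
  lo <- pmin(g$a1, g$a2)
  g$a2 <- pmax(g$a1, g$a2)
  g$a1 <- lo
  g
}

# random additive tree over n taxa; returns the tree and its exact
# path-length distance matrix (oracle for neighbor joining)
random_additive_tree <- function(n) {
  tr <- ape::rtree(n, rooted = FALSE, br = function(k) stats::runif(k, 0.1, 2))
  d <- as.matrix(ape::cophenetic.phylo(tr))
  list(tree = tr, d = d[sort(rownames(d)), sort(rownames(d))])
}
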