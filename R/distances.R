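# Allele-sharing distances, classical MDS, and Procrustes comparison of
# genetic coordinates with geography.

#' Pairwise allele-sharing distance between individuals
#'
#' `d(i, j) = 1 - (shared alleles) / (2 * loci used)`, where allele sharing
#' at a locus is the multiset-intersection size of the two genotypes, and
#' only loci at which neither individual is missing enter the calculation.
#' Equivalently `d = 1 - (p1/2 + p2)` in terms of the IBS profile.
#'
#' @param table a `genotype_table` with at least two individuals.
#' @return symmetric matrix of class `asd_matrix` with zero diagonal, values
#'   in \[0, 1\], labelled by individual id; attribute `n_loci` holds the
#'   per-cell count of loci used. A pair with zero usable loci is an error.
#' @export
individual_distance_matrix <- function(table) {
  if (n_individuals(table) < 2L) stop("need at least two individuals")
  ibs <- .pairwise_ibs(table, table)
  use <- ibs$n_used
  zero <- which(use == 0L & row(use) != col(use), arr.ind = TRUE)
  if (nrow(zero)) {
    stop("pair with no shared non-missing loci: ",
         table$individual_ids[zero[1, 1]], " / ",
         table$individual_ids[zero[1, 2]])
  }
  d <- 1 - (ibs$n1 + 2 * ibs$n2) / (2 * use)
  diag(d) <- 0
  d <- (d + t(d)) / 2  # exact symmetry despite independent row computation
  attr(d, "n_loci") <- use
  class(d) <- c("asd_matrix", class(d))
  d
}

# Per-locus mean proportion of shared alleles over all cross-population
# individual pairs with non-missing genotypes; rows = unordered population
# pairs, columns = loci; NA where no usable pair exists. This matrix is the
# sufficient statistic for population distances and locus bootstraps.
.population_locus_sharing <- function(table) {
  pops <- unique(unname(table$population_ids))
  if (length(pops) < 2L) stop("need at least two populations")
  L <- n_loci(table)
  pairs <- utils::combn(pops, 2L)
  S <- matrix(NA_real_, ncol(pairs), L,
              dimnames = list(paste(pairs[1, ], pairs[2, ], sep = "|"),
                              table$locus_names))
  pop_of <- unname(table$population_ids)
  idx_of <- split(seq_len(n_individuals(table)), pop_of)
  for (k in seq_len(ncol(pairs))) {
    ta <- gt_subset(table, individuals = table$individual_ids[idx_of[[pairs[1, k]]]])
    tb <- gt_subset(table, individuals = table$individual_ids[idx_of[[pairs[2, k]]]])
    # locus-resolved sharing: mean over usable cross pairs of shared/2
    na <- n_individuals(ta); nb <- n_individuals(tb)
    shared_sum <- numeric(L); n_pairs <- numeric(L)
    for (i in seq_len(na)) {
      x1 <- ta$allele1[i, ]; x2 <- ta$allele2[i, ]
      both <- !is.na(x1)[col(tb$allele1)] & !is.na(tb$allele1)
      e2 <- both & tb$allele1 == rep(x1, each = nb) & tb$allele2 == rep(x2, each = nb)
      e1 <- both & !e2 &
        (tb$allele1 == rep(x1, each = nb) | tb$allele1 == rep(x2, each = nb) |
           tb$allele2 == rep(x1, each = nb) | tb$allele2 == rep(x2, each = nb))
      shared_sum <- shared_sum + colSums(e1) + 2 * colSums(e2)
      n_pairs <- n_pairs + colSums(both)
    }
    S[k, ] <- ifelse(n_pairs > 0, shared_sum / (2 * n_pairs), NA_real_)
  }
  attr(S, "populations") <- pops
  attr(S, "pairs") <- pairs
  S
}

#' Population-level allele-sharing distance matrix
#'
#' For each pair of populations and each locus, the mean proportion of
#' shared alleles over all cross-population individual pairs with
#' non-missing genotypes; the distance is one minus the mean of these
#' per-locus proportions over usable loci. Loci for which one or both
#' populations have no data are ignored for that pair.
#'
#' @param table a `genotype_table` with at least two populations.
#' @param locus_weights optional nonnegative per-locus resampling counts
#'   (used by the locus bootstrap); default all 1.
#' @return symmetric matrix of class `asd_matrix` labelled by population;
#'   attribute `n_loci` counts usable loci per pair.
#' @export
population_distance_matrix <- function(table, locus_weights = NULL) {
  S <- .population_locus_sharing(table)
  .pop_dist_from_sharing(S, locus_weights)
}

.pop_dist_from_sharing <- function(S, locus_weights = NULL) {
  pops <- attr(S, "populations")
  pairs <- attr(S, "pairs")
  if (is.null(locus_weights)) locus_weights <- rep(1, ncol(S))
  w <- locus_weights
  num <- as.vector(ifelse(is.na(S), 0, S) %*% w)
  den <- as.vector((!is.na(S)) %*% w)
  if (any(den == 0)) {
    bad <- which(den == 0)[1]
    stop("population pair with no usable loci: ", rownames(S)[bad])
  }
  mean_sharing <- num / den
  d <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  n_used <- d
  for (k in seq_along(mean_sharing)) {
    i <- pairs[1, k]; j <- pairs[2, k]
    d[i, j] <- d[j, i] <- 1 - mean_sharing[k]
    n_used[i, j] <- n_used[j, i] <- den[k]
  }
  attr(d, "n_loci") <- n_used
  class(d) <- c("asd_matrix", class(d))
  d
}

#' Classical metric multidimensional scaling
#'
#' Double-centers the squared-distance matrix, eigendecomposes it, and scales
#' the top eigenvectors by the square roots of their (positive) eigenvalues.
#' Negative eigenvalues are excluded from the coordinates but reported. The
#' returned coordinates are centered at the origin, and the variance of
#' dimension `j` equals `eigenvalue_j / n`.
#'
#' @param distance_matrix symmetric distance matrix with zero diagonal.
#' @param k requested number of dimensions (default 2); reduced with a
#'   warning if fewer positive eigenvalues exist.
#' @return list of class `mds_result`: `coordinates` (n x k, labelled) and
#'   `eigenvalues` (all n, descending).
#' @export
classical_mds <- function(distance_matrix, k = 2L) {
  d <- unclass(distance_matrix)
  attr(d, "n_loci") <- NULL
  n <- nrow(d)
  fit <- stats::cmdscale(stats::as.dist(d), k = min(k, n - 1L), eig = TRUE)
  n_pos <- sum(fit$eig > sqrt(.Machine$double.eps) * max(abs(fit$eig)))
  if (k > n_pos) {
    warning("requested k = ", k, " but only ", n_pos,
            " positive eigenvalues; returning k = ", n_pos)
    k <- n_pos
  }
  coords <- fit$points[, seq_len(k), drop = FALSE]
  rownames(coords) <- rownames(d)
  structure(list(coordinates = coords,
                 eigenvalues = sort(fit$eig, decreasing = TRUE)),
            class = "mds_result")
}

#' Gall-Peters equal-area projection
#'
#' Cylindrical equal-area projection with standard parallels at 45 degrees:
#' `x = R * lon_rad`, `y = 2 * R * sin(lat_rad)`. The Jacobian determinant is
#' constant over latitude, so equal areas on the sphere map to equal areas in
#' the plane.
#'
#' @param lat,lon latitude and longitude in degrees (vectors).
#' @param radius sphere radius (default 6371, in km).
#' @return two-column matrix `(x, y)`.
#' @export
gall_peters_project <- function(lat, lon, radius = 6371) {
  cbind(x = radius * lon * pi / 180, y = 2 * radius * sin(lat * pi / 180))
}

#' Procrustes similarity between two planar configurations
#'
#' Finds the translation, isotropic scaling and rotation of `config_b`
#' minimizing the sum of squared differences to `config_a`, and reports the
#' similarity statistic `t0 = sqrt(1 - minimized normalized residual)`
#' together with the rotation angle. `t0` is symmetric in the two
#' configurations and invariant to translation, rotation and uniform
#' rescaling of either one. Reflections are allowed by default (full
#' orthogonal group); set `allow_reflection = FALSE` to restrict to proper
#' rotations.
#'
#' @param config_a,config_b numeric matrices with equal row counts and two
#'   columns.
#' @param allow_reflection logical (default TRUE).
#' @return list of class `procrustes_result`: `t0`, `theta` (degrees, the
#'   rotation carrying `config_a` onto the orientation of `config_b`),
#'   `reflection` (whether the optimal transform reflects).
#' @export
procrustes_similarity <- function(config_a, config_b, allow_reflection = TRUE) {
  X <- as.matrix(config_a); Y <- as.matrix(config_b)
  if (nrow(X) != nrow(Y) || ncol(X) != 2L || ncol(Y) != 2L) {
    stop("configurations must have equal row counts and 2 columns")
  }
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  nx <- sum(Xc^2); ny <- sum(Yc^2)
  if (nx == 0 || ny == 0) stop("degenerate (zero-variance) configuration")
  sv <- svd(crossprod(Yc, Xc))  # t(Yc) %*% Xc
  signs <- rep(1, length(sv$d))
  refl <- det(sv$u %*% t(sv$v)) < 0
  if (!allow_reflection && refl) signs[length(signs)] <- -1
  tr <- sum(sv$d * signs)
  t0 <- max(0, tr) / sqrt(nx * ny)
  R <- sv$u %*% diag(signs) %*% t(sv$v)  # rotation applied to Xc to match Yc
  theta <- atan2(R[2, 1], R[1, 1]) * 180 / pi
  structure(list(t0 = t0, theta = theta,
                 reflection = allow_reflection && refl),
            class = "procrustes_result")
}

#' Procrustes permutation test of genetic versus geographic coordinates
#'
#' Individuals carry the geographic coordinate of their population. The
#' observed similarity `t0` between the MDS configuration and the (projected)
#' geographic configuration is compared with the distribution obtained by
#' permuting which geographic location is assigned to which population;
#' individuals of a population move as a block, preserving the within-
#' population structure of the genetic configuration. The p-value uses the
#' add-one estimator `p = (1 + #\{t_perm >= t0\}) / (1 + n_perm)`, so it is
#' never exactly zero.
#'
#' @param mds_coords n x 2 matrix of genetic coordinates (one row per
#'   individual).
#' @param geo_coords P x 2 matrix of projected geographic coordinates, rows
#'   named by population.
#' @param population_labels length-n character vector assigning each
#'   individual to a row of `geo_coords`.
#' @param n_perm number of permutations (must be >= 1).
#' @param allow_reflection passed to the Procrustes fit.
#' @return list of class `procrustes_result`: `t0`, `theta`, `p_value`,
#'   `n_permutations`.
#' @export
procrustes_permutation_test <- function(mds_coords, geo_coords,
                                        population_labels, n_perm = 10000L,
                                        allow_reflection = TRUE) {
  if (n_perm < 1L) stop("n_perm must be at least 1")
  G <- as.matrix(geo_coords)
  P <- nrow(G)
  if (P < 3L) stop("need at least 3 populations")
  pop_idx <- match(population_labels, rownames(G))
  if (anyNA(pop_idx)) {
    stop("population label without geographic coordinates: ",
         paste(unique(population_labels[is.na(pop_idx)]), collapse = ", "))
  }
  X <- as.matrix(mds_coords)
  Xc <- scale(X, scale = FALSE)
  nx <- sum(Xc^2)
  n <- nrow(X)
  npop <- tabulate(pop_idx, nbins = P)
  # block structure: t(Xc) %*% Y depends on Y only through per-population
  # sums of Xc, so each permutation costs O(P)
  Xsum <- rowsum(Xc, group = pop_idx)            # P x 2 (populations present)
  present <- sort(unique(pop_idx))
  Xsum_full <- matrix(0, P, 2)
  Xsum_full[present, ] <- Xsum[match(present, sort(unique(pop_idx))), ]

  t_for <- function(perm) {
    Gp <- G[perm, , drop = FALSE]        # location assigned to population p
    mu <- colSums(Gp * npop) / n
    # sum over individuals of Yc rows crossed with Xc rows
    M <- crossprod(Gp, Xsum_full) - tcrossprod(mu, colSums(Xsum_full))
    ny <- sum(npop * rowSums(Gp^2)) - n * sum(mu^2)
    sv <- svd(M)
    refl <- det(sv$u %*% t(sv$v)) < 0
    signs <- rep(1, 2)
    if (!allow_reflection && refl) signs[2] <- -1
    max(0, sum(sv$d * signs)) / sqrt(nx * ny)
  }
  obs <- procrustes_similarity(X, G[pop_idx, , drop = FALSE],
                               allow_reflection = allow_reflection)
  t_obs <- t_for(seq_len(P))
  t_perm <- vapply(seq_len(n_perm), function(b) t_for(sample.int(P)), 0)
  p <- (1 + sum(t_perm >= t_obs)) / (1 + n_perm)
  structure(list(t0 = t_obs, theta = obs$theta, p_value = p,
                 n_permutations = n_perm),
            class = "procrustes_result")
}

#' @export
print.procrustes_result <- function(x, ...) {
  cat(sprintf("Procrustes: t0 = %.4f, theta = %.2f deg", x$t0, x$theta))
  if (!is.null(x$p_value)) {
    cat(sprintf(", p = %.4g (%d permutations)", x$p_value, x$n_permutations))
  }
  cat("\n")
  invisible(x)
}

#' Region-balanced subsample of individuals
#'
#' Samples the same number of individuals (without replacement) from each
#' geographic region, ignoring population membership, so populations are not
#' guaranteed to be represented.
#'
#' @param table a `genotype_table`.
#' @param region_grouping named character vector mapping population to region.
#' @param n_per_region individuals sampled per region; regions with fewer
#'   individuals contribute all of theirs.
#' @return character vector of sampled individual ids.
#' @export
region_balanced_subsample <- function(table, region_grouping, n_per_region) {
  regions <- unname(region_grouping[unname(table$population_ids)])
  out <- character(0)
  for (reg in unique(regions)) {
    ids <- table$individual_ids[regions == reg]
    out <- c(out, if (length(ids) <= n_per_region) ids else
      sample(ids, n_per_region))
  }
  out
}

#' Write / read a distance matrix
#'
#' Two plain-text formats: `"phylip"` (square matrix: count line, then one
#' row per taxon with the label first) and `"tsv"` (labelled header row and
#' row names).
#'
#' @param d symmetric labelled distance matrix.
#' @param path file path.
#' @param format `"phylip"` or `"tsv"`.
#' @return `read_distance_matrix` returns the labelled matrix;
#'   `write_distance_matrix` returns the path invisibly.
#' @export
write_distance_matrix <- function(d, path, format = c("phylip", "tsv")) {
  format <- match.arg(format)
  m <- unclass(as.matrix(d))
  attr(m, "n_loci") <- NULL
  if (format == "phylip") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", nrow(m)), con)
    for (i in seq_len(nrow(m))) {
      writeLines(paste(c(sprintf("%-10s", rownames(m)[i]),
                         format(m[i, ], digits = 10)), collapse = "  "), con)
    }
  } else {
    utils::write.table(m, path, sep = "\t", quote = FALSE,
                       col.names = NA)
  }
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path, format = c("phylip", "tsv")) {
  format <- match.arg(format)
  if (format == "phylip") {
    lines <- readLines(path)
    n <- as.integer(trimws(lines[1]))
    rows <- strsplit(trimws(lines[1 + seq_len(n)]), "[ \t]+")
    labels <- vapply(rows, `[[`, "", 1)
    m <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(n)))
    dimnames(m) <- list(labels, labels)
  } else {
    m <- as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
    colnames(m) <- rownames(m)
  }
  if (nrow(m) != ncol(m)) stop("distance matrix is not square in ", path)
  m
}
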