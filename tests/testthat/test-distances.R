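test_that("individual allele-sharing distances follow the hand cases", {
  same <- make_table(list(g_mat(100, 102, 98, 98), g_mat(100, 102, 98, 98)))
  expect_equal(unname(individual_distance_matrix(same)["i1", "i2"]), 0)

  one <- make_table(list(g_mat(100, 102), g_mat(100, 100)))
  expect_equal(unname(individual_distance_matrix(one)["i1", "i2"]), 0.5)

  disjoint <- make_table(list(g_mat(100, 102), g_mat(104, 106)))
  expect_equal(unname(individual_distance_matrix(disjoint)["i1", "i2"]), 1)

  # a pair with no shared non-missing loci is an error naming the pair
  gap <- make_table(list(g_mat(100, 100, NA, NA), g_mat(NA, NA, 102, 102)))
  expect_error(individual_distance_matrix(gap),
               "no shared non-missing loci: i[12] / i[12]")
})

test_that("individual distances equal 1 - (p1/2 + p2) from the IBS profile", {
  set.seed(81)
  f <- random_allele_freqs(50)
  g <- simulate_genotypes(f, 6)
  tab <- genotype_table(paste0("i", 1:6), rep("A", 6), rep("d", 6),
                        colnames(f), g$a1, g$a2)
  d <- individual_distance_matrix(tab)
  for (pair in list(c(1, 2), c(2, 5), c(3, 6))) {
    p <- ibs_profile(tab, paste0("i", pair[1]), paste0("i", pair[2]))
    expect_equal(unname(d[pair[1], pair[2]]), 1 - (p$p1 / 2 + p$p2))
  }
})

test_that("population distances reduce to individual distances and match brute force", {
  # singleton populations
  tab <- make_table(list(g_mat(100, 102, 120, 120), g_mat(100, 100, 122, 124)),
                    pops = c("A", "B"))
  di <- individual_distance_matrix(tab)
  dp <- population_distance_matrix(tab)
  expect_equal(unname(dp["A", "B"]), unname(di[1, 2]))

  # identical populations have distance zero
  twin <- make_table(list(g_mat(100, 102), g_mat(100, 102)),
                     pops = c("A", "B"))
  expect_equal(unname(population_distance_matrix(twin)["A", "B"]), 0)

  # 2x2-individual toy against explicit enumeration of the 4 cross pairs
  set.seed(82)
  f <- random_allele_freqs(10, n_alleles = 4)
  g <- simulate_genotypes(f, 4)
  tab4 <- genotype_table(paste0("i", 1:4), c("A", "A", "B", "B"),
                         rep("d", 4), colnames(f), g$a1, g$a2)
  want <- 1 - mean(vapply(1:10, function(l) {
    mean(c(bf_shared(c(g$a1[1, l], g$a2[1, l]), c(g$a1[3, l], g$a2[3, l])),
           bf_shared(c(g$a1[1, l], g$a2[1, l]), c(g$a1[4, l], g$a2[4, l])),
           bf_shared(c(g$a1[2, l], g$a2[2, l]), c(g$a1[3, l], g$a2[3, l])),
           bf_shared(c(g$a1[2, l], g$a2[2, l]), c(g$a1[4, l], g$a2[4, l])))) / 2
  }, 0))
  expect_equal(unname(population_distance_matrix(tab4)["A", "B"]), want)
})

test_that("classical MDS reproduces collinear and Euclidean configurations", {
  dm <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3,
               dimnames = list(1:3, 1:3))
  m <- suppressWarnings(classical_mds(dm, 2))
  expect_equal(abs(as.vector(m$coordinates)), c(1, 0, 1))
  expect_equal(m$eigenvalues[1], 2)
  expect_equal(m$eigenvalues[2], 0, tolerance = 1e-12)

  # planar points are recovered up to rigid motion
  set.seed(83)
  X <- matrix(rnorm(40), 20, 2)
  D <- as.matrix(dist(X))
  rec <- classical_mds(D, 2)
  expect_equal(procrustes_similarity(X, rec$coordinates)$t0, 1,
               tolerance = 1e-9)
  # distances reproduced exactly for a Euclidean matrix
  expect_equal(as.matrix(dist(rec$coordinates)), D, tolerance = 1e-9,
               ignore_attr = TRUE)
  # coordinates centered; variance of dimension j = eigenvalue_j / n
  expect_equal(colMeans(rec$coordinates), c(0, 0), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(colSums(rec$coordinates^2), rec$eigenvalues[1:2],
               tolerance = 1e-9, ignore_attr = TRUE)

  # all-equal distances on 3 points: equilateral triangle, equal eigenvalues
  eq <- matrix(1, 3, 3) - diag(3)
  dimnames(eq) <- list(1:3, 1:3)
  meq <- classical_mds(eq, 2)
  expect_equal(meq$eigenvalues[1], meq$eigenvalues[2])
})

test_that("the Gall-Peters projection is equal-area", {
  expect_equal(unname(gall_peters_project(0, 0)), c(0, 0), ignore_attr = TRUE)
  expect_equal(unname(gall_peters_project(90, 0)[, "y"]), 2 * 6371)
  # constant Jacobian determinant over latitude (finite differences)
  h <- 1e-4
  jac <- function(lat) {
    dy <- (gall_peters_project(lat + h, 0)[, "y"] -
             gall_peters_project(lat - h, 0)[, "y"]) / (2 * h)
    dx <- (gall_peters_project(lat, h)[, "x"] -
             gall_peters_project(lat, -h)[, "x"]) / (2 * h)
    # area scale on the sphere at this latitude ~ cos(lat); planar cell
    # area / spherical cell area must not depend on latitude
    dx * dy / cos(lat * pi / 180)
  }
  vals <- vapply(c(-60, -30, 0, 30, 60), jac, 0)
  expect_lt(diff(range(vals)) / mean(vals), 1e-6)
})

test_that("Procrustes similarity recovers transforms and is invariant", {
  set.seed(84)
  X <- matrix(rnorm(30), 15, 2)
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  Y <- X %*% t(R) + 7
  fit <- procrustes_similarity(X, Y)
  expect_equal(fit$t0, 1, tolerance = 1e-12)
  expect_equal(fit$theta, 30, tolerance = 1e-9)
  # scale invariance and symmetry
  expect_equal(procrustes_similarity(X, Y * 13)$t0, fit$t0, tolerance = 1e-12)
  Z <- matrix(rnorm(30), 15, 2)
  expect_equal(procrustes_similarity(X, Z)$t0,
               procrustes_similarity(Z, X)$t0, tolerance = 1e-12)
  # independent noise gives low similarity for large n
  set.seed(85)
  A <- matrix(rnorm(1000), 500, 2)
  B <- matrix(rnorm(1000), 500, 2)
  expect_lt(procrustes_similarity(A, B)$t0, 0.2)
  expect_error(procrustes_similarity(X, matrix(1, 15, 2)), "degenerate")
})

test_that("the permutation test matches its preconditions and sharp cases", {
  set.seed(86)
  P <- 8; npp <- 3
  labs <- rep(paste0("p", 1:P), each = npp)
  G <- matrix(rnorm(P * 2), P, 2, dimnames = list(paste0("p", 1:P), NULL))
  X <- G[labs, ] + 0  # geographic truth replicated to individuals
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  res <- procrustes_permutation_test(X %*% R * 2 + 1, G, labs, n_perm = 199)
  expect_equal(res$t0, 1, tolerance = 1e-12)
  expect_equal(res$p_value, 1 / 200)  # smallest attainable with add-one

  expect_error(procrustes_permutation_test(X, G, labs, n_perm = 0), "n_perm")
  G2 <- G[1:2, , drop = FALSE]
  expect_error(procrustes_permutation_test(X[1:6, ], G2, labs[1:6]),
               "3 populations")
})

test_that("permutation-test t statistics agree with the direct Procrustes fit", {
  set.seed(87)
  P <- 6; npp <- 4
  labs <- rep(paste0("p", 1:P), each = npp)
  X <- matrix(rnorm(P * npp * 2), P * npp, 2)
  G <- matrix(rnorm(P * 2), P, 2, dimnames = list(paste0("p", 1:P), NULL))
  res <- procrustes_permutation_test(X, G, labs, n_perm = 9)
  expect_equal(res$t0, procrustes_similarity(X, G[labs, ])$t0,
               tolerance = 1e-12)
})

test_that("vegan agrees with the Procrustes residual on random configurations", {
  skip_if_not_installed("vegan")
  set.seed(88)
  X <- matrix(rnorm(24), 12, 2)
  Y <- matrix(rnorm(24), 12, 2)
  ours <- procrustes_similarity(X, Y)
  ref <- vegan::protest(X, Y, permutations = 2)
  expect_equal(ours$t0, sqrt(1 - ref$ss), tolerance = 1e-8)
})

test_that("region-balanced subsampling draws equally per region", {
  set.seed(89)
  f <- random_allele_freqs(5)
  g <- simulate_genotypes(f, 30)
  tab <- genotype_table(paste0("i", 1:30), rep(c("A", "B", "C"), each = 10),
                        rep("d", 30), colnames(f), g$a1, g$a2)
  regions <- c(A = "R1", B = "R1", C = "R2")
  ids <- region_balanced_subsample(tab, regions, 8)
  reg_of <- regions[unname(tab$population_ids[ids])]
  expect_equal(unname(table(reg_of)["R1"]), 8L)
  expect_equal(unname(table(reg_of)["R2"]), 8L)
})

test_that("distance matrices round-trip through PHYLIP and TSV formats", {
  set.seed(90)
  f <- random_allele_freqs(20)
  g <- simulate_genotypes(f, 6)
  tab <- genotype_table(paste0("ind", 1:6), rep(c("A", "B"), 3), rep("d", 6),
                        colnames(f), g$a1, g$a2)
  d <- individual_distance_matrix(tab)
  for (fmt in c("phylip", "tsv")) {
    path <- withr::local_tempfile()
    write_distance_matrix(d, path, fmt)
    back <- read_distance_matrix(path, fmt)
    expect_equal(rownames(back), tab$individual_ids)
    expect_equal(unname(back), unname(unclass(d)[seq_len(6), seq_len(6)]),
                 tolerance = 1e-9)
  }
})
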