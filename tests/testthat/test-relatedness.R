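test_that("allele frequencies are count estimates over non-missing copies", {
  tab <- make_table(list(g_mat(100, 102), g_mat(100, 100)))
  f <- allele_frequencies(tab)
  expect_equal(unname(f["100", "L1"]), 0.75)
  expect_equal(unname(f["102", "L1"]), 0.25)

  mono <- make_table(list(g_mat(100, 100), g_mat(100, 100)))
  fm <- allele_frequencies(mono)
  expect_equal(unname(fm["100", "L1"]), 1)

  set.seed(51)
  g <- simulate_genotypes(random_allele_freqs(15), 10)
  tab2 <- genotype_table(paste0("i", 1:10), rep("A", 10), rep("d", 10),
                         paste0("L", 1:15), g$a1, g$a2)
  f2 <- allele_frequencies(tab2)
  expect_equal(unname(colSums(f2)), rep(1, 15))
})

test_that("pair likelihoods match closed-form IBD-state algebra", {
  f <- freq_mat(list(L1 = c("100" = 0.5, "102" = 0.5)))
  tab <- make_table(list(g_mat(100, 100), g_mat(100, 100)), ids = c("a", "b"))
  expect_equal(exp(pair_likelihood(tab, "a", "b", f, "UN")), 0.0625)
  expect_equal(exp(pair_likelihood(tab, "a", "b", f, "PO")), 0.125)
  expect_equal(exp(pair_likelihood(tab, "a", "b", f, "FS")), 0.140625)
  # UN likelihood = product of individual HWE genotype probabilities
  expect_equal(exp(pair_likelihood(tab, "a", "b", f, "UN")), 0.25 * 0.25)
})

test_that("pair likelihoods match exhaustive enumeration for <= 4 alleles", {
  set.seed(52)
  for (rep in 1:25) {
    na <- sample(2:4, 1)
    alleles <- sort(sample(seq(90, 120, 2), na))
    p <- stats::setNames(as.numeric(rmultinom(1, 20, rep(1, na))) / 20, alleles)
    p <- p[p > 0]
    if (length(p) < 2) next
    av <- as.integer(names(p))
    g1 <- sort(sample(av, 2, replace = TRUE))
    g2 <- sort(sample(av, 2, replace = TRUE))
    f <- freq_mat(list(L1 = p))
    tab <- make_table(list(g_mat(g1[1], g1[2]), g_mat(g2[1], g2[2])),
                      ids = c("a", "b"))
    for (r in relationship_types()) {
      got <- exp(pair_likelihood(tab, "a", "b", f, r))
      want <- bf_pair_lik(g1, g2, p, ibd_coefficients(r))
      expect_equal(got, unname(want), tolerance = 1e-12, ignore_attr = TRUE)
    }
  }
})

test_that("identical genotypes maximize the MZ likelihood", {
  set.seed(53)
  F <- random_allele_freqs(30, n_alleles = 6)
  g <- simulate_genotypes(F, 1)
  tab <- genotype_table(c("a", "b"), c("A", "A"), c("d", "d"), colnames(F),
                        rbind(g$a1, g$a1), rbind(g$a2, g$a2))
  lls <- vapply(relationship_types(), function(r)
    pair_likelihood(tab, "a", "b", F, r), 0)
  expect_equal(names(which.max(lls)), "MZ")
})

test_that("classify_pair accepts simulated close relatives and rejects UN", {
  set.seed(54)
  F <- random_allele_freqs(200, n_alleles = 8)
  cfg <- relatedness_config(error_rate = 0, threshold = 100)
  for (type in c("MZ", "PO", "FS", "UN")) {
    b <- simulate_relative_pairs(F, type, 10)
    hits <- 0
    for (i in 1:10) {
      tab <- genotype_table(c("a", "b"), c("A", "A"), c("d", "d"), colnames(F),
                            rbind(b$g1$a1[i, ], b$g2$a1[i, ]),
                            rbind(b$g1$a2[i, ], b$g2$a2[i, ]))
      call <- classify_pair(tab, "a", "b", F, cfg)
      if (type == "UN") {
        hits <- hits + call$accepted
      } else {
        hits <- hits + (call$accepted && call$best == type)
      }
    }
    if (type == "UN") expect_equal(hits, 0) else expect_equal(hits, 10)
  }
})

test_that("intra-population screening finds injected pairs population-wise", {
  cfg <- synth_config(founder_chain = c("P1", "P2"), n_individuals = 20,
                      n_loci = 250, missing_rate = 0, error_rate = 0,
                      pedigree = data.frame(type = c("PO", "MZ"),
                                            population1 = c("P1", "P2"),
                                            population2 = c("P1", "P2"),
                                            n = 1),
                      seed = 55)
  sim <- simulate_panel(cfg)
  tab <- sim$tables$ds1
  calls <- screen_intra_population(tab)
  truth <- sim$truth$relationships
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  expect_setequal(key(calls$id1, calls$id2), key(truth$id1, truth$id2))
  expect_equal(sort(calls$type), c("MZ", "PO"))
  # excluded populations are skipped
  calls2 <- screen_intra_population(
    tab, relatedness_config(exclude_populations = "P2"))
  expect_false("MZ" %in% calls2$type)
})

test_that("inter-population screening tests only cross-population pairs", {
  cfg <- synth_config(founder_chain = c("P1", "P2", "P3"), n_individuals = 15,
                      n_loci = 250, missing_rate = 0, error_rate = 0,
                      pedigree = data.frame(
                        type = c("PO", "FS"),
                        population1 = c("P1", "P3"),
                        population2 = c("P2", "P3"), n = 1),
                      seed = 56)
  sim <- simulate_panel(cfg)
  tab <- sim$tables$ds1
  regions <- c(P1 = "R1", P2 = "R1", P3 = "R2")
  calls <- screen_inter_population(tab, regions)
  # the cross-population PO pair is found; the intra-population FS pair is
  # never tested here
  truth <- sim$truth$relationships
  inter <- truth[truth$scope == "inter", ]
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  expect_true(all(key(inter$id1, inter$id2) %in% key(calls$id1, calls$id2)))
  intra <- truth[truth$scope == "intra", ]
  expect_false(any(key(intra$id1, intra$id2) %in% key(calls$id1, calls$id2)))
  # a region with a single population contributes nothing
  expect_false(any(calls$group == "R2"))
})

test_that("trio detection requires two unrelated parents of a shared child", {
  calls <- data.frame(id1 = c("M", "F"), id2 = c("C", "C"),
                      type = c("PO", "PO"), stringsAsFactors = FALSE)
  trios <- find_trios(calls)
  expect_equal(nrow(trios), 1L)
  expect_equal(trios$offspring, "C")
  expect_setequal(c(trios$parent1, trios$parent2), c("M", "F"))

  # three-generation chain A-B PO, B-C PO: once screening has also called
  # the grandparent-grandchild pair A-C, B is not reported as an offspring
  chain <- data.frame(id1 = c("A", "B", "A"), id2 = c("B", "C", "C"),
                      type = c("PO", "PO", "SECOND_DEGREE"),
                      stringsAsFactors = FALSE)
  expect_equal(nrow(find_trios(chain)), 0L)

  # parents who are themselves related are not a trio
  rel <- rbind(calls, data.frame(id1 = "M", id2 = "F", type = "FS"))
  expect_equal(nrow(find_trios(rel)), 0L)
  expect_equal(nrow(find_trios(calls[0, ])), 0L)
})

test_that("standardized subsets obey the removal rules and nest", {
  # star: A in FS pairs with B, C, D -> removing A alone suffices
  i_m <- stats::setNames(rep(0.1, 5), c("A", "B", "C", "D", "E"))
  star <- data.frame(id1 = "A", id2 = c("B", "C", "D"), scope = "intra",
                     degree = "first", stringsAsFactors = FALSE)
  subs <- build_subsets(star, i_m)
  expect_setequal(subs$level2, c("B", "C", "D", "E"))
  expect_equal(subs$level1, names(i_m))  # first-degree only bites at level 2

  # single FS pair: the member with more missing data is removed
  pair <- data.frame(id1 = "A", id2 = "B", scope = "intra", degree = "first",
                     stringsAsFactors = FALSE)
  im2 <- c(A = 0.1, B = 0.2, C = 0)
  expect_setequal(build_subsets(pair, im2)$level2, c("A", "C"))

  # inter-population PO pair: both members absent from all three sets
  inter <- data.frame(id1 = "A", id2 = "B", scope = "inter", degree = "first",
                      stringsAsFactors = FALSE)
  s <- build_subsets(inter, im2)
  expect_setequal(s$level1, "C")
  expect_setequal(s$level3, "C")

  # inter-population second-degree pairs are never excluded
  inter2 <- data.frame(id1 = "A", id2 = "B", scope = "inter",
                       degree = "second", stringsAsFactors = FALSE)
  expect_setequal(build_subsets(inter2, im2)$level3, c("A", "B", "C"))
})

test_that("greedy removal matches brute-force minimal covers on small graphs", {
  set.seed(57)
  for (rep in 1:30) {
    n <- sample(6:12, 1)
    nodes <- paste0("n", seq_len(n))
    m <- sample(2:(n - 1), 1)
    e <- t(replicate(m, sort(sample(nodes, 2))))
    edges <- unique(data.frame(id1 = e[, 1], id2 = e[, 2],
                               scope = "intra", degree = "first",
                               stringsAsFactors = FALSE))
    i_m <- stats::setNames(runif(n, 0, 0.2), nodes)
    subs <- build_subsets(edges, i_m)
    # exclusion satisfied
    expect_false(any(edges$id1 %in% subs$level2 & edges$id2 %in% subs$level2))
    # nesting
    expect_true(all(subs$level3 %in% subs$level2))
    expect_true(all(subs$level2 %in% subs$level1))
    # minimality vs exhaustive search
    removed <- setdiff(nodes, subs$level2)
    expect_equal(length(removed), bf_min_cover_size(edges, nodes))
  }
})
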