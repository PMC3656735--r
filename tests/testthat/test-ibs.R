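test_that("ibs_profile follows multiset-intersection semantics", {
  # X = {(100,102), (100,100), MISSING}; Y = {(100,104), (102,102), (100,100)}
  tab <- make_table(list(g_mat(100, 102, 100, 100, NA, NA),
                         g_mat(100, 104, 102, 102, 100, 100)),
                    ids = c("X", "Y"))
  p <- ibs_profile(tab, "X", "Y")
  expect_equal(p$n_loci_used, 2L)
  expect_equal(p$p1, 0.5)  # locus 1 shares allele 100
  expect_equal(p$p0, 0.5)  # locus 2 shares none
  expect_equal(p$p2, 0)

  # (100,102) vs (100,100) shares exactly one allele
  one <- make_table(list(g_mat(100, 102), g_mat(100, 100)))
  expect_equal(ibs_profile(one, "i1", "i2")$p1, 1)

  # identical individuals
  same <- make_table(list(g_mat(100, 102, 98, 98), g_mat(100, 102, 98, 98)))
  q <- ibs_profile(same, "i1", "i2")
  expect_equal(q$p2, 1)
  expect_equal(q$p0 + q$p1, 0)
})

test_that("ibs_profile is symmetric and matches the multiset oracle", {
  set.seed(31)
  f <- random_allele_freqs(40, n_alleles = 5)
  g <- simulate_genotypes(f, 6)
  tab <- genotype_table(paste0("i", 1:6), rep("A", 6), rep("d", 6),
                        colnames(f), g$a1, g$a2)
  for (pair in list(c(1, 2), c(3, 5), c(4, 6))) {
    i <- paste0("i", pair[1]); j <- paste0("i", pair[2])
    pij <- ibs_profile(tab, i, j)
    pji <- ibs_profile(tab, j, i)
    expect_equal(pij$p2, pji$p2)
    expect_equal(pij$p1, pji$p1)
    # oracle: per-locus multiset intersections
    shared <- vapply(seq_len(40), function(l)
      bf_shared(c(g$a1[pair[1], l], g$a2[pair[1], l]),
                c(g$a1[pair[2], l], g$a2[pair[2], l])), 0)
    expect_equal(pij$p2, mean(shared == 2))
    expect_equal(pij$p1, mean(shared == 1))
  }
})

test_that("find_duplicates recovers self-pairs and reports the gap", {
  set.seed(32)
  f <- random_allele_freqs(60)
  g <- simulate_genotypes(f, 8)
  tab <- genotype_table(paste0("i", 1:8), rep("A", 8), rep("d", 8),
                        colnames(f), g$a1, g$a2)
  res <- find_duplicates(tab, tab, 0.83)
  self <- res[res$id_a == res$id_b, ]
  expect_equal(nrow(self), 8L)
  expect_true(all(self$p2 == 1))
  expect_true(is.na(attr(res, "gap_p2")) || attr(res, "gap_p2") <= 0.83)
  # results sorted by descending p2
  expect_true(all(diff(res$p2) <= 0))

  disjoint <- gt_subset(tab, loci = character(0))
  expect_error(find_duplicates(tab, disjoint), "no loci|share no loci")
})

test_that("infer_offset recovers a hand-built constant shift", {
  # reference alleles span 100..110; incoming = reference + 4 for 3 duplicate
  # pairs -> search range [a-B, A-b] = [-14, 6], c* = -4
  ref <- make_table(list(g_mat(100, 102), g_mat(104, 110), g_mat(100, 108)),
                    ids = c("r1", "r2", "r3"))
  inc <- make_table(list(g_mat(104, 106), g_mat(108, 114), g_mat(104, 112)),
                    ids = c("c1", "c2", "c3"))
  pairs <- data.frame(id_a = c("r1", "r2", "r3"), id_b = c("c1", "c2", "c3"))
  r <- suppressWarnings(infer_offset(ref, inc, pairs, "L1"))
  expect_equal(r$search_range, c(-14, 6))
  expect_equal(r$c_star, -4L)
  expect_equal(r$g2, 1)
  expect_equal(r$g12, 1)
  expect_equal(r$classification, "offset")

  # identical tables -> exact with c* = 0
  r0 <- suppressWarnings(
    infer_offset(ref, ref, data.frame(id_a = paste0("r", 1:3),
                                      id_b = paste0("r", 1:3)), "L1"))
  expect_equal(r0$c_star, 0L)
  expect_equal(r0$classification, "exact")
})

test_that("infer_offset matches brute-force enumeration on random instances", {
  set.seed(33)
  for (rep in 1:40) {
    np <- sample(2:5, 1)
    alleles <- sort(sample(seq(90, 120, by = 2), sample(3:8, 1)))
    rg <- matrix(sample(alleles, 2 * np, replace = TRUE), np, 2)
    rg <- cbind(pmin(rg[, 1], rg[, 2]), pmax(rg[, 1], rg[, 2]))
    true_off <- sample(-6:6, 1)
    ig <- rg + true_off
    # corrupt one pair sometimes
    if (runif(1) < 0.5) ig[1, ] <- sort(sample(alleles, 2, TRUE)) + true_off
    ref <- make_table(lapply(seq_len(np), function(i) g_mat(rg[i, 1], rg[i, 2])),
                      ids = paste0("r", seq_len(np)))
    inc <- make_table(lapply(seq_len(np), function(i) g_mat(ig[i, 1], ig[i, 2])),
                      ids = paste0("c", seq_len(np)))
    pairs <- data.frame(id_a = paste0("r", seq_len(np)),
                        id_b = paste0("c", seq_len(np)))
    got <- suppressWarnings(infer_offset(ref, inc, pairs, "L1"))
    want <- bf_offset(rg, ig)
    expect_equal(got$c_star, want$c_star)
    expect_equal(got$g2, want$g2)
    # applying c* and re-running yields c* = 0 at the same maximum
    inc2 <- inc
    inc2$allele1 <- inc2$allele1 + got$c_star
    inc2$allele2 <- inc2$allele2 + got$c_star
    again <- suppressWarnings(infer_offset(ref, inc2, pairs, "L1"))
    expect_equal(again$c_star, 0L)
    expect_equal(again$g2, got$g2)
  }
})

test_that("offset ties break toward the smallest magnitude, then negative", {
  # one heterozygous duplicate pair (100,104) vs (100,104): c = 0 gives a
  # 2-IBS match; no other constant can, so no tie. Force a tie with
  # non-overlapping genotypes: (100,100) vs (102,102) -> candidates -2 only.
  # A genuine tie: ref (100,100) & (104,104) vs inc (102,102) & (102,102):
  # c = -2 matches pair 1, c = +2 matches pair 2 -> tie at g2 = 0.5,
  # resolved to -2 (negative preferred at equal magnitude).
  ref <- make_table(list(g_mat(100, 100), g_mat(104, 104)), ids = c("r1", "r2"))
  inc <- make_table(list(g_mat(102, 102), g_mat(102, 102)), ids = c("c1", "c2"))
  r <- suppressWarnings(infer_offset(ref, inc,
                                     data.frame(id_a = c("r1", "r2"),
                                                id_b = c("c1", "c2")), "L1"))
  expect_equal(r$c_star, -2L)
  expect_true(r$tie)
})

test_that("allele-specific shifts are classified as mismatch", {
  set.seed(34)
  f <- random_allele_freqs(1, n_alleles = 6)
  g <- simulate_genotypes(f, 12)
  ref <- genotype_table(paste0("r", 1:12), rep("A", 12), rep("d", 12), "L1",
                        g$a1, g$a2)
  # shift only alleles above the median by +4: no single constant can align
  a1 <- g$a1; a2 <- g$a2
  med <- stats::median(c(a1, a2))
  a1[a1 > med] <- a1[a1 > med] + 4L
  a2[a2 > med] <- a2[a2 > med] + 4L
  inc <- genotype_table(paste0("c", 1:12), rep("A", 12), rep("d", 12), "L1",
                        pmin(a1, a2), pmax(a1, a2))
  pairs <- data.frame(id_a = paste0("r", 1:12), id_b = paste0("c", 1:12))
  r <- infer_offset(ref, inc, pairs, "L1")
  expect_equal(r$classification, "mismatch")
})

test_that("zero usable pairs yields a flagged mismatch with a warning", {
  ref <- make_table(list(g_mat(NA, NA)), ids = "r1")
  inc <- make_table(list(g_mat(100, 102)), ids = "c1")
  expect_warning(
    r <- infer_offset(ref, inc, data.frame(id_a = "r1", id_b = "c1"), "L1"),
    "usable duplicate pairs")
  expect_equal(r$classification, "mismatch")
  expect_equal(r$n_pairs_used, 0L)
})
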