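# Synthetic multi-data-set microsatellite panels with a full truth record.
#
# Population genotypes are simulated by forward drift of per-locus allele-
# frequency vectors on a bounded dinucleotide allele-length ladder with
# symmetric single-step mutation; a founder chain of successive bottlenecks
# produces a serial-founder heterozygosity gradient. Data-set artifacts
# (per-locus integer allele-size offsets, duplicate samples, pedigree
# relatives, genotyping error, missingness) are injected on top, and every
# injected artifact is recorded exactly once in the truth object.

#' Random allele-frequency matrix on a length ladder
#'
#' Each locus receives a Dirichlet(1) frequency vector over a window of
#' adjacent ladder states (window position random), giving realistic
#' unimodal-support microsatellite frequency spectra with roughly
#' `n_alleles` segregating alleles.
#'
#' @param n_loci number of loci.
#' @param n_alleles alleles per locus window (default 10).
#' @param allele_range smallest/largest allele length in nucleotides.
#' @param motif repeat-unit length in nucleotides (ladder step; default 2).
#' @return an `allele_freqs` matrix (ladder x loci) with attribute `ladder`.
#' @export
random_allele_freqs <- function(n_loci, n_alleles = 10,
                                allele_range = c(80, 140), motif = 2) {
  ladder <- seq(allele_range[1], allele_range[2], by = motif)
  ns <- length(ladder)
  w <- min(n_alleles, ns)
  f <- matrix(0, ns, n_loci, dimnames = list(ladder, paste0("L", seq_len(n_loci))))
  for (j in seq_len(n_loci)) {
    start <- sample.int(ns - w + 1L, 1L)
    g <- stats::rgamma(w, 1)
    f[start:(start + w - 1L), j] <- g / sum(g)
  }
  attr(f, "ladder") <- ladder
  class(f) <- c("allele_freqs", class(f))
  f
}

# one generation of symmetric single-step mutation as deterministic flow;
# attempts beyond the ladder edge stay put
.mutate_freqs <- function(f, mu) {
  if (mu == 0) return(f)
  ns <- nrow(f)
  up <- rbind(0, f[-ns, , drop = FALSE])
  down <- rbind(f[-1, , drop = FALSE], 0)
  out <- (1 - 2 * mu) * f + mu * up + mu * down
  # moves attempted beyond the ladder edges stay put (mass conservation)
  out[1, ] <- out[1, ] + mu * f[1, ]
  out[ns, ] <- out[ns, ] + mu * f[ns, ]
  out
}

# forward drift: multinomial resampling of 2N gene copies per generation
.drift_freqs <- function(f, n_diploid, generations, mu) {
  copies <- 2L * n_diploid
  for (g in seq_len(generations)) {
    f <- .mutate_freqs(f, mu)
    for (j in seq_len(ncol(f))) {
      f[, j] <- stats::rmultinom(1L, copies, f[, j]) / copies
    }
  }
  f
}

#' Draw diploid genotypes from allele frequencies under HWE
#'
#' @param freqs an `allele_freqs` matrix (ladder x loci).
#' @param n number of individuals.
#' @return list with integer matrices `a1`, `a2` (n x loci), canonicalized
#'   so `a1 <= a2`.
#' @export
simulate_genotypes <- function(freqs, n) {
  ladder <- attr(freqs, "ladder")
  L <- ncol(freqs)
  a1 <- matrix(0L, n, L); a2 <- matrix(0L, n, L)
  for (j in seq_len(L)) {
    v <- sample(ladder, 2L * n, replace = TRUE, prob = freqs[, j])
    a1[, j] <- v[seq_len(n)]
    a2[, j] <- v[n + seq_len(n)]
  }
  list(a1 = pmin(a1, a2), a2 = pmax(a1, a2))
}

.draw_one <- function(freqs) {
  g <- simulate_genotypes(freqs, 1L)
  list(a1 = g$a1[1, ], a2 = g$a2[1, ])
}

# Mendelian transmission, batched: one allele per locus per row chosen from
# the parent genotype matrices
.transmit_m <- function(parent) {
  pick <- stats::runif(length(parent$a1)) < 0.5
  out <- ifelse(pick, parent$a1, parent$a2)
  if (is.matrix(parent$a1)) dim(out) <- dim(parent$a1)
  out
}

.child_of <- function(p1, p2) {
  a <- .transmit_m(p1); b <- .transmit_m(p2)
  list(a1 = pmin(a, b), a2 = pmax(a, b))
}

#' Simulate relative pairs by Mendelian transmission
#'
#' Parents (and further ancestors as needed) are drawn from the supplied
#' allele frequencies under HWE; `n` independent pairs of the requested type
#' are returned. Second-degree types are simulated as their specific pedigree
#' (HS, GG, AV), although the classifier collapses them.
#'
#' @param freqs an `allele_freqs` matrix.
#' @param type one of `"MZ"`, `"PO"`, `"FS"`, `"HS"`, `"GG"`, `"AV"`, `"UN"`.
#' @param n number of pairs.
#' @return list with elements `g1` and `g2`, each `list(a1, a2)` of
#'   `n x loci` matrices (row `i` of `g1` and of `g2` form pair `i`).
#' @export
simulate_relative_pairs <- function(freqs, type, n) {
  d <- function() simulate_genotypes(freqs, n)
  switch(type,
    MZ = { g <- d(); list(g1 = g, g2 = g) },
    PO = { p <- d(); m <- d(); list(g1 = p, g2 = .child_of(p, m)) },
    FS = { p <- d(); m <- d(); list(g1 = .child_of(p, m), g2 = .child_of(p, m)) },
    HS = { s <- d(); o1 <- d(); o2 <- d()
           list(g1 = .child_of(s, o1), g2 = .child_of(s, o2)) },
    GG = { gp <- d(); gm <- d(); pm <- d()
           parent <- .child_of(gp, gm)
           list(g1 = gp, g2 = .child_of(parent, pm)) },
    AV = { p <- d(); m <- d(); mate <- d()
           s1 <- .child_of(p, m); s2 <- .child_of(p, m)
           list(g1 = s1, g2 = .child_of(s2, mate)) },
    UN = list(g1 = d(), g2 = d()),
    stop("unknown relationship type: ", type))
}

#' @rdname simulate_relative_pairs
#' @export
simulate_relative_pair <- function(freqs, type) {
  b <- simulate_relative_pairs(freqs, type, 1L)
  list(g1 = list(a1 = b$g1$a1[1, ], a2 = b$g1$a2[1, ]),
       g2 = list(a1 = b$g2$a1[1, ], a2 = b$g2$a2[1, ]))
}

.COLLAPSED <- c(MZ = "MZ", PO = "PO", FS = "FS", HS = "SECOND_DEGREE",
                GG = "SECOND_DEGREE", AV = "SECOND_DEGREE", UN = "UN")

#' Configuration for the synthetic panel generator
#'
#' Defaults describe the study conditions the pipeline is validated under:
#' 600 dinucleotide loci with about 10 alleles each, populations of 25 along
#' a founder chain of successive 10% bottlenecks, genotyping error 0.008
#' (one-repeat-unit slips), missing rate 0.03.
#'
#' @param founder_chain ordered character vector of population names along
#'   the expansion route.
#' @param n_individuals individuals per population (scalar or named vector).
#' @param n_loci number of loci.
#' @param allele_range,motif allele-length ladder (see
#'   [random_allele_freqs()]).
#' @param n_alleles target segregating alleles per locus.
#' @param effective_size diploid population size during drift epochs.
#' @param generations drift generations per epoch.
#' @param bottleneck_size diploid founder size at each chain step (default
#'   10% of `effective_size`).
#' @param mutation_rate symmetric single-step mutation probability per gene
#'   copy per generation.
#' @param datasets named list; each element
#'   `list(populations =, loci =, offsets =)` gives the populations
#'   genotyped by that source data set, its locus panel (`NULL` = all) and a
#'   named integer vector of per-locus allele-size offsets added to its
#'   calls. Every population must belong to exactly one data set. `NULL`
#'   puts all populations in one data set `"ds1"`.
#' @param duplicates data.frame with columns `from`, `to`, `n`: `n`
#'   individuals genotyped in data set `from` are re-genotyped (duplicate
#'   samples) in data set `to`.
#' @param pedigree data.frame with columns `type` (MZ/PO/FS/HS/GG/AV),
#'   `population1`, `population2`, `n`: `n` relative pairs whose first
#'   member is labelled `population1` and second `population2` (equal for
#'   intra-population pairs; for inter-population pairs the genotypes come
#'   from `population1`, emulating mislabelled samples).
#' @param trios data.frame with columns `population`, `n`:
#'   parent/parent/offspring trios (all three individuals included).
#' @param missing_rate per-genotype missingness probability.
#' @param error_rate per-allele probability of a one-repeat-unit (+/- motif)
#'   calling slip.
#' @param seed integer; fixed seed gives byte-identical output.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(founder_chain = paste0("P", 1:5),
                         n_individuals = 25L,
                         n_loci = 600L,
                         allele_range = c(80, 140), motif = 2L,
                         n_alleles = 10L,
                         effective_size = 500L,
                         generations = 30L,
                         bottleneck_size = max(2L, round(0.1 * effective_size)),
                         mutation_rate = 5e-4,
                         datasets = NULL,
                         duplicates = NULL,
                         pedigree = NULL,
                         trios = NULL,
                         missing_rate = 0.03,
                         error_rate = 0.008,
                         seed = 1L) {
  if (is.null(datasets)) {
    datasets <- list(ds1 = list(populations = founder_chain, loci = NULL,
                                offsets = NULL))
  }
  cfg <- structure(
    list(founder_chain = founder_chain, n_individuals = n_individuals,
         n_loci = as.integer(n_loci), allele_range = allele_range,
         motif = as.integer(motif), n_alleles = n_alleles,
         effective_size = as.integer(effective_size),
         generations = as.integer(generations),
         bottleneck_size = as.integer(bottleneck_size),
         mutation_rate = mutation_rate, datasets = datasets,
         duplicates = duplicates, pedigree = pedigree, trios = trios,
         missing_rate = missing_rate, error_rate = error_rate,
         seed = as.integer(seed)),
    class = "synth_config")
  .validate_synth_config(cfg)
  cfg
}

.validate_synth_config <- function(cfg) {
  stopifnot(cfg$missing_rate >= 0, cfg$missing_rate <= 1,
            cfg$error_rate >= 0, cfg$error_rate <= 1,
            cfg$mutation_rate >= 0, cfg$mutation_rate <= 1,
            length(cfg$founder_chain) >= 1, cfg$n_loci >= 1)
  ds_pops <- unlist(lapply(cfg$datasets, `[[`, "populations"))
  if (anyDuplicated(ds_pops)) {
    stop("each population must belong to exactly one data set")
  }
  if (!setequal(ds_pops, cfg$founder_chain)) {
    stop("data sets must cover exactly the founder-chain populations")
  }
  for (d in names(cfg$datasets)) {
    off <- cfg$datasets[[d]]$offsets
    if (!is.null(off) && any(off != round(off))) {
      stop("offsets must be integers (data set ", d, ")")
    }
  }
  if (!is.null(cfg$pedigree)) {
    bad <- setdiff(c(cfg$pedigree$population1, cfg$pedigree$population2),
                   cfg$founder_chain)
    if (length(bad)) stop("pedigree references unknown population(s): ",
                          paste(unique(bad), collapse = ", "))
    if (!all(cfg$pedigree$type %in% names(.COLLAPSED)[1:6])) {
      stop("pedigree types must be MZ/PO/FS/HS/GG/AV")
    }
  }
  if (!is.null(cfg$trios)) {
    bad <- setdiff(cfg$trios$population, cfg$founder_chain)
    if (length(bad)) stop("trios reference unknown population(s): ",
                          paste(unique(bad), collapse = ", "))
  }
  if (!is.null(cfg$duplicates)) {
    bad <- setdiff(c(cfg$duplicates$from, cfg$duplicates$to),
                   names(cfg$datasets))
    if (length(bad)) stop("duplicates reference unknown data set(s): ",
                          paste(unique(bad), collapse = ", "))
  }
  invisible(cfg)
}

#' Simulate a multi-data-set microsatellite panel with known truth
#'
#' Runs the founder-chain frequency simulation, draws base individuals and
#' pedigree relatives, splits individuals into source data sets, injects
#' duplicate samples, per-locus allele-size offsets, genotyping error and
#' missingness, and records every injected artifact.
#'
#' @param config a [synth_config()].
#' @return list with `tables` (named list of `genotype_table`, one per data
#'   set) and `truth` (class `synth_truth`): `offsets` (per data set, named
#'   full-length vectors), `duplicates`, `relationships` (with exact and
#'   collapsed types), `trios`, `het_true` (per-population expected
#'   heterozygosity of the generating frequencies), `pop_coords`
#'   (populations placed along a great-circle route), `freqs` (generating
#'   frequency matrices), and `clean_merged` (the artifact-free target of a
#'   full merge: all data sets concatenated over their shared loci, offsets
#'   removed, duplicate copies dropped).
#' @export
simulate_panel <- function(config) {
  .validate_synth_config(config)
  set.seed(config$seed)
  chain <- config$founder_chain
  npop <- length(chain)
  nind <- config$n_individuals
  if (length(nind) == 1L) nind <- stats::setNames(rep(nind, npop), chain)

  anc <- random_allele_freqs(config$n_loci, config$n_alleles,
                             config$allele_range, config$motif)
  loci <- colnames(anc)
  freqs <- vector("list", npop)
  names(freqs) <- chain
  f <- .drift_freqs(anc, config$effective_size, config$generations,
                    config$mutation_rate)
  freqs[[chain[1]]] <- f
  for (k in seq_len(npop - 1L)) {
    f <- .drift_freqs(f, config$bottleneck_size, 1L, config$mutation_rate)
    f <- .drift_freqs(f, config$effective_size, config$generations,
                      config$mutation_rate)
    freqs[[chain[k + 1L]]] <- f
  }

  ids <- character(0); pops <- character(0)
  A1 <- NULL; A2 <- NULL
  add_ind <- function(id, pop, g) {
    ids <<- c(ids, id); pops <<- c(pops, pop)
    A1 <<- rbind(A1, g$a1); A2 <<- rbind(A2, g$a2)
  }
  for (p in chain) {
    g <- simulate_genotypes(freqs[[p]], nind[[p]])
    for (i in seq_len(nind[[p]])) {
      add_ind(sprintf("%s_i%03d", p, i), p,
              list(a1 = g$a1[i, ], a2 = g$a2[i, ]))
    }
  }

  relationships <- list()
  if (!is.null(config$pedigree)) {
    for (r in seq_len(nrow(config$pedigree))) {
      type <- config$pedigree$type[r]
      p1 <- config$pedigree$population1[r]
      p2 <- config$pedigree$population2[r]
      for (k in seq_len(config$pedigree$n[r])) {
        pair <- simulate_relative_pair(freqs[[p1]], type)
        id1 <- sprintf("%s_%s%02d_%s_a", p1, type, k, p2)
        id2 <- sprintf("%s_%s%02d_%s_b", p1, type, k, p2)
        add_ind(id1, p1, pair$g1)
        add_ind(id2, p2, pair$g2)
        relationships[[length(relationships) + 1L]] <-
          data.frame(id1 = id1, id2 = id2, type = type,
                     class = unname(.COLLAPSED[type]),
                     population1 = p1, population2 = p2,
                     scope = if (p1 == p2) "intra" else "inter",
                     stringsAsFactors = FALSE)
      }
    }
  }
  trios_truth <- list()
  if (!is.null(config$trios)) {
    for (r in seq_len(nrow(config$trios))) {
      p <- config$trios$population[r]
      for (k in seq_len(config$trios$n[r])) {
        fa <- .draw_one(freqs[[p]]); mo <- .draw_one(freqs[[p]])
        ch <- .child_of(fa, mo)
        idf <- sprintf("%s_trio%02d_f", p, k)
        idm <- sprintf("%s_trio%02d_m", p, k)
        idc <- sprintf("%s_trio%02d_c", p, k)
        add_ind(idf, p, fa); add_ind(idm, p, mo); add_ind(idc, p, ch)
        relationships[[length(relationships) + 1L]] <-
          data.frame(id1 = idf, id2 = idc, type = "PO", class = "PO",
                     population1 = p, population2 = p, scope = "intra",
                     stringsAsFactors = FALSE)
        relationships[[length(relationships) + 1L]] <-
          data.frame(id1 = idm, id2 = idc, type = "PO", class = "PO",
                     population1 = p, population2 = p, scope = "intra",
                     stringsAsFactors = FALSE)
        trios_truth[[length(trios_truth) + 1L]] <-
          data.frame(parent1 = idf, parent2 = idm, offspring = idc,
                     population = p, stringsAsFactors = FALSE)
      }
    }
  }
  relationships <- if (length(relationships)) do.call(rbind, relationships) else
    data.frame(id1 = character(0), id2 = character(0), type = character(0),
               class = character(0), population1 = character(0),
               population2 = character(0), scope = character(0),
               stringsAsFactors = FALSE)
  trios_truth <- if (length(trios_truth)) do.call(rbind, trios_truth) else
    data.frame(parent1 = character(0), parent2 = character(0),
               offspring = character(0), population = character(0),
               stringsAsFactors = FALSE)
  dimnames(A1) <- dimnames(A2) <- list(ids, loci)

  pop_of_dataset <- lapply(config$datasets, `[[`, "populations")
  ds_members <- lapply(pop_of_dataset, function(pp) ids[pops %in% pp])

  dup_truth <- list()
  if (!is.null(config$duplicates)) {
    for (r in seq_len(nrow(config$duplicates))) {
      from <- config$duplicates$from[r]; to <- config$duplicates$to[r]
      n <- config$duplicates$n[r]
      pool <- ds_members[[from]]
      if (n > length(pool)) stop("not enough individuals in data set ", from,
                                 " for ", n, " duplicates")
      chosen <- sample(pool, n)
      dup_truth[[r]] <- data.frame(
        id_ref = chosen, dataset_ref = from,
        id_dup = paste0(chosen, "@", to), dataset_dup = to,
        stringsAsFactors = FALSE)
    }
  }
  dup_truth <- if (length(dup_truth)) do.call(rbind, dup_truth) else
    data.frame(id_ref = character(0), dataset_ref = character(0),
               id_dup = character(0), dataset_dup = character(0),
               stringsAsFactors = FALSE)

  perturb <- function(a1, a2) {
    # genotyping error: each allele call slips +/- one repeat unit with
    # probability error_rate; then per-genotype missingness
    if (config$error_rate > 0) {
      for (m in c("a1", "a2")) {
        x <- get(m)
        hit <- matrix(stats::runif(length(x)) < config$error_rate, nrow(x))
        shift <- matrix(sample(c(-config$motif, config$motif), length(x),
                               replace = TRUE), nrow(x))
        x[hit] <- x[hit] + shift[hit]
        assign(m, x)
      }
      lo <- pmin(a1, a2); a2 <- pmax(a1, a2); a1 <- lo
    }
    if (config$missing_rate > 0) {
      gone <- matrix(stats::runif(length(a1)) < config$missing_rate, nrow(a1))
      a1[gone] <- NA_integer_; a2[gone] <- NA_integer_
    }
    list(a1 = a1, a2 = a2)
  }

  tables <- list()
  clean_tables <- list()
  offsets_truth <- list()
  for (d in names(config$datasets)) {
    panel <- config$datasets[[d]]$loci
    if (is.null(panel)) panel <- loci
    if (is.numeric(panel)) panel <- loci[panel]
    members <- ds_members[[d]]
    dup_in <- dup_truth[dup_truth$dataset_dup == d, , drop = FALSE]
    row_ids <- c(members, dup_in$id_dup)
    src_rows <- c(members, dup_in$id_ref)
    a1 <- A1[src_rows, panel, drop = FALSE]
    a2 <- A2[src_rows, panel, drop = FALSE]
    rownames(a1) <- rownames(a2) <- row_ids
    obs <- perturb(a1, a2)

    off <- stats::setNames(integer(length(panel)), panel)
    user_off <- config$datasets[[d]]$offsets
    if (!is.null(user_off)) {
      unknown <- setdiff(names(user_off), panel)
      if (length(unknown)) stop("offset for locus outside panel of ", d, ": ",
                                paste(unknown, collapse = ", "))
      off[names(user_off)] <- as.integer(user_off)
    }
    offsets_truth[[d]] <- off

    shifted1 <- sweep(obs$a1, 2L, off, `+`)
    shifted2 <- sweep(obs$a2, 2L, off, `+`)
    pop_labels <- c(pops[match(members, ids)],
                    pops[match(dup_in$id_ref, ids)])
    tables[[d]] <- genotype_table(row_ids, pop_labels, rep(d, length(row_ids)),
                                  panel, shifted1, shifted2)
    clean_tables[[d]] <- genotype_table(row_ids, pop_labels,
                                        rep(d, length(row_ids)),
                                        panel, obs$a1, obs$a2)
  }

  shared <- Reduce(intersect, lapply(tables, function(t) t$locus_names))
  clean_merged <- NULL
  for (d in names(clean_tables)) {
    part <- gt_subset(clean_tables[[d]], loci = shared)
    keep <- setdiff(part$individual_ids,
                    dup_truth$id_dup[dup_truth$dataset_dup == d])
    part <- gt_subset(part, individuals = keep)
    clean_merged <- if (is.null(clean_merged)) part else
      gt_rbind(clean_merged, part)
  }

  het_true <- vapply(freqs, function(f) mean(1 - colSums(f^2)), 0)
  pop_coords <- data.frame(population = chain,
                           latitude = rep(0, npop),
                           longitude = 10 + 15 * (seq_len(npop) - 1L),
                           stringsAsFactors = FALSE)

  truth <- structure(
    list(offsets = offsets_truth, duplicates = dup_truth,
         relationships = relationships, trios = trios_truth,
         het_true = het_true, pop_coords = pop_coords, freqs = freqs,
         clean_merged = clean_merged, config = config),
    class = "synth_truth")
  list(tables = tables, truth = truth)
}
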