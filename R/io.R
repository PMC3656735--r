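#' Read a genotype table from disk
#'
#' Two plain-text dialects are supported:
#' \describe{
#'   \item{`"long"`}{tab-separated with header
#'     `individual  population  dataset  locus  allele1  allele2`,
#'     one row per genotype.}
#'   \item{`"structure"`}{STRUCTURE-style: a header line of locus names, then
#'     two rows per individual, each row `id population dataset` followed by
#'     one allele per locus (whitespace-separated).}
#' }
#' The missing-data sentinel (default `-9`) is mapped to `NA`; both alleles
#' of a genotype must be missing together.
#'
#' @param path file to read.
#' @param dialect `"long"` or `"structure"`.
#' @param missing integer sentinel encoding missing alleles.
#' @return a [genotype_table()].
#' @export
read_genotype_table <- function(path, dialect = c("long", "structure"),
                                missing = -9L) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(dialect,
         long = .read_gt_long(path, missing),
         structure = .read_gt_structure(path, missing))
}

.read_gt_long <- function(path, missing) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("individual", "population", "dataset", "locus", "allele1", "allele2")
  if (!all(need %in% names(df))) {
    stop("long dialect requires columns: ", paste(need, collapse = ", "))
  }
  ids <- unique(df$individual)
  loci <- unique(df$locus)
  key_dup <- duplicated(df[c("individual", "locus")])
  if (any(key_dup)) {
    stop("duplicate (individual, locus) row at line ",
         which(key_dup)[1] + 1L, " of ", path)
  }
  a1 <- matrix(NA_integer_, length(ids), length(loci), dimnames = list(ids, loci))
  a2 <- a1
  idx <- cbind(match(df$individual, ids), match(df$locus, loci))
  a1[idx] <- as.integer(df$allele1)
  a2[idx] <- as.integer(df$allele2)
  a1[a1 == missing] <- NA_integer_
  a2[a2 == missing] <- NA_integer_
  meta <- df[!duplicated(df$individual), c("individual", "population", "dataset")]
  conflicting <- vapply(split(df$population, df$individual),
                        function(p) length(unique(p)) > 1L, logical(1))
  if (any(conflicting)) {
    stop("conflicting population labels for individual(s): ",
         paste(names(conflicting)[conflicting], collapse = ", "))
  }
  meta <- meta[match(ids, meta$individual), ]
  genotype_table(ids, meta$population, meta$dataset, loci, a1, a2)
}

.read_gt_structure <- function(path, missing) {
  lines <- readLines(path)
  if (length(lines) < 1L) stop("empty file: ", path)
  loci <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) %% 2L != 0L) {
    stop("STRUCTURE dialect requires two rows per individual; got ",
         length(body), " data rows in ", path)
  }
  nl <- length(loci)
  parse_row <- function(line, lineno) {
    fields <- strsplit(trimws(line), "[ \t]+")[[1]]
    if (length(fields) != nl + 3L) {
      stop("line ", lineno, " of ", path, ": expected ", nl + 3L,
           " fields (id, population, dataset, ", nl, " alleles), got ",
           length(fields))
    }
    alleles <- suppressWarnings(as.integer(fields[-(1:3)]))
    if (anyNA(alleles)) {
      stop("line ", lineno, " of ", path, ": non-integer allele value")
    }
    list(id = fields[1], pop = fields[2], ds = fields[3], alleles = alleles)
  }
  n <- length(body) / 2L
  ids <- character(n); pops <- character(n); dss <- character(n)
  a1 <- matrix(NA_integer_, n, nl)
  a2 <- matrix(NA_integer_, n, nl)
  for (i in seq_len(n)) {
    r1 <- parse_row(body[2L * i - 1L], 2L * i)
    r2 <- parse_row(body[2L * i], 2L * i + 1L)
    if (r1$id != r2$id) {
      stop("line ", 2L * i + 1L, " of ", path, ": the two rows of individual '",
           r1$id, "' disagree in id ('", r2$id, "')")
    }
    if (r1$pop != r2$pop || r1$ds != r2$ds) {
      stop("line ", 2L * i + 1L, " of ", path, ": the two rows of individual '",
           r1$id, "' disagree in population or dataset label")
    }
    ids[i] <- r1$id; pops[i] <- r1$pop; dss[i] <- r1$ds
    a1[i, ] <- r1$alleles
    a2[i, ] <- r2$alleles
  }
  a1[a1 == missing] <- NA_integer_
  a2[a2 == missing] <- NA_integer_
  # a genotype with exactly one sentinel allele is malformed, not half-called
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) {
    bad <- which(rowSums(half) > 0)[1]
    stop("individual '", ids[bad], "' in ", path,
         " has a genotype with exactly one missing allele")
  }
  genotype_table(ids, pops, dss, loci, a1, a2)
}

#' Write a genotype table to disk
#'
#' Inverse of [read_genotype_table()]; a written file parses back to a table
#' equal to the original in both dialects. Missing genotypes are emitted as
#' the sentinel in both allele slots.
#'
#' @param table a `genotype_table`.
#' @param path file to write.
#' @param dialect `"long"` or `"structure"`.
#' @param missing integer sentinel for missing alleles.
#' @export
write_genotype_table <- function(table, path, dialect = c("long", "structure"),
                                 missing = -9L) {
  dialect <- match.arg(dialect)
  if (dialect == "long") {
    a1 <- table$allele1; a2 <- table$allele2
    a1[is.na(a1)] <- missing
    a2[is.na(a2)] <- missing
    n <- n_individuals(table); l <- n_loci(table)
    df <- data.frame(
      individual = rep(table$individual_ids, times = l),
      population = rep(unname(table$population_ids), times = l),
      dataset = rep(unname(table$dataset_tags), times = l),
      locus = rep(table$locus_names, each = n),
      allele1 = as.vector(a1),
      allele2 = as.vector(a2),
      stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(table$locus_names, collapse = "\t"), con)
    a1 <- table$allele1; a2 <- table$allele2
    a1[is.na(a1)] <- missing
    a2[is.na(a2)] <- missing
    for (i in seq_len(n_individuals(table))) {
      prefix <- paste(table$individual_ids[i], table$population_ids[i],
                      table$dataset_tags[i], sep = "\t")
      writeLines(c(paste(c(prefix, a1[i, ]), collapse = "\t"),
                   paste(c(prefix, a2[i, ]), collapse = "\t")), con)
    }
  }
  invisible(path)
}

#' Read population metadata
#'
#' CSV with columns `population_id, name, region, latitude, longitude`.
#' Latitude/longitude are decimal degrees and may be empty (unknown sampling
#' location). Latitude must lie in \[-90, 90\] and longitude in (-180, 180\].
#'
#' @param path CSV file.
#' @return data.frame of class `population_info`.
#' @export
read_population_info <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("population_id", "name", "region", "latitude", "longitude")
  if (!all(need %in% names(df))) {
    stop("population info requires columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$population_id)) stop("duplicate population_id entries")
  ok_lat <- is.na(df$latitude) | (df$latitude >= -90 & df$latitude <= 90)
  ok_lon <- is.na(df$longitude) | (df$longitude > -180 & df$longitude <= 180)
  if (!all(ok_lat)) stop("latitude out of [-90, 90] for: ",
                         paste(df$population_id[!ok_lat], collapse = ", "))
  if (!all(ok_lon)) stop("longitude out of (-180, 180] for: ",
                         paste(df$population_id[!ok_lon], collapse = ", "))
  class(df) <- c("population_info", "data.frame")
  df
}
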