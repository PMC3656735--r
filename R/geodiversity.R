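# Expected heterozygosity (with correction for close relatives),
# waypoint-routed great-circle distances, and the diversity-distance
# regression used to examine serial-founder gradients.

#' Expected heterozygosity of a population
#'
#' Per-locus gene diversity with a finite-sample correction, optionally
#' adjusted for known close relatives. With `n` individuals non-missing at a
#' locus (2n gene copies) and count-estimated frequencies `p_hat`, the
#' uncorrected estimator is `2n/(2n-1) * (1 - sum(p_hat^2))`. When relative
#' pairs are supplied and `corrected = TRUE`, the factor becomes
#' `4n^2 / (4n^2 - 2n - S)` with `S = 8 * sum(theta)` over pairs in which
#' both members are non-missing at the locus, `theta` being the kinship
#' coefficient implied by the called relationship. This makes the estimator
#' unbiased under the kinship structure and reduces exactly to the
#' uncorrected form when no relatives are supplied. Loci at which every
#' individual is missing are omitted and recorded.
#'
#' @param table a `genotype_table`.
#' @param population population id whose individuals are used.
#' @param relative_pairs optional data.frame with columns `id1`, `id2`,
#'   `type` (a class from [relationship_types()]); pairs with members outside
#'   the population are ignored.
#' @param corrected apply the relative correction (default TRUE when pairs
#'   are supplied).
#' @return list of class `het_estimate`: `population`, `per_locus` (named),
#'   `mean` (over non-omitted loci), `n_individuals`, `corrected`,
#'   `loci_omitted`.
#' @export
expected_heterozygosity <- function(table, population, relative_pairs = NULL,
                                    corrected = !is.null(relative_pairs)) {
  ids <- table$individual_ids[unname(table$population_ids) == population]
  if (!length(ids)) stop("unknown or empty population: ", population)
  sub <- gt_subset(table, individuals = ids)
  a1 <- sub$allele1; a2 <- sub$allele2
  L <- n_loci(sub)

  pairs <- NULL
  if (corrected && !is.null(relative_pairs) && nrow(relative_pairs)) {
    keep <- relative_pairs$id1 %in% ids & relative_pairs$id2 %in% ids
    pairs <- relative_pairs[keep, , drop = FALSE]
    if (nrow(pairs)) {
      pairs$theta <- vapply(pairs$type, kinship_coefficient, 0)
      pairs$i <- match(pairs$id1, ids)
      pairs$j <- match(pairs$id2, ids)
    } else pairs <- NULL
  }

  per_locus <- rep(NA_real_, L)
  names(per_locus) <- sub$locus_names
  for (l in seq_len(L)) {
    obs <- !is.na(a1[, l])
    n <- sum(obs)
    if (n == 0L) next
    v <- c(a1[obs, l], a2[obs, l])
    p <- as.numeric(table(v)) / length(v)
    J <- sum(p^2)
    S <- 0
    if (!is.null(pairs)) {
      both <- obs[pairs$i] & obs[pairs$j]
      S <- 8 * sum(pairs$theta[both])
    }
    denom <- 4 * n^2 - 2 * n - S
    if (denom <= 0) {
      stop("relative correction degenerate at locus ", sub$locus_names[l],
           " (too few individuals for the supplied kinship)")
    }
    per_locus[l] <- 4 * n^2 / denom * (1 - J)
  }
  omitted <- names(per_locus)[is.na(per_locus)]
  if (length(omitted) == L) {
    stop("population ", population, ": all loci have only missing data")
  }
  structure(list(population = population,
                 per_locus = per_locus[!is.na(per_locus)],
                 mean = mean(per_locus, na.rm = TRUE),
                 n_individuals = length(ids),
                 corrected = corrected && !is.null(pairs),
                 loci_omitted = omitted),
            class = "het_estimate")
}

#' Great-circle distance along a waypoint route
#'
#' Sum of haversine great-circle leg lengths from the origin through the
#' waypoints (in order) to the destination, on a sphere of the given radius.
#' Inserting a waypoint already lying on the geodesic between its neighbours
#' leaves the distance unchanged.
#'
#' @param origin,destination numeric `c(lat, lon)` in degrees.
#' @param waypoints optional list of `c(lat, lon)` points, or a 2-column
#'   matrix (lat, lon rows in route order).
#' @param radius_km sphere radius in km (default 6371).
#' @return distance in km.
#' @export
waypoint_distance <- function(origin, destination, waypoints = NULL,
                              radius_km = 6371) {
  wp <- if (is.null(waypoints)) NULL else do.call(rbind, as.list(waypoints))
  route <- rbind(origin, wp, destination)
  lonlat <- route[, c(2, 1), drop = FALSE]
  if (nrow(route) < 2L) stop("route needs at least origin and destination")
  legs <- geosphere::distHaversine(lonlat[-nrow(lonlat), , drop = FALSE],
                                   lonlat[-1, , drop = FALSE], r = radius_km)
  sum(legs)
}

#' Default waypoint routing rules
#'
#' Encodes overland-migration routing from an East African origin
#' (Addis Ababa, 9N 38E): Sub-Saharan African populations (and the named
#' North-East African exceptions) are reached directly; European populations
#' (except the named exceptions) via Cairo then Istanbul; Oceanian
#' populations via Cairo then Phnom Penh; Native American populations via
#' Cairo, Anadyr and Prince Rupert; every other population via Cairo.
#' Waypoint city coordinates are standard values; the whole table is an
#' editable configuration, not a constant.
#'
#' @return list of class `routing_rules` with `origin`, `waypoints` (named
#'   list of `c(lat, lon)`), `region_chains` (region -> waypoint names) and
#'   `population_overrides` (population -> waypoint names).
#' @export
default_routing_rules <- function() {
  structure(list(
    origin = c(lat = 9, lon = 38),
    waypoints = list(
      cairo = c(lat = 30.06, lon = 31.25),
      istanbul = c(lat = 41.01, lon = 28.96),
      phnom_penh = c(lat = 11.55, lon = 104.92),
      anadyr = c(lat = 64.73, lon = 177.51),
      prince_rupert = c(lat = 54.32, lon = -130.32)),
    region_chains = list(
      "Sub-Saharan Africa" = character(0),
      "Africa" = "cairo",
      "Middle East" = "cairo",
      "Europe" = c("cairo", "istanbul"),
      "Central/South Asia" = "cairo",
      "East Asia" = "cairo",
      "Oceania" = c("cairo", "phnom_penh"),
      "Americas" = c("cairo", "anadyr", "prince_rupert")),
    default_chain = "cairo",
    population_overrides = list(
      Beja = character(0), Mozabite = character(0),
      Adygei = "cairo", Russian = "cairo")),
    class = "routing_rules")
}

#' Assign a waypoint route to each population
#'
#' Applies the routing rule table (per-population overrides first, then the
#' region chain, then the default chain) to build the ordered route from the
#' origin through waypoints to each population's location. Populations
#' without coordinates are excluded and reported.
#'
#' @param population_info data.frame with columns `population_id`, `region`,
#'   `latitude`, `longitude` (see [read_population_info()]).
#' @param rules a `routing_rules` list (default [default_routing_rules()]).
#' @return list with `routes` (named list of route matrices, lat/lon rows)
#'   and `excluded` (population ids without coordinates).
#' @export
assign_route <- function(population_info, rules = default_routing_rules()) {
  routes <- list()
  excluded <- character(0)
  for (r in seq_len(nrow(population_info))) {
    pop <- population_info$population_id[r]
    lat <- population_info$latitude[r]; lon <- population_info$longitude[r]
    if (is.na(lat) || is.na(lon)) {
      excluded <- c(excluded, pop)
      next
    }
    chain <- rules$population_overrides[[pop]]
    if (is.null(chain)) chain <- rules$region_chains[[population_info$region[r]]]
    if (is.null(chain)) chain <- rules$default_chain
    wps <- rules$waypoints[chain]
    route <- rbind(rules$origin,
                   if (length(wps)) do.call(rbind, wps),
                   c(lat = lat, lon = lon))
    rownames(route) <- c("origin", names(wps), pop)
    routes[[pop]] <- route
  }
  if (length(excluded)) {
    message("populations without coordinates excluded from routing: ",
            paste(excluded, collapse = ", "))
  }
  list(routes = routes, excluded = excluded)
}

#' Route length of an assigned route
#'
#' @param route a route matrix from [assign_route()] (lat/lon rows in order).
#' @param radius_km sphere radius in km.
#' @return distance in km.
#' @export
route_distance <- function(route, radius_km = 6371) {
  n <- nrow(route)
  waypoint_distance(route[1, ], route[n, ],
                    if (n > 2L) lapply(seq(2, n - 1L), function(i) route[i, ]),
                    radius_km = radius_km)
}

#' Regression of expected heterozygosity on geographic distance
#'
#' Ordinary least squares of mean expected heterozygosity on waypoint-routed
#' distance from the origin, over populations meeting a minimum sample size.
#' Under a serial founder history the slope is negative and the fit strong.
#'
#' @param het_estimates numeric vector of mean expected heterozygosities,
#'   one per population.
#' @param distances numeric vector of distances (km), aligned with
#'   `het_estimates`.
#' @param sample_sizes integer vector of population sample sizes, aligned.
#' @param min_sample_size populations below this size are excluded
#'   (default 5).
#' @return list of class `regression_fit`: `slope`, `intercept`, `r_squared`,
#'   `n_populations`, and the underlying `lm` fit.
#' @export
heterozygosity_distance_regression <- function(het_estimates, distances,
                                               sample_sizes = NULL,
                                               min_sample_size = 5L) {
  if (length(het_estimates) != length(distances)) {
    stop("het_estimates and distances must be aligned")
  }
  keep <- if (is.null(sample_sizes)) rep(TRUE, length(distances)) else
    sample_sizes >= min_sample_size
  h <- het_estimates[keep]; d <- distances[keep]
  if (sum(keep) < 3L) stop("fewer than 3 populations after filtering")
  fit <- stats::lm(h ~ d)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = summary(fit)$r.squared,
                 n_populations = sum(keep),
                 fit = fit),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("heterozygosity ~ distance: slope = %.3g per km, R^2 = %.3f (%d populations)\n",
              x$slope, x$r_squared, x$n_populations))
  invisible(x)
}
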