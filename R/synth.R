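# Seeded synthetic hospitalization records with the spatial-interaction
# structure the analysis assumes: a gravity model with exponential distance
# decay, Poisson journey counts, and a pseudo-random stream keyed per
# (seed, year, origin, destination) pair so that enlarging the scenario never
# perturbs existing draws.

# deterministic 31-bit hash of the pair key; every intermediate stays well
# below 2^53 so the arithmetic is exact in doubles
.pair_seed <- function(seed, year, origin, dest) {
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (v in c(year, as.numeric(origin), as.numeric(dest))) {
    h <- (h * 69069 + as.numeric(v)) %% m
    h <- (h * 69069 + 1) %% m
  }
  as.integer(h)
}

# run expr under a private RNG stream; the caller's RNG state is untouched
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Define a synthetic patient-flow scenario
#'
#' The defaults emulate a Bahia-like state: ~50 municipalities in a
#' state-sized bounding box, a handful of high-complexity provider
#' municipalities (the largest ones, as regionalized care concentrates
#' services in hubs), log-normal populations, a 13-year series, and a
#' distance-decay scale of 250 km. Expected journeys between origin O and
#' provider D follow a gravity model,
#' `lambda_OD = theta * pop_O * cap_D * exp(-d_OD / decay_km)`,
#' and `theta` is by default calibrated analytically so the expected total
#' record count over all years is `target_total` (about 1e4).
#'
#' @param n_municipalities Number of municipalities.
#' @param bbox Named numeric `c(lat_min, lat_max, lon_min, lon_max)` in
#'   decimal degrees; must have positive area.
#' @param n_providers Number of provider municipalities (largest populations).
#' @param years Integer vector of competence years.
#' @param procedure_codes Character vector of procedure codes to sample.
#' @param procedure_weights Sampling weights, recycled to `procedure_codes`.
#' @param theta Global rate scale; `NULL` (default) calibrates it to
#'   `target_total`.
#' @param target_total Expected total record count used when `theta` is `NULL`.
#' @param decay_km Distance-decay scale in km (> 0); larger means weaker decay.
#' @param seed Integer seed; the scenario and everything generated from it
#'   are deterministic given the seed.
#' @return A `synthetic_scenario`.
#' @export
synthetic_scenario <- function(n_municipalities = 50L,
                               bbox = c(lat_min = -18.3, lat_max = -8.5,
                                        lon_min = -46.6, lon_max = -37.3),
                               n_providers = 5L,
                               years = 2008:2020,
                               procedure_codes = c("0406010013", "0406010030", "0406011045"),
                               procedure_weights = c(0.5, 0.3, 0.2),
                               theta = NULL,
                               target_total = 10000,
                               decay_km = 250,
                               seed = 1L) {
  stopifnot(n_municipalities >= 2L, n_providers >= 1L,
            n_providers <= n_municipalities, length(years) >= 1L,
            decay_km > 0, is.null(theta) || theta >= 0)
  bbox <- bbox[c("lat_min", "lat_max", "lon_min", "lon_max")]
  if (anyNA(bbox) || bbox["lat_max"] <= bbox["lat_min"] ||
      bbox["lon_max"] <= bbox["lon_min"])
    stop("synthetic_scenario: bounding box must be named and have positive area")
  seed <- as.integer(seed)
  codes <- sprintf("29%04d", seq_len(n_municipalities))
  # Bahia-like municipality populations: median ~2e4, heavy right tail
  pops <- .with_seed(.pair_seed(seed, 0, 1, 1),
                     exp(rnorm(n_municipalities, mean = log(20000), sd = 1)))
  providers <- codes[order(-pops)][seq_len(n_providers)]
  caps <- setNames(pops[match(providers, codes)] / sum(pops), providers)
  structure(list(
    n_municipalities = as.integer(n_municipalities), bbox = bbox,
    codes = codes, populations = setNames(pops, codes),
    provider_codes = providers, capacities = caps,
    years = as.integer(years),
    procedure_codes = as.character(procedure_codes),
    procedure_weights = rep_len(procedure_weights, length(procedure_codes)),
    theta = theta, target_total = target_total,
    decay_km = decay_km, seed = seed
  ), class = "synthetic_scenario")
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat(sprintf("<synthetic_scenario> %d municipalities (%d providers), years %d-%d, decay %g km, seed %d\n",
              x$n_municipalities, length(x$provider_codes),
              min(x$years), max(x$years), x$decay_km, x$seed))
  invisible(x)
}

#' Generate the registry of a synthetic scenario
#'
#' Municipality coordinates are uniform in the bounding box; macroregion
#' labels are assigned by spatial quadrant around the box midpoint.
#' Deterministic given the scenario seed.
#'
#' @param s A `synthetic_scenario`.
#' @return A `municipality_registry`.
#' @export
generate_registry <- function(s) {
  stopifnot(inherits(s, "synthetic_scenario"))
  n <- s$n_municipalities
  xy <- .with_seed(.pair_seed(s$seed, 0, 2, 2), {
    list(lat = runif(n, s$bbox["lat_min"], s$bbox["lat_max"]),
         lon = runif(n, s$bbox["lon_min"], s$bbox["lon_max"]))
  })
  mid_lat <- mean(s$bbox[c("lat_min", "lat_max")])
  mid_lon <- mean(s$bbox[c("lon_min", "lon_max")])
  quadrant <- ifelse(xy$lat >= mid_lat,
                     ifelse(xy$lon >= mid_lon, "Northeast", "Northwest"),
                     ifelse(xy$lon >= mid_lon, "Southeast", "Southwest"))
  reg <- data.table::data.table(
    code = s$codes,
    name = sprintf("Municipality %s", s$codes),
    lat = xy$lat, lon = xy$lon,
    macroregion = quadrant
  )
  data.table::setkeyv(reg, "code")
  data.table::setattr(reg, "class", c("municipality_registry", class(reg)))
  reg
}

#' Expected gravity-model flows of a scenario
#'
#' The analytic Poisson means `lambda_OD` per (year, origin, provider) pair
#' with origin != destination, using great-circle distances between registry
#' coordinates. Useful as an oracle: monotone non-decreasing in `decay_km`,
#' and the expected outgoing flow of an origin is the row sum.
#'
#' @param s A `synthetic_scenario`.
#' @param registry Registry generated from `s`.
#' @return `data.table` with `origin, dest, distance_km, lambda` (per year).
#' @export
expected_flows <- function(s, registry) {
  stopifnot(inherits(s, "synthetic_scenario"))
  pairs <- data.table::CJ(origin = s$codes, dest = s$provider_codes)
  pairs <- pairs[pairs$origin != pairs$dest]
  oi <- match(pairs$origin, registry$code)
  di <- match(pairs$dest, registry$code)
  d <- haversine_km(registry$lat[oi], registry$lon[oi],
                    registry$lat[di], registry$lon[di])
  base <- s$populations[pairs$origin] * s$capacities[pairs$dest] *
    exp(-d / s$decay_km)
  theta <- s$theta
  if (is.null(theta)) {
    # calibrate so that the expected grand total across all years is target_total
    theta <- s$target_total / (length(s$years) * sum(base))
  }
  pairs[, `:=`(distance_km = d, lambda = theta * base)]
  pairs[]
}

#' Generate synthetic hospitalization records
#'
#' For each year and each origin-provider pair the journey count is Poisson
#' with the gravity-model mean (see [expected_flows()]); each journey becomes
#' one record with a month uniform in 1..12 and a procedure code sampled by
#' weight. Draws come from a private stream keyed by
#' `(seed, year, origin, dest)`, so runs are reproducible record-for-record
#' and adding municipalities or years never changes existing pairs' draws.
#'
#' @param s A `synthetic_scenario`.
#' @param registry Registry generated from `s` (or a compatible one).
#' @return A records `data.table` (`year, month, origin_code, dest_code,
#'   procedure_code`) sorted by year, origin, destination.
#' @export
generate_records <- function(s, registry) {
  stopifnot(inherits(s, "synthetic_scenario"))
  lam <- expected_flows(s, registry)
  out <- vector("list", length(s$years))
  for (k in seq_along(s$years)) {
    yr <- s$years[k]
    chunks <- vector("list", nrow(lam))
    for (i in seq_len(nrow(lam))) {
      o <- lam$origin[i]; d <- lam$dest[i]; lambda <- lam$lambda[i]
      if (lambda <= 0) next
      chunks[[i]] <- .with_seed(.pair_seed(s$seed, yr, o, d), {
        n <- rpois(1L, lambda)
        if (n == 0L) NULL else data.table::data.table(
          year = yr,
          month = sample.int(12L, n, replace = TRUE),
          origin_code = o, dest_code = d,
          procedure_code = sample(s$procedure_codes, n, replace = TRUE,
                                  prob = s$procedure_weights)
        )
      })
    }
    out[[k]] <- data.table::rbindlist(chunks)
  }
  rec <- data.table::rbindlist(out)
  if (nrow(rec) == 0L)
    return(data.table::data.table(year = integer(), month = integer(),
                                  origin_code = character(),
                                  dest_code = character(),
                                  procedure_code = character()))
  data.table::setorderv(rec, c("year", "origin_code", "dest_code"))
  rec[]
}
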