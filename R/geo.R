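# Coordinate handling: geographic (decimal degrees) -> UTM, and straight-line
# distances in km. No external geodesy dependency; the transverse Mercator
# forward projection is the standard series expansion (sub-mm within a zone).

.ELLIPSOIDS <- list(
  WGS84      = c(a = 6378137.0,  f = 1 / 298.257223563),
  GRS80      = c(a = 6378137.0,  f = 1 / 298.257222101),
  clarke1866 = c(a = 6378206.4,  f = 1 - 6356583.8 / 6378206.4)
)

#' UTM zone number of a longitude
#'
#' @param lon Longitude in decimal degrees.
#' @return Integer zone in 1..60.
#' @export
utm_zone <- function(lon) {
  stopifnot(all(lon >= -180 & lon <= 180))
  z <- floor((lon + 180) / 6) + 1L
  as.integer(pmin(z, 60L))
}

#' Project geographic coordinates to UTM
#'
#' Forward transverse Mercator projection with standard UTM parameters
#' (scale factor 0.9996, false easting 500 000 m, false northing 10 000 000 m
#' in the southern hemisphere). A `forced_zone` projects the point into that
#' zone's central meridian even when the point lies outside it, which is what
#' a planar Euclidean distance across a zone boundary requires.
#'
#' @param lat,lon Numeric vectors of decimal degrees; `abs(lat)` must be < 84
#'   (standard UTM applicability band).
#' @param forced_zone Optional integer zone 1..60; default is each point's
#'   natural zone.
#' @param ellipsoid One of `"WGS84"`, `"GRS80"`, `"clarke1866"`.
#' @return A `data.frame` with columns `easting`, `northing` (meters),
#'   `zone` (integer) and `hemisphere` (`"N"`/`"S"`).
#' @examples
#' latlon_to_utm(0, -51)  # on the zone 22 central meridian: E = 500000, N = 0
#' @export
latlon_to_utm <- function(lat, lon, forced_zone = NULL, ellipsoid = "WGS84") {
  stopifnot(length(lat) == length(lon))
  if (any(!is.finite(lat)) || any(!is.finite(lon)))
    stop("latlon_to_utm: non-finite coordinates")
  if (any(lat < -90 | lat > 90) || any(lon < -180 | lon > 180))
    stop("latlon_to_utm: coordinates out of range")
  if (any(abs(lat) >= 84))
    stop("latlon_to_utm: |lat| >= 84 is outside the UTM applicability band")
  ell <- .ELLIPSOIDS[[match.arg(ellipsoid, names(.ELLIPSOIDS))]]
  a <- ell[["a"]]; f <- ell[["f"]]
  e2 <- f * (2 - f)
  ep2 <- e2 / (1 - e2)
  k0 <- 0.9996

  zone <- if (is.null(forced_zone)) utm_zone(lon) else {
    stopifnot(length(forced_zone) == 1L, forced_zone >= 1, forced_zone <= 60)
    rep(as.integer(forced_zone), length(lon))
  }
  lon0 <- (zone - 1) * 6 - 180 + 3  # central meridian, degrees

  phi <- lat * pi / 180
  dlam <- (lon - lon0) * pi / 180

  sinp <- sin(phi); cosp <- cos(phi); tanp <- tan(phi)
  N <- a / sqrt(1 - e2 * sinp^2)
  T <- tanp^2
  C <- ep2 * cosp^2
  A <- cosp * dlam
  # meridian arc length from the equator
  M <- a * ((1 - e2 / 4 - 3 * e2^2 / 64 - 5 * e2^3 / 256) * phi -
            (3 * e2 / 8 + 3 * e2^2 / 32 + 45 * e2^3 / 1024) * sin(2 * phi) +
            (15 * e2^2 / 256 + 45 * e2^3 / 1024) * sin(4 * phi) -
            (35 * e2^3 / 3072) * sin(6 * phi))

  easting <- k0 * N * (A + (1 - T + C) * A^3 / 6 +
                       (5 - 18 * T + T^2 + 72 * C - 58 * ep2) * A^5 / 120) + 500000
  northing <- k0 * (M + N * tanp * (A^2 / 2 +
                    (5 - T + 9 * C + 4 * C^2) * A^4 / 24 +
                    (61 - 58 * T + T^2 + 600 * C - 330 * ep2) * A^6 / 720))
  south <- lat < 0
  northing[south] <- northing[south] + 10000000

  # a forced zone intentionally leaves the within-zone band; only the
  # natural-zone projection should look suspicious there
  out_of_band <- is.null(forced_zone) & (easting < 100000 | easting > 900000)
  if (any(out_of_band))
    warning(sprintf("latlon_to_utm: %d point(s) outside the within-zone easting sanity band",
                    sum(out_of_band)))
  data.frame(easting = easting, northing = northing, zone = zone,
             hemisphere = ifelse(south, "S", "N"))
}

#' Great-circle (haversine) distance in kilometers
#'
#' Uses the mean Earth radius 6371.0088 km.
#'
#' @param lat1,lon1,lat2,lon2 Decimal degrees (vectorized).
#' @return Kilometers.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  R <- 6371.0088
  torad <- pi / 180
  dlat <- (lat2 - lat1) * torad
  dlon <- (lon2 - lon1) * torad
  h <- sin(dlat / 2)^2 + cos(lat1 * torad) * cos(lat2 * torad) * sin(dlon / 2)^2
  2 * R * asin(pmin(1, sqrt(h)))
}

.muni_row <- function(registry, code) {
  code <- normalize_muni_code(code)
  i <- match(code, registry$code)
  if (is.na(i)) stop(sprintf("municipality '%s' not found in registry", code))
  registry[i, ]
}

.has_utm <- function(row) {
  all(c("easting", "northing", "utm_zone") %in% names(row)) &&
    !is.na(row$easting) && !is.na(row$northing) && !is.na(row$utm_zone)
}

#' Straight-line distance between two municipalities
#'
#' `method = "utm"` (the default) is the Euclidean norm of the UTM
#' easting/northing differences divided by 1000. Registry-supplied UTM
#' coordinates are used when both municipalities carry them; otherwise both
#' points are projected into the UTM zone of `a` (a single planar frame is
#' required for a meaningful Euclidean distance -- Bahia spans zones 23S/24S).
#' `method = "great_circle"` is the zone-free haversine distance; at state
#' scale the two agree to well under 0.5%.
#'
#' @param a,b Municipality codes (or single registry rows).
#' @param registry A registry as returned by [read_registry()].
#' @param method `"utm"` or `"great_circle"`.
#' @return Non-negative distance in kilometers (symmetric in `a`, `b`).
#' @export
distance_km <- function(a, b, registry, method = c("utm", "great_circle")) {
  method <- match.arg(method)
  ra <- if (is.character(a) || is.numeric(a)) .muni_row(registry, a) else a
  rb <- if (is.character(b) || is.numeric(b)) .muni_row(registry, b) else b
  for (r in list(ra, rb))
    if (is.na(r$lat) || is.na(r$lon))
      stop(sprintf("municipality '%s' has missing coordinates", r$code))
  if (method == "great_circle")
    return(haversine_km(ra$lat, ra$lon, rb$lat, rb$lon))
  if (.has_utm(ra) && .has_utm(rb) && identical(ra$utm_zone, rb$utm_zone)) {
    de <- ra$easting - rb$easting
    dn <- ra$northing - rb$northing
  } else {
    z <- utm_zone(ra$lon)
    pa <- latlon_to_utm(ra$lat, ra$lon, forced_zone = z)
    pb <- latlon_to_utm(rb$lat, rb$lon, forced_zone = z)
    de <- pa$easting - pb$easting
    dn <- pa$northing - pb$northing
  }
  sqrt(de^2 + dn^2) / 1000
}
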