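# Yearly origin-destination matrices and directed weighted flow networks.

#' Build the origin-destination matrix of one competence year
#'
#' Rows are municipalities of residence (origin), columns municipalities of
#' occurrence (destination); each cell counts that year's records, so the
#' matrix total equals the year's record count. Records should already be
#' procedure-filtered.
#'
#' @param records A records `data.table`.
#' @param year Competence year.
#' @return An `od_matrix`: list with `year`, `counts` (integer matrix with
#'   origin/destination codes as dimnames) and `total`.
#' @export
build_od_matrix <- function(records, year) {
  yr <- as.integer(year)
  sub <- records[records$year == yr]
  if (nrow(sub) == 0L) {
    m <- matrix(integer(), 0L, 0L, dimnames = list(character(), character()))
    return(structure(list(year = yr, counts = m, total = 0L), class = "od_matrix"))
  }
  rows <- sort(unique(sub$origin_code))
  cols <- sort(unique(sub$dest_code))
  m <- matrix(0L, length(rows), length(cols), dimnames = list(rows, cols))
  tab <- sub[, .N, by = .(origin_code, dest_code)]
  m[cbind(match(tab$origin_code, rows), match(tab$dest_code, cols))] <- tab$N
  structure(list(year = yr, counts = m, total = sum(m)), class = "od_matrix")
}

#' @export
print.od_matrix <- function(x, ...) {
  cat(sprintf("<od_matrix> year %d: %d origin(s) x %d destination(s), total %d journey(s)\n",
              x$year, nrow(x$counts), ncol(x$counts), x$total))
  invisible(x)
}

#' Write / read an OD matrix as CSV (origins as rows, destinations as columns)
#' @param m An `od_matrix`.
#' @param path CSV path; first column `origin` holds the row codes.
#' @export
write_od_matrix <- function(m, path) {
  dt <- data.table::as.data.table(m$counts, keep.rownames = "origin")
  if (nrow(m$counts) == 0L) dt <- data.table::data.table(origin = character())
  data.table::fwrite(dt, path)
  invisible(path)
}

#' @rdname write_od_matrix
#' @param year Competence year to stamp on the matrix read back.
#' @export
read_od_matrix <- function(path, year) {
  dt <- data.table::fread(path, colClasses = list(character = "origin"))
  if (nrow(dt) == 0L) {
    m <- matrix(integer(), 0L, 0L, dimnames = list(character(), character()))
    return(structure(list(year = as.integer(year), counts = m, total = 0L),
                     class = "od_matrix"))
  }
  cm <- as.matrix(dt[, -1L, with = FALSE])
  storage.mode(cm) <- "integer"
  rownames(cm) <- dt$origin
  structure(list(year = as.integer(year), counts = cm, total = sum(cm)),
            class = "od_matrix")
}

#' Convert an OD matrix to a directed weighted flow network
#'
#' One edge per nonzero cell, with the journey count as weight and the
#' straight-line distance attached. With `intermunicipal_only = TRUE` (the
#' default, matching the intermunicipal scope of the indices) diagonal cells
#' are dropped. Codes not resolvable in the registry -- e.g. out-of-state
#' residents -- are excluded with a warning; the excluded codes and journey
#' counts are kept in the network's `unresolved` field. Municipalities with
#' no incident edge in the year are omitted from the vertex set.
#'
#' @param m An `od_matrix`.
#' @param registry A `municipality_registry`.
#' @param intermunicipal_only Drop self-loops? Default `TRUE`.
#' @param distance_method `"utm"` or `"great_circle"` (see [distance_km()]).
#' @return A `flow_network`: list with `year`, `vertices` (registry rows of
#'   active municipalities), `edges` (`data.table` of
#'   `origin,dest,weight,distance_km`), `intermunicipal_only`, `unresolved`.
#' @export
matrix_to_network <- function(m, registry, intermunicipal_only = TRUE,
                              distance_method = c("utm", "great_circle")) {
  distance_method <- match.arg(distance_method)
  stopifnot(inherits(m, "od_matrix"))
  cm <- m$counts
  idx <- which(cm > 0L, arr.ind = TRUE)
  edges <- data.table::data.table(
    origin = rownames(cm)[idx[, 1L]],
    dest = colnames(cm)[idx[, 2L]],
    weight = cm[idx]
  )
  if (intermunicipal_only) edges <- edges[edges$origin != edges$dest]
  known <- registry$code
  bad <- !(edges$origin %in% known) | !(edges$dest %in% known)
  unresolved <- list(codes = sort(unique(c(edges$origin, edges$dest)[
    c(!(edges$origin %in% known), !(edges$dest %in% known))])),
    journeys = sum(edges$weight[bad]))
  if (any(bad)) {
    warning(sprintf("matrix_to_network: dropped %d edge(s) (%d journey(s)) with code(s) not in registry: %s",
                    sum(bad), unresolved$journeys,
                    paste(unresolved$codes, collapse = ", ")))
    edges <- edges[!bad]
  }
  if (nrow(edges)) {
    dists <- mapply(function(o, d) distance_km(o, d, registry, method = distance_method),
                    edges$origin, edges$dest)
    edges[, distance_km := as.numeric(dists)]
    edges[edges$origin == edges$dest, distance_km := 0]
  } else edges[, distance_km := numeric(0)]
  active <- sort(unique(c(edges$origin, edges$dest)))
  vertices <- registry[match(active, registry$code), ]
  structure(list(year = m$year, vertices = vertices, edges = edges,
                 intermunicipal_only = intermunicipal_only,
                 unresolved = unresolved),
            class = "flow_network")
}

#' @export
print.flow_network <- function(x, ...) {
  cat(sprintf("<flow_network> year %d: %d vertices, %d arcs, total flow %d%s\n",
              x$year, nrow(x$vertices), nrow(x$edges), sum(x$edges$weight),
              if (x$intermunicipal_only) " (intermunicipal only)" else ""))
  invisible(x)
}

#' Build one network per competence year straight from records
#'
#' @inheritParams matrix_to_network
#' @param records Procedure-filtered records.
#' @param years Years to build; default all years present in `records`.
#' @return Named list of `flow_network`, one per year (possibly empty
#'   networks for years without records).
#' @export
records_to_networks <- function(records, registry, years = NULL,
                                intermunicipal_only = TRUE,
                                distance_method = c("utm", "great_circle")) {
  distance_method <- match.arg(distance_method)
  if (is.null(years)) years <- sort(unique(records$year))
  nets <- lapply(years, function(y)
    matrix_to_network(build_od_matrix(records, y), registry,
                      intermunicipal_only = intermunicipal_only,
                      distance_method = distance_method))
  names(nets) <- as.character(years)
  nets
}

#' Hospitalization counts by service-provider municipality
#'
#' Counts every record by destination municipality, including residents
#' hospitalized in their own municipality -- self-journeys count here, unlike
#' in the intermunicipal network.
#'
#' @param records Procedure-filtered records.
#' @param year Competence year.
#' @return Named integer vector, destination code -> hospitalization count.
#' @export
count_by_provider <- function(records, year) {
  yr <- as.integer(year)  # evaluate outside the data.table frame: `year` is a column
  sub <- records[records$year == yr]
  if (nrow(sub) == 0L) return(setNames(integer(0), character(0)))
  tab <- sub[, .N, by = dest_code][order(-N, dest_code)]
  setNames(tab$N, tab$dest_code)
}

#' Flow network as an igraph object
#' @param net A `flow_network`.
#' @return A directed `igraph` graph with `weight` and `distance_km` edge
#'   attributes and `lat`, `lon`, `macroregion` vertex attributes.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "flow_network"))
  v <- data.frame(name = net$vertices$code, lat = net$vertices$lat,
                  lon = net$vertices$lon,
                  macroregion = if ("macroregion" %in% names(net$vertices))
                    net$vertices$macroregion else NA_character_)
  igraph::graph_from_data_frame(as.data.frame(net$edges), directed = TRUE,
                                vertices = v)
}

#' Write a network's edge list as CSV
#' @param net A `flow_network`.
#' @param path CSV path with columns `origin,destination,weight,distance_km`.
#' @export
write_edge_list <- function(net, path) {
  e <- data.table::data.table(origin = net$edges$origin,
                              destination = net$edges$dest,
                              weight = net$edges$weight,
                              distance_km = round(net$edges$distance_km, 2))
  data.table::fwrite(e, path)
  invisible(path)
}
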