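# The six journey indices of a focal municipality: in/out-degree, in/out
# flow, and flow-weighted mean arc lengths, plus their yearly time series and
# macroregion breakdowns.

.focal_edges <- function(net, focal, direction = c("incoming", "outgoing")) {
  direction <- match.arg(direction)
  focal <- normalize_muni_code(focal)
  if (direction == "incoming") net$edges[net$edges$dest == focal & net$edges$origin != focal]
  else net$edges[net$edges$origin == focal & net$edges$dest != focal]
}

#' In-degree of a municipality: number of distinct origin municipalities
#' with an arc into it
#'
#' A focal municipality absent from the network has degree 0. Self-loops
#' never enter any index (intermunicipal scope).
#'
#' @param net A `flow_network`.
#' @param focal Municipality code.
#' @return Non-negative integer count.
#' @export
in_degree <- function(net, focal) nrow(.focal_edges(net, focal, "incoming"))

#' Out-degree: number of distinct destination municipalities
#' @inheritParams in_degree
#' @export
out_degree <- function(net, focal) nrow(.focal_edges(net, focal, "outgoing"))

#' Incoming flow: total journey count on a municipality's incoming arcs
#' @inheritParams in_degree
#' @export
incoming_flow <- function(net, focal) sum(.focal_edges(net, focal, "incoming")$weight)

#' Outgoing flow: total journey count on a municipality's outgoing arcs
#' @inheritParams in_degree
#' @export
outgoing_flow <- function(net, focal) sum(.focal_edges(net, focal, "outgoing")$weight)

#' Flow-weighted mean arc length of a municipality
#'
#' The weighted average of the straight-line arc distances, weights being the
#' journey counts: with arcs a = 1..k carrying distance D_a (km) and flow F_a,
#' Dbar = sum(D_a F_a) / sum(F_a). `NA` when the municipality has no arc in
#' the requested direction (degree 0) -- a direction with no journeys has no
#' distance, not a zero distance.
#'
#' @inheritParams in_degree
#' @param direction `"incoming"` or `"outgoing"`.
#' @return Kilometers, or `NA` when the corresponding degree is 0.
#' @export
mean_arc_length <- function(net, focal, direction = c("incoming", "outgoing")) {
  e <- .focal_edges(net, focal, direction)
  if (nrow(e) == 0L) return(NA_real_)
  if (anyNA(e$distance_km))
    stop("mean_arc_length: network edges are missing distance_km")
  sum(e$distance_km * e$weight) / sum(e$weight)
}

#' The six indices of one focal municipality in one year
#'
#' @inheritParams in_degree
#' @return One-row `data.frame`: `year, in_degree, out_degree, incoming_flow,
#'   outgoing_flow, mean_in_length_km, mean_out_length_km` (the mean lengths
#'   `NA` iff the corresponding degree is 0).
#' @export
index_row <- function(net, focal) {
  data.frame(
    year = net$year,
    in_degree = in_degree(net, focal),
    out_degree = out_degree(net, focal),
    incoming_flow = incoming_flow(net, focal),
    outgoing_flow = outgoing_flow(net, focal),
    mean_in_length_km = mean_arc_length(net, focal, "incoming"),
    mean_out_length_km = mean_arc_length(net, focal, "outgoing")
  )
}

#' Multi-year index time series of a focal municipality
#'
#' @param networks List of yearly `flow_network`s with distinct years.
#' @param focal Municipality code.
#' @param years Optional years to report (default: full range spanned by
#'   `networks`); a year with no network yields the all-zero/NA row.
#' @return `data.frame`, one [index_row()] per year, sorted by year.
#' @export
time_series <- function(networks, focal, years = NULL) {
  net_years <- vapply(networks, function(n) n$year, integer(1))
  if (anyDuplicated(net_years))
    stop(sprintf("time_series: duplicate network year(s): %s",
                 paste(unique(net_years[duplicated(net_years)]), collapse = ", ")))
  if (is.null(years)) years <- seq(min(net_years), max(net_years))
  rows <- lapply(years, function(y) {
    i <- match(y, net_years)
    if (is.na(i))
      data.frame(year = as.integer(y), in_degree = 0L, out_degree = 0L,
                 incoming_flow = 0L, outgoing_flow = 0L,
                 mean_in_length_km = NA_real_, mean_out_length_km = NA_real_)
    else index_row(networks[[i]], focal)
  })
  out <- do.call(rbind, rows)
  out[order(out$year), , drop = FALSE]
}

#' Write an index time series as CSV
#'
#' Distances are rounded to 2 decimals at output time only; degree-0 mean
#' lengths are written as the literal string `NA`.
#'
#' @param ts A [time_series()] result.
#' @param path CSV path.
#' @export
write_index_table <- function(ts, path) {
  out <- ts
  out$mean_in_length_km <- ifelse(is.na(ts$mean_in_length_km), "NA",
                                  sprintf("%.2f", ts$mean_in_length_km))
  out$mean_out_length_km <- ifelse(is.na(ts$mean_out_length_km), "NA",
                                   sprintf("%.2f", ts$mean_out_length_km))
  data.table::fwrite(out, path, quote = FALSE)
  invisible(path)
}

#' Macroregion breakdown of a municipality's counterpart municipalities
#'
#' Partitions the focal municipality's distinct counterpart municipalities
#' (its degree, not its flow) by the macroregion label carried in the
#' registry; counterparts without a label fall into `"unknown"`. Percentages
#' are 100 * count / degree.
#'
#' @inheritParams mean_arc_length
#' @return A `macroregion_breakdown`: list with `year`, `direction`,
#'   `counts` (named integer, sums to the degree) and `percentages` (named
#'   numeric, sums to 100 up to rounding). Degree 0 yields empty vectors.
#' @export
macroregion_breakdown <- function(net, focal, direction = c("incoming", "outgoing")) {
  direction <- match.arg(direction)
  e <- .focal_edges(net, focal, direction)
  counterparts <- if (direction == "incoming") e$origin else e$dest
  labels <- net$vertices$macroregion[match(counterparts, net$vertices$code)]
  labels[is.na(labels) | labels == ""] <- "unknown"
  counts <- table(labels)
  counts <- setNames(as.integer(counts), names(counts))
  if (length(counts)) counts <- counts[order(-counts, names(counts))]
  else counts <- setNames(integer(0), character(0))
  pct <- if (length(counts)) 100 * counts / sum(counts) else setNames(numeric(0), character(0))
  structure(list(year = net$year, direction = direction,
                 counts = counts, percentages = pct),
            class = "macroregion_breakdown")
}

#' @export
print.macroregion_breakdown <- function(x, ...) {
  cat(sprintf("<macroregion_breakdown> year %d, %s (%d counterpart municipalities)\n",
              x$year, x$direction, sum(x$counts)))
  for (i in seq_along(x$counts))
    cat(sprintf("  %-14s %4d (%.1f%%)\n", names(x$counts)[i],
                x$counts[i], x$percentages[i]))
  invisible(x)
}
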