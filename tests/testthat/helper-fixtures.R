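# In-code fixtures shared across the suite.

make_records_dt <- function(year, month, origin, dest, proc = "0406010013") {
  data.table::data.table(year = as.integer(year), month = as.integer(month),
                         origin_code = as.character(origin),
                         dest_code = as.character(dest),
                         procedure_code = as.character(proc))
}

write_csv_fixture <- function(df, sep = ",") {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  data.table::fwrite(df, path, sep = sep)
  path
}

# registry of n municipalities laid out on a line inside one UTM zone
make_registry <- function(n = 5, macroregion = NULL, lat0 = -13, lon0 = -40) {
  reg <- data.table::data.table(
    code = sprintf("29%04d", seq_len(n)),
    name = sprintf("Town %d", seq_len(n)),
    lat = lat0 - 0.3 * (seq_len(n) - 1),
    lon = lon0 + 0.2 * (seq_len(n) - 1),
    macroregion = if (is.null(macroregion)) NA_character_
                  else rep_len(macroregion, n)
  )
  data.table::setkeyv(reg, "code")
  data.table::setattr(reg, "class", c("municipality_registry", class(reg)))
  reg
}

# a flow_network built directly from an edge table (distances given), so
# index tests do not depend on the geo module
make_network <- function(edges, year = 2010L, registry = NULL) {
  edges <- data.table::as.data.table(edges)
  data.table::setnames(edges, c("origin", "dest", "weight", "distance_km"))
  active <- sort(unique(c(edges$origin, edges$dest)))
  if (is.null(registry)) {
    registry <- data.table::data.table(
      code = active, name = active,
      lat = seq(-15, -10, length.out = max(length(active), 2))[seq_along(active)],
      lon = -40, macroregion = NA_character_)
  }
  vertices <- registry[match(active, registry$code), ]
  structure(list(year = as.integer(year), vertices = vertices, edges = edges,
                 intermunicipal_only = TRUE,
                 unresolved = list(codes = character(0), journeys = 0L)),
            class = "flow_network")
}

# independent Eq. 1 oracle: naive loop over arcs
naive_mean_arc_length <- function(edges, focal, direction) {
  tot_w <- 0; tot_dw <- 0
  for (i in seq_len(nrow(edges))) {
    hit <- if (direction == "incoming")
      edges$dest[i] == focal && edges$origin[i] != focal
    else edges$origin[i] == focal && edges$dest[i] != focal
    if (hit) {
      tot_w <- tot_w + edges$weight[i]
      tot_dw <- tot_dw + edges$weight[i] * edges$distance_km[i]
    }
  }
  if (tot_w == 0) NA_real_ else tot_dw / tot_w
}

# random small network with distances attached
random_network <- function(n_vertices, n_arcs, year = 2015L) {
  codes <- sprintf("29%04d", seq_len(n_vertices))
  od <- unique(data.table::data.table(
    origin = sample(codes, n_arcs, replace = TRUE),
    dest = sample(codes, n_arcs, replace = TRUE)))
  od <- od[od$origin != od$dest]
  if (nrow(od) == 0L)
    od <- data.table::data.table(origin = codes[1], dest = codes[2])
  od$weight <- sample.int(50L, nrow(od), replace = TRUE)
  od$distance_km <- runif(nrow(od), 5, 800)
  make_network(od, year = year)
}
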