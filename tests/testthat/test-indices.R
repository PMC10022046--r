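test_that("degrees and flows on hand-built networks", {
  star <- make_network(data.frame(
    o = sprintf("29%04d", 1:8), d = "299999",
    w = rep(2L, 8), km = seq(50, 400, by = 50)))
  expect_equal(in_degree(star, "299999"), 8L)
  expect_equal(out_degree(star, "299999"), 0L)
  expect_equal(incoming_flow(star, "299999"), 16L)
  expect_equal(outgoing_flow(star, "299999"), 0L)
  # focal absent from the network
  expect_equal(in_degree(star, "288888"), 0L)
  expect_equal(incoming_flow(star, "288888"), 0L)

  two_out <- make_network(data.frame(o = "290001", d = c("290002", "290003"),
                                     w = c(13L, 7L), km = c(100, 300)))
  expect_equal(out_degree(two_out, "290001"), 2L)
  expect_equal(outgoing_flow(two_out, "290001"), 20L)
  expect_equal(in_degree(two_out, "290002"), 1L)
  expect_equal(incoming_flow(two_out, "290002"), 13L)
})

test_that("mean_arc_length evaluates the flow-weighted mean and NA semantics", {
  one <- make_network(data.frame(o = "290001", d = "290002", w = 25L, km = 326.52))
  expect_equal(mean_arc_length(one, "290001", "outgoing"), 326.52)
  # (100*1 + 300*3) / 4 = 250
  two <- make_network(data.frame(o = "290001", d = c("290002", "290003"),
                                 w = c(1L, 3L), km = c(100, 300)))
  expect_equal(mean_arc_length(two, "290001", "outgoing"), 250)
  # degree 0 -> NA, never 0 and never an error
  expect_true(is.na(mean_arc_length(two, "290001", "incoming")))
  expect_true(is.na(mean_arc_length(two, "290002", "outgoing")))
  # missing distances are a data error
  broken <- make_network(data.frame(o = "290001", d = "290002", w = 1L, km = NA_real_))
  expect_error(mean_arc_length(broken, "290001", "outgoing"), "distance")
})

test_that("mean_arc_length equals the naive loop oracle on random networks", {
  set.seed(31)
  for (i in 1:60) {
    net <- random_network(sample(5:50, 1), sample(5:200, 1))
    focal <- sample(net$vertices$code, 1)
    for (dir in c("incoming", "outgoing")) {
      got <- mean_arc_length(net, focal, dir)
      want <- naive_mean_arc_length(net$edges, focal, dir)
      if (is.na(want)) expect_true(is.na(got))
      else expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("mean_arc_length is bounded by arc extremes and weight-scale invariant", {
  set.seed(32)
  for (i in 1:40) {
    net <- random_network(10, 40)
    focal <- sample(net$vertices$code, 1)
    e <- net$edges[net$edges$origin == focal & net$edges$dest != focal]
    if (nrow(e) == 0) next
    d <- mean_arc_length(net, focal, "outgoing")
    expect_gte(d, min(e$distance_km) - 1e-12)
    expect_lte(d, max(e$distance_km) + 1e-12)
    scaled <- net
    scaled$edges <- data.table::copy(net$edges)[, weight := weight * 7L]
    expect_equal(mean_arc_length(scaled, focal, "outgoing"), d, tolerance = 1e-12)
  }
})

test_that("index_row assembles the six indices consistently", {
  # weights/distances echo a one-in one-out year: 13 in over 131.57 km,
  # 25 out over 326.52 km
  net <- make_network(data.frame(o = c("290009", "293330"),
                                 d = c("293330", "292740"),
                                 w = c(13L, 25L), km = c(131.57, 326.52)))
  row <- index_row(net, "293330")
  expect_equal(row$in_degree, 1L)
  expect_equal(row$out_degree, 1L)
  expect_equal(row$incoming_flow, 13L)
  expect_equal(row$outgoing_flow, 25L)
  expect_equal(row$mean_in_length_km, 131.57)
  expect_equal(row$mean_out_length_km, 326.52)

  empty <- make_network(data.frame(o = "290001", d = "290002", w = 1L, km = 10))
  row0 <- index_row(empty, "299999")
  expect_equal(unlist(row0[c("in_degree", "out_degree", "incoming_flow", "outgoing_flow")]),
               c(in_degree = 0L, out_degree = 0L, incoming_flow = 0L, outgoing_flow = 0L))
  expect_true(is.na(row0$mean_in_length_km) && is.na(row0$mean_out_length_km))

  set.seed(33)
  net <- random_network(20, 80)
  focal <- sample(net$vertices$code, 1)
  row <- index_row(net, focal)
  expect_equal(row$in_degree, in_degree(net, focal))
  expect_equal(row$out_degree, out_degree(net, focal))
  expect_equal(row$incoming_flow, incoming_flow(net, focal))
  expect_equal(row$outgoing_flow, outgoing_flow(net, focal))
})

test_that("time_series orders years, fills gaps with zero/NA rows, rejects duplicates", {
  n1 <- make_network(data.frame(o = "290001", d = "290002", w = 3L, km = 100), year = 2010)
  n3 <- make_network(data.frame(o = "290002", d = "290001", w = 5L, km = 100), year = 2012)
  ts <- time_series(list(n3, n1), "290001")
  expect_equal(ts$year, 2010:2012)
  expect_equal(ts$out_degree, c(1L, 0L, 0L))
  expect_equal(ts$incoming_flow, c(0L, 0L, 5L))
  gap <- ts[ts$year == 2011, ]
  expect_equal(gap$in_degree + gap$out_degree + gap$incoming_flow + gap$outgoing_flow, 0L)
  expect_true(is.na(gap$mean_in_length_km) && is.na(gap$mean_out_length_km))
  expect_error(time_series(list(n1, n1), "290001"), "duplicate")
})

test_that("macroregion breakdown partitions the degree with percentages of it", {
  reg <- make_registry(6, macroregion = c("Southwest", "Southwest", "West",
                                          "South", "West", "Southwest"))
  edges <- data.frame(o = sprintf("29%04d", 1:5), d = "290006",
                      w = 1:5, km = 10 * (1:5))
  net <- make_network(edges, registry = reg)
  br <- macroregion_breakdown(net, "290006", "incoming")
  expect_equal(sum(br$counts), in_degree(net, "290006"))
  expect_equal(unname(br$counts[c("Southwest", "West", "South")]), c(2L, 2L, 1L))
  expect_equal(sum(br$percentages), 100)
  # degree 0 -> empty breakdown, valid
  empty <- macroregion_breakdown(net, "290001", "incoming")
  expect_length(empty$counts, 0L)
  # missing labels fall into "unknown"
  reg2 <- make_registry(3)
  net2 <- make_network(data.frame(o = c("290001", "290002"), d = "290003",
                                  w = 1L, km = 5), registry = reg2)
  br2 <- macroregion_breakdown(net2, "290003", "incoming")
  expect_equal(unname(br2$counts["unknown"]), 2L)
})

test_that("index table CSV writes NA as the literal string and rounds to 2 decimals", {
  n1 <- make_network(data.frame(o = "290001", d = "290002", w = 3L, km = 123.456), year = 2008)
  ts <- time_series(list(n1), "290001")
  path <- withr::local_tempfile(fileext = ".csv")
  write_index_table(ts, path)
  lines <- readLines(path)
  expect_equal(lines[1],
    "year,in_degree,out_degree,incoming_flow,outgoing_flow,mean_in_length_km,mean_out_length_km")
  expect_equal(lines[2], "2008,0,1,0,3,NA,123.46")
})
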