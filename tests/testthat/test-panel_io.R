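test_that("read_panel pivots a complete long file into matrices", {
  regions <- paste0("R", 1:9)
  years <- 2010:2019
  set.seed(1)
  obs <- matrix(rpois(90, 26), 9, 10)
  obs[1, 1] <- obs[1, 1] + (2340L - sum(obs))   # pin the panel total
  df <- make_long_panel(regions, years, obs, matrix(2e5, 9, 10))
  p <- read_panel(write_panel_csv(df))
  expect_s3_class(p, "count_panel")
  expect_identical(dim(p$observed), c(9L, 10L))
  expect_identical(dim(p$population), c(9L, 10L))
  expect_identical(p$region_ids, regions)
  expect_identical(p$years, years)
  expect_identical(sum(p$observed), 2340L)
})

test_that("read_panel fails loudly on gaps, duplicates and bad counts", {
  df <- make_long_panel(c("Hamadan", "Famenin"), 2012:2013,
                        matrix(5L, 2, 2), matrix(1e5, 2, 2))
  expect_error(read_panel(write_panel_csv(df[-4, ])), "Famenin/2013")
  expect_error(read_panel(write_panel_csv(rbind(df, df[1, ]))),
               "duplicate")
  df$observed[2] <- 3.5
  expect_error(read_panel(write_panel_csv(df)), "non-integer")
})

test_that("panel write-then-read round-trips exactly", {
  set.seed(2)
  p <- count_panel(c("b", "a", "c"), 2015:2018,
                   matrix(rpois(12, 30), 3, 4),
                   matrix(runif(12, 5e4, 5e5), 3, 4))
  path <- tempfile(fileext = ".csv")
  write_panel(p, path)
  q <- read_panel(path)
  expect_identical(q$region_ids, p$region_ids)
  expect_identical(q$years, p$years)
  expect_equal(unname(q$observed), unname(p$observed))
  expect_equal(unname(q$population), unname(p$population))
})

test_that("queen contiguity on lattices gives the textbook degrees", {
  g3 <- build_adjacency(write_lattice_geojson(3), lattice_ids(3))
  deg <- setNames(g3$degree, g3$region_ids)
  expect_identical(unname(deg[c("r1_1", "r1_3", "r3_1", "r3_3")]),
                   rep(3L, 4))                       # corners
  expect_identical(unname(deg["r2_2"]), 8L)          # interior
  expect_identical(unname(deg[c("r1_2", "r2_1", "r2_3", "r3_2")]),
                   rep(5L, 4))                       # edges
  # symmetry holds for every region
  for (i in seq_along(g3$region_ids))
    for (j in g3$neighbors[[i]])
      expect_true(i %in% g3$neighbors[[j]])
  # 2x2 lattice: all four squares meet at the centre point -> complete graph
  g2 <- build_adjacency(write_lattice_geojson(2), lattice_ids(2))
  expect_identical(g2$degree, rep(3L, 4))
})

test_that("disjoint polygons are flagged as islands", {
  path <- write_lattice_geojson(1)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  far <- gj$features[[1]]
  far$properties$region <- "far"
  far$geometry$coordinates[[1]] <- lapply(
    far$geometry$coordinates[[1]], function(p) list(p[[1]] + 10, p[[2]]))
  gj$features[[2]] <- far
  path2 <- tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, path2, auto_unbox = TRUE, digits = NA)
  expect_warning(g <- build_adjacency(path2, c("r1_1", "far")), "island")
  expect_identical(g$degree, c(0L, 0L))
  expect_identical(sort(g$islands), c("far", "r1_1"))
  expect_false(g$connected)
})

test_that("adjacency lists are parsed, validated and symmetrized", {
  p1 <- tempfile(); writeLines(c("A: B", "B: A"), p1)
  g <- read_adjacency_list(p1)
  expect_identical(g$degree, c(1L, 1L))
  p2 <- tempfile(); writeLines(c("A: B", "B:"), p2)
  expect_message(g2 <- read_adjacency_list(p2), "symmetrized")
  expect_identical(g2$degree, c(1L, 1L))
  p3 <- tempfile(); writeLines(c("A: Z", "B: A"), p3)
  expect_error(read_adjacency_list(p3), "unknown neighbour")
  # 9-region fixture round-trip: degrees match the hand-specified edge set
  fx <- hamadan_fixture()
  p4 <- tempfile()
  writeLines(vapply(seq_along(fx$graph$region_ids), function(i)
    paste0(fx$graph$region_ids[i], ": ",
           paste(fx$graph$region_ids[fx$graph$neighbors[[i]]],
                 collapse = " ")), character(1)), p4)
  g4 <- read_adjacency_list(p4)
  expect_identical(g4$degree, fx$graph$degree)
  expect_identical(sum(g4$degree), 32L)   # 16 hand-counted edges
})

test_that("results tables are deterministic with a fixed schema", {
  toy <- toy_scan_inputs()
  E <- expected_counts(toy$panel)
  res <- scan_clusters(toy$panel, toy$centroids, E,
                       scan_config(n_monte_carlo = 19, seed = 4))
  f1 <- tempfile(); f2 <- tempfile()
  write_results_table(as.data.frame(res), f1)
  write_results_table(as.data.frame(res), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  hdr <- strsplit(readLines(f1, n = 1), ",")[[1]]
  expect_identical(hdr, c("cluster_rank", "direction", "regions", "start",
                          "end", "population", "observed", "expected",
                          "oe", "rr", "llr", "p_value"))
  # empty result set -> header-only file
  empty <- res[0, , drop = FALSE]
  f3 <- tempfile()
  write_results_table(as.data.frame(empty), f3)
  expect_length(readLines(f3), 1L)
})
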