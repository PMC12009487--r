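test_that("scan LLR matches the two-rate likelihood-ratio oracle", {
  set.seed(11)
  for (i in 1:100) {
    C <- sample(200:3000, 1)
    e <- runif(1, 5, C - 5)
    c <- rbinom(1, C, e / C)
    c <- min(max(c, 1), C - 1)
    expect_equal(poisson_llr(c, e, C), oracle_llr(c, e, C),
                 tolerance = 1e-6)
  }
})

test_that("LLR edge behaviour and monotonicity", {
  expect_equal(poisson_llr(100, 100, 1000), 0)
  expect_error(poisson_llr(10, 0, 100), "0 < e < C")
  expect_error(poisson_llr(10, 100, 100), "0 < e < C")
  expect_error(poisson_llr(-1, 5, 100), "0 <= c <= C")
  # non-decreasing above e, non-increasing below e
  llr_hi <- poisson_llr(300:500, 300, 1000)
  expect_true(all(diff(llr_hi) >= 0))
  llr_lo <- poisson_llr(0:300, 300, 1000)
  expect_true(all(diff(llr_lo) <= 0))
})

test_that("relative risk contrasts inside against outside", {
  rr <- relative_risk(96, 52.21, 2340)
  expect_equal(round(rr$rr, 2), 1.87)
  expect_equal(round(rr$oe, 2), 1.84)
  expect_equal(relative_risk(50, 50, 500)$rr, 1)
  expect_identical(relative_risk(500, 50, 500)$rr, Inf)
  expect_true(relative_risk(10, 50, 500)$rr < 1)
})

test_that("cylinder enumeration respects the temporal and spatial caps", {
  # single region, 10 years, temporal cap 1/2: sum over L=1..5 of (11-L)
  p1 <- count_panel("A", 2010:2019, matrix(10L, 1, 10),
                    matrix(1e5, 1, 10))
  c1 <- region_centroids("A", 35, 48)
  cy <- enumerate_cylinders(p1, c1, expected_counts(p1),
                            scan_config(max_spatial_fraction = 1))
  expect_identical(nrow(cy), 40L)
  expect_true(all(cy$end - cy$start + 1 <= 5))
  # 4 equal regions, 2 years, caps 1/2: bases of at most 2 regions,
  # window length 1 -> 4 centers x 2 windows x k in {1, 2}
  toy <- toy_scan_inputs()
  cy2 <- enumerate_cylinders(toy$panel, toy$centroids,
                             expected_counts(toy$panel), scan_config())
  expect_identical(nrow(cy2), 16L)
  expect_true(all(cy2$k <= 2))
  total_pt <- 4e5   # person-time of one year across the four regions
  expect_true(all(cy2$population <= 0.5 * total_pt))
  # no cap: every center grows to all regions
  cy3 <- enumerate_cylinders(toy$panel, toy$centroids,
                             expected_counts(toy$panel),
                             scan_config(max_spatial_fraction = 1,
                                         max_temporal_fraction = 1))
  expect_identical(nrow(cy3), 4L * 4L * 3L)  # 4 centers x 4 k x 3 windows
})

test_that("scan equals brute-force argmax over enumerated cylinders", {
  set.seed(21)
  counts <- matrix(rpois(8, 50), 4, 2)
  counts[2, 2] <- counts[2, 2] + 40L          # make region B stand out
  toy <- toy_scan_inputs(counts = counts)
  E <- expected_counts(toy$panel)
  res <- scan_clusters(toy$panel, toy$centroids, E,
                       scan_config(n_monte_carlo = 99, seed = 5))
  cy <- enumerate_cylinders(toy$panel, toy$centroids, E, scan_config())
  llr <- poisson_llr(cy$c, cy$e, sum(counts))
  best_hi <- cy[cy$c > cy$e, ][which.max(llr[cy$c > cy$e]), ]
  prim <- res[res$direction == "high" & res$cluster_rank == "primary", ]
  expect_identical(prim$regions, best_hi$regions)
  expect_identical(prim$start, best_hi$start)
  expect_identical(prim$end, best_hi$end)
  expect_equal(prim$llr, max(llr[cy$c > cy$e]))
})

test_that("scan is seeded-reproducible and order-invariant", {
  set.seed(31)
  counts <- matrix(rpois(8, 50), 4, 2)
  toy <- toy_scan_inputs(counts = counts)
  E <- expected_counts(toy$panel)
  r1 <- scan_clusters(toy$panel, toy$centroids, E,
                      scan_config(n_monte_carlo = 99, seed = 6))
  r2 <- scan_clusters(toy$panel, toy$centroids, E,
                      scan_config(n_monte_carlo = 99, seed = 6))
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  # reversing region order must not change what is found
  perm <- 4:1
  panel_p <- count_panel(toy$panel$region_ids[perm], toy$panel$years,
                         toy$panel$observed[perm, ],
                         toy$panel$population[perm, ])
  cent_p <- region_centroids(toy$centroids$region_ids[perm],
                             toy$centroids$latitude[perm],
                             toy$centroids$longitude[perm])
  r3 <- scan_clusters(panel_p, cent_p, expected_counts(panel_p),
                      scan_config(n_monte_carlo = 99, seed = 6))
  canon <- function(r) {
    r$regions <- vapply(strsplit(r$regions, "|", fixed = TRUE),
                        function(v) paste(sort(v), collapse = "|"),
                        character(1))
    r[order(r$direction, -r$llr), c("regions", "start", "end", "llr")]
  }
  expect_equal(canon(as.data.frame(r1)), canon(as.data.frame(r3)),
               ignore_attr = TRUE)
})

test_that("a low-rate deficit cylinder is found by the low scan", {
  fx <- hamadan_fixture()
  sim <- simulate_panel(fx$panel, fx$graph, model_spec(),
                        sd_v = 0, sd_u = 0, sd_gamma = 0, sd_phi = 0,
                        seed = 41)
  inj <- inject_cluster(sim$panel, sim$truth, c("Malayer", "Nahavand"),
                        c(2010, 2014), rr = 0.5, seed = 42)
  res <- scan_clusters(inj$panel, fx$centroids,
                       expected_counts(inj$panel),
                       scan_config(n_monte_carlo = 199, seed = 43))
  low <- res[res$direction == "low" & res$cluster_rank == "primary", ]
  expect_identical(nrow(low), 1L)
  expect_setequal(strsplit(low$regions, "|", fixed = TRUE)[[1]],
                  c("Malayer", "Nahavand"))
  expect_lte(low$p_value, 0.01)
})
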