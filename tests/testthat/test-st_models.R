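path_graph <- function(n)
  adjacency_graph(paste0("P", seq_len(n)),
                  lapply(seq_len(n), function(i)
                    intersect(c(i - 1L, i + 1L), seq_len(n))))

test_that("ICAR kernel: zero maximum, relabeling invariance", {
  g <- path_graph(4)
  expect_equal(icar_log_prior(rep(0, 4), g, 2), 0)
  u <- c(0.3, -0.1, 0.2, -0.4)
  perm <- c(3, 1, 4, 2)
  gp <- adjacency_graph(g$region_ids[perm], lapply(perm, function(i)
    match(g$neighbors[[i]], perm)))
  expect_equal(icar_log_prior(u[perm], gp, 1.7),
               icar_log_prior(u, g, 1.7))
  expect_error(icar_log_prior(numeric(0),
                              adjacency_graph(character(0), list()), 1),
               "empty")
})

test_that("ICAR full conditionals are N(neighbour mean, sigma2/n_i)", {
  # derive the conditional of u_i numerically from the joint kernel on a
  # grid and compare with the stated CAR full conditional
  for (g in list(path_graph(3), path_graph(5), hamadan_fixture()$graph)) {
    n <- length(g$region_ids)
    set.seed(n)
    u <- rnorm(n, 0, 0.5)
    tau <- 1.6
    for (i in c(1L, n %/% 2L + 1L)) {
      nb0 <- g$neighbors[[i]]
      s0 <- 1 / sqrt(tau * length(nb0))
      grid <- seq(mean(u[nb0]) - 7 * s0, mean(u[nb0]) + 7 * s0,
                  length.out = 4001)
      lk <- vapply(grid, function(val) {
        uu <- u; uu[i] <- val
        icar_log_prior(uu, g, tau)
      }, numeric(1))
      w <- exp(lk - max(lk)); w <- w / sum(w)
      m_num <- sum(w * grid)
      v_num <- sum(w * (grid - m_num)^2)
      nb <- g$neighbors[[i]]
      expect_equal(m_num, mean(u[nb]), tolerance = 1e-6)
      expect_equal(v_num, 1 / (tau * length(nb)), tolerance = 1e-4)
    }
  }
})

test_that("RW2 kernel: linear null space and unit second difference", {
  expect_equal(rw2_log_prior(2 + 3 * (1:8), 5), 0)
  expect_equal(rw2_log_prior(c(0, 0, 1), 1), -0.5)
  g <- c(0.2, -0.4, 0.1, 0.6, -0.3)
  expect_equal(rw2_log_prior(g + 1.3 - 0.7 * (1:5), 2.2),
               rw2_log_prior(g, 2.2))
  expect_error(rw2_log_prior(c(1, 2), 1), "at least 3")
})

test_that("interaction kernels match their explicit quadratic forms", {
  g2 <- path_graph(2)
  for (type in c("I", "II", "III", "IV"))
    expect_equal(interaction_log_prior(matrix(0, 2, 3), type, g2,
                                       precision = 3), 0)
  d <- matrix(c(0.4, -0.2, 0.1, 0.3, -0.5, 0.2), 2, 3)
  tau <- 1.9
  # type I: plain sum of squares over cells
  expect_equal(interaction_log_prior(d, "I", g2, precision = tau),
               -tau / 2 * sum(d^2))
  # type II: independent RW1 within each region
  expect_equal(interaction_log_prior(d, "II", g2, 1, tau),
               -tau / 2 * sum((d[, -1] - d[, -3])^2))
  # type III: ICAR across the 2-region path within each year
  expect_equal(interaction_log_prior(d, "III", g2, 1, tau),
               -tau / 2 * sum((d[1, ] - d[2, ])^2))
  # type IV on a 2-region path x 3 years: expand the Kronecker quadratic
  # form by hand as the RW1 penalty applied to the spatial difference
  s <- d[1, ] - d[2, ]
  expect_equal(interaction_log_prior(d, "IV", g2, 1, tau),
               -tau / 2 * sum(diff(s)^2))
})

test_that("null data with Y = E shrinks all smoothed SIRs to 1", {
  fx <- hamadan_fixture()
  p <- count_panel(fx$panel$region_ids, fx$panel$years,
                   matrix(30L, 9, 10), fx$panel$population)
  E <- structure(list(expected = matrix(30, 9, 10),
                      stratification = "per_year"),
                 class = "expected_matrix")
  fit <- fit_st_model(p, E, fx$graph, model_spec(),
                      chains = 2, warmup = 300, draws = 300, seed = 2)
  expect_true(all(fit$theta_mean > 0.9 & fit$theta_mean < 1.1))
  tab <- adjusted_sir_table(fit, force = TRUE)
  expect_identical(nrow(tab), 90L)
  expect_true(all(abs(tab$sir - 1) < 0.1))
})

test_that("posterior-mean SIRs are smoother than crude SIRs", {
  fx <- hamadan_fixture()
  for (s in 1:3) {
    sim <- simulate_panel(fx$panel, fx$graph, model_spec(), seed = s)
    E <- sim$truth$expected
    fit <- suppressWarnings(
      fit_st_model(sim$panel, E, fx$graph, model_spec(),
                   chains = 2, warmup = 300, draws = 300, seed = 50 + s))
    crude <- as.vector(sim$panel$observed) / as.vector(E$expected)
    expect_lt(var(fit$theta_mean), var(crude))
  }
})

test_that("a high-risk region keeps an elevated smoothed SIR in all years", {
  fx <- hamadan_fixture()
  sim <- simulate_panel(fx$panel, fx$graph, model_spec(),
                        sd_v = 0, sd_u = 0, sd_gamma = 0, sd_phi = 0,
                        seed = 9)
  inj <- inject_cluster(sim$panel, sim$truth, "Malayer",
                        c(2010, 2019), rr = 1.6, seed = 10)
  fit <- suppressWarnings(
    fit_st_model(inj$panel, sim$truth$expected, fx$graph, model_spec(),
                 chains = 2, warmup = 300, draws = 300, seed = 11))
  tab <- adjusted_sir_table(fit, force = TRUE)
  expect_true(all(tab$sir[tab$region == "Malayer"] > 1))
})

test_that("flagged fits are refused downstream unless forced", {
  fake <- list(valid = FALSE, region_ids = "A", years = 1:3,
               theta_mean = rep(1, 3), theta_lower = rep(0.5, 3),
               theta_upper = rep(1.5, 3))
  expect_error(adjusted_sir_table(fake), "invalid")
  expect_silent(adjusted_sir_table(fake, force = TRUE))
})

test_that("model_spec validates the six variants", {
  expect_message(sp <- model_spec("parametric", "II"), "ignores")
  expect_identical(sp$interaction, "none")
  expect_error(model_spec("nonparametric", "V"))
  specs <- all_model_specs()
  expect_length(specs, 6L)
  expect_identical(vapply(specs, `[[`, character(1), "interaction"),
                   c(none = "none", typeI = "I", typeII = "II",
                     typeIII = "III", typeIV = "IV", parametric = "none"))
})
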