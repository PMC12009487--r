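#' Synthetic 9-county, 10-year study skeleton
#'
#' A fixture emulating a western-Iran provincial cancer registry extract:
#' the nine counties of Hamadan province over 2010-2019, with constant
#' per-year populations, a hand-specified queen-contiguity list and
#' approximate county-seat centroid coordinates (the province centres near
#' 34.97 N, 48.56 E). This is synthetic scaffolding, not the registry data:
#' the Nahavand and Malayer populations and the pairwise/group sums
#' (Tuyserkan+Hamadan, Asadabad+Bahar, Kabudarahang+Famenin+Razan+Bahar)
#' match published cluster-population totals, while the individual splits
#' of those groups and all coordinates are invented placeholders near
#' public census figures. Observed counts are zero: fill them with
#' [simulate_panel] or real data.
#'
#' @return List with `panel` (a [count_panel] skeleton with zero counts),
#'   `graph` (an [adjacency_graph]) and `centroids` (a [region_centroids]).
#' @export
hamadan_fixture <- function() {
  counties <- c("Hamadan", "Malayer", "Nahavand", "Tuyserkan", "Asadabad",
                "Kabudarahang", "Razan", "Bahar", "Famenin")
  pop <- c(Hamadan = 667614, Malayer = 299070, Nahavand = 193745,
           Tuyserkan = 99000, Asadabad = 113590, Kabudarahang = 131000,
           Razan = 105000, Bahar = 124646, Famenin = 49358)
  years <- 2010:2019
  I <- length(counties); J <- length(years)
  panel <- count_panel(
    counties, years,
    observed = matrix(0L, I, J),
    population = matrix(rep(pop, J), I, J))
  edges <- list(
    Hamadan = c("Bahar", "Tuyserkan", "Malayer", "Famenin"),
    Malayer = c("Hamadan", "Nahavand", "Tuyserkan"),
    Nahavand = c("Malayer", "Tuyserkan"),
    Tuyserkan = c("Nahavand", "Malayer", "Hamadan", "Asadabad", "Bahar"),
    Asadabad = c("Tuyserkan", "Bahar", "Kabudarahang"),
    Kabudarahang = c("Asadabad", "Bahar", "Razan", "Famenin"),
    Razan = c("Kabudarahang", "Famenin"),
    Bahar = c("Hamadan", "Tuyserkan", "Asadabad", "Kabudarahang", "Famenin"),
    Famenin = c("Hamadan", "Kabudarahang", "Razan", "Bahar"))
  graph <- adjacency_graph(
    counties, lapply(edges[counties], match, counties))
  centroids <- region_centroids(
    counties,
    latitude = c(34.80, 34.30, 34.19, 34.55, 34.78, 35.21, 35.39, 34.91,
                 35.11),
    longitude = c(48.51, 48.82, 48.38, 48.45, 48.12, 48.72, 49.03, 48.44,
                  48.97))
  list(panel = panel, graph = graph, centroids = centroids)
}

# draw a constrained Gaussian field in the positive-eigenvalue basis of a
# structure matrix: x = V diag(sd / sqrt(lambda)) z, z ~ N(0, 1)
.draw_structured <- function(basis, sd) {
  drop(basis$V %*% (stats::rnorm(length(basis$lambda)) *
                      sd / sqrt(basis$lambda)))
}

#' Simulate a count panel from a space-time model
#'
#' Generates a panel with the generative structure the models assume:
#' `Y_ij ~ Poisson(E_ij theta_ij)` with
#' `log theta_ij = alpha + v_i + u_i + gamma_j + phi_j + delta_ij`
#' (nonparametric) or `alpha + u_i + v_i + (beta + delta_i) t_j`
#' (parametric). `u` is a constrained ICAR field on the graph, `gamma` a
#' constrained RW2, `v`/`phi` exchangeable sum-to-zero, and `delta` follows
#' the requested interaction type. Baseline expected counts come from a
#' flat per-person incidence rate, `E_ij = n_ij * rate`, with the default
#' rate chosen so a province-scale fixture accrues on the order of 2e3
#' cases per decade (107.72 per 100,000 per decade, the scale of provincial
#' colorectal-cancer incidence).
#'
#' @param skeleton a [count_panel] supplying regions, years, populations.
#' @param graph an [adjacency_graph].
#' @param spec a [model_spec].
#' @param alpha overall log relative risk; default 0.
#' @param sd_v,sd_u,sd_gamma,sd_phi,sd_delta true standard deviations of
#'   the effects (a parametric spec uses `sd_delta` for the slope
#'   deviations; `sd_gamma`/`sd_phi` are then ignored).
#' @param beta global linear time slope (parametric only).
#' @param rate_per_100k_decade baseline incidence per 100,000 persons per
#'   10 years; scaled to per-year internally.
#' @param seed integer seed.
#' @return List with `panel` (a [count_panel]) and `truth`
#'   (class `simulation_truth`): the generating parameters, the true
#'   `theta` matrix, the baseline `expected` matrix (an `expected_matrix`
#'   usable as the fitting offset), and the injected-cluster registry.
#' @export
simulate_panel <- function(skeleton, graph, spec = model_spec(),
                           alpha = 0, sd_v = 0.2, sd_u = 0.3,
                           sd_gamma = 0.15, sd_phi = 0.1, sd_delta = 0,
                           beta = 0, rate_per_100k_decade = 107.72,
                           seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  set.seed(seed)
  I <- length(skeleton$region_ids)
  J <- length(skeleton$years)
  rate <- rate_per_100k_decade / 1e5 / 10
  E <- skeleton$population * rate
  v <- if (sd_v > 0) .draw_structured(.stz_basis(I), sd_v) else numeric(I)
  u <- if (sd_u > 0)
    .draw_structured(.posdef_basis(.icar_structure(graph)), sd_u)
  else numeric(I)
  log_theta <- matrix(alpha + v + u, I, J)
  params <- list(alpha = alpha, v = v, u = u, sd_v = sd_v, sd_u = sd_u)
  if (spec$kind == "nonparametric") {
    gamma <- if (sd_gamma > 0)
      .draw_structured(.posdef_basis(.rw_structure(J, 2)), sd_gamma)
    else numeric(J)
    phi <- if (sd_phi > 0) .draw_structured(.stz_basis(J), sd_phi)
    else numeric(J)
    log_theta <- log_theta + rep(gamma + phi, each = I)
    params <- c(params, list(gamma = gamma, phi = phi,
                             sd_gamma = sd_gamma, sd_phi = sd_phi))
    if (spec$interaction != "none" && sd_delta > 0) {
      w <- spec$interaction_walk_order
      delta <- switch(spec$interaction,
        I = matrix(stats::rnorm(I * J, 0, sd_delta), I, J),
        II = {
          bT <- .posdef_basis(.rw_structure(J, w))
          t(vapply(seq_len(I), function(i) .draw_structured(bT, sd_delta),
                   numeric(J)))
        },
        III = {
          bS <- .posdef_basis(.icar_structure(graph))
          vapply(seq_len(J), function(j) .draw_structured(bS, sd_delta),
                 numeric(I))
        },
        IV = {
          bS <- .posdef_basis(.icar_structure(graph))
          bT <- .posdef_basis(.rw_structure(J, w))
          lam <- outer(bS$lambda, bT$lambda)
          z <- matrix(stats::rnorm(length(lam)), nrow(lam))
          bS$V %*% (z * sd_delta / sqrt(lam)) %*% t(bT$V)
        })
      log_theta <- log_theta + delta
      params <- c(params, list(delta = delta, sd_delta = sd_delta))
    }
  } else {
    tj <- seq_len(J) - (J + 1) / 2
    delta_i <- if (sd_delta > 0) .draw_structured(.stz_basis(I), sd_delta)
    else numeric(I)
    log_theta <- log_theta + outer(beta + delta_i, tj)
    params <- c(params, list(beta = beta, delta_i = delta_i,
                             sd_delta = sd_delta))
  }
  if (any(!is.finite(log_theta)) || max(log_theta) > 20)
    stop("non-finite or extreme theta; check the hyperparameter values")
  theta <- exp(log_theta)
  Y <- matrix(stats::rpois(I * J, as.vector(E * theta)), I, J)
  panel <- count_panel(skeleton$region_ids, skeleton$years, Y,
                       skeleton$population)
  truth <- structure(
    list(spec = spec, params = params, theta_true = theta,
         expected = structure(list(expected = E, stratification = "overall"),
                              class = "expected_matrix"),
         injected_clusters = list()),
    class = "simulation_truth")
  list(panel = panel, truth = truth)
}

#' Inject a space-time risk cylinder into a simulated panel
#'
#' Multiplies the true relative risk by `rr` inside the given regions and
#' year window and redraws the affected counts, so the scan statistic can
#' be exercised against a known embedded cluster (`rr > 1` for a high-rate,
#' `rr < 1` for a low-rate cylinder).
#'
#' @param panel a [count_panel] from [simulate_panel].
#' @param truth the matching `simulation_truth`.
#' @param regions character vector of region labels in the cylinder.
#' @param window length-2 vector of first and last calendar year.
#' @param rr multiplicative relative risk applied inside the cylinder.
#' @param seed integer seed for the redraw.
#' @return List with updated `panel` and `truth` (the injection is appended
#'   to `truth$injected_clusters`).
#' @export
inject_cluster <- function(panel, truth, regions, window, rr, seed = 1L) {
  set.seed(seed)
  ri <- match(regions, panel$region_ids)
  if (anyNA(ri)) stop("unknown region(s): ",
                      paste(regions[is.na(ri)], collapse = ", "))
  yi <- which(panel$years >= window[1] & panel$years <= window[2])
  if (!length(yi)) stop("empty year window")
  theta <- truth$theta_true
  theta[ri, yi] <- theta[ri, yi] * rr
  E <- truth$expected$expected
  Y <- panel$observed
  Y[ri, yi] <- stats::rpois(length(ri) * length(yi),
                            as.vector(E[ri, yi] * theta[ri, yi]))
  truth$theta_true <- theta
  truth$injected_clusters <- c(
    truth$injected_clusters,
    list(list(regions = regions, window = window, rr = rr)))
  list(panel = count_panel(panel$region_ids, panel$years, Y,
                           panel$population),
       truth = truth)
}
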