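# small programmatic fixtures shared across test files

# long-format panel CSV on disk; returns the path
write_panel_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# a fully crossed long panel data.frame
make_long_panel <- function(regions, years, observed, population) {
  data.frame(
    region = rep(regions, times = length(years)),
    year = rep(years, each = length(regions)),
    observed = as.vector(observed),
    population = as.vector(population))
}

# k x k lattice of unit-square polygons as a GeoJSON file; region ids
# "r<row>_<col>"; optionally offset a subset to make them disjoint
write_lattice_geojson <- function(k, path = tempfile(fileext = ".geojson"),
                                  offsets = NULL) {
  feats <- list()
  for (i in seq_len(k)) for (j in seq_len(k)) {
    id <- sprintf("r%d_%d", i, j)
    dx <- if (!is.null(offsets) && id %in% names(offsets))
      offsets[[id]] else 0
    x0 <- j - 1 + dx; y0 <- i - 1
    ring <- list(c(x0, y0), c(x0 + 1, y0), c(x0 + 1, y0 + 1),
                 c(x0, y0 + 1), c(x0, y0))
    feats[[length(feats) + 1L]] <- list(
      type = "Feature",
      properties = list(region = id),
      geometry = list(type = "Polygon", coordinates = list(ring)))
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  path
}

lattice_ids <- function(k)
  as.vector(outer(seq_len(k), seq_len(k),
                  function(i, j) sprintf("r%d_%d", i, j)))

# 4 regions on a line with distinct coordinates and equal populations
toy_scan_inputs <- function(years = 2010:2011, pop = 1e5,
                            counts = NULL) {
  regions <- c("A", "B", "C", "D")
  I <- 4; J <- length(years)
  if (is.null(counts)) counts <- matrix(50L, I, J)
  panel <- count_panel(regions, years, counts,
                       matrix(pop, I, J))
  centroids <- region_centroids(regions, latitude = rep(35, 4),
                                longitude = c(48, 48.2, 48.4, 48.6))
  list(panel = panel, centroids = centroids)
}

# independent oracle: generalized likelihood ratio for two Poisson rates
# (inside vs outside the cylinder), all maximizations done numerically
oracle_llr <- function(c, e, C) {
  alt <- function(lp) {
    p <- exp(lp[1]); q <- exp(lp[2])
    -(dpois(c, p * e, log = TRUE) + dpois(C - c, q * (C - e), log = TRUE))
  }
  null <- function(lr) {
    r <- exp(lr)
    -(dpois(c, r * e, log = TRUE) + dpois(C - c, r * (C - e), log = TRUE))
  }
  la <- -optim(c(0, 0), alt, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))$value
  l0 <- -optimize(null, c(-6, 6), tol = 1e-12)$objective
  la - l0
}

# a duck-typed posterior "fit" from explicit lambda draws (single- or
# multi-cell), for exercising the criteria against closed-form posteriors
fit_from_lambda <- function(lambda_draws, y, E = rep(1, ncol(lambda_draws))) {
  theta <- sweep(lambda_draws, 2, E, `/`)
  loglik <- stats::dpois(matrix(y, nrow(theta), ncol(theta), byrow = TRUE),
                         lambda_draws, log = TRUE)
  list(theta = theta, loglik = loglik, y = y, E = E,
       theta_mean = colMeans(theta), valid = TRUE)
}
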