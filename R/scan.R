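#' Scan configuration
#'
#' Parameters of the retrospective space-time scan. The defaults are the
#' conventional ones for county-level incidence scans: cylinders may cover
#' at most 50% of the population at risk and 50% of the study period, and
#' significance uses 999 Monte Carlo replicates, so the smallest attainable
#' pseudo p-value is 0.001.
#'
#' @param max_spatial_fraction maximum fraction of the population at risk a
#'   cylinder base may cover, in (0, 1]; default 0.5.
#' @param max_temporal_fraction maximum fraction of the study period a
#'   cylinder may span, in (0, 1]; default 0.5.
#' @param n_monte_carlo number of Monte Carlo replicates; default 999.
#' @param directions which cluster directions to scan for, subset of
#'   `c("high", "low")`; default both.
#' @param seed integer seed for the Monte Carlo replicates.
#' @return A list of class `scan_config`.
#' @export
scan_config <- function(max_spatial_fraction = 0.5,
                        max_temporal_fraction = 0.5,
                        n_monte_carlo = 999,
                        directions = c("high", "low"),
                        seed = 1L) {
  stopifnot(max_spatial_fraction > 0, max_spatial_fraction <= 1,
            max_temporal_fraction > 0, max_temporal_fraction <= 1,
            n_monte_carlo >= 1)
  directions <- match.arg(directions, c("high", "low"), several.ok = TRUE)
  structure(list(max_spatial_fraction = max_spatial_fraction,
                 max_temporal_fraction = max_temporal_fraction,
                 n_monte_carlo = as.integer(n_monte_carlo),
                 directions = directions, seed = as.integer(seed)),
            class = "scan_config")
}

#' Discrete-Poisson scan log-likelihood ratio
#'
#' The log-likelihood ratio comparing a cylinder with its own Poisson rate
#' against the homogeneous-rate null, with the expected total calibrated to
#' the observed total (`E[C] = C`):
#' `LLR = c log(c/e) + (C - c) log((C - c)/(C - e))`,
#' with the convention `0 log 0 = 0`. The value is 0 when `c = e` and grows
#' in either direction of departure, so it serves both high- and low-rate
#' scanning.
#'
#' @param c observed cases inside the cylinder (vectorized).
#' @param e expected cases inside the cylinder, `0 < e < C`.
#' @param C total observed cases in the study area and period.
#' @return Non-negative log-likelihood ratio(s).
#' @export
poisson_llr <- function(c, e, C) {
  if (any(e <= 0) || any(e >= C))
    stop("expected count e must satisfy 0 < e < C (calibrated expecteds)")
  if (any(c < 0) || any(c > C))
    stop("observed count c must satisfy 0 <= c <= C")
  t1 <- ifelse(c > 0, c * log(c / e), 0)
  t2 <- ifelse(C - c > 0, (C - c) * log((C - c) / (C - e)), 0)
  pmax(t1 + t2, 0)
}

#' Relative risk inside versus outside a cylinder
#'
#' `RR = (c/e) / ((C-c)/(C-e))`: the rate inside the cylinder relative to
#' the rate outside it, both measured against the calibrated expecteds. The
#' observed-to-expected ratio `O/E = c/e` is returned alongside. `RR > 1`
#' exactly when `c > e`; when all cases fall inside (`c = C`) the relative
#' risk is infinite and reported as `Inf`.
#'
#' @inheritParams poisson_llr
#' @return List with elements `oe` and `rr`.
#' @export
relative_risk <- function(c, e, C) {
  if (any(e <= 0) || any(e >= C))
    stop("expected count e must satisfy 0 < e < C (calibrated expecteds)")
  if (any(c < 0) || any(c > C))
    stop("observed count c must satisfy 0 <= c <= C")
  oe <- c / e
  rr <- ifelse(c == C, Inf, oe / ((C - c) / (C - e)))
  list(oe = oe, rr = rr)
}

# great-circle distance matrix (km) between region centroids
.centroid_distances <- function(centroids) {
  pts <- cbind(centroids$longitude, centroids$latitude)
  n <- nrow(pts)
  D <- matrix(0, n, n)
  for (i in seq_len(n))
    D[i, ] <- geosphere::distHaversine(pts[i, , drop = FALSE], pts) / 1000
  D
}

# Enumerate candidate cylinders. Returns info data.frame plus, if
# with_membership, a 0/1 matrix over panel cells (regions vary fastest)
# used by the Monte Carlo machinery.
.enumerate <- function(panel, centroids, expected, config,
                       with_membership = FALSE) {
  I <- length(panel$region_ids)
  J <- length(panel$years)
  D <- .centroid_distances(centroids)
  if (any(D[upper.tri(D)] == 0))
    message("duplicate centroids: ties broken by region order")
  Lmax <- max(1L, floor(config$max_temporal_fraction * J))
  wins <- do.call(rbind, lapply(seq_len(J), function(t1) {
    t2 <- t1:min(J, t1 + Lmax - 1L)
    cbind(t1, t2)
  }))
  W <- nrow(wins)
  # per-window region sums of population, observed, expected
  sumw <- function(M) matrix(vapply(seq_len(W), function(w)
    rowSums(M[, wins[w, 1]:wins[w, 2], drop = FALSE]), numeric(I)), I, W)
  PW <- sumw(panel$population)
  YW <- sumw(panel$observed)
  EW <- sumw(expected$expected)
  rows <- vector("list", I * W)
  memb <- if (with_membership) vector("list", I * W) else NULL
  r <- 0L
  for (ctr in seq_len(I)) {
    ord <- order(D[ctr, ], seq_len(I))   # center first, ties by region order
    for (w in seq_len(W)) {
      cap <- config$max_spatial_fraction * sum(PW[, w])
      cpop <- cumsum(PW[ord, w])
      kmax <- sum(cpop <= cap + 1e-9)
      if (kmax == 0L) next
      cy <- cumsum(YW[ord, w])
      ce <- cumsum(EW[ord, w])
      k <- seq_len(kmax)
      r <- r + 1L
      rows[[r]] <- data.frame(
        center = ctr, k = k,
        start = panel$years[wins[w, 1]], end = panel$years[wins[w, 2]],
        regions = vapply(k, function(kk)
          paste(panel$region_ids[ord[seq_len(kk)]], collapse = "|"),
          character(1)),
        population = cpop[k], c = cy[k], e = ce[k])
      if (with_membership) {
        yrs <- wins[w, 1]:wins[w, 2]
        m <- matrix(0, kmax, I * J)
        cells <- outer(ord, (yrs - 1L) * I, `+`)  # cumulative member cells
        for (kk in k)
          m[kk, as.vector(cells[seq_len(kk), , drop = FALSE])] <- 1
        memb[[r]] <- m
      }
    }
  }
  info <- do.call(rbind, rows[seq_len(r)])
  info$center <- panel$region_ids[info$center]
  out <- list(info = info)
  if (with_membership) out$M <- do.call(rbind, memb[seq_len(r)])
  out
}

#' Enumerate scan cylinders
#'
#' For every center region, member sets grow over the k nearest regions by
#' great-circle centroid distance (the center alone is k = 1), crossed with
#' every time window no longer than the temporal cap; growth stops once the
#' cylinder's person-time exceeds the spatial cap (fraction of the total
#' person-time over the same window). Each cylinder carries its observed and
#' expected case sums.
#'
#' @param panel a [count_panel].
#' @param centroids a [region_centroids].
#' @param expected a per-year [expected_counts] result.
#' @param config a [scan_config].
#' @return data.frame with one row per cylinder: center, k, start, end,
#'   regions (pipe-joined labels, nearest-first), population (person-time),
#'   c, e.
#' @export
enumerate_cylinders <- function(panel, centroids, expected,
                                config = scan_config()) {
  .enumerate(panel, centroids, expected, config)$info
}

#' Retrospective space-time scan
#'
#' Scans all candidate cylinders for high-rate (`c > e`) and/or low-rate
#' (`c < e`) clusters by maximum Poisson log-likelihood ratio. The primary
#' cluster of a direction is the maximum-LLR cylinder; secondary clusters
#' are the next-highest-LLR cylinders sharing no region with any
#' better-ranked reported cluster of the same direction. Pseudo p-values
#' come from Monte Carlo replication under the null: the total case count is
#' redistributed over cells as a multinomial with probabilities proportional
#' to the expected counts, and each replicate contributes its
#' direction-restricted maximum LLR, so
#' `p = (1 + #[null max LLR >= observed LLR]) / (1 + n_monte_carlo)`.
#'
#' @inheritParams enumerate_cylinders
#' @return data.frame of class `scan_result`, one row per reported cluster,
#'   columns cluster_rank, direction, regions, start, end, population,
#'   observed, expected, oe, rr, llr, p_value.
#' @export
scan_clusters <- function(panel, centroids, expected,
                          config = scan_config()) {
  en <- .enumerate(panel, centroids, expected, config,
                   with_membership = TRUE)
  info <- en$info
  y <- as.vector(panel$observed)
  C <- sum(y)
  Etot <- sum(expected$expected)
  e <- info$e * (C / Etot)               # E[C] = C calibration
  cobs <- info$c
  ok <- e > 0 & e < C
  llr <- rep(0, nrow(info))
  llr[ok] <- poisson_llr(cobs[ok], e[ok], C)
  # null replicates: conditional multinomial redistribution of the cases,
  # stratified by year when the expecteds are year-calibrated (the year
  # totals are then fixed by construction, so the null must fix them too)
  set.seed(config$seed)
  B <- config$n_monte_carlo
  if (identical(expected$stratification, "per_year")) {
    I <- length(panel$region_ids)
    Yrep <- do.call(rbind, lapply(seq_along(panel$years), function(j) {
      Cj <- sum(panel$observed[, j])
      if (Cj == 0) matrix(0L, I, B)
      else stats::rmultinom(B, Cj, expected$expected[, j])
    }))
  } else {
    Yrep <- stats::rmultinom(B, C, as.vector(expected$expected) / Etot)
  }
  Crep <- en$M %*% Yrep                  # cylinders x replicates
  Lrep <- matrix(0, nrow(Crep), ncol(Crep))
  Lrep[ok, ] <- poisson_llr(Crep[ok, , drop = FALSE], e[ok], C)
  null_max <- list(
    high = apply(Lrep * (Crep > e), 2, max),
    low  = apply(Lrep * (Crep < e), 2, max))
  out <- list()
  for (dir in config$directions) {
    keep <- if (dir == "high") cobs > e else cobs < e
    keep <- keep & ok & llr > 0
    if (!any(keep)) next
    idx <- which(keep)[order(-llr[keep])]
    reported <- integer(0)
    used_regions <- character(0)
    for (i in idx) {
      regs <- strsplit(info$regions[i], "|", fixed = TRUE)[[1]]
      if (length(intersect(regs, used_regions))) next
      reported <- c(reported, i)
      used_regions <- c(used_regions, regs)
    }
    rr <- relative_risk(cobs[reported], e[reported], C)
    p <- vapply(llr[reported], function(l)
      (1 + sum(null_max[[dir]] >= l)) / (1 + B), numeric(1))
    out[[dir]] <- data.frame(
      cluster_rank = c("primary", rep("secondary",
                                      max(0, length(reported) - 1))),
      direction = dir,
      regions = info$regions[reported],
      start = info$start[reported], end = info$end[reported],
      population = info$population[reported],
      observed = cobs[reported], expected = e[reported],
      oe = rr$oe, rr = rr$rr, llr = llr[reported], p_value = p)
  }
  res <- if (length(out)) do.call(rbind, out) else data.frame(
    cluster_rank = character(0), direction = character(0),
    regions = character(0), start = integer(0), end = integer(0),
    population = numeric(0), observed = numeric(0), expected = numeric(0),
    oe = numeric(0), rr = numeric(0), llr = numeric(0),
    p_value = numeric(0))
  rownames(res) <- NULL
  attr(res, "n_cylinders") <- nrow(info)
  attr(res, "null_max") <- null_max
  class(res) <- c("scan_result", "data.frame")
  res
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("space-time scan: %d reported cluster(s) over %d cylinders\n",
              nrow(x), attr(x, "n_cylinders")))
  print.data.frame(x, digits = 4)
  invisible(x)
}
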