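# shared validation for criterion functions: any list with loglik / theta /
# y / E matrices duck-types as a fit, so closed-form posteriors can be fed
# to the same code paths in tests
.check_fit <- function(fit, force = FALSE) {
  stopifnot(is.matrix(fit$loglik))
  if (!is.null(fit$valid) && !fit$valid && !force)
    stop("fit is flagged invalid (non-convergence); use force = TRUE")
  invisible(fit)
}

.log_mean_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(mean(exp(x - m)))
}

#' Deviance information criterion
#'
#' `DIC = Dbar + pD` with `Dbar` the posterior mean deviance and
#' `pD = Dbar - D(plug-in)`, the plug-in deviance evaluated at the
#' posterior mean of the linear predictor (`log theta`), not of `theta`.
#'
#' @param fit a [fit_st_model] result (or compatible list with `loglik`,
#'   `theta`, `y`, `E`).
#' @param force accept fits flagged as non-converged.
#' @return List with `dic` and `p_dic`.
#' @export
dic <- function(fit, force = FALSE) {
  .check_fit(fit, force)
  dbar <- mean(-2 * rowSums(fit$loglik))
  eta_bar <- colMeans(log(fit$theta))
  dhat <- -2 * sum(stats::dpois(fit$y, fit$E * exp(eta_bar), log = TRUE))
  list(dic = dbar + (dbar - dhat), p_dic = dbar - dhat)
}

#' Watanabe-Akaike information criterion
#'
#' `WAIC = -2 (lppd - pW)`: `lppd` is the log pointwise predictive density
#' (log of the posterior-mean likelihood per cell, summed) and
#' `pW` the summed posterior variance of the per-cell log-likelihood.
#'
#' @inheritParams dic
#' @return List with `waic` and `p_waic`.
#' @export
waic <- function(fit, force = FALSE) {
  .check_fit(fit, force)
  lppd <- sum(apply(fit$loglik, 2, .log_mean_exp))
  p_w <- if (nrow(fit$loglik) < 2) 0
  else sum(apply(fit$loglik, 2, stats::var))
  list(waic = -2 * (lppd - p_w), p_waic = p_w)
}

#' Conditional predictive ordinates
#'
#' Per-cell leave-one-out predictive density estimated by the harmonic mean
#' of the cell likelihood over posterior draws:
#' `CPO = 1 / mean(1 / lik)`. The harmonic-mean estimator can be unstable;
#' cells whose inverse-likelihood weights have coefficient of variation
#' above `cv_threshold` are flagged. Cells with any zero-likelihood draw
#' are flagged and excluded from the sum with a warning.
#'
#' @inheritParams dic
#' @param cv_threshold flag cells whose inverse-likelihood CV exceeds this.
#' @return List with `cpo` (per-cell vector), `sum_log_cpo`, and `flagged`
#'   (cell indices).
#' @export
cpo <- function(fit, force = FALSE, cv_threshold = 20) {
  .check_fit(fit, force)
  inv <- exp(-fit$loglik)
  bad <- which(apply(inv, 2, function(v) any(!is.finite(v))))
  cpo_k <- 1 / colMeans(inv)
  cv <- apply(inv, 2, function(v) stats::sd(v) / mean(v))
  flagged <- sort(union(bad, which(is.finite(cv) & cv > cv_threshold)))
  if (length(bad)) {
    warning(length(bad),
            " cell(s) with zero-likelihood draws excluded from sum_log_cpo")
    cpo_k[bad] <- NA_real_
  }
  list(cpo = cpo_k,
       sum_log_cpo = sum(log(cpo_k), na.rm = TRUE),
       flagged = flagged)
}

#' Probability integral transform (mid-PIT for counts)
#'
#' For each cell, `PIT = mean F(y; lambda_draw) - 0.5 mean f(y; lambda_draw)`
#' over posterior draws, with `F`/`f` the Poisson CDF/PMF at
#' `lambda = E theta`. The mid-correction makes the PIT of a calibrated
#' model for discrete counts approximately Uniform(0, 1); the uncorrected
#' PIT is non-uniform even under the true model.
#'
#' @inheritParams dic
#' @return Numeric vector in [0, 1], one value per cell.
#' @export
pit <- function(fit, force = FALSE) {
  .check_fit(fit, force)
  lambda <- sweep(fit$theta, 2, fit$E, `*`)
  n <- ncol(lambda)
  vapply(seq_len(n), function(k) {
    mean(stats::ppois(fit$y[k], lambda[, k])) -
      0.5 * mean(stats::dpois(fit$y[k], lambda[, k]))
  }, numeric(1))
}

# asymptotic CDF of the Anderson-Darling statistic for a fully specified
# null (Marsaglia & Marsaglia 2004 approximation, max error ~ 2e-6)
.ad_cdf <- function(z) {
  if (z <= 0) return(0)
  if (z < 2)
    exp(-1.2337141 / z) / sqrt(z) *
      (2.00012 + (0.247105 - (0.0649821 - (0.0347962 -
        (0.011672 - 0.00168691 * z) * z) * z) * z) * z)
  else
    exp(-exp(1.0776 - (2.30695 - (0.43424 - (0.082433 -
      (0.008056 - 0.0003146 * z) * z) * z) * z) * z))
}

#' Anderson-Darling test of Uniform(0, 1)
#'
#' The fully-specified-distribution case:
#' `A2 = -n - (1/n) sum (2k - 1) [ln U_(k) + ln(1 - U_(n+1-k))]`, with the
#' p-value from the asymptotic null distribution of A2.
#'
#' @param u numeric vector in [0, 1], length >= 5.
#' @return List with `statistic` and `p_value`.
#' @export
anderson_darling_uniform <- function(u) {
  n <- length(u)
  if (n < 5) stop("need at least 5 values for the Anderson-Darling test")
  if (any(u < 0 | u > 1)) stop("values must lie in [0, 1]")
  us <- pmin(pmax(sort(u), 1e-12), 1 - 1e-12)
  k <- seq_len(n)
  a2 <- -n - mean((2 * k - 1) * (log(us) + log(1 - rev(us))))
  list(statistic = a2, p_value = 1 - .ad_cdf(a2))
}

#' SIR-scale R-squared of a fitted model
#'
#' Default: squared Pearson correlation between the crude SIRs and the
#' posterior-mean smoothed SIRs across cells — how much of the crude SIR
#' variability the model reproduces. Alternative: a deviance-based
#' pseudo-R-squared, `1 - D(model) / D(null)` with the null a single
#' common relative risk.
#'
#' @inheritParams dic
#' @param crude a [crude_sir] matrix (correlation method only).
#' @param method `"correlation"` (default) or `"deviance"`.
#' @return Scalar, at most 1.
#' @export
r_squared <- function(fit, crude = NULL, method = c("correlation",
                                                    "deviance"),
                      force = FALSE) {
  .check_fit(fit, force)
  method <- match.arg(method)
  if (method == "correlation") {
    if (is.null(crude)) stop("crude SIR matrix required")
    x <- as.vector(unclass(crude))
    yv <- fit$theta_mean
    if (stats::sd(yv, na.rm = TRUE) == 0) return(0)
    stats::cor(x, yv, use = "complete.obs")^2
  } else {
    eta_bar <- colMeans(log(fit$theta))
    dmod <- -2 * sum(stats::dpois(fit$y, fit$E * exp(eta_bar), log = TRUE))
    theta0 <- sum(fit$y) / sum(fit$E)
    dnull <- -2 * sum(stats::dpois(fit$y, fit$E * theta0, log = TRUE))
    1 - dmod / dnull
  }
}

#' Goodness-of-fit comparison across fitted models
#'
#' One row per fit with DIC, WAIC, sum log CPO, R-squared and the
#' Anderson-Darling uniformity test of the PIT values. The best-fitting
#' model by the conventional rule (lower DIC/WAIC, higher sum log CPO and
#' R-squared) is flagged using WAIC as the ordering criterion.
#'
#' @param fits named list of [fit_st_model] results.
#' @param crude a [crude_sir] matrix for the R-squared column.
#' @param force accept fits flagged as non-converged.
#' @return data.frame, one row per model, with a logical `best` column.
#' @export
compare_models <- function(fits, crude, force = FALSE) {
  stopifnot(length(fits) >= 1)
  nm <- names(fits)
  if (is.null(nm)) nm <- paste0("model", seq_along(fits))
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    d <- dic(f, force)
    w <- waic(f, force)
    cp <- cpo(f, force)
    p <- pit(f, force)
    ad <- anderson_darling_uniform(p)
    data.frame(model = nm[i], dic = d$dic, p_dic = d$p_dic,
               waic = w$waic, p_waic = w$p_waic,
               sum_log_cpo = cp$sum_log_cpo,
               r2 = r_squared(f, crude, force = force),
               ad_statistic = ad$statistic, ad_p = ad$p_value)
  })
  out <- do.call(rbind, rows)
  out$best <- seq_len(nrow(out)) == which.min(out$waic)
  out
}
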