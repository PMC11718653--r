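#' Fit a discrete power law to a count sequence
#'
#' Fits the discrete power-law model \eqn{p(k) \propto k^{-\alpha}}, \eqn{k \ge
#' k_{min}}, to a sequence of non-negative integer counts (node degrees, bait
#' usages, ...). The lower cutoff `kmin` is selected by minimising the
#' Kolmogorov-Smirnov (KS) distance between the empirical tail CDF and the
#' fitted model CDF over all candidate cutoffs (every distinct observed value
#' with at least two tail observations); for each candidate the exponent
#' \eqn{\alpha} is the maximiser of the discrete log-likelihood
#' \eqn{\ell(\alpha) = -n_{tail} \ln \zeta(\alpha, k_{min}) - \alpha \sum \ln
#' k_i}, found by golden-section search on `(1.01, alpha_max]`. Ties in the KS
#' distance are broken towards the smallest cutoff (largest tail).
#'
#' Zeros are removed before fitting (isolated nodes carry no tail information);
#' their count is kept in the returned object. If fewer than two distinct
#' positive values remain, estimation fails with an error of class
#' `"baitbias_fit_error"`.
#'
#' @param x Numeric vector of non-negative integers.
#' @param alpha_max Upper bound of the exponent search interval (default 6).
#' @return An object of class `"plfit"` with components `kmin`, `alpha`, `ks`,
#'   `ntail`, `n` (number of positive observations), `n_zero`, and `data`
#'   (the positive observations, sorted). Supports `print()`, `summary()`,
#'   `coef()`, `logLik()`, `plot()`, and `simulate()`.
#' @seealso [bootstrap_gof()] for the goodness-of-fit test, [rpowerlaw()] for
#'   sampling from the fitted family.
#' @examples
#' x <- rpowerlaw(500, alpha = 2.5, kmin = 1, seed = 1)
#' fit <- fit_power_law(x)
#' fit
#' coef(fit)
#' @export
fit_power_law <- function(x, alpha_max = 6) {
  if (!is.numeric(x) || length(x) == 0L) {
    stop_baitbias("`x` must be a non-empty numeric vector", "baitbias_invalid_parameter")
  }
  if (any(is.na(x)) || any(x < 0) || any(x != floor(x))) {
    stop_baitbias("`x` must contain non-negative integers", "baitbias_invalid_parameter")
  }
  n_zero <- sum(x == 0)
  pos <- sort.int(as.integer(x[x > 0]), method = "radix")
  if (length(unique(pos)) < 2L) {
    stop_baitbias(
      "power-law estimation failed: need >= 2 distinct positive values",
      "baitbias_fit_error"
    )
  }
  res <- .fit_pl_cpp(pos, 1.01, alpha_max)
  if (is.na(res$kmin)) {
    stop_baitbias("power-law estimation failed: no admissible cutoff",
                  "baitbias_fit_error")
  }
  structure(
    list(
      kmin = res$kmin, alpha = res$alpha, ks = res$ks, ntail = res$ntail,
      n = length(pos), n_zero = as.integer(n_zero), data = pos,
      alpha_max = alpha_max, call = match.call()
    ),
    class = "plfit"
  )
}

#' @export
print.plfit <- function(x, ...) {
  cat("Discrete power-law fit\n")
  cat(sprintf("  kmin = %d, alpha = %.4f, KS = %.4f\n", x$kmin, x$alpha, x$ks))
  cat(sprintf("  tail: %d of %d positive observations (%d zeros excluded)\n",
              x$ntail, x$n, x$n_zero))
  invisible(x)
}

#' @export
coef.plfit <- function(object, ...) {
  c(alpha = object$alpha, kmin = object$kmin)
}

#' @export
logLik.plfit <- function(object, ...) {
  tail <- object$data[object$data >= object$kmin]
  ll <- -object$ntail * log(hurwitz_zeta(object$alpha, object$kmin)) -
    object$alpha * sum(log(tail))
  structure(ll, df = 2L, nobs = object$ntail, class = "logLik")
}

#' @export
summary.plfit <- function(object, ...) {
  out <- list(
    fit = object,
    logLik = as.numeric(logLik(object)),
    tail_fraction = object$ntail / object$n,
    zero_fraction = object$n_zero / (object$n + object$n_zero),
    mean_tail = mean(object$data[object$data >= object$kmin])
  )
  class(out) <- "summary.plfit"
  out
}

#' @export
print.summary.plfit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  log-likelihood (tail): %.2f\n", x$logLik))
  cat(sprintf("  tail fraction: %.3f, zero fraction: %.3f, mean tail value: %.2f\n",
              x$tail_fraction, x$zero_fraction, x$mean_tail))
  invisible(x)
}

#' @export
plot.plfit <- function(x, ...,
                       xlab = "k", ylab = "Pr[K >= k]",
                       main = "Empirical CCDF and fitted power law") {
  vals <- sort(unique(x$data))
  ccdf <- vapply(vals, function(v) mean(x$data >= v), numeric(1))
  graphics::plot(vals, ccdf, log = "xy", pch = 16, cex = 0.6,
                 xlab = xlab, ylab = ylab, main = main, ...)
  tail_vals <- vals[vals >= x$kmin]
  z <- hurwitz_zeta(x$alpha, x$kmin)
  model_ccdf <- hurwitz_zeta(x$alpha, tail_vals) / z * (x$ntail / x$n)
  graphics::lines(tail_vals, model_ccdf, col = "red", lwd = 2)
  invisible(x)
}

#' Simulate datasets from a fitted power law
#'
#' Draws semi-parametric replicates of the data underlying a [fit_power_law()]
#' fit: each observation comes from the fitted tail power law with probability
#' `ntail / n`, and otherwise is resampled uniformly from the observed body
#' (values below `kmin`). This is the replicate scheme used by
#' [bootstrap_gof()].
#'
#' @param object A `"plfit"` object.
#' @param nsim Number of replicate datasets.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A list of `nsim` integer vectors, each of length `object$n`.
#' @export
simulate.plfit <- function(object, nsim = 1, seed = NULL, ...) {
  nsim <- check_count(nsim, "nsim", min = 1)
  with_seed(seed, {
    sampler <- make_pl_sampler(object$alpha, object$kmin)
    body <- object$data[object$data < object$kmin]
    p_tail <- object$ntail / object$n
    lapply(seq_len(nsim), function(i) {
      k_tail <- stats::rbinom(1L, object$n, p_tail)
      out <- integer(object$n)
      if (k_tail > 0) out[seq_len(k_tail)] <- sampler(k_tail)
      if (k_tail < object$n) {
        out[(k_tail + 1L):object$n] <-
          sample(body, object$n - k_tail, replace = TRUE)
      }
      out
    })
  })
}

# Sampler factory for the discrete power law: returns function(m) drawing m
# i.i.d. values via inverse-CDF lookup on a lazily grown table; the rare
# quantiles beyond the table are resolved exactly with Hurwitz zeta.
make_pl_sampler <- function(alpha, kmin) {
  z <- hurwitz_zeta(alpha, kmin)
  table_len <- 1024L
  cdf <- cumsum((kmin - 1 + seq_len(table_len))^(-alpha)) / z
  grow <- function(target) {
    while (cdf[length(cdf)] < target && length(cdf) < 2^24) {
      old_len <- length(cdf)
      extra <- (kmin - 1 + old_len + seq_len(old_len))^(-alpha)
      cdf <<- c(cdf, cdf[old_len] + cumsum(extra) / z)
    }
  }
  function(m) {
    u <- stats::runif(m)
    umax <- max(u)
    if (cdf[length(cdf)] < umax) grow(umax)
    k <- kmin + findInterval(u, cdf)
    over <- which(k > kmin - 1 + length(cdf)) # beyond table: solve exactly
    for (i in over) {
      kk <- kmin + length(cdf)
      while (1 - hurwitz_zeta(alpha, kk + 1) / z < u[i]) kk <- kk + 1L
      k[i] <- kk
    }
    as.integer(k)
  }
}

#' Sample from a discrete power-law distribution
#'
#' Draws i.i.d. samples with PMF \eqn{k^{-\alpha} / \zeta(\alpha, k_{min})} for
#' integer \eqn{k \ge k_{min}}, by exact inverse-CDF inversion.
#'
#' @param n Number of samples.
#' @param alpha Scaling exponent, must exceed 1 (the distribution is not
#'   normalisable otherwise).
#' @param kmin Lower cutoff (positive integer, default 1).
#' @param seed Optional integer seed.
#' @return Integer vector of length `n`, all values `>= kmin`.
#' @examples
#' x <- rpowerlaw(1000, alpha = 3.13, seed = 42)
#' mean(x == 1) # approx 1 / zeta(3.13) = 0.849
#' @export
rpowerlaw <- function(n, alpha, kmin = 1, seed = NULL) {
  n <- check_count(n, "n", min = 0)
  kmin <- check_count(kmin, "kmin", min = 1)
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha <= 1) {
    stop_baitbias("`alpha` must be > 1", "baitbias_invalid_parameter")
  }
  if (n == 0L) return(integer(0))
  with_seed(seed, make_pl_sampler(alpha, kmin)(n))
}

#' Bootstrap goodness-of-fit test for a power-law fit
#'
#' Semi-parametric bootstrap test of the power-law hypothesis: `n_boot`
#' replicate datasets are drawn from the fitted model (tail from the fitted
#' power law, body resampled from the observed values below `kmin`), each
#' replicate is re-fitted from scratch, and the p-value is the fraction of
#' replicate KS distances that are at least as large as the observed one.
#'
#' A replicate whose re-fit fails (e.g. all sampled values identical) counts
#' as failed; if more than 10% of replicates fail, the test is marked invalid.
#' The power law is considered a plausible model when the test is valid and
#' the p-value is at least 0.1 (the conventional threshold).
#'
#' @param fit A `"plfit"` object from [fit_power_law()].
#' @param n_boot Number of bootstrap replicates (default 100).
#' @param seed Optional integer seed.
#' @return An object of class `"plgof"` with components `p_value`, `n_boot`,
#'   `n_failed`, `valid`, `plausible`, `ks_obs` and `ks_boot`.
#' @examples
#' x <- rpowerlaw(300, alpha = 2.5, seed = 7)
#' gof <- bootstrap_gof(fit_power_law(x), n_boot = 50, seed = 8)
#' is_plausible(gof)
#' @export
bootstrap_gof <- function(fit, n_boot = 100, seed = NULL) {
  stopifnot(inherits(fit, "plfit"))
  n_boot <- check_count(n_boot, "n_boot", min = 1)
  with_seed(seed, {
    sampler <- make_pl_sampler(fit$alpha, fit$kmin)
    body <- fit$data[fit$data < fit$kmin]
    p_tail <- fit$ntail / fit$n
    ks_boot <- rep(NA_real_, n_boot)
    for (r in seq_len(n_boot)) {
      k_tail <- stats::rbinom(1L, fit$n, p_tail)
      x <- integer(fit$n)
      if (k_tail > 0) x[seq_len(k_tail)] <- sampler(k_tail)
      if (k_tail < fit$n) {
        x[(k_tail + 1L):fit$n] <- sample(body, fit$n - k_tail, replace = TRUE)
      }
      x <- sort.int(x, method = "radix")
      if (x[1] != x[fit$n]) { # needs >= 2 distinct values to be fittable
        refit <- .fit_pl_cpp(x, 1.01, fit$alpha_max)
        if (!is.na(refit$kmin)) ks_boot[r] <- refit$ks
      }
    }
    n_failed <- sum(is.na(ks_boot))
    ok <- ks_boot[!is.na(ks_boot)]
    p_value <- if (length(ok) > 0) mean(ok >= fit$ks) else NA_real_
    valid <- n_failed <= 0.1 * n_boot && !is.na(p_value)
    structure(
      list(
        p_value = p_value, n_boot = n_boot, n_failed = n_failed,
        valid = valid, plausible = valid && p_value >= 0.1,
        ks_obs = fit$ks, ks_boot = ks_boot
      ),
      class = "plgof"
    )
  })
}

#' @export
print.plgof <- function(x, ...) {
  cat("Bootstrap goodness-of-fit test for power-law hypothesis\n")
  cat(sprintf("  p-value = %s (%d bootstrap replicates, %d failed)\n",
              format(x$p_value, digits = 3), x$n_boot, x$n_failed))
  cat(sprintf("  valid: %s; power law plausible (p >= 0.1): %s\n",
              x$valid, x$plausible))
  invisible(x)
}

#' Is the power law a plausible model?
#'
#' Convention: the power law is plausible if the bootstrap goodness-of-fit
#' test is valid (at most 10% failed replicates) and its p-value is >= 0.1.
#'
#' @param gof A `"plgof"` object from [bootstrap_gof()].
#' @return Logical flag.
#' @export
is_plausible <- function(gof) {
  stopifnot(inherits(gof, "plgof"))
  isTRUE(gof$valid) && !is.na(gof$p_value) && gof$p_value >= 0.1
}
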