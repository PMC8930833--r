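#' Fit a two-Gaussian intensity mixture to a kymograph
#'
#' Fits a univariate two-component Gaussian mixture to the pixel intensities
#' of the non-excluded frames by EM (k-means initialization at the lower and
#' upper intensity quartiles, log-likelihood tolerance 1e-6, at most 500
#' iterations), then derives the binarization threshold as the intensity
#' between the two component means at which the posterior responsibilities
#' are equal. If no crossing lies between the means, the threshold falls
#' back to the midpoint of the means.
#'
#' The two components share a pooled standard deviation by default
#' (`equal_var = TRUE`): with separate variances the foreground component
#' absorbs the partial-volume edge ramp of the vessel, drags its mean down,
#' and the posterior crossing lands well below the half-intensity level,
#' biasing binarized widths upward. The pooled fit keeps both means on the
#' intensity plateaus and the threshold near their midpoint.
#'
#' @param kymo A `Kymograph`, or a plain numeric vector of intensities.
#' @param max_iter Maximum EM iterations.
#' @param tol Convergence tolerance on the log-likelihood.
#' @param equal_var Share one pooled SD between the components (default)?
#' @return A `MixtureFit` list: `mu_bg`, `sd_bg`, `w_bg`, `mu_fg`, `sd_fg`,
#'   `w_fg`, `threshold`, `loglik`, `iterations`.
#' @export
fit_intensity_mixture <- function(kymo, max_iter = 500, tol = 1e-6,
                                  equal_var = TRUE) {
  x <- if (inherits(kymo, "Kymograph")) {
    as.vector(kymo$grid[, !kymo$excluded, drop = FALSE])
  } else {
    as.numeric(kymo)
  }
  if (length(x) < 100) stopf("need >= 100 pixels to fit the mixture")
  rng <- diff(range(x))
  if (rng == 0) stopf("unimodal histogram: all pixel intensities identical")

  centers <- unname(stats::quantile(x, c(0.25, 0.75)))
  if (diff(centers) == 0) centers <- range(x)
  km <- stats::kmeans(x, centers = matrix(centers, ncol = 1))
  ord <- order(km$centers)
  mu <- as.numeric(km$centers[ord])
  grp <- match(km$cluster, ord)
  # SD floor at the 8-bit quantization scale, so constant plateaus (e.g.
  # noise-free synthetic data) do not collapse a component
  sd_floor <- max(0.3, 1e-3 * rng)
  sg <- vapply(1:2, function(g) stats::sd(x[grp == g]), numeric(1))
  sg[is.na(sg) | sg < sd_floor] <- 0.05 * rng
  if (equal_var) sg <- rep(sqrt(mean(sg^2)), 2)
  wt <- tabulate(grp, 2) / length(x)

  ll_old <- -Inf
  it <- 0
  repeat {
    it <- it + 1
    d1 <- wt[1] * stats::dnorm(x, mu[1], sg[1])
    d2 <- wt[2] * stats::dnorm(x, mu[2], sg[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    r2 <- d2 / tot
    r1 <- 1 - r2
    n1 <- sum(r1); n2 <- sum(r2)
    mu <- c(sum(r1 * x) / n1, sum(r2 * x) / n2)
    sg <- if (equal_var) {
      rep(sqrt((sum(r1 * (x - mu[1])^2) + sum(r2 * (x - mu[2])^2)) /
                 length(x)), 2)
    } else {
      sqrt(c(sum(r1 * (x - mu[1])^2) / n1, sum(r2 * (x - mu[2])^2) / n2))
    }
    sg <- pmax(sg, sd_floor)
    wt <- c(n1, n2) / length(x)
    if (any(!is.finite(sg)) || any(!is.finite(mu)))
      stopf("unimodal histogram: mixture component collapsed")
    if (abs(ll - ll_old) < tol) break
    if (it >= max_iter) stopf("EM did not converge in %d iterations", max_iter)
    ll_old <- ll
  }
  if (mu[1] > mu[2]) {
    mu <- rev(mu); sg <- rev(sg); wt <- rev(wt)
  }
  thr <- mixture_threshold(mu, sg, wt)
  structure(
    list(mu_bg = mu[1], sd_bg = sg[1], w_bg = wt[1],
         mu_fg = mu[2], sd_fg = sg[2], w_fg = wt[2],
         threshold = thr, loglik = ll, iterations = it),
    class = "MixtureFit"
  )
}

# Posterior-equality point between the two means: solve
# w1 * N(x; mu1, s1) = w2 * N(x; mu2, s2) and keep a root strictly between
# the means; midpoint of means if none exists. With strongly unequal
# component variances the crossing degenerates toward the low-variance
# mean (it then misclassifies the partial-volume edge ramp), so the
# threshold is clamped to the central band between the means; outside the
# band the midpoint is used. Symmetric mixtures are unaffected: their
# crossing is the midpoint exactly.
mixture_threshold <- function(mu, sg, wt, band = 0.2) {
  a <- 1 / sg[2]^2 - 1 / sg[1]^2
  b <- 2 * (mu[1] / sg[1]^2 - mu[2] / sg[2]^2)
  cc <- mu[2]^2 / sg[2]^2 - mu[1]^2 / sg[1]^2 +
    2 * log((wt[1] * sg[2]) / (wt[2] * sg[1]))
  mid <- mean(mu)
  roots <- if (abs(a) < 1e-12 * (1 / sg[1]^2)) {
    if (abs(b) < 1e-300) numeric(0) else -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) numeric(0) else (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  }
  delta <- mu[2] - mu[1]
  inside <- roots[roots > mu[1] + band * delta & roots < mu[2] - band * delta]
  if (length(inside) == 0) mid else inside[which.min(abs(inside - mid))]
}
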