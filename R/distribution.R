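# Distributions p(sigma) of the hyperfine spectrum width -- the central
# inversion output and the input of the heterogeneous forward model.

#' Distribution of hyperfine spectrum widths
#'
#' Constructs a normalized, non-negative distribution p(sigma) on an
#' ascending sigma grid (angular MHz). The trapezoid integral of the weights
#' is normalized to 1.
#'
#' @param sigma Strictly increasing grid of sigma values (angular MHz).
#' @param weights Non-negative weights, same length as `sigma`.
#' @param normalize Renormalize to unit trapezoid integral (default `TRUE`).
#' @return An object of class `"density_distribution"`: a list with elements
#'   `sigma` and `p`.
#' @seealso [dist_delta()], [dist_gaussian()], [distribution_stats()]
#' @export
density_distribution <- function(sigma, weights, normalize = TRUE) {
  sigma <- as.numeric(sigma)
  weights <- as.numeric(weights)
  if (length(sigma) != length(weights)) stop("sigma and weights lengths differ")
  if (any(diff(sigma) <= 0)) stop("sigma grid must be strictly increasing")
  if (any(!is.finite(weights)) || any(weights < -1e-12))
    stop("weights must be finite and non-negative")
  weights[weights < 0] <- 0
  if (normalize) {
    z <- trapz(sigma, weights)
    if (z <= 0) stop("distribution has zero mass")
    weights <- weights / z
  }
  structure(list(sigma = sigma, p = weights), class = "density_distribution")
}

#' Delta-like distribution on a grid
#'
#' Places all mass on the grid point nearest `sigma0`.
#'
#' @param sigma0 Location of the spike (angular MHz).
#' @param grid Sigma grid.
#' @export
dist_delta <- function(sigma0, grid = seq(0, 1.5, length.out = 81)) {
  w <- numeric(length(grid))
  w[which.min(abs(grid - sigma0))] <- 1
  density_distribution(grid, w)
}

#' Gaussian distribution of sigma on a grid
#'
#' @param mean,sd Centre and standard deviation (angular MHz).
#' @param grid Sigma grid.
#' @export
dist_gaussian <- function(mean, sd, grid = seq(0, 1, length.out = 81)) {
  density_distribution(grid, stats::dnorm(grid, mean, sd))
}

#' Mixture of distributions on a common grid
#'
#' @param components List of `density_distribution` objects on identical grids.
#' @param weights Mixture weights (default equal).
#' @export
dist_mixture <- function(components, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(components))
  g <- components[[1]]$sigma
  for (d in components) {
    if (!isTRUE(all.equal(d$sigma, g))) stop("component grids differ")
  }
  p <- Reduce(`+`, Map(function(d, w) w * d$p, components, weights))
  density_distribution(g, p)
}

#' Moments of a sigma distribution
#'
#' Trapezoid-quadrature mean, standard deviation and skewness of p(sigma).
#'
#' @param dist A `density_distribution`.
#' @return Named numeric vector `c(mean, sd, skewness)`. The skewness of a
#'   zero-width (delta-like) distribution is reported as 0.
#' @export
distribution_stats <- function(dist) {
  stopifnot(inherits(dist, "density_distribution"))
  s <- dist$sigma; p <- dist$p
  z <- trapz(s, p)
  m <- trapz(s, s * p) / z
  v <- trapz(s, (s - m)^2 * p) / z
  sk <- if (v > 0) trapz(s, (s - m)^3 * p) / z / v^1.5 else 0
  c(mean = m, sd = sqrt(max(v, 0)), skewness = sk)
}

# number of local maxima of p with topographic prominence of at least
# rel * max(p) -- detects noise-induced splitting of fitted distributions
# while ignoring sub-threshold ripples; plateaus count once and boundary
# peaks count
local_maxima <- function(p, rel = 0.05) {
  p <- as.numeric(p)
  thr <- rel * max(p)
  keep <- c(TRUE, diff(p) != 0)   # compress plateaus
  q <- p[keep]
  m <- length(q)
  peaks <- integer(0)
  if (m >= 3) {
    for (i in 2:(m - 1)) if (q[i] > q[i - 1] && q[i] > q[i + 1]) peaks <- c(peaks, i)
  }
  if (m >= 2) {
    if (q[1] > q[2]) peaks <- c(1L, peaks)
    if (q[m] > q[m - 1]) peaks <- c(peaks, m)
  }
  count <- 0L
  for (i in peaks) {
    lmin <- Inf; j <- i - 1L; higher_l <- FALSE
    while (j >= 1L) {
      if (q[j] > q[i]) { higher_l <- TRUE; break }
      lmin <- min(lmin, q[j]); j <- j - 1L
    }
    rmin <- Inf; j <- i + 1L; higher_r <- FALSE
    while (j <= m) {
      if (q[j] > q[i]) { higher_r <- TRUE; break }
      rmin <- min(rmin, q[j]); j <- j + 1L
    }
    saddle <- if (higher_l && higher_r) max(lmin, rmin) else min(lmin, rmin, 0)
    if (q[i] - saddle >= thr) count <- count + 1L
  }
  count
}

#' @export
print.density_distribution <- function(x, ...) {
  st <- distribution_stats(x)
  cat("p(sigma) on [", format(min(x$sigma)), ",", format(max(x$sigma)),
      "] angular MHz,", length(x$sigma), "points\n")
  cat(sprintf("  mean %.4f  sd %.4f  skewness %.3f\n",
              st["mean"], st["sd"], st["skewness"]))
  invisible(x)
}

#' @export
plot.density_distribution <- function(x, ...,
                                      xlab = expression(sigma ~ "(angular MHz)"),
                                      ylab = expression(p(sigma)), type = "l") {
  graphics::plot(x$sigma, x$p, type = type, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' @export
mean.density_distribution <- function(x, ...) {
  unname(distribution_stats(x)["mean"])
}
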