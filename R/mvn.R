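# Multivariate-normal rectangle probabilities.
#
# All power functions reduce to K-dimensional normal CDF / orthant
# probabilities. These are evaluated with mvtnorm using the deterministic
# Miwa lattice algorithm by default, so that integer sample sizes are stable
# across runs; the randomized Genz-Bretz algorithm is available for larger K.

lp_mvn_algorithm <- function(abseps = 1e-7, algorithm = c("miwa", "genz"),
                             steps = 2048L) {
  algorithm <- match.arg(algorithm)
  if (algorithm == "miwa") {
    mvtnorm::Miwa(steps = steps)
  } else {
    mvtnorm::GenzBretz(abseps = abseps, maxpts = 50000L)
  }
}

# P(l < Z < u) for Z ~ N_K(0, corr). Returns value with "error" attribute.
mvn_rectangle <- function(lower, upper, corr, abseps = 1e-7,
                          algorithm = c("miwa", "genz")) {
  K <- length(upper)
  stopifnot(length(lower) == K)
  if (K == 1L) {
    p <- pnorm(upper) - pnorm(lower)
    attr(p, "error") <- 0
    return(p)
  }
  alg <- lp_mvn_algorithm(abseps, algorithm)
  # +/-37 sd is 0/1 at double precision; avoids Miwa's Inf-clamping warning
  lower <- pmax(lower, -37)
  upper <- pmin(upper, 37)
  p <- mvtnorm::pmvnorm(lower = lower, upper = upper, corr = corr,
                        algorithm = alg)
  err <- attr(p, "error")
  if (is.null(err) || is.na(err)) err <- 0
  if (is.na(p) || p < -1e-8) {
    lp_abort("multivariate-normal quadrature failed",
             class = "lp_error_numeric")
  }
  out <- min(max(as.numeric(p), 0), 1)
  attr(out, "error") <- as.numeric(err)
  out
}

# Phi_K(upper; corr)
mvn_cdf <- function(upper, corr, ...) {
  mvn_rectangle(rep(-Inf, length(upper)), upper, corr, ...)
}

# P(Z_k > lower_k for all k) = Phi_K(-lower; corr) by symmetry
mvn_upper_orthant <- function(lower, corr, ...) {
  mvn_cdf(-lower, corr, ...)
}

# Vectorized bivariate-normal rectangle probabilities with a common 2x2
# covariance and per-row means: the first coordinate is integrated by
# Gauss-Legendre quadrature and the second enters through its conditional
# univariate normal CDF. Used by the likelihood when exactly two discrete
# outcomes are present (one rectangle per patient).
bvn_rect_rows <- function(lo, hi, mean_mat, cov2, nodes = 40L) {
  s1 <- sqrt(cov2[1, 1])
  s2 <- sqrt(cov2[2, 2])
  r <- cov2[1, 2] / (s1 * s2)
  sc <- s2 * sqrt(max(1 - r^2, 1e-12))
  slope <- r * s2 / s1
  m1 <- mean_mat[, 1]
  m2 <- mean_mat[, 2]
  a1 <- pmax(lo[, 1], m1 - 8.5 * s1)
  b1 <- pmin(hi[, 1], m1 + 8.5 * s1)
  width <- pmax(b1 - a1, 0)
  gl <- pracma::gaussLegendre(nodes, -1, 1)
  # n x nodes matrices of abscissae and weights
  tt <- outer((a1 + b1) / 2, rep(1, nodes)) + outer(width / 2, gl$x)
  ww <- outer(width / 2, gl$w)
  dens <- dnorm((tt - m1) / s1) / s1
  cmean <- m2 + slope * (tt - m1)
  band <- pnorm((hi[, 2] - cmean) / sc) - pnorm((lo[, 2] - cmean) / sc)
  pmin(pmax(rowSums(ww * dens * band), 0), 1)
}
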