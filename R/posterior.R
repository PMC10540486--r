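#' Grid posterior of one conditional survival probability
#'
#' With a binomial likelihood `p^x (1-p)^(n-x)` and a negative log-Gamma
#' prior, the posterior density of `p = p_{k|k-1}` is proportional to
#' `(-log p)^(shape - 1) * p^(rate - 1 + x) * (1 - p)^(n - x)`. The
#' likelihood factorizes over assessments and the priors are independent, so
#' the transition posteriors are mutually independent and one-dimensional;
#' they are represented on a deterministic quadrature grid instead of by
#' MCMC.
#'
#' Numerically the posterior is handled on the transformed axis
#' `v = (-log p)^shape`, which removes the prior's singularity at `p = 1`
#' exactly (the Jacobian cancels the `(-log p)^(shape-1)` factor), leaving a
#' bounded density. The grid spans `v` from 0 to a tail bound combining the
#' prior's Gamma quantile with a Beta quantile of the likelihood so that the
#' truncated mass is negligible (< 1e-14). Normalization, the CDF used for
#' inverse-CDF sampling, and moments are trapezoid quadratures on that axis.
#'
#' @param prior A [transition_prior()].
#' @param n_k Number of patients evaluated at the assessment.
#' @param x_k Number of survivors among them (`0 <= x_k <= n_k`). With
#'   `n_k = 0` the posterior equals the prior.
#' @param grid_size Number of grid nodes (default 4096).
#' @return A `transition_posterior` with fields `p` (grid, decreasing from 1
#'   towards 0), `density` (posterior density of `p` on the interior nodes),
#'   `cdf` (P(p <= grid value)), `mean`, and internals used by the sampler.
#' @examples
#' post <- transition_posterior(transition_prior(4, 0.464), n_k = 3, x_k = 3)
#' posterior_mean(post)
#' @export
transition_posterior <- function(prior, n_k, x_k, grid_size = 4096) {
  stopifnot(inherits(prior, "transition_prior"))
  if (x_k > n_k || x_k < 0 || n_k < 0) stop("need 0 <= x_k <= n_k", call. = FALSE)
  a <- prior$shape
  rate <- prior$rate + x_k
  fail <- n_k - x_k
  # grid extent in u = -log p: cover both the prior's heavy lower-p tail
  # (Gamma quantile) and the likelihood's location (Beta quantile of p)
  u_max <- max(
    stats::qgamma(1e-15, shape = a, rate = rate, lower.tail = FALSE),
    -log(stats::qbeta(1e-15, rate, fail + 1))
  )
  v <- seq(0, u_max^a, length.out = grid_size)
  u <- v^(1 / a)
  # density on the v axis: u^{a-1} e^{-rate*u} (1-e^{-u})^{fail} * du/dv,
  # du/dv = (1/a) u^{1-a}  =>  the u^{a-1} singularity cancels
  logf <- -rate * u + if (fail > 0) fail * log1p(-exp(-u)) else 0
  logf[1] <- if (fail > 0) -Inf else 0 # u = 0 endpoint
  f <- exp(logf - max(logf[is.finite(logf)]))
  f[!is.finite(f)] <- 0
  dv <- v[2] - v[1]
  z <- trapz(f, dv)
  f <- f / z
  cdf_u <- cumtrapz(f, dv) # P(U <= u) = P(p >= exp(-u))
  pmean <- trapz(exp(-u) * f, dv)
  p <- exp(-u)
  # density of p on interior nodes: f_v / |dp/dv|, dp/dv = -e^{-u} (1/a) u^{1-a}
  dens_p <- rep(NA_real_, grid_size)
  interior <- u > 0
  dens_p[interior] <- f[interior] /
    (exp(-u[interior]) * (1 / a) * u[interior]^(1 - a))
  structure(
    list(
      p = p, density = dens_p, cdf = 1 - cdf_u, mean = pmean,
      v = v, f_v = f, cdf_u = cdf_u,
      shape = a, rate = prior$rate, n_k = n_k, x_k = x_k
    ),
    class = "transition_posterior"
  )
}

trapz <- function(y, dx) dx * (sum(y) - (y[1] + y[length(y)]) / 2)

cumtrapz <- function(y, dx) {
  cs <- cumsum(c(0, dx * (y[-length(y)] + y[-1]) / 2))
  cs / cs[length(cs)]
}

#' @export
print.transition_posterior <- function(x, ...) {
  cat(sprintf(
    "Transition posterior (n = %d, x = %d, prior rate = %g): mean = %.4f\n",
    x$n_k, x$x_k, x$rate, x$mean
  ))
  invisible(x)
}

#' Posterior summaries and sampling
#'
#' `posterior_mean()` returns the quadrature mean of a single transition
#' posterior; `sample_posterior()` draws from it by inverse-CDF interpolation
#' on the internal grid.
#'
#' @param posterior A [transition_posterior()].
#' @param n_draws Number of draws.
#' @param unif Optional uniform variates to transform (overrides `n_draws`),
#'   enabling common-random-number designs.
#' @return `posterior_mean()`: a number; `sample_posterior()`: a numeric
#'   vector of draws in (0, 1).
#' @export
posterior_mean <- function(posterior) {
  stopifnot(inherits(posterior, "transition_posterior"))
  posterior$mean
}

#' @rdname posterior_mean
#' @export
sample_posterior <- function(posterior, n_draws, unif = NULL) {
  stopifnot(inherits(posterior, "transition_posterior"))
  if (is.null(unif)) unif <- stats::runif(n_draws)
  # invert the CDF of U = -log p on the v axis
  keep <- c(TRUE, diff(posterior$cdf_u) > 0)
  vq <- stats::approx(posterior$cdf_u[keep], posterior$v[keep],
    xout = unif, rule = 2
  )$y
  exp(-vq^(1 / posterior$shape))
}
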