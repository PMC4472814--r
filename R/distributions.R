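#' Distribution specifications for model parameters
#'
#' Every uncertain model quantity is stored as a distribution specification:
#' a beta distribution for probabilities, a gamma distribution for costs and
#' hours, or a fixed (point) value. The point estimate used in base-case
#' (deterministic) runs is the `mean` element; probabilistic sensitivity
#' analysis draws from the distribution itself.
#'
#' @param a,b Beta shape parameters (successes / failures scale).
#' @param mean Point estimate in native units. For `dist_beta()` it defaults
#'   to `a / (a + b)`; for `dist_gamma()` to `alpha / lambda`. Supplying a
#'   published mean that disagrees with the distribution mean is allowed
#'   (both are retained; the point estimate is the published mean).
#' @return A list of class `mt_dist` with elements `family`
#'   (`"beta"`, `"gamma"` or `"fixed"`), `a`, `b` and `mean`.
#' @examples
#' dist_beta(29, 61)            # mean 0.322
#' dist_gamma(351, 0.8)         # mean 438.75
#' dist_fixed(2867)
#' @export
dist_beta <- function(a, b, mean = NULL) {
  if (!is.numeric(a) || !is.numeric(b) || a <= 0 || b <= 0)
    stop("beta specification requires a > 0 and b > 0", call. = FALSE)
  m <- if (is.null(mean)) a / (a + b) else mean
  if (m < 0 || m > 1)
    stop("beta specification mean must lie in [0, 1]", call. = FALSE)
  structure(list(family = "beta", a = a, b = b, mean = m), class = "mt_dist")
}

#' @rdname dist_beta
#' @param alpha Gamma shape parameter (> 0).
#' @param lambda Gamma rate parameter (> 0, units 1/native-unit).
#' @param mean_tol Relative deviation between `alpha/lambda` and a supplied
#'   published `mean` above which a warning is emitted (the two disagree for
#'   several published cost rows; both values are kept).
#' @export
dist_gamma <- function(alpha, lambda, mean = NULL, mean_tol = 0.05) {
  if (!is.numeric(alpha) || !is.numeric(lambda) || alpha <= 0 || lambda <= 0)
    stop("gamma specification requires alpha > 0 and lambda > 0", call. = FALSE)
  m_dist <- alpha / lambda
  m <- if (is.null(mean)) m_dist else mean
  if (!is.null(mean) && abs(m_dist - mean) / mean > mean_tol)
    warning(sprintf(
      "gamma(%g, %g) implies mean %.4g but point estimate is %.4g (%.1f%% apart); PSA samples use the distribution, base case uses the point estimate",
      alpha, lambda, m_dist, mean, 100 * abs(m_dist - mean) / mean
    ), call. = FALSE)
  structure(list(family = "gamma", a = alpha, b = lambda, mean = m),
            class = "mt_dist")
}

#' @rdname dist_beta
#' @export
dist_fixed <- function(mean) {
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean))
    stop("fixed specification requires a single finite value", call. = FALSE)
  structure(list(family = "fixed", a = NA_real_, b = NA_real_, mean = mean),
            class = "mt_dist")
}

#' Beta specification from observed counts
#'
#' Constructs the beta distribution implied by a stratum of binomial trial
#' outcomes, the form in which the published pain-transition probabilities are
#' parameterised (alpha = events, beta = non-events).
#'
#' @param successes,failures Non-negative event / non-event counts; their sum
#'   must be positive.
#' @return An `mt_dist` beta specification with mean
#'   `successes / (successes + failures)`.
#' @examples
#' beta_from_counts(29, 61)  # Beta(29, 61), mean 0.3222
#' @export
beta_from_counts <- function(successes, failures) {
  if (successes < 0 || failures < 0)
    stop("counts must be non-negative", call. = FALSE)
  if (successes + failures == 0)
    stop("empty stratum: successes + failures must be positive", call. = FALSE)
  # Beta(0, b) / Beta(a, 0) degenerate corners collapse to fixed 0 / 1
  if (successes == 0) return(dist_fixed(0))
  if (failures == 0) return(dist_fixed(1))
  dist_beta(successes, failures)
}

#' @export
print.mt_dist <- function(x, ...) {
  switch(x$family,
    beta  = cat(sprintf("Beta(%g, %g), mean %.4g\n", x$a, x$b, x$mean)),
    gamma = cat(sprintf("Gamma(%g, %g), mean %.4g\n", x$a, x$b, x$mean)),
    fixed = cat(sprintf("Fixed(%.4g)\n", x$mean))
  )
  invisible(x)
}

is_sampled <- function(spec) {
  inherits(spec, "mt_dist") && spec$family %in% c("beta", "gamma")
}

draw_dist <- function(spec) {
  switch(spec$family,
    beta  = stats::rbeta(1L, spec$a, spec$b),
    gamma = stats::rgamma(1L, shape = spec$a, rate = spec$b),
    fixed = spec$mean
  )
}
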