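#' Probabilistic sensitivity analysis
#'
#' Draws `n_iterations` parameter sets (beta distributions for the
#' pain-transition probabilities, gamma distributions for costs and hours;
#' all other parameters fixed) and evaluates every strategy under each draw
#' in cohort-expectation mode. One master seed governs the analysis; each
#' iteration uses a deterministic [child_seed()] so single iterations can be
#' replayed with [sample_psa()]. Within an iteration all strategies share
#' the same draw.
#'
#' @param ps An `mt_params` object.
#' @param n_iterations Number of PSA draws.
#' @param seed Master seed.
#' @param ... Engine options (see [run_strategy()]).
#' @return An object of class `mt_psa`: matrices `qalys`, `direct_cost`,
#'   `time_cost` of dimension iterations x strategies, the engine options
#'   and the child seeds.
#' @examples
#' \donttest{
#' psa <- run_psa(default_parameters(), n_iterations = 100, seed = 1)
#' head(psa$qalys)
#' }
#' @export
run_psa <- function(ps, n_iterations, seed, ...) {
  stopifnot(inherits(ps, "mt_params"), n_iterations >= 1)
  opts <- engine_options(ps, ...)
  seeds <- vapply(seq_len(n_iterations), function(i) child_seed(seed, i),
                  integer(1L))
  P <- t(vapply(seeds,
                function(s) extract_engine_params(sample_psa(ps, s)),
                numeric(length(.engine_par_names))))
  colnames(P) <- .engine_par_names

  res <- lapply(strategies(), function(strat)
    cohort_run_multi(strat, ps, P, opts, keep_trajectory = FALSE))
  names(res) <- strategies()
  grab <- function(field) {
    m <- vapply(res, `[[`, numeric(n_iterations), field)
    if (n_iterations == 1L) m <- matrix(m, nrow = 1L,
                                        dimnames = list(NULL, strategies()))
    m
  }
  structure(list(
    qalys = grab("qalys"),
    direct_cost = grab("direct_cost"),
    time_cost = grab("time_cost"),
    strategies = strategies(),
    n_iterations = n_iterations,
    master_seed = seed,
    child_seeds = seeds,
    include_time_costs = isTRUE(opts$include_time_costs),
    options = opts[c("horizon_years", "include_time_costs",
                     "delayed_efficacy", "apm_progression_multiplier")]
  ), class = "mt_psa")
}

#' @export
print.mt_psa <- function(x, ...) {
  cat(sprintf("<mt_psa> %d iterations x %d strategies (seed %d)\n",
              x$n_iterations, length(x$strategies), x$master_seed))
  cat("  mean QALYs: ",
      paste(sprintf("%s %.3f", x$strategies, colMeans(x$qalys)),
            collapse = ", "), "\n", sep = "")
  cat("  mean direct cost: ",
      paste(sprintf("%s $%.0f", x$strategies, colMeans(x$direct_cost)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Total cost matrix of a PSA
#'
#' @param psa An `mt_psa` object.
#' @param include_time_costs Add productivity costs to direct medical costs;
#'   defaults to the perspective the PSA was run with.
#' @return Iterations x strategies cost matrix.
#' @export
psa_costs <- function(psa, include_time_costs = psa$include_time_costs) {
  psa$direct_cost + if (isTRUE(include_time_costs)) psa$time_cost else 0
}

#' Net-monetary-benefit matrix of a PSA
#'
#' @param psa An `mt_psa` object.
#' @param wtp Willingness-to-pay threshold (USD/QALY).
#' @param include_time_costs See [psa_costs()].
#' @return An iterations x strategies matrix of class `mt_nmb` with
#'   attribute `wtp`.
#' @export
nmb_matrix <- function(psa, wtp, include_time_costs = psa$include_time_costs) {
  stopifnot(inherits(psa, "mt_psa"), wtp >= 0)
  m <- nmb(psa_costs(psa, include_time_costs), psa$qalys, wtp)
  structure(m, wtp = wtp, class = c("mt_nmb", class(m)))
}
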