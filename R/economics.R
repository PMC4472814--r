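#' Net monetary benefit
#'
#' `NMB = wtp * qalys - cost`: the strategy's effectiveness valued at the
#' willingness-to-pay threshold, minus its cost.
#'
#' @param cost Cost in USD (vectorised).
#' @param qalys Effectiveness in QALYs.
#' @param wtp Willingness-to-pay threshold in USD/QALY (>= 0).
#' @return USD.
#' @examples
#' nmb(10800, 6.637, 50000)  # 321050
#' @export
nmb <- function(cost, qalys, wtp) {
  stopifnot(all(wtp >= 0))
  wtp * qalys - cost
}

#' Incremental cost-effectiveness table with dominance
#'
#' Orders strategies by ascending cost, removes strongly dominated
#' strategies (at least as costly and no more effective than another),
#' iteratively removes extendedly dominated strategies (those whose
#' incremental ICER exceeds that of the next more effective alternative,
#' i.e. strategies off the convex efficiency frontier), and computes ICERs
#' between adjacent frontier strategies.
#'
#' @param results A data.frame with columns `strategy`, `cost`, `qalys`
#'   (at least two rows).
#' @return A data.frame of class `mt_cea_table` ordered by cost with
#'   `status` (`"frontier"`, `"dominated"`, `"ext_dominated"`) and `icer`
#'   (USD/QALY versus the previous frontier strategy; `NA` for the cheapest
#'   frontier strategy and for dominated rows).
#' @examples
#' icer_table(data.frame(strategy = c("A", "B"),
#'                       cost = c(10800, 11900), qalys = c(6.637, 6.723)))
#' @export
icer_table <- function(results) {
  stopifnot(is.data.frame(results),
            all(c("strategy", "cost", "qalys") %in% names(results)),
            nrow(results) >= 2L)
  d <- results[order(results$cost, -results$qalys), , drop = FALSE]
  rownames(d) <- NULL
  n <- nrow(d)
  d$status <- "frontier"

  # strong dominance (weak convention: equal cost & effect -> later row out)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if ((d$cost[j] < d$cost[i] && d$qalys[j] >= d$qalys[i]) ||
        (d$cost[j] <= d$cost[i] && d$qalys[j] > d$qalys[i]) ||
        (d$cost[j] == d$cost[i] && d$qalys[j] == d$qalys[i] && j < i))
      d$status[i] <- "dominated"
  }

  # extended dominance: enforce increasing ICERs along the frontier
  repeat {
    f <- which(d$status == "frontier")
    if (length(f) < 3L) break
    ic <- diff(d$cost[f]) / diff(d$qalys[f])
    bad <- which(diff(ic) < 0)
    if (!length(bad)) break
    d$status[f[bad[1L] + 1L]] <- "ext_dominated"
  }

  f <- which(d$status == "frontier")
  d$icer <- NA_real_
  if (length(f) > 1L)
    d$icer[f[-1L]] <- diff(d$cost[f]) / diff(d$qalys[f])
  class(d) <- c("mt_cea_table", "data.frame")
  d
}

#' @export
print.mt_cea_table <- function(x, ...) {
  y <- as.data.frame(x)
  y$cost <- sprintf("$%s", format(round(y$cost / 100) * 100,
                                  big.mark = ",", trim = TRUE))
  y$qalys <- sprintf("%.3f", y$qalys)
  y$icer <- ifelse(x$status == "dominated", "Dominated",
            ifelse(x$status == "ext_dominated", "Ext. dominated",
            ifelse(is.na(x$icer), "",
                   sprintf("$%s", format(round(x$icer / 100) * 100,
                                         big.mark = ",", trim = TRUE)))))
  print(y, row.names = FALSE)
  invisible(x)
}

#' Default willingness-to-pay grid
#'
#' @return USD/QALY thresholds from 0 to 150,000 in 1,000 steps.
#' @export
wtp_grid_default <- function() seq(0, 150000, by = 1000)

# fraction of iterations in which each column attains the row maximum,
# splitting ties equally
.win_fractions <- function(nmb_mat) {
  mx <- do.call(pmax, as.data.frame(nmb_mat))
  winners <- nmb_mat == mx
  colMeans(winners / rowSums(winners))
}

#' Cost-effectiveness acceptability curves
#'
#' For each willingness-to-pay threshold, the fraction of PSA iterations in
#' which each strategy has the highest net monetary benefit (ties split
#' equally).
#'
#' @param psa An `mt_psa` object.
#' @param wtp_grid Vector of thresholds (USD/QALY).
#' @param include_time_costs See [psa_costs()].
#' @return A data.frame of class `mt_ceac`: `wtp`, one probability column
#'   per strategy (each row sums to one).
#' @export
ceac <- function(psa, wtp_grid = wtp_grid_default(),
                 include_time_costs = psa$include_time_costs) {
  stopifnot(inherits(psa, "mt_psa"))
  if (psa$n_iterations < 1L) stop("empty PSA", call. = FALSE)
  cost <- psa_costs(psa, include_time_costs)
  probs <- t(vapply(wtp_grid,
                    function(w) .win_fractions(nmb(cost, psa$qalys, w)),
                    numeric(length(psa$strategies))))
  out <- data.frame(wtp = wtp_grid, probs)
  names(out) <- c("wtp", psa$strategies)
  class(out) <- c("mt_ceac", "data.frame")
  out
}

#' Cost-effectiveness acceptability frontier
#'
#' At each willingness-to-pay threshold, identifies the strategy with the
#' highest *mean* net monetary benefit and reports the probability that this
#' strategy is cost-effective (its acceptability-curve value).
#'
#' @inheritParams ceac
#' @return A data.frame of class `mt_ceaf`: `wtp`, `preferred` (strategy id)
#'   and `prob_cost_effective`; switch points are in
#'   `attr(, "switch_points")`.
#' @export
ceaf <- function(psa, wtp_grid = wtp_grid_default(),
                 include_time_costs = psa$include_time_costs) {
  cv <- ceac(psa, wtp_grid, include_time_costs)
  cost <- colMeans(psa_costs(psa, include_time_costs))
  q <- colMeans(psa$qalys)
  pref <- vapply(wtp_grid, function(w)
    psa$strategies[which.max(nmb(cost, q, w))], character(1L))
  prob <- vapply(seq_along(wtp_grid), function(i) cv[i, pref[i]],
                 numeric(1L))
  out <- data.frame(wtp = wtp_grid, preferred = pref,
                    prob_cost_effective = prob)
  sw <- which(pref[-1L] != pref[-length(pref)])
  attr(out, "switch_points") <- data.frame(
    wtp = wtp_grid[sw + 1L],
    from = pref[sw], to = pref[sw + 1L])
  class(out) <- c("mt_ceaf", "data.frame")
  out
}
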