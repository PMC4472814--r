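# Shared fixtures and independent oracles.

# packaged parameter set, loaded once (gamma mean-mismatch warnings are
# expected and tested separately)
test_ps <- local({
  ps <- NULL
  function() {
    if (is.null(ps)) ps <<- suppressWarnings(mtcea::default_parameters())
    ps
  }
})

# life table with zero mortality, for hand-built-chain oracles
zero_mortality_table <- function() {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(age = 40:110, annual_death_prob = 0),
                   path, row.names = FALSE)
  mtcea::load_life_table(path)
}

# parameter set stripped of every stochastic-death channel
deathless_ps <- function(ps = test_ps()) {
  ps$adverse_events$APM$mortality <- 0
  ps$adverse_events$TKA$mortality <- 0
  ps$adverse_events$pharm$mortality <- 0
  ps
}

# write a modified copy of the default YAML config and return its path
config_with <- function(edit) {
  cfg <- yaml::read_yaml(mtcea::default_config_path())
  cfg <- edit(cfg)
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, path)
  path
}

# Independent convex-frontier oracle: a strategy lies on the frontier iff it
# attains the maximum net monetary benefit for some willingness-to-pay
# lambda >= 0. Candidate switch points are all pairwise ICERs; evaluating
# argmax between consecutive candidates enumerates the frontier exactly for
# generic instances.
frontier_oracle <- function(cost, qalys) {
  n <- length(cost)
  pairs <- utils::combn(n, 2)
  lams <- (cost[pairs[2, ]] - cost[pairs[1, ]]) /
    (qalys[pairs[2, ]] - qalys[pairs[1, ]])
  lams <- sort(unique(c(0, lams[is.finite(lams) & lams > 0])))
  probe <- c(lams[1] / 2, (lams[-length(lams)] + lams[-1]) / 2,
             lams[length(lams)] + 1, lams[length(lams)] * 2 + 1)
  on_frontier <- rep(FALSE, n)
  for (l in probe) {
    v <- l * qalys - cost
    best <- which(v == max(v))
    if (length(best) == 1L) on_frontier[best] <- TRUE
  }
  # among duplicates of (cost, qalys), only the first can win
  on_frontier
}
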