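test_that("net monetary benefit is WTP times effect minus cost", {
  expect_equal(nmb(10800, 6.637, 50000), 321050)
  expect_equal(nmb(0, 0, 123456), 0)
  expect_equal(nmb(500, 2, 0), -500)
  expect_error(nmb(1, 1, -1))
})

test_that("the ICER ladder reproduces published-style tables", {
  # base-case triple (rounded published inputs)
  base <- data.frame(strategy = c("PT", "delayed", "immediate"),
                     cost = c(10800, 11900, 12900),
                     qalys = c(6.637, 6.723, 6.732))
  tab <- icer_table(base)
  expect_equal(tab$status, rep("frontier", 3))
  expect_equal(tab$icer[2], 1100 / 0.086)     # ~12,800 from rounded inputs
  expect_equal(tab$icer[3], 1000 / 0.009)
  # optimistic delayed-efficacy triple: immediate APM is dominated
  sens <- data.frame(strategy = c("PT", "delayed", "immediate"),
                     cost = c(10800, 11600, 12900),
                     qalys = c(6.636, 6.744, 6.731))
  tab2 <- icer_table(sens)
  expect_equal(tab2$status[tab2$strategy == "immediate"], "dominated")
  expect_true(is.na(tab2$icer[tab2$strategy == "immediate"]))
  # weak dominance: an identical twin is dominated, not tied
  twin <- data.frame(strategy = c("a", "b"), cost = c(5, 5), qalys = c(1, 1))
  expect_equal(icer_table(twin)$status, c("frontier", "dominated"))
  expect_error(icer_table(base[1, ]))
})

test_that("extended dominance removes strategies off the convex frontier", {
  d <- data.frame(strategy = c("a", "b", "c"),
                  cost = c(0, 100, 120),
                  qalys = c(0, 0.001, 0.01))
  tab <- icer_table(d)
  expect_equal(tab$status, c("frontier", "ext_dominated", "frontier"))
  expect_equal(tab$icer[3], 120 / 0.01)
})

test_that("the ICER ladder agrees with a brute-force frontier oracle", {
  set.seed(11)
  for (i in 1:1000) {
    k <- sample(3:6, 1)
    d <- data.frame(strategy = paste0("s", seq_len(k)),
                    cost = round(runif(k, 0, 50000)),
                    qalys = runif(k, 0, 10))
    tab <- icer_table(d)
    d2 <- d[match(tab$strategy, d$strategy), ]
    expect_equal(tab$status == "frontier",
                 frontier_oracle(d2$cost, d2$qalys),
                 info = paste("instance", i))
    f <- which(tab$status == "frontier")
    if (length(f) > 1) {
      ic <- tab$icer[f[-1]]
      expect_true(all(diff(c(0, ic)) > 0))  # increasing along the frontier
      expect_true(all(diff(tab$cost[f]) > 0))
      expect_true(all(diff(tab$qalys[f]) > 0))
    }
  }
})

fake_psa <- function(qalys, cost, strategies = colnames(qalys)) {
  structure(list(qalys = qalys, direct_cost = cost,
                 time_cost = cost * 0, strategies = strategies,
                 n_iterations = nrow(qalys), include_time_costs = FALSE),
            class = "mt_psa")
}

test_that("acceptability curves are proper probabilities with fair ties", {
  q <- matrix(c(1, 2, 1, 2, 1.5, 1.5), 2, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  cost <- matrix(0, 2, 3, dimnames = dimnames(q))
  cv <- ceac(fake_psa(q, cost), wtp_grid = c(0, 1000))
  expect_equal(rowSums(cv[, -1]), c(1, 1))
  # at wtp 0 all costs equal: three-way tie split equally
  expect_equal(unlist(cv[1, -1], use.names = FALSE), rep(1 / 3, 3))
  # single iteration gives an indicator vector
  cv1 <- ceac(fake_psa(q[1, , drop = FALSE], cost[1, , drop = FALSE]),
              wtp_grid = 1000)
  expect_equal(unlist(cv1[1, -1], use.names = FALSE), c(0, 0, 1))
  # degenerate: identical strategies tie everywhere
  cv3 <- ceac(fake_psa(matrix(1, 5, 3, dimnames = dimnames(q)),
                       matrix(2, 5, 3, dimnames = dimnames(q))),
              wtp_grid = 50000)
  expect_equal(unlist(cv3[1, -1], use.names = FALSE), rep(1 / 3, 3))
})

test_that("CEAC sums to one across the full grid of a model PSA", {
  psa <- run_psa(test_ps(), 60, seed = 3)
  cv <- ceac(psa, wtp_grid = seq(0, 150000, by = 10000))
  expect_true(all(abs(rowSums(cv[, -1]) - 1) < 1e-12))
  expect_true(all(as.matrix(cv[, -1]) >= 0 & as.matrix(cv[, -1]) <= 1))
})

test_that("the frontier strategy switches exactly at the adjacent ICER", {
  set.seed(21)
  for (i in 1:50) {
    cost <- sort(runif(3, 1000, 30000))
    q <- sort(runif(3, 1, 8))
    tab <- icer_table(data.frame(strategy = c("a", "b", "c"),
                                 cost = cost, qalys = q))
    f <- which(tab$status == "frontier")
    if (length(f) < 2) next
    for (j in f[-1]) {
      lam <- tab$icer[j]
      below <- nmb(tab$cost, tab$qalys, lam * (1 - 1e-9))
      above <- nmb(tab$cost, tab$qalys, lam * (1 + 1e-9))
      expect_false(which.max(below) == j)
      expect_equal(which.max(above), j)
    }
  }
})

test_that("the acceptability frontier tracks the highest-mean-NMB strategy", {
  psa <- run_psa(test_ps(), 60, seed = 5)
  cf <- ceaf(psa, wtp_grid = seq(0, 150000, by = 5000))
  cv <- ceac(psa, wtp_grid = seq(0, 150000, by = 5000))
  for (i in seq_len(nrow(cf)))
    expect_equal(cf$prob_cost_effective[i], cv[i, cf$preferred[i]])
  # cheap strategies are preferred at WTP 0
  cost <- colMeans(psa_costs(psa))
  expect_equal(cf$preferred[1], psa$strategies[which.min(cost)])
  expect_s3_class(attr(cf, "switch_points"), "data.frame")
})
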