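# Independent G-statistic oracle: 2 * sum over the four cells of the 2x2
# respondent contingency table of O * ln(O / E).
g_statistic <- function(i_n, j_n, k11, n) {
  O <- c(k11, i_n - k11, j_n - k11, n - i_n - j_n + k11)
  rows <- c(i_n, i_n, n - i_n, n - i_n)
  cols <- c(j_n, n - j_n, j_n, n - j_n)
  E <- rows * cols / n
  keep <- O > 0
  2 * sum(O[keep] * log(O[keep] / E[keep]))
}

test_that("the worked repulsion examples reproduce in nats", {
  expect_equal(round(compute_llr(93, 97, 6, 505), 2), -7.27)
  expect_equal(round(compute_llr(99, 146, 13, 505), 1), -8.4)
})

test_that("exact independence gives zero with a pinned sign", {
  expect_identical(compute_llr(10, 10, 1, 100), 0)
  expect_identical(compute_llr(50, 50, 25, 100), 0)
})

test_that("twice the absolute LLR is the G statistic of the 2x2 table", {
  set.seed(42)
  for (rep in 1:1000) {
    n <- sample(20:2000, 1)
    i_n <- sample(1:(n - 1), 1)
    j_n <- sample(1:(n - 1), 1)
    lo <- max(0, i_n + j_n - n)
    hi <- min(i_n, j_n)
    k11 <- sample(lo:hi, 1)
    got <- 2 * abs(compute_llr(i_n, j_n, k11, n))
    want <- g_statistic(i_n, j_n, k11, n)
    # relative 1e-9, absolute floor where both formulas cancel to ~0
    expect_lt(abs(got - want), 1e-9 * max(1, abs(want)))
  }
})

test_that("LLR is symmetric in the two associations", {
  set.seed(7)
  for (rep in 1:50) {
    n <- sample(30:500, 1)
    i_n <- sample(1:(n - 1), 1); j_n <- sample(1:(n - 1), 1)
    k11 <- sample(max(0, i_n + j_n - n):min(i_n, j_n), 1)
    expect_equal(compute_llr(i_n, j_n, k11, n),
                 compute_llr(j_n, i_n, k11, n))
  }
})

test_that("sign tracks observed versus expected co-occurrence", {
  # fixed margins 40, 60 of 200: expectation 12
  lo <- 0; hi <- 40
  vals <- compute_llr(40, 60, lo:hi, 200)
  expect_true(all(vals[(lo:hi) > 12] > 0))
  expect_true(all(vals[(lo:hi) < 12] < 0))
  expect_equal(vals[which(lo:hi == 12)], 0)
  # monotone in k11: repulsion weakens toward the expectation, then
  # attraction strengthens beyond it
  expect_true(all(diff(vals) > 0))
})

test_that("count preconditions are enforced", {
  expect_error(compute_llr(10, 10, 11, 100), "domain error")
  expect_error(compute_llr(10, 10, -1, 100), "domain error")
  expect_error(compute_llr(90, 90, 10, 100), "domain error") # k11 < i+j-n
  expect_error(compute_llr(101, 10, 5, 100), "domain error")
})

test_that("expected co-occurrence truncates toward zero", {
  e1 <- expected_cooccurrence(93, 97, 505)
  e2 <- expected_cooccurrence(99, 146, 505)
  expect_identical(as.integer(e1), 17L)
  expect_identical(as.integer(e2), 28L)
  expect_equal(attr(e1, "exact"), 93 * 97 / 505)
  expect_identical(as.integer(expected_cooccurrence(0, 50, 100)), 0L)
  expect_error(expected_cooccurrence(5, 5, 0), "domain error")
})

test_that("the network carries the pairwise LLR of respondent counts", {
  # lemmas a, b always co-mentioned by the same 3 respondents of 10
  rows <- c(lapply(1:3, function(i)
    make_record(paste0("c", i), c("aa", "bb", "", "", ""))),
    lapply(4:10, function(i)
      make_record(paste0("c", i), c(paste0("other", i %% 2), "", "", "", ""))))
  recs <- do.call(make_records, rows)
  voc <- build_vocabulary(recs, 3)
  net <- build_coop_network(recs, voc)
  expect_setequal(net$nodes, c("aa", "bb", "other1", "other0"))
  expect_equal(net$weights["aa", "bb"], compute_llr(3, 3, 3, 10))
  expect_gt(net$weights["aa", "bb"], 0)

  # frequent but never co-mentioned lemmas repel
  rows2 <- c(lapply(1:5, function(i)
    make_record(paste0("d", i), c("xx", "", "", "", ""))),
    lapply(6:10, function(i)
      make_record(paste0("d", i), c("yy", "", "", "", ""))))
  recs2 <- do.call(make_records, rows2)
  net2 <- build_coop_network(recs2, build_vocabulary(recs2, 3))
  expect_lt(net2$weights["xx", "yy"], 0)
  expect_equal(net2$weights["xx", "yy"], compute_llr(5, 5, 0, 10))
})

test_that("the network is invariant to respondent order", {
  pop <- small_population(seed = 5, n = 100, vocab_size = 12)
  voc <- build_vocabulary(pop$records, 3)
  net <- build_coop_network(pop$records, voc)
  set.seed(1)
  shuffled <- pop$records[sample.int(nrow(pop$records)), ]
  net2 <- build_coop_network(shuffled, build_vocabulary(shuffled, 3))
  expect_equal(net2$weights[net$nodes, net$nodes], net$weights)
  # symmetry and empty diagonal
  expect_equal(net$weights, t(net$weights))
  expect_true(all(diag(net$weights) == 0))
  expect_true(all(net$node_freq >= net$threshold))
})

test_that("degenerate vocabularies are rejected", {
  recs <- make_records(make_record("r1", c("solo", "", "", "", "")))
  voc <- build_vocabulary(recs, 1)
  expect_error(build_coop_network(recs, voc), "degenerate")
})

test_that("edge list and chi-squared utility are consistent", {
  pop <- small_population(seed = 5, n = 100, vocab_size = 12)
  voc <- build_vocabulary(pop$records, 3)
  net <- build_coop_network(pop$records, voc)
  el <- coop_edge_list(net)
  expect_equal(nrow(el), choose(length(net$nodes), 2))
  expect_true(all(el$llr == net$weights[cbind(el$node_i, el$node_j)]))
  # p of a strong repulsion is small; p of a near-zero LLR is near 1
  expect_lt(llr_chisq_p(min(el$llr)), 0.01)
  expect_gt(llr_chisq_p(1e-8), 0.99)
})
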