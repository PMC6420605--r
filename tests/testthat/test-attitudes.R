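fixture_partition <- function() {
  structure(list(membership = c(w1 = 1, w2 = 1, w3 = 1, v1 = 2, v2 = 2,
                                v3 = 2),
                 Q = 0.2, n_modules = 2, resolution = 1),
            class = "coop_partition")
}

fixture_vocab <- function() {
  make_vocab(c("w1", "w2", "w3", "v1", "v2", "v3"), rep(10, 6))
}

test_that("respondents go to the strict majority module; ties are discarded", {
  recs <- make_records(
    make_record("maj", c("w1", "w2", "v1", "", ""), pot = 3),
    make_record("tie", c("w1", "w2", "v1", "v2", ""), pot = 3),
    make_record("all", c("w1", "w2", "w3", "w1", "w2"), pot = 3),
    make_record("none", c("zz", "", "", "", ""), pot = 3))
  asg <- assign_respondents(recs, fixture_partition(), fixture_vocab())
  expect_equal(asg$module[asg$respondent_id == "maj"], 1L)
  expect_equal(asg$weight[asg$respondent_id == "maj"], 2L)
  expect_true(asg$discarded[asg$respondent_id == "tie"])
  expect_equal(asg$reason[asg$respondent_id == "tie"], "tie")
  # five slots, three distinct retained lemmas, all in one module
  expect_equal(asg$weight[asg$respondent_id == "all"], 3L)
  expect_false(asg$discarded[asg$respondent_id == "all"])
  expect_equal(asg$reason[asg$respondent_id == "none"], "no_retained")
})

test_that("weighted moments match hand evaluation and the unweighted case", {
  m <- weighted_moments(c(2, 4), c(3, 1))
  expect_equal(m[["wam"]], 2.5)
  expect_equal(m[["wav"]], 0.75)

  x <- c(1.2, 3.4, 2.2, 4.9)
  u <- weighted_moments(x, rep(1, 4))
  expect_equal(u[["wam"]], mean(x))
  expect_equal(u[["wav"]], mean((x - mean(x))^2))

  expect_equal(weighted_moments(c(3, 3, 3), c(1, 2, 5))[["wav"]], 0)
  expect_error(weighted_moments(numeric(0), numeric(0)), "degenerate")
})

test_that("weighted t with unit weights matches the pooled t.test oracle", {
  set.seed(6)
  for (rep in 1:20) {
    a <- rnorm(sample(5:15, 1), 3, 1)
    b <- rnorm(sample(5:15, 1), 3.5, 1.2)
    got <- weighted_t_test(a, rep(1, length(a)), b, rep(1, length(b)))
    want <- t.test(a, b, var.equal = TRUE)
    expect_equal(got$t, unname(want$statistic))
    expect_equal(got$df, unname(want$parameter))
    expect_equal(got$p, want$p.value)
  }
})

test_that("scaling all weights leaves the statistic unchanged", {
  a <- c(2, 3, 4, 2.5); wa <- c(1, 2, 3, 1)
  b <- c(3, 4, 5); wb <- c(2, 2, 1)
  t1 <- weighted_t_test(a, wa, b, wb)
  t2 <- weighted_t_test(a, 2 * wa, b, 2 * wb)
  expect_equal(t1$t, t2$t)
  expect_equal(t1$df, t2$df)
  expect_equal(t1$d, t2$d)
})

test_that("identical groups give t = 0, p = 1, d = 0", {
  a <- c(1, 2, 3, 4)
  r <- weighted_t_test(a, rep(1, 4), a, rep(1, 4))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  expect_equal(r$d, 0)
  expect_error(weighted_t_test(c(2, 2), c(1, 1), c(2, 2), c(1, 1)),
               "degenerate")
})

test_that("the medium-effect power target needs 64 per group", {
  expect_identical(required_n_per_group(0.5, 0.05, 0.8), 64L)
  # bracketing against the closed-form oracle
  expect_gte(power.t.test(n = 64, delta = 0.5, sd = 1,
                          sig.level = 0.05)$power, 0.8)
  expect_lt(power.t.test(n = 63, delta = 0.5, sd = 1,
                         sig.level = 0.05)$power, 0.8)
  expect_lte(required_n_per_group(10), 3L)
  expect_error(required_n_per_group(-1), "parameter error")
})

test_that("the attitude report recovers a planted score gradient", {
  pop <- small_population(seed = 55, n = 350)
  voc <- build_vocabulary(pop$records, 3)
  net <- build_coop_network(pop$records, voc)
  truth <- structure(list(membership = pop$word_groups[net$nodes],
                          Q = NA_real_,
                          n_modules = max(pop$word_groups, na.rm = TRUE),
                          resolution = 1),
                     class = "coop_partition")
  names(truth$membership) <- net$nodes
  rep_ <- attitude_report(pop$records, truth, voc)
  pot <- rep_$moments[rep_$moments$scale == "pot", ]
  # planted POT means increase with group index
  expect_equal(order(pot$wam), order(pot$module))
  tests <- rep_$tests[rep_$tests$scale == "pot", ]
  expect_true(all(tests$p < 0.05))
  # planted direction: lower-index groups have lower POT means
  expect_true(all(tests$t[tests$module_a < tests$module_b] < 0))
  # weights sum over respondents' retained associations
  expect_true(all(rep_$assignment$weight[!rep_$assignment$discarded] >= 1))
  expect_true(all(rep_$moments$wav >= 0))
})

test_that("missing score columns are reported by name", {
  recs <- make_records(make_record("r1", c("w1", "", "", "", "")))
  recs$pot <- NULL; recs$gm <- NULL; recs$sdo <- NULL
  expect_error(attitude_report(recs, fixture_partition(), fixture_vocab()),
               "no attitude scale")
  recs2 <- make_records(make_record("r1", c("w1", "", "", "", ""), pot = 3))
  expect_error(attitude_report(recs2, fixture_partition(), fixture_vocab(),
                               scales = "sdo"),
               "sdo")
})
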