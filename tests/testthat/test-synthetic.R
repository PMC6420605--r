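test_that("generation is deterministic under a fixed seed", {
  cfg <- population_config(n_respondents = 60, vocab_size = 12)
  p1 <- generate_population(cfg, seed = 77)
  p2 <- generate_population(cfg, seed = 77)
  expect_identical(p1$records, p2$records)
  expect_identical(p1$groups, p2$groups)
  p3 <- generate_population(cfg, seed = 78)
  expect_false(identical(p1$records, p3$records))
})

test_that("generated records pass input validation and carry 5 responses", {
  pop <- small_population(seed = 2, n = 80)
  expect_silent(validate_responses(pop$records))
  expect_false(any(attr(pop$records, "incomplete")))
  rng <- attitude_ranges()
  for (s in names(rng))
    expect_true(all(pop$records[[s]] >= rng[[s]][1] &
                      pop$records[[s]] <= rng[[s]][2]))
  # five distinct associations per respondent
  acols <- paste0("assoc_", 1:5)
  for (r in seq_len(nrow(pop$records)))
    expect_equal(length(unique(unlist(pop$records[r, acols]))), 5)
})

test_that("association frequencies are heavy-tailed", {
  pop <- small_population(seed = 4, n = 400, vocab_size = 40)
  voc <- build_vocabulary(pop$records, 1)
  f <- sort(voc$count, decreasing = TRUE)
  lr <- log(seq_along(f)); lf <- log(f)
  slope <- stats::coef(stats::lm(lf ~ lr))[2]
  expect_lt(slope, -0.3)
  # convex rank-frequency curve in log-log space: the late-rank slope is
  # steeper than the early-rank slope
  half <- floor(length(f) / 2)
  s1 <- stats::coef(stats::lm(lf[1:half] ~ lr[1:half]))[2]
  s2 <- stats::coef(stats::lm(lf[(half + 1):length(f)] ~
                                lr[(half + 1):length(f)]))[2]
  expect_lt(s2, s1)
})

test_that("invalid configurations are rejected", {
  expect_error(population_config(vocab_size = 3), "too small")
  expect_error(population_config(proportions = c(0.5, 0.2, 0.2)),
               "sum to 1")
  expect_error(population_config(emotion_concentration = 1.5),
               "emotion_concentration")
  expect_error(population_config(
    attitude_means = list(pot = c(1, 2, 9), gm = c(2, 3, 4),
                          sdo = c(2, 3, 4))), "pot")
  expect_error(generate_paired_samples(population_config(), drift = -1),
               "drift")
})

test_that("a single group yields much weaker modular structure", {
  cfg1 <- population_config(n_respondents = 250, n_groups = 1,
                            vocab_size = 30, emotion_focus = 4)
  pop1 <- generate_population(cfg1, seed = 9)
  net1 <- build_coop_network(pop1$records, build_vocabulary(pop1$records, 3))
  q1 <- louvain_partition(net1$weights, seed = 1)$Q

  cfg3 <- population_config(n_respondents = 250, vocab_size = 30)
  pop3 <- generate_population(cfg3, seed = 9)
  net3 <- build_coop_network(pop3$records, build_vocabulary(pop3$records, 3))
  q3 <- louvain_partition(net3$weights, seed = 1)$Q
  expect_lt(q1, q3 / 2)
})

test_that("paired samples share structure at drift 0 and diverge with drift", {
  cfg <- population_config(n_respondents = 150, vocab_size = 20)
  pair0 <- generate_paired_samples(cfg, drift = 0, seed = 21)
  expect_silent(validate_responses(pair0$sample1$records))
  expect_silent(validate_responses(pair0$sample2$records))
  # same group vocabularies, so retained lemma sets overlap heavily
  v1 <- build_vocabulary(pair0$sample1$records, 3)
  v2 <- build_vocabulary(pair0$sample2$records, 3)
  shared0 <- length(intersect(v1$lemma[v1$retained], v2$lemma[v2$retained]))
  expect_gt(shared0 / min(attr(v1, "n_retained"), attr(v2, "n_retained")),
            0.7)
  # heavy drift reshuffles occurrence probabilities between the waves
  pairD <- generate_paired_samples(cfg, drift = 3, seed = 21)
  c1 <- build_vocabulary(pairD$sample1$records, 1)
  c2 <- build_vocabulary(pairD$sample2$records, 1)
  shared <- intersect(c1$lemma, c2$lemma)
  r <- stats::cor(c1$count[match(shared, c1$lemma)],
                  c2$count[match(shared, c2$lemma)],
                  method = "spearman")
  c1b <- build_vocabulary(pair0$sample1$records, 1)
  c2b <- build_vocabulary(pair0$sample2$records, 1)
  sharedb <- intersect(c1b$lemma, c2b$lemma)
  r0 <- stats::cor(c1b$count[match(sharedb, c1b$lemma)],
                   c2b$count[match(sharedb, c2b$lemma)],
                   method = "spearman")
  expect_lt(r, r0)
})

test_that("the end-to-end pipeline recovers planted groups from records", {
  pop <- small_population(seed = 30, n = 300, vocab_size = 24)
  voc <- build_vocabulary(pop$records, 3)
  net <- build_coop_network(pop$records, voc)
  cons <- consensus_partition(net$weights, n_runs = 40, n_check = 15,
                              seed = 3)
  truth <- stats::setNames(pop$word_groups[net$nodes], net$nodes)
  expect_gte(nmi(cons$partition$membership, truth), 0.9)
  aff <- affective_matrix(pop$records, voc)
  bc <- binned_llr_affect_correlation(net, aff, n_perm = 0)
  expect_gt(bc$rho, 0)
})
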