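# Independent oracle: standard Newman-Girvan weighted modularity for a
# non-negative matrix, computed directly from its definition.
newman_q <- function(w, m) {
  s <- rowSums(w)
  v <- sum(s)
  q <- 0
  for (i in seq_len(nrow(w))) for (j in seq_len(nrow(w)))
    if (m[i] == m[j]) q <- q + w[i, j] - s[i] * s[j] / v
  q / v
}

two_cliques <- function(k = 3) {
  w <- matrix(0, 2 * k, 2 * k)
  w[1:k, 1:k] <- 1
  w[(k + 1):(2 * k), (k + 1):(2 * k)] <- 1
  diag(w) <- 0
  rownames(w) <- colnames(w) <- paste0("v", seq_len(2 * k))
  w
}

test_that("the all-in-one partition always has Q = 0", {
  set.seed(5)
  for (rep in 1:10) {
    n <- sample(4:12, 1)
    w <- matrix(0, n, n)
    w[upper.tri(w)] <- rnorm(n * (n - 1) / 2)
    w <- w + t(w)
    expect_equal(signed_modularity(w, rep(1, n)), 0)
  }
})

canonical_membership_test <- function(m) unname(match(m, unique(m)))

test_that("two equal disconnected positive cliques split at Q = 0.5", {
  w <- two_cliques()
  expect_equal(signed_modularity(w, rep(1:2, each = 3)), 0.5)
  for (s in 1:20) {
    p <- louvain_partition(w, seed = s)
    expect_equal(p$Q, 0.5)
    expect_equal(canonical_membership_test(p$membership),
                 rep(1:2, each = 3))
  }
})

test_that("signed modularity reduces to Newman-Girvan on positive nets", {
  set.seed(17)
  for (rep in 1:20) {
    n <- sample(5:10, 1)
    w <- matrix(0, n, n)
    w[upper.tri(w)] <- runif(n * (n - 1) / 2)
    w <- w + t(w)
    m <- sample(1:3, n, replace = TRUE)
    expect_equal(signed_modularity(w, m), newman_q(w, m))
  }
})

test_that("Q is invariant to module relabeling and node reordering", {
  blk <- planted_block_matrix(block_size = 4, seed = 2)
  m <- blk$blocks
  q0 <- signed_modularity(blk$weights, m)
  relab <- c(3, 1, 2)[m]
  expect_equal(signed_modularity(blk$weights, relab), q0)
  set.seed(1)
  p <- sample(length(m))
  expect_equal(signed_modularity(blk$weights[p, p], m[p]), q0)
})

test_that("modularity input validation catches bad matrices", {
  w <- matrix(rnorm(16), 4, 4)
  expect_error(signed_modularity(w, rep(1, 4)), "symmetric")
  w2 <- (w + t(w)) / 2
  expect_error(signed_modularity(w2, rep(1, 4)), "diagonal")
  diag(w2) <- 0
  expect_error(signed_modularity(w2 * 0, rep(1, 4)), "degenerate")
})

test_that("Louvain attains the enumerated optimum on tiny networks", {
  set.seed(31)
  for (rep in 1:12) {
    n <- sample(4:6, 1)
    w <- matrix(0, n, n)
    w[upper.tri(w)] <- round(rnorm(n * (n - 1) / 2), 2)
    w <- w + t(w)
    qmax <- max(vapply(all_partitions(n),
                       function(p) signed_modularity(w, p), numeric(1)))
    ql <- max(vapply(1:10, function(s) louvain_partition(w, seed = s)$Q,
                     numeric(1)))
    expect_equal(ql, qmax, tolerance = 1e-10)
  }
})

test_that("Louvain's reported Q matches re-evaluation on its output", {
  blk <- planted_block_matrix(seed = 3)
  for (s in 1:5) {
    p <- louvain_partition(blk$weights, seed = s)
    expect_equal(p$Q, signed_modularity(blk$weights, p$membership))
  }
})

test_that("a single positive edge merges its two nodes", {
  w <- matrix(c(0, 1, 1, 0), 2, 2)
  p <- louvain_partition(w, seed = 1)
  expect_equal(p$n_modules, 1)
})

test_that("consensus recovers planted blocks and reports valid frequencies", {
  blk <- planted_block_matrix(block_size = 6, n_blocks = 3, seed = 4)
  cons <- consensus_partition(blk$weights, n_runs = 60, n_check = 20,
                              seed = 10)
  expect_equal(nmi(cons$partition$membership, blk$blocks), 1)
  D <- cons$consensus_matrix
  expect_true(all(D >= 0 & D <= 1))
  expect_equal(unname(diag(D)), rep(1, nrow(D)))
  expect_equal(D, t(D))
  expect_equal(cons$mean_Q, mean(cons$q_runs))
})

test_that("a unique optimum makes consensus equal the single run", {
  w <- two_cliques()
  cons <- consensus_partition(w, n_runs = 30, n_check = 10, seed = 2)
  single <- louvain_partition(w, seed = 99)
  expect_equal(nmi(cons$partition, single), 1)
  expect_equal(cons$rounds, 1L)
  # idempotence: consensus of an unambiguous structure returns itself
  cons2 <- consensus_partition(w, n_runs = 30, n_check = 10, seed = 3)
  expect_equal(nmi(cons$partition, cons2$partition), 1)
})

test_that("module labels use the two most frequent lemmas", {
  voc <- make_vocab(c("war", "refugee", "help", "unity"),
                    c(120, 97, 40, 3))
  part <- structure(list(membership = c(war = 1, refugee = 1, help = 1,
                                        unity = 2),
                         Q = 0.1, n_modules = 2, resolution = 1),
                    class = "coop_partition")
  labs <- label_modules(part, voc)
  expect_equal(labs[[1]], "War & Refugee")
  expect_equal(labs[[2]], "Unity")

  # tie for second place broken lexicographically
  voc2 <- make_vocab(c("war", "aid", "care"), c(10, 5, 5))
  part2 <- structure(list(membership = c(war = 1, aid = 1, care = 1),
                          Q = 0.1, n_modules = 1, resolution = 1),
                     class = "coop_partition")
  expect_equal(label_modules(part2, voc2)[[1]], "War & Aid")
})

test_that("small modules are flagged, not removed", {
  part <- structure(list(membership = c(a = 1, b = 1, c = 2, d = 3, e = 4),
                         Q = 0.1, n_modules = 4, resolution = 1),
                    class = "coop_partition")
  flt <- filter_small_modules(part)
  expect_setequal(flt$excluded, c(2, 3, 4))
  expect_equal(flt$kept, 1)
  expect_identical(flt$partition, part)
  expect_length(filter_small_modules(part, min_distinct = 1)$excluded, 0)

  part2 <- structure(list(membership = c(a = 1, b = 1, c = 2, d = 2),
                          Q = 0.1, n_modules = 2, resolution = 1),
                     class = "coop_partition")
  expect_length(filter_small_modules(part2)$excluded, 0)
})

test_that("partition table and consensus edges export consistently", {
  blk <- planted_block_matrix(block_size = 4, n_blocks = 2, seed = 6)
  cons <- consensus_partition(blk$weights, n_runs = 30, n_check = 10,
                              seed = 5)
  voc <- make_vocab(rownames(blk$weights),
                    seq(20, by = 2, length.out = nrow(blk$weights)))
  tab <- partition_table(cons$partition, voc)
  expect_setequal(tab$lemma, rownames(blk$weights))
  expect_true(all(tab$module_id %in% cons$partition$membership))
  ce <- consensus_edges(cons, threshold = 0.4)
  expect_true(all(ce$co_classification >= 0.4))
  # every within-block pair co-classifies at full frequency here
  expect_gte(nrow(ce), 2 * choose(4, 2))
})
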