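#' Signed modularity of a partition
#'
#' Generalized Newman-Girvan modularity for weighted networks carrying both
#' attractive (positive) and repulsive (negative) edges. With positive and
#' negative layers \eqn{w^+_{ij}, w^-_{ij}} (both non-negative), node
#' strengths \eqn{s^\pm_i = \sum_j w^\pm_{ij}} and layer totals
#' \eqn{v^\pm = \sum_i s^\pm_i}:
#' \deqn{Q = \frac{1}{v^+ + v^-} \sum_{ij}
#'   \left[(w^+_{ij} - e^+_{ij}) - (w^-_{ij} - e^-_{ij})\right]
#'   \delta_{M_i M_j},\qquad e^\pm_{ij} = \frac{s^\pm_i s^\pm_j}{v^\pm}.}
#' Positive weight concentrated within modules raises Q, negative weight
#' within modules lowers it. Q = 0 for the all-in-one partition.
#'
#' @param weights Symmetric signed weight matrix with zero diagonal.
#' @param membership Integer module assignment per node (or a
#'   `coop_partition`).
#' @param resolution Resolution multiplier on the expectation terms
#'   (default 1, the standard objective).
#' @return The modularity value Q.
#' @export
signed_modularity <- function(weights, membership, resolution = 1) {
  check_square_symmetric(weights)
  if (inherits(membership, "coop_partition"))
    membership <- membership$membership
  if (length(membership) != nrow(weights))
    stop_domain("membership length must match matrix dimension")
  if (any(abs(diag(weights)) > 0))
    stop_domain("domain error: weight matrix must have zero diagonal")
  if (all(weights == 0))
    stop_domain("degenerate input: all-zero weight matrix")
  signed_q(weights, as.integer(factor(membership)), resolution)
}

# Core Q on an original (single-signed-entry) matrix: split into layers.
signed_q <- function(w, m, resolution = 1) {
  signed_q_layers(pmax(w, 0), pmax(-w, 0), m, resolution)
}

# Q from explicit positive/negative layers that may carry self-loops
# (aggregated networks): sums run over ordered pairs including the
# diagonal once. The layers are kept separate because aggregation must not
# net out mixed-sign edge bundles.
signed_q_layers <- function(wp, wn, m, resolution = 1) {
  sp <- rowSums(wp); sn <- rowSums(wn)
  vp <- sum(sp); vn <- sum(sn)
  q <- 0
  for (c_ in unique(m)) {
    idx <- m == c_
    if (vp > 0)
      q <- q + sum(wp[idx, idx]) - resolution * sum(sp[idx])^2 / vp
    if (vn > 0)
      q <- q - (sum(wn[idx, idx]) - resolution * sum(sn[idx])^2 / vn)
  }
  q / (vp + vn)
}

# One Louvain level: greedy local moves on explicit positive/negative
# layers (possibly self-looped, from aggregation) until no single-node move
# improves Q. Candidate targets are every current community plus a fresh
# singleton (extraction can be the best move when repulsive weight
# dominates). Returns the membership.
louvain_moves <- function(wp, wn, init = NULL, resolution = 1,
                          eps = 1e-12) {
  n <- nrow(wp)
  sp <- rowSums(wp)
  sn <- rowSums(wn)
  vp <- sum(sp); vn <- sum(sn)
  # self-loops never move with a single node; drop them from the gain
  # terms but keep them in the strengths above
  wp <- wp - diag(diag(wp), n); wn <- wn - diag(diag(wn), n)
  m <- if (is.null(init)) seq_len(n) else as.integer(init)
  Sp <- numeric(n); Sn <- numeric(n)
  tmp <- rowsum(sp, m); Sp[as.integer(rownames(tmp))] <- tmp[, 1]
  tmp <- rowsum(sn, m); Sn[as.integer(rownames(tmp))] <- tmp[, 1]
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (i in sample.int(n)) {
      a <- m[i]
      # detach i from its community
      Sp[a] <- Sp[a] - sp[i]; Sn[a] <- Sn[a] - sn[i]
      kp <- rowsum(wp[, i], m)
      kn <- rowsum(wn[, i], m)
      comms <- as.integer(rownames(kp))
      gain <- numeric(length(comms))
      if (vp > 0)
        gain <- gain + (kp[, 1] - resolution * sp[i] * Sp[comms] / vp)
      if (vn > 0)
        gain <- gain - (kn[, 1] - resolution * sn[i] * Sn[comms] / vn)
      best <- which.max(gain)
      gain_stay <- gain[comms == a]
      if (gain[best] > gain_stay + eps && gain[best] > eps) {
        m[i] <- comms[best]
        improved <- TRUE
      } else if (gain_stay < -eps && gain[best] <= eps) {
        # a fresh singleton (gain 0) beats every occupied target
        m[i] <- which(tabulate(m, n) == 0L)[1]
        improved <- TRUE
      } else if (gain[best] > gain_stay + eps) {
        m[i] <- comms[best]
        improved <- TRUE
      }
      Sp[m[i]] <- Sp[m[i]] + sp[i]; Sn[m[i]] <- Sn[m[i]] + sn[i]
    }
  }
  canonical_membership(m)
}

# Multi-level pass: local moves (optionally warm-started), then aggregation
# with singleton re-initialization, repeated while communities shrink. The
# positive and negative layers are aggregated separately: netting mixed-sign
# edge bundles would change v+/v- and the strengths, hence Q.
louvain_pass <- function(wp, wn, init = NULL, resolution = 1) {
  lev <- louvain_moves(wp, wn, init, resolution)
  m <- lev
  while (max(lev) < nrow(wp)) {
    # aggregate: ordered-pair sums keep Q identical on the coarse network
    wp <- rowsum(t(rowsum(wp, lev)), lev)
    wn <- rowsum(t(rowsum(wn, lev)), lev)
    lev <- louvain_moves(wp, wn, NULL, resolution)
    m <- canonical_membership(lev[m])
  }
  m
}

# Iterate multi-level passes, re-starting each pass from the previous flat
# partition so that node-level refinement can break up merges made on the
# aggregated graph, until Q stops improving.
louvain_iterate <- function(wp, wn, init, resolution) {
  m <- louvain_pass(wp, wn, init, resolution)
  q_old <- signed_q_layers(wp, wn, m, resolution)
  repeat {
    m2 <- louvain_pass(wp, wn, m, resolution)
    q2 <- signed_q_layers(wp, wn, m2, resolution)
    if (q2 <= q_old + 1e-12) break
    m <- m2
    q_old <- q2
  }
  list(m = m, q = q_old)
}

# Full Louvain run: multi-start hill climbing. The classic singleton
# initialization can be trapped by configurations that only a simultaneous
# multi-node move escapes, so each run also climbs from random initial
# partitions and keeps the best optimum found.
louvain_run <- function(w, resolution = 1, n_starts = 2) {
  wp <- pmax(w, 0); wn <- pmax(-w, 0)
  n <- nrow(w)
  best <- louvain_iterate(wp, wn, NULL, resolution)
  for (s in seq_len(n_starts - 1)) {
    k <- sample(2:max(2, ceiling(n / 2)), 1)
    init <- canonical_membership(sample.int(k, n, replace = TRUE))
    cand <- louvain_iterate(wp, wn, init, resolution)
    if (cand$q > best$q + 1e-12) best <- cand
  }
  canonical_membership(best$m)
}

#' Louvain optimization of signed modularity
#'
#' Greedy two-phase Louvain maximization of [signed_modularity()]: repeated
#' single-node moves in shuffled order, then aggregation of modules into
#' super-nodes, until no improvement. Different seeds explore different
#' local optima, which is what the consensus procedure averages over.
#'
#' @param weights Symmetric signed weight matrix, zero diagonal.
#' @param seed RNG seed controlling the node visit order.
#' @param resolution Resolution parameter (default 1).
#' @return A `coop_partition`: list with `membership` (named when the matrix
#'   has dimnames), `Q`, `n_modules`.
#' @export
louvain_partition <- function(weights, seed = NULL, resolution = 1) {
  check_square_symmetric(weights)
  m <- with_seed(seed, louvain_run(weights, resolution))
  q <- signed_q(weights, m, resolution)
  names(m) <- rownames(weights)
  structure(list(membership = m, Q = q, n_modules = max(m),
                 resolution = resolution),
            class = "coop_partition")
}

#' @export
print.coop_partition <- function(x, ...) {
  cat("Partition:", x$n_modules, "modules, Q =", format(x$Q, digits = 4),
      "\n")
  print(table(module = x$membership))
  invisible(x)
}

#' Consensus partitioning over repeated Louvain runs
#'
#' Runs Louvain `n_runs` times on the signed network and records, for every
#' node pair, the fraction of runs in which the two nodes share a module
#' (the consensus matrix). The consensus matrix (non-negative, so the same
#' optimizer applies with an empty repulsive layer) is then re-partitioned
#' `n_check` times; if all `n_check` partitions agree, that partition is
#' the consensus, otherwise the consensus matrix is replaced by the
#' co-classification matrix of those `n_check` partitions and the step
#' repeats, up to `max_rounds`.
#'
#' @param weights Symmetric signed weight matrix, zero diagonal.
#' @param n_runs Initial Louvain runs building the consensus matrix
#'   (default 5000).
#' @param n_check Partitions per agreement round (default 100).
#' @param seed Master seed; per-run seeds are spawned deterministically.
#' @param max_rounds Agreement rounds allowed before a convergence error
#'   (default 50).
#' @param resolution Resolution parameter passed through to Louvain.
#' @param keep_runs Keep the `n_runs` x n membership matrix of the initial
#'   runs (needed for cross-sample run-pair comparisons; default TRUE).
#' @return A `coop_consensus`: list with `partition` (a `coop_partition`
#'   evaluated on the original signed network), `consensus_matrix`
#'   (unit-diagonal co-classification frequencies), `mean_Q` (mean
#'   modularity of the initial runs), `rounds`, and optionally `runs`.
#' @export
consensus_partition <- function(weights, n_runs = 5000, n_check = 100,
                                seed = NULL, max_rounds = 50,
                                resolution = 1, keep_runs = TRUE) {
  check_square_symmetric(weights)
  n <- nrow(weights)
  seeds <- spawn_seeds(seed, n_runs + max_rounds * n_check)
  runs <- matrix(0L, n_runs, n)
  qs <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    m <- with_seed(seeds[[r]], louvain_run(weights, resolution))
    runs[r, ] <- m
    qs[r] <- signed_q(weights, m, resolution)
  }
  D <- coclassification(runs)
  cons_full <- D # report the matrix from the initial runs
  rounds <- 0L
  final <- NULL
  si <- n_runs
  repeat {
    rounds <- rounds + 1L
    if (rounds > max_rounds)
      stop_domain("convergence error: no consensus agreement after ",
                  max_rounds, " rounds (last round had ",
                  nrow(unique(check_runs)), " distinct partitions)")
    Dw <- D
    diag(Dw) <- 0
    check_runs <- matrix(0L, n_check, n)
    for (r in seq_len(n_check)) {
      si <- si + 1L
      check_runs[r, ] <- with_seed(seeds[[si]], louvain_run(Dw, resolution))
    }
    if (all(check_runs == rep(check_runs[1, ], each = n_check))) {
      final <- check_runs[1, ]
      break
    }
    D <- coclassification(check_runs)
  }
  names(final) <- rownames(weights)
  part <- structure(list(membership = final,
                         Q = signed_q(weights, final, resolution),
                         n_modules = max(final), resolution = resolution),
                    class = "coop_partition")
  structure(list(partition = part, consensus_matrix = cons_full,
                 mean_Q = mean(qs), q_runs = qs, rounds = rounds,
                 n_runs = n_runs, n_check = n_check, seed = seed,
                 runs = if (keep_runs) runs else NULL),
            class = "coop_consensus")
}

# Pairwise co-classification frequency of a runs x nodes membership matrix.
coclassification <- function(runs) {
  n <- ncol(runs)
  D <- matrix(0, n, n)
  for (r in seq_len(nrow(runs))) {
    m <- runs[r, ]
    D <- D + outer(m, m, "==")
  }
  D / nrow(runs)
}

#' @export
print.coop_consensus <- function(x, ...) {
  cat("Consensus partition:", x$partition$n_modules, "modules after",
      x$rounds, "agreement round(s)\n")
  cat(sprintf("  mean Q over %d runs: %.4f; consensus partition Q: %.4f\n",
              x$n_runs, x$mean_Q, x$partition$Q))
  invisible(x)
}

#' Label modules by their two most frequent associations
#'
#' Builds a human-readable label "A & B" per module from the two highest-
#' frequency lemmas it contains (single-lemma modules are labeled by that
#' lemma). Frequency ties are broken lexicographically so labels are
#' deterministic.
#'
#' @param partition A `coop_partition` with named membership.
#' @param vocabulary The `coop_vocabulary` providing lemma frequencies.
#' @return Named character vector, one label per module id.
#' @export
label_modules <- function(partition, vocabulary) {
  m <- partition$membership
  if (is.null(names(m)))
    stop_domain("partition must carry node names to be labeled")
  freq <- stats::setNames(vocabulary$count, vocabulary$lemma)[names(m)]
  vapply(sort(unique(m)), function(mod) {
    lem <- names(m)[m == mod]
    ord <- order(-freq[lem], lem)
    top <- lem[ord][seq_len(min(2, length(lem)))]
    paste(titlecase(top), collapse = " & ")
  }, character(1))
}

#' Flag modules too small for downstream analysis
#'
#' Modules with fewer than `min_distinct` distinct lemmas (e.g. singletons)
#' are flagged as excluded from attitude comparisons; network membership is
#' unchanged.
#'
#' @param partition A `coop_partition`.
#' @param min_distinct Minimum distinct lemmas for a module to be kept
#'   (default 2).
#' @return List with `partition` (unchanged), `excluded` (module ids) and
#'   `kept` (module ids).
#' @export
filter_small_modules <- function(partition, min_distinct = 2) {
  sizes <- table(partition$membership)
  excluded <- as.integer(names(sizes)[sizes < min_distinct])
  list(partition = partition, excluded = excluded,
       kept = setdiff(as.integer(names(sizes)), excluded))
}

#' Export a partition table
#'
#' One row per association: lemma, module id, module label, frequency —
#' mirroring published module-membership tables.
#'
#' @param partition A `coop_partition` with named membership.
#' @param vocabulary The source `coop_vocabulary`.
#' @return Data frame `lemma`, `module_id`, `module_label`, `frequency`.
#' @export
partition_table <- function(partition, vocabulary) {
  labs <- label_modules(partition, vocabulary)
  m <- partition$membership
  freq <- stats::setNames(vocabulary$count, vocabulary$lemma)[names(m)]
  out <- data.frame(lemma = names(m), module_id = as.integer(m),
                    module_label = labs[m], frequency = as.integer(freq),
                    stringsAsFactors = FALSE)
  out[order(out$module_id, -out$frequency, out$lemma), ]
}

#' Consensus-graph edge list for visualization
#'
#' Edges between associations that fell into a common module in at least a
#' given fraction of the consensus runs (default 40%), the convention used
#' for module figures.
#'
#' @param consensus A `coop_consensus`.
#' @param nodes Node names (defaults to the consensus partition's).
#' @param threshold Minimum co-classification frequency (default 0.4).
#' @return Data frame `node_i`, `node_j`, `co_classification`.
#' @export
consensus_edges <- function(consensus, nodes = NULL, threshold = 0.4) {
  D <- consensus$consensus_matrix
  if (is.null(nodes)) nodes <- names(consensus$partition$membership)
  ut <- upper.tri(D)
  keep <- ut & D >= threshold
  data.frame(node_i = nodes[row(D)[keep]], node_j = nodes[col(D)[keep]],
             co_classification = D[keep], stringsAsFactors = FALSE)
}
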