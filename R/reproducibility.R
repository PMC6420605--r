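#' QAP permutation correlation between two weighted networks
#'
#' Spearman correlation of the edge weights of two networks on the same
#' node set, with significance from the quadratic assignment procedure:
#' the rows and columns of the first matrix are permuted jointly `n_perm`
#' times (preserving the within-node dependence of edges) and the p-value
#' is the add-one fraction of permutations whose absolute correlation
#' reaches the observed one.
#'
#' @param A,B Symmetric weighted matrices restricted to the shared node
#'   set, same ordering (or two `coop_network`s, which are restricted to
#'   their shared nodes automatically).
#' @param n_perm Number of permutations (default 5000).
#' @param seed RNG seed.
#' @return A `coop_qap`: list with `rho`, `p_qap`, `n_pairs`, `n_perm` and
#'   a summary of the permutation distribution.
#' @export
qap_correlation <- function(A, B, n_perm = 5000, seed = NULL) {
  if (inherits(A, "coop_network") && inherits(B, "coop_network")) {
    shared <- intersect(A$nodes, B$nodes)
    if (length(shared) < 3)
      stop_domain("degenerate input: fewer than 3 shared nodes")
    A <- A$weights[shared, shared]
    B <- B$weights[shared, shared]
  }
  check_square_symmetric(A, "A"); check_square_symmetric(B, "B")
  if (nrow(A) != nrow(B))
    stop_domain("A and B must cover the same node set")
  if (nrow(A) < 3)
    stop_domain("degenerate input: fewer than 3 shared nodes")
  ut <- upper.tri(A)
  ii <- row(A)[ut]; jj <- col(A)[ut]
  b <- B[ut]
  rb <- rank(b)
  rho <- stats::cor(rank(A[ut]), rb)
  n <- nrow(A)
  perm_abs <- with_seed(seed, vapply(seq_len(n_perm), function(k) {
    p <- sample.int(n)
    abs(stats::cor(rank(A[cbind(p[ii], p[jj])]), rb))
  }, numeric(1)))
  p_qap <- (1 + sum(perm_abs >= abs(rho))) / (n_perm + 1)
  structure(list(rho = rho, p_qap = p_qap, n_pairs = sum(ut),
                 n_perm = n_perm, seed = seed,
                 perm_abs_summary = summary(perm_abs)),
            class = "coop_qap")
}

#' @export
print.coop_qap <- function(x, ...) {
  cat(sprintf("QAP Spearman correlation: rs(%d) = %.3f, p_QAP = %.4g (%d permutations)\n",
              x$n_pairs - 2L, x$rho, x$p_qap, x$n_perm))
  invisible(x)
}

#' Normalized mutual information between two partitions
#'
#' Entropy-based similarity of two module partitions of a shared node set:
#' \deqn{nMI = 2\,\frac{H(M_1) + H(M_2) - H(M_1, M_2)}{H(M_1) + H(M_2)}}
#' with entropies from module-size frequencies and the joint entropy from
#' the co-membership contingency table. Symmetric, relabel-invariant, in
#' \[0, 1\]. Named memberships are restricted to the shared node set first.
#' If both partitions are trivial (single module) the limit 1 is returned;
#' if exactly one is trivial, 0.
#'
#' @param p1,p2 `coop_partition`s or membership vectors (named vectors are
#'   matched by name).
#' @return nMI value in \[0, 1\].
#' @export
nmi <- function(p1, p2) {
  m1 <- if (inherits(p1, "coop_partition")) p1$membership else p1
  m2 <- if (inherits(p2, "coop_partition")) p2$membership else p2
  if (!is.null(names(m1)) && !is.null(names(m2))) {
    shared <- intersect(names(m1), names(m2))
    if (length(shared) == 0) stop_domain("domain error: no shared nodes")
    m1 <- m1[shared]; m2 <- m2[shared]
  }
  if (length(m1) != length(m2))
    stop_domain("partitions must cover the same node set")
  if (length(m1) == 0) stop_domain("domain error: empty node set")
  ent <- function(counts) {
    p <- counts[counts > 0] / sum(counts)
    -sum(p * log(p))
  }
  h1 <- ent(table(m1)); h2 <- ent(table(m2))
  if (h1 == 0 && h2 == 0) return(1)
  if (h1 == 0 || h2 == 0) return(0)
  h12 <- ent(table(m1, m2))
  2 * (h1 + h2 - h12) / (h1 + h2)
}

#' Edge-, weight- and strength-preserving signed null network
#'
#' Randomizes a signed network while preserving, exactly, the per-node
#' positive and negative degree sequences and the multiset of edge weights
#' within each sign layer, and, approximately, the per-node positive and
#' negative strengths. Each layer is rewired by degree-preserving
#' double-edge swaps; the original layer's weights are then re-assigned to
#' the rewired edges by iterative rank-matching: edges are ranked by the
#' product of the residual strengths of their endpoints and matched to the
#' same-rank remaining weights, a batch at a time, so that node strengths
#' converge toward the originals.
#'
#' Layers with fewer than 4 edges cannot be rewired and are copied
#' unchanged with a warning.
#'
#' @param coop A `coop_network` (or any symmetric signed matrix).
#' @param seed RNG seed.
#' @param n_swaps_factor Attempted swaps per edge in each layer
#'   (default 10).
#' @param batch_frac Fraction of remaining edges assigned per strength
#'   re-evaluation during weight placement (default 0.1; smaller tracks
#'   strengths more closely at higher cost).
#' @return An object of the same shape as the input with randomized
#'   `weights` (a `coop_network` keeps its nodes, frequencies and counts).
#' @export
generate_null_model <- function(coop, seed = NULL, n_swaps_factor = 10,
                                batch_frac = 0.1) {
  w <- if (inherits(coop, "coop_network")) coop$weights else coop
  check_square_symmetric(w)
  n <- nrow(w)
  null_w <- with_seed(seed, {
    rw <- rewire_signed(w, n_swaps_factor)
    out <- matrix(0, n, n, dimnames = dimnames(w))
    for (sgn in c(1, -1)) {
      E <- if (sgn > 0) rw$pos else rw$neg
      if (nrow(E) == 0) next
      layer <- sgn * w
      wts <- layer[upper.tri(layer) & layer > 0]
      strengths <- rowSums(layer * (layer > 0))
      aw <- assign_weights(E[, 1], E[, 2], wts, strengths, batch_frac)
      out[E] <- out[E] + sgn * aw
    }
    out + t(out)
  })
  if (inherits(coop, "coop_network")) {
    coop$weights <- null_w
    coop$joint <- NULL # joint counts no longer meaningful after rewiring
    coop
  } else null_w
}

# Signed-degree-preserving rewiring of a simple signed graph. A swap of two
# same-sign edges (a,b),(c,d) -> (a,d),(c,b) is valid when the two target
# slots agree and do not carry that sign: both empty (the classic
# double-edge swap) or both of the opposite sign, in which case those two
# opposite-sign edges relocate to the vacated slots (a checkerboard swap,
# the only move available in dense signed networks). Either move preserves
# every node's positive and negative degree exactly.
rewire_signed <- function(w, n_swaps_factor) {
  n <- nrow(w)
  S <- sign(w)
  edge_list <- function(sgn) {
    sel <- upper.tri(w) & S == sgn
    cbind(row(w)[sel], col(w)[sel])
  }
  E <- list(pos = edge_list(1), neg = edge_list(-1))
  # idx[i, j]: position of edge (i, j) within its layer's edge list
  idx <- matrix(0L, n, n)
  for (l in c("pos", "neg")) {
    if (nrow(E[[l]]) > 0) {
      idx[E[[l]]] <- seq_len(nrow(E[[l]]))
      idx[E[[l]][, c(2, 1), drop = FALSE]] <- seq_len(nrow(E[[l]]))
    }
  }
  small <- vapply(E, nrow, integer(1)) < 4
  if (any(small & vapply(E, nrow, integer(1)) > 0))
    warning("sign layer with fewer than 4 edges cannot be rewired; ",
            "copied unchanged")
  for (l in c("pos", "neg")) {
    if (small[[l]]) next
    sgn <- if (l == "pos") 1 else -1
    ne <- nrow(E[[l]])
    attempts <- ceiling(n_swaps_factor * ne)
    pick <- matrix(sample.int(ne, 2 * attempts, replace = TRUE), ncol = 2)
    flip <- stats::runif(attempts) < 0.5
    for (t in seq_len(attempts)) {
      e1 <- pick[t, 1]; e2 <- pick[t, 2]
      if (e1 == e2) next
      a <- E[[l]][e1, 1]; b <- E[[l]][e1, 2]
      c_ <- E[[l]][e2, 1]; d <- E[[l]][e2, 2]
      if (flip[t]) { tmp <- c_; c_ <- d; d <- tmp }
      if (a == c_ || a == d || b == c_ || b == d) next
      t1 <- S[a, d]; t2 <- S[c_, b]
      if (t1 == sgn || t2 == sgn || t1 != t2) next
      other <- if (l == "pos") "neg" else "pos"
      if (t1 != 0) {
        # relocate the two opposite-sign edges into the vacated slots
        o1 <- idx[a, d]; o2 <- idx[c_, b]
        E[[other]][o1, ] <- sort(c(a, b))
        E[[other]][o2, ] <- sort(c(c_, d))
        idx[a, b] <- idx[b, a] <- o1
        idx[c_, d] <- idx[d, c_] <- o2
      } else {
        idx[a, b] <- idx[b, a] <- 0L
        idx[c_, d] <- idx[d, c_] <- 0L
      }
      S[a, b] <- S[b, a] <- t1
      S[c_, d] <- S[d, c_] <- t1
      S[a, d] <- S[d, a] <- sgn
      S[c_, b] <- S[b, c_] <- sgn
      E[[l]][e1, ] <- sort(c(a, d))
      E[[l]][e2, ] <- sort(c(c_, b))
      idx[a, d] <- idx[d, a] <- e1
      idx[c_, b] <- idx[b, c_] <- e2
    }
  }
  E
}

# Strength-tracking weight placement: repeatedly rank the unassigned edges
# by the product of their endpoints' residual strengths and give a randomly
# chosen batch the remaining weights of matching rank.
assign_weights <- function(ei, ej, wts, strengths, batch_frac = 0.1) {
  ne <- length(ei)
  res <- strengths
  w_sorted <- sort(wts, decreasing = TRUE)
  assigned <- numeric(ne)
  left <- seq_len(ne)
  while (length(left) > 0) {
    P <- res[ei[left]] * res[ej[left]]
    ordP <- order(-P, stats::runif(length(P))) # random tie-break
    b <- max(1L, ceiling(batch_frac * length(left)))
    chosen_pos <- sort(sample.int(length(left), b)) # positions in `left`
    # rank of each chosen edge among unassigned edges
    rank_of <- match(chosen_pos, ordP)
    take <- ordP[sort(rank_of)] # process in rank order
    rks <- sort(rank_of)
    assigned[left[take]] <- w_sorted[rks]
    for (k in seq_along(take)) {
      e <- left[take[k]]
      res[ei[e]] <- res[ei[e]] - assigned[e]
      res[ej[e]] <- res[ej[e]] - assigned[e]
    }
    w_sorted <- w_sorted[-rks]
    left <- left[-take]
  }
  assigned
}

#' Cross-sample modular similarity against signed null models
#'
#' Tests whether two CoOp networks share modular structure beyond what
#' their edge-, weight- and strength-preserving randomizations produce.
#' The observed nMI between the two networks' consensus partitions
#' (restricted to shared nodes) is compared with the nMI distribution
#' obtained from `n_null` paired null models: each of the two networks is
#' randomized, each null network is partitioned (single seeded Louvain run
#' per null network), and the nMI between the paired null partitions is
#' recorded. The networks are significantly similar when the observed nMI
#' exceeds the null distribution's 95th percentile; the reported p is the
#' add-one fraction of null nMI values at or above the observed.
#'
#' @param net1,net2 `coop_network`s.
#' @param n_null Number of paired null models (default 5000).
#' @param seed Master seed.
#' @param n_runs,n_check Consensus parameters for the observed partitions.
#' @param cross_pairs If > 0, also estimate the run-pair average nMI: mean
#'   nMI over this many random pairs of single Louvain runs from the two
#'   consensus ensembles (default 5000).
#' @return A `coop_null_report`: observed consensus nMI, run-pair mean nMI,
#'   null nMI sample, empirical p.
#' @export
modular_similarity_test <- function(net1, net2, n_null = 5000, seed = NULL,
                                    n_runs = 5000, n_check = 100,
                                    cross_pairs = 5000) {
  shared <- intersect(net1$nodes, net2$nodes)
  if (length(shared) < 3)
    stop_domain("degenerate input: fewer than 3 shared nodes")
  seeds <- spawn_seeds(seed, 4)
  cons1 <- consensus_partition(net1$weights, n_runs = n_runs,
                               n_check = n_check, seed = seeds[[1]])
  cons2 <- consensus_partition(net2$weights, n_runs = n_runs,
                               n_check = n_check, seed = seeds[[2]])
  observed <- nmi(cons1$partition, cons2$partition)
  mean_pair_nmi <- NA_real_
  if (cross_pairs > 0 && !is.null(cons1$runs)) {
    i1 <- match(shared, net1$nodes); i2 <- match(shared, net2$nodes)
    mean_pair_nmi <- with_seed(seeds[[3]], {
      a <- sample.int(nrow(cons1$runs), cross_pairs, replace = TRUE)
      b <- sample.int(nrow(cons2$runs), cross_pairs, replace = TRUE)
      mean(vapply(seq_len(cross_pairs), function(k)
        nmi(cons1$runs[a[k], i1], cons2$runs[b[k], i2]), numeric(1)))
    })
  }
  null_seeds <- spawn_seeds(seeds[[4]], 4 * n_null)
  null_nmi <- numeric(n_null)
  for (k in seq_len(n_null)) {
    nm1 <- generate_null_model(net1, seed = null_seeds[[4 * k - 3]])
    nm2 <- generate_null_model(net2, seed = null_seeds[[4 * k - 2]])
    p1 <- louvain_partition(nm1$weights, seed = null_seeds[[4 * k - 1]])
    p2 <- louvain_partition(nm2$weights, seed = null_seeds[[4 * k]])
    null_nmi[k] <- nmi(p1$membership[match(shared, net1$nodes)],
                       p2$membership[match(shared, net2$nodes)])
  }
  p <- (1 + sum(null_nmi >= observed)) / (n_null + 1)
  structure(list(observed_nmi = observed, mean_pair_nmi = mean_pair_nmi,
                 null_nmi = null_nmi, p = p, n_null = n_null,
                 n_shared = length(shared), seed = seed,
                 consensus1 = cons1, consensus2 = cons2),
            class = "coop_null_report")
}

#' @export
print.coop_null_report <- function(x, ...) {
  cat(sprintf("Cross-sample modular similarity: nMI = %.3f (consensus), p = %.4g\n",
              x$observed_nmi, x$p))
  if (!is.na(x$mean_pair_nmi))
    cat(sprintf("  run-pair average nMI = %.3f\n", x$mean_pair_nmi))
  cat(sprintf("  null nMI over %d paired null models: median %.3f, 95th pct %.3f\n",
              x$n_null, stats::median(x$null_nmi),
              stats::quantile(x$null_nmi, 0.95)))
  invisible(x)
}

#' Stability of edges and modules under the rare-association threshold
#'
#' Rebuilds two samples' CoOp networks for each minimum-occurrence
#' threshold and records the shared-node edge-level Spearman correlation
#' and consensus-partition nMI, together with the Spearman trend of each
#' curve against the threshold. Raising the threshold concentrates the
#' analysis on core (frequent, stable) associations, which is expected to
#' raise both similarities.
#'
#' @param records1,records2 Two validated respondent data frames.
#' @param thresholds Integer thresholds to sweep (default 3:13).
#' @param seed Master seed.
#' @param n_runs,n_check Consensus parameters per threshold.
#' @return A `coop_stability`: data frame `threshold`, `n_shared`,
#'   `edge_spearman`, `modular_nmi` (missing points flagged NA) plus trend
#'   correlations in attributes `trend_edge`, `trend_nmi`.
#' @export
threshold_sweep <- function(records1, records2, thresholds = 3:13,
                            seed = NULL, n_runs = 1000, n_check = 100) {
  seeds <- spawn_seeds(seed, 2 * length(thresholds))
  rows <- lapply(seq_along(thresholds), function(k) {
    th <- thresholds[k]
    out <- data.frame(threshold = th, n_shared = 0L,
                      edge_spearman = NA_real_, modular_nmi = NA_real_)
    v1 <- build_vocabulary(records1, th)
    v2 <- build_vocabulary(records2, th)
    if (attr(v1, "n_retained") < 2 || attr(v2, "n_retained") < 2)
      return(out)
    n1 <- build_coop_network(records1, v1)
    n2 <- build_coop_network(records2, v2)
    shared <- intersect(n1$nodes, n2$nodes)
    out$n_shared <- length(shared)
    if (length(shared) < 3) return(out)
    A <- n1$weights[shared, shared]; B <- n2$weights[shared, shared]
    ut <- upper.tri(A)
    out$edge_spearman <- stats::cor(A[ut], B[ut], method = "spearman")
    c1 <- consensus_partition(n1$weights, n_runs = n_runs,
                              n_check = n_check, seed = seeds[[2 * k - 1]],
                              keep_runs = FALSE)
    c2 <- consensus_partition(n2$weights, n_runs = n_runs,
                              n_check = n_check, seed = seeds[[2 * k]],
                              keep_runs = FALSE)
    out$modular_nmi <- nmi(c1$partition, c2$partition)
    out
  })
  curve <- do.call(rbind, rows)
  ok <- stats::complete.cases(curve)
  trend <- function(y) {
    if (sum(ok) < 3 || stats::sd(y[ok]) == 0) return(NA_real_)
    stats::cor(curve$threshold[ok], y[ok], method = "spearman")
  }
  structure(curve, class = c("coop_stability", "data.frame"),
            trend_edge = trend(curve$edge_spearman),
            trend_nmi = trend(curve$modular_nmi), seed = seed)
}

#' @export
print.coop_stability <- function(x, ...) {
  cat("Threshold sweep over", nrow(x), "thresholds\n")
  print.data.frame(x)
  cat(sprintf("Trend vs threshold (Spearman): edges %.3f, modules %.3f\n",
              attr(x, "trend_edge"), attr(x, "trend_nmi")))
  invisible(x)
}
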