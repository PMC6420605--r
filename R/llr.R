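#' Signed log-likelihood-ratio co-occurrence statistic
#'
#' Dunning-style collocation statistic for a pair of associations, signed by
#' attraction versus repulsion. For associations i and j mentioned by `i_n`
#' and `j_n` of `n` respondents, with `k11` respondents mentioning both, the
#' likelihood of the joint counts under independence (a single binomial rate
#' for j regardless of i) is compared with the maximum likelihood under
#' separate rates for j given i present and i absent:
#' \deqn{\lambda = \frac{L(k_{11}, i_n, j_n/n)\, L(j_n - k_{11}, n - i_n, j_n/n)}
#'                      {L(k_{11}, i_n, k_{11}/i_n)\, L(j_n - k_{11}, n - i_n, (j_n-k_{11})/(n-i_n))}}
#' The statistic is \eqn{-\ln\lambda} (positive, attraction) when the
#' observed joint count is at or above the independence expectation
#' \eqn{i_n j_n / n}, and \eqn{\ln\lambda} (negative, repulsion) below it.
#' Binomial coefficients cancel in the ratio, so only the
#' \eqn{k\ln p + (m-k)\ln(1-p)} kernels are evaluated, with the continuity
#' convention \eqn{0 \ln 0 = 0}. Twice the absolute value is the G statistic
#' of the 2x2 respondent contingency table and is asymptotically chi-squared
#' with 1 degree of freedom.
#'
#' All arguments recycle; the function is vectorised.
#'
#' @param i_n,j_n Respondent counts for the two associations.
#' @param k11 Respondents mentioning both.
#' @param n Total respondents.
#' @return Signed LLR in nats (natural-log units).
#' @export
#' @examples
#' compute_llr(93, 97, 6, 505)   # strong repulsion, about -7.27
#' compute_llr(10, 10, 1, 100)   # observed equals expected: 0
compute_llr <- function(i_n, j_n, k11, n) {
  m <- cbind(i_n, j_n, k11, n)
  i_n <- m[, 1]; j_n <- m[, 2]; k11 <- m[, 3]; n <- m[, 4]
  if (any(n < 1)) stop_domain("domain error: n must be positive")
  if (any(i_n < 0 | j_n < 0 | i_n > n | j_n > n))
    stop_domain("domain error: need 0 <= i_n, j_n <= n")
  if (any(k11 < 0 | k11 > pmin(i_n, j_n) | k11 < i_n + j_n - n))
    stop_domain("domain error: joint count k11 outside ",
                "[max(0, i_n + j_n - n), min(i_n, j_n)]")
  # log-binomial kernel k*log(p) + (m-k)*log(1-p) with 0*log(0) = 0
  kern <- function(k, m, p) {
    out <- numeric(length(k))
    a <- k > 0
    out[a] <- out[a] + k[a] * log(p[a])
    b <- (m - k) > 0
    out[b] <- out[b] + (m[b] - k[b]) * log1p(-p[b])
    out
  }
  k21 <- j_n - k11
  ni <- n - i_n
  p0 <- j_n / n
  ln_lambda <- kern(k11, i_n, p0) + kern(k21, ni, p0) -
    kern(k11, i_n, ifelse(i_n > 0, k11 / i_n, 0)) -
    kern(k21, ni, ifelse(ni > 0, k21 / ni, 0))
  expected <- i_n * j_n / n
  out <- ifelse(k11 >= expected, -ln_lambda, ln_lambda)
  # exact independence gives ln(1) up to roundoff; pin the sign convention
  out[abs(k11 - expected) < 1e-12] <- 0
  unname(out)
}

#' Expected co-occurrence count under independence
#'
#' The number of respondents expected to mention both associations were the
#' two independent: \eqn{n (i_n/n)(j_n/n)}. The integer is reported with
#' truncation toward zero; the continuous value is kept in the `exact`
#' attribute.
#'
#' @inheritParams compute_llr
#' @return Integer vector (truncated expectation) with attribute `exact`.
#' @export
#' @examples
#' expected_cooccurrence(93, 97, 505)   # 17 (exact 17.86)
expected_cooccurrence <- function(i_n, j_n, n) {
  m <- cbind(i_n, j_n, n)
  i_n <- m[, 1]; j_n <- m[, 2]; n <- m[, 3]
  if (any(n < 1)) stop_domain("domain error: n must be positive")
  if (any(i_n < 0 | j_n < 0 | i_n > n | j_n > n))
    stop_domain("domain error: need 0 <= i_n, j_n <= n")
  exact <- unname(i_n * j_n / n)
  structure(as.integer(trunc(exact)), exact = exact)
}

#' Tail probability of a co-occurrence LLR
#'
#' Utility exposing the chi-squared correspondence: `2 * abs(llr)` is
#' referred to a chi-squared distribution with 1 degree of freedom. Not used
#' to prune edges anywhere in the package.
#'
#' @param llr Signed LLR value(s).
#' @return Upper-tail p-value(s).
#' @export
llr_chisq_p <- function(llr) {
  stats::pchisq(2 * abs(llr), df = 1, lower.tail = FALSE)
}

#' Build a co-occurring-opinions (CoOp) network
#'
#' Constructs the complete weighted signed graph over the retained
#' association vocabulary: nodes are retained lemmas, and every pair carries
#' the signed LLR of its respondent-level co-occurrence (a pair co-occurs in
#' a respondent who mentions both lemmas, each respondent counted once).
#'
#' @param records Validated respondent data frame.
#' @param vocabulary A `coop_vocabulary` built from the same records
#'   ([build_vocabulary()]).
#' @return A `coop_network` object: list with `nodes` (retained lemmas),
#'   `weights` (symmetric LLR matrix, zero diagonal), `joint` (symmetric
#'   joint-count matrix), `node_freq` (respondent counts), `n` (total
#'   respondents) and `threshold` (the min-occurrence used).
#' @export
build_coop_network <- function(records, vocabulary) {
  nodes <- retained_lemmas(vocabulary)
  if (length(nodes) < 2)
    stop_domain("degenerate input: fewer than 2 retained lemmas")
  per_resp <- respondent_lemmas(records)
  n <- length(per_resp)
  # respondent x lemma incidence, then joint counts by crossproduct
  inc <- matrix(0L, n, length(nodes), dimnames = list(NULL, nodes))
  for (r in seq_len(n)) {
    hit <- match(per_resp[[r]], nodes)
    inc[r, hit[!is.na(hit)]] <- 1L
  }
  joint <- crossprod(inc)
  freq <- diag(joint)
  if (any(freq < attr(vocabulary, "min_occurrence")))
    stop_domain("vocabulary was not built from these records: ",
                "retained lemma below threshold")
  m <- length(nodes)
  w <- matrix(0, m, m, dimnames = list(nodes, nodes))
  ut <- upper.tri(w)
  ii <- row(w)[ut]; jj <- col(w)[ut]
  vals <- compute_llr(freq[ii], freq[jj], joint[cbind(ii, jj)], n)
  w[ut] <- vals
  w <- w + t(w)
  structure(list(nodes = nodes, weights = w, joint = joint,
                 node_freq = stats::setNames(as.integer(freq), nodes),
                 n = n, threshold = attr(vocabulary, "min_occurrence")),
            class = "coop_network")
}

#' @export
print.coop_network <- function(x, ...) {
  ut <- upper.tri(x$weights)
  cat("CoOp network:", length(x$nodes), "associations,", x$n,
      "respondents (min occurrence ", x$threshold, ")\n", sep = " ")
  cat(sprintf("  signed LLR edges: %d positive, %d negative, %d zero\n",
              sum(x$weights[ut] > 0), sum(x$weights[ut] < 0),
              sum(x$weights[ut] == 0)))
  cat(sprintf("  weight range [%.3f, %.3f]\n",
              min(x$weights[ut]), max(x$weights[ut])))
  invisible(x)
}

#' @export
summary.coop_network <- function(object, ...) {
  ut <- upper.tri(object$weights)
  w <- object$weights[ut]
  structure(list(n_nodes = length(object$nodes), n_respondents = object$n,
                 threshold = object$threshold,
                 n_positive = sum(w > 0), n_negative = sum(w < 0),
                 weight_summary = summary(w),
                 top_nodes = utils::head(
                   sort(object$node_freq, decreasing = TRUE), 10)),
            class = "summary.coop_network")
}

#' @export
print.summary.coop_network <- function(x, ...) {
  cat("CoOp network over", x$n_nodes, "retained associations (",
      x$n_respondents, "respondents, threshold", x$threshold, ")\n")
  cat("Edges:", x$n_positive, "attractive /", x$n_negative, "repulsive\n")
  cat("LLR weight distribution:\n")
  print(x$weight_summary)
  cat("Most frequent associations:\n")
  print(x$top_nodes)
  invisible(x)
}

#' Histogram of signed edge weights
#'
#' @param x A `coop_network`.
#' @param ... Passed to [graphics::hist()].
#' @export
plot.coop_network <- function(x, ...) {
  w <- x$weights[upper.tri(x$weights)]
  graphics::hist(w, breaks = 50, main = "Signed LLR edge weights",
                 xlab = "LLR (nats)", col = "grey80", border = "white", ...)
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}

#' Edge list of a CoOp network
#'
#' @param net A `coop_network`.
#' @return Data frame `node_i`, `node_j`, `llr`, `joint`, `expected` (one
#'   row per unordered pair).
#' @export
coop_edge_list <- function(net) {
  w <- net$weights
  ut <- upper.tri(w)
  ii <- row(w)[ut]; jj <- col(w)[ut]
  exp_ <- expected_cooccurrence(net$node_freq[ii], net$node_freq[jj], net$n)
  data.frame(node_i = net$nodes[ii], node_j = net$nodes[jj],
             llr = w[ut], joint = net$joint[cbind(ii, jj)],
             expected = attr(exp_, "exact"),
             stringsAsFactors = FALSE)
}

#' Export a CoOp network to GraphML
#'
#' Writes the full signed network with node frequency attributes for
#' Gephi-style viewers. Requires the igraph package.
#'
#' @param net A `coop_network`.
#' @param path Output path.
#' @param prune_abs Optional: drop edges with `abs(llr)` below this value.
#' @export
write_coop_graphml <- function(net, path, prune_abs = 0) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stop_domain("GraphML export requires the igraph package")
  w <- net$weights
  w[abs(w) < prune_abs] <- 0
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::V(g)$frequency <- as.integer(net$node_freq[igraph::V(g)$name])
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
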