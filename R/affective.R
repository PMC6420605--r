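#' Emotion-label profiles per association
#'
#' Builds the 20 x m count matrix E, where `E[e, i]` is the number of times
#' emotion label e was assigned to retained association i. Each respondent
#' who mentions an association contributes the two labels from its first
#' slot holding that lemma, so a retained lemma's column sum is at least
#' twice the occurrence threshold.
#'
#' @param records Validated respondent data frame.
#' @param vocabulary A `coop_vocabulary` from the same records.
#' @param emotions Emotion vocabulary (default [coop_emotions()]).
#' @return Integer matrix with `length(emotions)` rows (canonical label
#'   order) and one column per retained lemma.
#' @export
emotion_profiles <- function(records, vocabulary,
                             emotions = coop_emotions()) {
  nodes <- retained_lemmas(vocabulary)
  E <- matrix(0L, length(emotions), length(nodes),
              dimnames = list(emotions, nodes))
  acols <- paste0("assoc_", 1:5)
  am <- as.matrix(records[, acols, drop = FALSE])
  la <- as.matrix(records[, paste0("emo_", 1:5, "a"), drop = FALSE])
  lb <- as.matrix(records[, paste0("emo_", 1:5, "b"), drop = FALSE])
  for (r in seq_len(nrow(am))) {
    seen <- character(0)
    for (k in 1:5) {
      lemma <- am[r, k]
      if (lemma == "" || lemma %in% seen) next
      seen <- c(seen, lemma)
      ci <- match(lemma, nodes)
      if (is.na(ci)) next
      for (lab in c(la[r, k], lb[r, k])) {
        if (lab == "") next
        E[match(lab, emotions), ci] <- E[match(lab, emotions), ci] + 1L
      }
    }
  }
  E
}

#' Affective similarity between two associations
#'
#' Two minus the L1 distance between the normalized emotion-label
#' distributions of associations i and j:
#' \deqn{2 - \sum_{e=1}^{20} \left| \frac{E(e,i)}{\sum_e E(e,i)} -
#'       \frac{E(e,j)}{\sum_e E(e,j)} \right|}
#' 2 means identical label distributions, 0 disjoint ones.
#'
#' @param E Emotion-profile count matrix ([emotion_profiles()]).
#' @param i,j Column names or indices.
#' @return Similarity in \[0, 2\].
#' @export
#' @examples
#' E <- cbind(a = c(2, 0, 0), b = c(1, 1, 0))
#' affective_similarity(E, "a", "b")  # 1
affective_similarity <- function(E, i, j) {
  ci <- E[, i]; cj <- E[, j]
  if (sum(ci) == 0 || sum(cj) == 0)
    stop_domain("domain error: association with zero emotion-label counts ",
                "(rare association not filtered?)")
  2 - sum(abs(ci / sum(ci) - cj / sum(cj)))
}

#' Affective-similarity matrix over retained associations
#'
#' Pairwise [affective_similarity()] for every pair of retained lemmas.
#'
#' @inheritParams emotion_profiles
#' @return Symmetric matrix in \[0, 2\] with diagonal 2.
#' @export
affective_matrix <- function(records, vocabulary,
                             emotions = coop_emotions()) {
  E <- emotion_profiles(records, vocabulary, emotions)
  if (any(colSums(E) == 0))
    stop_domain("domain error: retained association with no emotion labels")
  P <- sweep(E, 2, colSums(E), "/")
  d <- as.matrix(stats::dist(t(P), method = "manhattan"))
  out <- 2 - d
  dimnames(out) <- list(colnames(E), colnames(E))
  out
}

#' Binned correlation between co-occurrence strength and affective similarity
#'
#' Tests whether strongly co-occurring associations carry more similar
#' emotion-label distributions. The LLR values of all unordered node pairs
#' are divided into `n_bins` equal-width intervals over their observed
#' range (right-most bin closed); within each non-empty bin the LLR and
#' affective-similarity values are averaged, and Spearman's correlation is
#' computed over the bin means. Binning moderates the mass of near-zero LLR
#' pairs so that low and high co-occurrence values are sampled comparably.
#'
#' Significance is a QAP permutation test: the node labels of the affective
#' matrix are permuted jointly over rows and columns, the binning-and-
#' averaging pipeline is re-run on the permuted pairing, and the p-value is
#' the add-one fraction of permutations whose absolute correlation reaches
#' the observed one.
#'
#' @param coop A `coop_network`.
#' @param aff Affective-similarity matrix with the same node ordering.
#' @param n_bins Number of equal-width LLR intervals (default 100).
#' @param n_perm QAP permutations (default 5000).
#' @param seed RNG seed for the permutations.
#' @return A `coop_binned_cor`: list with `rho`, `df` (non-empty bins minus
#'   2), `p_qap`, `n_bins_used`, `bins` (per-bin means) and metadata.
#' @export
binned_llr_affect_correlation <- function(coop, aff, n_bins = 100,
                                          n_perm = 5000, seed = NULL) {
  w <- coop$weights
  if (!identical(dim(w), dim(aff)))
    stop_domain("LLR and affective matrices must share node ordering")
  if (!is.null(dimnames(aff)) &&
      !identical(rownames(aff), coop$nodes))
    stop_domain("LLR and affective matrices must share node ordering")
  ut <- upper.tri(w)
  llr <- w[ut]
  rng <- range(llr)
  if (rng[1] == rng[2])
    stop_domain("degenerate input: constant LLR values")
  brk <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- findInterval(llr, brk, rightmost.closed = TRUE, all.inside = TRUE)
  bin_stat <- function(affv) {
    a <- tapply(affv, bin, mean)
    if (stats::sd(a) == 0)
      stop_domain("degenerate input: constant affective similarity ",
                  "across bins")
    l <- tapply(llr, bin, mean)
    stats::cor(l, a, method = "spearman")
  }
  n_used <- length(unique(bin))
  if (n_used < 3)
    stop_domain("degenerate input: fewer than 3 non-empty LLR bins")
  # pair indices once so a node permutation re-indexes the affect values
  ii <- row(w)[ut]; jj <- col(w)[ut]
  affv <- aff[cbind(ii, jj)]
  rho <- bin_stat(affv)
  p_qap <- NA_real_
  perm_abs <- numeric(0)
  if (n_perm > 0) {
    m <- nrow(w)
    perm_abs <- with_seed(seed, vapply(seq_len(n_perm), function(k) {
      p <- sample.int(m)
      abs(bin_stat(aff[cbind(p[ii], p[jj])]))
    }, numeric(1)))
    p_qap <- (1 + sum(perm_abs >= abs(rho))) / (n_perm + 1)
  }
  bins_df <- data.frame(bin = sort(unique(bin)),
                        mean_llr = as.numeric(tapply(llr, bin, mean)),
                        mean_affect = as.numeric(tapply(affv, bin, mean)),
                        n_pairs = as.integer(table(bin)))
  structure(list(rho = rho, df = n_used - 2L, p_qap = p_qap,
                 n_bins = n_bins, n_bins_used = n_used, n_perm = n_perm,
                 bins = bins_df, seed = seed,
                 permutation_order = "permute-then-rebin",
                 perm_abs_summary = if (length(perm_abs))
                   summary(perm_abs) else NULL),
            class = "coop_binned_cor")
}

#' @export
print.coop_binned_cor <- function(x, ...) {
  cat(sprintf("Binned LLR-affect correlation: rs(%d) = %.3f", x$df, x$rho))
  if (!is.na(x$p_qap))
    cat(sprintf(", p_QAP = %.4g (%d permutations)", x$p_qap, x$n_perm))
  cat("\n", x$n_bins_used, "of", x$n_bins, "bins non-empty;",
      "permutation order:", x$permutation_order, "\n")
  invisible(x)
}

#' Per-bin means of a binned correlation
#'
#' @param x A `coop_binned_cor`.
#' @param ... Unused.
#' @export
plot.coop_binned_cor <- function(x, ...) {
  graphics::plot(x$bins$mean_llr, x$bins$mean_affect,
                 xlab = "Mean LLR (bin)", ylab = "Mean affective similarity",
                 pch = 19, col = "grey30", ...)
  invisible(x)
}
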