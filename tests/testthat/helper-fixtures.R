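# Builders for small in-code fixtures shared across test files.

# A respondent row in the standard wide layout. Missing association slots
# are empty strings; emotion labels default to a fixed pair.
make_record <- function(id, assocs, labels = NULL, pot = NA, gm = NA,
                        sdo = NA) {
  assocs <- c(assocs, rep("", 5 - length(assocs)))
  if (is.null(labels))
    labels <- lapply(1:5, function(k)
      if (assocs[k] == "") c("", "") else c("fear", "hope"))
  row <- data.frame(id = id, stringsAsFactors = FALSE)
  for (k in 1:5) {
    row[[paste0("assoc_", k)]] <- assocs[k]
    row[[paste0("emo_", k, "a")]] <- labels[[k]][1]
    row[[paste0("emo_", k, "b")]] <- labels[[k]][2]
  }
  row$pot <- pot; row$gm <- gm; row$sdo <- sdo
  row
}

make_records <- function(...) {
  validate_responses(do.call(rbind, list(...)))
}

# A fabricated vocabulary table (counts chosen directly).
make_vocab <- function(lemmas, counts, min_occurrence = 3) {
  structure(data.frame(lemma = lemmas, count = as.integer(counts),
                       retained = counts >= min_occurrence,
                       stringsAsFactors = FALSE),
            class = c("coop_vocabulary", "data.frame"),
            n_respondents = max(counts), min_occurrence = min_occurrence,
            n_distinct = length(lemmas),
            n_retained = sum(counts >= min_occurrence),
            retained_tokens = sum(counts[counts >= min_occurrence]))
}

# Planted three-block signed matrix: attractive within blocks, repulsive
# between, plus small noise.
planted_block_matrix <- function(block_size = 6, n_blocks = 3,
                                 w_in = 1, w_out = -0.5, noise = 0.05,
                                 seed = 1) {
  n <- block_size * n_blocks
  blocks <- rep(seq_len(n_blocks), each = block_size)
  w <- matrix(w_out, n, n)
  for (b in seq_len(n_blocks))
    w[blocks == b, blocks == b] <- w_in
  set.seed(seed)
  eps <- matrix(stats::rnorm(n * n, 0, noise), n, n)
  eps <- (eps + t(eps)) / 2
  w <- w + eps
  diag(w) <- 0
  rownames(w) <- colnames(w) <- sprintf("n%02d", seq_len(n))
  list(weights = w, blocks = stats::setNames(blocks, rownames(w)))
}

# All set partitions of n elements, as membership vectors (restricted
# growth strings). Used as the brute-force modularity oracle.
all_partitions <- function(n) {
  out <- list()
  rec <- function(pref, mx) {
    if (length(pref) == n) {
      out[[length(out) + 1]] <<- pref
      return()
    }
    for (v in seq_len(mx + 1)) rec(c(pref, v), max(mx, v))
  }
  rec(integer(0), 0L)
  out
}

# Records for a small two-wave synthetic study, kept small for speed.
small_population <- function(seed, n = 320, vocab_size = 24) {
  cfg <- population_config(n_respondents = n, vocab_size = vocab_size)
  generate_population(cfg, seed = seed)
}

# Wrap a weight matrix as a coop_network-like object for the comparison
# machinery (nodes + weights are all it needs).
as_coop_net <- function(w, n_resp = 100, threshold = 3) {
  structure(list(nodes = rownames(w), weights = w,
                 joint = NULL,
                 node_freq = stats::setNames(rep(threshold, nrow(w)),
                                             rownames(w)),
                 n = n_resp, threshold = threshold),
            class = "coop_network")
}
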