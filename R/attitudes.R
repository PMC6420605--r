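#' Assign respondents to opinion modules by majority of associations
#'
#' Each respondent is assigned to the module holding the strict majority of
#' their retained associations, with that count as the respondent's weight.
#' Respondents whose maximum is tied across two or more modules, and
#' respondents with no retained association, are discarded from attitude
#' analysis.
#'
#' @param records Validated respondent data frame.
#' @param partition `coop_partition` over the retained lemmas (named
#'   membership).
#' @param vocabulary The `coop_vocabulary` defining retention.
#' @return Data frame `respondent_id`, `module` (NA when discarded),
#'   `weight`, `discarded`, `reason` ("tie", "no_retained" or "").
#' @export
assign_respondents <- function(records, partition, vocabulary) {
  m <- partition$membership
  if (is.null(names(m)))
    stop_domain("partition must carry node names")
  per_resp <- respondent_lemmas(records)
  out <- data.frame(respondent_id = records$id,
                    module = NA_integer_, weight = 0L,
                    discarded = TRUE, reason = "no_retained",
                    stringsAsFactors = FALSE)
  for (r in seq_along(per_resp)) {
    mods <- m[intersect(per_resp[[r]], names(m))]
    if (length(mods) == 0) next
    tab <- table(mods)
    top <- max(tab)
    winners <- names(tab)[tab == top]
    if (length(winners) > 1) {
      out$reason[r] <- "tie"
      out$weight[r] <- as.integer(top)
      next
    }
    out$module[r] <- as.integer(winners)
    out$weight[r] <- as.integer(top)
    out$discarded[r] <- FALSE
    out$reason[r] <- ""
  }
  out
}

#' Weighted mean and variance of attitude scores
#'
#' Association-count-weighted moments used in the module comparisons:
#' \deqn{WAM = \frac{\sum_i w_i x_i}{\sum_i w_i},\qquad
#'       WAV = \frac{\sum_i w_i (x_i - WAM)^2}{\sum_i w_i}.}
#'
#' @param scores Numeric attitude scores.
#' @param weights Positive weights (association counts).
#' @return Named numeric vector `wam`, `wav`, `n`, `total_weight`.
#' @export
#' @examples
#' weighted_moments(c(2, 4), c(3, 1))  # wam 2.5, wav 0.75
weighted_moments <- function(scores, weights) {
  keep <- !is.na(scores)
  scores <- scores[keep]; weights <- weights[keep]
  if (length(scores) == 0)
    stop_domain("degenerate input: no scored respondents")
  if (any(weights <= 0)) stop_domain("weights must be positive")
  tw <- sum(weights)
  wam <- sum(scores * weights) / tw
  wav <- sum(weights * (scores - wam)^2) / tw
  c(wam = wam, wav = wav, n = length(scores), total_weight = tw)
}

#' Weighted two-sample t test between two modules
#'
#' Independent two-sample t test on attitude scores where each respondent
#' is weighted by their association count. The group means and variances
#' are the weighted moments ([weighted_moments()]); the pooled variance
#' scales each group's weighted variance by its respondent count, and the
#' degrees of freedom use respondent counts (`n_a + n_b - 2`), so scaling
#' every weight by a constant leaves the statistic unchanged. Cohen's d is
#' the absolute standardized difference on the pooled SD. A Welch-type
#' variant is available.
#'
#' @param scores_a,scores_b Scores in the two modules.
#' @param weights_a,weights_b Respondent weights.
#' @param var "pooled" (default) or "welch".
#' @return List `t`, `df`, `p`, `d`, `wam` (length 2), `n` (length 2).
#' @export
weighted_t_test <- function(scores_a, weights_a, scores_b, weights_b,
                            var = c("pooled", "welch")) {
  var <- match.arg(var)
  ma <- weighted_moments(scores_a, weights_a)
  mb <- weighted_moments(scores_b, weights_b)
  na <- ma[["n"]]; nb <- mb[["n"]]
  if (na < 2 || nb < 2)
    stop_domain("degenerate input: each module needs >= 2 scored respondents")
  diff <- ma[["wam"]] - mb[["wam"]]
  if (var == "pooled") {
    s2 <- (na * ma[["wav"]] + nb * mb[["wav"]]) / (na + nb - 2)
    if (s2 <= 0) stop_domain("degenerate input: zero pooled variance")
    tt <- diff / sqrt(s2 * (1 / na + 1 / nb))
    df <- na + nb - 2
    d <- abs(diff) / sqrt(s2)
  } else {
    # Welch: unbiased-scaled weighted variances and Satterthwaite df
    va <- ma[["wav"]] * na / (na - 1)
    vb <- mb[["wav"]] * nb / (nb - 1)
    se2 <- va / na + vb / nb
    if (se2 <= 0) stop_domain("degenerate input: zero variance")
    tt <- diff / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    d <- abs(diff) / sqrt((va + vb) / 2)
  }
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  list(t = unname(tt), df = unname(df), p = unname(p), d = unname(d),
       wam = c(a = ma[["wam"]], b = mb[["wam"]]),
       n = c(a = na, b = nb))
}

# Exact power of the two-sided two-sample t test at per-group sizes na, nb,
# standardized mean difference d, via the noncentral t distribution.
two_sample_power <- function(na, nb, d = 0.5, alpha = 0.05) {
  df <- na + nb - 2
  ncp <- d / sqrt(1 / na + 1 / nb)
  tc <- stats::qt(1 - alpha / 2, df)
  stats::pt(tc, df, ncp = ncp, lower.tail = FALSE) +
    stats::pt(-tc, df, ncp = ncp)
}

#' Per-group sample size for a target power
#'
#' Smallest per-group n so that the two-sided two-sample t test on normal
#' outcomes with standardized mean difference `d` (SD 1) reaches the target
#' power at level `alpha`. For the conventional medium effect d = 0.5 at
#' alpha .05 and power .8 this is 64 respondents per module.
#'
#' @param d Cohen's d (default 0.5).
#' @param alpha Two-sided significance level (default 0.05).
#' @param power Target power (default 0.8).
#' @param n_max Search bound (default 1e6).
#' @return Integer per-group n.
#' @export
#' @examples
#' required_n_per_group()  # 64
required_n_per_group <- function(d = 0.5, alpha = 0.05, power = 0.8,
                                 n_max = 1e6) {
  if (!(alpha > 0 && alpha < 1) || !(power > 0 && power < 1) || d <= 0)
    stop_domain("parameter error: need d > 0, 0 < alpha < 1, 0 < power < 1")
  n <- 2L
  while (n <= n_max) {
    if (two_sample_power(n, n, d, alpha) >= power) return(n)
    n <- n + 1L
  }
  stop_domain("parameter error: power unattainable within n_max")
}

#' Module-level attitude report
#'
#' Assigns respondents to modules, computes weighted means and variances
#' per module and scale, and runs pairwise weighted t tests between every
#' pair of retained modules, annotating each comparison with Cohen's d and
#' whether it reaches the target power for a medium effect.
#'
#' @param records Validated respondent data frame carrying score columns.
#' @param partition `coop_partition` over retained lemmas.
#' @param vocabulary The `coop_vocabulary`.
#' @param scales Score columns to analyze (default those present among
#'   pot, gm, sdo).
#' @param min_distinct Module-size filter passed to
#'   [filter_small_modules()] (default 2).
#' @param power_d,power_alpha,power_target Power annotation parameters
#'   (defaults d = 0.5, alpha = .05, power .8).
#' @param var Variance convention for [weighted_t_test()].
#' @return A `coop_attitudes`: list with `assignment`, `moments` (per
#'   module x scale), `tests` (per module pair x scale), `excluded_modules`,
#'   `n_discarded`.
#' @export
attitude_report <- function(records, partition, vocabulary, scales = NULL,
                            min_distinct = 2, power_d = 0.5,
                            power_alpha = 0.05, power_target = 0.8,
                            var = "pooled") {
  if (is.null(scales))
    scales <- intersect(names(attitude_ranges()), names(records))
  if (length(scales) == 0)
    stop_domain("no attitude scale columns present in records")
  empty_sc <- scales[vapply(scales, function(sc)
    is.null(records[[sc]]) || all(is.na(records[[sc]])), logical(1))]
  if (length(empty_sc) > 0)
    stop_domain("score column absent or empty: ",
                paste(empty_sc, collapse = ", "))
  flt <- filter_small_modules(partition, min_distinct)
  asg <- assign_respondents(records, partition, vocabulary)
  asg$excluded_module <- !is.na(asg$module) & asg$module %in% flt$excluded
  keep <- !asg$discarded & !asg$excluded_module
  mods <- sort(unique(asg$module[keep]))
  if (length(mods) == 0)
    stop_domain("degenerate input: all modules excluded")
  labs <- label_modules(partition, vocabulary)
  moments <- do.call(rbind, lapply(mods, function(mod) {
    sel <- keep & !is.na(asg$module) & asg$module == mod
    do.call(rbind, lapply(scales, function(sc) {
      mm <- weighted_moments(records[[sc]][sel], asg$weight[sel])
      data.frame(module = mod, label = labs[mod], scale = sc,
                 wam = mm[["wam"]], wav = mm[["wav"]],
                 n = as.integer(mm[["n"]]),
                 total_weight = mm[["total_weight"]],
                 stringsAsFactors = FALSE)
    }))
  }))
  tests <- NULL
  if (length(mods) >= 2) {
    prs <- utils::combn(mods, 2)
    tests <- do.call(rbind, lapply(seq_len(ncol(prs)), function(k) {
      a <- prs[1, k]; b <- prs[2, k]
      sa <- keep & !is.na(asg$module) & asg$module == a
      sb <- keep & !is.na(asg$module) & asg$module == b
      do.call(rbind, lapply(scales, function(sc) {
        tt <- weighted_t_test(records[[sc]][sa], asg$weight[sa],
                              records[[sc]][sb], asg$weight[sb], var = var)
        powered <- two_sample_power(tt$n[["a"]], tt$n[["b"]],
                                    power_d, power_alpha) >= power_target
        data.frame(module_a = a, module_b = b,
                   label_a = labs[a], label_b = labs[b], scale = sc,
                   t = tt$t, df = tt$df, p = tt$p, d = tt$d,
                   n_a = tt$n[["a"]], n_b = tt$n[["b"]],
                   powered = powered, stringsAsFactors = FALSE)
      }))
    }))
  }
  rownames(moments) <- NULL
  if (!is.null(tests)) rownames(tests) <- NULL
  structure(list(assignment = asg, moments = moments, tests = tests,
                 excluded_modules = flt$excluded,
                 n_discarded = sum(asg$discarded),
                 n_comparisons = if (is.null(tests)) 0L else nrow(tests),
                 scales = scales, var = var),
            class = "coop_attitudes")
}

#' @export
print.coop_attitudes <- function(x, ...) {
  cat("Module attitude report (", paste(x$scales, collapse = ", "),
      "); variance: ", x$var, "\n", sep = "")
  cat(x$n_discarded, "respondents discarded (ties / no retained associations);",
      length(x$excluded_modules), "small module(s) excluded\n")
  cat("\nWeighted moments:\n")
  print.data.frame(x$moments, digits = 3)
  if (!is.null(x$tests)) {
    cat("\nPairwise weighted t tests (no multiplicity correction over",
        x$n_comparisons, "comparisons):\n")
    print.data.frame(x$tests, digits = 3)
  }
  invisible(x)
}
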