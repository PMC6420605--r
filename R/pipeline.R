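#' Run configuration for end-to-end analyses
#'
#' Bundles the tunable parameters of a full run: the rare-association
#' threshold, Monte Carlo sizes, the consensus-graph export threshold and
#' the master seed. Every artifact written by the `run_*` functions embeds
#' this configuration and a short hash of it, so identical configurations
#' produce identical artifacts.
#'
#' @param min_occurrence Rare-association threshold (default 3).
#' @param n_runs Louvain runs for the consensus matrix (default 5000).
#' @param n_check Partitions per consensus agreement round (default 100).
#' @param n_perm QAP permutations (default 5000).
#' @param n_null Null models for the modular similarity test (default 5000).
#' @param consensus_threshold Co-classification threshold for the exported
#'   consensus graph (default 0.4).
#' @param thresholds Threshold-sweep range (default 3:13).
#' @param seed Master seed (default 1).
#' @return A `coop_runconfig` list.
#' @export
run_config <- function(min_occurrence = 3, n_runs = 5000, n_check = 100,
                       n_perm = 5000, n_null = 5000,
                       consensus_threshold = 0.4, thresholds = 3:13,
                       seed = 1) {
  cfg <- list(min_occurrence = min_occurrence, n_runs = n_runs,
              n_check = n_check, n_perm = n_perm, n_null = n_null,
              consensus_threshold = consensus_threshold,
              thresholds = thresholds, seed = seed)
  if (any(unlist(cfg[c("min_occurrence", "n_runs", "n_check", "n_perm",
                       "n_null")]) < 1))
    stop_domain("configuration error: all counts must be positive")
  structure(cfg, class = "coop_runconfig")
}

config_hash <- function(config) {
  s <- paste(deparse(unclass(config)), collapse = "")
  b <- utf8ToInt(s)
  # polynomial rolling hash over the serialized config, mod a Mersenne prime
  h <- 0
  for (x in b) h <- (h * 31 + x) %% 2147483647
  sprintf("%08x", h)
}

run_log <- function(...) message("[coopnet] ", ...)

write_run_info <- function(dir, config, extra = list()) {
  info <- c(list(config = unclass(config), config_hash = config_hash(config),
                 package_version = as.character(
                   utils::packageVersion("coopnet")),
                 timestamp = format(Sys.time(), tz = "UTC")),
            extra)
  writeLines(deparse_json(info), file.path(dir, "run_info.json"))
}

# Minimal JSON writer for report structures (lists, vectors, strings).
deparse_json <- function(x, indent = "") {
  if (is.list(x)) {
    if (is.null(names(x))) {
      items <- vapply(x, deparse_json, character(1), indent = paste0(indent, "  "))
      paste0("[", paste(items, collapse = ", "), "]")
    } else {
      items <- vapply(seq_along(x), function(i)
        paste0("\"", names(x)[i], "\": ",
               deparse_json(x[[i]], paste0(indent, "  "))), character(1))
      paste0("{", paste(items, collapse = ", "), "}")
    }
  } else if (is.null(x)) {
    "null"
  } else if (length(x) > 1) {
    paste0("[", paste(vapply(x, deparse_json, character(1)),
                      collapse = ", "), "]")
  } else if (is.character(x)) {
    paste0("\"", gsub("\"", "\\\\\"", x), "\"")
  } else if (is.na(x)) {
    "null"
  } else if (is.logical(x)) {
    tolower(as.character(x))
  } else {
    format(x, digits = 15, scientific = FALSE, trim = TRUE)
  }
}

#' Build a CoOp network and its consensus modules from a respondent table
#'
#' End-to-end construction run: reads (or takes) a respondent table,
#' optionally applies a lemma merge map, builds the vocabulary and signed
#' LLR network, runs consensus module detection and writes the vocabulary
#' report, edge list, partition table, consensus-graph edges, GraphML
#' export (when igraph is installed) and a run-info file to `output_dir`.
#'
#' @param input Path to a respondent table, or a validated data frame.
#' @param output_dir Output directory (created if needed).
#' @param config A `coop_runconfig` (default [run_config()]).
#' @param lemma_map Optional lemma map path or named vector.
#' @return Invisibly, a list with `network`, `consensus`, `vocabulary`.
#' @export
run_build <- function(input, output_dir, config = run_config(),
                      lemma_map = NULL) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  records <- if (is.character(input)) read_responses(input) else
    validate_responses(input)
  if (!is.null(lemma_map)) {
    if (is.character(lemma_map) && length(lemma_map) == 1 &&
        file.exists(lemma_map))
      lemma_map <- read_lemma_map(lemma_map)
    records <- apply_lemma_map(records, lemma_map)
  }
  run_log("building vocabulary (threshold ", config$min_occurrence, ")")
  voc <- build_vocabulary(records, config$min_occurrence)
  net <- build_coop_network(records, voc)
  run_log("network: ", length(net$nodes), " nodes; running consensus (",
          config$n_runs, " runs, seed ", config$seed, ")")
  cons <- consensus_partition(net$weights, n_runs = config$n_runs,
                              n_check = config$n_check, seed = config$seed,
                              keep_runs = FALSE)
  utils::write.csv(as.data.frame(voc), file.path(output_dir, "vocabulary.csv"),
                   row.names = FALSE)
  utils::write.csv(coop_edge_list(net), file.path(output_dir, "edges.csv"),
                   row.names = FALSE)
  utils::write.csv(partition_table(cons$partition, voc),
                   file.path(output_dir, "partition.csv"), row.names = FALSE)
  utils::write.csv(consensus_edges(cons,
                                   threshold = config$consensus_threshold),
                   file.path(output_dir, "consensus_edges.csv"),
                   row.names = FALSE)
  if (requireNamespace("igraph", quietly = TRUE))
    write_coop_graphml(net, file.path(output_dir, "network.graphml"))
  write_run_info(output_dir, config, list(
    n_respondents = net$n, n_nodes = length(net$nodes),
    mean_Q = cons$mean_Q, consensus_Q = cons$partition$Q,
    n_modules = cons$partition$n_modules, rounds = cons$rounds))
  run_log("wrote artifacts to ", output_dir)
  invisible(list(network = net, consensus = cons, vocabulary = voc,
                 records = records))
}

#' Cross-sample reproducibility report
#'
#' Full two-sample comparison: edge-level QAP Spearman correlation on the
#' shared node set, consensus-partition nMI against paired signed null
#' models, and the rare-association threshold sweep. Writes a structured
#' JSON report plus the stability curve as CSV.
#'
#' @param input1,input2 Respondent tables (paths or data frames).
#' @param output_dir Output directory.
#' @param config A `coop_runconfig`.
#' @return Invisibly, a list with `qap`, `null_report`, `stability`.
#' @export
run_compare <- function(input1, input2, output_dir,
                        config = run_config()) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  r1 <- if (is.character(input1)) read_responses(input1) else
    validate_responses(input1)
  r2 <- if (is.character(input2)) read_responses(input2) else
    validate_responses(input2)
  if (config$n_perm < 100)
    warning("p-value granularity is coarse: the smallest attainable ",
            "p_QAP is ", format(1 / (config$n_perm + 1), digits = 3))
  seeds <- spawn_seeds(config$seed, 3)
  v1 <- build_vocabulary(r1, config$min_occurrence)
  v2 <- build_vocabulary(r2, config$min_occurrence)
  n1 <- build_coop_network(r1, v1)
  n2 <- build_coop_network(r2, v2)
  run_log("edge-level QAP (", config$n_perm, " permutations)")
  qap <- qap_correlation(n1, n2, n_perm = config$n_perm, seed = seeds[[1]])
  run_log("modular similarity vs ", config$n_null, " paired null models")
  nullrep <- modular_similarity_test(n1, n2, n_null = config$n_null,
                                     seed = seeds[[2]],
                                     n_runs = config$n_runs,
                                     n_check = config$n_check)
  run_log("threshold sweep ", min(config$thresholds), "..",
          max(config$thresholds))
  sweep <- threshold_sweep(r1, r2, thresholds = config$thresholds,
                           seed = seeds[[3]], n_runs = config$n_runs,
                           n_check = config$n_check)
  utils::write.csv(as.data.frame(sweep),
                   file.path(output_dir, "stability_curve.csv"),
                   row.names = FALSE)
  report <- list(
    edge_level = list(rho = qap$rho, p_qap = qap$p_qap,
                      n_pairs = qap$n_pairs, n_perm = qap$n_perm),
    modular_level = list(consensus_nmi = nullrep$observed_nmi,
                         run_pair_mean_nmi = nullrep$mean_pair_nmi,
                         p_null = nullrep$p, n_null = nullrep$n_null,
                         n_shared = nullrep$n_shared),
    stability = list(trend_edge = attr(sweep, "trend_edge"),
                     trend_nmi = attr(sweep, "trend_nmi")))
  writeLines(deparse_json(report), file.path(output_dir, "compare_report.json"))
  write_run_info(output_dir, config)
  invisible(list(qap = qap, null_report = nullrep, stability = sweep))
}

#' Attitude analysis run
#'
#' Builds the network and consensus modules, assigns respondents, and
#' writes the module-level weighted attitude report (moments, pairwise
#' weighted t tests, power annotations, discarded counts).
#'
#' @param input Respondent table (path or data frame) with score columns.
#' @param output_dir Output directory.
#' @param config A `coop_runconfig`.
#' @param scales Scales to analyze (default: those present).
#' @return Invisibly, the `coop_attitudes` report.
#' @export
run_attitudes <- function(input, output_dir, config = run_config(),
                          scales = NULL) {
  built <- run_build(input, output_dir, config)
  rep_ <- attitude_report(built$records, built$consensus$partition,
                          built$vocabulary, scales = scales)
  utils::write.csv(rep_$moments, file.path(output_dir, "attitude_moments.csv"),
                   row.names = FALSE)
  if (!is.null(rep_$tests))
    utils::write.csv(rep_$tests, file.path(output_dir, "attitude_tests.csv"),
                     row.names = FALSE)
  utils::write.csv(rep_$assignment,
                   file.path(output_dir, "respondent_assignment.csv"),
                   row.names = FALSE)
  run_log(rep_$n_discarded, " respondents discarded; ",
          length(rep_$excluded_modules), " module(s) excluded")
  invisible(rep_)
}
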