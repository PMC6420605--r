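#' The fixed 20-label emotion vocabulary
#'
#' Canonical ordering of the twenty emotion labels respondents may attach to
#' their associations (ten positive/negative pairs drawn from basic-emotion
#' inventories). The position of a label in this vector defines its row index
#' in every emotion-profile matrix.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' coop_emotions()
coop_emotions <- function() {
  c("interest", "alarm", "empathy", "contempt", "surprise", "indifference",
    "hope", "fear", "gratitude", "anger", "joy", "sadness", "calmness",
    "relief", "pride", "shame", "generosity", "envy", "love/sympathy",
    "hate/antipathy")
}

#' Attitude-scale score ranges
#'
#' Valid ranges for the three Likert attitude scales: perceived outgroup
#' threat (POT, 1-5), group malleability (GM, 1-6) and social dominance
#' orientation (SDO, 1-7).
#'
#' @return Named list of length-2 numeric ranges.
#' @export
attitude_ranges <- function() {
  list(pot = c(1, 5), gm = c(1, 6), sdo = c(1, 7))
}

resp_cols <- function() {
  c("id",
    paste0("assoc_", 1:5),
    paste0("emo_", rep(1:5, each = 2), c("a", "b")))
}

# Case-fold, trim and NFC-normalise so composed/decomposed accents in noisy
# survey exports compare equal. NFC uses ICU via stringi when available.
normalise_lemma <- function(x) {
  x <- trimws(tolower(enc2utf8(as.character(x))))
  if (requireNamespace("stringi", quietly = TRUE)) {
    ok <- !is.na(x)
    x[ok] <- stringi::stri_trans_nfc(x[ok])
  }
  x[is.na(x)] <- ""
  x
}

#' Read a respondent table
#'
#' Reads one-row-per-respondent survey exports: a respondent id, five
#' association slots (post-lemmatization strings), two emotion labels per
#' slot, and optional attitude-scale means (`pot`, `gm`, `sdo`). Association
#' strings are whitespace-trimmed and case-folded; emotion labels are
#' validated against the 20-label vocabulary; scores are range-checked.
#'
#' Records with fewer than five non-empty associations are kept (the LLR
#' counting is well defined on any respondent set) but flagged in the
#' `incomplete` attribute.
#'
#' @param path Path to a delimited text file with a header row.
#' @param sep Field separator (default comma).
#' @param emotions Emotion label vocabulary (default [coop_emotions()]).
#' @return A data frame of validated respondent records, one row per
#'   respondent, with attribute `incomplete` (logical vector).
#' @seealso [write_responses()], [apply_lemma_map()], [build_vocabulary()]
#' @export
read_responses <- function(path, sep = ",", emotions = coop_emotions()) {
  if (!file.exists(path)) stop_domain("input file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, fill = TRUE,
                          colClasses = "character", encoding = "UTF-8",
                          quote = "\"", comment.char = "")
  missing <- setdiff(resp_cols(), names(df))
  if (length(missing) > 0)
    stop_domain("format error: missing required columns: ",
                paste(missing, collapse = ", "))
  for (s in names(attitude_ranges())) {
    if (s %in% names(df)) df[[s]] <- suppressWarnings(as.numeric(df[[s]]))
  }
  validate_responses(df, emotions = emotions)
}

#' Validate a respondent table held in memory
#'
#' Applies the same normalisation and validation as [read_responses()] to a
#' data frame that is already loaded (e.g. produced by
#' [generate_population()]).
#'
#' @inheritParams read_responses
#' @param records Data frame with the respondent-table columns.
#' @return The validated data frame with attribute `incomplete`.
#' @export
validate_responses <- function(records, emotions = coop_emotions()) {
  missing <- setdiff(resp_cols(), names(records))
  if (length(missing) > 0)
    stop_domain("format error: missing required columns: ",
                paste(missing, collapse = ", "))
  acols <- paste0("assoc_", 1:5)
  ecols <- grep("^emo_", resp_cols(), value = TRUE)
  for (a in acols) records[[a]] <- normalise_lemma(records[[a]])
  for (e in ecols) {
    records[[e]] <- trimws(tolower(as.character(records[[e]])))
    records[[e]][is.na(records[[e]])] <- ""
  }
  for (e in ecols) {
    bad <- which(records[[e]] != "" & !(records[[e]] %in% emotions))
    if (length(bad) > 0)
      stop_domain("validation error: unknown emotion label \"",
                  records[[e]][bad[1]], "\" in column ", e, ", row ", bad[1])
  }
  # an emotion label is only meaningful where its association slot is filled
  for (k in 1:5) {
    empty <- records[[acols[k]]] == ""
    records[[paste0("emo_", k, "a")]][empty] <- ""
    records[[paste0("emo_", k, "b")]][empty] <- ""
  }
  rng <- attitude_ranges()
  for (s in names(rng)) {
    if (!s %in% names(records)) next
    v <- records[[s]]
    bad <- which(!is.na(v) & (v < rng[[s]][1] | v > rng[[s]][2]))
    if (length(bad) > 0)
      stop_domain("validation error: ", s, " score ", v[bad[1]],
                  " outside [", rng[[s]][1], ", ", rng[[s]][2],
                  "] in row ", bad[1])
  }
  records$id <- as.character(records$id)
  if (anyDuplicated(records$id))
    stop_domain("validation error: duplicated respondent id: ",
                records$id[duplicated(records$id)][1])
  n_assoc <- rowSums(as.matrix(records[, acols, drop = FALSE]) != "")
  attr(records, "incomplete") <- n_assoc < 5
  records
}

#' Write a respondent table
#'
#' Inverse of [read_responses()]: writes the standard respondent-table
#' layout so that reading the file back reproduces the records.
#'
#' @param records Validated respondent data frame.
#' @param path Output file path.
#' @param sep Field separator.
#' @export
write_responses <- function(records, path, sep = ",") {
  keep <- c(resp_cols(), intersect(names(attitude_ranges()), names(records)))
  utils::write.table(records[, keep, drop = FALSE], path, sep = sep,
                     row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Apply a lemma merge map
#'
#' Replaces every association by its canonical lemma where the raw form
#' appears in the merge map (an externally produced raw form -> lemma
#' table, e.g. from manual consensus coding). Slots that collapse to
#' duplicates are retained as slots; downstream counting is per respondent,
#' so duplicates contribute once.
#'
#' @param records Validated respondent data frame.
#' @param merge_map Named character vector (names = raw forms, values =
#'   lemmas) or a two-column data frame `raw_form`, `lemma`.
#' @return The records with associations mapped.
#' @export
apply_lemma_map <- function(records, merge_map) {
  if (is.data.frame(merge_map)) {
    if (!all(c("raw_form", "lemma") %in% names(merge_map)))
      stop_domain("merge map table needs columns raw_form, lemma")
    merge_map <- stats::setNames(as.character(merge_map$lemma),
                                 as.character(merge_map$raw_form))
  }
  if (length(merge_map) == 0) return(records)
  names(merge_map) <- normalise_lemma(names(merge_map))
  merge_map <- stats::setNames(normalise_lemma(merge_map), names(merge_map))
  # a map value that is itself remapped to something else makes the map
  # order-dependent (and can cycle): reject
  onward <- merge_map[merge_map] # lookup values as keys
  bad <- which(!is.na(onward) & onward != merge_map)
  if (length(bad) > 0)
    stop_domain("configuration error: merge map is not idempotent (\"",
                merge_map[bad[1]], "\" maps onward to \"", onward[bad[1]],
                "\")")
  for (a in paste0("assoc_", 1:5)) {
    hit <- records[[a]] %in% names(merge_map)
    records[[a]][hit] <- unname(merge_map[records[[a]][hit]])
  }
  records
}

#' Read a lemma merge map
#'
#' @param path Two-column delimited file with header `raw_form`, `lemma`.
#' @param sep Field separator.
#' @return Named character vector suitable for [apply_lemma_map()].
#' @export
read_lemma_map <- function(path, sep = ",") {
  if (!file.exists(path)) stop_domain("lemma map file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("raw_form", "lemma") %in% names(df)))
    stop_domain("format error: lemma map needs columns raw_form, lemma")
  stats::setNames(df$lemma, df$raw_form)
}

# Unique non-empty lemmas per respondent (duplicates within one respondent
# count once everywhere downstream).
respondent_lemmas <- function(records) {
  acols <- paste0("assoc_", 1:5)
  m <- as.matrix(records[, acols, drop = FALSE])
  lapply(seq_len(nrow(m)), function(i) {
    v <- m[i, ]
    unique(v[v != ""])
  })
}

#' Build the association vocabulary under a rare-association filter
#'
#' Counts, for every lemma, the number of distinct respondents who mentioned
#' it (a respondent contributes at most 1 per lemma, however many slots it
#' fills), and flags lemmas retained under the minimum-occurrence threshold.
#' Rare associations are idiosyncratic rather than part of the shared
#' representation, so the default drops lemmas mentioned by fewer than three
#' respondents.
#'
#' @param records Validated respondent data frame.
#' @param min_occurrence Minimum respondent count for a lemma to be retained
#'   (default 3).
#' @return A `coop_vocabulary`: data frame with columns `lemma`, `count`,
#'   `retained`, ordered by decreasing count; attributes `n_respondents`,
#'   `min_occurrence`, `n_distinct`, `n_retained`, `retained_tokens`.
#' @export
build_vocabulary <- function(records, min_occurrence = 3) {
  if (!is.numeric(min_occurrence) || min_occurrence < 1)
    stop_domain("parameter error: min_occurrence must be >= 1")
  per_resp <- respondent_lemmas(records)
  all_lemmas <- unlist(per_resp, use.names = FALSE)
  tab <- sort(table(all_lemmas), decreasing = TRUE)
  voc <- data.frame(lemma = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  voc$retained <- voc$count >= min_occurrence
  # stable ordering: by count desc, then lemma
  voc <- voc[order(-voc$count, voc$lemma), , drop = FALSE]
  rownames(voc) <- NULL
  structure(voc,
            class = c("coop_vocabulary", "data.frame"),
            n_respondents = nrow(records),
            min_occurrence = min_occurrence,
            n_distinct = nrow(voc),
            n_retained = sum(voc$retained),
            retained_tokens = sum(voc$count[voc$retained]))
}

#' @export
print.coop_vocabulary <- function(x, ...) {
  cat("Association vocabulary:", attr(x, "n_distinct"), "distinct lemmas from",
      attr(x, "n_respondents"), "respondents\n")
  cat("Retained at min occurrence", attr(x, "min_occurrence"), ":",
      attr(x, "n_retained"), "lemmas,", attr(x, "retained_tokens"),
      "tokens\n")
  invisible(x)
}

retained_lemmas <- function(vocabulary) {
  vocabulary$lemma[vocabulary$retained]
}
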