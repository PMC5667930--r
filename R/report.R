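# Corpus-level summaries and biased-vs-debiased comparison.
#
# Reporting conventions: percentages are rounded half-up to 2 decimals;
# quadrant percentages are expressed within their parent sentiment label
# (e.g. "62.00% of positive tweets are highly positive"); primary-emotion
# probabilities are computed over assigned (non-neutral) tweets only.

#' Summarize labels and emotion tags of one corpus
#'
#' @param labels character vector of sentiment labels
#'   (positive/negative/neutral), one per tweet.
#' @param tags data frame from [tag_emotion()] aligned with `labels`
#'   (may be NULL if only label-level summaries are needed).
#' @param corpus_name name carried into the summary.
#' @return list of class `corpus_summary`: n_tweets, label_counts,
#'   label_pcts, quadrant_counts, quadrant_pcts (within parent label),
#'   primary_counts, primary_probs (percent).
#' @export
summarize_corpus <- function(labels, tags = NULL, corpus_name = "corpus") {
  n <- length(labels)
  if (n == 0) stop("cannot summarize an empty corpus")
  lab_levels <- c("positive", "negative", "neutral")
  label_counts <- vapply(lab_levels, function(l) sum(labels == l), integer(1))
  label_pcts <- vapply(label_counts, pct2, numeric(1), total = n)
  names(label_pcts) <- lab_levels
  quadrant_counts <- quadrant_pcts <- NULL
  primary_counts <- primary_probs <- NULL
  if (!is.null(tags)) {
    stopifnot(nrow(tags) == n)
    quadrant_counts <- vapply(QUADRANTS, function(q)
      sum(tags$quadrant == q), integer(1))
    denom <- c(highly_positive = label_counts[["positive"]],
               passive_positive = label_counts[["positive"]],
               subdued_negative = label_counts[["negative"]],
               highly_negative = label_counts[["negative"]],
               neutral = n)
    quadrant_pcts <- vapply(QUADRANTS, function(q)
      pct2(quadrant_counts[[q]], denom[[q]]), numeric(1))
    assigned <- tags$primary != "none"
    primary_counts <- vapply(PRIMARY_EMOTIONS, function(p)
      sum(tags$primary == p), integer(1))
    primary_probs <- vapply(primary_counts, pct2, numeric(1),
                            total = sum(assigned))
    names(primary_probs) <- PRIMARY_EMOTIONS
  }
  structure(list(
    corpus_name = corpus_name, n_tweets = n,
    label_counts = label_counts, label_pcts = label_pcts,
    quadrant_counts = quadrant_counts, quadrant_pcts = quadrant_pcts,
    primary_counts = primary_counts, primary_probs = primary_probs
  ), class = "corpus_summary")
}

#' @export
print.corpus_summary <- function(x, ...) {
  cat(sprintf("Corpus summary: %s (%d tweets)\n", x$corpus_name, x$n_tweets))
  for (l in names(x$label_counts))
    cat(sprintf("  %-9s %8d (%6.2f%%)\n", l, x$label_counts[[l]],
                x$label_pcts[[l]]))
  if (!is.null(x$quadrant_pcts)) {
    cat("  quadrants (% within parent label):\n")
    for (q in setdiff(names(x$quadrant_counts), "neutral"))
      cat(sprintf("    %-17s %8d (%6.2f%%)\n", q, x$quadrant_counts[[q]],
                  x$quadrant_pcts[[q]]))
    cat("  primary emotions (% of assigned tweets):\n")
    for (p in names(x$primary_probs))
      cat(sprintf("    %-9s %6.2f%%\n", p, x$primary_probs[[p]]))
  }
  invisible(x)
}

#' Compare debiased and biased corpus summaries
#'
#' Side-by-side primary-emotion probabilities with deltas
#' (debiased - biased).
#'
#' @param summary_debiased,summary_biased `corpus_summary` objects computed
#'   with the same circumplex map (same primary-emotion set).
#' @return data frame of class `comparison_table`: emotion, debiased_pct,
#'   biased_pct, delta.
#' @export
compare_summaries <- function(summary_debiased, summary_biased) {
  a <- summary_debiased$primary_probs
  b <- summary_biased$primary_probs
  if (is.null(a) || is.null(b) || !identical(names(a), names(b)))
    stop("summaries carry mismatched primary-emotion sets")
  out <- data.frame(emotion = names(a), debiased_pct = unname(a),
                    biased_pct = unname(b),
                    delta = unname(a) - unname(b),
                    stringsAsFactors = FALSE)
  class(out) <- c("comparison_table", "data.frame")
  out
}

#' @export
print.comparison_table <- function(x, ...) {
  cat("Primary-emotion probability (%) by corpus:\n")
  cat(sprintf("  %-9s %9s %9s %8s\n", "emotion", "debiased", "biased",
              "delta"))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-9s %9.2f %9.2f %+8.2f\n", x$emotion[i],
                x$debiased_pct[i], x$biased_pct[i], x$delta[i]))
  invisible(x)
}

#' Serialize a corpus summary to JSON
#' @param x a `corpus_summary`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(x, path) {
  jsonlite::write_json(
    list(schema_version = "1.0", summary = unclass(x)), path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
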