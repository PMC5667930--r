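# Corpus container and JSON-lines readers/writers.
#
# In memory a corpus is two data frames (tweets, accounts) plus provenance;
# on disk it is one JSONL file where each line carries a "record_type" tag.
# Timestamps are epoch seconds in memory, ISO-8601 UTC strings in files.

CORPUS_SCHEMA_VERSION <- "1.0"

#' Construct a tweet corpus
#'
#' @param tweets data frame with columns tweet_id, account_id, timestamp
#'   (UTC epoch seconds), text, source_client (mobile/desktop/other),
#'   is_retweet, mention_count.
#' @param accounts data frame with columns account_id, followers, followees
#'   and optionally ground_truth_role (human/bot/marketing; synthetic corpora
#'   only).
#' @param provenance one of raw, debiased, bots_only, marketing_only.
#' @param truth optional sidecar data frame of planted ground truth
#'   (tweet_id, account_id, role, planted_sentiment, plain).
#' @param validate check invariants (unique tweet ids, resolvable accounts).
#' @param window optional c(start, end) epoch seconds; with strict = TRUE
#'   out-of-window timestamps are an error.
#' @param strict enforce the collection window.
#' @return an object of class `corpus`.
#' @export
corpus <- function(tweets, accounts, provenance = "raw", truth = NULL,
                   validate = TRUE, window = NULL, strict = FALSE) {
  provenance <- match.arg(provenance,
                          c("raw", "debiased", "bots_only", "marketing_only"))
  tweets <- as.data.frame(tweets, stringsAsFactors = FALSE)
  accounts <- as.data.frame(accounts, stringsAsFactors = FALSE)
  # canonical column types (JSONL stores second-resolution timestamps)
  if (nrow(tweets)) {
    tweets$tweet_id <- as.character(tweets$tweet_id)
    tweets$account_id <- as.character(tweets$account_id)
    tweets$timestamp <- as.numeric(tweets$timestamp)
    tweets$text <- as.character(tweets$text)
    tweets$is_retweet <- as.logical(tweets$is_retweet)
    tweets$mention_count <- as.integer(tweets$mention_count)
  }
  if (nrow(accounts)) {
    accounts$account_id <- as.character(accounts$account_id)
    accounts$followers <- as.integer(accounts$followers)
    accounts$followees <- as.integer(accounts$followees)
  }
  obj <- structure(
    list(tweets = tweets, accounts = accounts, provenance = provenance,
         truth = truth, schema_version = CORPUS_SCHEMA_VERSION),
    class = "corpus"
  )
  if (validate) validate_corpus(obj, window = window, strict = strict)
  obj
}

validate_corpus <- function(x, window = NULL, strict = FALSE) {
  tw <- x$tweets
  need <- c("tweet_id", "account_id", "timestamp", "text", "source_client",
            "is_retweet", "mention_count")
  miss <- setdiff(need, names(tw))
  if (length(miss)) stop("tweets missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(tw$tweet_id))
    stop("duplicate tweet_id values in corpus")
  if (nrow(tw)) {
    orphan <- setdiff(tw$account_id, x$accounts$account_id)
    if (length(orphan))
      stop("tweets reference missing accounts: ",
           paste(utils::head(orphan, 5), collapse = ", "))
    if (any(tw$mention_count < 0)) stop("mention_count must be non-negative")
    bad_client <- setdiff(unique(tw$source_client),
                          c("mobile", "desktop", "other"))
    if (length(bad_client))
      stop("unknown source_client values: ", paste(bad_client, collapse = ", "))
    if (strict && !is.null(window)) {
      out <- tw$timestamp < window[1] | tw$timestamp > window[2]
      if (any(out))
        stop(sum(out), " tweet(s) outside the collection window, e.g. ",
             paste(utils::head(tw$tweet_id[out], 3), collapse = ", "))
    }
  }
  if (nrow(x$accounts) &&
      (any(x$accounts$followers < 0) || any(x$accounts$followees < 0)))
    stop("follower/followee counts must be non-negative")
  invisible(x)
}

#' @export
print.corpus <- function(x, ...) {
  cat(sprintf("<corpus: %d tweets, %d accounts, provenance=%s>\n",
              nrow(x$tweets), nrow(x$accounts), x$provenance))
  invisible(x)
}

#' Number of tweets in a corpus
#' @param x a `corpus`.
#' @return integer tweet count.
#' @export
n_tweets <- function(x) nrow(x$tweets)

#' Tweet ids of one account, ordered by timestamp
#' @param x a `corpus`.
#' @param account_id account to look up.
#' @return character vector of tweet ids.
#' @export
account_tweet_ids <- function(x, account_id) {
  tw <- x$tweets[x$tweets$account_id == account_id, ]
  tw$tweet_id[order(tw$timestamp)]
}

iso8601 <- function(ts) {
  format(as.POSIXct(ts, origin = "1970-01-01", tz = "UTC"),
         "%Y-%m-%dT%H:%M:%SZ")
}

from_iso8601 <- function(s) {
  as.numeric(as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
}

#' Write a corpus as JSON-lines
#'
#' One JSON object per line; account records first, then tweet records, each
#' tagged with `record_type`. Timestamps are written as ISO-8601 UTC.
#'
#' @param x a `corpus`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(x, path) {
  con <- file(path, open = "wb")  # binary: newline-stable across platforms
  on.exit(close(con))
  header <- jsonlite::toJSON(
    list(record_type = "header", schema_version = x$schema_version,
         provenance = x$provenance),
    auto_unbox = TRUE)
  writeLines(header, con, sep = "\n")
  acc <- x$accounts
  if (nrow(acc)) {
    acc_out <- data.frame(record_type = "account", acc,
                          stringsAsFactors = FALSE)
    jsonlite::stream_out(acc_out, con, verbose = FALSE)
  }
  tw <- x$tweets
  if (nrow(tw)) {
    tw_out <- tw
    tw_out$timestamp <- iso8601(tw_out$timestamp)
    tw_out <- data.frame(record_type = "tweet", tw_out,
                         stringsAsFactors = FALSE)
    jsonlite::stream_out(tw_out, con, verbose = FALSE)
  }
  invisible(path)
}

#' Read a corpus from JSON-lines
#'
#' Malformed lines are counted and reported via a warning (and the
#' `malformed` attribute), never silently dropped without notice.
#'
#' @param path JSONL file written by [write_corpus()] or following its schema.
#' @param schema_version expected schema version string.
#' @param window optional collection window c(start, end) epoch seconds.
#' @param strict error on tweets outside `window`.
#' @return a `corpus`; attribute `malformed` holds the bad-line count.
#' @export
read_corpus <- function(path, schema_version = CORPUS_SCHEMA_VERSION,
                        window = NULL, strict = FALSE) {
  if (!file.exists(path)) stop("cannot read corpus file: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- vector("list", length(lines))
  bad <- 0L
  for (i in seq_along(lines)) {
    recs[[i]] <- tryCatch(jsonlite::fromJSON(lines[i]),
                          error = function(e) NULL)
    if (is.null(recs[[i]])) bad <- bad + 1L
  }
  recs <- Filter(Negate(is.null), recs)
  types <- vapply(recs, function(r) r$record_type %||% "unknown", character(1))
  provenance <- "raw"
  hdr <- recs[types == "header"]
  if (length(hdr)) {
    sv <- hdr[[1]]$schema_version %||% "?"
    if (!identical(sv, schema_version))
      stop("corpus schema version mismatch: file has ", sv,
           ", expected ", schema_version)
    provenance <- hdr[[1]]$provenance %||% "raw"
  }
  row_of <- function(r, fields) {
    as.data.frame(r[fields], stringsAsFactors = FALSE)
  }
  acc_fields <- c("account_id", "followers", "followees")
  accs <- recs[types == "account"]
  accounts <- if (length(accs)) {
    has_role <- all(vapply(accs, function(r) !is.null(r$ground_truth_role),
                           logical(1)))
    f <- if (has_role) c(acc_fields, "ground_truth_role") else acc_fields
    do.call(rbind, lapply(accs, row_of, fields = f))
  } else {
    data.frame(account_id = character(), followers = integer(),
               followees = integer(), stringsAsFactors = FALSE)
  }
  tw_fields <- c("tweet_id", "account_id", "timestamp", "text",
                 "source_client", "is_retweet", "mention_count")
  tws <- recs[types == "tweet"]
  tweets <- if (length(tws)) {
    d <- do.call(rbind, lapply(tws, row_of, fields = tw_fields))
    d$timestamp <- from_iso8601(d$timestamp)
    d
  } else {
    data.frame(tweet_id = character(), account_id = character(),
               timestamp = numeric(), text = character(),
               source_client = character(), is_retweet = logical(),
               mention_count = integer(), stringsAsFactors = FALSE)
  }
  if (bad > 0)
    warning(bad, " malformed line(s) skipped while reading ", path)
  out <- corpus(tweets, accounts, provenance = provenance,
                window = window, strict = strict)
  attr(out, "malformed") <- bad
  out
}

#' Default root terms of the study corpus
#'
#' The hookah-related collection terms, with plural variants handled by an
#' explicit "s" suffix expansion during matching. "waterpipe" is deliberately
#' absent: it is academic vocabulary, rarely used in organic social-media
#' posts.
#'
#' @return character vector of root terms.
#' @export
default_root_terms <- function() c("hookah", "hooka", "sheesha", "shisha", "sesh")

#' Filter a corpus to posts matching root terms
#'
#' Case-insensitive, token-boundary aware match on text and hashtags: a term
#' matches `#term` and `terms` (explicit plural suffix) but never a longer
#' word containing it.
#'
#' @param x a `corpus`.
#' @param root_terms character vector of terms; must be non-empty.
#' @param plural_suffixes suffix expansions applied to each term.
#' @return a `corpus` restricted to matching tweets (accounts kept if they
#'   still own at least one tweet).
#' @export
keyword_filter <- function(x, root_terms = default_root_terms(),
                           plural_suffixes = c("", "s")) {
  if (length(root_terms) == 0 || all(!nzchar(root_terms)))
    stop("root_terms must be non-empty")
  alts <- unlist(lapply(tolower(root_terms),
                        function(t) paste0(t, plural_suffixes)))
  pat <- paste0("(?<![a-z0-9])#?(?:",
                paste(alts, collapse = "|"),
                ")(?![a-z0-9])")
  keep <- grepl(pat, tolower(x$tweets$text), perl = TRUE)
  subset_corpus(x, keep)
}

# subset by logical/indices over tweets; drop accounts with no tweets left
subset_corpus <- function(x, keep, provenance = x$provenance) {
  tweets <- x$tweets[keep, , drop = FALSE]
  rownames(tweets) <- NULL
  accounts <- x$accounts[x$accounts$account_id %in% tweets$account_id, ,
                         drop = FALSE]
  rownames(accounts) <- NULL
  truth <- x$truth
  if (!is.null(truth)) {
    truth <- truth[truth$tweet_id %in% tweets$tweet_id, , drop = FALSE]
    rownames(truth) <- NULL
  }
  corpus(tweets, accounts, provenance = provenance, truth = truth,
         validate = FALSE)
}
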