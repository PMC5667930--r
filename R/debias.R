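# Social-bot scoring and corpus debiasing.
#
# Six account-level behavioral features, each mapped onto [0, 1] (1 =
# bot-like), are combined as a weighted mean into a single bot score;
# accounts at or above the threshold are flagged and ALL their tweets
# removed. Marketing posts are then removed by keyword from the remainder,
# so bot / marketing / clean form an exact partition of the input corpus.

#' Debias configuration
#'
#' Baselines describing "the average human Twitter user" are declared
#' configuration, not estimates: mobile fraction of client use, acceptable
#' log10 follower:followee band, reference noun/verb/adverb profile, and
#' the dispersion of per-account compound sentiment (the value for scores
#' spread uniformly over \[-1, 1\]).
#'
#' @param threshold combined-score cutoff for flagging a bot.
#' @param weights named or unnamed non-negative weights for the six features
#'   (timing, spam, client, follower, content, sentiment).
#' @param human_mobile_fraction baseline mobile share among mobile+desktop.
#' @param follower_log_band half-width (log10) of the human follower band.
#' @param human_content_profile reference (noun, verb, adverb) frequencies.
#' @param human_compound_sd baseline per-account compound-score dispersion.
#' @param spam_phrases phrase list for the spam feature.
#' @param marketing_keywords keyword list for the marketing filter.
#' @return list of class `debias_config`.
#' @export
debias_config <- function(threshold = 0.5,
                          weights = c(timing = 1, spam = 1, client = 1,
                                      follower = 1, content = 1,
                                      sentiment = 1),
                          human_mobile_fraction = 0.6,
                          follower_log_band = 2,
                          human_content_profile = c(noun = 0.55, verb = 0.30,
                                                    adverb = 0.15),
                          human_compound_sd = 1 / sqrt(3),
                          spam_phrases = default_spam_phrases(),
                          marketing_keywords = default_marketing_keywords()) {
  stopifnot(length(weights) == 6, all(weights >= 0), sum(weights) > 0,
            threshold >= 0, threshold <= 1,
            human_mobile_fraction > 0, human_mobile_fraction < 1)
  structure(list(threshold = threshold, weights = unname(weights),
                 human_mobile_fraction = human_mobile_fraction,
                 follower_log_band = follower_log_band,
                 human_content_profile = human_content_profile /
                   sum(human_content_profile),
                 human_compound_sd = human_compound_sd,
                 spam_phrases = spam_phrases,
                 marketing_keywords = marketing_keywords),
            class = "debias_config")
}

#' Timing regularity of an account
#'
#' 1/(1+CV) of the inter-tweet intervals: perfectly periodic posting gives 1,
#' increasingly irregular (human, heavy-tailed) timing decays toward 0.
#' Fewer than two intervals cannot show (ir)regularity: the feature is
#' missing (NA) and excluded from the combination.
#'
#' @param timestamps UTC epoch seconds of one account's tweets.
#' @return regularity in \[0, 1\], or NA.
#' @export
timing_regularity <- function(timestamps) {
  ts <- sort(unique(timestamps))
  if (length(ts) < 3) return(NA_real_)
  iv <- diff(ts)
  cv <- stats::sd(iv) / mean(iv)
  1 / (1 + cv)
}

phrase_pattern <- function(phrases) {
  esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", tolower(phrases))
  paste0("(?<![a-z0-9])(?:", paste(esc, collapse = "|"), ")(?![a-z0-9])")
}

#' Spam score of an account
#'
#' Fraction of the account's tweets whose text contains at least one known
#' spam phrase (case-insensitive, word-boundary match).
#'
#' @param texts character vector of the account's tweet texts.
#' @param spam_phrases phrase list.
#' @return fraction in \[0, 1\].
#' @export
spam_score <- function(texts, spam_phrases = default_spam_phrases()) {
  if (!length(spam_phrases)) stop("spam phrase list is empty")
  if (!length(texts)) return(NA_real_)
  pat <- phrase_pattern(spam_phrases)
  mean(grepl(pat, tolower(texts), perl = TRUE))
}

#' Client-ratio deviation of an account
#'
#' Deviation of the account's mobile share (among mobile+desktop tweets)
#' from the human baseline, normalized by the headroom in the deviation's
#' direction so that an all-mobile or all-desktop account scores exactly 1
#' whatever the baseline. "Other" clients are excluded from the fraction.
#'
#' @param clients character vector of source clients per tweet.
#' @param human_mobile_fraction baseline in (0, 1).
#' @return deviation in \[0, 1\], or NA if only "other" clients.
#' @export
client_ratio_deviation <- function(clients, human_mobile_fraction = 0.6) {
  md <- clients[clients %in% c("mobile", "desktop")]
  if (!length(md)) return(NA_real_)
  obs <- mean(md == "mobile")
  if (obs >= human_mobile_fraction)
    (obs - human_mobile_fraction) / (1 - human_mobile_fraction)
  else
    (human_mobile_fraction - obs) / human_mobile_fraction
}

#' Follower-ratio extremeness of an account
#'
#' |log10((followers+1)/(followees+1))| relative to the configured human
#' band half-width, clipped to \[0, 1\]. Equal counts score 0.
#'
#' @param followers follower count.
#' @param followees followee count.
#' @param band_halfwidth log10 half-width of the human band.
#' @return extremeness in \[0, 1\].
#' @export
follower_ratio_score <- function(followers, followees, band_halfwidth = 2) {
  r <- log10((followers + 1) / (followees + 1))
  min(1, abs(r) / band_halfwidth)
}

#' Content divergence of an account
#'
#' Total-variation distance between the account's pooled noun/verb/adverb
#' frequency triple and the human reference triple, both renormalized over
#' the three tags.
#'
#' @param pos_tags character vector of all the account's token tags.
#' @param human_profile reference (noun, verb, adverb) triple.
#' @return TV distance in \[0, 1\], or NA without tagged content tokens.
#' @export
content_score <- function(pos_tags,
                          human_profile = c(noun = 0.55, verb = 0.30,
                                            adverb = 0.15)) {
  cnt <- c(noun = sum(pos_tags == "noun"), verb = sum(pos_tags == "verb"),
           adverb = sum(pos_tags == "adverb"))
  if (sum(cnt) == 0) return(NA_real_)
  p <- cnt / sum(cnt)
  q <- human_profile / sum(human_profile)
  sum(abs(p - q[names(p)])) / 2
}

#' Sentiment-dispersion feature of an account
#'
#' Bots recycle near-identical text, so their per-tweet compound scores
#' barely vary. Feature = 1 - sd(compounds)/human baseline sd, clipped;
#' human-like dispersion scores near 0, a constant score exactly 1.
#'
#' @param compounds compound scores of the account's tweets.
#' @param human_sd baseline dispersion.
#' @return score in \[0, 1\], or NA with fewer than 3 scored tweets.
#' @export
sentiment_feature_score <- function(compounds, human_sd = 1 / sqrt(3)) {
  if (length(compounds) < 3) return(NA_real_)
  clamp01(1 - stats::sd(compounds) / human_sd)
}

#' Combine bot features into a single score
#'
#' Weighted mean of the available (non-missing) features; weights of missing
#' features are renormalized away. If every feature is missing the account
#' is undecidable and conservatively retained (not a bot).
#'
#' @param features numeric vector of 6 features in \[0, 1\] (NA = missing),
#'   order: timing, spam, client, follower, content, sentiment.
#' @param weights non-negative weights, sum > 0.
#' @param threshold bot cutoff; flagged iff combined >= threshold.
#' @return list: combined, is_bot, undecidable.
#' @export
combine_bot_score <- function(features, weights = rep(1, 6),
                              threshold = 0.5) {
  stopifnot(length(features) == length(weights), sum(weights) > 0)
  ok <- !is.na(features)
  if (!any(ok))
    return(list(combined = NA_real_, is_bot = FALSE, undecidable = TRUE))
  combined <- sum(features[ok] * weights[ok]) / sum(weights[ok])
  list(combined = combined, is_bot = combined >= threshold,
       undecidable = FALSE)
}

#' Bot features and scores for every account of a corpus
#'
#' @param x a `corpus`.
#' @param config a `debias_config`.
#' @param pp optional precomputed [preprocess_corpus()] output.
#' @param scores optional precomputed [score_corpus()] output.
#' @return data frame: account_id, the six features, combined, is_bot,
#'   undecidable.
#' @export
score_accounts <- function(x, config = debias_config(), pp = NULL,
                           scores = NULL) {
  if (is.null(pp)) pp <- preprocess_corpus(x)
  if (is.null(scores)) scores <- score_corpus(x, pp = pp)
  comp <- stats::setNames(scores$compound, scores$tweet_id)
  tw <- x$tweets
  rows <- lapply(x$accounts$account_id, function(aid) {
    sel <- tw$account_id == aid
    acc <- x$accounts[x$accounts$account_id == aid, ]
    tags <- unlist(lapply(pp[tw$tweet_id[sel]], `[[`, "pos_tags"),
                   use.names = FALSE)
    f <- c(
      timing = timing_regularity(tw$timestamp[sel]),
      spam = spam_score(tw$text[sel], config$spam_phrases),
      client = client_ratio_deviation(tw$source_client[sel],
                                      config$human_mobile_fraction),
      follower = follower_ratio_score(acc$followers, acc$followees,
                                      config$follower_log_band),
      content = content_score(tags, config$human_content_profile),
      sentiment = sentiment_feature_score(comp[tw$tweet_id[sel]],
                                          config$human_compound_sd)
    )
    cb <- combine_bot_score(f, config$weights, config$threshold)
    data.frame(account_id = aid, t(f), combined = cb$combined,
               is_bot = cb$is_bot, undecidable = cb$undecidable,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Split tweets on marketing keywords
#'
#' A tweet is marketing iff its lowercased text contains any keyword
#' (word-boundary match). An empty keyword list warns and removes nothing.
#'
#' @param texts character vector of tweet texts.
#' @param keywords marketing keyword list.
#' @return logical vector, TRUE = marketing.
#' @export
is_marketing <- function(texts, keywords = default_marketing_keywords()) {
  if (!length(keywords)) {
    warning("empty marketing keyword list: nothing removed")
    return(rep(FALSE, length(texts)))
  }
  grepl(phrase_pattern(keywords), tolower(texts), perl = TRUE)
}

#' Sample-derivation arithmetic
#'
#' From the raw, bot-removed and marketing-removed counts computes the
#' analytic sample, the biased-comparison corpus (raw minus marketing:
#' humans and bots together), and removal percentages of the raw corpus.
#'
#' @param n_total raw corpus size.
#' @param n_bots tweets removed as bot posts.
#' @param n_marketing tweets removed as marketing posts.
#' @return list of class `debias_report`.
#' @export
debias_report <- function(n_total, n_bots, n_marketing) {
  n_clean <- n_total - n_bots - n_marketing
  structure(list(
    n_total = n_total, n_bots = n_bots, n_marketing = n_marketing,
    n_clean = n_clean,
    n_biased_comparison = n_total - n_marketing,
    pct_bots = pct2(n_bots, n_total),
    pct_marketing = pct2(n_marketing, n_total),
    pct_clean = pct2(n_clean, n_total)
  ), class = "debias_report")
}

#' @export
print.debias_report <- function(x, ...) {
  cat(sprintf(
    paste0("Debias report: %d tweets collected\n",
           "  bot posts removed:       %8d (%.2f%%)\n",
           "  marketing posts removed: %8d (%.2f%%)\n",
           "  analytic sample:         %8d (%.2f%%)\n",
           "  biased comparison corpus (humans+bots): %d\n"),
    x$n_total, x$n_bots, x$pct_bots, x$n_marketing, x$pct_marketing,
    x$n_clean, x$pct_clean, x$n_biased_comparison))
  invisible(x)
}

#' Debias a corpus
#'
#' Flags bot accounts via [score_accounts()] and removes all their tweets,
#' then removes marketing posts by keyword from the remainder. The three
#' output corpora partition the input exactly; a bot tweet containing a
#' marketing keyword counts as bot.
#'
#' @param x a `corpus`.
#' @param config a `debias_config`.
#' @param pp,scores optional precomputed preprocessing / sentiment scores.
#' @return list: clean, bots_only, marketing_only (corpora), account_scores,
#'   report (a `debias_report`).
#' @export
debias_corpus <- function(x, config = debias_config(), pp = NULL,
                          scores = NULL) {
  if (is.null(pp)) pp <- preprocess_corpus(x)
  if (is.null(scores)) scores <- score_corpus(x, pp = pp)
  acc <- score_accounts(x, config, pp = pp, scores = scores)
  bot_accounts <- acc$account_id[acc$is_bot]
  bot_tweet <- x$tweets$account_id %in% bot_accounts
  mkt_tweet <- !bot_tweet & is_marketing(x$tweets$text,
                                         config$marketing_keywords)
  clean <- subset_corpus(x, !bot_tweet & !mkt_tweet, provenance = "debiased")
  bots <- subset_corpus(x, bot_tweet, provenance = "bots_only")
  mkt <- subset_corpus(x, mkt_tweet, provenance = "marketing_only")
  list(clean = clean, bots_only = bots, marketing_only = mkt,
       account_scores = acc,
       report = debias_report(n_tweets(x), sum(bot_tweet), sum(mkt_tweet)))
}
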