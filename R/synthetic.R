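# Seeded synthetic corpus generator.
#
# Stands in for the undeposited study corpus: human accounts post
# sentiment-bearing template text (planted positive/negative/neutral mix,
# heavy-tailed posting times, mixed clients, balanced follower ratios); bot
# accounts post near-periodic, spam-laden, single-client, extreme-ratio,
# near-constant-sentiment tweets; marketing accounts embed product keywords
# in otherwise positive text. Because text is assembled by slot-filling from
# the package lexica, the planted sentiment label is exact by construction.

#' Generator configuration
#'
#' Defaults encode the emulated study population: a roughly 30% bot share of
#' tweets and a 59.5/30/10.5 positive/negative/neutral human sentiment mix.
#'
#' @param n_human_accounts,n_bot_accounts,n_marketing_accounts account counts.
#' @param tweets_per_account_mean mean tweets per human account (Poisson,
#'   min 3).
#' @param tweets_per_bot_mean,tweets_per_marketing_mean role-specific means.
#' @param sentiment_mix c(pos, neg, neu), must sum to 1.
#' @param bot_period_seconds bot posting period.
#' @param bot_timing_jitter fractional jitter of the bot period, in \[0, 1).
#' @param human_interarrival_shape log-normal sdlog of human inter-arrival
#'   times.
#' @param human_interarrival_mean_seconds mean human inter-arrival time.
#' @param human_mobile_fraction mobile share among human mobile+desktop use.
#' @param p_exclaim,p_caps,p_elong,p_emoticon,p_contrast,p_negation rates of
#'   emphatic / grammatical features in human tweets.
#' @param marketing_keywords keywords embedded in marketing posts.
#' @param spam_phrases phrases embedded in bot posts (entries containing
#'   valence-bearing words are skipped so planted labels stay exact).
#' @param window collection window c(start, end), epoch seconds.
#' @param seed integer RNG seed; same seed, same corpus, byte for byte.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_human_accounts = 200,
                             n_bot_accounts = 25,
                             n_marketing_accounts = 15,
                             tweets_per_account_mean = 25,
                             tweets_per_bot_mean = 100,
                             tweets_per_marketing_mean = 40,
                             sentiment_mix = c(pos = 0.595, neg = 0.30,
                                               neu = 0.105),
                             bot_period_seconds = 3600,
                             bot_timing_jitter = 0.05,
                             human_interarrival_shape = 1.2,
                             human_interarrival_mean_seconds = 6 * 3600,
                             human_mobile_fraction = 0.6,
                             p_exclaim = 0.12, p_caps = 0.06,
                             p_elong = 0.06, p_emoticon = 0.10,
                             p_contrast = 0.05, p_negation = 0.08,
                             marketing_keywords = default_marketing_keywords(),
                             spam_phrases = default_spam_phrases(),
                             window = default_window(),
                             seed = 1) {
  if (abs(sum(sentiment_mix) - 1) > 1e-9)
    stop("sentiment_mix must sum to 1")
  if (any(c(n_human_accounts, n_bot_accounts, n_marketing_accounts) < 0))
    stop("account counts must be non-negative")
  if (bot_timing_jitter < 0 || bot_timing_jitter >= 1)
    stop("bot_timing_jitter must lie in [0, 1)")
  stopifnot(tweets_per_account_mean > 0, bot_period_seconds > 0,
            human_interarrival_shape > 0)
  structure(as.list(environment()), class = "generator_config")
}

syn_vocab <- function() {
  list(
    pos_strong = c("happy", "wonderful", "great", "amazing", "awesome",
                   "lovely", "fantastic", "excellent", "perfect",
                   "delicious"),
    pos_calm = c("relaxing", "chill", "mellow", "calm", "cozy"),
    pos_excited = c("excited", "pumped", "thrilled"),
    neg_strong = c("horrible", "terrible", "awful", "bad", "nasty",
                   "disgusting", "gross", "harsh", "smelly"),
    neg_low = c("sad", "bored", "tired", "gloomy", "depressed"),
    neg_high = c("stressed", "angry", "mad", "upset"),
    boosters = c("very", "really", "so", "extremely", "absolutely",
                 "totally"),
    neutral_templates = c(
      "smoking hookah at the lounge tonight",
      "hookah with the crew later",
      "picked up a new shisha flavor",
      "heading to the hookah bar downtown",
      "another hookah sesh before the weekend",
      "grape shisha and music at the spot"
    )
  )
}

syn_elongate <- function(word) {
  pos <- regexpr("[aeiou]", word)
  if (pos < 0) pos <- 2
  paste0(substr(word, 1, pos - 1), strrep(substr(word, pos, pos), 4),
         substr(word, pos + 1, nchar(word)))
}

# one human tweet text with its planted label; returns list(text, plain)
syn_human_text <- function(label, cfg, vb) {
  plain <- TRUE
  if (label == "neutral") {
    text <- sample(vb$neutral_templates, 1)
    if (stats::runif(1) < cfg$p_caps)
      text <- sub("hookah", "HOOKAH", text, fixed = TRUE)
    if (stats::runif(1) < cfg$p_exclaim) text <- paste0(text, "!")
    return(list(text = text, plain = plain))
  }
  positive <- label == "positive"
  adj <- if (positive) {
    sample(c(vb$pos_strong, vb$pos_calm, vb$pos_excited), 1)
  } else {
    sample(c(vb$neg_strong, vb$neg_low, vb$neg_high), 1)
  }
  u <- stats::runif(1)
  if (positive && u < cfg$p_contrast) {
    plain <- FALSE
    neg <- sample(vb$neg_strong, 1)
    strong <- sample(vb$pos_strong, 1)
    text <- sprintf("the wait was %s but the hookah was %s", neg, strong)
  } else if (!positive && u < cfg$p_negation) {
    plain <- FALSE
    pos <- sample(vb$pos_strong, 1)
    text <- sample(c(
      sprintf("this hookah is not %s at all", pos),
      sprintf("the shisha here was not %s", pos)
    ), 1)
  } else {
    booster <- if (stats::runif(1) < 0.35)
      paste0(sample(vb$boosters, 1), " ") else ""
    slot <- paste0(booster, adj)
    templates <- if (positive) c(
      sprintf("feeling %s smoking hookah with the crew", slot),
      sprintf("this hookah lounge is %s", slot),
      sprintf("%s shisha flavor tonight", slot),
      sprintf("hookah night with friends was %s", slot),
      sprintf("that %s hookah sesh hit the spot", slot)
    ) else c(
      sprintf("this hookah tastes %s", slot),
      sprintf("the shisha here was %s", slot),
      sprintf("feeling %s after that hookah sesh", slot),
      sprintf("%s coals ruined the whole hookah night", slot),
      sprintf("hookah spot downtown was %s", slot)
    )
    text <- sample(templates, 1)
    if (stats::runif(1) < cfg$p_caps)
      text <- sub(adj, toupper(adj), text, fixed = TRUE)
    else if (stats::runif(1) < cfg$p_elong)
      text <- sub(adj, syn_elongate(adj), text, fixed = TRUE)
  }
  if (stats::runif(1) < cfg$p_exclaim) text <- paste0(text, "!")
  if (stats::runif(1) < cfg$p_emoticon)
    text <- paste0(text, if (positive) " :)" else " :(")
  list(text = text, plain = plain)
}

syn_human_times <- function(n, cfg) {
  span <- cfg$window[2] - cfg$window[1]
  start <- cfg$window[1] + stats::runif(1, 0, span / 2)
  mu <- log(cfg$human_interarrival_mean_seconds) -
    cfg$human_interarrival_shape^2 / 2
  iv <- stats::rlnorm(n - 1, meanlog = mu, sdlog = cfg$human_interarrival_shape)
  floor(pmin(start + cumsum(c(0, iv)), cfg$window[2]))
}

syn_bot_times <- function(n, cfg) {
  span <- cfg$window[2] - cfg$window[1]
  start <- cfg$window[1] + stats::runif(1, 0, span / 2)
  iv <- cfg$bot_period_seconds *
    (1 + cfg$bot_timing_jitter * stats::runif(n - 1, -1, 1))
  floor(pmin(start + cumsum(c(0, iv)), cfg$window[2]))
}

#' Generate a synthetic corpus with planted structure
#'
#' @param config a `generator_config`.
#' @return a `corpus` with `ground_truth_role` on every account and a truth
#'   sidecar table (tweet_id, account_id, role, planted_sentiment, plain).
#' @export
generate_corpus <- function(config = generator_config()) {
  cfg <- config
  total_accounts <- cfg$n_human_accounts + cfg$n_bot_accounts +
    cfg$n_marketing_accounts
  if (total_accounts == 0) stop("cannot generate a corpus with 0 accounts")
  set.seed(cfg$seed)
  vb <- syn_vocab()
  lex <- default_lexicon()
  # spam phrases whose tokens carry no valence, so bot labels stay exact
  safe_spam <- cfg$spam_phrases[vapply(cfg$spam_phrases, function(p) {
    toks <- strsplit(tolower(p), "\\s+")[[1]]
    all(vapply(toks, function(t) is.na(token_valence(t, lex)), logical(1)))
  }, logical(1))]
  if (!length(safe_spam)) safe_spam <- "follow back"

  tw_rows <- list(); acc_rows <- list(); truth_rows <- list()
  tid <- 0L
  add_tweet <- function(aid, ts, text, client, role, label, plain,
                        is_rt = FALSE, mentions = 0L) {
    tid <<- tid + 1L
    id <- sprintf("t%07d", tid)
    tw_rows[[tid]] <<- data.frame(
      tweet_id = id, account_id = aid, timestamp = ts, text = text,
      source_client = client, is_retweet = is_rt,
      mention_count = mentions, stringsAsFactors = FALSE)
    truth_rows[[tid]] <<- data.frame(
      tweet_id = id, account_id = aid, role = role,
      planted_sentiment = label, plain = plain, stringsAsFactors = FALSE)
  }
  client_levels <- c("mobile", "desktop", "other")
  hf <- cfg$human_mobile_fraction
  human_client_p <- c(hf * 0.95, (1 - hf) * 0.95, 0.05)

  # --- human accounts -------------------------------------------------
  for (i in seq_len(cfg$n_human_accounts)) {
    aid <- sprintf("h%04d", i)
    n <- max(3L, stats::rpois(1, cfg$tweets_per_account_mean))
    ts <- syn_human_times(n, cfg)
    followees <- round(10^stats::runif(1, 1.5, 3))
    followers <- round(followees * 10^stats::rnorm(1, 0, 0.3))
    acc_rows[[length(acc_rows) + 1]] <- data.frame(
      account_id = aid, followers = followers, followees = followees,
      ground_truth_role = "human", stringsAsFactors = FALSE)
    labels <- sample(c("positive", "negative", "neutral"), n, replace = TRUE,
                     prob = cfg$sentiment_mix)
    for (k in seq_len(n)) {
      ht <- syn_human_text(labels[k], cfg, vb)
      add_tweet(aid, ts[k], ht$text,
                sample(client_levels, 1, prob = human_client_p),
                "human", labels[k], ht$plain,
                is_rt = stats::runif(1) < 0.05,
                mentions = stats::rpois(1, 0.3))
    }
  }

  # --- bot accounts ---------------------------------------------------
  for (i in seq_len(cfg$n_bot_accounts)) {
    aid <- sprintf("b%04d", i)
    n <- max(5L, stats::rpois(1, cfg$tweets_per_bot_mean))
    ts <- syn_bot_times(n, cfg)
    followers <- round(10^stats::runif(1, 0, 1))
    followees <- round(10^stats::runif(1, 3, 4))
    acc_rows[[length(acc_rows) + 1]] <- data.frame(
      account_id = aid, followers = followers, followees = followees,
      ground_truth_role = "bot", stringsAsFactors = FALSE)
    spam <- sample(safe_spam, 1)
    if (stats::runif(1) < 0.7) {
      neg <- sample(vb$neg_strong, 1)
      text <- sprintf("%s hookah deals %s", neg, spam)
      label <- "negative"
    } else {
      text <- sprintf("hookah hookah hookah %s", spam)
      label <- "neutral"
    }
    for (k in seq_len(n))
      add_tweet(aid, ts[k], text, "desktop", "bot", label, TRUE,
                mentions = stats::rpois(1, 1))
  }

  # --- marketing accounts ---------------------------------------------
  for (i in seq_len(cfg$n_marketing_accounts)) {
    aid <- sprintf("m%04d", i)
    n <- max(3L, stats::rpois(1, cfg$tweets_per_marketing_mean))
    ts <- syn_human_times(n, cfg)
    followees <- round(10^stats::runif(1, 1.5, 3))
    followers <- round(followees * 10^stats::rnorm(1, 0, 0.3))
    acc_rows[[length(acc_rows) + 1]] <- data.frame(
      account_id = aid, followers = followers, followees = followees,
      ground_truth_role = "marketing", stringsAsFactors = FALSE)
    for (k in seq_len(n)) {
      kw <- sample(cfg$marketing_keywords, 1)
      adj <- sample(vb$pos_strong, 1)
      text <- sample(c(
        sprintf("%s hookah pen 1100mah battery %s", adj, kw),
        sprintf("order now %s shisha %s", adj, kw),
        sprintf("%s hookah sale %s today", adj, kw)
      ), 1)
      add_tweet(aid, ts[k], text,
                sample(client_levels, 1, prob = human_client_p),
                "marketing", "positive", TRUE)
    }
  }

  tweets <- do.call(rbind, tw_rows)
  accounts <- do.call(rbind, acc_rows)
  truth <- do.call(rbind, truth_rows)
  corpus(tweets, accounts, provenance = "raw", truth = truth)
}

#' Planted ground truth of a synthetic corpus
#'
#' @param x a `corpus` generated by [generate_corpus()].
#' @return data frame: tweet_id, account_id, role, planted_sentiment, plain.
#' @export
ground_truth <- function(x) {
  if (is.null(x$truth))
    stop("corpus carries no ground-truth sidecar (not generated here?)")
  x$truth
}

#' Write the ground-truth sidecar as CSV
#' @param x a synthetic `corpus`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(x, path) {
  utils::write.csv(ground_truth(x), path, row.names = FALSE)
  invisible(path)
}
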