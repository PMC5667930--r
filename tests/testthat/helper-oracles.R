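# Independent oracles and shared fixtures.
#
# oracle_raw_sum() is a naive sequential enumeration of the sentiment rules,
# written against the rule definitions (not the scorer's code), used to
# cross-check score_tweet on random inputs. oracle_nearest_emotion() is an
# exhaustive-distance nearest-anchor search.

oracle_raw_sum <- function(tt, lex) {
  surf <- tt$surface
  raw <- tt$raw
  n <- length(surf)
  if (n == 0) return(0)
  special <- c(lex$boosters, lex$negators, lex$contrast)
  cpos <- which(surf %in% lex$contrast)
  split_at <- if (length(cpos)) max(cpos) else NA
  excl <- tt$emphasis$exclamation_count > 0
  total <- 0
  for (i in seq_len(n)) {
    tok <- surf[i]
    if (tok %in% special) next
    v <- if (tok %in% names(lex$valences)) {
      lex$valences[[tok]]
    } else {
      st <- porter_stem(tok)
      if (st %in% names(lex$stem_index)) lex$stem_index[[st]] else NA
    }
    if (is.na(v)) next
    triggers <- 0
    if (i > 1 && surf[i - 1] %in% lex$boosters) triggers <- triggers + 1
    if (grepl("^[A-Z]{2,}$", raw[i]) &&
        !surf[i] %in% c("SMILE", "FROWN")) triggers <- triggers + 1
    if (excl) triggers <- triggers + 1
    mult <- min(2^triggers, 4)
    if (i > 1 && any(surf[max(1, i - 3):(i - 1)] %in% lex$negators)) v <- -v
    w <- 1
    if (!is.na(split_at)) w <- if (i < split_at) 0.5 else 1.5
    total <- total + w * v * mult
  }
  total
}

oracle_nearest_emotion <- function(v, a, map) {
  q <- if (v > 0) {
    if (a >= 0) "highly_positive" else "passive_positive"
  } else {
    if (a >= 0) "highly_negative" else "subdued_negative"
  }
  anc <- map[map$quadrant == q, ]
  d <- sqrt((anc$valence - v)^2 + (anc$arousal - a)^2)
  anc$emotion[order(d, anc$emotion)[1]]
}

# random sentiment-bearing texts exercising every scoring rule
random_rule_texts <- function(n, seed) {
  set.seed(seed)
  lex <- default_lexicon()
  val_words <- setdiff(names(lex$valences), c("SMILE", "FROWN"))
  fillers <- c("hookah", "shisha", "lounge", "coals", "flavor", "crew",
               "night", "spot", "music")
  vapply(seq_len(n), function(i) {
    k <- sample(3:9, 1)
    words <- character(k)
    for (j in seq_len(k)) {
      r <- runif(1)
      words[j] <- if (r < 0.35) sample(val_words, 1)
      else if (r < 0.45) sample(lex$boosters, 1)
      else if (r < 0.55) sample(lex$negators, 1)
      else if (r < 0.60) "but"
      else sample(fillers, 1)
      if (runif(1) < 0.08) words[j] <- toupper(words[j])
    }
    txt <- paste(words, collapse = " ")
    if (runif(1) < 0.25) txt <- paste0(txt, "!")
    txt
  }, character(1))
}

# one synthetic corpus under the default study conditions, preprocessed and
# scored once, shared across test files
.shared <- new.env(parent = emptyenv())

shared_synth <- function() {
  if (is.null(.shared$res)) {
    x <- generate_corpus(generator_config(seed = 42))
    ctx <- preprocess_context()
    pp <- preprocess_corpus(x, ctx)
    sc <- score_corpus(x, pp = pp)
    .shared$res <- list(x = x, ctx = ctx, pp = pp, sc = sc,
                        truth = ground_truth(x))
  }
  .shared$res
}

# tiny hand-written corpus fixture
tiny_corpus <- function(texts = c("loving this #hookah tonight",
                                  "off the hook ah well",
                                  "shisha time"),
                        account_id = "u1") {
  n <- length(texts)
  tweets <- data.frame(
    tweet_id = sprintf("t%02d", seq_len(n)), account_id = account_id,
    timestamp = 1443657600 + 3600 * seq_len(n), text = texts,
    source_client = "mobile", is_retweet = FALSE, mention_count = 0L,
    stringsAsFactors = FALSE)
  accounts <- data.frame(account_id = unique(account_id), followers = 100L,
                         followees = 100L, stringsAsFactors = FALSE)
  corpus(tweets, accounts)
}
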