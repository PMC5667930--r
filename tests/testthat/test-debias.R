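test_that("timing regularity maps interval CV onto [0,1]", {
  expect_equal(timing_regularity(c(0, 60, 120, 180)), 1)       # CV = 0
  # two intervals with sd equal to their mean: CV = 1 -> 1/(1+1)
  expect_equal(timing_regularity(c(0, 1, 1 + 3 + 2 * sqrt(2))), 0.5,
               tolerance = 1e-9)
  expect_true(is.na(timing_regularity(c(0, 60))))              # too short
})

test_that("spam score is the matching-tweet fraction", {
  phrases <- c("follow me", "click here")
  expect_equal(spam_score(c("hookah night", "great shisha"), phrases), 0)
  expect_equal(spam_score(c("follow me now", "CLICK HERE free"), phrases), 1)
  texts <- c(rep("follow me for hookah", 3), rep("plain hookah post", 7))
  expect_equal(spam_score(texts, phrases), 0.3)
  expect_error(spam_score("x", character()), "empty")
})

test_that("client-ratio deviation follows the scaled absolute difference", {
  expect_equal(client_ratio_deviation(c("mobile", "desktop"), 0.5), 0)
  expect_equal(client_ratio_deviation(rep("mobile", 4), 0.5), 1)
  expect_equal(client_ratio_deviation(c(rep("mobile", 8), rep("desktop", 2)), 0.6),
               0.5)
  expect_true(is.na(client_ratio_deviation(rep("other", 3), 0.6)))
})

test_that("follower-ratio extremeness is clipped log-ratio distance", {
  expect_equal(follower_ratio_score(500, 500), 0)
  expect_equal(follower_ratio_score(0, 10000), 1)
  expect_equal(follower_ratio_score(99, 9, band_halfwidth = 2), 0.5)
})

test_that("content score is total-variation distance over noun/verb/adverb", {
  prof <- c(noun = 0.4, verb = 0.4, adverb = 0.2)
  tags <- c(rep("noun", 5), rep("verb", 3), rep("adverb", 2))
  expect_equal(content_score(tags, prof), 0.1)
  expect_equal(content_score(tags, c(noun = .5, verb = .3, adverb = .2)), 0)
  expect_equal(content_score(rep("noun", 4), c(noun = 0, verb = 1, adverb = 0)), 1)
  expect_true(is.na(content_score(rep("other", 5), prof)))
})

test_that("sentiment dispersion feature: constancy scores 1, human spread 0", {
  expect_equal(sentiment_feature_score(rep(0.4, 5)), 1)
  half <- (1 / sqrt(3)) / 2
  expect_equal(sentiment_feature_score(c(-half, 0, half)), 0.5,
               tolerance = 1e-9)
  set.seed(1)
  expect_lt(sentiment_feature_score(runif(500, -1, 1)), 0.1)
  expect_true(is.na(sentiment_feature_score(c(0.1, 0.2))))
})

test_that("feature combination is a weighted mean with missing renormalization", {
  expect_false(combine_bot_score(rep(0, 6))$is_bot)
  expect_true(combine_bot_score(rep(1, 6))$is_bot)
  expect_equal(combine_bot_score(c(1, 1, 0, 0, 0, 0))$combined, 1 / 3)
  cb <- combine_bot_score(c(1, NA, NA, NA, NA, 0))
  expect_equal(cb$combined, 0.5)
  und <- combine_bot_score(rep(NA_real_, 6))
  expect_true(und$undecidable)
  expect_false(und$is_bot)
})

test_that("marketing keyword filtering removes exactly the flagged posts", {
  expect_true(is_marketing("new hookah pen 1100mah battery"))
  expect_false(is_marketing("relaxing hookah tonight"))
  texts <- c(rep("discount shisha order now", 5), rep("chill hookah", 15))
  expect_equal(sum(is_marketing(texts)), 5)
  expect_warning(out <- is_marketing(texts, character()), "empty")
  expect_false(any(out))
})

test_that("sample-derivation arithmetic matches the removal counts", {
  rep_ <- debias_report(1000, 300, 100)
  expect_equal(rep_$n_clean, 600)
  expect_equal(rep_$n_biased_comparison, 900)
  expect_equal(rep_$pct_bots, 30)
})

test_that("debiasing partitions the corpus exactly and finds planted bots", {
  sh <- shared_synth()
  db <- debias_corpus(sh$x, pp = sh$pp, scores = sh$sc)
  expect_equal(n_tweets(db$clean) + n_tweets(db$bots_only) +
                 n_tweets(db$marketing_only), n_tweets(sh$x))
  role <- sh$x$accounts$ground_truth_role[
    match(db$account_scores$account_id, sh$x$accounts$account_id)]
  flagged <- db$account_scores$is_bot
  precision <- sum(flagged & role == "bot") / max(1, sum(flagged))
  recall <- sum(flagged & role == "bot") / sum(role == "bot")
  expect_gte(precision, 0.9)
  expect_gte(recall, 0.9)
  # account-level accuracy of the bot decision
  expect_gte(mean((role == "bot") == flagged), 0.95)
})

test_that("a corpus without bots or keywords passes through unchanged", {
  x <- generate_corpus(generator_config(
    seed = 9, n_human_accounts = 15, n_bot_accounts = 0,
    n_marketing_accounts = 0))
  db <- debias_corpus(x)
  expect_equal(n_tweets(db$clean), n_tweets(x))
  expect_equal(n_tweets(db$bots_only), 0)
  expect_equal(n_tweets(db$marketing_only), 0)
})

test_that("raising the bot threshold never enlarges the bot corpus", {
  sh <- shared_synth()
  sizes <- vapply(c(0.3, 0.5, 0.7, 0.9), function(th) {
    db <- debias_corpus(sh$x, debias_config(threshold = th),
                        pp = sh$pp, scores = sh$sc)
    n_tweets(db$bots_only)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("planted bots and humans separate on interval regularity", {
  sh <- shared_synth()
  reg <- vapply(sh$x$accounts$account_id, function(aid)
    timing_regularity(sh$x$tweets$timestamp[sh$x$tweets$account_id == aid]),
    numeric(1))
  role <- sh$x$accounts$ground_truth_role
  expect_gt(mean(reg[role == "bot"]), mean(reg[role == "human"]))
  expect_gt(min(reg[role == "bot"]), max(reg[role == "human"]))
})
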