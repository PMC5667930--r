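test_that("empty file yields an empty corpus", {
  f <- withr::local_tempfile(fileext = ".jsonl")
  file.create(f)
  x <- read_corpus(f)
  expect_equal(n_tweets(x), 0)
  expect_equal(nrow(x$accounts), 0)
})

test_that("a hand-written fixture file reads with the counts on inspection", {
  f <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"record_type":"header","schema_version":"1.0","provenance":"raw"}',
    '{"record_type":"account","account_id":"u1","followers":10,"followees":20}',
    '{"record_type":"tweet","tweet_id":"t1","account_id":"u1","timestamp":"2015-06-01T10:00:00Z","text":"hookah night","source_client":"mobile","is_retweet":false,"mention_count":0}',
    '{"record_type":"tweet","tweet_id":"t2","account_id":"u1","timestamp":"2015-06-01T11:00:00Z","text":"more shisha","source_client":"desktop","is_retweet":false,"mention_count":1}',
    '{"record_type":"tweet","tweet_id":"t3","account_id":"u1","timestamp":"2015-06-01T12:00:00Z","text":"hookah again","source_client":"other","is_retweet":true,"mention_count":2}'
  ), f)
  x <- read_corpus(f)
  expect_equal(n_tweets(x), 3)
  expect_equal(nrow(x$accounts), 1)
  expect_equal(attr(x, "malformed"), 0L)
  expect_identical(account_tweet_ids(x, "u1"), c("t1", "t2", "t3"))
})

test_that("malformed lines are counted and reported, not silently dropped", {
  f <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"record_type":"account","account_id":"u1","followers":1,"followees":1}',
    "{this is not json",
    '{"record_type":"tweet","tweet_id":"t1","account_id":"u1","timestamp":"2015-06-01T10:00:00Z","text":"hookah","source_client":"mobile","is_retweet":false,"mention_count":0}'
  ), f)
  expect_warning(x <- read_corpus(f), "malformed")
  expect_equal(attr(x, "malformed"), 1L)
  expect_equal(n_tweets(x), 1)
})

test_that("tweets referencing missing accounts fail validation", {
  tw <- tiny_corpus()$tweets
  acc <- data.frame(account_id = "someone_else", followers = 1L,
                    followees = 1L)
  expect_error(corpus(tw, acc), "missing accounts")
})

test_that("strict mode rejects timestamps outside the collection window", {
  x <- tiny_corpus()
  w <- default_window()
  expect_error(
    corpus(transform(x$tweets, timestamp = w[1] - 100), x$accounts,
           window = w, strict = TRUE),
    "outside the collection window")
  expect_silent(corpus(x$tweets, x$accounts, window = w, strict = TRUE))
})

test_that("write/read round-trip reproduces the corpus exactly", {
  x <- generate_corpus(generator_config(
    seed = 5, n_human_accounts = 12, n_bot_accounts = 2,
    n_marketing_accounts = 2))
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(x, f)
  y <- read_corpus(f)
  expect_identical(y$tweets, x$tweets)
  expect_identical(y$accounts, x$accounts)
  expect_identical(y$provenance, x$provenance)
})

test_that("schema version mismatches are refused", {
  f <- withr::local_tempfile(fileext = ".jsonl")
  writeLines('{"record_type":"header","schema_version":"0.9","provenance":"raw"}', f)
  expect_error(read_corpus(f), "schema version")
})

test_that("keyword filter matches token boundaries, hashtags and plurals", {
  x <- tiny_corpus(c("loving this #hookah tonight",  # hashtag form
                     "off the hook ah well",          # no boundary match
                     "two hookahs going",             # plural expansion
                     "hookahville is a festival",     # longer word, no match
                     "shisha time"))
  kept <- keyword_filter(x, "hookah")
  expect_identical(kept$tweets$tweet_id, c("t01", "t03"))
  expect_error(keyword_filter(x, character()), "non-empty")
})

test_that("keyword filter keeps the documented count on a mixed fixture", {
  texts <- c(rep("great shisha tonight", 4), rep("nothing to see", 6))
  x <- tiny_corpus(sample(texts))
  expect_equal(n_tweets(keyword_filter(x, "shisha")), 4)
})

test_that("keyword filter is idempotent", {
  x <- tiny_corpus()
  once <- keyword_filter(x)
  twice <- keyword_filter(once)
  expect_identical(twice$tweets, once$tweets)
})
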