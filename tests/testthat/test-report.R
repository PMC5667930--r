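mk_labels <- function(pos, neg, neu)
  c(rep("positive", pos), rep("negative", neg), rep("neutral", neu))

mk_tags <- function(hp, pp_, sn, hn, neu) {
  q <- c(rep("highly_positive", hp), rep("passive_positive", pp_),
         rep("subdued_negative", sn), rep("highly_negative", hn),
         rep("neutral", neu))
  p <- c(rep("joy", hp + pp_), rep("sadness", sn), rep("fear", hn),
         rep("none", neu))
  data.frame(tweet_id = as.character(seq_along(q)), valence = 0, arousal = 0,
             emotion = "happy", quadrant = q, primary = p,
             stringsAsFactors = FALSE)
}

test_that("label percentages reproduce count/total at 2-decimal half-up rounding", {
  s <- summarize_corpus(mk_labels(352116, 177537, 62139))
  expect_equal(s$n_tweets, 591792)
  expect_equal(s$label_pcts[["positive"]], 59.50)
  expect_equal(s$label_pcts[["negative"]], 30.00)
  expect_equal(s$label_pcts[["neutral"]], 10.50)
  expect_equal(sum(s$label_pcts), 100, tolerance = 0.02)
})

test_that("quadrant percentages are computed within their parent label", {
  labels <- mk_labels(352116, 177537, 62139)
  tags <- mk_tags(218312, 133804, 95870, 81667, 62139)
  s <- summarize_corpus(labels, tags)
  expect_equal(s$quadrant_pcts[["highly_positive"]], 62.00)
  expect_equal(s$quadrant_pcts[["passive_positive"]], 38.00)
  expect_equal(s$quadrant_pcts[["subdued_negative"]], 54.00)
  expect_equal(s$quadrant_pcts[["highly_negative"]], 46.00)
  expect_equal(s$quadrant_pcts[["highly_positive"]] +
                 s$quadrant_pcts[["passive_positive"]], 100,
               tolerance = 0.02)
  expect_equal(sum(s$primary_probs), 100, tolerance = 0.05)
})

test_that("a single positive tweet summarizes to 100 percent", {
  s <- summarize_corpus("positive")
  expect_equal(s$label_pcts[["positive"]], 100.00)
  expect_error(summarize_corpus(character()), "empty")
})

test_that("summaries are invariant to tweet order", {
  set.seed(3)
  labels <- sample(mk_labels(30, 15, 5))
  a <- summarize_corpus(labels)
  b <- summarize_corpus(sample(labels))
  expect_equal(a$label_counts, b$label_counts)
  expect_equal(a$label_pcts, b$label_pcts)
})

test_that("comparisons of identical corpora have zero deltas", {
  labels <- mk_labels(40, 20, 10)
  tags <- mk_tags(25, 15, 12, 8, 10)
  s <- summarize_corpus(labels, tags)
  cmp <- compare_summaries(s, s)
  expect_equal(cmp$delta, rep(0, 5))
  expect_equal(cmp$debiased_pct - cmp$biased_pct, cmp$delta)
})

test_that("mismatched primary-emotion sets are rejected", {
  labels <- mk_labels(4, 2, 1)
  s_lab_only <- summarize_corpus(labels)
  s_full <- summarize_corpus(labels, mk_tags(3, 1, 1, 1, 1))
  expect_error(compare_summaries(s_full, s_lab_only), "mismatched")
})

test_that("half-up rounding is used for reported percentages", {
  expect_equal(pct2(1, 16), 6.25)
  expect_equal(pct2(1, 800), 0.13)   # 0.125 rounds up, not to even
  expect_equal(pct2(5, 1000), 0.5)
})
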