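lex <- default_lexicon()

test_that("anchor lexicon entries carry their documented valences", {
  expect_equal(token_valence("horrible", lex), -2.5)
  expect_equal(token_valence("wonderful", lex), 2.7)
  expect_true(is.na(token_valence("xyzzy", lex)))
  # stemmed fallback reaches inflected forms
  expect_equal(token_valence("ruining", lex), token_valence("ruined", lex))
})

test_that("lexicon construction enforces range and disjointness", {
  expect_error(valence_lexicon(c(bad = -5), "very", "not", "but"),
               "\\[-4, 4\\]")
  expect_error(valence_lexicon(c(very = 1), "very", "not", "but"),
               "disjoint")
})

test_that("degree modifiers double the following word", {
  plain <- score_tweet(preprocess_tweet("happy smoking hookah"), lex)
  boosted <- score_tweet(preprocess_tweet("very happy smoking hookah"), lex)
  expect_equal(plain$raw_sum, 2.7)
  expect_equal(boosted$raw_sum, 2 * 2.7)   # "happy" counted twice
  expect_gt(boosted$compound, plain$compound)
})

test_that("negation within the window flips polarity: the hedged-praise case", {
  sc <- score_tweet(preprocess_tweet("the hookah here isn't really all that great"), lex)
  expect_identical(sc$label, "negative")
  expect_lt(sc$raw_sum, 0)
})

test_that("contrast markers shift weight onto the trailing clause", {
  sc <- score_tweet(preprocess_tweet("the wait was horrible but the hookah was wonderful"), lex)
  expect_equal(sc$raw_sum, 0.5 * (-2.5) + 1.5 * 2.7)
  expect_identical(sc$label, "positive")
})

test_that("caps and exclamation each double once, capped at one quadrupling", {
  base <- score_tweet(preprocess_tweet("wonderful hookah"), lex)$raw_sum
  caps <- score_tweet(preprocess_tweet("WONDERFUL hookah"), lex)$raw_sum
  excl <- score_tweet(preprocess_tweet("wonderful hookah!"), lex)$raw_sum
  all3 <- score_tweet(preprocess_tweet("very WONDERFUL hookah!"), lex)$raw_sum
  expect_equal(caps, 2 * base)
  expect_equal(excl, 2 * base)
  expect_equal(all3, 4 * base)  # three triggers, multiplier capped at 4
})

test_that("empty or valence-free tweets are neutral with compound 0", {
  sc <- score_tweet(preprocess_tweet(""), lex)
  expect_equal(sc$compound, 0)
  expect_identical(sc$label, "neutral")
  sc2 <- score_tweet(preprocess_tweet("hookah lounge tonight"), lex)
  expect_equal(sc2$compound, 0)
})

test_that("classification uses an inclusive symmetric neutral band", {
  expect_identical(classify_sentiment(0), "neutral")
  expect_identical(classify_sentiment(1), "positive")
  expect_identical(classify_sentiment(-0.05), "negative")
  expect_identical(classify_sentiment(0.05), "positive")
  expect_identical(classify_sentiment(0.049), "neutral")
})

test_that("compound is odd under lexicon sign flip and bounded", {
  flipped <- valence_lexicon(-lex$valences, lex$boosters, lex$negators,
                             lex$contrast)
  texts <- random_rule_texts(50, seed = 99)
  for (txt in texts) {
    tt <- preprocess_tweet(txt)
    a <- score_tweet(tt, lex)
    b <- score_tweet(tt, flipped)
    expect_equal(b$compound, -a$compound, tolerance = 1e-12)
    expect_lt(abs(a$compound), 1)
  }
})

test_that("adding a positive token never decreases the raw sum", {
  base <- score_tweet(preprocess_tweet("good hookah night"), lex)$raw_sum
  more <- score_tweet(preprocess_tweet("good lovely hookah night"), lex)$raw_sum
  expect_gte(more, base)
})

test_that("raw sums equal the brute-force rule enumerator on random tweets", {
  texts <- random_rule_texts(300, seed = 7)
  ctx <- preprocess_context(lex)
  for (txt in texts) {
    tt <- preprocess_tweet(txt, ctx)
    expect_equal(score_tweet(tt, lex)$raw_sum, oracle_raw_sum(tt, lex),
                 tolerance = 1e-12)
  }
})

test_that("precision/recall/F follow the harmonic-mean identities", {
  # P = R = 1
  ev <- evaluate_labels(c("a", "b"), c("a", "b"))
  expect_equal(attr(ev, "macro")[["f1"]], 1)
  # P = R = 0.5 per class => F = 0.5
  ev2 <- evaluate_labels(c("a", "b", "a", "b"), c("a", "a", "b", "b"))
  expect_equal(ev2$f1, c(0.5, 0.5))
  # class a: P = 1, R = 0.5 => F = 2/3
  ev3 <- evaluate_labels(c("a", "b", "b", "b"), c("a", "a", "b", "b"))
  expect_equal(ev3$f1[ev3$class == "a"], 2 / 3)
  expect_error(evaluate_labels("a", c("a", "b")), "length")
})

test_that("undefined precision/recall ratios report 0 with a flag", {
  ev <- evaluate_labels(c("a", "a"), c("a", "b"), classes = c("a", "b", "c"))
  cc <- ev[ev$class == "c", ]
  expect_equal(cc$f1, 0)
  expect_true(cc$undefined)
})
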