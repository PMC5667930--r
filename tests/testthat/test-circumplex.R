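map <- circumplex_map()

test_that("the default map defines 20 anchors partitioned 6/5/4/5", {
  expect_equal(nrow(map), 20)
  tab <- table(map$quadrant)
  expect_equal(tab[["highly_positive"]], 6)
  expect_equal(tab[["passive_positive"]], 5)
  expect_equal(tab[["subdued_negative"]], 4)
  expect_equal(tab[["highly_negative"]], 5)
  # anchors sit on the unit circle
  expect_equal(map$valence^2 + map$arousal^2, rep(1, 20), tolerance = 1e-4)
})

test_that("the primary reduction is total and surjective onto the 5 primaries", {
  red <- reduce_primary(map$emotion, map)
  expect_length(red, 20)
  expect_setequal(unique(red), c("anger", "fear", "joy", "sadness", "disgust"))
  expect_identical(reduce_primary(c("happy", "sad", "tense"), map),
                   c("joy", "sadness", "fear"))
  expect_identical(reduce_primary(c("upset", "unpleasant"), map),
                   c("anger", "disgust"))
  expect_error(reduce_primary("serenity", map), "unknown emotion")
})

test_that("points at an anchor are tagged with that emotion and quadrant", {
  i <- which(map$emotion == "happy")
  tg <- tag_emotion(map$valence[i], map$arousal[i], "positive", map)
  expect_identical(tg$emotion, "happy")
  expect_identical(tg$quadrant, "highly_positive")
  expect_identical(tg$primary, "joy")
})

test_that("positive-valence negative-arousal points are passive positive", {
  tg <- tag_emotion(0.6, -0.5, "positive", map)
  expect_identical(tg$quadrant, "passive_positive")
})

test_that("neutral-labelled tweets get quadrant neutral and primary none", {
  tg <- tag_emotion(0.01, 0.4, "neutral", map)
  expect_identical(tg$quadrant, "neutral")
  expect_identical(tg$primary, "none")
})

test_that("nearest-anchor tagging matches exhaustive search on a dense grid", {
  g <- seq(-0.99, 0.99, length.out = 100)
  pts <- expand.grid(v = g, a = g)
  tg <- tag_emotion(pts$v, pts$a, rep("positive", nrow(pts)), map)
  expected <- mapply(oracle_nearest_emotion, pts$v, pts$a,
                     MoreArgs = list(map = map))
  expect_identical(tg$emotion, unname(expected))
})

test_that("arousal scoring reacts to lexicon words and emphasis", {
  expect_equal(arousal_score(preprocess_tweet("hookah lounge")), 0)
  expect_lt(arousal_score(preprocess_tweet("calm hookah evening")), 0)
  expect_gt(arousal_score(preprocess_tweet("SO PUMPED hookah!!")), 0.5)
  expect_gt(arousal_score(preprocess_tweet("excited for hookah")), 0)
})

test_that("aggregate emotion scores behave as a linear combination", {
  one <- data.frame(tweet_id = "t1", valence = 0.5, arousal = 0.5,
                    emotion = "happy", quadrant = "highly_positive",
                    primary = "joy", stringsAsFactors = FALSE)
  agg <- aggregate_emotion_score(one)
  expect_equal(agg[["joy"]], 1)
  expect_equal(sum(agg), 1)
  five <- data.frame(tweet_id = paste0("t", 1:5), valence = 0, arousal = 0,
                     emotion = "happy",
                     quadrant = "highly_positive",
                     primary = c("anger", "fear", "joy", "sadness", "disgust"),
                     stringsAsFactors = FALSE)
  expect_equal(unname(aggregate_emotion_score(five)), rep(0.2, 5))
  # weighted fixture: weights 2,1 on joy,fear
  two <- five[2:3, ]
  agg2 <- aggregate_emotion_score(two, weights = c(1, 2), normalize = FALSE)
  expect_equal(agg2[["joy"]], 2)
  expect_equal(agg2[["fear"]], 1)
  expect_warning(out <- aggregate_emotion_score(five[0, ]), "empty")
  expect_equal(sum(out), 0)
})

test_that("corpus quadrant shares sum to 100 percent", {
  sh <- shared_synth()
  tags <- tag_corpus(sh$x, sh$sc, pp = sh$pp, map = map)
  shares <- table(tags$quadrant) / nrow(tags) * 100
  expect_equal(sum(shares), 100, tolerance = 1e-9)
  expect_setequal(unique(tags$primary[sh$sc$label == "neutral"]), "none")
})
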