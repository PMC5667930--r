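# hookahsent

Debiased sentiment infoveillance for hookah-related tweet corpora.

## What it is for

Public-health researchers use social-media streams to measure attitudes
toward tobacco products such as hookah (waterpipe). Raw Twitter-style data
is a poor measure of human attitudes, though: social bots post with
machine-like regularity to amplify content, and marketing accounts push
advertising. `hookahsent` implements an end-to-end pipeline for this kind of
study:

1. **Corpus handling** — JSON-lines tweet/account corpora, keyword filtering
   on root terms (`hookah(s)`, `hooka(s)`, `sheesha(s)`, `shisha(s)`,
   `sesh(s)`, hashtags included).
2. **Debiasing** — six account-level bot features (posting-time regularity,
   spam content, mobile/desktop client ratio, follower:followee ratio,
   noun/verb/adverb profile, sentiment dispersion) combined into a single
   bot score; flagged accounts and keyword-matched marketing posts are
   removed, partitioning the corpus exactly into clean / bot / marketing.
3. **Rule-based sentiment** — token valences on a −4..4 spectrum
   (*horrible* = −2.5, *wonderful* = +2.7) plus grammar rules: degree
   modifiers, ALL-CAPS and exclamations double a token ("considered
   twice"), negators within a 3-token window flip sign, and *but* shifts
   weight onto the trailing clause. The summed score is squashed to a
   compound in (−1, 1) by `s / sqrt(s² + 15)` and labelled with a ±0.05
   neutral band.
4. **Emotion tagging** — each scored tweet is placed on Russell's
   valence–arousal circumplex (20 emotions, four quadrants, 6/5/4/5),
   reduced to 5 primary emotions (anger, fear, joy, sadness, disgust).
5. **Reporting** — label/quadrant counts and percentages (half-up, 2
   decimals; quadrants within parent label) and biased-vs-debiased
   primary-emotion probability tables.
6. **Synthetic corpora** — a seeded generator plants human, bot and
   marketing accounts with known sentiment labels, providing ground truth
   for every recovery test. A supervised n-gram SVM classifier
   (`train_ngram_classifier()` / `predict()`) serves as the automated
   counterpart to the rule engine.

## Worked example

```r
library(hookahsent)

# the rule engine on a hedged phrase
score_tweet(preprocess_tweet("the hookah here isn't really all that great"))
#> $raw_sum   -6.2        ("great" doubled by "really", sign-flipped by "isn't")
#> $compound  -0.848
#> $label     "negative"

# full pipeline on a seeded synthetic corpus
res <- run_pipeline(pipeline_config(seed = 1, generator = list(
  n_human_accounts = 50, n_bot_accounts = 6, n_marketing_accounts = 4)))
res$report
#> Debias report: 2114 tweets collected
#>   bot posts removed:            640 (30.27%)
#>   marketing posts removed:      194 (9.18%)
#>   analytic sample:             1280 (60.55%)
#>   biased comparison corpus (humans+bots): 1920
res$comparison
#> Primary-emotion probability (%) by corpus:
#>   emotion    debiased    biased    delta
#>   anger          1.78      1.38    +0.40
#>   fear           5.60      4.36    +1.24
#>   joy           63.56     49.45   +14.11
#>   sadness        9.60      7.47    +2.13
#>   disgust       19.47     37.34   -17.87
```

The debias report shows the corpus partition (bot accounts are detected
from their behavioral features, then marketing posts are removed by
keyword). The comparison table shows why debiasing matters: with the bots'
negative spam included ("biased" column), the probability that a tweet
expresses joy drops sharply and disgust rises — the debiased column is the
one that reflects human sentiment.

A command-line wrapper with `synth` / `filter` / `debias` / `score` /
`emotions` / `report` / `run` subcommands is installed at
`system.file("cli", "hookahsent.R", package = "hookahsent")`.

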