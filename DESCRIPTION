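Package: hookahsent
Title: Debiased Sentiment Infoveillance for Hookah-Related Tweet Corpora
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An infoveillance pipeline for measuring public sentiment toward
    hookah (waterpipe) tobacco on Twitter-like corpora. Provides a seeded
    synthetic corpus generator with planted human, social-bot and marketing
    accounts; multi-feature social-bot scoring and corpus debiasing; a
    rule-based lexicon-and-grammar sentiment engine producing compound
    valence scores; mapping of scored posts onto Russell's 20-emotion
    valence-arousal circumplex with reduction to five primary emotions; a
    supervised n-gram sentiment classifier; and corpus-level summaries
    comparing biased and debiased corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    e1071,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
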