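---
title: "Debiased sentiment infoveillance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Debiased sentiment infoveillance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hookahsent)
```

## The problem

Public attitudes toward hookah (waterpipe) tobacco can be read off social
media at scale, but raw Twitter-style streams are contaminated: social bots
amplify content with machine-like regularity, and marketing accounts push
product advertising that does not reflect any person's sentiment. A corpus
summary computed on the raw stream therefore measures a mixture of human
opinion, automation and advertising. `hookahsent` implements the full
chain needed to study this: corpus handling, bot and marketing removal
("debiasing"), rule-based and supervised sentiment scoring, emotion tagging
on a valence–arousal circumplex, and biased-versus-debiased reporting.

Because no raw tweet corpus of this kind can be redistributed, the package
ships a first-class synthetic generator whose defaults encode the study
conditions the pipeline is meant to operate under: a tweet population with a
59.5/30/10.5 positive/negative/neutral human sentiment mix and roughly a 30%
bot share of posts.

## The rule-based sentiment engine

Each token has a valence on a spectrum from −4 (most unpleasant) to +4 (most
pleasant); for example *horrible* carries −2.5 and *wonderful* +2.7. The
per-tweet raw score is a weighted sum over valence-bearing tokens,

$$ s \;=\; \sum_i w_i \, \sigma_i \, m_i \, v_i, $$

with three grammar mechanisms:

* **Emphasis doubling** ($m_i$): a token is "considered twice" when it is
  immediately preceded by a degree modifier (*very*, *extremely*, ...), when
  it is written in ALL CAPS, or when the clause carries an exclamation mark.
  Each trigger class doubles at most once and the combined multiplier is
  capped at 4, because stacking semantics beyond one emphatic doubling are
  not linguistically meaningful for short posts.
* **Negation flip** ($\sigma_i$): a negator within the three tokens
  preceding a valence token flips its sign. The window is measured on the
  token stream after stop-word removal, which is what lets hedged phrasings
  such as "isn't really all that great" resolve to negative.
* **Contrast shift** ($w_i$): the last contrast marker (*but*, *however*)
  splits the tweet; tokens before it get weight 0.5 and tokens after it 1.5.
  The shift re-weights emphasis toward the trailing clause rather than
  hard-flipping it, and both weights are configurable.

The raw sum is squashed to a compound score in $(-1, 1)$ by
$c = s / \sqrt{s^2 + \alpha}$ with $\alpha = 15$, and labelled by a
symmetric neutral band: positive if $c \ge 0.05$, negative if
$c \le -0.05$, else neutral. The squashing constant and band half-width
follow the established lexicon-and-grammar sentiment tradition this engine
belongs to; the band is the package's declared convention for how neutral
posts arise, since a three-way split cannot be recovered from a two-sided
rule alone. Lexicon lookups try the surface token first and fall back to a
Porter-stemmed index, so inflected forms inherit the base form's valence.

The engine's fidelity is checked two ways: hand-traced scores for the
anchor examples above, and equality of the raw sum against an independent
brute-force rule enumerator on 1,000 randomized token sequences that
exercise every rule (boosters, negators, contrast, caps, exclamations).

## Preprocessing

Tokenization removes URLs and HTML, counts emphasis (exclamation marks,
ALL-CAPS tokens) *before* any lowercasing, and removes stop words
afterwards — with the grammar word classes (boosters, negators, contrast
markers) protected from removal. Normalization unifies emoticon variants
into two classes (smile/frown), strips apostrophes so contraction variants
collapse, applies a small slang table, compresses character elongations
("grrrrrreat") to the shortest dictionary-valid form — falling back to a
run of two when no dictionary form exists — and Porter-stems last. The
stemmer is a direct implementation of the classic five-step
suffix-stripping algorithm.

Part-of-speech tagging is deliberately coarse (noun, verb, adjective,
adverb, preposition, other): the tags feed only the bot content feature,
which needs noun/verb/adverb rates. The default tagger is a shipped tag
lexicon plus suffix rules, and any tagger with the same
tokens-to-tags contract can be plugged in.

## Bot scoring and debiasing

Six account-level features, each mapped onto $[0,1]$ with 1 = bot-like:

| feature | definition | default baseline |
|---|---|---|
| timing | $1/(1+\mathrm{CV})$ of inter-tweet intervals | — |
| spam | fraction of tweets containing a known spam phrase | — |
| client | deviation of mobile share from the human baseline, normalized by directional headroom | mobile fraction 0.6 |
| follower | $\min(1, |\log_{10}(\mathrm{ratio})| / 2)$, pseudocount 1 | band half-width 2 |
| content | total-variation distance of noun/verb/adverb profile from the human reference | (0.55, 0.30, 0.15) |
| sentiment | $1 - \mathrm{sd}(\text{compounds})/\mathrm{sd}_\text{human}$, clipped | $1/\sqrt{3}$ |

The human baselines are declared configuration, not estimates; the
sentiment-dispersion baseline $1/\sqrt{3}$ is the standard deviation of a
compound score spread uniformly over $[-1, 1]$. A feature that cannot be
measured (fewer than three tweets, only "other" clients, no tagged content
tokens) is reported missing and its weight renormalized away; an account
with no measurable features at all is *undecidable* and conservatively
retained. The combined score is a weighted mean (equal weights by default —
the combination is kept as a transparent linear rule so every flagging
decision is auditable), and an account is flagged at a combined score of
0.5 or above. Timing regularity needs at least two intervals: with a single
interval a sample coefficient of variation is undefined, so two-tweet
accounts report the feature as missing rather than as perfectly periodic.

The bot decision is account-level — every cited feature is a behavioral
signature of an account, not of a single post — so all tweets of a flagged
account are removed. Marketing posts are then removed by keyword
(e.g. "1100mah", a battery-strength spec common in ads) from the remainder,
which makes clean/bot/marketing an exact partition of the input: a bot
tweet containing a marketing keyword counts as bot. The companion
"biased comparison" corpus is the input minus marketing only, i.e. humans
and bots together. Information-diffusion features are reduced to per-account
mention rates: full retweet-cascade analysis needs graph data the corpus
format does not carry, and this simplification is deliberate.

## The emotion circumplex

Twenty named emotions sit on the unit circle of the valence–arousal plane,
partitioned 6/5/4/5 into four quadrants (highly positive, passive positive,
subdued negative, highly negative) with equal angular spacing inside each
quadrant. The coordinates ship as a data file so alternative placements can
be swapped in. A scored tweet is placed at (compound valence, arousal); its
quadrant is fixed by the signs of the two coordinates and its emotion is
the nearest anchor within that quadrant, with ties broken alphabetically.
Fixing the quadrant from the signs first keeps quadrant membership exactly
consistent with the affect plane even in the thin wedges near quadrant
boundaries where an anchor of the neighbouring quadrant would be marginally
closer. Tweets labelled neutral by the rule engine are not placed: they get
quadrant `neutral` and primary emotion `none`.

Arousal is not part of the sentiment engine, so the package defines it
explicitly and in one place: the mean arousal of lexicon-matched tokens
plus an emphasis term (0.25 per exclamation, 0.15 per ALL-CAPS token, 0.10
per elongation, each counted at most twice), squashed by `tanh`. A tweet
with no arousal signal of either kind scores exactly 0.

The reduction of the 20 emotions to 5 primaries (anger, fear, joy, sadness,
disgust) is a declared, fully overridable table: both positive quadrants
map to joy; sad, unhappy, depressed and bored map to sadness; tense,
nervous and stressed to fear; upset to anger; unpleasant to disgust. One
naming wrinkle is worth recording: *subdued* is itself a listed
passive-positive emotion, distinct from the "subdued negative" quadrant.

Corpus-level primary-emotion probabilities are computed over assigned
(non-neutral) tweets; quadrant percentages are reported within their parent
label; all percentages are rounded half-up at two decimals, the convention
under which every published count/percentage pair in this problem's
results tables reproduces exactly.

## The supervised n-gram classifier

The automated counterpart to the rule engine is a linear max-margin
(support-vector) multi-class model over unigram and bigram term-frequency
vectors, with document-frequency pruning (minimum df 2, at most 2,000
features) and 5-fold cross-validation. Since the emotion datasets used in
the original line of work cannot be redistributed, training here uses the
synthetic labelled corpus; users holding such datasets can pass any
(tokens, label) pairs to `train_ngram_classifier()` unchanged. Tweets whose
n-grams are entirely out of vocabulary fall back to the training prior
class and are flagged. Evaluation is the standard
$F = 2PR/(P+R)$ per class with unweighted macro averaging; ratios with
empty denominators are reported as 0 and flagged rather than dropped.

## What the generator emulates — and what it does not

Human accounts draw inter-arrival times from a log-normal distribution
(sdlog 1.2, mean 6 h — heavy-tailed, coefficient of variation well above
1), mixed clients (60% mobile among mobile+desktop), balanced follower
ratios ($\log_{10}$ ratio $\sim N(0, 0.3)$), and template text slot-filled
from the package lexica with controlled rates of exclamations (0.12),
ALL-CAPS (0.06), elongation (0.06), emoticons (0.10), contrast clauses
(0.05) and negated phrasings (0.08). Bots post at a fixed period (1 h)
with ±5% jitter, embed spam phrases, use a single client, have extreme
follower:followee ratios, and recycle one template per account, so their
per-account sentiment dispersion is near zero; 70% of bot accounts emit
negative product spam and the rest neutral repetition, which is what makes
the biased corpus joy-poorer than the debiased one. Marketing accounts are
human-like in every behavioral feature but embed marketing keywords in
positive ad copy. Defaults produce about 8,000 tweets (200 human, 25 bot,
15 marketing accounts), giving a ~30% bot tweet share; the quantitative bot
behavior is declared, not inferred — no published description of bot
posting dynamics exists at this granularity.

Because text is assembled from unambiguous lexicon words, the planted
label is exact by construction and the rule engine recovers it almost
perfectly. That is the point — the generator provides ground truth for
*parameter recovery*, not linguistic realism. Passing the recovery tests
says the pipeline's machinery is faithful (features separate the planted
populations, labels are recovered, the debiased/biased contrast has the
right direction); it says nothing about accuracy on real tweets with
sarcasm, misspellings, topic drift or adversarial bots. Retweet graphs,
follower networks and multilingual text are likewise out of scope.

## Numerical and design choices

* Squashing constant $\alpha = 15$, neutral band $\pm 0.05$, negation
  window 3, contrast weights 0.5/1.5, doubling cap 4 — all configurable;
  defaults as motivated above.
* Timestamps are epoch seconds in memory and ISO-8601 UTC strings on disk
  at second resolution; the generator emits whole seconds so that
  write/read round-trips are exact.
* Retweets are kept by default (`drop_retweets` flips this): deduplication
  of retweets is a corpus-design decision the package exposes rather than
  imposes.
* The keyword filter expands root terms with an explicit plural "s" suffix
  (not stemming) and matches hashtags; *waterpipe* is excluded from the
  default terms because it is academic vocabulary rarely used in organic
  posts.
* Problem sizes in the test-suite and acceptance runs: the default
  generator corpus (~8,000 tweets) for recovery checks, 1,000 randomized
  tweets for the rule-engine oracle, a 10,000-point grid for the circumplex
  oracle, and 2,000 labelled tweets for classifier cross-validation. These
  sizes give stable statistics at interactive runtimes.
* Ties in nearest-anchor search are broken by alphabetical anchor order;
  boundary compounds exactly at ±0.05 are classified non-neutral
  (inclusive threshold).

## Limitations

The bot features are behavioral summaries, not a reimplementation of any
published bot-detection classifier; the marketing filter is a keyword
rule and inherits its precision. Arousal scoring is this package's own
operationalization and drives only the within-polarity quadrant split,
never the positive/negative/neutral decision. All performance floors
asserted in the test suite are measured on synthetic template text and
should be read as machinery checks, not field accuracy claims.
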