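# Rule-based sentiment engine.
#
# Token valences on the -4..4 pleasantness spectrum are combined with
# grammar heuristics: degree modifiers, ALL-CAPS and exclamation emphasis
# each double a token's contribution ("considered twice"), a negator within
# the three preceding tokens flips the sign, and a contrast marker ("but")
# shifts weight onto the clause that follows it. The summed score is
# squashed into [-1, 1].

COMPOUND_ALPHA <- 15      # normalization constant of the squashing curve
NEUTRAL_BAND <- 0.05      # symmetric neutral band on the compound score
NEGATION_WINDOW <- 3      # tokens a negator reaches forward
CONTRAST_BEFORE <- 0.5    # clause weights around a contrast marker
CONTRAST_AFTER <- 1.5
MULTIPLIER_CAP <- 4       # at most two independent doublings per token

#' Look up the valence of a normalized token
#'
#' Exact match on the surface form first, then a Porter-stemmed fallback.
#'
#' @param token normalized (pre-stem) token.
#' @param lexicon a `valence_lexicon`.
#' @return valence in \[-4, 4\], or NA if the token carries none.
#' @export
token_valence <- function(token, lexicon = default_lexicon()) {
  v <- lexicon$valences[token]
  if (!is.na(v)) return(unname(v))
  unname(lexicon$stem_index[porter_stem(token)])
}

#' Squash a raw valence sum into \[-1, 1\]
#' @param raw_sum summed weighted token valences.
#' @param alpha normalization constant.
#' @return compound score in (-1, 1).
#' @export
compound_score <- function(raw_sum, alpha = COMPOUND_ALPHA) {
  raw_sum / sqrt(raw_sum^2 + alpha)
}

#' Label a compound score
#'
#' Positive for compound >= band, negative for <= -band (boundary
#' inclusive), neutral in between.
#'
#' @param compound compound score(s) in \[-1, 1\].
#' @param neutral_band half-width of the neutral band (>= 0).
#' @return character vector of labels.
#' @export
classify_sentiment <- function(compound, neutral_band = NEUTRAL_BAND) {
  stopifnot(neutral_band >= 0)
  ifelse(compound >= neutral_band, "positive",
         ifelse(compound <= -neutral_band, "negative", "neutral"))
}

#' Score one preprocessed tweet
#'
#' @param tt a `tokenized_tweet` from [preprocess_tweet()].
#' @param lexicon a `valence_lexicon`.
#' @param neutral_band neutral band half-width.
#' @return list: raw_sum, compound, label.
#' @export
score_tweet <- function(tt, lexicon = default_lexicon(),
                        neutral_band = NEUTRAL_BAND) {
  surf <- tt$surface
  n <- length(surf)
  if (n == 0)
    return(list(raw_sum = 0, compound = 0, label = "neutral"))
  raw <- tt$raw
  caps <- grepl("^[A-Z]{2,}$", raw) & !(surf %in% c(SMILE_TOKEN, FROWN_TOKEN))
  has_excl <- tt$emphasis$exclamation_count >= 1
  is_boost <- surf %in% lexicon$boosters
  is_neg <- surf %in% lexicon$negators
  contrast_pos <- which(surf %in% lexicon$contrast)
  split_at <- if (length(contrast_pos)) max(contrast_pos) else NA_integer_
  raw_sum <- 0
  for (i in seq_len(n)) {
    if (is_boost[i] || is_neg[i] || (i %in% contrast_pos)) next
    v <- token_valence(surf[i], lexicon)
    if (is.na(v)) next
    mult <- 1
    if (i > 1 && is_boost[i - 1]) mult <- mult * 2
    if (caps[i]) mult <- mult * 2
    if (has_excl) mult <- mult * 2
    mult <- min(mult, MULTIPLIER_CAP)
    lo <- max(1, i - NEGATION_WINDOW)
    if (i > 1 && any(is_neg[lo:(i - 1)])) v <- -v
    w <- 1
    if (!is.na(split_at))
      w <- if (i < split_at) CONTRAST_BEFORE else CONTRAST_AFTER
    raw_sum <- raw_sum + w * v * mult
  }
  comp <- compound_score(raw_sum)
  list(raw_sum = raw_sum, compound = comp,
       label = classify_sentiment(comp, neutral_band))
}

#' Score every tweet of a corpus
#'
#' @param x a `corpus`.
#' @param pp optional precomputed [preprocess_corpus()] output.
#' @param lexicon a `valence_lexicon`.
#' @param neutral_band neutral band half-width.
#' @return data frame: tweet_id, raw_sum, compound, label.
#' @export
score_corpus <- function(x, pp = NULL, lexicon = default_lexicon(),
                         neutral_band = NEUTRAL_BAND) {
  if (is.null(pp)) pp <- preprocess_corpus(x, preprocess_context(lexicon))
  sc <- lapply(pp, score_tweet, lexicon = lexicon,
               neutral_band = neutral_band)
  data.frame(
    tweet_id = names(pp),
    raw_sum = vapply(sc, `[[`, numeric(1), "raw_sum"),
    compound = vapply(sc, `[[`, numeric(1), "compound"),
    label = vapply(sc, `[[`, character(1), "label"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Precision, recall and F score per class
#'
#' F is the harmonic mean of precision and recall, 2PR/(P+R). Undefined
#' ratios (empty denominator) are reported as 0 and flagged.
#'
#' @param predicted character vector of predicted labels.
#' @param gold character vector of true labels, same length.
#' @param classes label set; defaults to the union observed.
#' @return data frame (class, precision, recall, f1, undefined) with the
#'   unweighted macro means in attribute `macro` (named vector).
#' @export
evaluate_labels <- function(predicted, gold, classes = NULL) {
  if (length(predicted) != length(gold))
    stop("predicted and gold label vectors differ in length")
  if (is.null(classes)) classes <- sort(unique(c(predicted, gold)))
  rows <- lapply(classes, function(cl) {
    tp <- sum(predicted == cl & gold == cl)
    fp <- sum(predicted == cl & gold != cl)
    fn <- sum(predicted != cl & gold == cl)
    undef <- FALSE
    p <- if (tp + fp == 0) { undef <- TRUE; 0 } else tp / (tp + fp)
    r <- if (tp + fn == 0) { undef <- TRUE; 0 } else tp / (tp + fn)
    f <- if (p + r == 0) { undef <- TRUE; 0 } else 2 * p * r / (p + r)
    data.frame(class = cl, precision = p, recall = r, f1 = f,
               undefined = undef, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "macro") <- c(precision = mean(out$precision),
                          recall = mean(out$recall),
                          f1 = mean(out$f1))
  out
}

#' Macro F score
#' @param predicted predicted labels.
#' @param gold true labels.
#' @param classes optional label set.
#' @return unweighted mean F over classes.
#' @export
macro_f1 <- function(predicted, gold, classes = NULL) {
  unname(attr(evaluate_labels(predicted, gold, classes), "macro")["f1"])
}
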