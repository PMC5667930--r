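# Russell-style valence-arousal circumplex: 20 named emotions placed on the
# unit circle at equal angular spacing within four quadrants, a 5-way primary
# reduction (anger, fear, joy, sadness, disgust), and the arousal scorer
# needed to place tweets on the second axis.

#' Load a circumplex map
#'
#' The map file carries, per emotion, unit-circle (valence, arousal)
#' coordinates, its quadrant and its primary-emotion reduction. The default
#' map ships 20 emotions partitioned 6/5/4/5 over the four quadrants.
#'
#' @param path TSV file (emotion, valence, arousal, quadrant, primary);
#'   defaults to the bundled map.
#' @return a `circumplex_map` data frame, alphabetical by emotion.
#' @export
circumplex_map <- function(path = NULL) {
  if (is.null(path)) path <- extdata("circumplex.tsv")
  m <- utils::read.delim(path, header = FALSE, comment.char = "#",
                         stringsAsFactors = FALSE,
                         col.names = c("emotion", "valence", "arousal",
                                       "quadrant", "primary"))
  if (nrow(m) != 20) stop("circumplex map must define exactly 20 emotions")
  qs <- sort(table(m$quadrant))
  expected <- c(highly_positive = 6L, highly_negative = 5L,
                passive_positive = 5L, subdued_negative = 4L)
  if (!all(names(expected) %in% names(table(m$quadrant))) ||
      !all(table(m$quadrant)[names(expected)] == expected))
    stop("quadrants must partition the 20 emotions 6/5/4/5")
  bad <- setdiff(m$primary, c("anger", "fear", "joy", "sadness", "disgust"))
  if (length(bad)) stop("unknown primary emotions: ", paste(bad, collapse = ", "))
  m <- m[order(m$emotion), ]   # alphabetical order fixes tie-breaking
  rownames(m) <- NULL
  class(m) <- c("circumplex_map", "data.frame")
  m
}

PRIMARY_EMOTIONS <- c("anger", "fear", "joy", "sadness", "disgust")
QUADRANTS <- c("highly_positive", "passive_positive", "subdued_negative",
               "highly_negative", "neutral")

#' Arousal score of a preprocessed tweet
#'
#' Mean arousal of lexicon-matched tokens plus an emphasis term from
#' exclamations, ALL-CAPS tokens and elongations, squashed into \[-1, 1\]
#' by tanh. No signal of either kind gives exactly 0.
#'
#' @param tt a `tokenized_tweet`.
#' @param arousal_lexicon named numeric vector token -> arousal.
#' @return arousal in \[-1, 1\].
#' @export
arousal_score <- function(tt, arousal_lexicon = default_arousal_lexicon()) {
  vals <- arousal_lexicon[tt$surface]
  miss <- is.na(vals)
  if (any(miss)) {
    stem_lex <- arousal_lexicon
    names(stem_lex) <- porter_stem(tolower(names(arousal_lexicon)))
    stem_lex <- stem_lex[!duplicated(names(stem_lex))]
    vals[miss] <- stem_lex[tt$tokens[miss]]
  }
  vals <- vals[!is.na(vals)]
  a_lex <- if (length(vals)) mean(vals) else 0
  e <- tt$emphasis
  emph <- 0.25 * min(e$exclamation_count, 2) +
    0.15 * min(e$allcaps_token_count, 2) +
    0.10 * min(e$elongation_count, 2)
  tanh(a_lex + emph)
}

sign_quadrant <- function(valence, arousal) {
  ifelse(valence > 0,
         ifelse(arousal >= 0, "highly_positive", "passive_positive"),
         ifelse(arousal >= 0, "highly_negative", "subdued_negative"))
}

#' Tag tweets on the emotion circumplex
#'
#' The quadrant is fixed by the signs of (valence, arousal); the emotion is
#' the nearest anchor of that quadrant in Euclidean distance (ties broken by
#' alphabetical anchor order). Tweets labelled neutral get quadrant
#' "neutral" and primary "none".
#'
#' @param valence compound valence in \[-1, 1\] (vector).
#' @param arousal arousal in \[-1, 1\] (vector, recycled).
#' @param label sentiment label per tweet; neutral short-circuits tagging.
#' @param map a `circumplex_map`.
#' @param tweet_id optional ids carried through.
#' @return data frame: tweet_id, valence, arousal, emotion, quadrant, primary.
#' @export
tag_emotion <- function(valence, arousal, label, map = circumplex_map(),
                        tweet_id = NULL) {
  stopifnot(all(abs(valence) <= 1), all(abs(arousal) <= 1))
  n <- length(valence)
  arousal <- rep_len(arousal, n)
  label <- rep_len(label, n)
  if (is.null(tweet_id)) tweet_id <- as.character(seq_len(n))
  quad <- sign_quadrant(valence, arousal)
  emotion <- character(n)
  for (q in unique(quad)) {
    anchors <- map[map$quadrant == q, ]
    idx <- which(quad == q)
    # squared distances to each quadrant anchor; which.min takes the first
    # (alphabetically smallest) on ties
    d <- outer(valence[idx], anchors$valence, "-")^2 +
      outer(arousal[idx], anchors$arousal, "-")^2
    emotion[idx] <- anchors$emotion[apply(d, 1, which.min)]
  }
  primary <- unname(stats::setNames(map$primary, map$emotion)[emotion])
  neutral <- label == "neutral"
  quad[neutral] <- "neutral"
  primary[neutral] <- "none"
  data.frame(tweet_id = tweet_id, valence = valence, arousal = arousal,
             emotion = emotion, quadrant = quad, primary = primary,
             stringsAsFactors = FALSE)
}

#' Reduce a circumplex emotion to its primary emotion
#'
#' @param emotion character vector of anchor names.
#' @param map a `circumplex_map`.
#' @return character vector over anger/fear/joy/sadness/disgust.
#' @export
reduce_primary <- function(emotion, map = circumplex_map()) {
  tab <- stats::setNames(map$primary, map$emotion)
  out <- tab[emotion]
  if (anyNA(out))
    stop("unknown emotion name(s): ",
         paste(unique(emotion[is.na(out)]), collapse = ", "))
  unname(out)
}

#' Aggregate emotion score of a tag set
#'
#' Linear combination over tweets of per-primary-emotion indicators with the
#' given weights (default uniform), normalized to a probability vector over
#' the assigned (non-"none") tweets.
#'
#' @param tags data frame from [tag_emotion()].
#' @param weights per-tweet weights, recycled; default 1.
#' @param normalize divide by the total assigned weight.
#' @return named numeric vector over the 5 primary emotions.
#' @export
aggregate_emotion_score <- function(tags, weights = 1, normalize = TRUE) {
  if (nrow(tags) == 0) {
    warning("empty tag set: aggregate is all zero")
    return(stats::setNames(numeric(5), PRIMARY_EMOTIONS))
  }
  w <- rep_len(weights, nrow(tags))
  keep <- tags$primary != "none"
  agg <- vapply(PRIMARY_EMOTIONS,
                function(p) sum(w[keep][tags$primary[keep] == p]),
                numeric(1))
  if (normalize && sum(agg) > 0) agg <- agg / sum(agg)
  agg
}

#' Tag a whole scored corpus
#'
#' @param x a `corpus`.
#' @param scores data frame from [score_corpus()].
#' @param pp optional precomputed preprocessing (else recomputed).
#' @param map a `circumplex_map`.
#' @param arousal_lexicon arousal lexicon.
#' @return data frame from [tag_emotion()], one row per tweet.
#' @export
tag_corpus <- function(x, scores, pp = NULL, map = circumplex_map(),
                       arousal_lexicon = default_arousal_lexicon()) {
  if (is.null(pp)) pp <- preprocess_corpus(x)
  pp <- pp[scores$tweet_id]
  ar <- vapply(pp, arousal_score, numeric(1),
               arousal_lexicon = arousal_lexicon)
  tag_emotion(scores$compound, unname(ar), scores$label, map = map,
              tweet_id = scores$tweet_id)
}
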