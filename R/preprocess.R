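# Tokenization and normalization pipeline.
#
# Three stages mirror the usual tweet-NLP preparation: (1) tokenize — strip
# URLs and HTML, count emphasis (exclamations, ALL-CAPS) before any
# lowercasing, drop stop words; (2) normalize — unify emoticons and
# apostrophe contractions, apply the slang table, compress elongations,
# Porter-stem; (3) POS-tag with a pluggable coarse tagger.

SMILE_TOKEN <- "SMILE"
FROWN_TOKEN <- "FROWN"

smile_variants <- c(":)", ":-)", ":d", ":-d", "=)", ":]", "(:", "^_^")
frown_variants <- c(":(", ":-(", "=(", ":[", ":'(", "):", ";(")

empty_emphasis <- function() {
  list(allcaps_token_count = 0L, exclamation_count = 0L,
       elongation_count = 0L,
       emoticon_class_counts = c(smile = 0L, frown = 0L))
}

strip_urls_html <- function(text) {
  text <- gsub("<[^>]*>", " ", text)               # HTML tags -> whitespace
  text <- gsub("&[a-zA-Z#0-9]+;", " ", text)       # HTML entities
  text <- gsub("https?://\\S+", " ", text)         # scheme-prefixed URLs
  text <- gsub("www\\.\\S+", " ", text)
  # trailing bare-domain patterns left over after shortening
  gsub("\\S+\\.(com|net|org|co|io|ly|gl)(/\\S*)?(\\s|$)", " ", text)
}

is_emoticon <- function(tok) {
  tolower(tok) %in% c(smile_variants, frown_variants)
}

#' Tokenize a tweet
#'
#' Removes URLs and HTML, drops undecodable characters, records emphasis
#' (exclamation marks, ALL-CAPS tokens) before lowercasing, and removes stop
#' words afterwards. Boosters, negators and contrast markers are never
#' removed even when they appear in the stop-word list, because the sentiment
#' grammar needs them.
#'
#' @param text a single character string (may be empty or NA).
#' @param stopwords character vector of stop words.
#' @param protected words exempt from stop-word removal.
#' @return list with `tokens` (case-preserved) and `emphasis` record.
#' @export
tokenize <- function(text, stopwords = default_stopwords(),
                     protected = character()) {
  emph <- empty_emphasis()
  if (is.null(text) || is.na(text) || !nzchar(text))
    return(list(tokens = character(), emphasis = emph))
  text <- chartr("☺☻", "", text)   # pictographic faces
  text <- gsub("", " :) ", text, fixed = TRUE)
  text <- gsub("", " :( ", text, fixed = TRUE)
  text <- strip_urls_html(text)
  text <- iconv(text, from = "UTF-8", to = "ASCII", sub = " ")
  emph$exclamation_count <- lengths(regmatches(text, gregexpr("!", text, fixed = TRUE)))
  toks <- strsplit(trimws(gsub("\\s+", " ", text)), " ")[[1]]
  toks <- toks[nzchar(toks)]
  # strip punctuation at token edges, except emoticons; drop leading '#'/'@'
  clean1 <- function(tok) {
    if (is_emoticon(tok)) return(tok)
    tok <- sub("^[#@]+", "", tok)
    tok <- gsub("^[^A-Za-z0-9':;=(\\[^-]+|[^A-Za-z0-9)\\]']+$", "", tok)
    if (is_emoticon(tok)) return(tok)
    gsub("[!?.,\"]+", "", tok)
  }
  toks <- vapply(toks, clean1, character(1), USE.NAMES = FALSE)
  toks <- toks[nzchar(toks)]
  emph$allcaps_token_count <- sum(grepl("^[A-Z]{2,}$", toks))
  drop <- tolower(toks) %in% setdiff(tolower(stopwords), tolower(protected)) &
    !vapply(toks, is_emoticon, logical(1))
  list(tokens = toks[!drop], emphasis = emph)
}

compress_elongation <- function(tok, vocab) {
  if (!grepl("(.)\\1{2,}", tok)) return(list(tok = tok, runs = 0L))
  runs <- length(gregexpr("(.)\\1{2,}", tok)[[1]])
  to1 <- gsub("(.)\\1{2,}", "\\1", tok)
  to2 <- gsub("(.)\\1{2,}", "\\1\\1", tok)
  out <- if (to1 %in% vocab) to1 else if (to2 %in% vocab) to2 else to2
  list(tok = out, runs = runs)
}

normalize_vocab <- function(lexicon = default_lexicon()) {
  unique(c(names(lexicon$valences), lexicon$boosters, lexicon$negators,
           lexicon$contrast, names(default_arousal_lexicon()),
           default_stopwords(), names(default_slang()),
           names(default_pos_lexicon())))
}

#' Normalize raw tokens
#'
#' Lowercases, unifies emoticon variants into single SMILE/FROWN tokens,
#' strips apostrophes so contraction variants collapse ("don't" = "dont"),
#' applies the slang table, compresses character elongations (runs of 3+)
#' to the shortest vocabulary-valid form (else to length 2) incrementing the
#' elongation count, and finally Porter-stems.
#'
#' @param tokens character vector from [tokenize()].
#' @param emphasis emphasis record from [tokenize()].
#' @param vocab dictionary used to resolve elongations.
#' @param slang named character vector, slang -> replacement.
#' @return list with `tokens` (stemmed), `surface` (normalized, pre-stem,
#'   parallel to `tokens`) and updated `emphasis`.
#' @export
normalize_tokens <- function(tokens, emphasis = empty_emphasis(),
                             vocab = normalize_vocab(),
                             slang = default_slang()) {
  if (!length(tokens))
    return(list(tokens = character(), surface = character(),
                emphasis = emphasis))
  already <- tokens %in% c(SMILE_TOKEN, FROWN_TOKEN)  # re-normalization
  low <- tolower(tokens)
  emo <- ifelse(already, tokens,
                ifelse(low %in% smile_variants, SMILE_TOKEN,
                       ifelse(low %in% frown_variants, FROWN_TOKEN,
                              NA_character_)))
  emphasis$emoticon_class_counts["smile"] <-
    emphasis$emoticon_class_counts["smile"] +
    sum(emo == SMILE_TOKEN & !already, na.rm = TRUE)
  emphasis$emoticon_class_counts["frown"] <-
    emphasis$emoticon_class_counts["frown"] +
    sum(emo == FROWN_TOKEN & !already, na.rm = TRUE)
  surf <- gsub("['’]", "", low)
  hit <- surf %in% names(slang)
  surf[hit] <- unname(slang[surf[hit]])
  el <- lapply(surf, compress_elongation, vocab = vocab)
  surf <- vapply(el, `[[`, character(1), "tok")
  emphasis$elongation_count <- emphasis$elongation_count +
    sum(vapply(el, `[[`, integer(1), "runs"))
  surf <- ifelse(is.na(emo), surf, emo)
  keep <- nzchar(surf)
  surf <- surf[keep]
  stems <- porter_stem(surf)
  list(tokens = stems, surface = surf, emphasis = emphasis, kept = keep)
}

suffix_tag <- function(tok) {
  if (tok %in% c(SMILE_TOKEN, FROWN_TOKEN)) return("other")
  if (grepl("ly$", tok)) return("adverb")
  if (grepl("(ing|ed)$", tok) && nchar(tok) > 4) return("verb")
  if (grepl("(ous|ful|ive|able|ible|ic|ish)$", tok)) return("adjective")
  if (grepl("(tion|ment|ness|ity|ah|er)$", tok) && nchar(tok) > 3) return("noun")
  "other"
}

#' Coarse part-of-speech tagging
#'
#' Assigns one of noun/verb/adjective/adverb/preposition/other per token.
#' The default tagger combines a small shipped tag lexicon with suffix rules;
#' a custom tagger function (tokens -> tags) can be plugged in.
#'
#' @param tokens normalized (pre-stem) tokens.
#' @param tagger optional function(character) -> character of equal length.
#' @param tag_lexicon named character vector token -> tag.
#' @return character vector of tags, parallel to `tokens`.
#' @export
pos_tag <- function(tokens, tagger = NULL,
                    tag_lexicon = default_pos_lexicon()) {
  if (!length(tokens)) return(character())
  if (!is.null(tagger)) {
    tags <- tagger(tokens)
    if (length(tags) != length(tokens))
      stop("tagger must return one tag per token")
    return(tags)
  }
  tags <- unname(tag_lexicon[tokens])
  miss <- is.na(tags)
  tags[miss] <- vapply(tokens[miss], suffix_tag, character(1))
  tags
}

#' Preprocessing context
#'
#' Loads all word-list resources once so corpus-scale preprocessing does not
#' touch the filesystem per tweet.
#'
#' @param lexicon a `valence_lexicon`.
#' @param stopwords stop-word list.
#' @param tagger optional POS tagger function (tokens -> tags).
#' @return list of class `preprocess_context`.
#' @export
preprocess_context <- function(lexicon = default_lexicon(),
                               stopwords = default_stopwords(),
                               tagger = NULL) {
  structure(list(
    lexicon = lexicon, stopwords = stopwords,
    protected = c(lexicon$boosters, lexicon$negators, lexicon$contrast),
    vocab = normalize_vocab(lexicon),
    slang = default_slang(),
    tag_lexicon = default_pos_lexicon(),
    tagger = tagger
  ), class = "preprocess_context")
}

#' Full preprocessing of one tweet text
#'
#' Runs [tokenize()], [normalize_tokens()] and [pos_tag()]; the grammar
#' word classes of the lexicon are protected from stop-word removal.
#'
#' @param text tweet text.
#' @param ctx a [preprocess_context()] (build once per corpus).
#' @return a `tokenized_tweet` list: raw (case-preserved tokens), surface
#'   (normalized pre-stem), tokens (stemmed), pos_tags, emphasis.
#' @export
preprocess_tweet <- function(text, ctx = preprocess_context()) {
  tk <- tokenize(text, ctx$stopwords, protected = ctx$protected)
  nm <- normalize_tokens(tk$tokens, tk$emphasis, vocab = ctx$vocab,
                         slang = ctx$slang)
  raw <- tk$tokens[nm$kept]  # raw tokens aligned to surviving surface tokens
  structure(
    list(raw = raw, surface = nm$surface, tokens = nm$tokens,
         pos_tags = pos_tag(nm$surface, tagger = ctx$tagger,
                            tag_lexicon = ctx$tag_lexicon),
         emphasis = nm$emphasis),
    class = "tokenized_tweet"
  )
}

#' Preprocess every tweet of a corpus
#'
#' @param x a `corpus`.
#' @param ctx a [preprocess_context()]; built once by default.
#' @return named list of `tokenized_tweet`, names = tweet ids.
#' @export
preprocess_corpus <- function(x, ctx = preprocess_context()) {
  out <- lapply(x$tweets$text, preprocess_tweet, ctx = ctx)
  names(out) <- x$tweets$tweet_id
  out
}
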