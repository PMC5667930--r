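# Word-list resources. All lexica ship as plain-text files under extdata so
# they can be audited or swapped without touching code.

#' Build a valence lexicon
#'
#' Bundles the token valence map (each value on the -4 to 4 pleasantness
#' spectrum) together with the grammar word sets the rule engine needs:
#' degree modifiers (boosters), negators and contrast markers.
#'
#' @param valences named numeric vector, token -> valence in \[-4, 4\].
#' @param boosters character vector of degree modifiers.
#' @param negators character vector of negation words (apostrophe-free form).
#' @param contrast character vector of contrast markers ("but", ...).
#' @return an object of class `valence_lexicon`.
#' @export
valence_lexicon <- function(valences, boosters, negators, contrast) {
  stopifnot(is.numeric(valences), !is.null(names(valences)))
  if (any(valences < -4 | valences > 4))
    stop("valence values must lie in [-4, 4]")
  special <- c(boosters, negators, contrast)
  clash <- intersect(names(valences), special)
  if (length(clash))
    stop("boosters/negators/contrast must be disjoint from valence keys: ",
         paste(clash, collapse = ", "))
  stems <- porter_stem(tolower(names(valences)))
  # first entry wins on stem collisions
  stem_idx <- valences[!duplicated(stems)]
  names(stem_idx) <- stems[!duplicated(stems)]
  structure(
    list(valences = valences, boosters = boosters, negators = negators,
         contrast = contrast, stem_index = stem_idx),
    class = "valence_lexicon"
  )
}

#' Load the bundled default valence lexicon
#'
#' @return a `valence_lexicon`.
#' @export
default_lexicon <- function() {
  valence_lexicon(
    valences = read_tsv_map("valence_lexicon.tsv"),
    boosters = read_wordlist("boosters.txt"),
    negators = read_wordlist("negators.txt"),
    contrast = read_wordlist("contrast.txt")
  )
}

#' @export
print.valence_lexicon <- function(x, ...) {
  cat("Valence lexicon:", length(x$valences), "scored tokens,",
      length(x$boosters), "boosters,", length(x$negators), "negators,",
      length(x$contrast), "contrast markers\n")
  invisible(x)
}

#' Load the bundled arousal lexicon
#'
#' Token -> arousal (activation) score in \[-1, 1\].
#' @return named numeric vector.
#' @export
default_arousal_lexicon <- function() read_tsv_map("arousal_lexicon.tsv")

#' Default stop-word list
#' @return character vector.
#' @export
default_stopwords <- function() read_wordlist("stopwords.txt")

#' Default spam phrase list (bot feature)
#' @return character vector of phrases.
#' @export
default_spam_phrases <- function() read_wordlist("spam_phrases.txt")

#' Default marketing keyword list
#' @return character vector of keywords.
#' @export
default_marketing_keywords <- function() read_wordlist("marketing_keywords.txt")

default_slang <- function() read_tsv_map("slang.tsv", value_numeric = FALSE)

default_pos_lexicon <- function() read_tsv_map("pos_lexicon.tsv", value_numeric = FALSE)
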