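# Porter (1980) suffix-stripping stemmer.
#
# Straight transcription of the five-step algorithm. Operates on lowercase
# ASCII words; anything of length <= 2 is returned unchanged.

ps_is_cons <- function(chars, i) {
  ch <- chars[i]
  if (ch %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (ch == "y") {
    if (i == 1) return(TRUE)
    return(!ps_is_cons(chars, i - 1))
  }
  TRUE
}

# measure m of the stem: [C](VC)^m[V]
ps_measure <- function(stem) {
  chars <- strsplit(stem, "")[[1]]
  n <- length(chars)
  if (n == 0) return(0L)
  types <- vapply(seq_len(n), function(i) ps_is_cons(chars, i), logical(1))
  # collapse runs, count VC transitions
  runs <- rle(types)$values
  sum(runs[-length(runs)] == FALSE & runs[-1] == TRUE)
}

ps_has_vowel <- function(stem) {
  chars <- strsplit(stem, "")[[1]]
  n <- length(chars)
  if (n == 0) return(FALSE)
  any(!vapply(seq_len(n), function(i) ps_is_cons(chars, i), logical(1)))
}

ps_double_cons <- function(stem) {
  n <- nchar(stem)
  if (n < 2) return(FALSE)
  a <- substr(stem, n - 1, n - 1); b <- substr(stem, n, n)
  if (a != b) return(FALSE)
  chars <- strsplit(stem, "")[[1]]
  ps_is_cons(chars, n)
}

# *o condition: stem ends cvc where the final c is not w, x or y
ps_cvc <- function(stem) {
  n <- nchar(stem)
  if (n < 3) return(FALSE)
  chars <- strsplit(stem, "")[[1]]
  if (!ps_is_cons(chars, n - 2) || ps_is_cons(chars, n - 1) ||
      !ps_is_cons(chars, n)) return(FALSE)
  !(chars[n] %in% c("w", "x", "y"))
}

ps_ends <- function(word, suffix) {
  n <- nchar(word); s <- nchar(suffix)
  n > s && substr(word, n - s + 1, n) == suffix
}

ps_chop <- function(word, suffix) substr(word, 1, nchar(word) - nchar(suffix))

# apply first matching (suffix -> replacement) rule whose stem passes `cond`
ps_rule_set <- function(word, rules, cond) {
  for (k in seq_len(nrow(rules))) {
    suf <- rules$suf[k]
    if (ps_ends(word, suf)) {
      stem <- ps_chop(word, suf)
      if (cond(stem)) return(paste0(stem, rules$rep[k]))
      return(word)
    }
  }
  word
}

ps_step1a <- function(w) {
  if (ps_ends(w, "sses")) return(ps_chop(w, "es"))
  if (ps_ends(w, "ies"))  return(ps_chop(w, "es"))
  if (ps_ends(w, "ss"))   return(w)
  if (ps_ends(w, "s"))    return(ps_chop(w, "s"))
  w
}

ps_step1b <- function(w) {
  if (ps_ends(w, "eed")) {
    stem <- ps_chop(w, "d")
    if (ps_measure(ps_chop(w, "eed")) > 0) return(stem)
    return(w)
  }
  fired <- FALSE
  if (ps_ends(w, "ed") && ps_has_vowel(ps_chop(w, "ed"))) {
    w <- ps_chop(w, "ed"); fired <- TRUE
  } else if (ps_ends(w, "ing") && ps_has_vowel(ps_chop(w, "ing"))) {
    w <- ps_chop(w, "ing"); fired <- TRUE
  }
  if (fired) {
    if (ps_ends(w, "at") || ps_ends(w, "bl") || ps_ends(w, "iz")) {
      w <- paste0(w, "e")
    } else if (ps_double_cons(w) &&
               !substr(w, nchar(w), nchar(w)) %in% c("l", "s", "z")) {
      w <- substr(w, 1, nchar(w) - 1)
    } else if (ps_measure(w) == 1 && ps_cvc(w)) {
      w <- paste0(w, "e")
    }
  }
  w
}

ps_step1c <- function(w) {
  if (ps_ends(w, "y") && ps_has_vowel(ps_chop(w, "y")))
    return(paste0(ps_chop(w, "y"), "i"))
  w
}

ps_rules2 <- data.frame(
  suf = c("ational", "tional", "enci", "anci", "izer", "abli", "alli",
          "entli", "eli", "ousli", "ization", "ation", "ator", "alism",
          "iveness", "fulness", "ousness", "aliti", "iviti", "biliti",
          "logi"),
  rep = c("ate", "tion", "ence", "ance", "ize", "able", "al",
          "ent", "e", "ous", "ize", "ate", "ate", "al",
          "ive", "ful", "ous", "al", "ive", "ble",
          "log"),
  stringsAsFactors = FALSE
)

ps_rules3 <- data.frame(
  suf = c("icate", "ative", "alize", "iciti", "ical", "ful", "ness"),
  rep = c("ic", "", "al", "ic", "ic", "", ""),
  stringsAsFactors = FALSE
)

ps_step4 <- function(w) {
  sufs <- c("al", "ance", "ence", "er", "ic", "able", "ible", "ant",
            "ement", "ment", "ent", "ion", "ou", "ism", "ate", "iti",
            "ous", "ive", "ize")
  for (suf in sufs) {
    if (ps_ends(w, suf)) {
      stem <- ps_chop(w, suf)
      if (ps_measure(stem) > 1) {
        if (suf == "ion" &&
            !substr(stem, nchar(stem), nchar(stem)) %in% c("s", "t"))
          return(w)
        return(stem)
      }
      return(w)
    }
  }
  w
}

ps_step5 <- function(w) {
  if (ps_ends(w, "e")) {
    stem <- ps_chop(w, "e")
    m <- ps_measure(stem)
    if (m > 1 || (m == 1 && !ps_cvc(stem))) w <- stem
  }
  if (ps_double_cons(w) && substr(w, nchar(w), nchar(w)) == "l" &&
      ps_measure(substr(w, 1, nchar(w) - 1)) > 1)
    w <- substr(w, 1, nchar(w) - 1)
  w
}

porter_stem_word <- function(word) {
  if (nchar(word) <= 2 || grepl("[^a-z]", word)) return(word)
  w <- ps_step1a(word)
  w <- ps_step1b(w)
  w <- ps_step1c(w)
  w <- ps_rule_set(w, ps_rules2, function(s) ps_measure(s) > 0)
  w <- ps_rule_set(w, ps_rules3, function(s) ps_measure(s) > 0)
  w <- ps_step4(w)
  ps_step5(w)
}

#' Porter stemmer
#'
#' Reduces inflected English words to a common stem using the classic
#' five-step Porter suffix-stripping algorithm (gerunds, plurals,
#' derivational suffixes). Used for lexicon fallback lookups and token
#' normalization.
#'
#' @param words character vector of lowercase words.
#' @return character vector of stems, same length.
#' @examples
#' porter_stem(c("smoking", "ponies", "relational"))
#' @export
porter_stem <- function(words) {
  vapply(words, porter_stem_word, character(1), USE.NAMES = FALSE)
}
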