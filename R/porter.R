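#' Porter suffix-stripping stemmer
#'
#' Reduces English words to stems by the classic five-step Porter algorithm,
#' so that inflectional variants ("nightmares", "nightmaring", "nightmare")
#' collapse onto a common stem ("nightmar"). Used by [preprocess()] to
#' normalize narrative tokens before keyword counting.
#'
#' Words of two letters or fewer are returned unchanged. Input is expected to
#' be lowercase alphabetic; the function does not itself strip punctuation.
#'
#' @param words character vector of lowercase words.
#' @return character vector of stems, same length as `words`.
#' @examples
#' porter_stem(c("nightmares", "nightmaring", "relational", "happy"))
#' @export
porter_stem <- function(words) {
  stopifnot(is.character(words))
  vapply(words, .porter_one, character(1), USE.NAMES = FALSE)
}

# consonant flags; y counts as a vowel when preceded by a consonant
.porter_cons <- function(chars) {
  n <- length(chars)
  cons <- logical(n)
  for (i in seq_len(n)) {
    ch <- chars[i]
    cons[i] <- if (ch %in% c("a", "e", "i", "o", "u")) FALSE
    else if (ch == "y") (i == 1L) || !cons[i - 1L]
    else TRUE
  }
  cons
}

# m in the canonical [C](VC)^m[V] decomposition
.porter_m <- function(stem) {
  if (!nzchar(stem)) return(0L)
  cons <- .porter_cons(strsplit(stem, "", fixed = TRUE)[[1L]])
  if (length(cons) < 2L) return(0L)
  sum(cons[-1L] & !cons[-length(cons)])
}

.porter_has_vowel <- function(stem) {
  if (!nzchar(stem)) return(FALSE)
  any(!.porter_cons(strsplit(stem, "", fixed = TRUE)[[1L]]))
}

.porter_double_cons <- function(stem) {
  n <- nchar(stem)
  if (n < 2L) return(FALSE)
  chars <- strsplit(stem, "", fixed = TRUE)[[1L]]
  chars[n] == chars[n - 1L] && .porter_cons(chars)[n]
}

# *o condition: ends consonant-vowel-consonant, final consonant not w, x or y
.porter_cvc <- function(stem) {
  n <- nchar(stem)
  if (n < 3L) return(FALSE)
  chars <- strsplit(stem, "", fixed = TRUE)[[1L]]
  cons <- .porter_cons(chars)
  cons[n] && !cons[n - 1L] && cons[n - 2L] && !(chars[n] %in% c("w", "x", "y"))
}

.chop <- function(w, k) substr(w, 1L, nchar(w) - k)

# apply the longest matching rule of a (suffix -> replacement) table, subject
# to m(stem) exceeding mmin; only the longest literal match is attempted
.porter_rule_step <- function(w, rules, mmin) {
  sufs <- names(rules)
  sufs <- sufs[order(-nchar(sufs))]
  for (s in sufs) {
    if (endsWith(w, s)) {
      stem <- .chop(w, nchar(s))
      if (.porter_m(stem) > mmin) w <- paste0(stem, rules[[s]])
      return(w)
    }
  }
  w
}

.porter_one <- function(word) {
  if (is.na(word) || nchar(word) <= 2L) return(word)
  w <- word

  # step 1a: plurals
  if (endsWith(w, "sses")) w <- .chop(w, 2L)
  else if (endsWith(w, "ies")) w <- paste0(.chop(w, 3L), "i")
  else if (!endsWith(w, "ss") && endsWith(w, "s")) w <- .chop(w, 1L)

  # step 1b: -eed / -ed / -ing
  fired <- FALSE
  if (endsWith(w, "eed")) {
    if (.porter_m(.chop(w, 3L)) > 0L) w <- .chop(w, 1L)
  } else if (endsWith(w, "ed")) {
    stem <- .chop(w, 2L)
    if (.porter_has_vowel(stem)) { w <- stem; fired <- TRUE }
  } else if (endsWith(w, "ing")) {
    stem <- .chop(w, 3L)
    if (.porter_has_vowel(stem)) { w <- stem; fired <- TRUE }
  }
  if (fired) {
    if (endsWith(w, "at") || endsWith(w, "bl") || endsWith(w, "iz")) {
      w <- paste0(w, "e")
    } else if (.porter_double_cons(w) &&
               !substr(w, nchar(w), nchar(w)) %in% c("l", "s", "z")) {
      w <- .chop(w, 1L)
    } else if (.porter_m(w) == 1L && .porter_cvc(w)) {
      w <- paste0(w, "e")
    }
  }

  # step 1c: y -> i after a stem containing a vowel
  if (endsWith(w, "y") && .porter_has_vowel(.chop(w, 1L))) {
    w <- paste0(.chop(w, 1L), "i")
  }

  # step 2 (m > 0)
  w <- .porter_rule_step(w, c(
    ational = "ate", tional = "tion", enci = "ence", anci = "ance",
    izer = "ize", abli = "able", alli = "al", entli = "ent", eli = "e",
    ousli = "ous", ization = "ize", ation = "ate", ator = "ate",
    alism = "al", iveness = "ive", fulness = "ful", ousness = "ous",
    aliti = "al", iviti = "ive", biliti = "ble"), 0L)

  # step 3 (m > 0)
  w <- .porter_rule_step(w, c(
    icate = "ic", ative = "", alize = "al", iciti = "ic", ical = "ic",
    ful = "", ness = ""), 0L)

  # step 4 (m > 1); -ion additionally requires the stem to end in s or t
  sufs4 <- c("al", "ance", "ence", "er", "ic", "able", "ible", "ant",
             "ement", "ment", "ent", "ion", "ou", "ism", "ate", "iti",
             "ous", "ive", "ize")
  sufs4 <- sufs4[order(-nchar(sufs4))]
  for (s in sufs4) {
    if (endsWith(w, s)) {
      stem <- .chop(w, nchar(s))
      ok <- .porter_m(stem) > 1L
      if (s == "ion") {
        last <- substr(stem, nchar(stem), nchar(stem))
        ok <- ok && last %in% c("s", "t")
      }
      if (ok) w <- stem
      break
    }
  }

  # step 5a: drop final e
  if (endsWith(w, "e")) {
    stem <- .chop(w, 1L)
    m <- .porter_m(stem)
    if (m > 1L || (m == 1L && !.porter_cvc(stem))) w <- stem
  }

  # step 5b: -ll -> -l when m > 1
  if (.porter_m(w) > 1L && .porter_double_cons(w) && endsWith(w, "l")) {
    w <- .chop(w, 1L)
  }

  w
}
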