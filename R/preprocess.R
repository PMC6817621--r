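#' Default English stop-word list
#'
#' Returns the small general-purpose stop list shipped with the package
#' (function words, pronouns, auxiliaries). Contraction forms are absent
#' because [preprocess()] expands contractions before filtering.
#'
#' @return character vector of lowercase stop words.
#' @export
default_stoplist <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "textprior")
  readLines(path, encoding = "UTF-8")
}

# common contractions expanded before tokenization; possessive and
# genitive clitics are simply dropped
.expand_contractions <- function(x) {
  x <- gsub("n['’]t\\b", " not", x)
  x <- gsub("['’]m\\b", " am", x)
  x <- gsub("['’]re\\b", " are", x)
  x <- gsub("['’]ve\\b", " have", x)
  x <- gsub("['’]ll\\b", " will", x)
  x <- gsub("['’]d\\b", "", x)
  x <- gsub("['’]s\\b", "", x)
  x
}

#' Preprocess a raw narrative into normalized token stems
#'
#' Standardizes a free-text self-narrative for keyword analysis: lowercases,
#' expands common contractions, discards tokens containing digits and
#' punctuation-only strings, removes stop words, and Porter-stems the rest.
#' Stop-word filtering is applied both before and after stemming so the
#' returned stems never coincide with a stop-list entry.
#'
#' @param text a single character string (may be empty).
#' @param stoplist character vector of stop words; defaults to
#'   [default_stoplist()].
#' @param id optional document identifier.
#' @param label optional class label: `1` (case, e.g. PTSD) or `2`
#'   (non-case).
#' @return an object of class `tokenized_doc`: a list with elements `id`,
#'   `tokens` (character vector of stems, possibly empty) and `label`.
#' @examples
#' preprocess("I have nightmares, nightmaring at 3am")$tokens
#' @export
preprocess <- function(text, stoplist = default_stoplist(), id = NULL,
                       label = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  x <- tolower(text)
  x <- .expand_contractions(x)
  toks <- strsplit(x, "[^a-z0-9]+")[[1L]]
  toks <- toks[nzchar(toks)]
  toks <- toks[!grepl("[0-9]", toks)]
  toks <- toks[!toks %in% stoplist]
  toks <- porter_stem(toks)
  toks <- toks[nzchar(toks) & !toks %in% stoplist]
  tokenized_doc(tokens = toks, id = id, label = label)
}

#' Construct a tokenized document
#'
#' Low-level constructor used by [preprocess()] and by the synthetic
#' narrative generator, whose output is already a stem sequence.
#'
#' @param tokens character vector of token stems.
#' @param id optional identifier.
#' @param label optional class label in `{1, 2}` or `NULL`.
#' @return object of class `tokenized_doc`.
#' @export
tokenized_doc <- function(tokens, id = NULL, label = NULL) {
  if (!is.null(label)) {
    label <- as.integer(label)
    if (!label %in% c(1L, 2L)) stop("label must be 1, 2 or NULL")
  }
  structure(list(id = id, tokens = as.character(tokens), label = label),
            class = "tokenized_doc")
}

#' @export
print.tokenized_doc <- function(x, ...) {
  cat("<tokenized_doc", if (!is.null(x$id)) paste0("'", x$id, "'"), ">",
      length(x$tokens), "tokens,",
      if (is.null(x$label)) "unlabeled" else paste("class", x$label), "\n")
  invisible(x)
}

#' Read a labeled narrative corpus from JSON lines
#'
#' Each line must be a JSON object with fields `id`, `label` (1, 2 or null)
#' and `text`. Narratives are preprocessed with [preprocess()].
#'
#' @param path path to a JSONL file.
#' @param stoplist stop words passed to [preprocess()].
#' @return list of `tokenized_doc`.
#' @export
read_corpus_jsonl <- function(path, stoplist = default_stoplist()) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    rec <- jsonlite::fromJSON(ln)
    if (is.null(rec$text)) stop("corpus record without 'text' field")
    preprocess(rec$text, stoplist = stoplist, id = rec$id,
               label = if (is.null(rec$label)) NULL else rec$label)
  })
}

#' Write tokenized documents as JSON lines
#'
#' The inverse-direction writer for [read_corpus_jsonl()]: token stems are
#' joined by single spaces into the `text` field (stems are fixed points of
#' the preprocessing pipeline, so the round trip is lossless).
#'
#' @param docs list of `tokenized_doc`.
#' @param path output file path.
#' @export
write_corpus_jsonl <- function(docs, path) {
  lines <- vapply(docs, function(d) {
    jsonlite::toJSON(list(id = d$id,
                          label = if (is.null(d$label)) NULL else d$label,
                          text = paste(d$tokens, collapse = " ")),
                     auto_unbox = TRUE, null = "null")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
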