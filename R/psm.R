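#' Fit a product score model (PSM) text classifier
#'
#' The PSM is a naive-Bayes-style binary classifier over keyword stems. Each
#' class score is the product of smoothed class-conditional keyword rates
#' times the class prior,
#' \deqn{S_c = P(C_c) \prod_w \left[(n_{cw} + a) / \mathrm{len}(C_c)\right]^{x_w},}
#' where \eqn{n_{cw}} counts occurrences of keyword \eqn{w} in the pooled
#' class-\eqn{c} training corpus, \eqn{\mathrm{len}(C_c)} is that corpus's
#' total keyword count, and \eqn{a > 0} is an additive smoothing constant.
#' A document is assigned to class 1 when \eqn{\log(S_1/S_2) > b}; the
#' log-ratio itself is the document's text score.
#'
#' Token occurrences count with multiplicity; tokens outside `vocab` are
#' ignored both in training counts and in scoring.
#'
#' @param docs list of labeled `tokenized_doc` objects (labels 1 and 2 must
#'   both be present).
#' @param vocab optional character vector of keyword stems. Defaults to the
#'   union of stems observed in `docs`.
#' @param a smoothing constant added to each keyword count (default 0.5).
#' @param b decision threshold on the log-ratio scale (default 0; ties go to
#'   class 2).
#' @param priors optional numeric length-2 vector of class prior
#'   probabilities `c(P1, P2)` summing to 1; defaults to the training
#'   document proportions.
#' @return an object of class `psm` with components `vocab`, `u`, `v`
#'   (named per-keyword counts for class 1 and 2), `len1`, `len2`, `prior1`,
#'   `prior2`, `a`, `b`, `n_docs`.
#' @seealso [predict.psm()], [standardize_scores()]
#' @examples
#' docs <- list(
#'   tokenized_doc(c("nightmar", "flashback", "fear", "nightmar"), "d1", 1),
#'   tokenized_doc(c("happi", "calm", "fear", "sleep"), "d2", 2))
#' fit <- psm(docs)
#' predict(fit, list(tokenized_doc(c("nightmar", "fear"), "new")))
#' @export
psm <- function(docs, vocab = NULL, a = 0.5, b = 0, priors = NULL) {
  stopifnot(is.list(docs), length(docs) >= 1L, is.numeric(a), a > 0,
            is.numeric(b), is.finite(b))
  labels <- vapply(docs, function(d) {
    if (is.null(d$label)) NA_integer_ else d$label
  }, integer(1))
  if (anyNA(labels)) stop("all training documents must be labeled")
  if (!all(c(1L, 2L) %in% labels)) {
    stop("both classes (1 and 2) must be present in the training corpus")
  }
  if (is.null(vocab)) {
    vocab <- sort(unique(unlist(lapply(docs, `[[`, "tokens"))))
  }
  vocab <- unique(as.character(vocab))
  count_class <- function(cls) {
    toks <- unlist(lapply(docs[labels == cls], `[[`, "tokens"))
    toks <- toks[toks %in% vocab]
    tab <- table(factor(toks, levels = vocab))
    as.integer(tab)
  }
  u <- count_class(1L)
  v <- count_class(2L)
  names(u) <- names(v) <- vocab
  if (sum(u) == 0L || sum(v) == 0L) {
    stop("each class corpus must contain at least one in-vocabulary token")
  }
  if (is.null(priors)) {
    priors <- c(mean(labels == 1L), mean(labels == 2L))
  }
  stopifnot(length(priors) == 2L, all(priors > 0),
            abs(sum(priors) - 1) < 1e-8)
  structure(list(vocab = vocab, u = u, v = v,
                 len1 = sum(u), len2 = sum(v),
                 prior1 = priors[1L], prior2 = priors[2L],
                 a = a, b = b, n_docs = length(docs),
                 call = match.call()),
            class = "psm")
}

#' @export
print.psm <- function(x, ...) {
  cat("Product score model\n")
  cat(sprintf("  vocabulary: %d keyword stems\n", length(x$vocab)))
  cat(sprintf("  corpus lengths: len(C1) = %d, len(C2) = %d\n",
              x$len1, x$len2))
  cat(sprintf("  priors: P(C1) = %.3f, P(C2) = %.3f\n", x$prior1, x$prior2))
  cat(sprintf("  smoothing a = %g, threshold b = %g\n", x$a, x$b))
  invisible(x)
}

#' Per-keyword log-ratio weights of a PSM
#'
#' @param object a fitted [psm()] model.
#' @param ... unused.
#' @return named numeric vector: the contribution of one occurrence of each
#'   keyword to the document log-ratio score.
#' @export
coef.psm <- function(object, ...) {
  log((object$u + object$a) / object$len1) -
    log((object$v + object$a) / object$len2)
}

#' Score documents with a product score model
#'
#' Computes the text score `raw = log(S1/S2)` for each document, entirely in
#' the log domain, and the implied class (`1` if `raw > b`, else `2`).
#' Out-of-vocabulary tokens are skipped; an empty document scores
#' `log(P1/P2)`.
#'
#' @param object a fitted [psm()] model.
#' @param newdata a `tokenized_doc` or a list of them.
#' @param type `"score"` returns the numeric raw scores, `"class"` the
#'   predicted classes, `"frame"` (default) a data frame with both.
#' @param ... unused.
#' @return numeric vector, integer vector, or data frame with columns `id`,
#'   `raw`, `predicted_class`.
#' @export
predict.psm <- function(object, newdata,
                        type = c("frame", "score", "class"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "tokenized_doc")) newdata <- list(newdata)
  w <- coef(object)
  base <- log(object$prior1 / object$prior2)
  raw <- vapply(newdata, function(d) {
    toks <- d$tokens[d$tokens %in% object$vocab]
    base + if (length(toks)) sum(w[toks]) else 0
  }, numeric(1))
  cls <- ifelse(raw > object$b, 1L, 2L)
  ids <- vapply(seq_along(newdata), function(i) {
    id <- newdata[[i]]$id
    if (is.null(id)) paste0("doc", i) else as.character(id)
  }, character(1))
  switch(type,
         score = stats::setNames(raw, ids),
         class = stats::setNames(cls, ids),
         frame = data.frame(id = ids, raw = raw, predicted_class = cls,
                            stringsAsFactors = FALSE))
}

#' Standardize text scores to zero mean and unit variance
#'
#' Affine z-scoring of raw log-ratio scores over the analyzed cohort, using
#' the sample standard deviation (n - 1 denominator). The standardized
#' score `y` is the covariate entering the latent regression prior.
#'
#' @param raws numeric vector of at least two scores with nonzero variance.
#' @return numeric vector of the same length with sample mean 0 and sample
#'   SD 1, order preserved.
#' @export
standardize_scores <- function(raws) {
  stopifnot(is.numeric(raws))
  if (length(raws) < 2L) stop("need at least 2 scores to standardize")
  if (anyNA(raws) || any(!is.finite(raws))) stop("scores must be finite")
  s <- stats::sd(raws)
  if (s == 0) stop("scores have zero variance; cannot standardize")
  (raws - mean(raws)) / s
}

#' Persist a PSM to JSON / restore it
#'
#' @param object a fitted [psm()] model.
#' @param path file path.
#' @return `read_psm` returns the restored `psm` object.
#' @export
write_psm <- function(object, path) {
  stopifnot(inherits(object, "psm"))
  out <- list(vocab = object$vocab,
              u = as.integer(object$u), v = as.integer(object$v),
              len1 = object$len1, len2 = object$len2,
              prior1 = object$prior1, prior2 = object$prior2,
              a = object$a, b = object$b, n_docs = object$n_docs)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_psm
#' @export
read_psm <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj <- list(vocab = x$vocab,
              u = stats::setNames(as.integer(x$u), x$vocab),
              v = stats::setNames(as.integer(x$v), x$vocab),
              len1 = as.integer(x$len1), len2 = as.integer(x$len2),
              prior1 = x$prior1, prior2 = x$prior2,
              a = x$a, b = x$b, n_docs = x$n_docs, call = NULL)
  class(obj) <- "psm"
  obj
}
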