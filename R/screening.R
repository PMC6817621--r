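#' Classify latent trait estimates against a cutoff
#'
#' @param theta_hats numeric vector of finite latent trait estimates.
#' @param cutoff latent-scale cutoff.
#' @param boundary `"ge"` (default): the boundary is inclusive, an estimate
#'   exactly at the cutoff is classified positive; `"gt"`: strictly above.
#' @return integer labels: `1` = positive (case), `2` = negative.
#' @examples
#' classify(c(-1, 0, 1), cutoff = -0.15)
#' @export
classify <- function(theta_hats, cutoff, boundary = c("ge", "gt")) {
  boundary <- match.arg(boundary)
  stopifnot(all(is.finite(theta_hats)), is.finite(cutoff))
  pos <- if (boundary == "ge") theta_hats >= cutoff else theta_hats > cutoff
  ifelse(pos, 1L, 2L)
}

#' Confusion counts from predicted and true labels
#'
#' @param predicted,truth label vectors; `positive` marks the case label.
#' @param positive the label value counted as positive (default 1).
#' @return object of class `confusion_counts`: list with `tp`, `fp`, `tn`,
#'   `fn`.
#' @export
confusion_counts <- function(predicted, truth, positive = 1L) {
  stopifnot(length(predicted) == length(truth), length(truth) > 0L)
  p <- predicted == positive
  t <- truth == positive
  structure(list(tp = sum(p & t), fp = sum(p & !t),
                 tn = sum(!p & !t), fn = sum(!p & t)),
            class = "confusion_counts")
}

#' Screening performance metrics
#'
#' The five standard screening metrics from a 2 x 2 confusion table:
#' accuracy `(tp + tn) / N`, sensitivity `tp / (tp + fn)`, specificity
#' `tn / (tn + fp)`, positive predictive value `tp / (tp + fp)` and
#' negative predictive value `tn / (tn + fn)`. A metric whose denominator
#' is zero is returned as `NA` and listed in the `"undefined"` attribute.
#'
#' @param counts a [confusion_counts()] object, or a list/vector with
#'   elements `tp`, `fp`, `tn`, `fn`.
#' @return named numeric vector of the five metrics.
#' @examples
#' metrics(confusion_counts(c(1, 1, 2), c(1, 2, 2)))
#' metrics(list(tp = 34, fn = 0, fp = 3, tn = 62))
#' @export
metrics <- function(counts) {
  counts <- as.list(counts)
  stopifnot(all(c("tp", "fp", "tn", "fn") %in% names(counts)))
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  stopifnot(all(c(tp, fp, tn, fn) >= 0))
  n <- tp + fp + tn + fn
  if (n == 0L) stop("empty confusion table")
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  out <- c(accuracy = (tp + tn) / n,
           sensitivity = ratio(tp, tp + fn),
           specificity = ratio(tn, tn + fp),
           ppv = ratio(tp, tp + fp),
           npv = ratio(tn, tn + fn))
  attr(out, "undefined") <- names(out)[is.na(out)]
  out
}

#' Per-item criterion validity coefficients
#'
#' Pearson correlation between each item's 0/1 responses and a criterion
#' score (the point-biserial correlation). Items with a constant response
#' column are returned as `NA` and flagged.
#'
#' @param responses N x I matrix of 0/1 responses.
#' @param criterion numeric length-N criterion scores (e.g. estimated
#'   latent scores, or raw sum scores).
#' @return named numeric vector of correlations, one per item; attribute
#'   `"undefined"` lists items where the correlation does not exist.
#' @export
validity_coefficients <- function(responses, criterion) {
  stopifnot(is.matrix(responses), nrow(responses) == length(criterion))
  if (stats::sd(criterion) == 0) stop("criterion has zero variance")
  r <- apply(responses, 2L, function(col) {
    keep <- !is.na(col)
    if (sum(keep) < 2L || stats::sd(col[keep]) == 0) return(NA_real_)
    stats::cor(col[keep], criterion[keep])
  })
  ids <- colnames(responses)
  if (!is.null(ids)) names(r) <- ids
  attr(r, "undefined") <- names(r)[is.na(r)]
  r
}
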