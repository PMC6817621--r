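#' Standard setting: midpoint of group medians
#'
#' Cutoff halfway between the median latent score of the diagnosed-positive
#' group and that of the diagnosed-negative group.
#'
#' @param scores_pos,scores_neg numeric latent scores of the two diagnostic
#'   groups; both must be nonempty.
#' @return scalar cutoff on the latent scale.
#' @export
cutoff_midpoint_medians <- function(scores_pos, scores_neg) {
  .check_groups(scores_pos, scores_neg)
  (stats::median(scores_pos) + stats::median(scores_neg)) / 2
}

#' Standard setting: contrasting-groups method
#'
#' Logistic regression of diagnostic membership (1 = positive) on the latent
#' score; the cutoff is the score at which the fitted probability of
#' positive membership is 50%, i.e. `-intercept / slope`.
#'
#' @inheritParams cutoff_midpoint_medians
#' @return scalar cutoff.
#' @export
cutoff_contrasting_groups <- function(scores_pos, scores_neg) {
  .check_groups(scores_pos, scores_neg)
  x <- c(scores_pos, scores_neg)
  g <- rep(c(1L, 0L), c(length(scores_pos), length(scores_neg)))
  fit <- suppressWarnings(stats::glm(g ~ x, family = stats::binomial()))
  cf <- stats::coef(fit)
  p <- stats::fitted(fit)
  separated <- all(p[g == 1L] > 1 - 1e-6) && all(p[g == 0L] < 1e-6)
  if (!fit$converged || anyNA(cf) || separated) {
    stop("logistic fit did not yield finite estimates (complete or ",
         "quasi-complete separation of the groups)")
  }
  if (cf[2L] == 0) stop("zero slope: groups are indistinguishable")
  unname(-cf[1L] / cf[2L])
}

#' Standard setting: Bayesian discriminant boundary
#'
#' Fits a normal density to each group's latent scores (sample mean and SD)
#' and returns the decision boundary of the Bayes classifier under zero-one
#' loss: the point solving
#' \eqn{P_1 \phi(x; \mu_1, \sigma_1) = P_2 \phi(x; \mu_2, \sigma_2)}.
#' With unequal variances the quadratic is solved and the root lying
#' between the two group means is returned (or, if none lies between, the
#' root nearest their midpoint).
#'
#' @inheritParams cutoff_midpoint_medians
#' @param priors optional class priors `c(P_pos, P_neg)`; defaults to the
#'   group proportions.
#' @return scalar cutoff.
#' @export
cutoff_bayes_discriminant <- function(scores_pos, scores_neg,
                                      priors = NULL) {
  .check_groups(scores_pos, scores_neg)
  if (length(unique(scores_pos)) < 2L || length(unique(scores_neg)) < 2L) {
    stop("each group needs at least 2 distinct scores")
  }
  n1 <- length(scores_pos); n2 <- length(scores_neg)
  if (is.null(priors)) priors <- c(n1, n2) / (n1 + n2)
  stopifnot(length(priors) == 2L, all(priors > 0))
  mu1 <- mean(scores_pos); s1 <- stats::sd(scores_pos)
  mu2 <- mean(scores_neg); s2 <- stats::sd(scores_neg)
  if (s1 == 0 || s2 == 0) stop("zero within-group variance")
  # P1 phi(x; mu1, s1) = P2 phi(x; mu2, s2)  <=>  A x^2 + B x + C = 0
  A <- 1 / (2 * s2^2) - 1 / (2 * s1^2)
  B <- mu1 / s1^2 - mu2 / s2^2
  C <- mu2^2 / (2 * s2^2) - mu1^2 / (2 * s1^2) +
    log(priors[1L] * s2) - log(priors[2L] * s1)
  if (abs(A) < 1e-12) {
    if (B == 0) stop("degenerate boundary: identical group densities")
    return(-C / B)
  }
  disc <- B^2 - 4 * A * C
  if (disc < 0) stop("no real decision boundary for the fitted densities")
  roots <- (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
  lohi <- range(mu1, mu2)
  inside <- roots >= lohi[1L] & roots <= lohi[2L]
  if (any(inside)) roots[inside][1L]
  else roots[which.min(abs(roots - mean(lohi)))]
}

#' Average of three standard-setting cutoffs
#'
#' @param c1,c2,c3 finite cutoff values from the three methods.
#' @return their arithmetic mean.
#' @export
cutoff_average <- function(c1, c2, c3) {
  vals <- c(c1, c2, c3)
  if (length(vals) != 3L || any(!is.finite(vals))) {
    stop("three finite cutoffs are required")
  }
  mean(vals)
}

#' All standard-setting methods at once
#'
#' Convenience wrapper running [cutoff_midpoint_medians()],
#' [cutoff_contrasting_groups()] and [cutoff_bayes_discriminant()] on the
#' same grouped scores and averaging them.
#'
#' @param scores numeric latent scores.
#' @param labels diagnostic labels aligned with `scores`; `1` = positive,
#'   `2` (or `0`) = negative.
#' @param priors optional class priors for the discriminant method.
#' @return list with the three cutoffs and their `average`.
#' @export
set_standard <- function(scores, labels, priors = NULL) {
  stopifnot(length(scores) == length(labels))
  pos <- scores[labels == 1L]
  neg <- scores[labels != 1L]
  c1 <- cutoff_midpoint_medians(pos, neg)
  c2 <- cutoff_contrasting_groups(pos, neg)
  c3 <- cutoff_bayes_discriminant(pos, neg, priors)
  list(midpoint_medians = c1, contrasting_groups = c2,
       bayes_discriminant = c3, average = cutoff_average(c1, c2, c3))
}

.check_groups <- function(scores_pos, scores_neg) {
  if (length(scores_pos) == 0L || length(scores_neg) == 0L) {
    stop("both diagnostic groups must be nonempty")
  }
  if (anyNA(scores_pos) || anyNA(scores_neg)) {
    stop("latent scores must not contain NA")
  }
  invisible(TRUE)
}
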