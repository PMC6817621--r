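#' Two-parameter logistic item response function
#'
#' Probability of a positive ("yes") response,
#' \deqn{P(X=1\mid\theta) = \frac{\exp[\alpha(\theta-\beta)]}{1+\exp[\alpha(\theta-\beta)]},}
#' where \eqn{\theta} is the latent trait, \eqn{\beta} the item difficulty
#' (severity) and \eqn{\alpha \ge 0} the discrimination. The Rasch model is
#' the special case \eqn{\alpha = 1}. Arguments are recycled as usual.
#'
#' @param theta latent trait value(s) on the logit scale.
#' @param alpha discrimination parameter(s), non-negative.
#' @param beta difficulty parameter(s).
#' @return probabilities in (0, 1).
#' @examples
#' irf_2pl(-0.15, alpha = 1.86, beta = -0.55)
#' @export
irf_2pl <- function(theta, alpha, beta) {
  stopifnot(all(alpha >= 0))
  stats::plogis(alpha * (theta - beta))
}

#' Fisher information of a 2PL item
#'
#' \eqn{I(\theta) = \alpha^2 P(\theta)\{1 - P(\theta)\}}; maximal at
#' \eqn{\theta = \beta}, where it equals \eqn{\alpha^2/4}.
#'
#' @inheritParams irf_2pl
#' @return item information value(s).
#' @export
item_information <- function(theta, alpha, beta) {
  p <- irf_2pl(theta, alpha, beta)
  alpha^2 * p * (1 - p)
}

#' Test information of an item set
#'
#' Sum of [item_information()] over the rows of an item bank; additive and
#' non-negative. Its reciprocal square root is the usual large-sample
#' standard-error approximation at \eqn{\theta}.
#'
#' @param theta a single latent trait value.
#' @param bank an `item_bank` (possibly a subset of rows).
#' @return scalar test information.
#' @export
test_information <- function(theta, bank) {
  stopifnot(length(theta) == 1L)
  if (nrow(bank) == 0L) return(0)
  sum(item_information(theta, bank$alpha, bank$beta))
}

.PCLAMP <- 1e-12

#' Log-likelihood of a dichotomous response pattern
#'
#' \eqn{\sum_i [x_i \log P_i(\theta) + (1-x_i)\log\{1-P_i(\theta)\}]} over
#' the bank's items. Missing responses are skipped; probabilities are
#' clamped to `[1e-12, 1 - 1e-12]` so the value is finite for finite
#' \eqn{\theta}.
#'
#' @param theta latent trait value(s); vectorized over `theta`.
#' @param responses 0/1 vector aligned with the rows of `bank` (NA allowed).
#' @param bank an `item_bank`.
#' @return log-likelihood, one value per element of `theta`.
#' @export
response_loglik <- function(theta, responses, bank) {
  responses <- .check_responses(responses, nrow(bank))
  keep <- !is.na(responses)
  if (!any(keep)) return(rep(0, length(theta)))
  x <- responses[keep]
  alpha <- bank$alpha[keep]
  beta <- bank$beta[keep]
  vapply(theta, function(th) {
    p <- pmin(pmax(irf_2pl(th, alpha, beta), .PCLAMP), 1 - .PCLAMP)
    sum(x * log(p) + (1 - x) * log(1 - p))
  }, numeric(1))
}

.check_responses <- function(responses, n_items) {
  responses <- as.numeric(responses)
  if (length(responses) != n_items) {
    stop("response vector length (", length(responses),
         ") does not match bank size (", n_items, ")")
  }
  ok <- is.na(responses) | responses %in% c(0, 1)
  if (!all(ok)) {
    stop("non-binary response value(s) at position(s) ",
         paste(which(!ok), collapse = ", "))
  }
  responses
}

# default quadrature grid: 0.1-spaced points on [-6, 6], widened so that at
# least 99.999% of every person's prior mass is always covered
.quad_grid <- function(prior_mean, prior_sd) {
  lo <- min(-6, min(prior_mean - 4.5 * prior_sd))
  hi <- max(6, max(prior_mean + 4.5 * prior_sd))
  by <- min(0.1, min(prior_sd) / 10)
  seq(lo, hi, by = by)
}

# shared quadrature engine: X is an N x I matrix of 0/1/NA responses;
# prior_mean / prior_sd are scalars or length-N vectors
.eap_engine <- function(X, alpha, beta, prior_mean, prior_sd, grid = NULL) {
  n <- nrow(X)
  prior_mean <- rep_len(prior_mean, n)
  prior_sd <- rep_len(prior_sd, n)
  stopifnot(all(prior_sd > 0))
  if (is.null(grid)) grid <- .quad_grid(prior_mean, prior_sd)
  cover <- stats::pnorm(max(grid), prior_mean, prior_sd) -
    stats::pnorm(min(grid), prior_mean, prior_sd)
  if (any(cover < 1 - 1e-5)) {
    stop("quadrature grid too narrow: it covers less than 99.999% of the ",
         "prior mass for at least one person")
  }
  G <- length(grid)
  if (length(alpha)) {
    logit <- outer(grid, alpha) -
      matrix(alpha * beta, G, length(alpha), byrow = TRUE)
    P <- pmin(pmax(stats::plogis(logit), .PCLAMP), 1 - .PCLAMP)
    LP <- log(P)
    LQ <- log1p(-P)
    X1 <- X; X1[is.na(X1)] <- 0
    X0 <- 1 - X; X0[is.na(X0)] <- 0
    LL <- X1 %*% t(LP) + X0 %*% t(LQ)
  } else {
    LL <- matrix(0, n, G)
  }
  LPRI <- t(vapply(seq_len(n), function(i) {
    stats::dnorm(grid, prior_mean[i], prior_sd[i], log = TRUE)
  }, numeric(G)))
  W <- LL + LPRI
  W <- W - apply(W, 1L, max)
  w <- exp(W)
  w <- w / rowSums(w)
  m1 <- as.numeric(w %*% grid)
  m2 <- as.numeric(w %*% grid^2)
  list(theta_hat = m1, post_sd = sqrt(pmax(m2 - m1^2, 0)), grid = grid)
}

#' EAP estimation of the latent trait
#'
#' Expected a posteriori estimate of \eqn{\theta} under a normal prior,
#' computed by deterministic quadrature: the posterior mean and SD are
#' evaluated on an equally spaced grid (by default 121 points spaced 0.1 on
#' \eqn{[-6, 6]}, widened automatically when the prior is located or scaled
#' such that this interval would cover less than 99.999% of its mass). A
#' prior-only estimate (no responses, or an all-NA pattern) returns the
#' prior mean and SD.
#'
#' @param responses a 0/1 response vector aligned to `bank` (NA = not
#'   administered), or an N x I matrix for a cohort.
#' @param bank an `item_bank`.
#' @param prior_mean,prior_var mean and variance of the normal prior;
#'   defaults 0 and 1. May be length-N vectors when `responses` is a matrix.
#' @param grid optional explicit quadrature grid; an error is raised if it
#'   covers less than 99.999% of the prior mass.
#' @return for a single pattern, a `latent_posterior` (list with
#'   `theta_hat`, `post_sd`, `prior_spec`); for a matrix, a data frame with
#'   one row per person and columns `person_id`, `theta_hat`, `post_sd`.
#' @examples
#' bank <- ncsr_bank()
#' eap_estimate(rep(1, 21), bank)
#' @export
eap_estimate <- function(responses, bank, prior_mean = 0, prior_var = 1,
                         grid = NULL) {
  stopifnot(is.finite(prior_var), all(prior_var > 0))
  single <- !is.matrix(responses)
  if (single && length(responses) == 0L) {
    responses <- rep(NA_real_, nrow(bank))  # prior-only estimate
  }
  X <- if (single) matrix(.check_responses(responses, nrow(bank)), nrow = 1L)
  else {
    apply(responses, 1L, .check_responses, n_items = nrow(bank))
    matrix(as.numeric(responses), nrow(responses), ncol(responses),
           dimnames = dimnames(responses))
  }
  res <- .eap_engine(X, bank$alpha, bank$beta, prior_mean,
                     sqrt(prior_var), grid)
  prior_spec <- list(type = "normal", mean = prior_mean, var = prior_var)
  if (single) {
    structure(list(theta_hat = res$theta_hat, post_sd = res$post_sd,
                   prior_spec = prior_spec),
              class = "latent_posterior")
  } else {
    ids <- rownames(X)
    if (is.null(ids)) ids <- paste0("P", seq_len(nrow(X)))
    out <- data.frame(person_id = ids, theta_hat = res$theta_hat,
                      post_sd = res$post_sd, stringsAsFactors = FALSE)
    attr(out, "prior_spec") <- prior_spec
    out
  }
}

#' @export
print.latent_posterior <- function(x, ...) {
  cat(sprintf("Latent posterior: theta_hat = %.4f, post_sd = %.4f\n",
              x$theta_hat, x$post_sd))
  ps <- x$prior_spec
  if (!is.null(ps$type)) {
    cat("  prior:", ps$type,
        sprintf("(mean %.3f, var %.3f)\n", ps$mean[1], ps$var[1]))
  }
  invisible(x)
}
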