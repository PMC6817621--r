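#' Latent regression coefficients
#'
#' Container for the linear latent regression
#' \eqn{\theta_n = b_0 + b_1 y_n + \varepsilon_n},
#' \eqn{\varepsilon_n \sim N(0, \sigma^2)}, which links the standardized
#' text score \eqn{y_n} to the latent trait and defines the informative
#' prior \eqn{\theta_n \mid y_n \sim N(b_0 + b_1 y_n, \sigma^2)}.
#'
#' @param b0 intercept.
#' @param b1 slope on the standardized text score.
#' @param sigma2 residual variance, strictly positive.
#' @return object of class `latent_regression`.
#' @examples
#' latent_regression(-0.41, 1.44, 3.57)
#' @export
latent_regression <- function(b0, b1, sigma2) {
  stopifnot(is.finite(b0), is.finite(b1), is.finite(sigma2), sigma2 > 0)
  structure(list(b0 = b0, b1 = b1, sigma2 = sigma2),
            class = "latent_regression")
}

#' @export
print.latent_regression <- function(x, ...) {
  cat(sprintf("Latent regression: theta | y ~ N(%.3f + %.3f y, %.3f)\n",
              x$b0, x$b1, x$sigma2))
  invisible(x)
}

.as_latent_regression <- function(reg) {
  if (inherits(reg, "latent_regression")) return(reg)
  if (inherits(reg, "latreg")) {
    cf <- stats::coef(reg)
    return(latent_regression(cf[["b0"]], cf[["b1"]], cf[["sigma2"]]))
  }
  if (is.list(reg) && all(c("b0", "b1", "sigma2") %in% names(reg))) {
    return(latent_regression(reg$b0, reg$b1, reg$sigma2))
  }
  stop("cannot interpret 'reg' as a latent regression")
}

#' Informative text-score prior for the latent trait
#'
#' Maps a standardized text score to the normal prior
#' \eqn{N(b_0 + b_1 y, \sigma^2)} implied by the latent regression.
#'
#' @param reg a `latent_regression`, a fitted [fit_latent_regression()]
#'   object, or a list with `b0`, `b1`, `sigma2`.
#' @param y standardized text score(s).
#' @return list with elements `mean` (same length as `y`) and `var`.
#' @examples
#' text_prior(latent_regression(-0.41, 1.44, 3.57), y = 0)
#' @export
text_prior <- function(reg, y) {
  reg <- .as_latent_regression(reg)
  list(mean = reg$b0 + reg$b1 * y, var = reg$sigma2)
}

#' Hybrid EAP estimation under a text-score prior
#'
#' Posterior mean and SD of the latent trait when the standard normal prior
#' of [eap_estimate()] is replaced by the informative prior
#' \eqn{N(b_0 + b_1 y_n, \sigma^2)} derived from each person's standardized
#' text score. Uses the same deterministic quadrature engine as
#' [eap_estimate()], so with `b0 = 0`, `b1 = 0`, `sigma2 = 1` the two
#' estimators coincide exactly.
#'
#' @param responses 0/1 vector (single person) or N x I matrix.
#' @param bank an `item_bank`.
#' @param reg latent regression coefficients (see [text_prior()]).
#' @param y standardized text score(s); length 1 or N.
#' @param grid optional quadrature grid (see [eap_estimate()]).
#' @return as [eap_estimate()]; `prior_spec` records `(b0, b1, sigma2, y)`.
#' @export
hybrid_eap <- function(responses, bank, reg, y, grid = NULL) {
  reg <- .as_latent_regression(reg)
  pr <- text_prior(reg, y)
  out <- eap_estimate(responses, bank, prior_mean = pr$mean,
                      prior_var = pr$var, grid = grid)
  spec <- list(type = "text", b0 = reg$b0, b1 = reg$b1,
               sigma2 = reg$sigma2, y = y)
  if (inherits(out, "latent_posterior")) out$prior_spec <- spec
  else attr(out, "prior_spec") <- spec
  out
}

#' Fit the Bayesian latent regression by MCMC
#'
#' Joint posterior sampling of the person traits \eqn{\theta_1,\dots,\theta_N}
#' and the latent regression parameters \eqn{(b_0, b_1, \sigma^2)} given
#' fixed 2PL item parameters, item responses and standardized text scores:
#' \deqn{x_{ni} \sim \mathrm{Bernoulli}\{P_i(\theta_n)\}, \quad
#'       \theta_n \sim N(b_0 + b_1 y_n, \sigma^2).}
#' A Metropolis-within-Gibbs sampler is used: each \eqn{\theta_n} is updated
#' by a random-walk Metropolis step whose scale is tuned to a 30--50%
#' acceptance rate during burn-in, while \eqn{(b_0, b_1)} and
#' \eqn{\sigma^2} are drawn from their conjugate full conditionals under
#' \eqn{b_0, b_1 \sim N(0, 100)} and
#' \eqn{\sigma^2 \sim \mathrm{InvGamma}(0.01, 0.01)} priors. Runs are
#' reproducible given `seed`; with more than one chain a split-chain
#' \eqn{\widehat{R}} diagnostic is reported.
#'
#' @param responses N x I matrix of 0/1 responses (NA = not administered).
#' @param bank an `item_bank` aligned with the columns of `responses`.
#' @param y numeric length-N vector of standardized text scores.
#' @param n_iter total iterations per chain (default 5000).
#' @param burn_in discarded initial iterations (default 1000).
#' @param chains number of chains (default 2).
#' @param seed integer seed; chain c uses `seed + c - 1`.
#' @param prior_b_var prior variance of `b0` and `b1` (default 100).
#' @param sigma2_prior shape and rate of the inverse-gamma prior on
#'   `sigma2` (default `c(0.01, 0.01)`).
#' @param init_step initial random-walk proposal SD (default 2.4).
#' @param store_theta keep per-person draws (needed for Monte Carlo
#'   standard errors; default TRUE).
#' @param fix_coefficients optional named vector `c(b0=, b1=, sigma2=)`;
#'   when given, the regression block is held at these values and only the
#'   person traits are sampled (useful for validating the trait sampler
#'   against quadrature, and for two-stage scoring studies).
#' @return object of class `latreg` with posterior summaries for
#'   `(b0, b1, sigma2)` (pooled over chains), per-person `theta` estimates
#'   with posterior SD and batch-means MCSE, the retained draws, acceptance
#'   rates, and `rhat`.
#' @seealso [hybrid_eap()] for the two-stage quadrature path,
#'   [predict.latreg()] for scoring new persons with the fitted
#'   coefficients.
#' @export
fit_latent_regression <- function(responses, bank, y, n_iter = 5000,
                                  burn_in = 1000, chains = 2, seed = 1L,
                                  prior_b_var = 100,
                                  sigma2_prior = c(0.01, 0.01),
                                  init_step = 2.4, store_theta = TRUE,
                                  fix_coefficients = NULL) {
  if (!is.matrix(responses)) responses <- as.matrix(responses)
  n <- nrow(responses)
  if (n < 2L) stop("fewer than 2 persons: latent regression is not fittable")
  if (n < 10L) warning("fewer than 10 persons; estimates will be unstable")
  if (length(y) != n) stop("length of y must match the number of persons")
  if (any(!is.finite(y))) stop("non-finite text score(s) in y")
  if (ncol(responses) != nrow(bank)) {
    stop("number of response columns does not match bank size")
  }
  stopifnot(burn_in < n_iter, chains >= 1L)
  apply(responses, 1L, .check_responses, n_items = nrow(bank))
  X <- matrix(as.numeric(responses), n, ncol(responses))
  alpha <- bank$alpha
  beta <- bank$beta
  ab <- alpha * beta
  X1 <- X; X1[is.na(X1)] <- 0
  X0 <- 1 - X; X0[is.na(X0)] <- 0

  bern_ll <- function(theta) {
    logit <- theta %o% alpha - matrix(ab, n, length(alpha), byrow = TRUE)
    P <- pmin(pmax(stats::plogis(logit), .PCLAMP), 1 - .PCLAMP)
    rowSums(X1 * log(P) + X0 * log1p(-P))
  }

  D <- cbind(1, y)
  DtD <- crossprod(D)
  kept <- n_iter - burn_in
  a0 <- sigma2_prior[1L]; r0 <- sigma2_prior[2L]
  fixed <- !is.null(fix_coefficients)
  if (fixed) {
    stopifnot(all(c("b0", "b1", "sigma2") %in% names(fix_coefficients)),
              fix_coefficients[["sigma2"]] > 0)
  }

  run_chain <- function(chain) {
    set.seed(as.integer(seed) + chain - 1L)
    theta <- y
    b <- if (fixed) unname(fix_coefficients[c("b0", "b1")]) else c(0, 1)
    s2 <- if (fixed) fix_coefficients[["sigma2"]] else 1
    step <- rep(init_step, n)
    ll_cur <- bern_ll(theta)
    acc_win <- integer(n)
    acc_tot <- integer(n)
    draws <- matrix(NA_real_, kept, 3L,
                    dimnames = list(NULL, c("b0", "b1", "sigma2")))
    th_draws <- if (store_theta) matrix(NA_real_, kept, n) else NULL
    for (it in seq_len(n_iter)) {
      mu <- D %*% b
      prop <- theta + stats::rnorm(n, 0, step)
      ll_prop <- bern_ll(prop)
      logr <- ll_prop - ll_cur +
        stats::dnorm(prop, mu, sqrt(s2), log = TRUE) -
        stats::dnorm(theta, mu, sqrt(s2), log = TRUE)
      acc <- log(stats::runif(n)) < logr
      theta[acc] <- prop[acc]
      ll_cur[acc] <- ll_prop[acc]
      acc_win <- acc_win + acc
      if (it > burn_in) acc_tot <- acc_tot + acc
      if (it <= burn_in && it %% 50L == 0L) {
        rate <- acc_win / 50
        step <- step * ifelse(rate < 0.3, 0.8, ifelse(rate > 0.5, 1.25, 1))
        acc_win <- integer(n)
      }
      if (!fixed) {
        # conjugate block update of (b0, b1) given theta and sigma2
        V <- solve(DtD / s2 + diag(1 / prior_b_var, 2L))
        m <- V %*% (crossprod(D, theta) / s2)
        b <- as.numeric(m + t(chol(V)) %*% stats::rnorm(2L))
        resid <- theta - as.numeric(D %*% b)
        s2 <- 1 / stats::rgamma(1L, shape = a0 + n / 2,
                                rate = r0 + sum(resid^2) / 2)
      }
      if (it > burn_in) {
        k <- it - burn_in
        draws[k, ] <- c(b[1L], b[2L], s2)
        if (store_theta) th_draws[k, ] <- theta
      }
    }
    list(draws = draws, theta_draws = th_draws,
         accept = acc_tot / kept, step = step)
  }

  res <- lapply(seq_len(chains), run_chain)
  all_draws <- do.call(rbind, lapply(res, `[[`, "draws"))
  coefs <- colMeans(all_draws)
  coef_sd <- apply(all_draws, 2L, stats::sd)
  ci <- apply(all_draws, 2L, stats::quantile, probs = c(0.025, 0.975))
  rhat <- if (chains > 1L || kept >= 4L) {
    vapply(1:3, function(j) {
      .split_rhat(lapply(res, function(r) r$draws[, j]))
    }, numeric(1))
  } else rep(NA_real_, 3L)
  names(rhat) <- names(coefs)

  ids <- rownames(responses)
  if (is.null(ids)) ids <- paste0("P", seq_len(n))
  th_mean <- Reduce(`+`, lapply(res, function(r) {
    if (store_theta) colMeans(r$theta_draws) else rep(NA_real_, n)
  })) / chains
  th_sd <- if (store_theta) {
    pooled <- do.call(rbind, lapply(res, `[[`, "theta_draws"))
    apply(pooled, 2L, stats::sd)
  } else rep(NA_real_, n)
  th_mcse <- if (store_theta) {
    per_chain <- vapply(res, function(r) {
      apply(r$theta_draws, 2L, .batch_mcse)
    }, numeric(n))
    per_chain <- matrix(per_chain, nrow = n)
    sqrt(rowSums(per_chain^2)) / chains
  } else rep(NA_real_, n)

  structure(list(
    coefficients = coefs, coef_sd = coef_sd, coef_ci = ci, rhat = rhat,
    draws = lapply(res, `[[`, "draws"),
    theta = data.frame(person_id = ids, y = y, theta_hat = th_mean,
                       post_sd = th_sd, mcse = th_mcse,
                       stringsAsFactors = FALSE),
    acceptance = rowMeans(vapply(res, `[[`, numeric(n), "accept")),
    bank = bank, n = n,
    config = list(n_iter = n_iter, burn_in = burn_in, chains = chains,
                  seed = as.integer(seed), prior_b_var = prior_b_var,
                  sigma2_prior = sigma2_prior),
    call = match.call()),
    class = "latreg")
}

# batch-means Monte Carlo standard error of the mean of one chain
.batch_mcse <- function(x) {
  m <- length(x)
  nb <- max(2L, floor(sqrt(m)))
  bs <- floor(m / nb)
  bm <- vapply(seq_len(nb), function(j) {
    mean(x[((j - 1L) * bs + 1L):(j * bs)])
  }, numeric(1))
  stats::sd(bm) / sqrt(nb)
}

# split-chain potential scale reduction factor
.split_rhat <- function(chains_list) {
  halves <- unlist(lapply(chains_list, function(x) {
    h <- floor(length(x) / 2)
    list(x[seq_len(h)], x[(h + 1L):(2L * h)])
  }), recursive = FALSE)
  m <- length(halves)
  len <- length(halves[[1L]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- len * stats::var(means)
  if (W <= 0) return(NA_real_)
  sqrt(((len - 1) / len * W + B / len) / W)
}

#' @export
print.latreg <- function(x, ...) {
  cat("Bayesian latent regression (text-score prior for a 2PL trait)\n")
  cat(sprintf("  %d persons, %d items, %d chain(s) x %d iterations (burn-in %d)\n",
              x$n, nrow(x$bank), x$config$chains, x$config$n_iter,
              x$config$burn_in))
  cf <- x$coefficients
  cat(sprintf("  posterior means: b0 = %.3f, b1 = %.3f, sigma2 = %.3f\n",
              cf[["b0"]], cf[["b1"]], cf[["sigma2"]]))
  if (!anyNA(x$rhat)) {
    cat(sprintf("  split-Rhat: %s\n",
                paste(sprintf("%s %.3f", names(x$rhat), x$rhat),
                      collapse = ", ")))
  }
  invisible(x)
}

#' @export
coef.latreg <- function(object, ...) object$coefficients

#' @export
summary.latreg <- function(object, ...) {
  tab <- cbind(mean = object$coefficients, sd = object$coef_sd,
               `2.5%` = object$coef_ci[1L, ], `97.5%` = object$coef_ci[2L, ],
               Rhat = object$rhat)
  structure(list(coefficients = tab,
                 acceptance = mean(object$acceptance),
                 theta = object$theta, config = object$config),
            class = "summary.latreg")
}

#' @export
print.summary.latreg <- function(x, ...) {
  cat("Bayesian latent regression: posterior summary\n\n")
  print(round(x$coefficients, 4))
  cat(sprintf("\nMean Metropolis acceptance rate (theta updates): %.2f\n",
              x$acceptance))
  cat(sprintf("Persons: %d; mean posterior SD of theta: %.3f\n",
              nrow(x$theta), mean(x$theta$post_sd)))
  invisible(x)
}

#' Trace plots for a fitted latent regression
#'
#' @param x a `latreg` object.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.latreg <- function(x, ...) {
  old <- graphics::par(mfrow = c(3, 1), mar = c(3, 4, 2, 1))
  on.exit(graphics::par(old))
  for (j in colnames(x$draws[[1L]])) {
    graphics::matplot(sapply(x$draws, function(d) d[, j]), type = "l",
                      lty = 1, ylab = j, xlab = "", ...)
  }
  invisible(x)
}

#' Two-stage scoring of persons with fitted coefficients
#'
#' Plug-in alternative to refitting: the posterior-mean coefficients of a
#' fitted latent regression define each person's text prior, and the trait
#' is estimated by [hybrid_eap()] quadrature. Suitable for routing and for
#' scoring persons not in the training cohort.
#'
#' @param object a fitted `latreg`.
#' @param responses 0/1 vector or matrix of item responses.
#' @param y standardized text score(s).
#' @param bank item bank; defaults to the bank used in fitting.
#' @param ... unused.
#' @return as [hybrid_eap()].
#' @export
predict.latreg <- function(object, responses, y, bank = object$bank, ...) {
  hybrid_eap(responses, bank, object, y)
}
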