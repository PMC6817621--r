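#' Rank items by information at the diagnostic cutoff
#'
#' Orders the bank's items by [item_information()] evaluated at the cutoff
#' trait value, descending, as in information-based adaptive item selection
#' for a screening (mastery) decision. Ties are broken by bank row order.
#'
#' @param bank an `item_bank`.
#' @param cutoff_theta latent-scale diagnostic cutoff (default -0.15, the
#'   value carried over from the n = 880 NCS-R calibration).
#' @return object of class `routing_plan`: list with `cutoff_theta`,
#'   `ranked_items` (a permutation of the bank's ids), `information`
#'   (named, in ranked order) and `tie_rule`.
#' @examples
#' rank_items(ncsr_bank())$ranked_items[1:4]  # C6 B5 C4 B3
#' @export
rank_items <- function(bank, cutoff_theta = -0.15) {
  stopifnot(nrow(bank) >= 1L, is.finite(cutoff_theta))
  info <- item_information(cutoff_theta, bank$alpha, bank$beta)
  ord <- order(-info)  # stable: ties keep bank order
  structure(list(cutoff_theta = cutoff_theta,
                 ranked_items = bank$item_id[ord],
                 information = stats::setNames(info[ord], bank$item_id[ord]),
                 tie_rule = "bank order"),
            class = "routing_plan")
}

#' @export
print.routing_plan <- function(x, ...) {
  cat(sprintf("Routing plan at cutoff theta = %.2f\n", x$cutoff_theta))
  cat("  order:", paste(x$ranked_items, collapse = ", "), "\n")
  invisible(x)
}

#' Standard-error curve over increasing test length
#'
#' For each m = 1..M, estimates every person's trait from the first m items
#' of the routing plan and records the cohort mean of a standard-error
#' measure. With `prior_mode = "standard"` estimation uses the N(0, 1)
#' prior (questionnaire-only); with `prior_mode = "text"` each person's
#' prior is the text-score prior `N(b0 + b1 y_n, sigma2)`.
#'
#' Two SE measures are available. The default, `"information"`, is the
#' large-sample standard error
#' \eqn{1/\sqrt{\pi_0 + I_m(\hat\theta_n)}}, where \eqn{I_m} is the test
#' information of the first m items and \eqn{\pi_0} is the prior precision
#' contributed by the text prior (\eqn{1/\sigma^2}; 0 in standard mode,
#' where the questionnaire alone carries the measurement). The information
#' function is evaluated, for both modes, at a common reference estimate of
#' each person's trait -- the EAP from the full questionnaire -- because
#' interim estimates at very short test lengths are too noisy to anchor the
#' information function and would make the two curves incomparable.
#' `"posterior_sd"` instead averages the exact posterior SD from the
#' quadrature engine under each mode's own prior and interim estimate;
#' note that this measure can rank the two modes in the opposite order
#' when the text prior's variance exceeds 1, since it reflects prior
#' precision but not how well the prior is centered.
#'
#' @param responses N x I matrix of 0/1 responses, columns aligned with
#'   `bank`.
#' @param bank an `item_bank`.
#' @param plan a [rank_items()] routing plan over the same bank.
#' @param prior_mode `"standard"` or `"text"`.
#' @param reg,y latent regression and standardized scores, required for
#'   `prior_mode = "text"`.
#' @param se_measure `"information"` (default) or `"posterior_sd"`.
#' @return data frame of class `se_curve` with columns `m` and
#'   `mean_post_sd`; attributes `with_text_prior` and `se_measure`.
#' @export
se_curve <- function(responses, bank, plan = rank_items(bank),
                     prior_mode = c("standard", "text"), reg = NULL,
                     y = NULL, se_measure = c("information", "posterior_sd")) {
  prior_mode <- match.arg(prior_mode)
  se_measure <- match.arg(se_measure)
  stopifnot(is.matrix(responses), nrow(responses) >= 1L,
            ncol(responses) == nrow(bank))
  idx <- match(plan$ranked_items, bank$item_id)
  if (anyNA(idx)) stop("routing plan does not match the bank's item ids")
  if (prior_mode == "text") {
    if (is.null(reg) || is.null(y)) {
      stop("prior_mode = 'text' requires 'reg' and 'y'")
    }
    pr <- text_prior(reg, y)
    pm <- pr$mean; pv <- pr$var
    prior_prec <- 1 / pr$var
  } else {
    pm <- 0; pv <- 1
    prior_prec <- 0
  }
  M <- length(idx)
  if (se_measure == "information") {
    ref <- eap_estimate(responses, bank)$theta_hat
    means <- vapply(seq_len(M), function(m) {
      sub_bank <- bank[idx[seq_len(m)], , drop = FALSE]
      info <- vapply(ref, test_information, numeric(1), bank = sub_bank)
      mean(1 / sqrt(prior_prec + info))
    }, numeric(1))
  } else {
    means <- vapply(seq_len(M), function(m) {
      sub <- idx[seq_len(m)]
      est <- eap_estimate(responses[, sub, drop = FALSE],
                          bank[sub, , drop = FALSE],
                          prior_mean = pm, prior_var = pv)
      mean(est$post_sd)
    }, numeric(1))
  }
  out <- data.frame(m = seq_len(M), mean_post_sd = means)
  attr(out, "with_text_prior") <- prior_mode == "text"
  attr(out, "se_measure") <- se_measure
  class(out) <- c("se_curve", "data.frame")
  out
}

#' Test-length saving implied by a pair of SE curves
#'
#' Finds the smallest test length `m_star` at which the with-prior curve
#' reaches (<=) the precision of the full-length without-prior test; the
#' saving is `M - m_star`. No interpolation between integer test lengths is
#' used. If even the full with-prior test stays above the reference level,
#' `m_star = M` and the saving is 0.
#'
#' @param curve_with SE curve estimated with the text prior.
#' @param curve_without SE curve estimated with the standard prior.
#' @return list with `m_star`, `saving` and `reference` (the final value of
#'   `curve_without`).
#' @export
items_saved <- function(curve_with, curve_without) {
  M <- nrow(curve_without)
  stopifnot(nrow(curve_with) == M, M >= 1L)
  ref <- curve_without$mean_post_sd[M]
  hit <- which(curve_with$mean_post_sd <= ref)
  m_star <- if (length(hit)) min(hit) else M
  list(m_star = m_star, saving = M - m_star, reference = ref)
}

#' Plot a pair of SE curves
#'
#' @param x an `se_curve`.
#' @param other optional second curve drawn for comparison.
#' @param ... passed to [graphics::plot()].
#' @export
plot.se_curve <- function(x, other = NULL, ...) {
  ylim <- range(x$mean_post_sd, if (!is.null(other)) other$mean_post_sd)
  graphics::plot(x$m, x$mean_post_sd, type = "b", pch = 16,
                 xlab = "number of items", ylab = "mean posterior SD",
                 ylim = ylim, ...)
  if (!is.null(other)) {
    graphics::lines(other$m, other$mean_post_sd, type = "b", pch = 1,
                    lty = 2)
    graphics::legend("topright", legend = c("curve 1", "curve 2"),
                     pch = c(16, 1), lty = c(1, 2), bty = "n")
  }
  invisible(x)
}
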