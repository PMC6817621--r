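# Independent oracles and small fixture builders used across the suite.

# Fine-grid Riemann-sum EAP oracle. Deliberately independent of the package's
# quadrature path: direct product-form likelihood, plain sums.
riemann_eap <- function(responses, alpha, beta, prior_mean = 0, prior_sd = 1,
                        lo = -6, hi = 6, n_points = 1211L) {
  grid <- seq(lo, hi, length.out = n_points)
  keep <- !is.na(responses)
  like <- vapply(grid, function(th) {
    p <- 1 / (1 + exp(-alpha[keep] * (th - beta[keep])))
    prod(ifelse(responses[keep] == 1, p, 1 - p))
  }, numeric(1))
  w <- like * stats::dnorm(grid, prior_mean, prior_sd)
  w <- w / sum(w)
  m1 <- sum(w * grid)
  list(theta_hat = m1, post_sd = sqrt(sum(w * grid^2) - m1^2))
}

# Brute-force product-score oracle: multiplies the smoothed rates directly
# (no log domain) and takes the log of the ratio at the end.
psm_product_oracle <- function(fit, tokens) {
  S1 <- fit$prior1
  S2 <- fit$prior2
  for (tok in tokens) {
    if (tok %in% fit$vocab) {
      S1 <- S1 * (fit$u[[tok]] + fit$a) / fit$len1
      S2 <- S2 * (fit$v[[tok]] + fit$a) / fit$len2
    }
  }
  log(S1 / S2)
}

tiny_bank <- function(alpha, beta, ids = sprintf("I%02d", seq_along(alpha))) {
  item_bank(data.frame(item_id = ids, alpha = alpha, beta = beta,
                       stringsAsFactors = FALSE))
}

# the worked two-document training corpus used by several PSM tests
psm_train_docs <- function() {
  list(tokenized_doc(c("nightmar", "flashback", "fear", "nightmar"), "d1", 1),
       tokenized_doc(c("happi", "calm", "fear", "sleep"), "d2", 2))
}

# random labeled corpora over a small vocabulary, for property-style tests
random_docs <- function(n_per_class, vocab, len = 6L) {
  lapply(seq_len(2L * n_per_class), function(i) {
    tokenized_doc(sample(vocab, len, replace = TRUE),
                  id = paste0("r", i),
                  label = if (i <= n_per_class) 1L else 2L)
  })
}
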