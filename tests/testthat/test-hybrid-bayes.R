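bank <- ncsr_bank()
reg_paper <- latent_regression(-0.41, 1.44, 3.57)

test_that("text prior maps scores to the regression-implied normal", {
  pr <- text_prior(reg_paper, y = 0)
  expect_equal(pr$mean, -0.41)
  expect_equal(pr$var, 3.57)

  pr2 <- text_prior(latent_regression(0.3, 0, 2.2), y = c(-5, 0, 5))
  expect_equal(pr2$mean, rep(0.3, 3))

  pr3 <- text_prior(latent_regression(0, 2, 1), y = 1)
  expect_equal(pr3$mean, 2)
  expect_equal(pr3$var, 1)
})

test_that("hybrid EAP reduces to its prior without responses", {
  est <- hybrid_eap(numeric(0), bank, reg_paper, y = 0.8)
  expect_equal(est$theta_hat, -0.41 + 1.44 * 0.8, tolerance = 1e-6)
  expect_equal(est$post_sd, sqrt(3.57), tolerance = 1e-4)
  expect_equal(est$prior_spec$b0, -0.41)
})

test_that("a standard-normal text prior reproduces approach-1 EAP exactly", {
  set.seed(8)
  X <- matrix(rbinom(5 * 21, 1, 0.5), 5, 21)
  null_reg <- latent_regression(0, 0, 1)
  a <- eap_estimate(X, bank)
  h <- hybrid_eap(X, bank, null_reg, y = rnorm(5))
  expect_identical(h$theta_hat, a$theta_hat)
  expect_identical(h$post_sd, a$post_sd)
})

test_that("a very diffuse text prior matches diffuse-prior EAP", {
  x <- rbinom(21, 1, 0.6)
  h <- hybrid_eap(x, bank, latent_regression(0, 0, 1e6), y = 3)
  d <- eap_estimate(x, bank, prior_mean = 0, prior_var = 1e6)
  expect_equal(h$theta_hat, d$theta_hat, tolerance = 1e-3)
  expect_equal(h$post_sd, d$post_sd, tolerance = 1e-3)
})

test_that("halving the prior variance tightens every pattern's posterior", {
  set.seed(13)
  pats <- rbind(matrix(rbinom(30 * 21, 1, 0.5), 30, 21),
                rep(0, 21), rep(1, 21))
  tight <- hybrid_eap(pats, bank, latent_regression(0, 0, 0.5),
                      y = rep(0, nrow(pats)))
  std <- eap_estimate(pats, bank)
  expect_true(all(tight$post_sd < std$post_sd))
})

test_that("the hybrid estimate is monotone non-decreasing in the text score", {
  x <- rbinom(21, 1, 0.4)
  ys <- seq(-3, 3, by = 0.5)
  ests <- vapply(ys, function(y) {
    hybrid_eap(x, bank, reg_paper, y)$theta_hat
  }, numeric(1))
  expect_true(all(diff(ests) >= 0))
  expect_gt(ests[length(ests)], ests[1])
})

test_that("the trait sampler agrees with quadrature at fixed coefficients", {
  spec <- cohort_spec(n = 8, seed = 3)
  coh <- gen_cohort(spec)
  X <- gen_item_responses(coh$theta, bank, seed = 4)
  truth <- c(b0 = -0.41, b1 = 1.44, sigma2 = 3.57)
  fit <- suppressWarnings(  # deliberately small cohort
    fit_latent_regression(X, bank, coh$y, n_iter = 6000,
                          burn_in = 1000, chains = 1, seed = 11,
                          fix_coefficients = truth))
  quad <- hybrid_eap(X, bank, as.list(truth), coh$y)
  tol <- pmax(3 * fit$theta$mcse, 1e-3)
  expect_true(all(abs(fit$theta$theta_hat - quad$theta_hat) < tol))
  # tuned Metropolis acceptance lands in the targeted band
  expect_true(all(fit$acceptance > 0.2 & fit$acceptance < 0.65))
})

test_that("MCMC runs are bit-reproducible given a seed", {
  spec <- cohort_spec(n = 25, seed = 9)
  coh <- gen_cohort(spec)
  X <- gen_item_responses(coh$theta, bank, seed = 10)
  f1 <- fit_latent_regression(X, bank, coh$y, n_iter = 400, burn_in = 100,
                              chains = 2, seed = 77)
  f2 <- fit_latent_regression(X, bank, coh$y, n_iter = 400, burn_in = 100,
                              chains = 2, seed = 77)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$theta, f2$theta)
  f3 <- fit_latent_regression(X, bank, coh$y, n_iter = 400, burn_in = 100,
                              chains = 2, seed = 78)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("a null text slope is recovered: CIs cover zero across replicates", {
  covered <- 0L
  for (rep in 1:20) {
    spec <- cohort_spec(n = 60, b1 = 0, seed = 100 + rep)
    coh <- gen_cohort(spec)
    X <- gen_item_responses(coh$theta, bank, seed = 200 + rep)
    fit <- fit_latent_regression(X, bank, coh$y, n_iter = 1200,
                                 burn_in = 300, chains = 1,
                                 seed = 300 + rep, store_theta = FALSE)
    ci <- fit$coef_ci[, "b1"]
    covered <- covered + (ci[1] <= 0 && 0 <= ci[2])
  }
  expect_gte(covered, 18L)
})

test_that("degenerate fitting inputs are rejected", {
  X <- matrix(rbinom(21, 1, 0.5), 1, 21)
  expect_error(fit_latent_regression(X, bank, y = 0.2), "fewer than 2")
  X2 <- rbind(X, X)
  expect_error(suppressWarnings(fit_latent_regression(X2, bank, y = c(0, NA))),
               "non-finite")
  expect_error(suppressWarnings(fit_latent_regression(X2, bank, y = c(0, Inf))),
               "non-finite")
  expect_error(suppressWarnings(
    fit_latent_regression(X2, bank, y = c(0, 1), n_iter = 100,
                          burn_in = 200)))
})
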