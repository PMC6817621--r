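bank <- ncsr_bank()

test_that("2PL item response function behaves as a logistic in theta", {
  expect_equal(irf_2pl(0.7, alpha = 2.1, beta = 0.7), 0.5)
  expect_equal(irf_2pl(-0.15, alpha = 1.86, beta = -0.55), 0.678,
               tolerance = 1e-3)
  expect_equal(irf_2pl(c(-3, 0, 3), alpha = 0, beta = 1), rep(0.5, 3))
  # strictly increasing in theta, decreasing in beta
  th <- seq(-4, 4, by = 0.5)
  expect_true(all(diff(irf_2pl(th, 1.3, -0.2)) > 0))
  expect_true(all(diff(irf_2pl(0.3, 1.3, th)) < 0))
  # Rasch is the alpha = 1 special case
  expect_equal(irf_2pl(th, 1, 0.4), plogis(th - 0.4))
})

test_that("response log-likelihood sums item terms and skips missings", {
  empty <- tiny_bank(numeric(0), numeric(0))
  expect_equal(response_loglik(0.3, numeric(0), empty), 0)

  one <- tiny_bank(1.2, 0.5)
  expect_equal(response_loglik(0.5, 1, one), log(0.5))
  expect_equal(response_loglik(0.5, NA, one), 0)

  # all-ones pattern prefers high theta
  ones <- rep(1, nrow(bank))
  expect_gt(response_loglik(2, ones, bank), response_loglik(-2, ones, bank))
  expect_error(response_loglik(0, c(1, 2), tiny_bank(c(1, 1), c(0, 0))),
               "non-binary")
})

test_that("item information peaks at the difficulty with value alpha^2/4", {
  expect_equal(item_information(-0.55, 1.86, -0.55), 1.86^2 / 4)
  expect_equal(item_information(-0.15, 1.86, -0.55), 0.756, tolerance = 1e-3)
  expect_equal(item_information(2.2, 0, 1), 0)
  th <- seq(-3, 3, by = 0.01)
  curve <- item_information(th, 1.4, 0.8)
  expect_equal(th[which.max(curve)], 0.8, tolerance = 0.011)
  # C6 carries the most information at the diagnostic cutoff
  info <- item_information(-0.15, bank$alpha, bank$beta)
  expect_identical(bank$item_id[which.max(info)], "C6")
})

test_that("test information is additive over items", {
  expect_equal(test_information(0.2, bank[0, ]), 0)
  expect_equal(test_information(0.2, bank[3, ]),
               item_information(0.2, bank$alpha[3], bank$beta[3]))
  expect_equal(test_information(-0.15, bank),
               sum(item_information(-0.15, bank$alpha, bank$beta)))
})

test_that("EAP reduces to the prior with no responses and is symmetric", {
  pri <- eap_estimate(numeric(0), bank)
  expect_equal(pri$theta_hat, 0, tolerance = 1e-8)
  expect_equal(pri$post_sd, 1, tolerance = 1e-6)

  one <- tiny_bank(1, 0)
  expect_equal(eap_estimate(1, one)$theta_hat,
               -eap_estimate(0, one)$theta_hat, tolerance = 1e-10)
})

test_that("EAP matches a 10x finer Riemann-sum oracle to 1e-4", {
  set.seed(314)
  for (rep in 1:6) {
    x <- rbinom(nrow(bank), 1, 0.5)
    est <- eap_estimate(x, bank)
    orc <- riemann_eap(x, bank$alpha, bank$beta)
    expect_equal(est$theta_hat, orc$theta_hat, tolerance = 1e-4)
    expect_equal(est$post_sd, orc$post_sd, tolerance = 1e-4)
  }
  # a sparse routed pattern (most items not administered)
  x <- rep(NA, nrow(bank)); x[c(12, 6)] <- c(1, 0)
  expect_equal(eap_estimate(x, bank)$theta_hat,
               riemann_eap(x, bank$alpha, bank$beta)$theta_hat,
               tolerance = 1e-4)
})

test_that("turning a negative response positive never decreases the EAP", {
  set.seed(21)
  x <- rbinom(nrow(bank), 1, 0.3)
  for (i in sample(which(x == 0))) {
    before <- eap_estimate(x, bank)$theta_hat
    x[i] <- 1
    expect_gte(eap_estimate(x, bank)$theta_hat, before)
  }
})

test_that("posterior SD shrinks on average as items accumulate", {
  set.seed(5)
  theta <- rnorm(40)
  X <- gen_item_responses(theta, bank, seed = 6)
  sds <- sapply(c(3, 9, 21), function(k) {
    mean(eap_estimate(X[, 1:k, drop = FALSE], bank[1:k, ])$post_sd)
  })
  expect_true(all(diff(sds) < 0))
})

test_that("an explicit grid missing prior mass is rejected", {
  expect_error(eap_estimate(rep(1, 21), bank, grid = seq(-1, 1, 0.1)),
               "99.999%")
  # and a grid that does cover the prior is accepted
  expect_silent(eap_estimate(rep(1, 21), bank, grid = seq(-8, 8, 0.05)))
})
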