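bank <- ncsr_bank()
published_order <- c("C6", "B5", "C4", "B3", "C5", "C2", "D5", "B2", "B4",
                     "D3", "D2", "F2", "C7", "D4", "D1", "C1", "B1", "C3",
                     "F1", "E1", "A2")

test_that("items rank by information at the cutoff in the published order", {
  plan <- rank_items(bank, cutoff_theta = -0.15)
  expect_identical(plan$ranked_items, published_order)
  expect_identical(plan$ranked_items[1], "C6")
  expect_true(all(diff(plan$information) <= 0))
  expect_setequal(plan$ranked_items, bank$item_id)
})

test_that("ties keep bank order and ranking is permutation-invariant", {
  twin <- tiny_bank(c(1.3, 1.3, 0.9), c(0.2, 0.2, 0.2),
                    ids = c("first", "second", "weak"))
  expect_identical(rank_items(twin, 0)$ranked_items,
                   c("first", "second", "weak"))
  expect_identical(rank_items(twin[3, ], 0)$ranked_items, "weak")

  set.seed(1)
  perm <- bank[sample(nrow(bank)), ]
  expect_identical(rank_items(item_bank(perm), -0.15)$ranked_items,
                   published_order)
})

test_that("SE curves fall with test length and a tighter prior helps everywhere", {
  spec <- cohort_spec(n = 60, seed = 42)
  coh <- gen_cohort(spec)
  X <- gen_item_responses(coh$theta, bank, seed = 43)
  plan <- rank_items(bank)

  co <- se_curve(X, bank, plan, prior_mode = "standard")
  expect_identical(nrow(co), nrow(bank))
  expect_gte(co$mean_post_sd[1], co$mean_post_sd[nrow(bank)])

  # posterior-SD measure: variance-0.5 prior centered like the standard one
  # is pointwise tighter (quadrature precision ordering)
  tight <- se_curve(X, bank, plan, prior_mode = "text",
                    reg = latent_regression(0, 0, 0.5), y = rep(0, 60),
                    se_measure = "posterior_sd")
  std_sd <- se_curve(X, bank, plan, prior_mode = "standard",
                     se_measure = "posterior_sd")
  expect_true(all(tight$mean_post_sd < std_sd$mean_post_sd))
})

test_that("the text prior lowers the SE curve with a shrinking gap", {
  spec <- cohort_spec(n = 200, seed = 7)
  coh <- gen_cohort(spec)
  X <- gen_item_responses(coh$theta, bank, seed = 8)
  plan <- rank_items(bank)
  reg <- latent_regression(spec$b0, spec$b1, spec$sigma2)

  with_ <- se_curve(X, bank, plan, prior_mode = "text", reg = reg, y = coh$y)
  without <- se_curve(X, bank, plan, prior_mode = "standard")
  expect_lt(with_$mean_post_sd[1], without$mean_post_sd[1])
  gap <- without$mean_post_sd - with_$mean_post_sd
  expect_gt(gap[1], gap[21])
  expect_true(all(gap > 0))
  # the informative prior buys a shorter test
  sv <- items_saved(with_, without)
  expect_gte(sv$saving, 1L)
  expect_lte(sv$m_star, 20L)
})

test_that("the crossing rule converts curve pairs into item savings", {
  mk <- function(v) {
    structure(data.frame(m = seq_along(v), mean_post_sd = v),
              class = c("se_curve", "data.frame"))
  }
  flat <- mk(seq(1.5, 0.7, length.out = 21))
  expect_identical(items_saved(flat, flat)$m_star, 21L)
  expect_identical(items_saved(flat, flat)$saving, 0L)

  # described crossing: reference 0.68 reached first at 17 items
  with_ <- mk(c(seq(1.4, 0.69, length.out = 16), 0.68, 0.67, 0.66, 0.655, 0.65))
  without <- mk(c(seq(1.6, 0.7, length.out = 20), 0.68))
  sv <- items_saved(with_, without)
  expect_identical(sv$m_star, 17L)
  expect_identical(sv$saving, 4L)

  # hand-evaluated rule: 1/m crosses 0.25 at m = 4
  expect_identical(items_saved(mk(1 / (1:8)),
                               mk(c(rep(1, 7), 0.25)))$m_star, 4L)

  # lowering the with-prior curve never delays the crossing
  lower <- mk(with_$mean_post_sd - 0.05)
  expect_lte(items_saved(lower, without)$m_star, sv$m_star)
})
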