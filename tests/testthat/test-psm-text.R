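test_that("preprocessing lowercases, strips digits/stop words and stems", {
  d <- preprocess("I have nightmares, nightmaring at 3am")
  expect_identical(sum(d$tokens == "nightmar"), 2L)
  expect_false(any(grepl("[0-9]", d$tokens)))
  expect_false(any(c("i", "at", "have") %in% d$tokens))

  expect_identical(preprocess("")$tokens, character(0))
  expect_identical(preprocess("The the THE", stoplist = "the")$tokens,
                   character(0))

  # contractions expand before stop filtering
  d2 <- preprocess("I'm terrified, isn't it awful?")
  expect_false(any(c("m", "isn", "t") %in% d2$tokens))
  expect_true("terrifi" %in% d2$tokens)
})

test_that("training counts keyword occurrences per class with multiplicity", {
  fit <- psm(psm_train_docs())
  expect_identical(unname(fit$u["nightmar"]), 2L)
  expect_identical(unname(fit$v["nightmar"]), 0L)
  expect_identical(unname(fit$u["fear"]), 1L)
  expect_identical(unname(fit$v["fear"]), 1L)
  expect_identical(fit$len1, 4L)
  expect_identical(fit$len2, 4L)
  expect_equal(c(fit$prior1, fit$prior2), c(0.5, 0.5))
  # structural invariants
  expect_identical(sum(fit$u), fit$len1)
  expect_identical(sum(fit$v), fit$len2)
})

test_that("identical corpora give symmetric counts; single class errors", {
  toks <- c("fear", "sleep", "fear")
  fit <- psm(list(tokenized_doc(toks, "a", 1), tokenized_doc(toks, "b", 2)))
  expect_identical(fit$u, fit$v)
  expect_identical(fit$len1, fit$len2)

  expect_error(psm(list(tokenized_doc("fear", "a", 1),
                        tokenized_doc("calm", "b", 1))),
               "both classes")
  expect_error(psm(list(tokenized_doc("fear", "a", 1))), "both classes")
})

test_that("log-ratio scoring matches the hand-evaluated product", {
  fit <- psm(psm_train_docs())
  sc <- predict(fit, tokenized_doc(c("nightmar", "fear"), "new"))
  # S1 = .5 * (2.5/4)(1.5/4), S2 = .5 * (0.5/4)(1.5/4) -> ratio 5
  expect_equal(sc$raw, log(5), tolerance = 1e-12)
  expect_identical(sc$predicted_class, 1L)

  # symmetric model: any doc scores 0 and ties go to class 2
  toks <- c("fear", "sleep")
  sym <- psm(list(tokenized_doc(toks, "a", 1), tokenized_doc(toks, "b", 2)))
  sc2 <- predict(sym, tokenized_doc(c("fear", "fear", "sleep"), "x"))
  expect_equal(sc2$raw, 0)
  expect_identical(sc2$predicted_class, 2L)

  # empty doc with equal priors: empty product
  expect_equal(predict(fit, tokenized_doc(character(0), "e"))$raw, 0)
  # out-of-vocabulary tokens are skipped
  expect_equal(predict(fit, tokenized_doc(c("zzz", "qqq"), "o"))$raw, 0)
})

test_that("log-domain score equals the brute-force product on small models", {
  set.seed(42)
  vocab <- letters[1:8]
  for (rep in 1:20) {
    docs <- random_docs(n_per_class = 3L, vocab = vocab, len = 5L)
    fit <- psm(docs, vocab = vocab, a = 0.5)
    doc <- tokenized_doc(sample(c(vocab, "oov"), sample(0:8, 1),
                                replace = TRUE), "t")
    expect_equal(predict(fit, doc)$raw, psm_product_oracle(fit, doc$tokens),
                 tolerance = 1e-10)
  }
})

test_that("appending one keyword shifts the score by exactly its weight", {
  set.seed(7)
  vocab <- letters[1:6]
  docs <- random_docs(4L, vocab, len = 6L)
  fit <- psm(docs, vocab = vocab)
  w <- coef(fit)
  base_doc <- tokenized_doc(c("a", "c"), "b0")
  base <- predict(fit, base_doc)$raw
  for (tok in vocab) {
    ext <- tokenized_doc(c(base_doc$tokens, tok), "b1")
    expect_equal(predict(fit, ext)$raw - base, unname(w[tok]),
                 tolerance = 1e-12)
  }
})

test_that("swapping class labels negates every score under equal priors", {
  set.seed(99)
  vocab <- letters[1:7]
  docs <- random_docs(4L, vocab, len = 5L)
  swapped <- lapply(docs, function(d) {
    tokenized_doc(d$tokens, d$id, ifelse(d$label == 1L, 2L, 1L))
  })
  f1 <- psm(docs, vocab = vocab, priors = c(0.5, 0.5))
  f2 <- psm(swapped, vocab = vocab, priors = c(0.5, 0.5))
  probe <- lapply(1:10, function(i) {
    tokenized_doc(sample(vocab, 6, replace = TRUE), paste0("p", i))
  })
  expect_equal(predict(f1, probe, type = "score"),
               -predict(f2, probe, type = "score"), tolerance = 1e-12)
})

test_that("standardization is an order-preserving affine map to mean 0, SD 1", {
  expect_equal(standardize_scores(c(1, 2, 3)), c(-1, 0, 1))
  x <- rnorm(50, mean = 3, sd = 7)
  z <- standardize_scores(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_identical(order(z), order(x))
  expect_equal(standardize_scores(z), z, tolerance = 1e-12)
  expect_error(standardize_scores(c(5, 5, 5)), "variance")
  expect_error(standardize_scores(3), "at least 2")
})

test_that("a PSM round-trips through its JSON persistence", {
  fit <- psm(psm_train_docs(), a = 0.5, b = 0.25)
  path <- withr::local_tempfile(fileext = ".json")
  write_psm(fit, path)
  back <- read_psm(path)
  probe <- tokenized_doc(c("nightmar", "fear", "calm"), "p")
  expect_equal(predict(back, probe)$raw, predict(fit, probe)$raw)
  expect_identical(back$u, fit$u)
  expect_identical(back$b, fit$b)
})
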