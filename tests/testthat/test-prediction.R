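test_that("cohort returns continuations only, as in the for- example", {
  lex <- formula_lexicon()
  co <- cohort(lex, "f o r")
  expect_setequal(co$orth, c("formula", "forbid", "forceps"))
  # a full word with no longer competitor has an empty cohort
  expect_identical(nrow(cohort(lex, "f o r b i d")), 0L)
  # empty prefix: the whole lexicon continues
  expect_identical(nrow(cohort(lex, character(0))), nrow(lex$entries))
})

test_that("cohort agrees with a brute-force linear scan", {
  set.seed(501)
  for (i in 1:60) {
    lex <- rand_lexicon(n = 20)
    pre <- sample(c("a", "b", "c", "d"), sample(0:3, 1), replace = TRUE)
    expect_setequal(cohort(lex, pre)$form, oracle_cohort(lex, pre))
  }
})

test_that("predict_next reproduces the hand-worked probabilities", {
  lex <- formula_lexicon()
  # all continuations of /formju/ end in /l/
  p <- predict_next(lex, "f o r m j u")
  expect_equal(unname(p$probs[["l"]]), 1.0)
  expect_equal(sum(p$probs), 1.0)
  expect_false(p$empty_cohort)

  # two continuations, frequencies 30 vs 10 -> 0.75 / 0.25
  lex2 <- lexicon(c("a b c", "a b d"), c(30, 10))
  p2 <- predict_next(lex2, "a b")
  expect_equal(unname(p2$probs[["c"]]), 0.75)
  expect_equal(unname(p2$probs[["d"]]), 0.25)

  # k equal-frequency continuations -> 1/k each
  lex3 <- lexicon(c("a b", "a c", "a d"), 5)
  p3 <- predict_next(lex3, "a")
  expect_equal(unname(p3$probs[c("b", "c", "d")]), rep(1 / 3, 3))
})

test_that("predict_next agrees with a brute-force oracle and normalizes", {
  set.seed(502)
  for (i in 1:80) {
    lex <- rand_lexicon(n = 18)
    pre <- sample(c("a", "b", "c", "d"), sample(0:3, 1), replace = TRUE)
    p <- predict_next(lex, pre)
    o <- oracle_predict(lex, pre)
    if (is.null(o)) {
      expect_true(p$empty_cohort)
      expect_equal(unname(p$probs), rep(1 / 4, 4))       # uniform fallback
      pz <- predict_next(lex, pre, fallback = "zero")
      expect_equal(unname(pz$probs), rep(0, 4))
    } else {
      expect_false(p$empty_cohort)
      expect_equal(p$probs, o)
      expect_equal(sum(p$probs), 1, tolerance = 1e-9)
    }
  }
})

test_that("log1p frequency weighting is exposed and differs when it should", {
  lex <- lexicon(c("a b", "a c"), c(100, 1))
  raw <- predict_next(lex, "a")$probs
  lg <- predict_next(lex, "a", freq_transform = "log1p")$probs
  expect_equal(unname(raw[["b"]]), 100 / 101)
  expect_equal(unname(lg[["b"]]), log1p(100) / (log1p(100) + log1p(1)))
})

test_that("prediction_error reproduces the worked example and its identity", {
  lex <- formula_lexicon()
  p <- predict_next(lex, "f o r m j u")   # probs[l] = 1
  expect_identical(prediction_error(p, "b"), 2)
  expect_identical(prediction_error(p, "l"), 0)

  # normalized prediction with probs[observed] = 0.25 -> error 1.5
  lex2 <- lexicon(c("a b", "a c"), c(1, 3))
  p2 <- predict_next(lex2, "a")
  expect_equal(prediction_error(p2, "b"), 1.5)

  # identity 2*(1 - probs[observed]) against direct summation
  set.seed(503)
  for (i in 1:200) {
    k <- sample(3:10, 1)
    probs <- stats::setNames(stats::rexp(k), paste0("q", seq_len(k)))
    probs <- probs / sum(probs)
    obs <- sample(names(probs), 1)
    direct <- sum(abs(probs - as.numeric(names(probs) == obs)))
    expect_equal(prediction_error(probs, obs), direct)
    expect_equal(direct, 2 * (1 - probs[[obs]]))
    expect_gte(direct, 0); expect_lte(direct, 2)
  }
})

test_that("error_trajectory matches brute-force recomputation", {
  lex <- lexicon("a b c")     # single-word lexicon
  et <- error_trajectory(lex, "a b c")
  expect_equal(et$error[2:3], c(0, 0))

  set.seed(504)
  for (i in 1:30) {
    lex <- rand_lexicon(n = 15)
    item <- strsplit(sample(lex$entries$form, 1), " ")[[1]]
    et <- error_trajectory(lex, item)
    for (pos in seq_along(item)) {
      o <- oracle_predict(lex, item[seq_len(pos - 1)])
      if (is.null(o)) {
        expect_true(et$empty_cohort[pos])
        expect_equal(et$error[pos],
                     sum(abs(rep(1 / 4, 4) - as.numeric(c("a", "b", "c", "d") == item[pos]))))
      } else {
        expect_equal(et$error[pos], 2 * (1 - o[[item[pos]]]))
      }
    }
    expect_true(all(et$error >= 0 & et$error <= 2))
  }
})

test_that("a divergent phoneme with no cohort support scores the full error 2", {
  lex <- formula_lexicon()
  et <- error_trajectory(lex, "f o r m j u t i")  # baseline nonword
  expect_equal(et$error[7], 2)                    # /t/ after formu- unsupported
  expect_false(et$empty_cohort[7])                # cohort exists, support is 0
})

test_that("training shifts errors in the expected directions around the DP", {
  lex <- formula_lexicon()
  tri <- formula_triples()
  post <- train_lexicon(lex, tri, "A")
  dp <- tri$dp[1]
  novel <- tri$nonword_a[1]; base <- tri$nonword_b[1]; src <- tri$source[1]
  pre_nov <- error_trajectory(lex, novel);  post_nov <- error_trajectory(post, novel)
  pre_base <- error_trajectory(lex, base);  post_base <- error_trajectory(post, base)
  pre_src <- error_trajectory(lex, src);    post_src <- error_trajectory(post, src)
  # novel item's divergent phoneme becomes predictable; baseline's does not
  expect_lt(post_nov$error[dp + 1], pre_nov$error[dp + 1])
  expect_gte(post_base$error[dp + 1], pre_base$error[dp + 1])
  # pre-DP: the added entry supports every shared phoneme, so error can only drop
  expect_true(all(post_src$error[1:dp] <= pre_src$error[1:dp] + 1e-12))
})

test_that("raising a cohort member's frequency shifts probability monotonically", {
  set.seed(505)
  for (i in 1:30) {
    lex <- rand_lexicon(n = 12)
    pre <- character(0)
    co <- cohort(lex, pre)
    j <- sample(nrow(co), 1)
    target_form <- co$form[j]
    target_next <- strsplit(target_form, " ")[[1]][1]
    bumped <- lexicon(lex$entries$form,
                      ifelse(lex$entries$form == target_form,
                             lex$entries$frequency * 3, lex$entries$frequency),
                      inventory = lex$inventory)
    p0 <- predict_next(lex, pre)$probs
    p1 <- predict_next(bumped, pre)$probs
    expect_gte(p1[[target_next]], p0[[target_next]] - 1e-12)
    others <- setdiff(names(p0), target_next)
    expect_true(all(p1[others] <= p0[others] + 1e-12))
  }
})
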