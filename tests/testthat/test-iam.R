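test_that("iam_params validates its invariants", {
  expect_s3_class(iam_params(), "iam_params")
  expect_error(iam_params(act_min = 0))           # act_min < rest
  expect_error(iam_params(decay_word = 1.5))
  expect_error(iam_params(feedback_word_phoneme = -0.1))
})

test_that("build_network allocates the expected units and constituency", {
  par <- iam_params(slices_per_phoneme = 4L)
  lex <- lexicon("a b", inventory = phoneme_inventory(c("a", "b")))
  net <- build_network(lex, par, n_slices = 16L)  # 4 slices/phoneme, 4 phonemes of room
  # word extent 8 slices -> alignments 1..9
  expect_identical(nrow(net$words), 9L)
  expect_identical(net$words$start, 1:9)
  # unit count scales linearly with lexicon size
  lex2 <- lexicon(c("a b", "b a"), inventory = phoneme_inventory(c("a", "b")))
  expect_identical(nrow(build_network(lex2, par, 16L)$words), 18L)
  # constituency agrees with an independent scan over forms and alignments
  Cd <- as.matrix(net$C)
  for (j in seq_len(nrow(net$words))) {
    s <- net$words$start[j]
    expected <- rep(0, 2 * 16)
    expected[match("a", c("a", "b")) + (s - 1) * 2] <- 1
    expected[match("b", c("a", "b")) + (s + 4 - 1) * 2] <- 1
    expect_equal(unname(Cd[j, ]), expected)
  }
})

test_that("encode_input builds gated triangular ramps", {
  inv <- phoneme_inventory(c("a", "b", "c"))
  par0 <- iam_params(slices_per_phoneme = 3L, input_spread = 0L)
  e <- encode_input("a", par0, 6L, inv)
  expect_equal(e$D[1, ], c(1, 0, 0, 0, 0, 0))
  expect_true(all(e$D[2:3, ] == 0))

  par <- iam_params(slices_per_phoneme = 3L, input_spread = 2L)
  e2 <- encode_input(c("a", "b", "c"), par, 12L, inv)
  e3 <- encode_input(c("a", "b", "b"), par, 12L, inv)
  # identical drive over slices reached only by the shared two-phoneme prefix
  # (the third phoneme's ramp begins at slice 7 - 2 = 5)
  expect_equal(e2$D[, 1:4], e3$D[, 1:4])
  # interior phonemes carry equal total drive mass (edge ramps are truncated)
  expect_equal(sum(e2$D[2, ]), sum(e2$D[3, ]))
  expect_true(all(e2$D >= 0 & e2$D <= 1))
})

test_that("the resting state is a fixed point under zero drive", {
  lex <- lexicon(c("a b c", "b c a"), c(3, 1))
  par <- fast_params()
  net <- build_network(lex, par, 24L)
  state <- list(p = matrix(par$rest_phoneme, net$n_phon, net$n_slices),
                w = rep(par$rest_word, nrow(net$words)), cycle = 0L)
  nxt <- iam_step(state, matrix(0, net$n_phon, net$n_slices), net)
  expect_equal(nxt$p, state$p)
  expect_equal(nxt$w, state$w)
  expect_identical(nxt$total_feedback, 0)
})

test_that("a hand-computed two-unit step matches the closed-form update", {
  # one word "a", one slice per phoneme, one-slice trace: a single word unit
  # over a single phoneme unit
  par <- iam_params(slices_per_phoneme = 1L, input_spread = 0L, n_cycles = 5L)
  lex <- lexicon("a", inventory = phoneme_inventory("a"))
  net <- build_network(lex, par, 1L)
  expect_identical(nrow(net$words), 1L)
  a_p <- 0.2; a_w <- 0.5; drive <- matrix(0.8, 1, 1)
  state <- list(p = matrix(a_p, 1, 1), w = a_w, cycle = 0L)
  nxt <- iam_step(state, drive, net)
  # phoneme: net = 0.1*0.8 + 0.03*0.5 (no other phoneme units to inhibit)
  net_p <- par$excite_input_phoneme * 0.8 + par$feedback_word_phoneme * a_w
  exp_p <- a_p + net_p * (par$act_max - a_p) -
    par$decay_phoneme * (a_p - par$rest_phoneme)
  # word: net = 0.05*0.2 (no competing word units)
  net_w <- par$excite_phoneme_word * a_p
  exp_w <- a_w + net_w * (par$act_max - a_w) -
    par$decay_word * (a_w - par$rest_word)
  expect_equal(nxt$p[1, 1], exp_p)
  expect_equal(nxt$w, exp_w)
  expect_equal(nxt$total_feedback, par$feedback_word_phoneme * a_w * 1)
})

test_that("iam_step matches a naive dense oracle on random states", {
  set.seed(601)
  lex <- rand_lexicon(n = 6, inv = c("a", "b", "c"), min_len = 2, max_len = 4)
  par <- iam_params(slices_per_phoneme = 3L, input_spread = 2L)
  net <- build_network(lex, par, 15L)
  for (i in 1:25) {
    state <- list(
      p = matrix(stats::runif(net$n_phon * net$n_slices, par$act_min,
                              par$act_max), net$n_phon, net$n_slices),
      w = stats::runif(nrow(net$words), par$act_min, par$act_max), cycle = 0L)
    drive <- matrix(stats::runif(net$n_phon * net$n_slices), net$n_phon,
                    net$n_slices)
    got <- iam_step(state, drive, net)
    want <- oracle_iam_step(state, drive, net)
    expect_equal(got$p, want$p, tolerance = 1e-12)
    expect_equal(got$w, want$w, tolerance = 1e-12)
  }
})

test_that("run_iam is deterministic, internally consistent and bounded", {
  lex <- rand_lexicon(n = 8, inv = c("a", "b", "c"), min_len = 2, max_len = 4)
  par <- fast_params()
  item <- strsplit(lex$entries$form[which.max(lex$entries$len)], " ")[[1]]
  t1 <- run_iam(item, lex, par)
  t2 <- run_iam(item, lex, par)
  expect_identical(t1$totals, t2$totals)
  expect_identical(t1$phoneme_act, t2$phoneme_act)
  for (cyc in c(1L, 10L, par$n_cycles)) {
    expect_equal(t1$totals$total_phoneme_act[cyc], sum(t1$phoneme_act[, , cyc]))
    expect_equal(t1$totals$total_word_act[cyc], sum(t1$word_act[, cyc]))
  }
  expect_true(all(t1$totals$total_feedback >= 0))
  expect_true(all(t1$phoneme_act >= par$act_min & t1$phoneme_act <= par$act_max))
  expect_true(all(t1$word_act >= par$act_min & t1$word_act <= par$act_max))
})

test_that("feedback ablation zeroes the flow and any anticipation", {
  lex <- formula_lexicon()
  par0 <- fast_params(feedback_word_phoneme = 0)
  tr <- run_iam("f o r m j u l ^", lex, par0)
  expect_true(all(tr$totals$total_feedback == 0))
  # before the divergent input arrives, the post-DP phoneme unit cannot rise
  onset <- dp_onset_cycle(6L, par0)
  tc <- phoneme_timecourse(tr, "l", 7L)
  expect_true(all(tc[seq_len(onset - 1L)] <= par0$rest_phoneme + 1e-12))
})

test_that("a matching word rises from rest and settles", {
  lex <- lexicon("a b c d", inventory = phoneme_inventory(c("a", "b", "c", "d")))
  par <- iam_params(n_cycles = 100L)
  tr <- run_iam("a b c d", lex, par)
  best <- max(tr$word_act[, 100])
  expect_gt(best, par$rest_word)
  j <- which.max(tr$word_act[, 100])
  traj <- tr$word_act[j, ]
  expect_gt(traj[60], traj[20])                       # burn-in rise
  expect_lt(abs(traj[100] - traj[90]), 0.02)          # approaches a plateau
})

test_that("phoneme_timecourse reads the input-aligned unit and validates", {
  lex <- formula_lexicon()
  tr <- run_iam("p a r t l i", lex, fast_params())
  tc <- phoneme_timecourse(tr, "l", 5L)
  expect_length(tc, 30L)
  expect_gt(max(tc), tr$params$rest_phoneme)          # presented phoneme rises
  expect_error(phoneme_timecourse(tr, "l", 9L), "outside")
  expect_error(phoneme_timecourse(tr, "zz", 5L), "no unit")
})
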