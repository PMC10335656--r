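test_that("task configuration enforces 1 <= m < n and o >= 1", {
  expect_error(task_config(4, 4), "n_human")
  expect_error(task_config(4, 0), "n_human")
  expect_error(task_config(4, 2, 0), "episode_length")
  cfg <- task_config(10, 2)  # imbalanced case is supported
  expect_equal(cfg$n_subtasks, 10)
})

test_that("human assignments are uniform over m-subsets", {
  cfg <- task_config(4, 2)
  set.seed(91)
  draws <- replicate(6000, paste(sample_assignment(cfg)$human_set, collapse = "-"))
  counts <- table(draws)
  expect_length(counts, 6)  # all C(4,2) subsets occur
  # each subset ~1000 draws; chi-square against uniform
  chisq <- sum((counts - 1000)^2 / 1000)
  expect_lt(chisq, stats::qchisq(0.999, df = 5))
  # n = 2, m = 1: each subtask roughly half the time
  cfg2 <- task_config(2, 1)
  set.seed(92)
  picks <- replicate(2000, sample_assignment(cfg2)$human_set)
  expect_equal(mean(picks == 1), 0.5, tolerance = 0.05)
})

test_that("episodes are i.i.d. uniform draws with replacement", {
  cfg <- task_config(4, 2, episode_length = 10)
  set.seed(93)
  ep <- sample_episode(cfg)
  expect_length(ep, 10)
  expect_true(all(ep %in% 1:4))
  freq <- table(factor(unlist(replicate(3000, sample_episode(cfg))), 1:4))
  expect_equal(as.vector(freq) / 30000, rep(0.25, 4), tolerance = 0.02)
  expect_equal(sample_episode(task_config(2, 1, 5)) %in% 1:2, rep(TRUE, 5))
})

test_that("the true actor is determined by set membership", {
  cfg <- task_config(5, 2)
  set.seed(94)
  asg <- sample_assignment(cfg)
  ep <- sample_episode(cfg)
  actors <- true_actor(ep, asg)
  for (k in seq_along(ep)) {
    expect_equal(actors[k], if (ep[k] %in% asg$human_set) "H" else "R")
  }
  expect_error(true_actor(6, asg), "unknown subtask")
  expect_error(true_actor(0, asg), "unknown subtask")
})

test_that("degenerate decoder rates are deterministic", {
  perfect <- uniform_decoder_rates(100)
  broken <- uniform_decoder_rates(0)
  set.seed(95)
  for (ctx in list(c("H", "H"), c("H", "R"), c("R", "R"), c("R", "H"))) {
    expect_equal(simulate_decoded_anticipation(ctx[1], ctx[2], perfect), ctx[2])
    expect_equal(simulate_decoded_anticipation(ctx[1], ctx[2], broken),
                 setdiff(c("H", "R"), ctx[2]))
  }
  expect_error(decoder_rates(101, 50, 50, 50), "\\[0, 100\\]")
})

test_that("decoded-anticipation correctness converges to the context rate", {
  rates <- empirical_decoder_rates()
  set.seed(96)
  # the human-takeover context at its empirical rate, high precision
  hits <- replicate(1e5, simulate_decoded_anticipation("R", "H", rates) == "H")
  expect_equal(mean(hits), 0.561, tolerance = 0.005)
  # all four contexts at 3 standard errors, lighter sampling
  ctxs <- list(c("H", "H", rates$tnr_hh), c("H", "R", rates$tpr_hr),
               c("R", "R", rates$tnr_rr), c("R", "H", rates$tpr_rh))
  for (ctx in ctxs) {
    p <- as.numeric(ctx[3]) / 100
    ok <- replicate(1e4, simulate_decoded_anticipation(ctx[1], ctx[2], rates) == ctx[2])
    expect_lt(abs(mean(ok) - p), 3 * sqrt(p * (1 - p) / 1e4))
  }
})

test_that("minimum-jerk profile satisfies its boundary conditions", {
  tf <- 0.8
  expect_equal(minimum_jerk_profile(0, tf), 0)
  expect_equal(minimum_jerk_profile(tf, tf), 1)
  expect_equal(minimum_jerk_profile(tf / 2, tf), 0.5)
  # zero velocity and acceleration at both endpoints by finite differences
  h <- 1e-5
  s <- function(t) minimum_jerk_profile(t, tf)
  expect_lt(abs((s(h) - s(0)) / h), 1e-5)
  expect_lt(abs((s(tf) - s(tf - h)) / h), 1e-5)
  expect_lt(abs((s(2 * h) - 2 * s(h) + s(0)) / h^2), 1e-2)
  expect_lt(abs((s(tf) - 2 * s(tf - h) + s(tf - 2 * h)) / h^2), 1e-2)
  # monotone within the movement, rejected outside it
  expect_true(all(diff(s(seq(0, tf, length.out = 50))) > 0))
  expect_error(minimum_jerk_profile(-0.1, tf), "within")
  expect_error(minimum_jerk_profile(1, tf), "within")
})
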