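test_that("repetition traces have full length and start at indifference", {
  spec <- sim_spec(n_episodes = 12, n_repetitions = 1, seed = 111)
  set.seed(111)
  trace <- run_repetition(spec)
  expect_length(trace, 12 * 10)
  # first trial: no predecessor, no update, fresh uniform policy
  expect_equal(trace[1], 0.5)
  expect_true(all(trace >= 0 & trace <= 1))
})

test_that("simulations are reproducible from the master seed", {
  spec <- sim_spec(n_episodes = 10, n_repetitions = 3, seed = 112)
  c1 <- run_sim(spec)
  c2 <- run_sim(spec)
  expect_identical(c1$traces, c2$traces)
  c3 <- run_sim(sim_spec(n_episodes = 10, n_repetitions = 3, seed = 113))
  expect_false(identical(c1$traces, c3$traces))
})

test_that("the mean curve lies within the envelope of repetition traces", {
  curve <- run_sim(sim_spec(n_episodes = 15, n_repetitions = 8, seed = 114))
  lo <- apply(curve$traces, 1, min)
  hi <- apply(curve$traces, 1, max)
  expect_true(all(curve$mean_trial >= lo & curve$mean_trial <= hi))
  expect_length(curve$mean_episode, 15)
  expect_equal(curve$mean_episode[1], mean(curve$mean_trial[1:10]))
})

test_that("doubling repetitions shrinks the mean-curve SE by about sqrt(2)", {
  se_of <- function(reps, seed) {
    curve <- run_sim(sim_spec(n_episodes = 20, n_repetitions = reps, seed = seed))
    mean(apply(curve$traces, 1, stats::sd)) / sqrt(reps)
  }
  ratio <- se_of(40, 115) / se_of(80, 116)
  expect_gt(ratio, 1.2)
  expect_lt(ratio, 1.7)
})

test_that("reassignment is periodic and scored against the current choice", {
  expect_error(sim_spec(n_episodes = 40, reassignment_every = 40),
               "reassignment_every")
  with_re <- run_sim(sim_spec(n_episodes = 50, n_repetitions = 5,
                              reassignment_every = 10, seed = 117))
  without <- run_sim(sim_spec(n_episodes = 50, n_repetitions = 5, seed = 117))
  # identical seeding until the first boundary, divergence afterwards
  expect_equal(with_re$traces[1:100, ], without$traces[1:100, ])
  expect_false(identical(with_re$traces[101:500, ], without$traces[101:500, ]))
})

test_that("episodes-to-threshold finds the first crossing of the mean curve", {
  curve <- run_sim(sim_spec(rates = uniform_decoder_rates(100),
                            n_episodes = 30, n_repetitions = 3, seed = 118))
  ep70 <- episodes_to_threshold(curve, 0.7)
  expect_true(is.finite(ep70))
  expect_gte(curve$mean_episode[ep70], 0.7)
  if (ep70 > 1) expect_true(all(curve$mean_episode[seq_len(ep70 - 1)] < 0.7))
  expect_true(is.na(episodes_to_threshold(curve, 1.1)))
})

test_that("results round-trip through CSV with a reproducible spec snapshot", {
  curve <- run_sim(sim_spec(n_episodes = 8, n_repetitions = 2, seed = 119))
  path <- withr::local_tempfile(fileext = ".csv")
  paths <- write_results(curve, path)
  df <- read_results(path)
  expect_equal(nrow(df), 80)
  expect_named(df, c("trial", "episode", "mean_accuracy", "sd_accuracy"))
  expect_equal(df$mean_accuracy, curve$mean_trial, tolerance = 1e-12)
  snap <- jsonlite::read_json(paths[["json"]])
  expect_equal(snap$seed, 119)
  expect_equal(snap$task$n_subtasks, 4)
  expect_equal(snap$rates$tnr_rr, 57.9)
})

test_that("the scalability suite reports per-variant learning summaries", {
  suite <- run_scalability_suite(rates = uniform_decoder_rates(90),
                                 n_episodes = 15, n_repetitions = 2, seed = 120)
  expect_named(suite$curves, c("n4_m2", "n6_m3", "n10_m5", "n10_m2"))
  expect_named(suite$summary,
               c("variant", "n_subtasks", "n_human", "episodes_to_70",
                 "final_accuracy"))
  expect_equal(suite$summary$n_subtasks, c(4, 6, 10, 10))
  expect_true(all(suite$summary$final_accuracy >= 0 &
                    suite$summary$final_accuracy <= 1))
})
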