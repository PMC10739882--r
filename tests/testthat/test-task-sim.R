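test_that("staircase updates apply condition deltas and clamp to bounds", {
  cfg <- task_config()
  expect_equal(staircase_update("easy", 100, "win", cfg), 97)
  expect_equal(staircase_update("easy", 100, "loss", cfg), 112)
  expect_equal(staircase_update("hard", 100, "win", cfg), 88)
  expect_equal(staircase_update("hard", 20, "win", cfg), 15)   # floor clamp
  expect_equal(staircase_update("easy", 195, "loss", cfg), 200) # ceiling clamp
  # no feedback, no update
  expect_equal(staircase_update("easy", 100, "neutral", cfg), 100)
  expect_equal(staircase_update("hard", 100, "missing", cfg), 100)
  expect_error(staircase_update("medium", 100, "win", cfg), "condition")
  expect_error(staircase_update("easy", 100, "draw", cfg), "outcome")
})

test_that("agent trials follow the exact outcome rule", {
  # near-zero noise: every non-neutral trial wins at any tolerance >= floor
  ag <- agent_config(timing_bias = 0, timing_sd = 1e-9)
  set.seed(1)
  outs <- replicate(50, simulate_agent_trial(ag, 15, 0)$outcome)
  expect_true(all(outs == "win"))
  # fixed tolerance 15 ms, sd 60 ms: win rate ~ 2*pnorm(0.25) - 1
  ag <- agent_config(timing_sd = 0.06)
  set.seed(2)
  wins <- mean(replicate(4000, simulate_agent_trial(ag, 15, 0)$outcome) == "win")
  expect_equal(wins, 2 * pnorm(0.25) - 1, tolerance = 0.12)
  # neutral outcomes at the configured rate, independent of error
  set.seed(3)
  outs <- replicate(5000, simulate_agent_trial(ag, 100, 0.12)$outcome)
  expect_equal(mean(outs == "neutral"), 0.12, tolerance = 0.15)
  # lapses give missing outcomes with NA reward
  ag_l <- agent_config(timing_sd = 0.06, lapse_rate = 1 - 1e-12)
  tr <- simulate_agent_trial(ag_l, 100, 0)
  expect_identical(tr$outcome, "missing")
  expect_true(is.na(tr$rt) && is.na(tr$reward))
})

test_that("sessions are reproducible and respect block structure", {
  cfg <- task_config()
  ag <- agent_config(timing_sd = 0.08)
  a <- run_session(cfg, ag, seed = 7)
  b <- run_session(cfg, ag, seed = 7)
  expect_identical(a, b)
  expect_equal(nrow(a), 300)
  expect_equal(unique(a$condition[a$block_index == 1]), "easy")
  expect_equal(unique(a$condition[a$block_index == 3]), "hard")
  # win/loss labeling is exactly the tolerance indicator on every trial
  wl <- a$outcome %in% c("win", "loss")
  expect_identical(a$outcome[wl] == "win",
                   abs(a$error_s[wl]) * 1000 <= a$tolerance_ms[wl])
  expect_equal(a$reward[wl], ifelse(a$outcome[wl] == "win", 1, -1))
})

test_that("tolerance never leaves the configured bounds", {
  cfg <- task_config(trials_per_block = 400,
                     block_order = rep(c("easy", "hard"), 4),
                     tolerance_bounds = c(15, 200))
  tr <- run_session(cfg, agent_config(timing_sd = 0.05), seed = 3)
  expect_true(all(tr$tolerance_ms >= 15 & tr$tolerance_ms <= 200))
})

test_that("staircase clamps accuracy near up/(up + down) with interior tolerance", {
  # timing sd chosen so both equilibria sit inside the 15-400 ms bounds
  cfg <- task_config(trials_per_block = 1500, block_order = c("easy", "hard"),
                     tolerance_bounds = c(15, 400),
                     initial_tolerance = c(easy = 190, hard = 40))
  tr <- run_session(cfg, agent_config(timing_sd = 0.15), seed = 5)
  expect_equal(mean(tr$outcome[tr$condition == "easy"] == "win"), 0.8,
               tolerance = 0.03)
  expect_equal(mean(tr$outcome[tr$condition == "hard"] == "win"), 0.2,
               tolerance = 0.12)
})

test_that("behavioral rejection removes missing, out-of-range and outlier RTs", {
  mk <- function(rts) data.frame(trial_index = seq_along(rts), block_index = 1,
                                 condition = "easy", tolerance_ms = 100,
                                 rt_s = rts, error_s = rts - 1,
                                 outcome = ifelse(is.na(rts), "missing", "win"),
                                 reward = 1, score_delta = 100)
  out <- reject_trials(mk(c(1.0, 1.1, 0.4)))
  expect_equal(out$rt_s, c(1.0, 1.1))
  # in-range, within 3 SD: identity
  set.seed(4)
  rts <- rnorm(100, 1, 0.05)
  expect_identical(reject_trials(mk(rts)), mk(rts))
  # a 1.45 s RT inside the hard bounds but > 3 SD from the mean is removed
  rts2 <- c(rts, 1.45)
  stopifnot(abs(1.45 - mean(rts2)) > 3 * sd(rts2))  # constructed to hold
  out2 <- reject_trials(mk(rts2))
  expect_equal(nrow(out2), 100)
  expect_false(1.45 %in% out2$rt_s)
  # missing removed; empty input passes through
  expect_equal(nrow(reject_trials(mk(c(1, NA, 1.1)))), 2)
  expect_equal(nrow(reject_trials(mk(1.0)[0, ])), 0)
})

test_that("rt_change_table drops block-initial and post-gap transitions", {
  tr <- data.frame(trial_index = 1:6, block_index = c(1, 1, 1, 2, 2, 2),
                   rt_s = c(1.2, 0.9, 1.0, 1.1, 1.05, 0.95),
                   outcome = "win")
  rc <- rt_change_table(tr)
  expect_equal(nrow(rc), 4)  # 6 trials - 2 block-initial
  expect_equal(rc$rt_change[1], -0.3)
  expect_equal(rc$prev_rt[1], 1.2)
  expect_false(any(rc$prev_trial_index == 3 & rc$trial_index == 4))
  # removing trial 2 (e.g. missing) breaks the chain into trial 3
  tr2 <- tr[-2, ]
  rc2 <- rt_change_table(tr2)
  expect_false(3 %in% rc2$trial_index)
  # row count identity: cleaned - blocks - trials following gaps
  cfg <- task_config(neutral_rate = 0.1)
  ses <- run_session(cfg, agent_config(timing_sd = 0.1, lapse_rate = 0.05),
                     seed = 11)
  cl <- reject_trials(ses)
  rc3 <- rt_change_table(cl)
  has_prev <- (cl$trial_index - 1) %in% cl$trial_index &
    cl$block_index == cl$block_index[match(cl$trial_index - 1, cl$trial_index)]
  has_prev[is.na(has_prev)] <- FALSE
  expect_equal(nrow(rc3), sum(has_prev))
  # fewer than 2 trials: no rows
  expect_equal(nrow(rt_change_table(tr[1, ])), 0)
})

test_that("trial tables round-trip through TSV", {
  tr <- quick_session(seed = 2)
  path <- tempfile(fileext = ".tsv")
  write_trials(tr, path)
  back <- read_trials(path)
  expect_equal(back$trial_index, tr$trial_index)
  expect_equal(back$tolerance_ms, tr$tolerance_ms)
  expect_equal(back$rt_s, tr$rt_s, tolerance = 1e-12)
  unlink(path)
})
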