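#' Task configuration for the interval-timing staircase task
#'
#' Defines the blocked easy/hard interval-timing task: participants (or
#' simulated agents) try to respond exactly at a fixed target interval, and an
#' error tolerance around the target determines win/loss feedback. Tolerance is
#' adapted by two independent asymmetric staircases, one per difficulty
#' condition, which clamp accuracy near `up / (up + down)` for each condition
#' (0.8 in easy blocks, 0.2 in hard blocks with the default step sizes).
#'
#' @param trials_per_block Trials per block (default 75).
#' @param block_order Character vector over `"easy"`/`"hard"` giving the block
#'   sequence, e.g. `c("easy","easy","hard","hard")`.
#' @param target_interval Target interval in seconds (default 1).
#' @param step_easy,step_hard Named numeric `c(win =, loss =)` tolerance deltas
#'   in milliseconds applied after wins/losses. Defaults: easy `-3/+12`,
#'   hard `-12/+3`.
#' @param tolerance_bounds `c(floor, ceiling)` tolerance bounds in ms
#'   (default `c(15, 200)`; some task versions used a 400 ms ceiling).
#' @param neutral_rate Probability of a neutral outcome replacing feedback on a
#'   random trial (0 or 0.12 depending on task version).
#' @param initial_tolerance Named numeric `c(easy =, hard =)` starting
#'   tolerances in ms, standing in for the training block that initialized the
#'   staircases to individual performance.
#'
#' @return A list of class `task_config`.
#' @export
task_config <- function(trials_per_block = 75,
                        block_order = c("easy", "easy", "hard", "hard"),
                        target_interval = 1,
                        step_easy = c(win = -3, loss = 12),
                        step_hard = c(win = -12, loss = 3),
                        tolerance_bounds = c(15, 200),
                        neutral_rate = 0,
                        initial_tolerance = c(easy = 100, hard = 30)) {
  stopifnot(trials_per_block > 0,
            all(block_order %in% c("easy", "hard")),
            tolerance_bounds[1] < tolerance_bounds[2],
            neutral_rate >= 0, neutral_rate < 1)
  # easy shrinks on win by less than it grows on loss; hard the reverse
  stopifnot(step_easy["win"] < 0, step_easy["loss"] > 0,
            step_hard["win"] < 0, step_hard["loss"] > 0,
            abs(step_easy["win"]) < abs(step_easy["loss"]),
            abs(step_hard["win"]) > abs(step_hard["loss"]))
  structure(list(trials_per_block = trials_per_block,
                 block_order = block_order,
                 target_interval = target_interval,
                 step = list(easy = step_easy, hard = step_hard),
                 tolerance_bounds = tolerance_bounds,
                 neutral_rate = neutral_rate,
                 initial_tolerance = initial_tolerance),
            class = "task_config")
}

#' Stationary ideal-observer agent
#'
#' A stationary observer whose response times are Gaussian around the target:
#' `rt = target + timing_bias + N(0, timing_sd)`. With probability
#' `lapse_rate` the response is omitted entirely.
#'
#' @param timing_bias Constant timing bias in seconds.
#' @param timing_sd Timing noise SD in seconds (> 0).
#' @param lapse_rate Probability of an omitted response.
#' @return A list of class `agent_config`.
#' @export
agent_config <- function(timing_bias = 0, timing_sd = 0.06, lapse_rate = 0) {
  stopifnot(timing_sd > 0, lapse_rate >= 0, lapse_rate < 1)
  structure(list(timing_bias = timing_bias, timing_sd = timing_sd,
                 lapse_rate = lapse_rate),
            class = "agent_config")
}

#' Asymmetric staircase update
#'
#' Applies the condition's tolerance delta after a win or loss and clamps to
#' the configured bounds. Neutral and missing outcomes leave the tolerance
#' unchanged (no performance feedback is delivered on those trials).
#'
#' @param condition `"easy"` or `"hard"`.
#' @param tolerance_ms Current tolerance in ms.
#' @param outcome One of `"win"`, `"loss"`, `"neutral"`, `"missing"`.
#' @param config A [task_config()].
#' @return Updated tolerance in ms.
#' @export
staircase_update <- function(condition, tolerance_ms, outcome, config) {
  if (!condition %in% c("easy", "hard"))
    stop_contract("unknown condition: ", condition)
  if (!outcome %in% c("win", "loss", "neutral", "missing"))
    stop_contract("unknown outcome: ", outcome)
  if (outcome %in% c("neutral", "missing")) return(tolerance_ms)
  delta <- unname(config$step[[condition]][[outcome]])
  clamp(tolerance_ms + delta,
        config$tolerance_bounds[1], config$tolerance_bounds[2])
}

#' Simulate one trial of a stationary agent
#'
#' Draws one response at the given tolerance, consuming the current RNG
#' stream. The outcome rule is exact: win iff the absolute timing error in ms
#' is within tolerance; neutral outcomes are assigned independently of the
#' response error; a lapse yields a missing outcome.
#'
#' @param agent An [agent_config()].
#' @param tolerance_ms Tolerance in effect (ms).
#' @param neutral_rate Probability of a neutral outcome.
#' @param target_interval Target interval (s).
#' @return List with `rt`, `error`, `outcome`, `reward`, `score_delta`.
#' @export
simulate_agent_trial <- function(agent, tolerance_ms, neutral_rate,
                                 target_interval = 1) {
  lapse <- runif(1) < agent$lapse_rate
  neutral <- runif(1) < neutral_rate
  rt_noise <- rnorm(1, 0, agent$timing_sd)
  if (lapse) {
    rt <- NA_real_
    error <- NA_real_
    outcome <- "missing"
  } else {
    rt <- target_interval + agent$timing_bias + rt_noise
    error <- rt - target_interval
    outcome <- if (neutral) "neutral"
      else if (abs(s_to_ms(error)) <= tolerance_ms) "win" else "loss"
  }
  reward <- switch(outcome, win = 1, loss = -1, neutral = 0, missing = NA_real_)
  score <- switch(outcome, win = 100, loss = -100, neutral = 0,
                  missing = NA_real_)
  list(rt = rt, error = error, outcome = outcome, reward = reward,
       score_delta = score)
}

#' Simulate a full task session
#'
#' Runs the configured block sequence with a stationary agent. Staircase state
#' is carried within each condition across blocks; the tolerance recorded for a
#' trial is the value in effect before that trial's update. All stochastic
#' draws (lapse, neutral assignment, timing noise) consume a single seeded RNG
#' stream in trial order, so sessions are reproducible given the seed.
#'
#' The optional `rpe_slowing` argument makes the agent non-stationary: the
#' response time on trial *t* is shifted by
#' `rpe_slowing["prpe"] * pRPE(t-1) + rpe_slowing["nrpe"] * nRPE(t-1)` seconds,
#' where the previous trial's RPE magnitudes are computed against the
#' closed-form Gaussian win probability of the agent
#' (`p = 2 * pnorm(tol / sd) - 1` for an unbiased observer). This plants a
#' known RPE effect on trial-to-trial RT adaptation for recovery studies.
#'
#' @param config A [task_config()].
#' @param agent An [agent_config()].
#' @param seed Integer seed; if `NULL` the current RNG state is used.
#' @param rpe_slowing Named numeric `c(prpe =, nrpe =)` in seconds per unit
#'   RPE magnitude (default zero: stationary agent).
#' @return A `data.frame` with one row per trial: `trial_index`, `block_index`,
#'   `condition`, `tolerance_ms`, `rt_s`, `error_s`, `outcome`, `reward`,
#'   `score_delta`.
#' @export
run_session <- function(config, agent, seed = NULL,
                        rpe_slowing = c(prpe = 0, nrpe = 0)) {
  if (!is.null(seed)) set.seed(seed)
  tol <- config$initial_tolerance
  n_blocks <- length(config$block_order)
  n <- n_blocks * config$trials_per_block
  bounds <- config$tolerance_bounds
  # all stochastic draws are made up front, in trial order per source, so the
  # staircase loop itself is pure arithmetic
  lapse <- runif(n) < agent$lapse_rate
  neutral <- runif(n) < config$neutral_rate
  noise <- rnorm(n, 0, agent$timing_sd)
  condition <- rep(config$block_order, each = config$trials_per_block)
  block_index <- rep(seq_len(n_blocks), each = config$trials_per_block)
  tolerance_ms <- numeric(n)
  rt <- rep(NA_real_, n)
  outcome <- character(n)
  slowing <- any(rpe_slowing != 0)
  # true expected value of the unbiased agent per tolerance, for planted RPE
  # effects; tabulated over the reachable (integer-offset) tolerance grid
  ev_true <- NULL
  if (slowing) {
    grid <- seq(bounds[1], bounds[2], by = 1)
    z <- ms_to_s(grid) / agent$timing_sd
    b <- agent$timing_bias / agent$timing_sd
    ev_true <- stats::approxfun(grid, 2 * (pnorm(z - b) - pnorm(-z - b)) - 1)
  }
  step_win <- c(easy = unname(config$step$easy[["win"]]),
                hard = unname(config$step$hard[["win"]]))
  step_loss <- c(easy = unname(config$step$easy[["loss"]]),
                 hard = unname(config$step$hard[["loss"]]))
  tol_e <- unname(tol[["easy"]]); tol_h <- unname(tol[["hard"]])
  g_p <- rpe_slowing[["prpe"]]; g_n <- rpe_slowing[["nrpe"]]
  target <- config$target_interval
  bias <- agent$timing_bias
  prev_shift <- 0
  for (i in seq_len(n)) {
    easy_now <- condition[i] == "easy"
    tol_now <- if (easy_now) tol_e else tol_h
    tolerance_ms[i] <- tol_now
    if (lapse[i]) {
      outcome[i] <- "missing"
      if (slowing) prev_shift <- 0
    } else {
      rt_i <- target + bias + prev_shift + noise[i]
      rt[i] <- rt_i
      won <- abs(rt_i - target) * 1000 <= tol_now
      o <- if (neutral[i]) "neutral" else if (won) "win" else "loss"
      outcome[i] <- o
      if (o != "neutral") {
        d <- if (won) step_win[[condition[i]]] else step_loss[[condition[i]]]
        tnew <- min(max(tol_now + d, bounds[1]), bounds[2])
        if (easy_now) tol_e <- tnew else tol_h <- tnew
      }
      if (slowing) {
        reward_i <- if (o == "neutral") 0 else if (won) 1 else -1
        srpe <- reward_i - ev_true(tol_now)
        prev_shift <- g_p * max(srpe, 0) + g_n * max(-srpe, 0)
      }
    }
  }
  reward <- ifelse(outcome == "win", 1,
                   ifelse(outcome == "loss", -1,
                          ifelse(outcome == "neutral", 0, NA_real_)))
  data.frame(trial_index = seq_len(n), block_index = block_index,
             condition = condition, tolerance_ms = tolerance_ms,
             rt_s = rt, error_s = rt - config$target_interval,
             outcome = outcome, reward = reward,
             score_delta = reward * 100)
}

#' Reject behavioral outlier trials
#'
#' Removes trials with missing responses, response times outside
#' \eqn{[0.5, 1.5]} s, and response times more than `sd_mult` standard
#' deviations from the session mean. The mean and SD are computed over the
#' in-range response times only, so a single extreme RT cannot mask itself.
#'
#' @param trials Trial table from [run_session()] (or the same schema).
#' @param sd_mult SD multiplier for the outlier rule (default 3).
#' @return The surviving trials, in their original order.
#' @export
reject_trials <- function(trials, sd_mult = 3) {
  if (nrow(trials) == 0) return(trials)
  rt <- trials$rt_s
  in_range <- !is.na(rt) & rt >= 0.5 & rt <= 1.5
  m <- mean(rt[in_range])
  s <- sd(rt[in_range])
  keep <- in_range
  if (is.finite(s) && s > 0)
    keep <- keep & abs(rt - m) <= sd_mult * s
  trials[keep, , drop = FALSE]
}

#' Trial-to-trial RT-change table
#'
#' Builds the response-time adaptation table: for each retained trial, the
#' change in RT relative to the immediately preceding trial of the same block,
#' together with the previous trial's RT, outcome, and index (for joining
#' previous-trial RPE variables). The first trial of each block contributes no
#' row, and neither does any trial whose predecessor is absent from `trials`
#' (missing responses and rejected trials break the chain).
#'
#' @param trials A cleaned trial table (after [reject_trials()]).
#' @return A `data.frame` with columns `trial_index`, `block_index`,
#'   `rt_change`, `prev_rt`, `prev_outcome`, `prev_trial_index`.
#' @export
rt_change_table <- function(trials) {
  empty <- data.frame(trial_index = integer(), block_index = integer(),
                      rt_change = numeric(), prev_rt = numeric(),
                      prev_outcome = character(),
                      prev_trial_index = integer())
  if (nrow(trials) < 2) return(empty)
  idx <- trials$trial_index
  prev_pos <- match(idx - 1L, idx)
  ok <- !is.na(prev_pos) &
    trials$block_index[prev_pos] == trials$block_index &
    !is.na(trials$rt_s) & !is.na(trials$rt_s[prev_pos])
  ok[is.na(ok)] <- FALSE
  if (!any(ok)) return(empty)
  p <- prev_pos[ok]
  data.frame(trial_index = idx[ok],
             block_index = trials$block_index[ok],
             rt_change = trials$rt_s[ok] - trials$rt_s[p],
             prev_rt = trials$rt_s[p],
             prev_outcome = trials$outcome[p],
             prev_trial_index = idx[p])
}

#' Read/write behavioral trial tables as TSV
#'
#' Fixed-schema tab-separated files holding one trial per row.
#'
#' @param trials Trial table.
#' @param path File path.
#' @return `read_trials` returns the trial `data.frame`; `write_trials`
#'   returns `path` invisibly.
#' @export
write_trials <- function(trials, path) {
  write.table(trials, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
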