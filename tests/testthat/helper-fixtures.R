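# Small fixture builders shared across test files. Everything is generated
# in code at test time; no stored data.

# A short cleaned session with RL variables, cheap enough for repeated use.
quick_session <- function(seed = 1, neutral_rate = 0, blocks = 4) {
  cfg <- task_config(neutral_rate = neutral_rate,
                     block_order = rep(c("easy", "hard"), length.out = blocks))
  tr <- run_session(cfg, agent_config(timing_sd = 0.1), seed = seed)
  add_rl_variables(reject_trials(tr))
}

# Independent brute-force BH step-up, used as the oracle for fdr_correct().
bh_bruteforce <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  q <- numeric(n)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Hand-built conditional coefficient series for one channel, for exercising
# the classification decision table without model fits.
fake_coef_series <- function(channel, prpe_est, prpe_p, nrpe_est, nrpe_p) {
  n <- length(prpe_est)
  data.frame(channel = channel, subject = "S01",
             window = rep(seq(0, by = 25, length.out = n), 2),
             term = rep(c("prpe", "nrpe"), each = n),
             estimate = c(prpe_est, nrpe_est),
             se = 0.1, p = c(prpe_p, nrpe_p))
}
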