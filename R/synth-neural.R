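#' Ground truth for one synthetic channel
#'
#' Draws the generative gains of a channel so that its gain signs are
#' consistent with a target coding category and polarity. The feedback-locked
#' HFA response of the channel is `(g_ev*EV + g_p*pRPE + g_n*nRPE) * K(t)` plus
#' autocorrelated noise, so a channel's category is fully determined by which
#' gains are non-zero and their signs:
#' \itemize{
#'   \item `pRPE`: only `g_p` non-zero (regular `> 0`, inverted `< 0`);
#'   \item `nRPE`: only `g_n` non-zero (regular `< 0`, i.e. HFA decreases with
#'     growing negative-RPE magnitude; inverted `> 0`);
#'   \item `sRPE`: opposite signs (regular `g_p > 0 > g_n`);
#'   \item `uRPE`: same signs (`increasing` both `> 0`, `decreasing` both `< 0`);
#'   \item `none`: all RPE gains zero.
#' }
#'
#' @param category One of `"pRPE"`, `"nRPE"`, `"sRPE"`, `"uRPE"`, `"none"`.
#' @param polarity `"regular"`/`"inverted"` for pRPE/nRPE/sRPE,
#'   `"increasing"`/`"decreasing"` for uRPE; ignored for `"none"`.
#' @param gain_scale Gain magnitude in z-units per predictor unit (default 0.5).
#' @param region `"dMPFC"` or `"INS"`; sets the kernel peak latency (300 vs
#'   275 ms) and the synthetic coordinate cloud.
#' @param subject,channel Identifiers.
#' @param noise_sd,ar_coef Trial-noise SD (z-units) and AR(1) coefficient per
#'   25 ms step.
#' @return One-row `data.frame` of ground truth (gains, kernel, noise, xyz,
#'   labels).
#' @export
make_channel_ground_truth <- function(category, polarity = "regular",
                                      gain_scale = 0.5, region = "dMPFC",
                                      subject = "S01", channel = "ch1",
                                      noise_sd = 1, ar_coef = 0.5) {
  valid <- list(pRPE = c("regular", "inverted"),
                nRPE = c("regular", "inverted"),
                sRPE = c("regular", "inverted"),
                uRPE = c("increasing", "decreasing"),
                none = c("regular", "inverted", "increasing", "decreasing"))
  if (!category %in% names(valid))
    stop_contract("unknown category: ", category)
  if (!polarity %in% valid[[category]])
    stop_contract("invalid category/polarity combination: ",
                  category, "/", polarity)
  g <- category_gains(category, polarity, gain_scale)
  s <- gain_scale
  g_ev <- if (category == "none") 0 else 0.5 * s
  center <- if (region == "dMPFC") c(6, 20, 40) else c(-38, 2, 2)
  xyz <- rnorm(3, center, 8)
  data.frame(subject = subject, channel = channel, region = region,
             x = xyz[1], y = xyz[2], z = xyz[3],
             g_ev = g_ev, g_p = unname(g["p"]), g_n = unname(g["n"]),
             kernel_peak = if (region == "INS") 0.275 else 0.3,
             kernel_width = 0.1,
             noise_sd = noise_sd, ar_coef = ar_coef,
             category = category,
             polarity = if (category == "none") "none" else polarity,
             stringsAsFactors = FALSE)
}

#' Gain signs implied by a coding category
#'
#' Shared sign table mapping a category/polarity pair to (positive-RPE,
#' negative-RPE) gains of magnitude `scale`; used for both channel HFA gains
#' and pair coupling-modulation gains so that ground-truth labels and the
#' classifier's decision table are consistent by construction.
#'
#' @param category,polarity See [make_channel_ground_truth()].
#' @param scale Gain magnitude.
#' @return Named numeric `c(p =, n =)`.
#' @export
category_gains <- function(category, polarity, scale) {
  s <- scale
  switch(category,
    pRPE = c(p = if (polarity == "regular") s else -s, n = 0),
    nRPE = c(p = 0, n = if (polarity == "regular") -s else s),
    sRPE = if (polarity == "regular") c(p = s, n = -s) else c(p = -s, n = s),
    uRPE = if (polarity == "increasing") c(p = s, n = s) else c(p = -s, n = -s),
    none = c(p = 0, n = 0),
    stop_contract("unknown category: ", category))
}

#' Feedback-locked response kernel
#'
#' Unit-peak Gaussian bump at the channel's peak latency; the smooth temporal
#' profile by which a channel's trial-level RPE drive unfolds over time.
#'
#' @param time_grid Time points in seconds relative to feedback.
#' @param peak,width Kernel peak latency and width (SD), seconds.
#' @return Numeric vector on `time_grid` with maximum 1 at `peak`.
#' @export
hfa_response_kernel <- function(time_grid, peak = 0.3, width = 0.1) {
  exp(-((time_grid - peak)^2) / (2 * width^2))
}

# AR(1) noise matrix (trials x time) with stationary SD `sd`.
ar1_noise <- function(n_trials, n_time, sd, ar) {
  innov_sd <- sd * sqrt(1 - ar^2)
  e <- matrix(rnorm(n_trials * n_time, 0, innov_sd), n_trials, n_time)
  if (n_time >= 1) e[, 1] <- rnorm(n_trials, 0, sd)
  if (ar != 0 && n_time > 1)
    for (j in 2:n_time) e[, j] <- ar * e[, j - 1] + e[, j]
  e
}

#' Simulate baseline-normalized HFA envelopes for one channel
#'
#' Generates the trials-by-time envelope (in z-units, i.e. already
#' baseline-normalized) implied by the channel's ground truth and the trial
#' table's RL variables: deterministic kernel-shaped drive plus AR(1) noise.
#'
#' @param channel One-row ground-truth `data.frame` from
#'   [make_channel_ground_truth()].
#' @param rl_table Trial table with `ev`, `prpe`, `nrpe` columns.
#' @param time_grid Time points (s) relative to feedback.
#' @return Matrix `trials x time`.
#' @export
simulate_hfa_envelopes <- function(channel, rl_table, time_grid) {
  k <- hfa_response_kernel(time_grid, channel$kernel_peak, channel$kernel_width)
  drive <- channel$g_ev * rl_table$ev + channel$g_p * rl_table$prpe +
    channel$g_n * rl_table$nrpe
  drive[is.na(drive)] <- 0
  sig <- outer(drive, k)
  if (channel$noise_sd > 0)
    sig <- sig + ar1_noise(nrow(sig), ncol(sig), channel$noise_sd,
                           channel$ar_coef)
  sig
}

#' Render an HFA envelope as a raw broadband voltage trace
#'
#' Optional fidelity layer for exercising the spectral-power pipeline: the
#' envelope amplitude-modulates band-limited (70-150 Hz) noise, on top of a
#' 1/f-like background and white sensor noise, so that the log band power of
#' the trace is approximately linear in the envelope for small modulation
#' depths. A stimulus-locked pre-trial segment is generated with zero envelope
#' for baseline normalization.
#'
#' @param envelope Matrix `trials x time` on the envelope time grid (z-units).
#' @param time_grid Envelope time points (s) relative to feedback.
#' @param fs Sampling rate in Hz (default 1000, the clinical-recording rate;
#'   must be at least 500 to carry the 150 Hz band and must make the 25 ms
#'   analysis step an integer number of samples).
#' @param mod_depth Fractional amplitude modulation per envelope z-unit
#'   (default 0.3).
#' @param baseline_window Stimulus-locked baseline span in seconds (default
#'   `c(-0.25, -0.05)`).
#' @return List with `feedback` (`trials x samples`), `baseline`
#'   (`trials x samples`), `fs`, `feedback_start` (s), `baseline_start` (s).
#' @export
envelope_to_raw_trace <- function(envelope, time_grid, fs = 1000,
                                  mod_depth = 0.3,
                                  baseline_window = c(-0.25, -0.05)) {
  if (fs < 500)
    stop_contract("fs must be >= 500 Hz to carry the 70-150 Hz band")
  n_trials <- nrow(envelope)
  t_hi <- seq(min(time_grid), max(time_grid), by = 1 / fs)
  bf <- signal::butter(4, c(70, 150) / (fs / 2), type = "pass")
  lf <- signal::butter(2, 10 / (fs / 2), type = "low")
  gen_seg <- function(env_row, n_samp) {
    carrier <- signal::filtfilt(bf, rnorm(n_samp + 200))[101:(n_samp + 100)]
    slow <- signal::filtfilt(lf, rnorm(n_samp + 200, 0, 3))[101:(n_samp + 100)]
    (1 + mod_depth * env_row) * carrier + slow + rnorm(n_samp, 0, 0.2)
  }
  fb <- t(vapply(seq_len(n_trials), function(i) {
    env_hi <- stats::approx(time_grid, envelope[i, ], xout = t_hi,
                            rule = 2)$y
    gen_seg(env_hi, length(t_hi))
  }, numeric(length(t_hi))))
  n_base <- round(diff(baseline_window) * fs)
  bl <- t(vapply(seq_len(n_trials), function(i) gen_seg(0, n_base),
                 numeric(n_base)))
  list(feedback = fb, baseline = bl, fs = fs,
       feedback_start = min(time_grid), baseline_start = baseline_window[1])
}

#' Specification of a lag-coupled INS-dMPFC channel pair
#'
#' Coupling strength is specified on the correlation scale: the pair's
#' expected lagged Pearson correlation on a trial is
#' `base_r + m_ev*EV + m_p*pRPE + m_n*nRPE`, so ground-truth modulation gains
#' live in the same units as the coefficients fitted by [fit_lag_models()]
#' (mirroring how channel envelope gains are planted directly in z-units).
#'
#' @param ins_channel,dmpfc_channel Channel ids.
#' @param lag_ms Coupling lag in ms on the 25 ms grid within +/-400 ms;
#'   positive means INS leads dMPFC.
#' @param base_r Baseline lagged correlation (default 0.4).
#' @param mod_gains Named numeric `c(ev =, prpe =, nrpe =)` modulation of the
#'   expected correlation per predictor unit.
#' @param noise_sd Independent noise SD added to each channel (latent process
#'   has unit SD, so `noise_sd = 1` gives coupling SNR 1).
#' @return List of class `coupling_spec`.
#' @export
coupling_spec <- function(ins_channel, dmpfc_channel, lag_ms = 75,
                          base_r = 0.4,
                          mod_gains = c(ev = 0, prpe = 0, nrpe = 0),
                          noise_sd = 1) {
  if (abs(lag_ms) > 400 || lag_ms %% 25 != 0)
    stop_contract("lag must lie on the 25 ms grid within +/-400 ms")
  structure(list(ins_channel = ins_channel, dmpfc_channel = dmpfc_channel,
                 lag_ms = lag_ms, base_r = base_r,
                 mod_gains = mod_gains, noise_sd = noise_sd),
            class = "coupling_spec")
}

#' Simulate a lag-coupled channel pair
#'
#' The INS channel carries a smooth latent process (AR(1) on the 25 ms grid,
#' unit SD) plus independent noise; the dMPFC channel receives a time-shifted
#' copy of the latent process scaled by a trial-varying coupling gain, plus
#' its own noise. Positive lags delay the dMPFC copy, so INS leads. The gain
#' on each trial is back-computed from the trial's target correlation
#' `base_r + m_ev*EV + m_p*pRPE + m_n*nRPE` through the analytic
#' gain-correlation map, so the expected lagged Pearson correlation is linear
#' in the RL predictors by construction.
#'
#' @param spec A [coupling_spec()].
#' @param rl_table Trial table with `ev`, `prpe`, `nrpe`.
#' @param time_grid Time points (s), 25 ms spacing.
#' @param latent_ar AR(1) coefficient of the latent process (default 0.5).
#' @return List with matrices `ins` and `dmpfc` (`trials x time`).
#' @export
simulate_coupled_pair <- function(spec, rl_table, time_grid, latent_ar = 0.5) {
  step <- round(mean(diff(time_grid)) * 1000)
  k <- spec$lag_ms / step
  if (k != round(k)) stop_contract("lag is not a multiple of the grid step")
  n_tr <- nrow(rl_table)
  n_t <- length(time_grid)
  pad <- abs(k)
  latent <- ar1_noise(n_tr, n_t + 2 * pad, 1, latent_ar)
  ins_lat <- latent[, (pad + 1):(pad + n_t), drop = FALSE]
  dm_lat <- latent[, (pad + 1 - k):(pad + n_t - k), drop = FALSE]
  rho <- spec$base_r + spec$mod_gains[["ev"]] * rl_table$ev +
    spec$mod_gains[["prpe"]] * rl_table$prpe +
    spec$mod_gains[["nrpe"]] * rl_table$nrpe
  rho[is.na(rho)] <- spec$base_r
  # invert r(g) = g / (sqrt(g^2 + sd^2) * sqrt(1 + si^2)); unit-SD latent.
  # without noise the lagged copy is perfectly correlated at any gain
  if (spec$noise_sd == 0) {
    gain <- rep(1, n_tr)
  } else {
    a <- sqrt(1 + spec$noise_sd^2)
    rho <- clamp(rho, -0.95 / a, 0.95 / a)
    gain <- rho * a * spec$noise_sd / sqrt(pmax(1 - (rho * a)^2, 1e-6))
  }
  ins <- ins_lat
  dmpfc <- dm_lat * gain
  if (spec$noise_sd > 0) {
    ins <- ins + matrix(rnorm(n_tr * n_t, 0, spec$noise_sd), n_tr, n_t)
    dmpfc <- dmpfc + matrix(rnorm(n_tr * n_t, 0, spec$noise_sd), n_tr, n_t)
  }
  list(ins = ins, dmpfc = dmpfc)
}

#' Configuration for a synthetic cohort
#'
#' @param n_subjects Number of simulated participants.
#' @param channels_per_region Named counts, e.g. `c(dMPFC = 4, INS = 4)`.
#' @param category_mix Either named probabilities over
#'   `pRPE/nRPE/sRPE/uRPE/none` (sampled per channel) or a character vector of
#'   explicit labels recycled over channels. The default mix puts roughly one
#'   third of channels in pRPE and one third in uRPE, with the remainder
#'   split over nRPE, sRPE and unresponsive channels.
#' @param regular_prob Named probabilities that each category uses regular
#'   (or, for uRPE, increasing) polarity; the default makes inverted coding
#'   common only for nRPE.
#' @param gain_scale,noise_sd,ar_coef Channel generative parameters.
#' @param task,agent Behavioral configurations (see [task_config()],
#'   [agent_config()]).
#' @param time_grid Envelope time grid (s) relative to feedback.
#' @param n_pairs Coupled INS-dMPFC pairs per subject (0 disables).
#' @param coupling List controlling pair generation: `mix` (category labels
#'   recycled over pairs, or named probabilities), `lag_ms` (scalar, or named
#'   by category to plant lag differences), `mod_scale` (correlation-scale
#'   modulation per predictor unit, see [coupling_spec()]), `mod_jitter`
#'   (relative uniform jitter of each pair's modulation magnitude, giving
#'   pairs heterogeneous coupling strength), `base_r`, and `noise_sd`.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 5,
                          channels_per_region = c(dMPFC = 4, INS = 4),
                          category_mix = c(pRPE = 1/3, uRPE = 1/3,
                                           nRPE = 1/9, sRPE = 1/9, none = 1/9),
                          regular_prob = c(pRPE = 0.95, nRPE = 1/3,
                                           sRPE = 0.85, uRPE = 0.95),
                          gain_scale = 0.5, noise_sd = 1, ar_coef = 0.5,
                          task = task_config(), agent = agent_config(),
                          time_grid = seq(-0.25, 1.2, by = 0.025),
                          n_pairs = 0,
                          coupling = list(mix = "pRPE", lag_ms = 75,
                                          base_r = 0.4, mod_scale = 0.08,
                                          mod_jitter = 0.3, noise_sd = 1)) {
  structure(as.list(environment()), class = "cohort_config")
}

#' Generate a synthetic cohort with known ground truth
#'
#' Runs one behavioral session per subject, derives RL variables, draws
#' channel ground truths, and simulates feedback-locked HFA envelopes and
#' (optionally) lag-coupled INS-dMPFC channel pairs. Deterministic given the
#' seed. Envelopes are generated directly in z-units so ground-truth gains are
#' comparable to fitted coefficients; [envelope_to_raw_trace()] provides the
#' raw-voltage fidelity layer when the spectral pipeline itself is under study.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return List of class `synthetic_cohort`: `trials` (per-subject cleaned,
#'   RL-augmented tables), `channels` (ground-truth data.frame), `envelopes`
#'   (`envelopes[[subject]][[channel]]` = trials x time matrix), `pairs`
#'   (per-subject list of coupling spec + `ins`/`dmpfc` matrices), and
#'   `time_grid`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1) {
  set.seed(seed)
  subjects <- sprintf("S%02d", seq_len(config$n_subjects))
  cats <- names(config$category_mix %||% NULL)
  trials <- list(); envelopes <- list(); pairs <- list()
  channels <- NULL
  for (s in seq_along(subjects)) {
    sid <- subjects[s]
    tr <- run_session(config$task, config$agent)
    tr <- reject_trials(tr)
    tr <- add_rl_variables(tr)
    trials[[sid]] <- tr
    env_s <- list()
    ci <- 0
    for (region in names(config$channels_per_region)) {
      for (j in seq_len(config$channels_per_region[[region]])) {
        ci <- ci + 1
        lab <- if (is.character(config$category_mix)) {
          config$category_mix[(ci - 1) %% length(config$category_mix) + 1]
        } else {
          sample(cats, 1, prob = config$category_mix)
        }
        pol <- if (lab == "none") "regular"
          else if (runif(1) < config$regular_prob[[lab]]) {
            if (lab == "uRPE") "increasing" else "regular"
          } else {
            if (lab == "uRPE") "decreasing" else "inverted"
          }
        ch_id <- sprintf("%s_%s_ch%02d", sid, region, j)
        gt <- make_channel_ground_truth(lab, pol, config$gain_scale, region,
                                        subject = sid, channel = ch_id,
                                        noise_sd = config$noise_sd,
                                        ar_coef = config$ar_coef)
        channels <- rbind(channels, gt)
        env_s[[ch_id]] <- simulate_hfa_envelopes(gt, tr, config$time_grid)
      }
    }
    envelopes[[sid]] <- env_s
    if (config$n_pairs > 0) {
      cp <- config$coupling
      pairs[[sid]] <- lapply(seq_len(config$n_pairs), function(pj) {
        lab <- if (is.character(cp$mix))
          cp$mix[(pj - 1) %% length(cp$mix) + 1]
        else sample(names(cp$mix), 1, prob = cp$mix)
        pol <- if (lab == "none") "regular"
          else if (runif(1) < (config$regular_prob[[lab]] %||% 1)) {
            if (lab == "uRPE") "increasing" else "regular"
          } else {
            if (lab == "uRPE") "decreasing" else "inverted"
          }
        jit <- 1 + runif(1, -cp$mod_jitter %||% 0, cp$mod_jitter %||% 0)
        g <- category_gains(lab, pol, cp$mod_scale * jit)
        lag <- if (length(cp$lag_ms) > 1) cp$lag_ms[[lab]] else cp$lag_ms
        sp <- coupling_spec(
          ins_channel = sprintf("%s_INS_p%02d", sid, pj),
          dmpfc_channel = sprintf("%s_dMPFC_p%02d", sid, pj),
          lag_ms = lag, base_r = cp$base_r %||% 0.4,
          mod_gains = c(ev = 0, prpe = unname(g["p"]), nrpe = unname(g["n"])),
          noise_sd = cp$noise_sd)
        c(list(spec = sp, category = lab, polarity = if (lab == "none")
          "none" else pol),
          simulate_coupled_pair(sp, tr, config$time_grid))
      })
    }
  }
  structure(list(trials = trials, channels = channels, envelopes = envelopes,
                 pairs = pairs, time_grid = config$time_grid,
                 config = config, seed = seed),
            class = "synthetic_cohort")
}

#' Ground-truth table for a cohort's coupled pairs
#'
#' @param cohort A [generate_cohort()] result with pairs.
#' @return Data frame: `subject`, `pair` (matching [pair_xcorr_table()] ids),
#'   `category`, `polarity`, `lag_ms`, `m_p`, `m_n`.
#' @export
pair_ground_truth <- function(cohort) {
  do.call(rbind, lapply(names(cohort$pairs), function(sid) {
    do.call(rbind, lapply(seq_along(cohort$pairs[[sid]]), function(pj) {
      pr <- cohort$pairs[[sid]][[pj]]
      data.frame(subject = sid,
                 pair = paste(sid, sprintf("pair%02d", pj), sep = ":"),
                 category = pr$category, polarity = pr$polarity,
                 lag_ms = pr$spec$lag_ms,
                 m_p = unname(pr$spec$mod_gains[["prpe"]]),
                 m_n = unname(pr$spec$mod_gains[["nrpe"]]))
    }))
  }))
}
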