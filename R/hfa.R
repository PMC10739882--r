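#' Multitaper sub-band log power of epoched traces
#'
#' Extracts high-frequency power from raw voltage epochs: in sliding 50 ms
#' windows stepping by 25 ms, each windowed segment is Hann-tapered,
#' zero-padded, Fourier transformed, and band power is averaged over FFT bins
#' within +/- `half_bw` Hz of each sub-band center (centers 70 to 150 Hz in
#' 10 Hz steps by default). Power is natural-log transformed, since band power
#' is approximately log-normal. Window timestamps refer to the window start
#' (half-open `[start, start + 50 ms)` convention).
#'
#' @param epochs Matrix `trials x samples`.
#' @param fs Sampling rate (Hz), at least 300.
#' @param epoch_start Time (s) of the first sample relative to the event.
#' @param centers Sub-band center frequencies (Hz).
#' @param half_bw Half-bandwidth of spectral smoothing per sub-band (Hz).
#' @param window_s,step_s Window length and step (s).
#' @return List with `power` (array `trials x bands x windows` of log power),
#'   `time` (window starts, s), `bands` (centers).
#' @export
extract_hfa_power <- function(epochs, fs, epoch_start = 0,
                              centers = seq(70, 150, by = 10), half_bw = 10,
                              window_s = 0.05, step_s = 0.025) {
  if (fs < 2 * max(centers))
    stop_contract("sampling rate too low for the requested bands")
  n_win_samp <- round(window_s * fs)
  n_step <- round(step_s * fs)
  if (abs(n_step - step_s * fs) > 1e-9 || abs(n_win_samp - window_s * fs) > 1e-9)
    stop_contract("window/step must be integer numbers of samples at fs = ", fs)
  n_samp <- ncol(epochs)
  if (n_samp < n_win_samp)
    stop_contract("epoch shorter than one analysis window")
  starts <- seq(1, n_samp - n_win_samp + 1, by = n_step)
  nfft <- 512
  while (nfft < n_win_samp) nfft <- nfft * 2
  freqs <- (seq_len(nfft) - 1) * fs / nfft
  taper <- 0.5 - 0.5 * cos(2 * pi * seq_len(n_win_samp) / (n_win_samp + 1))
  taper <- taper / sqrt(mean(taper^2))
  bins <- lapply(centers, function(fc)
    which(freqs >= fc - half_bw & freqs <= fc + half_bw))
  out <- array(NA_real_, c(nrow(epochs), length(centers), length(starts)))
  for (w in seq_along(starts)) {
    seg <- epochs[, starts[w]:(starts[w] + n_win_samp - 1), drop = FALSE]
    seg <- seg - rowMeans(seg)
    seg <- sweep(seg, 2, taper, `*`)
    spec <- Mod(stats::mvfft(t(cbind(seg, matrix(0, nrow(seg),
                                                 nfft - n_win_samp)))))^2
    for (b in seq_along(centers))
      out[, b, w] <- log(colMeans(spec[bins[[b]], , drop = FALSE]))
  }
  list(power = out,
       time = epoch_start + (starts - 1) / fs,
       bands = centers)
}

#' Bootstrap baseline z-scoring of feedback-locked power
#'
#' Normalizes feedback-locked log power against pre-stimulus baseline
#' activity. For each sub-band, `n_boot` bootstrap resamples of trials are
#' drawn from the baseline segment; the mean and SD of baseline log power are
#' computed on each resample and averaged across resamples, and the
#' feedback-locked values are z-scored with those averaged statistics. The
#' trial resampling makes the baseline statistics robust to occasional extreme
#' baseline trials. Sub-band z-scores are then averaged into a single HFA
#' series per trial.
#'
#' @param feedback_power `trials x bands x time` log power (feedback-locked),
#'   from [extract_hfa_power()].
#' @param baseline_power `trials x bands x time` log power over the
#'   pre-stimulus baseline window.
#' @param n_boot Number of bootstrap resamples (default 500).
#' @param seed Optional seed for the resampling.
#' @return List with `z` (matrix `trials x time`, sub-band averaged),
#'   `baseline_stats` (per-band mean/SD used).
#' @export
bootstrap_baseline_normalize <- function(feedback_power, baseline_power,
                                         n_boot = 500, seed = NULL) {
  stopifnot(n_boot >= 1,
            dim(feedback_power)[1] == dim(baseline_power)[1],
            dim(feedback_power)[2] == dim(baseline_power)[2])
  if (!is.null(seed)) set.seed(seed)
  n_tr <- dim(baseline_power)[1]
  n_b <- dim(baseline_power)[2]
  idx <- matrix(sample.int(n_tr, n_tr * n_boot, replace = TRUE), n_tr, n_boot)
  mu <- numeric(n_b); sg <- numeric(n_b)
  for (b in seq_len(n_b)) {
    vals <- baseline_power[, b, , drop = TRUE]
    vals <- matrix(vals, nrow = n_tr)
    ms <- colMeans(matrix(rowMeans(vals)[idx], n_tr))
    sds <- vapply(seq_len(n_boot),
                  function(k) sd(as.vector(vals[idx[, k], ])), 0)
    mu[b] <- mean(ms)
    sg[b] <- mean(sds)
    if (!is.finite(sg[b]) || sg[b] <= 0)
      stop_contract("zero baseline variance in sub-band ", b)
  }
  z_bands <- array(NA_real_, dim(feedback_power))
  for (b in seq_len(n_b))
    z_bands[, b, ] <- (feedback_power[, b, ] - mu[b]) / sg[b]
  z <- apply(z_bands, c(1, 3), mean)
  list(z = z, baseline_stats = data.frame(band = seq_len(n_b),
                                          mean = mu, sd = sg))
}

#' Sliding-window averages of normalized HFA
#'
#' Averages a z-scored HFA series (on a 25 ms grid) in 50 ms windows stepping
#' by 25 ms from 0 to 0.6 s post-feedback, giving exactly 23 windows
#' (`floor((600 - 50) / 25) + 1`). Each window covers the half-open span
#' `[start, start + 50 ms)` on the grid.
#'
#' @param z Matrix `trials x time` of normalized HFA.
#' @param time_grid Time points (s) of the columns of `z`; must align with a
#'   25 ms grid covering 0 to 0.6 s.
#' @param from,to Analysis range in seconds (default 0 to 0.6).
#' @param width_s,step_s Window width and step (default 0.05 / 0.025).
#' @return Matrix `trials x windows`; column names are window starts in ms.
#' @export
window_average <- function(z, time_grid, from = 0, to = 0.6,
                           width_s = 0.05, step_s = 0.025) {
  stopifnot(ncol(z) == length(time_grid))
  starts <- seq(from, to - width_s, by = step_s)
  tol <- 1e-9
  grid_ms <- round(time_grid * 1000)
  if (any(abs(time_grid * 1000 - grid_ms) > 1e-6) ||
      any(grid_ms %% round(step_s * 1000) != 0))
    stop_contract("time grid is not aligned to the ", step_s * 1000,
                  " ms window step")
  out <- matrix(NA_real_, nrow(z), length(starts))
  for (k in seq_along(starts)) {
    sel <- time_grid >= starts[k] - tol & time_grid < starts[k] + width_s - tol
    if (!any(sel)) stop_contract("window ", k, " not covered by the time grid")
    out[, k] <- rowMeans(z[, sel, drop = FALSE])
  }
  colnames(out) <- round(starts * 1000)
  out
}

#' Full HFA pipeline from raw epochs
#'
#' Convenience wrapper: sub-band log power for feedback and baseline epochs,
#' bootstrap baseline z-scoring, sub-band averaging, and 0-0.6 s window
#' averaging.
#'
#' @param raw List as returned by [envelope_to_raw_trace()] (`feedback`,
#'   `baseline`, `fs`, `feedback_start`).
#' @param n_boot,seed Passed to [bootstrap_baseline_normalize()].
#' @return List with `z` (trials x time), `time` (s), `windows`
#'   (trials x 23 window means).
#' @export
hfa_from_raw <- function(raw, n_boot = 500, seed = NULL) {
  fb <- extract_hfa_power(raw$feedback, raw$fs, raw$feedback_start)
  bl <- extract_hfa_power(raw$baseline, raw$fs, raw$baseline_start %||% -0.25)
  norm <- bootstrap_baseline_normalize(fb$power, bl$power, n_boot, seed)
  keep <- fb$time >= -1e-9 & fb$time <= 0.6 + 1e-9
  list(z = norm$z, time = fb$time,
       windows = window_average(norm$z[, keep, drop = FALSE],
                                round(fb$time[keep], 6)))
}
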