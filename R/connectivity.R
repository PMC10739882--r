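#' Lag grid for directed connectivity
#'
#' Symmetric grid of time lags on the HFA sampling step. Positive lags mean
#' INS activity precedes dMPFC activity; negative lags mean dMPFC leads.
#'
#' @param max_ms Maximum absolute lag (default 400 ms).
#' @param step_ms Grid step (default 25 ms, the HFA grid spacing).
#' @return Integer vector of lags in ms (33 lags by default).
#' @export
lag_grid <- function(max_ms = 400, step_ms = 25) {
  if (max_ms %% step_ms != 0) stop_contract("step must divide the lag range")
  seq(-max_ms, max_ms, by = step_ms)
}

#' Per-trial time-lagged cross-correlation between two channels
#'
#' For each trial and lag k, the Pearson correlation between the dMPFC series
#' at time t and the INS series at time t - k over their overlapping samples,
#' so positive lags quantify how well earlier INS activity predicts later
#' dMPFC activity. Correlations are computed on the 25 ms HFA grid restricted
#' to `epoch` (default 0-1.0 s post-feedback); lags whose overlap falls below
#' `min_overlap` samples are dropped, and zero-variance segments yield NA.
#'
#' @param hfa_ins,hfa_dmpfc Matrices `trials x time` on a common time grid.
#' @param time_grid Time points (s) of the columns.
#' @param lags Lag grid in ms (see [lag_grid()]).
#' @param epoch Correlation epoch in seconds (default `c(0, 1)`).
#' @param min_overlap Minimum overlapping samples per lag (default 8).
#' @return Matrix `trials x lags` of correlation coefficients; attribute
#'   `n_overlap` gives samples per lag.
#' @export
trial_lagged_xcorr <- function(hfa_ins, hfa_dmpfc, time_grid,
                               lags = lag_grid(), epoch = c(0, 1),
                               min_overlap = 8) {
  stopifnot(all(dim(hfa_ins) == dim(hfa_dmpfc)),
            ncol(hfa_ins) == length(time_grid))
  step <- round(mean(diff(time_grid)) * 1000)
  keep <- time_grid >= epoch[1] - 1e-9 & time_grid <= epoch[2] + 1e-9
  ins <- hfa_ins[, keep, drop = FALSE]
  dm <- hfa_dmpfc[, keep, drop = FALSE]
  n_t <- ncol(ins)
  row_cor <- function(a, b) {
    a <- a - rowMeans(a); b <- b - rowMeans(b)
    num <- rowSums(a * b)
    den <- sqrt(rowSums(a^2) * rowSums(b^2))
    r <- num / den
    r[den == 0] <- NA_real_
    r
  }
  out <- matrix(NA_real_, nrow(ins), length(lags))
  n_overlap <- integer(length(lags))
  for (j in seq_along(lags)) {
    k <- lags[j] / step
    if (k != round(k))
      stop_contract("lag ", lags[j], " ms not on the ", step, " ms grid")
    k <- as.integer(k)
    n_overlap[j] <- n_t - abs(k)
    if (n_overlap[j] < min_overlap) next
    if (k >= 0) {
      # dmpfc(t) vs ins(t - k): INS leads for positive k
      out[, j] <- row_cor(dm[, (k + 1):n_t, drop = FALSE],
                          ins[, 1:(n_t - k), drop = FALSE])
    } else {
      out[, j] <- row_cor(dm[, 1:(n_t + k), drop = FALSE],
                          ins[, (1 - k):n_t, drop = FALSE])
    }
  }
  colnames(out) <- lags
  attr(out, "n_overlap") <- setNames(n_overlap, lags)
  out
}

#' Long lag-correlation table for a cohort's coupled pairs
#'
#' Computes [trial_lagged_xcorr()] for every coupled pair in a synthetic
#' cohort and joins trial RL variables, producing the table consumed by
#' [fit_lag_models()].
#'
#' @param cohort A [generate_cohort()] result with `n_pairs > 0`.
#' @param lags Lag grid (ms).
#' @param epoch Correlation epoch (s).
#' @return Data frame: `subject`, `pair`, `sub_pair`, `trial`, `lag`, `r`,
#'   `ev`, `prpe`, `nrpe`.
#' @export
pair_xcorr_table <- function(cohort, lags = lag_grid(), epoch = c(0, 1)) {
  if (length(cohort$pairs) == 0) stop_contract("cohort has no coupled pairs")
  rows <- lapply(names(cohort$pairs), function(sid) {
    rl <- cohort$trials[[sid]]
    do.call(rbind, lapply(seq_along(cohort$pairs[[sid]]), function(pj) {
      pr <- cohort$pairs[[sid]][[pj]]
      r <- trial_lagged_xcorr(pr$ins, pr$dmpfc, cohort$time_grid, lags,
                              epoch = epoch)
      pid <- sprintf("pair%02d", pj)
      n_tr <- nrow(r)
      data.frame(subject = sid, pair = pid,
                 sub_pair = paste(sid, pid, sep = ":"),
                 trial = rep(rl$trial_index, length(lags)),
                 lag = rep(lags, each = n_tr),
                 r = as.vector(r),
                 ev = rep(rl$ev, length(lags)),
                 prpe = rep(rl$prpe, length(lags)),
                 nrpe = rep(rl$nrpe, length(lags)))
    }))
  })
  out <- do.call(rbind, rows)
  out[complete.cases(out), , drop = FALSE]
}

#' Per-lag mixed models of RPE-modulated connectivity
#'
#' For each time lag, fits the asymmetric RPE model to the per-trial
#' correlation coefficients, `r ~ ev + prpe + nrpe`, with subject and
#' subject:pair nested random effects. Fixed-effect p-values are FDR-corrected
#' across lags separately per predictor; pair-level conditional coefficients
#' are left uncorrected.
#'
#' @param xcorr_table Output of [pair_xcorr_table()] (raw Pearson r by
#'   default; apply Fisher z to the `r` column beforehand if desired).
#' @param random `"full"` (slopes at both levels), `"pair"` (slopes at
#'   subject:pair, subject intercept), or `"intercept"`.
#' @param robust Robust fits.
#' @return List of class `lag_model_results`: `fixed` (lag x term
#'   coefficients with q), `fits` (per lag).
#' @export
fit_lag_models <- function(xcorr_table, random = "pair", robust = FALSE) {
  re <- switch(random,
    full = "(1 + prpe + nrpe + ev | subject) + (1 + prpe + nrpe + ev | sub_pair)",
    pair = "(1 | subject) + (1 + prpe + nrpe + ev | sub_pair)",
    intercept = "(1 | subject) + (1 | sub_pair)",
    stop_contract("unknown random structure: ", random))
  f <- as.formula(paste("r ~ ev + prpe + nrpe +", re))
  lags <- sort(unique(xcorr_table$lag))
  fits <- setNames(lapply(lags, function(lg) {
    fit_lmm(f, xcorr_table[xcorr_table$lag == lg, , drop = FALSE],
            robust = robust)
  }), as.character(lags))
  fixed <- do.call(rbind, lapply(as.character(lags), function(lg) {
    cbind(lag = as.integer(lg), fits[[lg]]$fixed)
  }))
  fixed$q <- NA_real_
  for (tm in unique(fixed$term)) {
    sel <- fixed$term == tm
    fixed$q[sel] <- fdr_correct(fixed$p[sel])
  }
  structure(list(fixed = fixed, fits = fits, lags = lags),
            class = "lag_model_results")
}

#' Pair-level conditional coefficient series over lags
#'
#' @param results A [fit_lag_models()] result with pair-level random slopes.
#' @param terms Terms to extract (default `prpe`, `nrpe`).
#' @return Data frame: `pair` (sub_pair id), `subject`, `lag`, `term`,
#'   `estimate`, `se`, `p`.
#' @export
extract_pair_coefficients <- function(results, terms = c("prpe", "nrpe")) {
  out <- do.call(rbind, lapply(as.character(results$lags), function(lg) {
    fit <- results$fits[[lg]]
    d <- fit$model@frame
    nest <- setNames(as.character(d$subject), as.character(d$sub_pair))
    nest <- nest[!duplicated(names(nest))]
    cc <- conditional_coefficients(fit, terms, unit = "sub_pair",
                                   nest_map = nest)
    data.frame(pair = cc$unit, subject = unname(nest[cc$unit]),
               lag = as.integer(lg), term = cc$term,
               estimate = cc$estimate, se = cc$se, p = cc$p)
  }))
  rownames(out) <- NULL
  out
}

#' Peak-lag extraction per pair and term
#'
#' The lag at which each predictor best modulates a pair's connectivity: the
#' lag maximizing the absolute conditional coefficient. Ties resolve to the
#' earliest (most negative) lag.
#'
#' @param pair_series Output of [extract_pair_coefficients()].
#' @return Data frame: `pair`, `subject`, `term`, `peak_estimate`, `peak_lag`,
#'   `peak_p`.
#' @export
extract_peak_lag <- function(pair_series) {
  one <- function(d) {
    d <- d[order(d$lag), , drop = FALSE]
    i <- which.max(abs(d$estimate))  # first max = most negative lag on ties
    data.frame(pair = d$pair[1], subject = d$subject[1], term = d$term[1],
               peak_estimate = d$estimate[i], peak_lag = d$lag[i],
               peak_p = d$p[i])
  }
  out <- do.call(rbind, lapply(split(pair_series,
                                     list(pair_series$pair, pair_series$term),
                                     drop = TRUE), one))
  rownames(out) <- NULL
  out
}

#' Classify channel pairs into RPE connectivity categories
#'
#' Applies the same four-category decision table used for channels to the
#' pair-level peak coefficients: a term is significant for a pair when its
#' conditional p at the peak lag is below `alpha` (uncorrected).
#'
#' @param peaks Output of [extract_peak_lag()] covering terms `prpe`, `nrpe`.
#' @param alpha Significance threshold (default 0.05).
#' @return Data frame per pair: `pair`, `subject`, `category`, `polarity`,
#'   peak estimates/lags per term.
#' @export
classify_pairs <- function(peaks, alpha = 0.05) {
  one <- function(d) {
    g <- function(tm, col) {
      v <- d[d$term == tm, col]
      if (length(v) == 0) NA_real_ else v
    }
    sig_p <- isTRUE(g("prpe", "peak_p") < alpha)
    sig_n <- isTRUE(g("nrpe", "peak_p") < alpha)
    est_p <- if (sig_p) g("prpe", "peak_estimate") else 0
    est_n <- if (sig_n) g("nrpe", "peak_estimate") else 0
    cls <- classify_from_peaks(sig_p, sig_n, est_p, est_n)
    data.frame(pair = d$pair[1], subject = d$subject[1],
               category = unname(cls["category"]),
               polarity = unname(cls["polarity"]),
               prpe_peak = g("prpe", "peak_estimate"),
               prpe_lag = g("prpe", "peak_lag"),
               nrpe_peak = g("nrpe", "peak_estimate"),
               nrpe_lag = g("nrpe", "peak_lag"))
  }
  out <- do.call(rbind, lapply(split(peaks, peaks$pair), one))
  rownames(out) <- NULL
  out
}

#' Category and peak-lag statistics for channel pairs
#'
#' Per-subject proportions of pairs per category compared with a
#' Kruskal-Wallis test and FDR-corrected pairwise Wilcoxon rank-sum tests;
#' the same procedure applied to the peak-lag distributions per category,
#' with median/IQR summaries.
#'
#' @param pair_categories Output of [classify_pairs()].
#' @param lag_term Which term's peak lags to compare (default `"prpe"`).
#' @return List: `proportions`, `prop_kruskal`, `prop_pairwise`, `lag_summary`,
#'   `lag_kruskal`, `lag_pairwise`.
#' @export
connectivity_category_stats <- function(pair_categories, lag_term = "prpe") {
  cats <- c("pRPE", "nRPE", "sRPE", "uRPE")
  d <- pair_categories
  present <- intersect(cats, unique(d$category))
  props <- do.call(rbind, lapply(split(d, d$subject), function(g)
    data.frame(subject = g$subject[1], category = cats,
               prop = vapply(cats, function(cc) mean(g$category == cc), 0))))
  rownames(props) <- NULL
  if (length(present) < 2) {
    warning("fewer than two pair categories present; tests degenerate")
    return(list(proportions = props, prop_kruskal = NULL,
                prop_pairwise = NULL, lag_summary = NULL,
                lag_kruskal = NULL, lag_pairwise = NULL))
  }
  kw_p <- kruskal.test(prop ~ factor(category), data = props)
  pw <- function(values, groups) {
    pairs <- utils::combn(sort(unique(groups)), 2, simplify = FALSE)
    out <- do.call(rbind, lapply(pairs, function(pr) {
      a <- values[groups == pr[1]]; b <- values[groups == pr[2]]
      p <- if (length(a) == 0 || length(b) == 0 ||
               (all(a %in% b) && all(b %in% a) && length(a) == length(b))) 1
        else suppressWarnings(wilcox.test(a, b))$p.value
      data.frame(cat1 = pr[1], cat2 = pr[2], p = p)
    }))
    out$q <- fdr_correct(out$p)
    out
  }
  prop_pw <- pw(props$prop, props$category)
  lag_col <- paste0(lag_term, "_lag")
  dl <- d[d$category %in% present & !is.na(d[[lag_col]]), , drop = FALSE]
  lag_summary <- do.call(rbind, lapply(split(dl, dl$category), function(g)
    data.frame(category = g$category[1], n = nrow(g),
               median_lag = median(g[[lag_col]]),
               iqr_lo = unname(quantile(g[[lag_col]], 0.25)),
               iqr_hi = unname(quantile(g[[lag_col]], 0.75)))))
  rownames(lag_summary) <- NULL
  lag_kw <- if (length(unique(dl$category)) >= 2)
    kruskal.test(dl[[lag_col]], factor(dl$category)) else NULL
  lag_pw <- if (length(unique(dl$category)) >= 2)
    pw(dl[[lag_col]], dl$category) else NULL
  list(proportions = props,
       prop_kruskal = list(chi2 = unname(kw_p$statistic),
                           df = unname(kw_p$parameter), p = kw_p$p.value),
       prop_pairwise = prop_pw,
       lag_summary = lag_summary,
       lag_kruskal = if (is.null(lag_kw)) NULL
         else list(chi2 = unname(lag_kw$statistic),
                   df = unname(lag_kw$parameter), p = lag_kw$p.value),
       lag_pairwise = lag_pw)
}
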