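#' Long window-level HFA table for a cohort region
#'
#' Stacks window-averaged HFA (0-0.6 s grid, 23 windows) for all channels of
#' one region into the long table consumed by [fit_window_models()], joined
#' with each trial's RL variables.
#'
#' @param cohort A [generate_cohort()] result.
#' @param region `"dMPFC"` or `"INS"`.
#' @return Data frame: `subject`, `channel`, `sub_chan`, `trial`, `window`
#'   (start, ms), `hfa`, `ev`, `srpe`, `urpe`, `prpe`, `nrpe`.
#' @export
window_table <- function(cohort, region) {
  chans <- cohort$channels[cohort$channels$region == region, , drop = FALSE]
  if (nrow(chans) == 0) stop_contract("no channels in region ", region)
  rows <- lapply(seq_len(nrow(chans)), function(i) {
    sid <- chans$subject[i]; ch <- chans$channel[i]
    env <- cohort$envelopes[[sid]][[ch]]
    win <- window_average(env, cohort$time_grid)
    rl <- cohort$trials[[sid]]
    n_tr <- nrow(win); n_w <- ncol(win)
    data.frame(subject = sid, channel = ch,
               sub_chan = ch,  # channel ids are globally unique
               trial = rep(rl$trial_index, n_w),
               window = rep(as.integer(colnames(win)), each = n_tr),
               hfa = as.vector(win),
               ev = rep(rl$ev, n_w), srpe = rep(rl$srpe, n_w),
               urpe = rep(rl$urpe, n_w), prpe = rep(rl$prpe, n_w),
               nrpe = rep(rl$nrpe, n_w))
  })
  out <- do.call(rbind, rows)
  out[complete.cases(out[c("hfa", "ev", "srpe")]), , drop = FALSE]
}

#' Encoding model specifications
#'
#' The three competing single-trial HFA models: RPE value (signed RPE + EV),
#' RPE salience (unsigned RPE + EV), and the asymmetric model with separate
#' positive and negative RPE magnitudes. Random-effect structure follows the
#' nested subject / subject:channel scheme; `random` controls how rich it is:
#' `"full"` puts intercepts and predictor slopes at both levels, `"channel"`
#' keeps slopes at the channel level only (with a subject intercept), and
#' `"intercept"` uses intercepts only.
#'
#' @param random One of `"full"`, `"channel"`, `"intercept"`.
#' @return Named list of formulas (`value`, `salience`, `asymmetric`).
#' @export
encoding_model_specs <- function(random = c("full", "channel", "intercept")) {
  random <- match.arg(random)
  terms <- list(value = "srpe + ev", salience = "urpe + ev",
                asymmetric = "nrpe + prpe + ev")
  lapply(terms, function(tt) {
    re <- switch(random,
      full = sprintf("(1 + %s | subject) + (1 + %s | sub_chan)", tt, tt),
      channel = sprintf("(1 | subject) + (1 + %s | sub_chan)", tt),
      intercept = "(1 | subject) + (1 | sub_chan)")
    as.formula(paste("hfa ~", tt, "+", re))
  })
}

#' Window-wise mixed-model fits of HFA encoding models
#'
#' Fits the requested encoding models separately in each post-feedback time
#' window, collecting fixed-effect coefficient time courses (with
#' Benjamini-Hochberg q-values across windows, per term and model) and AIC per
#' window and model. Models within a window are fit to identical rows, so
#' their AICs are directly comparable.
#'
#' @param win_table Output of [window_table()] (one region).
#' @param models Subset of `c("value", "salience", "asymmetric")`.
#' @param random Random-structure richness, see [encoding_model_specs()].
#' @param windows Window starts (ms) to fit (default: all present).
#' @param robust Robust (Huber-reweighted) fits.
#' @return List of class `window_model_results`: `fixed` (data.frame with
#'   window, model, term, estimate, se, ci_lo, ci_hi, p, q, aic), `aic`
#'   (window x model data.frame), `fits` (named `list[[model]][[window]]`).
#' @export
fit_window_models <- function(win_table, models = c("value", "salience",
                                                    "asymmetric"),
                              random = "full", windows = NULL,
                              robust = FALSE) {
  if (length(unique(win_table$subject)) < 2)
    stop_contract("need at least 2 subjects")
  specs <- encoding_model_specs(random)[models]
  if (is.null(windows)) windows <- sort(unique(win_table$window))
  fits <- lapply(models, function(m) {
    setNames(lapply(windows, function(w) {
      d <- win_table[win_table$window == w, , drop = FALSE]
      fit_lmm(specs[[m]], d, robust = robust)
    }), as.character(windows))
  })
  names(fits) <- models
  fixed <- do.call(rbind, lapply(models, function(m) {
    do.call(rbind, lapply(as.character(windows), function(w) {
      f <- fits[[m]][[w]]
      cbind(window = as.integer(w), model = m, f$fixed, aic = f$aic)
    }))
  }))
  # BH across windows per model x term
  fixed$q <- NA_real_
  for (m in models) for (tm in unique(fixed$term)) {
    sel <- fixed$model == m & fixed$term == tm
    if (any(sel)) fixed$q[sel] <- fdr_correct(fixed$p[sel])
  }
  aic <- do.call(rbind, lapply(as.character(windows), function(w) {
    data.frame(window = as.integer(w),
               setNames(lapply(models, function(m) fits[[m]][[w]]$aic),
                        models))
  }))
  structure(list(fixed = fixed, aic = aic, fits = fits,
                 windows = windows, models = models),
            class = "window_model_results")
}

#' Per-window AIC model ranking
#'
#' @param results A [fit_window_models()] result (all models fit on identical
#'   rows per window).
#' @return Data frame: `window`, per-model AIC, `winner`, `delta_aic` (margin
#'   of the winner over the runner-up).
#' @export
compare_models_aic <- function(results) {
  aic <- results$aic
  mods <- results$models
  if (length(mods) < 2) stop_contract("need at least two models to compare")
  n_obs <- vapply(mods, function(m) results$fits[[m]][[1]]$n_obs, 0)
  if (length(unique(n_obs)) != 1)
    stop_contract("models were fit to different rows; AIC not comparable")
  vals <- as.matrix(aic[mods])
  win <- mods[apply(vals, 1, which.min)]
  d <- apply(vals, 1, function(v) sort(v)[2] - min(v))
  cbind(aic, winner = win, delta_aic = d)
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up q-values controlling the FDR; monotone in the sorted p-values.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Vector of q-values, same length and order.
#' @export
fdr_correct <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_contract("p-values outside [0,1]")
  p.adjust(p, method = "BH")
}

#' Channel-level conditional coefficient time courses
#'
#' Extracts per-channel conditional (BLUP) coefficients of the asymmetric
#' model's terms in every window: fixed effect plus subject and
#' subject:channel deviations, with conditional SEs and uncorrected two-sided
#' p-values (the shrinkage of conditional modes is relied on for
#' conservatism, so no multiplicity correction is applied at channel level).
#'
#' @param results A [fit_window_models()] result including the asymmetric
#'   model with channel-level random slopes.
#' @param terms Fixed terms to extract (default `prpe`, `nrpe`).
#' @return Data frame: `channel` (sub_chan id), `subject`, `window`, `term`,
#'   `estimate`, `se`, `p`.
#' @export
extract_channel_coefficients <- function(results, terms = c("prpe", "nrpe")) {
  if (!"asymmetric" %in% names(results$fits))
    stop_contract("asymmetric model fits required")
  out <- do.call(rbind, lapply(as.character(results$windows), function(w) {
    fit <- results$fits$asymmetric[[w]]
    d <- fit$model@frame
    nest <- setNames(as.character(d$subject), as.character(d$sub_chan))
    nest <- nest[!duplicated(names(nest))]
    cc <- conditional_coefficients(fit, terms, unit = "sub_chan",
                                   nest_map = nest)
    data.frame(channel = cc$unit, subject = unname(nest[cc$unit]),
               window = as.integer(w), term = cc$term,
               estimate = cc$estimate, se = cc$se, p = cc$p)
  }))
  rownames(out) <- NULL
  out
}

# Shared four-category decision table for channels and channel pairs.
# Inputs: per-term significance flags and peak (max |estimate|) signed values.
classify_from_peaks <- function(sig_p, sig_n, peak_p, peak_n) {
  if (!sig_p && !sig_n) return(c(category = "none", polarity = "none"))
  if (sig_p && !sig_n)
    return(c(category = "pRPE",
             polarity = if (peak_p > 0) "regular" else "inverted"))
  if (!sig_p && sig_n)
    return(c(category = "nRPE",
             polarity = if (peak_n < 0) "regular" else "inverted"))
  if (sign(peak_p) != sign(peak_n))
    return(c(category = "sRPE",
             polarity = if (peak_p > 0) "regular" else "inverted"))
  c(category = "uRPE",
    polarity = if (peak_p > 0) "increasing" else "decreasing")
}

#' Classify channels into RPE responsiveness categories
#'
#' Applies the four-category scheme: a channel is significantly responsive to
#' a term if any window has conditional p < `alpha`; the channel's peak
#' coefficient per term is the significant-window estimate of maximum absolute
#' value (ties resolved to the earliest window). Channels responsive to only
#' one valence are pRPE or nRPE; responsiveness to both with opposite peak
#' signs is signed RPE, with equal signs unsigned RPE. Polarity is `regular`
#' when HFA rises with pRPE magnitude / falls with nRPE magnitude, `inverted`
#' otherwise; uRPE channels are labeled `increasing`/`decreasing`.
#'
#' @param coef_series Output of [extract_channel_coefficients()].
#' @param alpha Channel-level significance threshold (default 0.05,
#'   uncorrected).
#' @return Data frame per channel: `channel`, `subject`, `category`,
#'   `polarity`, peak estimates and windows per term.
#' @export
classify_channels <- function(coef_series, alpha = 0.05) {
  one <- function(d) {
    peak_of <- function(tm) {
      dd <- d[d$term == tm & d$p < alpha, , drop = FALSE]
      if (nrow(dd) == 0) return(c(est = 0, win = NA_real_, sig = 0))
      i <- which.max(abs(dd$estimate))
      c(est = dd$estimate[i], win = dd$window[i], sig = 1)
    }
    pp <- peak_of("prpe"); pn <- peak_of("nrpe")
    cls <- classify_from_peaks(pp["sig"] > 0, pn["sig"] > 0,
                               pp["est"], pn["est"])
    data.frame(channel = d$channel[1], subject = d$subject[1],
               category = unname(cls["category"]),
               polarity = unname(cls["polarity"]),
               peak_prpe = unname(pp["est"]), peak_prpe_win = unname(pp["win"]),
               peak_nrpe = unname(pn["est"]), peak_nrpe_win = unname(pn["win"]))
  }
  out <- do.call(rbind, lapply(split(coef_series, coef_series$channel), one))
  rownames(out) <- NULL
  out
}

#' Region and category proportion statistics
#'
#' Per-subject, per-region proportions of channels in each responsive
#' category, compared between regions with Wilcoxon signed-rank tests
#' (FDR-corrected over the four categories; subjects lacking a region are
#' excluded), then averaged across regions and compared between categories
#' with a Kruskal-Wallis test followed by FDR-corrected pairwise signed-rank
#' tests.
#'
#' @param categories Data frame with `subject`, `channel`, `category`.
#' @param regions Named character vector mapping channel id to region, or a
#'   `region` column already present in `categories`.
#' @return List: `proportions` (subject x region x category), `region_tests`,
#'   `kruskal`, `pairwise`.
#' @export
category_proportion_stats <- function(categories, regions = NULL) {
  d <- categories
  if (!is.null(regions)) d$region <- unname(regions[d$channel])
  if (!"region" %in% names(d)) stop_contract("region information required")
  cats <- c("pRPE", "nRPE", "sRPE", "uRPE")
  props <- do.call(rbind, lapply(split(d, list(d$subject, d$region),
                                       drop = TRUE), function(g) {
    n <- nrow(g)
    data.frame(subject = g$subject[1], region = g$region[1],
               category = cats,
               prop = vapply(cats, function(cc) mean(g$category == cc), 0))
  }))
  rownames(props) <- NULL
  if (all(props$prop == 0)) {
    warning("all category proportions are zero; tests skipped")
    return(list(proportions = props, region_tests = NULL, kruskal = NULL,
                pairwise = NULL))
  }
  # subject x region x category array keeps paired tests aligned by subject
  arr <- tapply(props$prop, list(props$subject, props$region, props$category),
                mean)
  both <- rownames(arr)[rowSums(is.na(arr[, , 1, drop = FALSE])) == 0]
  region_tests <- NULL
  if (length(both) >= 2 && dim(arr)[2] == 2) {
    rg <- dimnames(arr)[[2]]
    region_tests <- do.call(rbind, lapply(cats, function(cc) {
      a <- arr[both, rg[1], cc]; b <- arr[both, rg[2], cc]
      p <- if (all(a == b)) 1
        else suppressWarnings(wilcox.test(a, b, paired = TRUE))$p.value
      data.frame(category = cc, p = p)
    }))
    region_tests$q <- fdr_correct(region_tests$p)
  }
  avg_mat <- apply(arr, c(1, 3), mean, na.rm = TRUE)  # subject x category
  avg <- data.frame(subject = rep(rownames(avg_mat), ncol(avg_mat)),
                    category = rep(colnames(avg_mat), each = nrow(avg_mat)),
                    prop = as.vector(avg_mat))
  kw <- kruskal.test(prop ~ factor(category), data = avg)
  pw <- do.call(rbind, lapply(utils::combn(cats, 2, simplify = FALSE),
                              function(pair) {
    a <- avg_mat[, pair[1]]; b <- avg_mat[, pair[2]]
    p <- if (all(a == b)) 1
      else suppressWarnings(wilcox.test(a, b, paired = TRUE))$p.value
    data.frame(cat1 = pair[1], cat2 = pair[2], p = p)
  }))
  pw$q <- fdr_correct(pw$p)
  list(proportions = props, region_tests = region_tests,
       kruskal = list(chi2 = unname(kw$statistic), df = unname(kw$parameter),
                      p = kw$p.value),
       pairwise = pw)
}

#' Spatial gradient test via multinomial logistic regression
#'
#' Tests whether category membership varies along the x, y, z electrode
#' coordinates: multinomial logistic regression of category on the three
#' coordinates with uRPE as the reference category, reporting Wald z-test
#' p-values per coordinate and category. Categories with fewer than two
#' members are removed with a warning; with fewer than two categories left no
#' test is run.
#'
#' @param categories Data frame with `channel`, `category` (responsive
#'   categories; `none` rows are ignored).
#' @param xyz Data frame or matrix with `channel` ids and `x`, `y`, `z`, or
#'   columns already present in `categories`.
#' @return Data frame `category`, `coord`, `estimate`, `se`, `p`, or `NULL`
#'   (with a warning) when degenerate.
#' @export
spatial_gradient_test <- function(categories, xyz = NULL) {
  d <- categories[categories$category != "none", , drop = FALSE]
  if (!is.null(xyz))
    d <- merge(d, as.data.frame(xyz), by = "channel")
  if (!all(c("x", "y", "z") %in% names(d)))
    stop_contract("x/y/z coordinates required")
  tab <- table(d$category)
  small <- names(tab)[tab < 2]
  if (length(small)) {
    warning("removing categories with < 2 members: ",
            paste(small, collapse = ", "))
    d <- d[!d$category %in% small, , drop = FALSE]
  }
  if (length(unique(d$category)) < 2) {
    warning("fewer than two categories present; no spatial gradient test")
    return(NULL)
  }
  d$category <- stats::relevel(factor(d$category), ref =
    if ("uRPE" %in% d$category) "uRPE" else levels(factor(d$category))[1])
  fit <- nnet::multinom(category ~ x + y + z, data = d, trace = FALSE)
  cf <- coef(fit)
  se <- summary(fit)$standard.errors
  if (is.null(dim(cf))) {  # two categories: vector
    cf <- matrix(cf, 1, dimnames = list(levels(d$category)[2], names(cf)))
    se <- matrix(se, 1, dimnames = dimnames(cf))
  }
  out <- expand.grid(category = rownames(cf), coord = c("x", "y", "z"),
                     stringsAsFactors = FALSE)
  out$estimate <- mapply(function(cc, co) cf[cc, co], out$category, out$coord)
  out$se <- mapply(function(cc, co) se[cc, co], out$category, out$coord)
  out$p <- 2 * pnorm(-abs(out$estimate / out$se))
  out
}

#' Rank-based inverse-normal (rankit) transform
#'
#' Maps values to normal quantiles by rank: \eqn{\Phi^{-1}((r - 0.5)/n)} with
#' average ranks for ties. Used as a normality sensitivity analysis for model
#' residuals.
#'
#' @param values Numeric vector without missing values.
#' @return Transformed vector, same order.
#' @export
rankit_transform <- function(values) {
  if (anyNA(values)) stop_contract("missing values not allowed")
  n <- length(values)
  if (n == 0) return(numeric(0))
  qnorm((rank(values, ties.method = "average") - 0.5) / n)
}
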