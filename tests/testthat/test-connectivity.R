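test_that("lag grid is symmetric on the 25 ms step", {
  lg <- lag_grid()
  expect_length(lg, 33)
  expect_equal(lg, -rev(lg))
  expect_true(all(diff(lg) == 25))
  expect_error(lag_grid(max_ms = 390), "divide")
})

test_that("lagged cross-correlation honors the sign convention", {
  tg <- seq(0, 1, by = 0.025)
  set.seed(1)
  x <- matrix(rnorm(20 * length(tg)), 20)
  # identical series: r = 1 at lag 0
  r <- trial_lagged_xcorr(x, x, tg)
  expect_true(all(abs(r[, "0"] - 1) < 1e-12))
  # dmpfc = ins shifted later by 75 ms -> per-trial peak at +75 (INS leads)
  shift <- 3  # samples
  dm <- cbind(matrix(rnorm(20 * shift, 0, 1e-8), 20), x[, 1:(ncol(x) - shift)])
  r2 <- trial_lagged_xcorr(x, dm, tg)
  peaks <- as.integer(colnames(r2))[apply(abs(r2), 1, which.max)]
  expect_true(all(peaks == 75))
  # independent noise: mean r near zero at every lag
  set.seed(2)
  y <- matrix(rnorm(20 * length(tg)), 20)
  r3 <- trial_lagged_xcorr(x, y, tg)
  expect_lt(max(abs(colMeans(r3, na.rm = TRUE))), 0.2)
  expect_lt(abs(mean(colMeans(r3, na.rm = TRUE))), 0.05)
  # overlap shrinks with |lag|; short overlaps are dropped as NA
  ov <- attr(r3, "n_overlap")
  expect_true(all(diff(ov[1:17]) > 0))  # rising toward lag 0
  r4 <- trial_lagged_xcorr(x[, 1:20], dm[, 1:20], tg[1:20],
                           lags = c(-375, 0, 375))
  expect_true(all(is.na(r4[, "-375"])))
  expect_false(anyNA(r4[, "0"]))
  # zero-variance segments give NA rather than an error
  x0 <- x; x0[1, ] <- 5
  r5 <- trial_lagged_xcorr(x0, y, tg)
  expect_true(is.na(r5[1, "0"]))
})

test_that("peak-lag extraction takes the absolute maximum, earliest on ties", {
  d <- data.frame(pair = "p1", subject = "S01",
                  lag = seq(-100, 100, by = 25),
                  term = "prpe",
                  estimate = c(0, 0.1, -0.2, 0, 0.5, 0, 0.3, -0.1, 0),
                  se = 0.1, p = 0.01)
  pk <- extract_peak_lag(d)
  expect_equal(pk$peak_lag, 0)
  expect_equal(pk$peak_estimate, 0.5)
  # tie on |estimate|: earliest (most negative) lag wins
  d2 <- d; d2$estimate <- c(0, 0.5, 0, 0, 0.5, 0, 0, 0, 0)
  expect_equal(extract_peak_lag(d2)$peak_lag, -75)
  # all-zero series: tie-break lag, zero estimate
  d3 <- d; d3$estimate <- 0; d3$p <- 0.9
  pk3 <- extract_peak_lag(d3)
  expect_equal(pk3$peak_estimate, 0)
  expect_equal(pk3$peak_lag, -100)
})

test_that("pair classification shares the channel decision table", {
  mk_peaks <- function(p_est, p_p, n_est, n_p)
    data.frame(pair = "p1", subject = "S01", term = c("prpe", "nrpe"),
               peak_estimate = c(p_est, n_est), peak_lag = c(75, 0),
               peak_p = c(p_p, n_p))
  expect_identical(classify_pairs(mk_peaks(0.3, 0.01, 0.1, 0.4))$category,
                   "pRPE")
  # decreasing correlation with prpe -> inverted pRPE
  cl_inv <- classify_pairs(mk_peaks(-0.3, 0.01, 0.1, 0.4))
  expect_identical(cl_inv$category, "pRPE")
  expect_identical(cl_inv$polarity, "inverted")
  # both terms significant with equal signs -> uRPE
  expect_identical(classify_pairs(mk_peaks(0.3, 0.01, 0.2, 0.02))$category,
                   "uRPE")
  expect_identical(classify_pairs(mk_peaks(0.3, 0.01, -0.2, 0.02))$category,
                   "sRPE")
  expect_identical(classify_pairs(mk_peaks(0.1, 0.4, 0.1, 0.6))$category,
                   "none")
})

test_that("per-lag mixed models recover a planted EV-only modulation", {
  cfg <- cohort_config(n_subjects = 2, channels_per_region = c(dMPFC = 0,
                                                               INS = 0),
                       n_pairs = 3,
                       coupling = list(mix = "pRPE", lag_ms = 75,
                                       base_r = 0.4, mod_scale = 0.1,
                                       mod_jitter = 0.2, noise_sd = 1))
  # replace prpe modulation by ev modulation at generation time
  cfg$coupling$mix <- "none"
  coh <- generate_cohort(cfg, seed = 4)
  for (sid in names(coh$pairs)) for (pj in seq_along(coh$pairs[[sid]])) {
    sp <- coh$pairs[[sid]][[pj]]$spec
    sp$mod_gains <- c(ev = 0.1, prpe = 0, nrpe = 0)
    set.seed(1000 + pj)
    coh$pairs[[sid]][[pj]][c("ins", "dmpfc")] <-
      simulate_coupled_pair(sp, coh$trials[[sid]], coh$time_grid)
  }
  xt <- pair_xcorr_table(coh, lags = seq(25, 125, by = 25))
  lmr <- fit_lag_models(xt, random = "intercept")
  fx <- lmr$fixed[lmr$fixed$lag == 75, ]
  expect_gt(fx$estimate[fx$term == "ev"], 0.05)
  expect_lt(fx$p[fx$term == "ev"], 0.001)
  # no leakage into the RPE magnitude terms beyond noise
  expect_gt(fx$p[fx$term == "prpe"], 0.01)
  expect_gt(fx$p[fx$term == "nrpe"], 0.01)
  # FDR across lags never lowers p
  expect_true(all(lmr$fixed$q >= lmr$fixed$p - 1e-12))
})

test_that("category statistics detect planted lag differences", {
  set.seed(5)
  subs <- rep(sprintf("S%02d", 1:8), each = 6)
  cats <- rep(c("uRPE", "uRPE", "sRPE", "pRPE", "pRPE", "none"), 8)
  lags <- ifelse(cats == "uRPE", 100, ifelse(cats == "sRPE", -180, 50)) +
    sample(c(-25, 0, 25), length(cats), replace = TRUE)
  pc <- data.frame(pair = paste0(subs, "_p", seq_along(subs)), subject = subs,
                   category = cats, polarity = "regular",
                   prpe_peak = 0.1, prpe_lag = lags,
                   nrpe_peak = 0.05, nrpe_lag = lags)
  st <- connectivity_category_stats(pc)
  expect_lt(st$prop_kruskal$p, 0.05)   # none category depresses sRPE props
  expect_lt(st$lag_kruskal$p, 0.001)
  lp <- st$lag_pairwise
  expect_lt(lp$q[lp$cat1 == "sRPE" & lp$cat2 == "uRPE"], 0.05)
  med <- st$lag_summary
  expect_lt(abs(med$median_lag[med$category == "uRPE"] - 100), 26)
  expect_lt(abs(med$median_lag[med$category == "sRPE"] + 180), 26)
  # single-category input degenerates with a warning
  expect_warning(st0 <- connectivity_category_stats(pc[pc$category == "uRPE", ]),
                 "degenerate")
  expect_null(st0$prop_kruskal)
})
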