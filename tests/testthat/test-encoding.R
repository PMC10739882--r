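test_that("the four-category decision table is exhaustive and exclusive", {
  classify <- asymrpe:::classify_from_peaks
  # enumerate significance flags and peak signs
  got <- list()
  for (sp in c(TRUE, FALSE)) for (sn in c(TRUE, FALSE))
    for (pp in c(-1, 1)) for (pn in c(-1, 1)) {
      cls <- classify(sp, sn, pp * 0.3, pn * 0.2)
      expect_true(cls["category"] %in% c("pRPE", "nRPE", "sRPE", "uRPE",
                                         "none"))
      got[[paste(sp, sn, pp, pn)]] <- unname(cls["category"])
    }
  # no significance -> none regardless of signs
  expect_true(all(unlist(got[grep("FALSE FALSE", names(got))]) == "none"))
  # single-term significance maps to that term's category
  expect_true(all(unlist(got[grep("TRUE FALSE", names(got))]) == "pRPE"))
  expect_true(all(unlist(got[grep("FALSE TRUE", names(got))]) == "nRPE"))
  # joint significance splits by peak-sign agreement
  expect_identical(got[["TRUE TRUE 1 1"]], "uRPE")
  expect_identical(got[["TRUE TRUE -1 -1"]], "uRPE")
  expect_identical(got[["TRUE TRUE 1 -1"]], "sRPE")
  expect_identical(got[["TRUE TRUE -1 1"]], "sRPE")
})

test_that("channel classification applies polarity and peak tie-breaks", {
  # only prpe significant with positive peak -> regular pRPE
  s <- fake_coef_series("c1", prpe_est = c(0.1, 0.5, 0.2),
                        prpe_p = c(0.2, 0.001, 0.03),
                        nrpe_est = c(0, 0.1, 0), nrpe_p = c(0.9, 0.4, 0.8))
  cl <- classify_channels(s)
  expect_identical(cl$category, "pRPE")
  expect_identical(cl$polarity, "regular")
  expect_equal(cl$peak_prpe, 0.5)
  expect_equal(cl$peak_prpe_win, 25)
  # only nrpe significant with positive peak -> inverted nRPE
  s2 <- fake_coef_series("c2", prpe_est = c(0, 0, 0), prpe_p = rep(0.5, 3),
                         nrpe_est = c(0.4, 0.2, 0.1), nrpe_p = c(0.01, 0.2, 0.6))
  cl2 <- classify_channels(s2)
  expect_identical(cl2$category, "nRPE")
  expect_identical(cl2$polarity, "inverted")
  # both significant, peaks (+, -) -> regular sRPE; (+, +) -> increasing uRPE
  s3 <- fake_coef_series("c3", prpe_est = c(0.5, 0.1, 0), prpe_p = c(0.01, 0.5, 0.9),
                         nrpe_est = c(-0.4, 0, 0), nrpe_p = c(0.02, 0.9, 0.9))
  expect_identical(classify_channels(s3)$category, "sRPE")
  expect_identical(classify_channels(s3)$polarity, "regular")
  s4 <- fake_coef_series("c4", prpe_est = c(0.5, 0, 0), prpe_p = c(0.01, 0.9, 0.9),
                         nrpe_est = c(0.4, 0, 0), nrpe_p = c(0.02, 0.9, 0.9))
  expect_identical(classify_channels(s4)$category, "uRPE")
  expect_identical(classify_channels(s4)$polarity, "increasing")
  # the peak is selected among significant windows only
  s5 <- fake_coef_series("c5", prpe_est = c(0.9, 0.3, 0),
                         prpe_p = c(0.5, 0.01, 0.9),
                         nrpe_est = c(0, 0, 0), nrpe_p = rep(0.9, 3))
  expect_equal(classify_channels(s5)$peak_prpe, 0.3)
})

test_that("BH q-values match an independent brute-force step-up", {
  expect_identical(fdr_correct(numeric(0)), numeric(0))
  expect_equal(fdr_correct(rep(1, 5)), rep(1, 5))
  expect_equal(fdr_correct(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(1)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    expect_equal(fdr_correct(p), bh_bruteforce(p), tolerance = 1e-12)
  }
  expect_error(fdr_correct(c(0.5, 1.2)), "outside")
  # FDR control under the global null
  set.seed(2)
  fp <- replicate(200, mean(fdr_correct(runif(23)) < 0.05))
  expect_lte(mean(fp), 0.05)
})

test_that("window models recover planted gains and rank by AIC", {
  cfg <- cohort_config(n_subjects = 3, channels_per_region = c(dMPFC = 0,
                                                               INS = 3),
                       category_mix = c("pRPE", "uRPE", "nRPE"))
  coh <- generate_cohort(cfg, seed = 3)
  wt <- window_table(coh, "INS")
  expect_error(window_table(coh, "dMPFC"), "no channels")
  peak_w <- 275  # INS kernel peak window
  wmr <- fit_window_models(wt, random = "channel", windows = c(25, peak_w))
  expect_s3_class(wmr, "window_model_results")
  # fixed prpe at the peak approximates the mean planted positive gain
  fx <- wmr$fixed
  est_p <- fx$estimate[fx$model == "asymmetric" & fx$term == "prpe" &
                         fx$window == peak_w]
  true_mean_gp <- mean(coh$channels$g_p)
  expect_lt(abs(est_p - true_mean_gp), 0.12)
  # early window carries little signal
  est_p0 <- fx$estimate[fx$model == "asymmetric" & fx$term == "prpe" &
                          fx$window == 25]
  expect_lt(abs(est_p0), abs(est_p))
  # value-model srpe is attenuated relative to asymmetric prpe
  est_s <- fx$estimate[fx$model == "value" & fx$term == "srpe" &
                         fx$window == peak_w]
  expect_lt(abs(est_s), abs(est_p))
  # q-values are BH over windows and never smaller than p
  expect_true(all(fx$q >= fx$p - 1e-12))
  rank <- compare_models_aic(wmr)
  expect_true(all(c("winner", "delta_aic") %in% names(rank)))
  expect_true(all(rank$delta_aic >= 0))
  # AIC comparability requires identical rows
  wmr_bad <- wmr
  wmr_bad$fits$value[[1]]$n_obs <- wmr_bad$fits$value[[1]]$n_obs - 1
  expect_error(compare_models_aic(wmr_bad), "different rows")
  # conditional series carry one row per channel x window x term
  cc <- extract_channel_coefficients(wmr)
  expect_equal(nrow(cc), 9 * 2 * 2)
  expect_true(all(cc$channel %in% coh$channels$channel))
  expect_identical(unique(cc$subject[cc$channel == "S02_INS_ch01"]), "S02")
})

test_that("category proportion statistics detect planted prevalence", {
  # identical proportions in both regions: all region differences are ties
  subs <- sprintf("S%02d", 1:10)
  mk <- function(sub, region, cats)
    data.frame(subject = sub, region = region,
               channel = paste0(sub, region, seq_along(cats)),
               category = cats)
  same <- do.call(rbind, lapply(subs, function(s)
    rbind(mk(s, "dMPFC", c("pRPE", "uRPE", "nRPE", "sRPE")),
          mk(s, "INS", c("pRPE", "uRPE", "nRPE", "sRPE")))))
  st <- category_proportion_stats(same)
  expect_true(all(st$region_tests$p == 1))
  # perfectly balanced categories: the test statistic is degenerate (all
  # proportions identical), so p is NaN or near 1
  expect_true(is.na(st$kruskal$p) || st$kruskal$p > 0.9)
  # planted 3x pRPE prevalence shows up in the pairwise contrast
  set.seed(4)
  skew <- do.call(rbind, lapply(subs, function(s) {
    cats <- sample(c(rep("pRPE", 6), rep("nRPE", 2), rep("uRPE", 4),
                     rep("sRPE", 2), rep("none", 2)))
    rbind(mk(s, "dMPFC", cats), mk(s, "INS", cats))
  }))
  st2 <- category_proportion_stats(skew)
  expect_lt(st2$kruskal$p, 0.01)
  pw <- st2$pairwise
  expect_lt(pw$q[(pw$cat1 == "nRPE" & pw$cat2 == "pRPE") |
                   (pw$cat1 == "pRPE" & pw$cat2 == "nRPE")], 0.05)
  # degenerate all-zero proportions are skipped with a warning
  none_only <- do.call(rbind, lapply(subs[1:3], function(s)
    mk(s, "dMPFC", rep("none", 4))))
  expect_warning(st3 <- category_proportion_stats(none_only), "skipped")
  expect_null(st3$kruskal)
})

test_that("spatial gradient test recovers a planted anterior gradient", {
  set.seed(5)
  n <- 240
  xyz <- data.frame(channel = paste0("c", 1:n),
                    x = rnorm(n, 0, 8), y = rnorm(n, 0, 8), z = rnorm(n, 0, 8))
  # pRPE probability rises along y; uRPE is the reference
  p_prpe <- plogis(-0.5 + 0.25 * xyz$y)
  cat <- ifelse(runif(n) < p_prpe, "pRPE", "uRPE")
  res <- spatial_gradient_test(data.frame(channel = xyz$channel,
                                          category = cat), xyz)
  y_row <- res[res$category == "pRPE" & res$coord == "y", ]
  expect_lt(y_row$p, 0.01)
  expect_gt(y_row$estimate, 0)
  # categories independent of location: no strong gradient expected
  set.seed(6)
  ps <- replicate(10, {
    cat0 <- sample(c("pRPE", "uRPE"), n, replace = TRUE)
    r <- spatial_gradient_test(data.frame(channel = xyz$channel,
                                          category = cat0), xyz)
    mean(r$p)
  })
  expect_gt(mean(ps), 0.2)
  # degenerate inputs
  expect_warning(
    expect_null(spatial_gradient_test(
      data.frame(channel = xyz$channel[1:5], category = "pRPE",
                 x = 1:5, y = 1:5, z = 1:5))),
    "fewer than two")
  expect_warning(spatial_gradient_test(
    data.frame(channel = xyz$channel[1:20],
               category = c(rep("pRPE", 10), rep("uRPE", 9), "sRPE"),
               x = rnorm(20), y = rnorm(20), z = rnorm(20))),
    "< 2 members")
})

test_that("rankit transform normalizes while preserving order", {
  expect_equal(rankit_transform(0.7), 0)  # single value maps to the median
  expect_identical(rankit_transform(numeric(0)), numeric(0))
  set.seed(7)
  x <- rnorm(1000)
  expect_gt(cor(x, rankit_transform(x)), 0.99)
  # heavy-tailed input passes a normality check only after transformation
  y <- rt(500, df = 1)
  expect_lt(shapiro.test(y)$p.value, 1e-6)
  expect_gt(shapiro.test(rankit_transform(y))$p.value, 0.05)
  # ties share the average rank
  z <- rankit_transform(c(1, 1, 2))
  expect_equal(z[1], z[2])
  expect_error(rankit_transform(c(1, NA)), "missing")
})
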