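#' Fit a linear mixed model with reporting conventions used throughout
#'
#' Thin wrapper around [lme4::lmer()] that standardizes how models are fit and
#' summarized across the behavioral and neural analyses: maximum likelihood by
#' default (so log-likelihoods, AIC and likelihood-ratio tests are comparable
#' across nested fits), Wald fixed-effect tests (Satterthwaite degrees of
#' freedom via lmerTest on request, normal approximation otherwise), and an
#' optional robust refit that iteratively downweights observations with large
#' standardized residuals (Huber weights) to protect against heavy-tailed
#' residuals.
#'
#' Singular (boundary) random-effect fits are retained — they are the ML
#' solution, and replacing the covariance structure under one member of a
#' nested pair would invalidate likelihood-ratio comparisons. When the
#' optimizer genuinely fails, the model is refit with a diagonal
#' (uncorrelated) random covariance and flagged via `converged = FALSE`. If
#' every grouping factor has fewer than two levels the model degenerates to
#' ordinary least squares.
#'
#' @param formula Model formula in Wilkinson notation, with random terms as in
#'   lme4, e.g. `y ~ x + (1 + x | subject)`.
#' @param data Data frame with no missing values in the model variables.
#' @param robust Iteratively reweight large residuals (default FALSE).
#' @param reml Use REML (default FALSE: ML, required for LRT/AIC comparison).
#' @param satterthwaite Use lmerTest Satterthwaite df for fixed-effect p-values
#'   (default FALSE: normal approximation, much faster for windowed fits).
#' @return An object of class `lmm_fit`: list with `model` (the merMod or lm),
#'   `fixed` (data.frame of term, estimate, se, ci_lo, ci_hi, p), `loglik`,
#'   `aic`, `n_params`, `n_obs`, `converged`, `robust_weights`.
#' @export
fit_lmm <- function(formula, data, robust = FALSE, reml = FALSE,
                    satterthwaite = FALSE) {
  vars <- all.vars(formula)
  miss <- vars[!vars %in% names(data)]
  if (length(miss))
    stop_contract("model variables missing from data: ",
                  paste(miss, collapse = ", "))
  if (anyNA(data[vars]))
    stop_contract("missing values in model variables")

  bars <- lme4::findbars(formula)
  grp_vars <- unique(vapply(bars, function(b) deparse(b[[3]]), ""))
  # a single grouping level or a constant response cannot support random
  # effects; fall back to ordinary least squares on the fixed part
  response <- data[[deparse(formula[[2]])]]
  degenerate_groups <- length(bars) > 0 &&
    (all(vapply(grp_vars, function(g) length(unique(data[[g]])) < 2, TRUE)) ||
       var(response) == 0)

  fitter <- function(f, w = NULL) {
    if (degenerate_groups || length(bars) == 0) {
      fixed_f <- lme4::nobars(f)
      if (is.null(w)) lm(fixed_f, data = data)
      else lm(fixed_f, data = data, weights = w)
    } else {
      data$.w <- if (is.null(w)) rep(1, nrow(data)) else w
      suppressMessages(suppressWarnings(
        lme4::lmer(f, data = data, REML = reml, weights = .w,
                   control = lme4::lmerControl(calc.derivs = FALSE,
                                               check.conv.singular = "ignore"))))
    }
  }

  converged <- TRUE
  m <- tryCatch(fitter(formula), error = function(e) e)
  # singular (boundary) fits are retained: they are the ML solution, and
  # swapping the covariance structure underneath one member of a nested pair
  # would invalidate likelihood-ratio comparisons. Only a genuine optimizer
  # failure triggers the diagonal-covariance refit.
  bad <- inherits(m, "error") ||
    (inherits(m, "merMod") && !is.null(m@optinfo$conv$opt) &&
       m@optinfo$conv$opt != 0)
  if (bad && length(bars) > 0 && !degenerate_groups) {
    converged <- FALSE
    f2 <- diagonalize_random(formula)
    m2 <- tryCatch(fitter(f2), error = function(e) e)
    if (!inherits(m2, "error")) m <- m2
  }
  if (inherits(m, "error")) stop_contract("model fit failed: ", conditionMessage(m))

  w <- rep(1, nobs(m))
  if (robust) {
    # Huber weights with k = 2: only clearly outlying residuals (> 2 robust
    # SDs) are downweighted, leaving clean Gaussian fits essentially unchanged
    for (it in 1:10) {
      r <- residuals(m)
      s <- stats::mad(r)
      if (s <= 0) break
      w_new <- pmin(1, 2 / abs(r / s))
      if (max(abs(w_new - w)) < 1e-3) { w <- w_new; break }
      w <- w_new
      m <- fitter(formula(m), w)
    }
  }

  structure(c(summarize_fit(m, satterthwaite),
              list(model = m, converged = converged,
                   random_cov = if (inherits(m, "merMod"))
                     lme4::VarCorr(m) else NULL,
                   robust_weights = if (robust) w else NULL,
                   formula = formula)),
            class = "lmm_fit")
}

# Re-optimize a mixed fit with bobyqa and return its log-likelihood.
refit_loglik <- function(fit) {
  m <- fit$model
  if (!inherits(m, "merMod")) return(NULL)
  d <- m@frame
  if ("(weights)" %in% names(d)) names(d)[names(d) == "(weights)"] <- ".w"
  else d$.w <- 1
  m2 <- tryCatch(suppressMessages(suppressWarnings(
    lme4::lmer(formula(m), data = d, REML = FALSE, weights = .w,
               control = lme4::lmerControl(optimizer = "bobyqa",
                                           calc.derivs = FALSE,
                                           check.conv.singular = "ignore")))),
    error = function(e) NULL)
  if (is.null(m2)) NULL else as.numeric(logLik(m2))
}

# Replace correlated random terms (x | g) with diagonal ones (x || g).
diagonalize_random <- function(formula) {
  txt <- paste(deparse(formula), collapse = " ")
  as.formula(gsub("\\|", "||", gsub("\\|\\|", "|", txt)), env = environment(formula))
}

summarize_fit <- function(m, satterthwaite = FALSE) {
  ll <- logLik(m)
  if (inherits(m, "merMod")) {
    if (satterthwaite) {
      mt <- tryCatch(lmerTest::as_lmerModLmerTest(m), error = function(e) NULL)
      if (!is.null(mt)) {
        cs <- coef(summary(mt))
        est <- cs[, "Estimate"]; se <- cs[, "Std. Error"]; p <- cs[, "Pr(>|t|)"]
      } else satterthwaite <- FALSE
    }
    if (!satterthwaite) {
      cs <- coef(summary(m))
      est <- cs[, "Estimate"]; se <- cs[, "Std. Error"]
      p <- 2 * pnorm(-abs(est / se))
    }
  } else {
    cs <- coef(summary(m))
    est <- cs[, "Estimate"]; se <- cs[, "Std. Error"]; p <- cs[, 4]
  }
  fixed <- data.frame(term = rownames(cs), estimate = unname(est),
                      se = unname(se),
                      ci_lo = unname(est - 1.96 * se),
                      ci_hi = unname(est + 1.96 * se),
                      p = unname(p), row.names = NULL)
  list(fixed = fixed, loglik = as.numeric(ll),
       n_params = attr(ll, "df"), aic = AIC(m), n_obs = nobs(m))
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Linear mixed model fit (", if (x$converged) "converged"
      else "diagonal-covariance fallback", ")\n", sep = "")
  cat("  logLik", format(x$loglik, digits = 6), " AIC",
      format(x$aic, digits = 6), " params", x$n_params,
      " n", x$n_obs, "\n")
  print(x$fixed, digits = 3)
  invisible(x)
}

#' Likelihood-ratio test between nested ML fits
#'
#' One-sided chi-square test on twice the log-likelihood difference. The
#' degrees of freedom are the difference in total parameter count (fixed
#' effects plus random variances/covariances plus the residual variance), the
#' bookkeeping under which adding a random slope to an intercept-only model
#' costs 3 df.
#'
#' @param fit_null,fit_full Nested [fit_lmm()] results on identical rows, both
#'   fit by ML.
#' @return List of class `lrt_result` with `df`, `chi2`, `p`.
#' @export
likelihood_ratio_test <- function(fit_null, fit_full) {
  if (fit_null$n_obs != fit_full$n_obs)
    stop_contract("fits use different numbers of rows; LRT is not valid")
  df <- fit_full$n_params - fit_null$n_params
  if (df < 1) stop_contract("models are not nested (df < 1)")
  chi2 <- 2 * (fit_full$loglik - fit_null$loglik)
  if (chi2 < -1e-6) {
    # a nested full model can only score worse if its optimizer stalled in a
    # local optimum; retry with a second optimizer before crying foul
    ll2 <- refit_loglik(fit_full)
    if (!is.null(ll2)) chi2 <- max(chi2, 2 * (ll2 - fit_null$loglik))
  }
  if (chi2 < -1e-6)
    stop_contract("full model has lower likelihood; fits are not nested")
  chi2 <- max(chi2, 0)
  structure(list(df = df, chi2 = chi2, p = pchisq(chi2, df, lower.tail = FALSE)),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT: chi2(%d) = %.3f, p = %.4g\n", x$df, x$chi2, x$p))
  invisible(x)
}

#' Conditional (group-level) coefficients from a mixed model
#'
#' Returns per-unit coefficient estimates for the requested fixed-effect terms:
#' the fixed effect plus the summed conditional-mode deviations of every
#' enclosing random-effect level that carries the term. Conditional standard
#' errors combine the fixed-effect SE with the conditional variances of the
#' deviations (a normal approximation); two-sided p-values are left
#' uncorrected, relying on the shrinkage of conditional modes for conservatism.
#'
#' @param fit An [fit_lmm()] result whose `model` is a merMod.
#' @param terms Character vector of fixed-effect term names.
#' @param unit Name of the grouping factor identifying the units of interest
#'   (e.g. the subject:channel factor).
#' @param nest_map Optional named character vector mapping each unit level to
#'   its enclosing level in coarser grouping factors (e.g. channel -> subject);
#'   deviations from those factors are added in.
#' @return Data frame: `unit`, `term`, `estimate`, `se`, `p`.
#' @export
conditional_coefficients <- function(fit, terms, unit, nest_map = NULL) {
  m <- fit$model
  if (!inherits(m, "merMod"))
    stop_contract("conditional coefficients require a mixed-model fit")
  re <- lme4::ranef(m, condVar = TRUE)
  if (!unit %in% names(re))
    stop_contract("grouping factor not in model: ", unit)
  fx <- fit$fixed
  units <- rownames(re[[unit]])
  out <- expand.grid(unit = units, term = terms, stringsAsFactors = FALSE)
  out$estimate <- NA_real_; out$se <- NA_real_
  for (tm in terms) {
    i_fx <- match(tm, fx$term)
    if (is.na(i_fx)) stop_contract("term not in fixed effects: ", tm)
    est <- rep(fx$estimate[i_fx], length(units))
    var <- rep(fx$se[i_fx]^2, length(units))
    for (g in names(re)) {
      dev <- dev_and_var(re[[g]], tm)
      if (is.null(dev)) next
      if (g == unit) lev <- units
      else if (!is.null(nest_map)) lev <- unname(nest_map[units])
      else next
      j <- match(lev, rownames(re[[g]]))
      keep <- !is.na(j)
      est[keep] <- est[keep] + dev$dev[j[keep]]
      var[keep] <- var[keep] + dev$var[j[keep]]
    }
    sel <- out$term == tm
    out$estimate[sel] <- est
    out$se[sel] <- sqrt(var)
  }
  out$p <- 2 * pnorm(-abs(out$estimate / out$se))
  out
}

# Deviations and conditional variances of one term from a ranef data.frame.
dev_and_var <- function(re_g, term) {
  cn <- colnames(re_g)
  k <- match(term, cn)
  if (is.na(k)) return(NULL)
  pv <- attr(re_g, "postVar")
  v <- if (is.list(pv)) {
    # diagonalized (||) models store a list per term block
    blk <- which(vapply(pv, function(a) dim(a)[1], 0L) >= 1)
    # locate term within blocks by matching column order
    offs <- 0; out <- NULL
    for (b in pv) {
      nb <- dim(b)[1]
      if (k > offs && k <= offs + nb) { out <- b[k - offs, k - offs, ]; break }
      offs <- offs + nb
    }
    out
  } else pv[k, k, ]
  list(dev = re_g[[k]], var = v)
}
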