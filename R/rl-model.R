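#' Fit the tolerance-logistic value model
#'
#' Maximum-likelihood logistic regression of binary win/loss outcomes on the
#' error tolerance (in ms) across the whole session. The task minimizes
#' learning by cueing the tolerance explicitly on every trial, so single-trial
#' values are estimated from this static psychometric model rather than a
#' temporal-difference learner. Neutral-outcome trials are delivered at random
#' and are excluded from the fit, as are trials with missing responses.
#'
#' @param trials Trial table with `tolerance_ms` and `outcome` columns.
#' @return A list of class `value_model_fit` with elements `beta0` (log-odds
#'   intercept), `beta1` (log-odds slope per ms of tolerance), `n_trials_fit`,
#'   and `degenerate` (TRUE when the fit was separated and coefficients were
#'   clamped).
#' @export
fit_value_model <- function(trials) {
  d <- trials[trials$outcome %in% c("win", "loss"), , drop = FALSE]
  if (length(unique(d$outcome)) < 2)
    stop_contract("need both win and loss outcomes to fit the value model")
  y <- as.integer(d$outcome == "win")
  fit <- suppressWarnings(glm(y ~ d$tolerance_ms, family = binomial()))
  beta <- unname(coef(fit))
  # complete separation inflates |coefficients|; clamp and flag
  degenerate <- !fit$converged || any(abs(beta) > 1e3) ||
    max(fitted(fit)) > 1 - 1e-10 && min(fitted(fit)) < 1e-10
  if (degenerate) {
    warning("value model fit is degenerate (separation); coefficients clamped")
    beta <- clamp(beta, -100, 100)
  }
  structure(list(beta0 = beta[1], beta1 = beta[2], n_trials_fit = nrow(d),
                 degenerate = degenerate),
            class = "value_model_fit")
}

#' Win probability at a given tolerance
#'
#' Inverse-logit of the fitted linear predictor:
#' \eqn{p = 1 / (1 + e^{-(\beta_0 + \beta_1 t)})} with tolerance \eqn{t} in ms.
#'
#' @param fit A [fit_value_model()] result (or any list with `beta0`, `beta1`).
#' @param tolerance_ms Tolerance value(s) in ms.
#' @return Win probability in (0, 1).
#' @export
win_probability <- function(fit, tolerance_ms) {
  stopifnot(all(is.finite(tolerance_ms)))
  plogis(fit$beta0 + fit$beta1 * tolerance_ms)
}

#' Expected value from win probability
#'
#' Linearly rescales win probability onto the reward range \eqn{[-1, 1]}
#' (rewards are +1 for a win, 0 for a neutral outcome, -1 for a loss):
#' \eqn{EV = 2 p_{win} - 1}.
#'
#' @param p_win Win probability in \[0, 1\].
#' @return Expected value in \[-1, 1\].
#' @export
expected_value <- function(p_win) {
  if (any(p_win < 0 | p_win > 1, na.rm = TRUE))
    stop_contract("p_win must lie in [0, 1]")
  2 * p_win - 1
}

#' Single-trial reward prediction errors
#'
#' The signed RPE is the delivered reward minus the expected value; its
#' absolute value is the unsigned RPE (salience), which splits exactly into
#' valence-specific magnitudes: `prpe = max(srpe, 0)`, `nrpe = max(-srpe, 0)`.
#' By construction `prpe - nrpe = srpe`, `prpe + nrpe = urpe`, and
#' `prpe * nrpe = 0` on every trial. Because expected value differs between
#' easy and hard blocks, neutral outcomes (reward 0) carry negative RPEs in
#' easy blocks and positive RPEs in hard blocks.
#'
#' @param reward Reward value(s) in `{+1, 0, -1}` (NA allowed for missing).
#' @param ev Expected value(s) in \[-1, 1\].
#' @return A `data.frame` with columns `srpe`, `urpe`, `prpe`, `nrpe`.
#' @export
compute_rpes <- function(reward, ev) {
  stopifnot(all(reward %in% c(-1, 0, 1) | is.na(reward)),
            all(abs(ev) <= 1 + 1e-12, na.rm = TRUE))
  srpe <- reward - ev
  data.frame(srpe = srpe, urpe = abs(srpe),
             prpe = pmax(srpe, 0), nrpe = pmax(-srpe, 0))
}

#' Augment a trial table with RL variables
#'
#' Fits the value model (unless one is supplied) and appends `p_win`, `ev`,
#' `srpe`, `urpe`, `prpe`, `nrpe` columns. Missing-response trials get NA RPEs.
#'
#' @param trials Trial table.
#' @param fit Optional pre-fitted [fit_value_model()] result.
#' @return The augmented trial table; the fit is attached as
#'   `attr(, "value_model")`.
#' @export
add_rl_variables <- function(trials, fit = NULL) {
  if (is.null(fit)) fit <- fit_value_model(trials)
  p <- win_probability(fit, trials$tolerance_ms)
  ev <- expected_value(p)
  out <- cbind(trials, p_win = p, ev = ev, compute_rpes(trials$reward, ev))
  attr(out, "value_model") <- fit
  out
}
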