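#' Build the RT-adaptation modeling table for a cohort
#'
#' Combines [rt_change_table()] rows across subjects and joins each row's
#' previous-trial RL variables (`prev_srpe`, `prev_urpe`, `prev_prpe`,
#' `prev_nrpe`, `prev_ev`), producing the table consumed by
#' [run_model_ladder()]. The previous-outcome factor uses treatment coding
#' with `"win"` as the reference level.
#'
#' @param sessions Named list of per-subject trial tables that already carry
#'   RL variables (see [add_rl_variables()]); names are subject ids. Tables
#'   are cleaned with [reject_trials()] first unless `reject = FALSE`.
#' @param reject Apply the behavioral rejection rules (default TRUE).
#' @return A `data.frame` with one row per usable trial transition.
#' @export
behavior_table <- function(sessions, reject = TRUE) {
  stopifnot(is.list(sessions), !is.null(names(sessions)))
  rows <- lapply(names(sessions), function(sid) {
    tr <- sessions[[sid]]
    if (reject) tr <- reject_trials(tr)
    rc <- rt_change_table(tr)
    if (nrow(rc) == 0) return(NULL)
    j <- match(rc$prev_trial_index, tr$trial_index)
    rc$subject <- sid
    rc$prev_ev <- tr$ev[j]
    rc$prev_srpe <- tr$srpe[j]
    rc$prev_urpe <- tr$urpe[j]
    rc$prev_prpe <- tr$prpe[j]
    rc$prev_nrpe <- tr$nrpe[j]
    rc
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop_contract("no usable trial transitions in any session")
  lev <- intersect(c("win", "loss", "neutral"), unique(out$prev_outcome))
  out$prev_outcome <- factor(out$prev_outcome, levels = lev)
  out
}

#' Model specifications for the RT-adaptation ladder
#'
#' The hierarchical ladder of linear mixed models for trial-to-trial RT
#' change, built up from an intercept-only model: previous RT (b1), previous
#' outcome (b2), their interaction (b3), then one RPE quantity each — signed
#' RPE value (b4), unsigned RPE salience (b5), and the asymmetric model with
#' separate positive and negative RPE magnitudes (b6). All models include
#' by-subject random intercepts and (from b1 on) random slopes for previous RT.
#'
#' @return Named list of formulas `b0` ... `b6`.
#' @export
behavior_model_specs <- function() {
  list(
    b0 = rt_change ~ 1 + (1 | subject),
    b1 = rt_change ~ prev_rt + (1 + prev_rt | subject),
    b2 = rt_change ~ prev_rt + prev_outcome + (1 + prev_rt | subject),
    b3 = rt_change ~ prev_rt * prev_outcome + (1 + prev_rt | subject),
    b4 = rt_change ~ prev_rt * prev_outcome + prev_srpe + (1 + prev_rt | subject),
    b5 = rt_change ~ prev_rt * prev_outcome + prev_urpe + (1 + prev_rt | subject),
    b6 = rt_change ~ prev_rt * prev_outcome + prev_prpe + prev_nrpe +
      (1 + prev_rt | subject)
  )
}

#' Run the hierarchical RT-adaptation model comparison
#'
#' Fits the full ladder of [behavior_model_specs()] by maximum likelihood and
#' reports one-sided likelihood-ratio tests of each model against its
#' designated null (b1 vs b0, b2 vs b1, b3 vs b2, and b4/b5/b6 each vs b3)
#' plus AIC for every model. The value (b4) and salience (b5) models have equal
#' parameter counts and are compared by AIC only, never by LRT.
#'
#' @param table Output of [behavior_table()].
#' @param models Subset of ladder names to fit (default all).
#' @param satterthwaite,robust Passed to [fit_lmm()].
#' @return List with `fits` (named list of `lmm_fit`), `lrt` (data.frame:
#'   model, null, df, chi2, p), and `aic` (data.frame: model, aic, loglik,
#'   n_params).
#' @export
run_model_ladder <- function(table, models = names(behavior_model_specs()),
                             satterthwaite = FALSE, robust = FALSE) {
  need <- c("prev_srpe", "prev_urpe", "prev_prpe", "prev_nrpe")
  if (!all(need %in% names(table)))
    stop_contract("table lacks previous-trial RPE columns; see behavior_table()")
  if (is.factor(table$subject)) {
    empty <- setdiff(levels(table$subject), unique(as.character(table$subject)))
    if (length(empty)) {
      warning("dropping subjects with no rows: ", paste(empty, collapse = ", "))
      table$subject <- droplevels(table$subject)
    }
  }
  specs <- behavior_model_specs()[models]
  # a 2-level outcome factor cannot support the neutral contrast; formulas
  # adapt automatically through treatment coding
  fits <- lapply(specs, fit_lmm, data = table,
                 satterthwaite = satterthwaite, robust = robust)
  nulls <- c(b1 = "b0", b2 = "b1", b3 = "b2", b4 = "b3", b5 = "b3", b6 = "b3")
  nulls <- nulls[names(nulls) %in% names(fits) & nulls %in% names(fits)]
  lrt <- do.call(rbind, lapply(names(nulls), function(mname) {
    res <- likelihood_ratio_test(fits[[nulls[mname]]], fits[[mname]])
    data.frame(model = mname, null = unname(nulls[mname]), df = res$df,
               chi2 = res$chi2, p = res$p)
  }))
  aic <- data.frame(model = names(fits),
                    aic = vapply(fits, `[[`, 0, "aic"),
                    loglik = vapply(fits, `[[`, 0, "loglik"),
                    n_params = vapply(fits, `[[`, 0, "n_params"),
                    row.names = NULL)
  list(fits = fits, lrt = lrt, aic = aic)
}

#' Simulate a behavioral cohort with known RT-adaptation effects
#'
#' Runs one task session per subject (optionally with a planted RPE-dependent
#' RT shift, see [run_session()]), derives RL variables from the fitted
#' tolerance-logistic model per subject, and assembles the ladder table.
#'
#' @param n_subjects Number of simulated participants.
#' @param config,agent Task and agent configurations.
#' @param rpe_slowing Named numeric `c(prpe =, nrpe =)` planted RT shift in
#'   seconds per unit previous-trial RPE magnitude.
#' @param seed Integer seed; subject sessions use `seed + 1 ... seed + n`.
#' @return List with `table` (ladder table) and `sessions` (per-subject
#'   RL-augmented trial tables).
#' @export
simulate_behavior_cohort <- function(n_subjects, config = task_config(),
                                     agent = agent_config(),
                                     rpe_slowing = c(prpe = 0, nrpe = 0),
                                     seed = 1) {
  sessions <- lapply(seq_len(n_subjects), function(s) {
    tr <- run_session(config, agent, seed = seed + s,
                      rpe_slowing = rpe_slowing)
    add_rl_variables(tr)
  })
  names(sessions) <- sprintf("S%02d", seq_len(n_subjects))
  list(table = behavior_table(sessions), sessions = sessions)
}
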