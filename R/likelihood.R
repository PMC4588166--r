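REQUIRED_TRIAL_COLS <- c("subject_id", "group", "day", "block", "trial",
                         "condition", "choice1", "transition", "state2",
                         "choice2", "reward", "stroop_correct")

# encode trial columns for the C++ core; assumes validated input. An
# optional logical `scored` column restricts which trials enter the
# likelihood (Q-values still update on every trial).
encode_trials <- function(trials) {
  scored <- trials[["scored"]] %||% rep(TRUE, nrow(trials))
  list(
    day = as.integer(trials$day),
    choice1 = as.integer(trials$choice1 == "B"),
    state2 = ifelse(trials$state2 == "s_B", 1L, 2L),
    choice2 = as.integer(trials$choice2 == "B"),
    reward = as.integer(trials$reward),
    scored = as.integer(scored)
  )
}

check_chronology <- function(trials) {
  days <- trials$day
  if (is.unsorted(days))
    abort("trials must be in chronological order (non-decreasing day).",
          class = "twostep_input_error")
  ud <- unique(days)
  if (length(ud) > 1 && any(diff(ud) != 1L))
    abort("day gaps in trial sequence: days must be consecutive.",
          class = "twostep_input_error")
  for (d in ud) {
    tr <- trials$trial[days == d]
    if (is.unsorted(tr, strictly = TRUE))
      abort(sprintf("trials out of order within day %d.", d),
            class = "twostep_input_error")
  }
  invisible(trials)
}

#' Session log-likelihood under the hybrid model family
#'
#' Scores one subject's chronologically ordered trials under the hybrid
#' model-free/model-based learner: Q-values start at zero (reset at each day
#' boundary by default, since reward walks change across days), the
#' first-stage values mix model-based Bellman values with the model-free
#' cached values via the (possibly day-modulated) weight, and both stage
#' choices are scored with the softmax-plus-lapse rule. Simulation
#' ([simulate_session()]) uses the identical compiled code path.
#'
#' @param trials Tibble of one subject's trials in chronological order. An
#'   optional logical `scored` column restricts the likelihood to a subset
#'   of choices (e.g. one condition's trials) while Q-values still evolve
#'   over every supplied trial.
#' @param params An [agent_params()] object (or coercible list).
#' @param spec Optional [model_spec()]; when supplied its fixed values
#'   override `params` (e.g. `w = 0` for the model-free family).
#' @param p_common Common-transition probability of the agent's (true)
#'   transition model.
#' @param reset_each_day Reset Q-values at day boundaries (default `TRUE`).
#' @param trial_probs If `TRUE`, attach the per-trial chosen-action
#'   probabilities as attribute `"probs"` (n x 2 matrix).
#' @return Total log-likelihood (scalar), optionally with attribute `probs`.
#' @export
session_loglik <- function(trials, params, spec = NULL, p_common = 0.7,
                           reset_each_day = TRUE, trial_probs = FALSE) {
  if (nrow(trials) == 0) return(0)
  if ("subject_id" %in% names(trials) &&
      length(unique(trials$subject_id)) > 1)
    abort("`session_loglik()` scores one subject at a time.",
          class = "twostep_input_error")
  check_chronology(trials)
  if (!inherits(params, "twostep_params")) params <- do.call(agent_params, params)
  if (!is.null(spec)) {
    pl <- unclass(params)
    pl <- modifyList(pl, spec$fixed)
    params <- do.call(agent_params, pl[c("alpha", "beta", "eps", "w",
                                         "lambda", "sigma", "alpha1", "alpha2",
                                         "beta1", "beta2")])
  }
  enc <- encode_trials(trials)
  n <- nrow(trials)
  par <- cbind(params$alpha1, params$alpha2, params$beta1, params$beta2,
               params$eps, params$w)[rep(1, n), , drop = FALSE]
  out <- ll_session_cpp(enc$day, enc$choice1, enc$state2, enc$choice2,
                        enc$reward, enc$scored, par, params$lambda,
                        params$sigma, p_common, reset_each_day, trial_probs)
  ll <- out$loglik
  if (trial_probs) attr(ll, "probs") <- out$probs
  ll
}
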