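STATES <- c("s_A", "s_B", "s_C")
ACTIONS <- c("a_A", "a_B")

#' Agent parameters on the natural scale
#'
#' @param alpha Learning rate in \[0, 1\]; used for both stages unless
#'   `alpha1`/`alpha2` are given.
#' @param beta Softmax inverse temperature, >= 0; split with `beta1`/`beta2`.
#' @param eps Lapse rate in \[0, 0.5).
#' @param w Model-based weight in \[0, 1\] (0 = pure model-free, 1 = pure
#'   model-based).
#' @param lambda Eligibility trace in \[0, 1\].
#' @param sigma Cross-day slope on `w` (unbounded); the per-day weight is
#'   `w * exp(sigma * (day - 2))` clipped to \[0, 1\].
#' @param alpha1,alpha2,beta1,beta2 Optional stage-specific learning rates and
#'   inverse temperatures for the stage-split model family.
#' @return A `twostep_params` list with resolved stage-specific fields.
#' @export
agent_params <- function(alpha = 0.5, beta = 5, eps = 0.05, w = 0.5,
                         lambda = 1, sigma = 0,
                         alpha1 = NULL, alpha2 = NULL,
                         beta1 = NULL, beta2 = NULL) {
  p <- list(alpha = alpha, beta = beta, eps = eps, w = w,
            lambda = lambda, sigma = sigma,
            alpha1 = alpha1 %||% alpha, alpha2 = alpha2 %||% alpha,
            beta1 = beta1 %||% beta, beta2 = beta2 %||% beta)
  chk <- function(ok, msg) if (!ok) abort(msg, class = "twostep_input_error")
  chk(all(c(p$alpha1, p$alpha2, p$w, p$lambda) >= 0 &
            c(p$alpha1, p$alpha2, p$w, p$lambda) <= 1),
      "alpha, w and lambda must lie in [0, 1].")
  chk(all(c(p$beta1, p$beta2) >= 0), "beta must be >= 0.")
  chk(p$eps >= 0 && p$eps < 0.5, "eps must lie in [0, 0.5).")
  structure(p, class = "twostep_params")
}

#' Fresh Q-state
#'
#' All state-action values start at zero; the transition matrix is the true
#' one (learnt during practice): action a_A leads to s_B with `p_common`,
#' action a_B to s_C with `p_common`.
#'
#' @param p_common Common-transition probability.
#' @return A `twostep_q` list with `Q` (3 states x 2 actions) and `trans`
#'   (2 actions x 2 second-stage states).
#' @export
q_state <- function(p_common = 0.7) {
  Q <- matrix(0, 3, 2, dimnames = list(STATES, ACTIONS))
  trans <- matrix(c(p_common, 1 - p_common, 1 - p_common, p_common),
                  2, 2, byrow = TRUE,
                  dimnames = list(ACTIONS, c("s_B", "s_C")))
  structure(list(Q = Q, trans = trans, p_common = p_common),
            class = "twostep_q")
}

#' Temporal-difference update of the visited state-action value
#'
#' Applies `Q(s,a) <- Q(s,a) + alpha * delta` with reward-prediction error
#' `delta = r + gamma * max_a Q(s', a) - Q(s, a)`. At stage 1 the reward is
#' zero and the continuation value is the maximum over the realized
#' second-stage state; at stage 2 the continuation value is zero (terminal).
#'
#' @param q A [q_state()] object.
#' @param stage 1 or 2.
#' @param state,action Names of the visited state and chosen action.
#' @param reward Reward received (0 at stage 1).
#' @param next_state For stage 1, the realized second-stage state.
#' @param alpha Learning rate.
#' @param gamma Discount factor (fixed at 1 in all model families).
#' @return List with the updated `q` and the prediction error `delta`.
#' @export
td_update <- function(q, stage, state, action, reward = 0, next_state = NULL,
                      alpha, gamma = 1) {
  if (!state %in% STATES || !action %in% ACTIONS)
    abort("unknown state or action.", class = "twostep_input_error")
  if (alpha < 0 || alpha > 1)
    abort("alpha must lie in [0, 1].", class = "twostep_input_error")
  cont <- if (stage == 1) {
    if (!next_state %in% STATES)
      abort("unknown next_state.", class = "twostep_input_error")
    max(q$Q[next_state, ])
  } else 0
  delta <- reward + gamma * cont - q$Q[state, action]
  q$Q[state, action] <- q$Q[state, action] + alpha * delta
  list(q = q, delta = delta)
}

#' Eligibility-trace update of the first-stage action
#'
#' After outcome delivery the second-stage prediction error is credited to
#' the first-stage choice: `Q(s_A, a1) <- Q(s_A, a1) + alpha * lambda * delta2`.
#'
#' @param q A [q_state()] object.
#' @param first_action The first-stage action name.
#' @param delta2 Second-stage reward-prediction error.
#' @param alpha Learning rate.
#' @param lambda Eligibility trace in \[0, 1\].
#' @return The updated `q`.
#' @export
eligibility_update <- function(q, first_action, delta2, alpha, lambda) {
  if (lambda < 0 || lambda > 1)
    abort("lambda must lie in [0, 1].", class = "twostep_input_error")
  q$Q["s_A", first_action] <- q$Q["s_A", first_action] + alpha * lambda * delta2
  q
}

#' Model-based first-stage values
#'
#' Bellman combination of the transition model with the current second-stage
#' values: `Q_MB(s_A, a) = sum_s' P(s'|s_A, a) max_a' Q(s', a')`, recomputed
#' from the current Q-state on every call.
#'
#' @param q A [q_state()] object.
#' @return Named numeric vector of model-based values per first-stage action.
#' @export
mb_values <- function(q) {
  m <- c(max(q$Q["s_B", ]), max(q$Q["s_C", ]))
  setNames(as.numeric(q$trans %*% m), ACTIONS)
}

#' Hybrid first-stage values
#'
#' Convex combination `w * Q_MB + (1 - w) * Q_TD(s_A, .)` of model-based and
#' model-free valuations.
#'
#' @param q A [q_state()] object.
#' @param w_eff Effective model-based weight in \[0, 1\].
#' @return Named numeric vector per first-stage action.
#' @export
hybrid_values <- function(q, w_eff) {
  if (w_eff < 0 || w_eff > 1)
    abort("w_eff must lie in [0, 1].", class = "twostep_input_error")
  w_eff * mb_values(q) + (1 - w_eff) * q$Q["s_A", ]
}

#' Day-modulated model-based weight
#'
#' `w_D = w * exp(sigma * (day - 2))`, clipped to \[0, 1\] so the hybrid
#' mixture stays convex (the raw formula can exceed 1).
#'
#' @param w Baseline weight in \[0, 1\].
#' @param sigma Cross-day slope.
#' @param day Training day (1, 2 or 3).
#' @return Effective weight in \[0, 1\].
#' @export
effective_w <- function(w, sigma, day) {
  pmin(1, pmax(0, w * exp(sigma * (day - 2))))
}

#' Softmax choice probabilities with lapse
#'
#' `P(a) = eps + (1 - 2 eps) * softmax(beta * Q)[a]`, computed with
#' max-subtraction for numerical stability. Probabilities sum to 1 and each
#' lies in \[eps, 1 - eps\].
#'
#' @param values Numeric vector of action values.
#' @param beta Inverse temperature, >= 0.
#' @param eps Lapse rate in \[0, 0.5).
#' @return Named probabilities, one per action.
#' @export
choice_prob <- function(values, beta, eps = 0) {
  if (beta < 0) abort("beta must be >= 0.", class = "twostep_input_error")
  if (eps < 0 || eps >= 0.5)
    abort("eps must lie in [0, 0.5).", class = "twostep_input_error")
  z <- beta * values
  z <- z - max(z)
  sm <- exp(z) / sum(exp(z))
  eps + (1 - 2 * eps) * sm
}
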