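#' Simulate one subject-day of the two-step task
#'
#' Generates a full day of trials under the configured block protocol. The
#' agent's choices come from the same compiled hybrid-learner code path used
#' by [session_loglik()]; the second-stage state is drawn with `p_common`
#' given the first-stage choice, and reward is Bernoulli in the current value
#' of the walk for the chosen second-stage fractal. Walks are continuous
#' across blocks within the day.
#'
#' @param params An [agent_params()] object, or an n_trials x 6 matrix of
#'   per-trial parameters (columns alpha1, alpha2, beta1, beta2, eps, w) for
#'   condition-dependent agents; `lambda`/`sigma` are then taken from
#'   `lambda`, `sigma`.
#' @param config A [task_config()].
#' @param walks A `twostep_walk_set` (one element of [generate_walk_pool()]).
#' @param seed Integer seed for this session.
#' @param group,day Which protocol row to simulate.
#' @param subject_id Identifier stamped on every trial.
#' @param lambda,sigma Session constants when `params` is a matrix.
#' @return Tibble of trial records: `subject_id`, `group`, `day`, `block`,
#'   `trial`, `condition`, `choice1`, `transition`, `state2`, `choice2`,
#'   `reward`, `stroop_correct` (all `NA`; filled by [simulate_cohort()]).
#' @export
simulate_session <- function(params, config, walks, seed = 1L,
                             group = "high_load", day = 1L,
                             subject_id = "s01", lambda = NULL, sigma = NULL) {
  stopifnot(inherits(config, "twostep_config"),
            inherits(walks, "twostep_walk_set"))
  proto <- day_protocol(config, group, day)
  n <- sum(proto$n_trials)
  if (nrow(walks$series) < n)
    abort(sprintf("walk set has %d steps but the day needs %d trials.",
                  nrow(walks$series), n),
          class = "twostep_input_error")
  if (inherits(params, "twostep_params")) {
    par <- cbind(params$alpha1, params$alpha2, params$beta1, params$beta2,
                 params$eps, params$w)[rep(1, n), , drop = FALSE]
    lambda <- lambda %||% params$lambda
    sigma <- sigma %||% params$sigma
  } else {
    par <- as.matrix(params)
    if (nrow(par) != n || ncol(par) != 6)
      abort("per-trial parameter matrix must be n_trials x 6.",
            class = "twostep_input_error")
    lambda <- lambda %||% 1
    sigma <- sigma %||% 0
  }
  set.seed(seed)
  u <- matrix(runif(n * 4), n, 4)
  out <- sim_session_cpp(rep(as.integer(day), n),
                         walks$series[seq_len(n), , drop = FALSE], u, par,
                         lambda, sigma, config$p_common, TRUE)
  tibble(
    subject_id = subject_id,
    group = group,
    day = as.integer(day),
    block = rep(proto$block, proto$n_trials),
    trial = seq_len(n),
    condition = rep(proto$condition, proto$n_trials),
    choice1 = c("A", "B")[out$choice1 + 1L],
    transition = c("uncommon", "common")[out$common + 1L],
    state2 = c("s_B", "s_C")[out$state2],
    choice2 = c("A", "B")[out$choice2 + 1L],
    reward = as.integer(out$reward),
    stroop_correct = NA_integer_
  )
}

#' Default condition/day parameter offsets and concurrent-task accuracies
#'
#' `default_offsets()` gives the transformed-scale parameter shifts applied
#' on dual-task trials: a `w` deficit that shrinks over training days in the
#' high-load group and is absent in the trained low-load group on day 3,
#' plus training-independent load costs on `alpha` and `beta`.
#' `default_stroop()` gives the per-group/day dual-task accuracy rates.
#'
#' @return A tibble (see [cohort_spec()] for the column contracts).
#' @export
default_offsets <- function() {
  tibble(
    parameter = c("w", "w", "w", "w", "alpha", "beta"),
    group = c("high_load", "high_load", "high_load", "low_load", "all", "all"),
    condition = "dual",
    day = c(1L, 2L, 3L, 3L, NA_integer_, NA_integer_),
    delta = c(-0.5, -0.25, 0, 0, -0.4, -0.3)
  )
}

#' @rdname default_offsets
#' @export
default_stroop <- function() {
  tibble(
    group = c("high_load", "high_load", "high_load", "low_load"),
    day = c(1L, 2L, 3L, 3L),
    p_correct = c(0.819, 0.855, 0.895, 0.832)
  )
}

#' Cohort specification for synthetic two-group studies
#'
#' Subjects' parameters are drawn from group-level Gaussians on the
#' transformed (fitting) scale and un-transformed; condition/day offsets are
#' applied on the transformed scale before un-transforming, so e.g. a dual-task
#' `w` offset of -0.5 shifts the logit of `w`. Defaults emulate the study
#' design: 22 + 23 subjects, a load-induced `w` deficit that shrinks across
#' training days in the high-load group and is absent in the trained low-load
#' group on day 3, mild load costs on `alpha` and `beta`, and concurrent-task
#' accuracies matching the reported group means.
#'
#' @param n_subjects Named vector of group sizes.
#' @param hyper_mean_natural Named list of natural-scale hyper-means for
#'   `alpha`, `beta`, `eps`, `w`.
#' @param hyper_sd Named vector of transformed-scale hyper-SDs.
#' @param offsets Tibble (`parameter`, `group`, `condition`, `day`, `delta`)
#'   of transformed-scale shifts; `group = "all"` or `day = NA` match
#'   everything.
#' @param stroop_p_correct Tibble (`group`, `day`, `p_correct`) of
#'   concurrent-task accuracy on dual-task trials.
#' @param lambda,sigma Generative eligibility trace and day slope.
#' @param seed Master seed; all subject, walk and trial streams derive from it.
#' @return A `twostep_cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = c(high_load = 22L, low_load = 23L),
                        hyper_mean_natural = list(alpha = 0.5, beta = 5,
                                                  eps = 0.05, w = 0.6),
                        hyper_sd = c(alpha = 0.5, beta = 0.5,
                                     eps = 0.5, w = 0.5),
                        offsets = default_offsets(),
                        stroop_p_correct = default_stroop(),
                        lambda = 1, sigma = 0, seed = 1L) {
  if (any(n_subjects < 1))
    abort("n_subjects must be >= 1 in every group.",
          class = "twostep_input_error")
  if (any(hyper_sd < 0))
    abort("hyper_sd must be >= 0.", class = "twostep_input_error")
  if (any(stroop_p_correct$p_correct < 0 | stroop_p_correct$p_correct > 1))
    abort("stroop_p_correct must lie in [0, 1].",
          class = "twostep_input_error")
  mu <- to_transformed(unlist(hyper_mean_natural))
  structure(
    list(n_subjects = n_subjects, hyper_mu = mu,
         hyper_sd = hyper_sd[names(mu)],
         offsets = offsets, stroop_p_correct = stroop_p_correct,
         lambda = lambda, sigma = sigma, seed = as.integer(seed)),
    class = "twostep_cohort_spec"
  )
}

# transformed-scale offset for one parameter on one (group, condition, day)
lookup_offset <- function(offsets, param, group, condition, day) {
  hit <- offsets$parameter == param &
    (offsets$group == group | offsets$group == "all") &
    offsets$condition == condition &
    (is.na(offsets$day) | offsets$day == day)
  sum(offsets$delta[hit])
}

#' Simulate a synthetic cohort
#'
#' Draws per-subject parameters from the group-level Gaussians, applies
#' condition/day offsets, simulates every subject-day with walks sampled
#' (without replacement across days) from a shared pool of
#' `config$walk_pool_size` walk sets, and draws dual-task concurrent-task
#' correctness as Bernoulli outcomes. Ground-truth parameters are returned
#' for recovery testing.
#'
#' @param spec A [cohort_spec()].
#' @param config A [task_config()].
#' @return A `twostep_cohort`: list with `trials` (tibble of all trial
#'   records) and `truth` (tibble of per subject/condition/day natural- and
#'   transformed-scale generative parameters).
#' @export
simulate_cohort <- function(spec, config = task_config()) {
  stopifnot(inherits(spec, "twostep_cohort_spec"),
            inherits(config, "twostep_config"))
  pool <- generate_walk_pool(config, seed = derive_seed(spec$seed, 0L))
  pnames <- names(spec$hyper_mu)
  groups <- names(spec$n_subjects)

  trials <- list()
  truth <- list()
  idx <- 0L
  for (g in groups) {
    n_g <- spec$n_subjects[[g]]
    set.seed(derive_seed(spec$seed, 1L, match(g, groups)))
    base_z <- sapply(pnames, function(p)
      rnorm(n_g, spec$hyper_mu[[p]], spec$hyper_sd[[p]]))
    base_z <- matrix(base_z, nrow = n_g,
                     dimnames = list(NULL, pnames))
    for (i in seq_len(n_g)) {
      idx <- idx + 1L
      sid <- sprintf("%s_%02d", g, i)
      days <- as.integer(names(config$protocol[[g]]))
      set.seed(derive_seed(spec$seed, 2L, idx))
      walk_ids <- sample.int(config$walk_pool_size, length(days))
      for (d in days) {
        proto <- day_protocol(config, g, d)
        conds <- rep(proto$condition, proto$n_trials)
        n <- length(conds)
        # per-condition transformed-scale parameters for this subject-day
        theta_by_cond <- lapply(unique(conds), function(cc) {
          z <- base_z[i, ]
          for (p in pnames)
            z[[p]] <- z[[p]] + lookup_offset(spec$offsets, p, g, cc, d)
          to_natural(z)
        })
        names(theta_by_cond) <- unique(conds)
        par <- t(vapply(conds, function(cc) {
          th <- theta_by_cond[[cc]]
          c(th[["alpha"]], th[["alpha"]], th[["beta"]], th[["beta"]],
            th[["eps"]], th[["w"]])
        }, numeric(6)))
        ws <- pool[[walk_ids[match(d, days)]]]
        tr <- simulate_session(par, config, ws,
                               seed = derive_seed(spec$seed, 3L, idx * 10L + d),
                               group = g, day = d, subject_id = sid,
                               lambda = spec$lambda, sigma = spec$sigma)
        # concurrent-task correctness on dual trials only
        sp <- spec$stroop_p_correct
        p_ok <- sp$p_correct[sp$group == g & sp$day == d]
        dual <- tr$condition == "dual"
        if (any(dual) && length(p_ok) == 1) {
          set.seed(derive_seed(spec$seed, 4L, idx * 10L + d))
          tr$stroop_correct[dual] <- rbinom(sum(dual), 1L, p_ok)
        }
        trials[[length(trials) + 1L]] <- tr
        for (cc in names(theta_by_cond)) {
          th <- theta_by_cond[[cc]]
          z <- base_z[i, ]
          for (p in pnames)
            z[[p]] <- z[[p]] + lookup_offset(spec$offsets, p, g, cc, d)
          truth[[length(truth) + 1L]] <- tibble(
            subject_id = sid, group = g, day = d, condition = cc,
            parameter = pnames, z_value = as.numeric(z),
            value = as.numeric(th[pnames])
          )
        }
      }
    }
  }
  structure(
    list(trials = dplyr::bind_rows(trials), truth = dplyr::bind_rows(truth),
         spec = spec, config = config),
    class = "twostep_cohort"
  )
}

#' @export
print.twostep_cohort <- function(x, ...) {
  cat(sprintf("<twostep_cohort> %d subjects, %d trials (%d dual)\n",
              length(unique(x$trials$subject_id)), nrow(x$trials),
              sum(x$trials$condition == "dual")))
  invisible(x)
}
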