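#' M-step hyperparameter update
#'
#' Moment-matching update of the empirical prior: the group mean is the mean
#' of the subject-level MAP estimates, and the group variance is the mean of
#' the subjects' second moments (MAP estimate squared plus Laplace variance)
#' minus the squared mean.
#'
#' @param theta_z Matrix of transformed-scale MAP estimates, subjects x
#'   parameters.
#' @param sigma_diag Matrix of Laplace posterior variances (diagonals of the
#'   per-subject covariances), same shape.
#' @param var_floor Lower bound applied to the updated variances.
#' @return List with `mu` and `sigma2` (named numeric vectors).
#' @export
em_m_step <- function(theta_z, sigma_diag, var_floor = 1e-6) {
  mu <- colMeans(theta_z)
  sigma2 <- colMeans(theta_z^2 + sigma_diag) - mu^2
  list(mu = mu, sigma2 = pmax(sigma2, var_floor))
}

#' Hierarchical empirical-Bayes fit by expectation-maximization
#'
#' Alternates subject-level MAP fits under the current empirical Gaussian
#' prior (E-step, Laplace approximation) with the moment-matching
#' hyperparameter update (M-step) until every hyperparameter's relative
#' change falls below `tol` or `max_iter` is reached. The first E-step uses
#' `restarts` random initializations per subject; later iterations warm-start
#' from the previous MAP estimates.
#'
#' @param trials Trials tibble covering >= 2 subjects (split on
#'   `subject_id`), or a named list of per-subject data for custom
#'   interfaces.
#' @param spec A [model_spec()]; ignored if `interface` is supplied.
#' @param interface Optional custom [model_interface()]-style list.
#' @param restarts Random restarts per subject in the first E-step.
#' @param max_iter,tol EM stopping rule (relative hyperparameter change,
#'   with a 0.1 floor on the denominator).
#' @param init_hyper Optional starting hyperparameters (`mu`, `sigma2`).
#' @param seed Seed for all restart draws.
#' @param verbose Print per-iteration progress.
#' @return A `twostep_fit` with per-subject estimates, Laplace covariances,
#'   final hyperparameters, the EM objective trace and convergence info.
#' @export
em_fit <- function(trials, spec = model_spec("hybrid"), interface = NULL,
                   restarts = 5, max_iter = 100, tol = 1e-3,
                   init_hyper = NULL, seed = 1L, verbose = FALSE) {
  interface <- interface %||% model_interface(spec)
  pn <- interface$param_names
  if (is.data.frame(trials)) {
    data_by_subj <- split(trials, trials$subject_id)
  } else {
    data_by_subj <- trials
  }
  N <- length(data_by_subj)
  if (N < 2)
    abort("hierarchical fitting requires >= 2 subjects.",
          class = "twostep_input_error")
  hyper <- init_hyper %||%
    (if (!is.null(interface$spec)) default_hyper_init(interface$spec)
     else list(mu = setNames(rep(0, length(pn)), pn),
               sigma2 = setNames(rep(1, length(pn)), pn)))
  hyper$mu <- hyper$mu[pn]
  hyper$sigma2 <- hyper$sigma2[pn]

  theta_z <- matrix(NA_real_, N, length(pn), dimnames = list(names(data_by_subj), pn))
  sigma_diag <- theta_z
  Sigmas <- vector("list", N)
  names(Sigmas) <- names(data_by_subj)
  prev_theta <- NULL
  trace <- list()
  converged <- FALSE

  for (it in seq_len(max_iter)) {
    lp_total <- 0
    ll_total <- 0
    flagged <- character(0)
    for (i in seq_len(N)) {
      fit <- map_fit(data_by_subj[[i]], hyper, interface,
                     restarts = if (it == 1) restarts else 1,
                     seed = derive_seed(seed, it, i),
                     init = if (!is.null(prev_theta)) prev_theta[i, ])
      theta_z[i, ] <- fit$theta_z
      sigma_diag[i, ] <- diag(fit$Sigma)
      Sigmas[[i]] <- fit$Sigma
      lp_total <- lp_total + fit$logpost
      ll_total <- ll_total + fit$loglik
      if (!fit$converged) flagged <- c(flagged, names(data_by_subj)[i])
    }
    new_hyper <- em_m_step(theta_z, sigma_diag)
    rel <- max(abs(c(new_hyper$mu - hyper$mu, new_hyper$sigma2 - hyper$sigma2)) /
                 pmax(abs(c(hyper$mu, hyper$sigma2)), 0.1))
    trace[[it]] <- tibble(iter = it, objective = lp_total,
                          loglik = ll_total, max_rel_change = rel)
    if (verbose)
      message(sprintf("EM iter %d: objective %.2f, max rel change %.2e",
                      it, lp_total, rel))
    prev_theta <- theta_z
    hyper <- new_hyper
    if (rel < tol) { converged <- TRUE; break }
  }

  n_trials <- if (is.data.frame(trials)) nrow(trials) else
    sum(vapply(data_by_subj, function(d) if (is.data.frame(d)) nrow(d) else length(d),
               numeric(1)))
  estimates <- dplyr::bind_rows(lapply(seq_len(N), function(i) {
    tibble(subject_id = names(data_by_subj)[i], parameter = pn,
           z = theta_z[i, ],
           estimate = as.numeric(to_natural(theta_z[i, ])),
           laplace_var = sigma_diag[i, ])
  }))
  structure(
    list(estimates = estimates, Sigma = Sigmas,
         hyper = list(mu = hyper$mu, sigma2 = hyper$sigma2),
         trace = dplyr::bind_rows(trace),
         interface = interface, spec = interface$spec,
         n_subjects = N, n_trials = n_trials,
         n_choices = 2L * n_trials,
         converged = converged, iterations = length(trace),
         flagged_subjects = flagged,
         seed = seed),
    class = "twostep_fit"
  )
}

#' @export
print.twostep_fit <- function(x, ...) {
  cat(sprintf("<twostep_fit> %s: %d subjects, %d trials, EM %s in %d iter\n",
              if (!is.null(x$spec)) x$spec$label else "custom model",
              x$n_subjects, x$n_trials,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  mu_nat <- to_natural(x$hyper$mu)
  cat("  group means (natural scale):",
      paste(sprintf("%s=%.3f", names(mu_nat), mu_nat), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.twostep_fit <- function(x, ...) x$estimates

#' @export
glance.twostep_fit <- function(x, ...) {
  tibble(n_subjects = x$n_subjects, n_trials = x$n_trials,
         n_choices = x$n_choices,
         n_params = length(x$interface$param_names),
         iterations = x$iterations, converged = x$converged,
         objective = x$trace$objective[nrow(x$trace)])
}
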