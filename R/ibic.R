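log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Integrated BIC by Monte-Carlo model evidence
#'
#' Approximates each subject's evidence `p(C_i | hyperparameters)` by
#' averaging the likelihood over `K` parameter vectors drawn from the fitted
#' empirical prior (computed in log space with log-sum-exp), and penalizes
#' the summed log evidence by `|M|/2 * log |C|`, where `|C|` counts all
#' choices of all subjects (two per trial) and `|M|` the fitted
#' hyperparameters (two per free parameter). Lower iBIC indicates the better
#' model. The Monte-Carlo standard error of the total evidence is always
#' reported; a warning is raised when it exceeds 1 nat.
#'
#' @param trials The data the model was fit to (trials tibble or per-subject
#'   list, as in [em_fit()]).
#' @param fit A `twostep_fit`.
#' @param K Number of Monte-Carlo draws from the empirical prior (>= 100).
#' @param seed Seed for the draws; results are bit-reproducible given
#'   (`seed`, `K`).
#' @return A `twostep_ibic` list: `ibic`, `log_evidence`, `mc_se`,
#'   `n_choices`, `n_hyper`, `K`, `seed`, per-subject evidences.
#' @export
ibic <- function(trials, fit, K = 2000, seed = 1L) {
  stopifnot(inherits(fit, "twostep_fit"))
  if (K < 100)
    abort("K must be >= 100.", class = "twostep_input_error")
  interface <- fit$interface
  pn <- interface$param_names
  data_by_subj <- if (is.data.frame(trials)) split(trials, trials$subject_id) else trials
  set.seed(seed)
  draws <- sapply(pn, function(p)
    rnorm(K, fit$hyper$mu[[p]], sqrt(fit$hyper$sigma2[[p]])))
  draws <- matrix(draws, nrow = K, dimnames = list(NULL, pn))
  nat <- t(apply(draws, 1, to_natural))
  if (length(pn) == 1) nat <- matrix(nat, ncol = 1, dimnames = list(NULL, pn))

  evid <- numeric(length(data_by_subj))
  se2 <- numeric(length(data_by_subj))
  for (i in seq_along(data_by_subj)) {
    ll_fn <- if (!is.null(interface$make_loglik))
      interface$make_loglik(data_by_subj[[i]])
    else function(th) interface$loglik(th, data_by_subj[[i]])
    ll <- vapply(seq_len(K), function(k)
      ll_fn(setNames(nat[k, ], pn)), numeric(1))
    evid[i] <- log_sum_exp(ll) - log(K)
    wgt <- exp(ll - max(ll))
    se2[i] <- var(wgt) / (K * mean(wgt)^2)  # delta-method SE on the log scale
  }
  # |C| counts scored choices only (two per scored trial)
  n_trials <- sum(vapply(data_by_subj, function(d) {
    if (is.data.frame(d)) sum(d[["scored"]] %||% rep(TRUE, nrow(d))) else length(d)
  }, numeric(1)))
  n_choices <- 2L * n_trials
  n_hyper <- 2L * length(pn)
  mc_se <- sqrt(sum(se2))
  if (mc_se > 1)
    warn(sprintf("Monte-Carlo SE of the evidence is %.2f nats (> 1); increase K.",
                 mc_se))
  structure(
    list(ibic = -2 * sum(evid) + n_hyper * log(n_choices),
         log_evidence = sum(evid), subject_evidence = evid,
         mc_se = mc_se, n_choices = n_choices, n_hyper = n_hyper,
         K = K, seed = seed),
    class = "twostep_ibic"
  )
}

#' @export
print.twostep_ibic <- function(x, ...) {
  cat(sprintf("<twostep_ibic> iBIC %.1f (log evidence %.1f, MC SE %.3f, K=%d, |C|=%d, |M|=%d)\n",
              x$ibic, x$log_evidence, x$mc_se, x$K, x$n_choices, x$n_hyper))
  invisible(x)
}

#' Fit and compare a set of model specifications
#'
#' Runs [em_fit()] and [ibic()] for each specification on the same data with
#' a shared seed policy; the winner is the lowest iBIC. A specification that
#' fails to fit is recorded as failed and the comparison proceeds.
#'
#' @param trials Trials tibble (>= 2 subjects).
#' @param specs Named list of [model_spec()] objects (>= 1).
#' @param K,seed Monte-Carlo settings passed to [ibic()].
#' @param ... Passed to [em_fit()].
#' @return A `twostep_comparison`: tibble of per-model results plus the
#'   fitted objects.
#' @export
compare_models <- function(trials, specs, K = 2000, seed = 1L, ...) {
  if (!length(specs))
    abort("supply at least one model spec.", class = "twostep_input_error")
  if (is.null(names(specs)))
    names(specs) <- vapply(specs, function(s) s$label, character(1))
  fits <- vector("list", length(specs))
  names(fits) <- names(specs)
  rows <- lapply(seq_along(specs), function(j) {
    fit <- tryCatch(em_fit(trials, specs[[j]], seed = seed, ...),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      return(tibble(model = names(specs)[j], failed = TRUE,
                    n_params = length(specs[[j]]$free_params),
                    n_hyper = 2L * length(specs[[j]]$free_params),
                    converged = NA, log_evidence = NA_real_,
                    mc_se = NA_real_, ibic = NA_real_))
    }
    fits[[j]] <<- fit
    ib <- ibic(trials, fit, K = K, seed = seed)
    tibble(model = names(specs)[j], failed = FALSE,
           n_params = length(specs[[j]]$free_params),
           n_hyper = ib$n_hyper, converged = fit$converged,
           log_evidence = ib$log_evidence, mc_se = ib$mc_se, ibic = ib$ibic)
  })
  table <- dplyr::bind_rows(rows)
  table$winner <- !is.na(table$ibic) & table$ibic == min(table$ibic, na.rm = TRUE)
  structure(list(table = table, fits = fits),
            class = "twostep_comparison")
}

#' @export
print.twostep_comparison <- function(x, ...) {
  cat("<twostep_comparison>\n")
  print(x$table)
  invisible(x)
}

#' @export
tidy.twostep_comparison <- function(x, ...) x$table
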