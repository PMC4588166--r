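#' Lagged model-free / model-based regressor coding
#'
#' For each trial, codes whether events `k` trials back push a model-free or
#' a model-based learner toward repeating fractal A (+1) or away from it
#' (-1): `MF_k = choice_sign(t-k) * reward_sign(t-k)` and
#' `MB_k = MF_k * transition_sign(t-k)` with common coded +1, so the two
#' systems agree after common and disagree after uncommon transitions. Lags
#' never cross a day or block boundary; undefined lags are coded 0.
#'
#' @param trials Trials tibble.
#' @param n_back Number of lags (default 3).
#' @return The input plus `response` (1 if fractal A chosen first) and
#'   columns `MF1..MFk`, `MB1..MBk`.
#' @export
code_3back <- function(trials, n_back = 3L) {
  out <- trials |>
    dplyr::arrange(.data$subject_id, .data$day, .data$block, .data$trial) |>
    dplyr::group_by(.data$subject_id, .data$day, .data$block) |>
    dplyr::mutate(
      response = as.integer(.data$choice1 == "A"),
      .cs = ifelse(.data$choice1 == "A", 1, -1),
      .rs = ifelse(.data$reward == 1L, 1, -1),
      .ts = ifelse(.data$transition == "common", 1, -1)
    )
  for (k in seq_len(n_back)) {
    out <- out |>
      dplyr::mutate(
        !!paste0("MF", k) := dplyr::lag(.data$.cs * .data$.rs, k, default = 0),
        !!paste0("MB", k) := dplyr::lag(.data$.cs * .data$.rs * .data$.ts, k,
                                        default = 0)
      )
  }
  out |>
    dplyr::ungroup() |>
    dplyr::select(-".cs", -".rs", -".ts")
}

# ridge-penalized logistic regression by Newton iterations; the penalty is
# 0.5 * penalty * sum(beta^2) over non-intercept coefficients
ridge_logistic <- function(X, y, penalty = 0.01, max_iter = 100, tol = 1e-9) {
  k <- ncol(X)
  P <- diag(c(0, rep(penalty, k - 1)), k)
  beta <- numeric(k)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    g <- drop(crossprod(X, y - p)) - drop(P %*% beta)
    W <- p * (1 - p)
    H <- crossprod(X, X * W) + P
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) return(list(beta = beta, converged = FALSE))
    beta <- beta + step
    if (max(abs(g)) < tol) return(list(beta = beta, converged = TRUE))
  }
  list(beta = beta, converged = max(abs(g)) < 1e-4)
}

#' Random-effects lagged logistic regression
#'
#' Fits a per-subject logistic regression of the first-stage response on the
#' six lagged model-free/model-based regressors (with intercept and a small
#' ridge penalty against separation on short sessions), then summarizes at
#' the group level with one-sample t-tests per coefficient — the two-stage
#' summary-statistics (random effects) procedure. Per-subject summed MF and
#' MB indices (sums of the three lag coefficients) are reported with
#' confidence intervals.
#'
#' @param design Output of [code_3back()], optionally pre-filtered (e.g. by
#'   condition or day).
#' @param penalty Ridge penalty on non-intercept coefficients.
#' @param conf_level Confidence level for index intervals.
#' @return A `twostep_lag_fit`: per-subject `coefficients`, `group_stats`
#'   (mean, SEM, t, df, p per term), per-subject `indices`, and
#'   `index_stats`.
#' @export
fit_lag_regression <- function(design, penalty = 0.01, conf_level = 0.95) {
  terms <- grep("^M[FB][0-9]+$", names(design), value = TRUE)
  terms <- terms[order(substr(terms, 1, 2), as.integer(substring(terms, 3)))]
  subj <- split(design, design$subject_id)
  if (length(subj) < 2)
    abort("group inference requires >= 2 subjects.",
          class = "twostep_input_error")
  coefs <- list()
  flagged <- character(0)
  for (s in names(subj)) {
    d <- subj[[s]]
    X <- cbind(`(Intercept)` = 1, as.matrix(d[terms]))
    fit <- ridge_logistic(X, d$response, penalty = penalty)
    if (!fit$converged || any(abs(fit$beta) > 15)) {
      flagged <- c(flagged, s)
      next
    }
    coefs[[s]] <- tibble(subject_id = s,
                         term = c("(Intercept)", terms),
                         estimate = fit$beta)
  }
  if (length(flagged))
    warn(sprintf("dropped %d subject(s) with separated/non-converged fits: %s",
                 length(flagged), paste(flagged, collapse = ", ")))
  coefficients <- dplyr::bind_rows(coefs)
  group_stats <- coefficients |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      mean = mean(.data$estimate),
      sem = sd(.data$estimate) / sqrt(dplyr::n()),
      t = unname(t.test(.data$estimate)$statistic),
      df = dplyr::n() - 1L,
      p = t.test(.data$estimate)$p.value,
      .groups = "drop"
    )
  mf_terms <- grep("^MF", terms, value = TRUE)
  mb_terms <- grep("^MB", terms, value = TRUE)
  indices <- coefficients |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      mf_index = sum(.data$estimate[.data$term %in% mf_terms]),
      mb_index = sum(.data$estimate[.data$term %in% mb_terms]),
      .groups = "drop"
    )
  idx_stats <- function(x, name) {
    tt <- t.test(x, conf.level = conf_level)
    tibble(index = name, mean = mean(x),
           ci_low = tt$conf.int[1], ci_high = tt$conf.int[2],
           t = unname(tt$statistic), df = length(x) - 1L, p = tt$p.value)
  }
  structure(
    list(coefficients = coefficients, group_stats = group_stats,
         indices = indices,
         index_stats = dplyr::bind_rows(idx_stats(indices$mf_index, "MF"),
                                        idx_stats(indices$mb_index, "MB")),
         flagged_subjects = flagged, penalty = penalty),
    class = "twostep_lag_fit"
  )
}

#' @export
print.twostep_lag_fit <- function(x, ...) {
  cat(sprintf("<twostep_lag_fit> %d subjects\n",
              length(unique(x$coefficients$subject_id))))
  print(x$group_stats)
  invisible(x)
}

#' @export
tidy.twostep_lag_fit <- function(x, ...) x$group_stats
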