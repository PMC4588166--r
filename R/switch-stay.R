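#' Switch-stay probability table
#'
#' The probability of repeating the previous first-stage choice as a
#' function of the previous trial's transition (common vs. uncommon) and
#' outcome (rewarded vs. unrewarded) — the canonical behavioural signature
#' separating model-free (reward main effect) from model-based
#' (reward-by-transition crossover) control. Pairs never cross day or block
#' boundaries; a subject cell with fewer than `min_pairs` consecutive-trial
#' pairs is reported missing, not 0.
#'
#' @param trials Trials tibble.
#' @param by Extra grouping columns for the per-subject cells (default
#'   condition and day of the current trial).
#' @param min_pairs Minimum pairs per cell.
#' @return A `twostep_switch_stay`: `subject` (per-subject cell
#'   probabilities and pair counts) and `group` (mean and SEM across
#'   subjects per cell).
#' @export
switch_stay_table <- function(trials, by = c("condition", "day"),
                              min_pairs = 2L) {
  pairs <- stay_pairs(trials)
  subject <- pairs |>
    dplyr::group_by(.data$subject_id, .data$group,
                    dplyr::across(dplyr::all_of(by)),
                    transition = .data$prev_transition,
                    rewarded = ifelse(.data$prev_reward == 1L,
                                      "rewarded", "unrewarded")) |>
    dplyr::summarise(p_stay = mean(.data$stay), n_pairs = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(p_stay = ifelse(.data$n_pairs < min_pairs,
                                  NA_real_, .data$p_stay))
  group <- subject |>
    dplyr::group_by(.data$group, dplyr::across(dplyr::all_of(by)),
                    .data$transition, .data$rewarded) |>
    dplyr::summarise(
      mean_stay = mean(.data$p_stay, na.rm = TRUE),
      sem = sd(.data$p_stay, na.rm = TRUE) /
        sqrt(sum(!is.na(.data$p_stay))),
      n_subjects = sum(!is.na(.data$p_stay)),
      .groups = "drop"
    )
  structure(list(subject = subject, group = group, by = by),
            class = "twostep_switch_stay")
}

#' @export
print.twostep_switch_stay <- function(x, ...) {
  cat("<twostep_switch_stay>\n")
  print(x$group)
  invisible(x)
}

#' @export
tidy.twostep_switch_stay <- function(x, ...) x$group

# residualize y against its parent column (Gram-Schmidt step)
orthogonalize <- function(y, parent) {
  denom <- sum(parent^2)
  if (denom == 0) return(y)
  y - sum(y * parent) / denom * parent
}

#' One-back switch-stay regression with day interactions
#'
#' Per-subject logistic regression of staying with the previous first-stage
#' choice on the previous trial's reward (+1/-1), transition (+1/-1), their
#' product, centred day (day - 2), and day-interaction terms, where each
#' day-interaction regressor is residualized (Gram-Schmidt, within subject)
#' against its parent term — `reward x day` against `reward`,
#' `transition x day` against `transition`, and
#' `reward x transition x day` against `reward x transition` — so it
#' captures only variance unexplained by the parent. Group-level inference
#' is by one-sample t-tests across subjects.
#'
#' @param trials Trials tibble with all three days per subject; subjects
#'   missing a day are dropped with a warning.
#' @param condition Optional condition filter (`"single"` or `"dual"`).
#' @param penalty Ridge penalty on non-intercept coefficients.
#' @return A `twostep_oneback_fit` with per-subject `coefficients`, group
#'   `group_stats`, and the per-subject design matrices in `designs`.
#' @export
oneback_regression <- function(trials, condition = NULL, penalty = 0.01) {
  if (!is.null(condition))
    trials <- dplyr::filter(trials, .data$condition == !!condition)
  pairs <- stay_pairs(trials)
  full_days <- pairs |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(n_days = dplyr::n_distinct(.data$day), .groups = "drop")
  dropped <- full_days$subject_id[full_days$n_days < 3]
  if (length(dropped))
    warn(sprintf("dropped %d subject(s) without all 3 days: %s",
                 length(dropped), paste(dropped, collapse = ", ")))
  pairs <- pairs[!pairs$subject_id %in% dropped, ]
  terms <- c("reward", "transition", "reward_x_transition", "day",
             "reward_x_day", "transition_x_day", "reward_x_transition_x_day")
  subj <- split(pairs, pairs$subject_id)
  if (length(subj) < 2)
    abort("group inference requires >= 2 subjects with complete data.",
          class = "twostep_input_error")
  coefs <- list()
  designs <- list()
  for (s in names(subj)) {
    d <- subj[[s]]
    rew <- ifelse(d$prev_reward == 1L, 1, -1)
    trans <- ifelse(d$prev_transition == "common", 1, -1)
    rxt <- rew * trans
    day_c <- d$day - 2
    X <- cbind(
      `(Intercept)` = 1, reward = rew, transition = trans,
      reward_x_transition = rxt, day = day_c,
      reward_x_day = orthogonalize(rew * day_c, rew),
      transition_x_day = orthogonalize(trans * day_c, trans),
      reward_x_transition_x_day = orthogonalize(rxt * day_c, rxt)
    )
    designs[[s]] <- X
    fit <- ridge_logistic(X, d$stay, penalty = penalty)
    coefs[[s]] <- tibble(subject_id = s, term = colnames(X),
                         estimate = fit$beta)
  }
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
  structure(list(coefficients = coefficients, group_stats = group_stats,
                 designs = designs, terms = terms),
            class = "twostep_oneback_fit")
}

#' @export
print.twostep_oneback_fit <- function(x, ...) {
  cat(sprintf("<twostep_oneback_fit> %d subjects\n", length(x$designs)))
  print(x$group_stats)
  invisible(x)
}

#' @export
tidy.twostep_oneback_fit <- function(x, ...) x$group_stats
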