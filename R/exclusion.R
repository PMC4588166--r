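# consecutive first-stage choice pairs (never crossing day or block
# boundaries): one row per trial that has an immediate predecessor
stay_pairs <- function(trials) {
  trials |>
    dplyr::arrange(.data$subject_id, .data$day, .data$block, .data$trial) |>
    dplyr::group_by(.data$subject_id, .data$day, .data$block) |>
    dplyr::mutate(
      prev_trial = dplyr::lag(.data$trial),
      prev_choice1 = dplyr::lag(.data$choice1),
      prev_transition = dplyr::lag(.data$transition),
      prev_reward = dplyr::lag(.data$reward)
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$prev_trial),
                  .data$prev_trial == .data$trial - 1L) |>
    dplyr::mutate(stay = as.integer(.data$choice1 == .data$prev_choice1))
}

#' Subject exclusion filter
#'
#' Applies the three preregistered-style exclusion rules, all with strict
#' inequalities: (1) concurrent-task accuracy below 70% on any day that has
#' dual-task trials; (2) the same first-stage fractal chosen on more than
#' 90% of trials on any day; (3) probability of repeating the first-stage
#' action after a common, rewarded transition below 0.25 on day 1. A subject
#' is excluded iff at least one rule triggers; a rule whose data are absent
#' (e.g. no dual-task trials) is skipped, not triggered.
#'
#' @param trials Trials tibble.
#' @param stroop_min,same_fractal_max,stay_min Rule thresholds.
#' @return Tibble with one row per subject: `included`, the three rule
#'   flags, and the supporting values (`min_stroop_acc`,
#'   `max_same_fractal`, `stay_common_rewarded`).
#' @export
exclusion_filter <- function(trials, stroop_min = 0.70,
                             same_fractal_max = 0.90, stay_min = 0.25) {
  stroop <- trials |>
    dplyr::filter(.data$condition == "dual", !is.na(.data$stroop_correct)) |>
    dplyr::group_by(.data$subject_id, .data$day) |>
    dplyr::summarise(acc = mean(.data$stroop_correct), .groups = "drop") |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(min_stroop_acc = min(.data$acc, Inf),
                     stroop_below = any(.data$acc < stroop_min),
                     .groups = "drop")

  fractal <- trials |>
    dplyr::group_by(.data$subject_id, .data$day) |>
    dplyr::summarise(
      same = max(mean(.data$choice1 == "A"), mean(.data$choice1 == "B")),
      .groups = "drop"
    ) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(max_same_fractal = max(.data$same),
                     fractal_above = any(.data$same > same_fractal_max),
                     .groups = "drop")

  stay1 <- stay_pairs(trials) |>
    dplyr::filter(.data$day == 1L, .data$prev_transition == "common",
                  .data$prev_reward == 1L) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(stay_common_rewarded = mean(.data$stay),
                     stay_below = .data$stay_common_rewarded < stay_min,
                     .groups = "drop")

  out <- trials |>
    dplyr::distinct(.data$subject_id, .data$group) |>
    dplyr::left_join(stroop, by = "subject_id") |>
    dplyr::left_join(fractal, by = "subject_id") |>
    dplyr::left_join(stay1, by = "subject_id") |>
    dplyr::mutate(
      stroop_below_70 = dplyr::coalesce(.data$stroop_below, FALSE),
      same_fractal_above_90 = dplyr::coalesce(.data$fractal_above, FALSE),
      stay_common_rewarded_below_0.25 = dplyr::coalesce(.data$stay_below, FALSE),
      included = !(.data$stroop_below_70 | .data$same_fractal_above_90 |
                     .data$stay_common_rewarded_below_0.25)
    ) |>
    dplyr::select("subject_id", "group", "included", "stroop_below_70",
                  "same_fractal_above_90", "stay_common_rewarded_below_0.25",
                  "min_stroop_acc", "max_same_fractal",
                  "stay_common_rewarded")
  out
}

#' Keep only included subjects
#'
#' @param trials Trials tibble.
#' @param report Optional precomputed [exclusion_filter()] report.
#' @return The trials of subjects passing all exclusion rules.
#' @export
apply_exclusions <- function(trials, report = NULL) {
  report <- report %||% exclusion_filter(trials)
  dplyr::semi_join(trials, report[report$included, "subject_id", drop = FALSE],
                   by = "subject_id")
}
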