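#' Concurrent-task (numerical Stroop) accuracy summary
#'
#' Proportion correct among dual-task trials with a recorded response, per
#' subject and day, with group means and SEMs. Subjects (or subject-days)
#' without dual-task trials are absent from the summary, not 0%. Optionally
#' runs paired t-tests between consecutive days (and first vs. last) on
#' subjects with complete data.
#'
#' @param trials Trials tibble.
#' @param day_tests If `TRUE`, include across-day paired t-tests per group.
#' @return A `twostep_stroop_summary`: `subject` (per subject/day accuracy),
#'   `group` (per group/day mean, SEM, n), and optionally `tests`.
#' @export
stroop_summary <- function(trials, day_tests = FALSE) {
  dual <- trials |>
    dplyr::filter(.data$condition == "dual", !is.na(.data$stroop_correct))
  subject <- dual |>
    dplyr::group_by(.data$subject_id, .data$group, .data$day) |>
    dplyr::summarise(accuracy = mean(.data$stroop_correct),
                     n_trials = dplyr::n(), .groups = "drop")
  group <- subject |>
    dplyr::group_by(.data$group, .data$day) |>
    dplyr::summarise(mean_accuracy = mean(.data$accuracy),
                     sem = sd(.data$accuracy) / sqrt(dplyr::n()),
                     n_subjects = dplyr::n(), .groups = "drop")
  tests <- NULL
  if (day_tests) {
    tests <- list()
    for (g in unique(subject$group)) {
      sg <- subject[subject$group == g, ]
      days <- sort(unique(sg$day))
      if (length(days) < 2) next
      prs <- utils::combn(days, 2, simplify = FALSE)
      for (pr in prs) {
        wide <- tidyr::pivot_wider(sg[sg$day %in% pr, c("subject_id", "day", "accuracy")],
                                   names_from = "day", values_from = "accuracy")
        wide <- wide[stats::complete.cases(wide), ]
        if (nrow(wide) < 2) next
        tt <- t.test(wide[[2]], wide[[3]], paired = TRUE)
        tests[[length(tests) + 1L]] <- tibble(
          group = g, day_a = pr[1], day_b = pr[2],
          mean_diff = unname(tt$estimate), t = unname(tt$statistic),
          df = unname(tt$parameter), p = tt$p.value)
      }
    }
    tests <- dplyr::bind_rows(tests)
  }
  structure(list(subject = subject, group = group, tests = tests),
            class = "twostep_stroop_summary")
}

#' @export
print.twostep_stroop_summary <- function(x, ...) {
  cat("<twostep_stroop_summary>\n")
  print(x$group)
  invisible(x)
}

#' @export
tidy.twostep_stroop_summary <- function(x, ...) x$group
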