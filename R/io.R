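TRIAL_COL_TYPES <- readr::cols(
  subject_id = readr::col_character(),
  group = readr::col_character(),
  day = readr::col_integer(),
  block = readr::col_integer(),
  trial = readr::col_integer(),
  condition = readr::col_character(),
  choice1 = readr::col_character(),
  transition = readr::col_character(),
  state2 = readr::col_character(),
  choice2 = readr::col_character(),
  reward = readr::col_integer(),
  stroop_correct = readr::col_integer()
)

validate_trials <- function(trials) {
  missing_cols <- setdiff(REQUIRED_TRIAL_COLS, names(trials))
  if (length(missing_cols))
    abort(paste0("missing trial columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "twostep_input_error")
  extra <- setdiff(names(trials), REQUIRED_TRIAL_COLS)
  if (length(extra))
    warn(paste0("ignoring unknown columns: ", paste(extra, collapse = ", ")))
  checks <- list(
    group = function(x) x %in% c("high_load", "low_load"),
    condition = function(x) x %in% c("single", "dual"),
    choice1 = function(x) x %in% c("A", "B"),
    choice2 = function(x) x %in% c("A", "B"),
    transition = function(x) x %in% c("common", "uncommon"),
    state2 = function(x) x %in% c("s_B", "s_C"),
    reward = function(x) x %in% c(0L, 1L),
    stroop_correct = function(x) is.na(x) | x %in% c(0L, 1L)
  )
  for (col in names(checks)) {
    bad <- which(!checks[[col]](trials[[col]]))
    if (length(bad))
      abort(sprintf("invalid value in column '%s' at row %d: %s",
                    col, bad[1], as.character(trials[[col]][bad[1]])),
            class = "twostep_input_error")
  }
  # n/a concurrent-task outcome iff single-task
  bad <- which(trials$condition == "single" & !is.na(trials$stroop_correct))
  if (length(bad))
    abort(sprintf("stroop_correct must be NA on single-task trials (row %d).",
                  bad[1]),
          class = "twostep_input_error")
  invisible(trials)
}

#' Read a trial table
#'
#' Reads the documented comma-separated dialect (header row, UTF-8, no index
#' column), validates every categorical column (errors name the offending
#' row and column), and returns the trials ordered chronologically within
#' subject. An empty file with a header is an empty dataset, not an error.
#'
#' @param path CSV file path.
#' @return Validated trials tibble.
#' @export
read_trials <- function(path) {
  trials <- readr::read_csv(path, col_types = TRIAL_COL_TYPES)
  validate_trials(trials)
  trials <- trials[REQUIRED_TRIAL_COLS]
  dplyr::arrange(trials, .data$subject_id, .data$day, .data$block, .data$trial)
}

#' Write a trial table
#'
#' @param trials Trials tibble.
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  readr::write_csv(trials[REQUIRED_TRIAL_COLS], path)
  invisible(path)
}

#' Read or write a pipeline configuration
#'
#' Configurations round-trip losslessly through YAML: task and cohort
#' sections mirror [task_config()] and [cohort_spec()] fields; `fit`
#' controls the model fits; `analyses` toggles pipeline stages.
#'
#' @param path YAML file path.
#' @param config A pipeline configuration list ([pipeline_config()]).
#' @return `read_pipeline_config`: the configuration list;
#'   `write_pipeline_config`: `path`, invisibly.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- pipeline_config(seed = raw$seed %||% 1L)
  task <- raw$task %||% list()
  task$protocol <- NULL
  cfg$task <- do.call(task_config, task)
  ch <- raw$cohort %||% list()
  args <- list()
  if (!is.null(ch$n_subjects)) args$n_subjects <- unlist(ch$n_subjects)
  if (!is.null(ch$hyper_mean_natural)) args$hyper_mean_natural <- ch$hyper_mean_natural
  if (!is.null(ch$hyper_sd)) args$hyper_sd <- unlist(ch$hyper_sd)
  if (!is.null(ch$offsets)) args$offsets <- dplyr::bind_rows(ch$offsets)
  if (!is.null(ch$stroop_p_correct))
    args$stroop_p_correct <- dplyr::bind_rows(ch$stroop_p_correct)
  args$seed <- raw$seed %||% 1L
  cfg$cohort <- do.call(cohort_spec, args)
  cfg$fit <- modifyList(cfg$fit, raw$fit %||% list())
  cfg$analyses <- modifyList(cfg$analyses, raw$analyses %||% list())
  cfg
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  out <- list(
    seed = config$seed,
    task = config$task[c("p_common", "walk_sd", "walk_low", "walk_high",
                         "walk_pool_size", "trials_single_block",
                         "trials_dual_block", "blocks_per_day", "days")],
    cohort = list(
      n_subjects = as.list(config$cohort$n_subjects),
      hyper_mean_natural = as.list(to_natural(config$cohort$hyper_mu)),
      hyper_sd = as.list(config$cohort$hyper_sd),
      offsets = purrr::transpose(as.list(config$cohort$offsets)),
      stroop_p_correct = purrr::transpose(as.list(config$cohort$stroop_p_correct))
    ),
    fit = config$fit,
    analyses = config$analyses
  )
  yaml::write_yaml(out, path)
  invisible(path)
}
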