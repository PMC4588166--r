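#' Default block protocol
#'
#' Per-group, per-day sequences of task blocks. The high-load group plays
#' alternating single-task (128-trial) and dual-task (64-trial) blocks on all
#' three days; the low-load group plays two consecutive single-task blocks on
#' days 1-2 and the alternating protocol on day 3.
#'
#' @return A named list (`high_load`, `low_load`) of per-day character vectors
#'   of block conditions.
#' @export
default_protocol <- function() {
  alt <- c("single", "dual", "single", "dual")
  list(
    high_load = list(`1` = alt, `2` = alt, `3` = alt),
    low_load  = list(`1` = c("single", "single"),
                     `2` = c("single", "single"),
                     `3` = alt)
  )
}

#' Task configuration
#'
#' Parameters of the two-step task environment: the first-stage transition
#' probability, the Gaussian reward-probability walks (step SD, reflecting
#' bounds, pool size) and the block protocol. Defaults reproduce the study
#' design: 70% common transitions, walk SD 0.025 with bounds \[0.25, 0.75\],
#' a pool of 15 walk sets, 128-trial single-task and 64-trial dual-task
#' blocks, two blocks of each type per day, three days.
#'
#' @param p_common Probability of the common first-stage transition, in (0.5, 1).
#' @param walk_sd SD of the Gaussian walk step, in probability units per trial.
#' @param walk_low,walk_high Reflecting bounds on every reward probability.
#' @param walk_pool_size Number of walk sets in the pregenerated pool.
#' @param trials_single_block,trials_dual_block Trials per block by condition.
#' @param blocks_per_day Blocks of each condition per day (informational; the
#'   `protocol` list is authoritative).
#' @param days Number of training days.
#' @param protocol Named list mapping group to per-day block sequences; see
#'   [default_protocol()].
#' @return A `twostep_config` object (a validated list).
#' @export
task_config <- function(p_common = 0.7, walk_sd = 0.025,
                        walk_low = 0.25, walk_high = 0.75,
                        walk_pool_size = 15,
                        trials_single_block = 128, trials_dual_block = 64,
                        blocks_per_day = 2, days = 3,
                        protocol = default_protocol()) {
  if (!(p_common > 0.5 && p_common < 1))
    abort("`p_common` must lie in (0.5, 1).", class = "twostep_config_error")
  if (!(walk_sd >= 0))
    abort("`walk_sd` must be non-negative.", class = "twostep_config_error")
  if (!(walk_low >= 0 && walk_low < walk_high && walk_high <= 1))
    abort("walk bounds must satisfy 0 <= walk_low < walk_high <= 1.",
          class = "twostep_config_error")
  counts <- c(walk_pool_size, trials_single_block, trials_dual_block,
              blocks_per_day, days)
  if (any(counts < 1))
    abort("all counts must be >= 1.", class = "twostep_config_error")
  structure(
    list(p_common = p_common, walk_sd = walk_sd,
         walk_low = walk_low, walk_high = walk_high,
         walk_pool_size = as.integer(walk_pool_size),
         trials_single_block = as.integer(trials_single_block),
         trials_dual_block = as.integer(trials_dual_block),
         blocks_per_day = as.integer(blocks_per_day),
         days = as.integer(days), protocol = protocol),
    class = "twostep_config"
  )
}

#' @export
print.twostep_config <- function(x, ...) {
  cat("<twostep_config>\n")
  cat(sprintf("  p_common: %.2f | walk: sd %.3f in [%.2f, %.2f], pool %d\n",
              x$p_common, x$walk_sd, x$walk_low, x$walk_high, x$walk_pool_size))
  cat(sprintf("  blocks: single %d / dual %d trials, %d day(s)\n",
              x$trials_single_block, x$trials_dual_block, x$days))
  invisible(x)
}

# block layout for one group-day: tibble(block, condition, n_trials)
day_protocol <- function(config, group, day) {
  seqs <- config$protocol[[group]]
  if (is.null(seqs))
    abort(sprintf("unknown group '%s' in protocol.", group),
          class = "twostep_input_error")
  conditions <- seqs[[as.character(day)]]
  if (is.null(conditions))
    abort(sprintf("no protocol for group '%s', day %s.", group, day),
          class = "twostep_input_error")
  tibble(
    block = seq_along(conditions),
    condition = conditions,
    n_trials = ifelse(conditions == "single",
                      config$trials_single_block, config$trials_dual_block)
  )
}

# longest day across all groups/days, used to size walks
max_trials_per_day <- function(config) {
  m <- 0L
  for (g in names(config$protocol)) {
    for (d in names(config$protocol[[g]])) {
      m <- max(m, sum(day_protocol(config, g, as.integer(d))$n_trials))
    }
  }
  m
}
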