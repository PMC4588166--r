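# shared fixtures, all generated in code

# single-condition config: `n_blocks` single-task blocks of `block_trials`
# trials per day, for `days` days, one group
flat_config <- function(block_trials = 150, n_blocks = 2, days = 1,
                        group = "high_load", ...) {
  proto <- setNames(
    lapply(seq_len(days), function(d) rep("single", n_blocks)),
    seq_len(days)
  )
  task_config(trials_single_block = block_trials, days = days,
              protocol = setNames(list(proto), group), ...)
}

# cohort of agents with *identical, exactly specified* parameters (allows
# w = 0 / w = 1 exactly, unlike the Gaussian cohort generator)
sim_agents <- function(n, params, config, seed = 1L, group = "high_load") {
  pool <- generate_walk_pool(config, seed = seed)
  days <- as.integer(names(config$protocol[[group]]))
  dplyr::bind_rows(lapply(seq_len(n), function(i) {
    dplyr::bind_rows(lapply(days, function(d) {
      ws <- pool[[1L + (i + d) %% length(pool)]]
      simulate_session(params, config, ws, seed = seed + 1000L * i + d,
                       group = group, day = d,
                       subject_id = sprintf("s%02d", i))
    }))
  }))
}

# Gaussian cohort with no condition/day offsets, single group
flat_cohort_spec <- function(n = 10, seed = 1L,
                             hyper_mean_natural = list(alpha = 0.5, beta = 5,
                                                       eps = 0.05, w = 0.6),
                             hyper_sd = c(alpha = 0.5, beta = 0.5,
                                          eps = 0.5, w = 0.5)) {
  cohort_spec(n_subjects = c(high_load = n),
              hyper_mean_natural = hyper_mean_natural,
              hyper_sd = hyper_sd,
              offsets = default_offsets()[0, ],
              seed = seed)
}

# minimal hand-built trial tibble; transition kept consistent with
# choice1/state2 under the default transition structure
make_trials <- function(choice1, reward, transition = NULL,
                        choice2 = "A", day = 1L, block = 1L,
                        subject_id = "s01", group = "high_load",
                        condition = "single", stroop_correct = NA_integer_) {
  n <- length(choice1)
  transition <- transition %||% rep("common", n)
  state2 <- ifelse((choice1 == "A") == (transition == "common"), "s_B", "s_C")
  day <- rep_len(as.integer(day), n)
  block <- rep_len(as.integer(block), n)
  tibble::tibble(
    subject_id = subject_id, group = group,
    day = day, block = block,
    trial = stats::ave(seq_len(n), day, block, FUN = seq_along),
    condition = rep_len(condition, n),
    choice1 = choice1, transition = transition, state2 = state2,
    choice2 = rep_len(choice2, n), reward = as.integer(reward),
    stroop_correct = rep_len(as.integer(stroop_correct), n)
  )
}

`%||%` <- rlang::`%||%`
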