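test_that("exclusion rules use the printed strict thresholds", {
  # helper: n dual trials on one day with k correct concurrent responses
  dual_day <- function(sid, day, k, n = 100) {
    make_trials(choice1 = rep(c("A", "B"), length.out = n),
                reward = rep(0:1, length.out = n),
                day = day, subject_id = sid, condition = "dual",
                stroop_correct = rep(c(1L, 0L), c(k, n - k)))
  }
  ok_day1 <- function(sid) {
    # day-1 block with plenty of stays after common-rewarded trials
    make_trials(choice1 = rep(c("A", "A", "B", "B"), 10),
                reward = rep(1, 40), day = 1, subject_id = sid)
  }

  t_69 <- dplyr::bind_rows(ok_day1("s69"), dual_day("s69", 2, 69))
  t_70 <- dplyr::bind_rows(ok_day1("s70"), dual_day("s70", 2, 70))
  rep_ <- exclusion_filter(dplyr::bind_rows(t_69, t_70))
  expect_false(rep_$included[rep_$subject_id == "s69"])
  expect_true(rep_$stroop_below_70[rep_$subject_id == "s69"])
  expect_true(rep_$included[rep_$subject_id == "s70"])   # exactly 70%: kept

  # same-fractal rule: > 90% on any day excludes, exactly 90% does not
  frac_day <- function(sid, n_a) {
    day2 <- make_trials(choice1 = rep(c("A", "B"), c(n_a, 100 - n_a)),
                        reward = rep(c(1, 0), 50), day = 2, subject_id = sid)
    dplyr::bind_rows(ok_day1(sid), day2)
  }
  rep2 <- exclusion_filter(dplyr::bind_rows(frac_day("s91", 91),
                                            frac_day("s90", 90)))
  expect_false(rep2$included[rep2$subject_id == "s91"])
  expect_true(rep2$same_fractal_above_90[rep2$subject_id == "s91"])
  expect_true(rep2$included[rep2$subject_id == "s90"])

  # stay-after-common-rewarded rule on day 1: < 0.25 excludes
  all_stay <- make_trials(choice1 = rep(c("A", "A", "B", "B"), 8),
                          reward = rep(1, 32),
                          day = 1, subject_id = "sstay")
  all_switch <- make_trials(choice1 = rep(c("A", "B"), 15),
                            reward = rep(1, 30), day = 1,
                            subject_id = "sswitch")
  rep3 <- exclusion_filter(dplyr::bind_rows(all_stay, all_switch))
  expect_true(rep3$included[rep3$subject_id == "sstay"])
  expect_false(rep3$included[rep3$subject_id == "sswitch"])
  expect_true(rep3$stay_common_rewarded_below_0.25[rep3$subject_id == "sswitch"])

  # idempotence and order-independence over subjects
  joined <- dplyr::bind_rows(t_69, t_70, frac_day("s91", 91))
  r_a <- exclusion_filter(joined)
  r_b <- exclusion_filter(joined[sample.int(nrow(joined)), ])
  expect_equal(r_a, dplyr::arrange(r_b, match(subject_id, r_a$subject_id)))
  kept <- apply_exclusions(joined, r_a)
  expect_equal(exclusion_filter(kept)$included, rep(TRUE, 1))
})

test_that("lagged MF/MB codes enumerate correctly over all 8 cells", {
  cells <- expand.grid(choice = c("A", "B"),
                       transition = c("common", "uncommon"),
                       reward = c(1L, 0L), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cells))) {
    cl <- cells[i, ]
    tr <- make_trials(choice1 = c(cl$choice, "A"),
                      reward = c(cl$reward, 0),
                      transition = c(cl$transition, "common"))
    d <- code_3back(tr)
    cs <- if (cl$choice == "A") 1 else -1
    rs <- if (cl$reward == 1) 1 else -1
    ts <- if (cl$transition == "common") 1 else -1
    expect_equal(d$MF1[2], cs * rs)
    expect_equal(d$MB1[2], cs * rs * ts)
    expect_true(all(c(d$MF1[2], d$MB1[2]) %in% c(-1, 1)))
    if (cl$transition == "common") expect_equal(d$MF1[2], d$MB1[2])
    else expect_equal(d$MF1[2], -d$MB1[2])
  }
  # undefined lags (start of block / crossing boundaries) are zero
  two_blocks <- dplyr::bind_rows(
    make_trials(choice1 = rep("A", 4), reward = rep(1, 4), block = 1),
    make_trials(choice1 = rep("A", 4), reward = rep(1, 4), block = 2)
  )
  d2 <- code_3back(two_blocks)
  expect_equal(d2$MF1[c(1, 5)], c(0, 0))
  expect_equal(d2$MF3[c(3, 7)], c(0, 0))
  expect_equal(d2$MB2[c(2, 6)], c(0, 0))
  # all-common history: the two systems coincide
  all_common <- make_trials(choice1 = rep(c("A", "B"), 10),
                            reward = rep(c(1, 0), 10))
  dc <- code_3back(all_common)
  expect_equal(dc$MF1, dc$MB1)
  expect_equal(dc$MF3, dc$MB3)
})

test_that("the ridge logistic fit agrees with glm in the no-penalty limit", {
  set.seed(14)
  n <- 400
  X <- cbind(1, matrix(sample(c(-1, 0, 1), n * 3, replace = TRUE), n, 3))
  eta <- X %*% c(0.2, 0.8, -0.5, 0.3)
  y <- rbinom(n, 1, plogis(eta))
  ours <- twostepr:::ridge_logistic(X, y, penalty = 0)
  ref <- glm.fit(X, y, family = binomial())
  expect_equal(ours$beta, unname(coef(ref)), tolerance = 1e-6)
  # the penalty shrinks coefficients toward zero
  pen <- twostepr:::ridge_logistic(X, y, penalty = 5)
  expect_true(all(abs(pen$beta[-1]) < abs(ours$beta[-1])))
})

test_that("lag regression finds no structure in valueless choices", {
  cfg <- flat_config(block_trials = 150, n_blocks = 2)
  tr <- sim_agents(10, agent_params(beta = 0, eps = 0), cfg, seed = 8)
  fit <- fit_lag_regression(code_3back(tr))
  non_int <- fit$group_stats[fit$group_stats$term != "(Intercept)", ]
  expect_true(all(abs(non_int$mean) < 0.1))
  expect_equal(nrow(fit$indices), 10)
})

test_that("lag regression recovers the generative signatures", {
  cfg <- flat_config(block_trials = 150, n_blocks = 2)
  mb <- sim_agents(20, agent_params(alpha = 0.6, beta = 6, eps = 0.02, w = 1),
                   cfg, seed = 15)
  fit_mb <- fit_lag_regression(code_3back(mb))
  gs <- fit_mb$group_stats
  expect_gt(gs$mean[gs$term == "MB1"], 0)
  expect_lt(gs$p[gs$term == "MB1"], 0.05)

  mf <- sim_agents(20, agent_params(alpha = 0.6, beta = 6, eps = 0.02,
                                    w = 0, lambda = 1),
                   cfg, seed = 16)
  fit_mf <- fit_lag_regression(code_3back(mf))
  gs2 <- fit_mf$group_stats
  expect_gt(gs2$mean[gs2$term == "MF1"], 0)
  expect_lt(gs2$p[gs2$term == "MF1"], 0.05)

  # summed MB index ranks cohorts by generative w
  hy <- sim_agents(20, agent_params(alpha = 0.6, beta = 6, eps = 0.02,
                                    w = 0.5),
                   cfg, seed = 17)
  fit_hy <- fit_lag_regression(code_3back(hy))
  mb_index <- function(f) mean(f$indices$mb_index)
  expect_true(mb_index(fit_mf) < mb_index(fit_hy) &&
                mb_index(fit_hy) < mb_index(fit_mb))
})

test_that("switch-stay tables capture the canonical signatures", {
  # constant policy: every cell at 1
  stay_all <- make_trials(choice1 = rep("A", 40),
                          reward = rep(c(1, 0), 20),
                          transition = rep(c("common", "uncommon"), c(30, 10)))
  stay_all2 <- stay_all; stay_all2$subject_id <- "s02"
  tab <- switch_stay_table(dplyr::bind_rows(stay_all, stay_all2))
  expect_true(all(tab$subject$p_stay == 1))
  # first trial of each block contributes no pair
  expect_equal(sum(tab$subject$n_pairs) / 2, 39)

  cfg <- flat_config(block_trials = 200, n_blocks = 2)
  mf <- sim_agents(12, agent_params(alpha = 0.7, beta = 8, eps = 0.02,
                                    w = 0, lambda = 1), cfg, seed = 5)
  g_mf <- switch_stay_table(mf, by = "condition")$group
  cell <- function(g, tr, rw)
    g$mean_stay[g$transition == tr & g$rewarded == rw]
  # model-free: reward main effect for both transitions
  expect_gt(cell(g_mf, "common", "rewarded"),
            cell(g_mf, "common", "unrewarded"))
  expect_gt(cell(g_mf, "uncommon", "rewarded"),
            cell(g_mf, "uncommon", "unrewarded"))

  mb <- sim_agents(12, agent_params(alpha = 0.7, beta = 8, eps = 0.02,
                                    w = 1), cfg, seed = 6)
  g_mb <- switch_stay_table(mb, by = "condition")$group
  # model-based: reward-by-transition crossover
  expect_gt(cell(g_mb, "common", "rewarded"),
            cell(g_mb, "uncommon", "rewarded"))
  expect_gt(cell(g_mb, "uncommon", "unrewarded"),
            cell(g_mb, "common", "unrewarded"))
})

test_that("one-back day-interaction regressors are exactly orthogonalized", {
  cfg3 <- flat_config(block_trials = 80, n_blocks = 2, days = 3)
  tr <- sim_agents(6, agent_params(w = 0.5), cfg3, seed = 9)
  fit <- oneback_regression(tr)
  for (X in fit$designs) {
    expect_lt(abs(sum(X[, "reward_x_day"] * X[, "reward"])), 1e-10)
    expect_lt(abs(sum(X[, "transition_x_day"] * X[, "transition"])), 1e-10)
    expect_lt(abs(sum(X[, "reward_x_transition_x_day"] *
                        X[, "reward_x_transition"])), 1e-10)
  }
  # residualization is idempotent / leaves orthogonal vectors unchanged
  y <- c(1, -1, 1, -1)
  parent <- c(1, 1, -1, -1)
  expect_equal(twostepr:::orthogonalize(y, parent), y)
  once <- twostepr:::orthogonalize(c(1, 2, 3, 4), parent)
  expect_equal(twostepr:::orthogonalize(once, parent), once)

  # subjects without all 3 days are dropped with a warning
  partial <- tr[!(tr$subject_id == "s01" & tr$day == 3), ]
  expect_warning(f2 <- oneback_regression(partial), "s01")
  expect_false("s01" %in% names(f2$designs))
})

test_that("a w trend across days loads on the three-way interaction", {
  cfg3 <- flat_config(block_trials = 100, n_blocks = 2, days = 3)
  pool <- generate_walk_pool(cfg3, seed = 30)
  # w rising across days: day 1 mostly model-free, day 3 mostly model-based
  w_by_day <- c(0.1, 0.5, 0.9)
  tr <- dplyr::bind_rows(lapply(1:10, function(i) {
    dplyr::bind_rows(lapply(1:3, function(d) {
      simulate_session(agent_params(alpha = 0.6, beta = 6, eps = 0.02,
                                    w = w_by_day[d]),
                       cfg3, pool[[1 + (i + d) %% 15]],
                       seed = 40 + 100 * i + d,
                       day = d, subject_id = sprintf("s%02d", i))
    }))
  }))
  fit <- oneback_regression(tr)
  gs <- fit$group_stats
  expect_gt(gs$mean[gs$term == "reward_x_transition_x_day"], 0)
})

test_that("concurrent-task summaries respect missing-data contracts", {
  d1 <- make_trials(choice1 = rep("A", 10), reward = rep(1, 10),
                    condition = "dual", stroop_correct = 1L)
  s <- stroop_summary(d1)
  expect_equal(s$subject$accuracy, 1)
  # a subject without dual trials is absent, not 0%
  d2 <- make_trials(choice1 = rep("A", 10), reward = rep(1, 10),
                    subject_id = "s02")
  s2 <- stroop_summary(dplyr::bind_rows(d1, d2))
  expect_false("s02" %in% s2$subject$subject_id)

  # binomial sampling check at scale: 20 subjects x 128 dual trials at 0.82
  spec <- cohort_spec(n_subjects = c(high_load = 20),
                      stroop_p_correct = tibble::tibble(
                        group = "high_load", day = 1:3,
                        p_correct = c(0.82, 0.82, 0.82)),
                      seed = 44)
  co <- simulate_cohort(spec, task_config())
  g <- stroop_summary(co$trials)$group
  expect_lt(abs(g$mean_accuracy[g$day == 1] - 0.82), 0.02)
})
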