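# toy interfaces exercising the generic fitting machinery ---------------

# Gaussian-mean model with identity transform (parameter named "sigma"):
# conjugate, so the posterior mode is available in closed form
gaussian_toy <- list(
  param_names = "sigma",
  loglik = function(theta, x) sum(dnorm(x, theta[["sigma"]], 1, log = TRUE))
)

# Bernoulli model on the logit scale (parameter named "w")
bernoulli_toy <- list(
  param_names = "w",
  loglik = function(theta, x) {
    p <- theta[["w"]]
    sum(x) * log(p) + (length(x) - sum(x)) * log(1 - p)
  }
)

test_that("the M-step matches the printed moment-matching update", {
  # two subjects, one parameter: theta = (1, 3), Laplace variances 0.5
  out <- em_m_step(matrix(c(1, 3), 2, 1), matrix(c(0.5, 0.5), 2, 1))
  expect_equal(unname(out$mu), 2)
  expect_equal(unname(out$sigma2), (1.5 + 9.5) / 2 - 4)  # = 1.5
  # identical subjects with vanishing Laplace variance: group variance -> 0
  out0 <- em_m_step(matrix(c(1.2, 1.2, 1.2), 3, 1), matrix(0, 3, 1))
  expect_lt(unname(out0$sigma2), 1e-5)
})

test_that("MAP fitting matches the conjugate closed form", {
  set.seed(5)
  x <- rnorm(25, 1.4, 1)
  prior <- list(mu = c(sigma = 0), sigma2 = c(sigma = 0.5^2))
  fit <- map_fit(x, prior, gaussian_toy, restarts = 3, seed = 1)
  post_prec <- 1 / 0.5^2 + length(x)
  post_mode <- (0 / 0.5^2 + sum(x)) / post_prec
  expect_equal(unname(fit$theta_z), post_mode, tolerance = 1e-5)
  # Laplace variance equals the exact posterior variance here
  expect_equal(unname(diag(fit$Sigma)), 1 / post_prec, tolerance = 1e-3)
})

test_that("an infinitely tight prior pins the MAP at the prior mean", {
  cfg <- flat_config(block_trials = 40, n_blocks = 1)
  pool <- generate_walk_pool(cfg, seed = 1)
  tr <- simulate_session(agent_params(), cfg, pool[[1]], seed = 3)
  iface <- model_interface(model_spec("hybrid"))
  mu <- c(alpha = 0.3, beta = 0.9, eps = -2, w = -0.4)
  fit <- map_fit(tr, list(mu = mu, sigma2 = setNames(rep(1e-6, 4), names(mu))),
                 iface, restarts = 2, seed = 1)
  expect_equal(fit$theta_z, mu, tolerance = 1e-2)
})

test_that("MAP self-consistency at large n under a diffuse prior", {
  cfg <- flat_config(block_trials = 5000, n_blocks = 2)
  pool <- generate_walk_pool(cfg, seed = 2)
  gen <- agent_params(alpha = 0.5, beta = 5, eps = 0.05, w = 0.6)
  tr <- simulate_session(gen, cfg, pool[[1]], seed = 12)
  iface <- model_interface(model_spec("hybrid"))
  prior <- list(mu = c(alpha = 0, beta = 0, eps = -2, w = 0),
                sigma2 = c(alpha = 25, beta = 25, eps = 25, w = 25))
  fit <- map_fit(tr, prior, iface, restarts = 3, seed = 4)
  truth <- to_transformed(c(alpha = 0.5, beta = 5, eps = 0.05, w = 0.6))
  post_sd <- sqrt(diag(fit$Sigma))
  for (p in names(truth))
    expect_lt(abs(fit$theta_z[[p]] - truth[[p]]), 3 * post_sd[[p]])
})

test_that("the EM objective is non-decreasing and degenerate cases error", {
  co <- simulate_cohort(flat_cohort_spec(n = 8, seed = 6),
                        flat_config(block_trials = 100, n_blocks = 2))
  fit <- em_fit(co$trials, model_spec("hybrid"), seed = 2, max_iter = 30)
  # monotonicity surrogate of the penalized objective, small tolerance for
  # Laplace/optimizer noise
  expect_true(all(diff(fit$trace$objective) > -0.5))
  expect_equal(fit$n_subjects, 8)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(nrow(tidy(fit)), 8 * 4)
  expect_equal(glance(fit)$n_choices, 2 * nrow(co$trials))

  one <- co$trials[co$trials$subject_id == co$trials$subject_id[1], ]
  expect_error(em_fit(one, model_spec("hybrid")),
               class = "twostep_input_error")
})

test_that("iBIC evidence matches quadrature on a Bernoulli toy model", {
  set.seed(9)
  data <- list(s1 = rbinom(40, 1, 0.7), s2 = rbinom(40, 1, 0.55))
  hyper <- list(mu = c(w = 0.3), sigma2 = c(w = 0.8^2))
  fit <- structure(list(hyper = hyper, interface = bernoulli_toy),
                   class = "twostep_fit")
  ib <- ibic(data, fit, K = 4000, seed = 2)
  exact <- sum(vapply(data, function(x) {
    log(integrate(function(z) {
      vapply(z, function(zz)
        exp(bernoulli_toy$loglik(c(w = plogis(zz)), x)) *
          dnorm(zz, 0.3, 0.8), numeric(1))
    }, -10, 10)$value)
  }, numeric(1)))
  expect_lt(abs(ib$log_evidence - exact), 3 * ib$mc_se)
  # the iBIC assembles evidence, choice count and hyperparameter count
  expect_equal(ib$ibic, -2 * ib$log_evidence + 2 * log(2 * 80))
  # bit-reproducible under a fixed seed and K
  ib2 <- ibic(data, fit, K = 4000, seed = 2)
  expect_identical(ib$ibic, ib2$ibic)
  # invariant to subject ordering
  ib_rev <- ibic(rev(data), fit, K = 4000, seed = 2)
  expect_equal(ib_rev$ibic, ib$ibic, tolerance = 1e-12)
  expect_error(ibic(data, fit, K = 50), class = "twostep_input_error")
})

test_that("an uninformative extra parameter costs exactly the iBIC penalty", {
  set.seed(3)
  data <- list(s1 = rbinom(60, 1, 0.6), s2 = rbinom(60, 1, 0.75))
  padded <- list(
    param_names = c("w", "sigma"),
    loglik = function(theta, x) bernoulli_toy$loglik(theta, x)
  )
  hyper1 <- list(mu = c(w = 0.2), sigma2 = c(w = 0.5))
  hyper2 <- list(mu = c(w = 0.2, sigma = 0), sigma2 = c(w = 0.5, sigma = 1))
  fit1 <- structure(list(hyper = hyper1, interface = bernoulli_toy),
                    class = "twostep_fit")
  fit2 <- structure(list(hyper = hyper2, interface = padded),
                    class = "twostep_fit")
  ib1 <- ibic(data, fit1, K = 4000, seed = 5)
  ib2 <- ibic(data, fit2, K = 4000, seed = 5)
  # identical likelihood, two extra hyperparameters -> penalty grows by
  # 2 * (1/2) log|C| in -0.5*BIC units, i.e. 2 log|C| on the BIC scale
  expect_equal(ib2$ibic - ib1$ibic, 2 * log(2 * 120),
               tolerance = 3 * sqrt(ib1$mc_se^2 + ib2$mc_se^2) * 2 + 1e-8)
})

test_that("doubling K shrinks the Monte-Carlo error of the evidence", {
  set.seed(11)
  data <- list(s1 = rbinom(30, 1, 0.65), s2 = rbinom(30, 1, 0.5))
  hyper <- list(mu = c(w = 0), sigma2 = c(w = 1))
  fit <- structure(list(hyper = hyper, interface = bernoulli_toy),
                   class = "twostep_fit")
  ev <- function(K) vapply(1:24, function(s)
    ibic(data, fit, K = K, seed = 100 + s)$log_evidence, numeric(1))
  ratio <- var(ev(400)) / var(ev(800))
  expect_gt(ratio, 1.2)
})

test_that("group contrasts reduce to the textbook paired t-test", {
  co <- simulate_cohort(flat_cohort_spec(n = 5, seed = 13),
                        flat_config(block_trials = 60, n_blocks = 1))
  fit <- em_fit(co$trials, model_spec("hybrid"), seed = 1, max_iter = 5)
  self <- group_contrasts(fit, fit, paired = TRUE)
  expect_true(all(self$t == 0))
  expect_true(all(self$mean_diff == 0))
  expect_true(all(self$p == 1))

  # hand-entered estimates against the closed-form paired t
  fa <- fit; fb <- fit
  a <- c(0.50, 0.62, 0.41, 0.55, 0.47)
  b <- c(0.44, 0.51, 0.40, 0.49, 0.50)
  fa$estimates <- tibble::tibble(subject_id = paste0("s", 1:5),
                                 parameter = "w", estimate = a)
  fb$estimates <- fa$estimates
  fb$estimates$estimate <- b
  fa$interface <- fb$interface <- list(param_names = "w")
  ct <- group_contrasts(fa, fb, paired = TRUE)
  d <- a - b
  t_manual <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(ct$t, t_manual, tolerance = 1e-12)
  expect_equal(ct$mean_diff, mean(d))
  expect_equal(ct$df, 4)

  fb$estimates$subject_id <- paste0("x", 1:5)
  expect_error(group_contrasts(fa, fb, paired = TRUE),
               class = "twostep_input_error")
})

test_that("recovery error does not improve with fewer trials", {
  err_at <- function(block_trials, seeds) {
    mean(vapply(seeds, function(s) {
      co <- simulate_cohort(flat_cohort_spec(n = 10, seed = s),
                            flat_config(block_trials = block_trials,
                                        n_blocks = 1))
      fit <- em_fit(co$trials, model_spec("hybrid"), seed = s, max_iter = 40)
      truth <- to_transformed(c(alpha = 0.5, beta = 5, eps = 0.05, w = 0.6))
      mean(abs(fit$hyper$mu - truth))
    }, numeric(1)))
  }
  seeds <- c(31, 32, 33)
  expect_gte(err_at(75, seeds), err_at(300, seeds) - 0.02)
})
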