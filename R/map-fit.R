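# Generic model interface used by map_fit / em_fit / ibic: a list with
#   param_names : free-parameter names (transform determined by name)
#   loglik      : function(theta_nat, data) -> scalar log-likelihood
# Tests exercise the machinery with toy interfaces (e.g. Gaussian-mean,
# Bernoulli) through the same code path.

#' Model interface for the hybrid RL family
#'
#' Packages a [model_spec()] as the generic interface consumed by
#' [map_fit()], [em_fit()] and [ibic()].
#'
#' @param spec A [model_spec()].
#' @param p_common Transition probability of the agent's transition model.
#' @param reset_each_day Reset Q-values at day boundaries.
#' @return A list with `param_names`, `loglik(theta_nat, trials)` and `spec`.
#' @export
model_interface <- function(spec, p_common = 0.7, reset_each_day = TRUE) {
  force(spec); force(p_common); force(reset_each_day)
  fixed <- spec$fixed
  # pre-encodes one subject's trials and returns a fast theta -> loglik closure
  make_loglik <- function(trials) {
    if (nrow(trials) == 0) return(function(theta_nat) 0)
    check_chronology(trials)
    enc <- encode_trials(trials)
    function(theta_nat) {
      p <- as.list(theta_nat)
      p[names(fixed)] <- fixed
      a <- p$alpha %||% 0.5
      b <- p$beta %||% 1
      ll_session_const_cpp(enc$day, enc$choice1, enc$state2, enc$choice2,
                           enc$reward, enc$scored,
                           p$alpha1 %||% a, p$alpha2 %||% a,
                           p$beta1 %||% b, p$beta2 %||% b,
                           p$eps %||% 0, p$w %||% 0.5,
                           p$lambda %||% 1, p$sigma %||% 0,
                           p_common, reset_each_day)
    }
  }
  list(
    param_names = spec$free_params,
    loglik = function(theta_nat, trials) make_loglik(trials)(theta_nat),
    make_loglik = make_loglik,
    spec = spec
  )
}

# central-difference Hessian, step h on each coordinate
hessian_cd <- function(f, x, h = 1e-4) {
  k <- length(x)
  H <- matrix(NA_real_, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) {
    ei <- replace(numeric(k), i, h)
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h^2
    if (i < k) for (j in (i + 1):k) {
      ej <- replace(numeric(k), j, h)
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h^2)
    }
  }
  H
}

# floor eigenvalues of a symmetric matrix at `floor_at`
repair_pd <- function(M, floor_at = 1e-6) {
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  vals <- pmax(e$values, floor_at)
  e$vectors %*% diag(vals, length(vals)) %*% t(e$vectors)
}

#' Maximum a posteriori fit of one subject
#'
#' Maximizes the session log-likelihood plus the log Gaussian prior on the
#' transformed scale, from the best of several random initializations drawn
#' from the prior. The posterior covariance is the inverse of the
#' central-finite-difference Hessian of the negative log posterior at the
#' mode, repaired to the nearest positive-definite matrix when needed
#' (Laplace approximation).
#'
#' @param data One subject's data (a trials tibble for the RL interface).
#' @param prior List with transformed-scale `mu` and `sigma2` (named by the
#'   interface's `param_names`).
#' @param interface A [model_interface()] (or any list with `param_names`
#'   and `loglik`).
#' @param restarts Number of random initializations.
#' @param seed Integer seed for the initializations.
#' @param init Optional transformed-scale warm start, tried in addition to
#'   the random restarts.
#' @return List with `theta_z`, `theta_nat`, `Sigma`, `logpost`, `loglik`
#'   and a `converged` flag (`FALSE` means every restart failed and the
#'   prior mean was returned).
#' @export
map_fit <- function(data, prior, interface, restarts = 5, seed = 1L,
                    init = NULL) {
  pn <- interface$param_names
  mu <- prior$mu[pn]
  sdv <- sqrt(prior$sigma2[pn])
  if (any(!is.finite(sdv)) || any(sdv <= 0))
    abort("prior variances must be positive.", class = "twostep_input_error")
  ll_fn <- if (!is.null(interface$make_loglik)) interface$make_loglik(data)
           else function(th) interface$loglik(th, data)
  # inlined to_natural for the optimizer hot path
  kinds <- vapply(pn, transform_kind, character(1))
  k_logit <- which(kinds == "logit01")
  k_log <- which(kinds == "log")
  k_eps <- which(kinds == "logit_half")
  tn <- function(z) {
    out <- z
    if (length(k_logit)) out[k_logit] <- plogis(z[k_logit])
    if (length(k_log)) out[k_log] <- exp(z[k_log])
    if (length(k_eps)) out[k_eps] <- 0.5 * plogis(z[k_eps])
    names(out) <- pn
    out
  }
  negpost <- function(z) {
    ll <- ll_fn(tn(z))
    if (!is.finite(ll)) return(1e10)
    -(ll + sum(dnorm(z, mu, sdv, log = TRUE)))
  }
  set.seed(seed)
  starts <- c(if (is.null(init)) list(mu) else list(init[pn]),
              lapply(seq_len(max(restarts - 1, 0)),
                     function(i) rnorm(length(pn), mu, sdv)))
  best <- NULL
  n_ok <- 0L
  for (s in starts) {
    fit <- tryCatch(
      optim(s, negpost, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-9)),
      error = function(e) NULL
    )
    if (is.null(fit) || !is.finite(fit$value)) next
    n_ok <- n_ok + 1L
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    warn("MAP optimization failed on every restart; returning prior mean.")
    z <- mu
    H <- diag(1 / prior$sigma2[pn], length(pn))
    Sigma <- diag(prior$sigma2[pn], length(pn))
    conv <- FALSE
    lp <- -negpost(z)
  } else {
    z <- setNames(best$par, pn)
    H <- hessian_cd(negpost, z, h = 1e-4)
    Hp <- repair_pd(H, 1e-6)
    Sigma <- repair_pd(solve(Hp), 1e-10)
    conv <- TRUE
    lp <- -best$value
  }
  dimnames(Sigma) <- list(pn, pn)
  th_nat <- to_natural(z)
  list(theta_z = z, theta_nat = th_nat, Sigma = Sigma,
       logpost = lp, loglik = ll_fn(th_nat),
       converged = conv, n_restarts_ok = n_ok)
}
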