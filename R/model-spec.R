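#' Model specification
#'
#' Defines one member of the nested model family: which parameters are free,
#' fixed, or split by stage. The model-free and model-based families are the
#' hybrid model with `w` fixed at 0 and 1 respectively. The eligibility trace
#' is fixed at 1 unless freed; the cross-day slope `sigma` is only available
#' in the multi-day family; the discount factor is always 1.
#'
#' @param family `"hybrid"`, `"model_free"` or `"model_based"`.
#' @param multi_day If `TRUE`, the slope `sigma` is a free parameter.
#' @param stage_split_alpha,stage_split_beta Fit separate first/second-stage
#'   learning rates / inverse temperatures.
#' @param free_lambda Fit the eligibility trace instead of fixing it at 1.
#' @param free_lapse Fit the lapse rate (default) or fix it at 0.
#' @param label Optional display label.
#' @return A `twostep_model_spec`.
#' @export
model_spec <- function(family = c("hybrid", "model_free", "model_based"),
                       multi_day = FALSE,
                       stage_split_alpha = FALSE, stage_split_beta = FALSE,
                       free_lambda = FALSE, free_lapse = TRUE,
                       label = NULL) {
  family <- match.arg(family)
  free <- c(
    if (stage_split_alpha) c("alpha1", "alpha2") else "alpha",
    if (stage_split_beta) c("beta1", "beta2") else "beta",
    if (free_lapse) "eps",
    if (family == "hybrid") "w",
    if (free_lambda) "lambda",
    if (multi_day) "sigma"
  )
  fixed <- list()
  if (family == "model_free") fixed$w <- 0
  if (family == "model_based") fixed$w <- 1
  if (!free_lapse) fixed$eps <- 0
  if (!free_lambda) fixed$lambda <- 1
  if (!multi_day) fixed$sigma <- 0
  structure(
    list(family = family, multi_day = multi_day,
         stage_split_alpha = stage_split_alpha,
         stage_split_beta = stage_split_beta,
         free_lambda = free_lambda, free_lapse = free_lapse,
         free_params = free, fixed = fixed,
         label = label %||% family),
    class = "twostep_model_spec"
  )
}

#' @export
print.twostep_model_spec <- function(x, ...) {
  cat(sprintf("<twostep_model_spec> %s%s\n  free: %s\n  fixed: %s\n",
              x$family, if (x$multi_day) " (multi-day)" else "",
              paste(x$free_params, collapse = ", "),
              paste(sprintf("%s=%g", names(x$fixed), unlist(x$fixed)),
                    collapse = ", ")))
  invisible(x)
}

# expand a named vector of free natural-scale parameters into a full
# twostep_params, applying the spec's fixed values
spec_full_params <- function(theta_nat, spec) {
  p <- as.list(theta_nat)
  p <- modifyList(p, spec$fixed)
  args <- list(
    alpha = p$alpha %||% 0.5, beta = p$beta %||% 1,
    eps = p$eps %||% 0, w = p$w %||% 0.5,
    lambda = p$lambda %||% 1, sigma = p$sigma %||% 0,
    alpha1 = p$alpha1, alpha2 = p$alpha2,
    beta1 = p$beta1, beta2 = p$beta2
  )
  do.call(agent_params, args)
}

# default hyperprior initialization on the transformed scale
default_hyper_init <- function(spec) {
  nat <- c(alpha = 0.5, alpha1 = 0.5, alpha2 = 0.5,
           beta = 1, beta1 = 1, beta2 = 1,
           eps = 0.05, w = 0.5, lambda = 0.9, sigma = 0)
  mu <- to_transformed(nat[spec$free_params])
  list(mu = mu, sigma2 = setNames(rep(1, length(mu)), names(mu)))
}
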