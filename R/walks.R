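#' Generate a pool of reward-probability walk sets
#'
#' Each walk set holds four independent Gaussian random walks, one per
#' second-stage fractal, confined to `[walk_low, walk_high]`. Steps are
#' proposed from N(0, `walk_sd`); a proposal that would leave the bounds is
#' resampled, so accepted increments remain Gaussian away from the bounds.
#' All raw proposals (including rejected ones) are retained for diagnostics.
#'
#' @param config A [task_config()] object.
#' @param n_steps Length of each series; defaults to the longest day in the
#'   protocol.
#' @param seed Integer seed; the same seed reproduces the pool exactly.
#' @return A `twostep_walk_pool`: a list of `walk_pool_size` walk sets, each
#'   a list with `series` (an `n_steps` x 4 matrix of reward probabilities)
#'   and `raw_increments` (numeric vector of all Gaussian proposals).
#' @export
generate_walk_pool <- function(config, n_steps = NULL, seed = 1L) {
  stopifnot(inherits(config, "twostep_config"))
  n_steps <- n_steps %||% max_trials_per_day(config)
  set.seed(seed)
  pool <- vector("list", config$walk_pool_size)
  for (k in seq_len(config$walk_pool_size)) {
    series <- matrix(NA_real_, n_steps, 4)
    colnames(series) <- c("sB_aA", "sB_aB", "sC_aA", "sC_aB")
    raw <- vector("list", 4L)
    for (j in 1:4) {
      x <- numeric(n_steps)
      x[1] <- runif(1, config$walk_low, config$walk_high)
      props <- numeric(0)
      for (t in seq_len(n_steps - 1L)) {
        repeat {
          step <- rnorm(1, 0, config$walk_sd)
          props[length(props) + 1L] <- step
          cand <- x[t] + step
          if (cand >= config$walk_low && cand <= config$walk_high) {
            x[t + 1L] <- cand
            break
          }
        }
      }
      series[, j] <- x
      raw[[j]] <- props
    }
    pool[[k]] <- structure(
      list(series = series, raw_increments = unlist(raw)),
      class = "twostep_walk_set"
    )
  }
  structure(pool, class = "twostep_walk_pool",
            config = config, seed = seed, n_steps = n_steps)
}

#' Pool raw walk increments
#'
#' Convenience accessor returning every raw Gaussian step proposal across a
#' walk pool, used to check the configured step SD empirically.
#'
#' @param pool A `twostep_walk_pool`.
#' @return Numeric vector of raw increments.
#' @export
walk_raw_increments <- function(pool) {
  stopifnot(inherits(pool, "twostep_walk_pool"))
  unlist(lapply(unclass(pool), function(ws) ws$raw_increments))
}

#' @export
print.twostep_walk_pool <- function(x, ...) {
  rng <- range(vapply(unclass(x), function(w) range(w$series), numeric(2)))
  cat(sprintf("<twostep_walk_pool> %d sets x %d steps, values in [%.3f, %.3f]\n",
              length(x), attr(x, "n_steps"), rng[1], rng[2]))
  invisible(x)
}
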