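#' Parameter transforms between natural and unconstrained scales
#'
#' Fitting operates on an unconstrained scale: log for the inverse
#' temperatures, inverse-sigmoid scaled to \[0, 1\] for learning rates, the
#' model-based weight and the eligibility trace, inverse-sigmoid scaled to
#' \[0, 0.5\] for the lapse rate, and identity for the cross-day slope.
#'
#' @param theta Named numeric vector on the natural scale (`to_transformed`)
#'   or the unconstrained scale (`to_natural`). Recognised names: `alpha`,
#'   `alpha1`, `alpha2`, `beta`, `beta1`, `beta2`, `eps`, `w`, `lambda`,
#'   `sigma`.
#' @return Named numeric vector on the other scale.
#' @export
to_transformed <- function(theta) {
  vapply(names(theta), function(nm) {
    x <- theta[[nm]]
    switch(transform_kind(nm),
           logit01 = qlogis(x),
           log = log(x),
           logit_half = qlogis(x / 0.5),
           identity = x)
  }, numeric(1))
}

#' @rdname to_transformed
#' @export
to_natural <- function(theta) {
  vapply(names(theta), function(nm) {
    z <- theta[[nm]]
    switch(transform_kind(nm),
           logit01 = plogis(z),
           log = exp(z),
           logit_half = 0.5 * plogis(z),
           identity = z)
  }, numeric(1))
}

transform_kind <- function(name) {
  switch(name,
         alpha = , alpha1 = , alpha2 = , w = , lambda = "logit01",
         beta = , beta1 = , beta2 = "log",
         eps = "logit_half",
         sigma = "identity",
         abort(sprintf("unknown parameter '%s'.", name),
               class = "twostep_input_error"))
}
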