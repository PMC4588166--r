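#' Group-level parameter contrasts between two fits
#'
#' Paired (or two-sample Welch) t-tests per parameter on the natural-scale
#' MAP estimates of two fits of the same model family, reporting the mean
#' difference with a 95% confidence interval. When every paired difference
#' is exactly zero the t statistic is reported as 0 with p = 1.
#'
#' @param fit_a,fit_b `twostep_fit` objects with the same parameterization.
#' @param paired Paired test over matched subjects (default); requires
#'   identical subject sets.
#' @param conf_level Confidence level of the reported interval.
#' @return Tibble with one row per parameter: `mean_a`, `mean_b`,
#'   `mean_diff`, `ci_low`, `ci_high`, `t`, `df`, `p`.
#' @export
group_contrasts <- function(fit_a, fit_b, paired = TRUE, conf_level = 0.95) {
  pa <- fit_a$interface$param_names
  pb <- fit_b$interface$param_names
  if (!identical(pa, pb))
    abort("fits have different parameterizations.",
          class = "twostep_input_error")
  ea <- fit_a$estimates
  eb <- fit_b$estimates
  if (paired) {
    sa <- sort(unique(ea$subject_id))
    sb <- sort(unique(eb$subject_id))
    if (!identical(sa, sb))
      abort("paired contrasts require matched subject sets.",
            class = "twostep_input_error")
  }
  dplyr::bind_rows(lapply(pa, function(p) {
    xa <- ea[ea$parameter == p, ]
    xb <- eb[eb$parameter == p, ]
    if (paired) {
      xa <- xa[order(xa$subject_id), ]
      xb <- xb[order(xb$subject_id), ]
      d <- xa$estimate - xb$estimate
      if (all(d == 0)) {
        tt <- list(statistic = 0, parameter = length(d) - 1, p.value = 1,
                   conf.int = c(0, 0))
      } else {
        tt <- t.test(d, conf.level = conf_level)
      }
    } else {
      tt <- t.test(xa$estimate, xb$estimate, conf.level = conf_level)
    }
    tibble(parameter = p,
           mean_a = mean(xa$estimate), mean_b = mean(xb$estimate),
           mean_diff = mean(xa$estimate) - mean(xb$estimate),
           ci_low = tt$conf.int[1], ci_high = tt$conf.int[2],
           t = unname(tt$statistic), df = unname(tt$parameter),
           p = tt$p.value)
  }))
}
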