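#' Tidy a fitted co-activation response model
#'
#' One row per coefficient, in the style of broom tidiers.
#'
#' @param x A `coact_fit`.
#' @param ... Passed on.
#' @return A tibble with `term`, `estimate`, `std_error`, `statistic`,
#'   `p_value`.
#' @export
tidy.coact_fit <- function(x, ...) {
  s <- summary(x$glm)$coefficients
  tibble(term = rownames(s), estimate = s[, 1], std_error = s[, 2],
         statistic = s[, 3], p_value = s[, 4])
}

#' One-line model summary
#'
#' @param x A `coact_fit`.
#' @param ... Ignored.
#' @return A one-row tibble: `n`, `n_terms`, `n_coef`, `log_lik`,
#'   `aic`, `converged`, `separation`.
#' @export
glance.coact_fit <- function(x, ...) {
  tibble(n = nrow(x$frame), n_terms = length(x$terms),
         n_coef = length(coef(x$glm)),
         log_lik = as.numeric(logLik(x$glm)), aic = AIC(x$glm),
         converged = x$converged, separation = x$separation)
}

#' @export
tidy.coact_anova <- function(x, ...) as_tibble(x)

#' @export
tidy.coact_contrasts <- function(x, ...) as_tibble(x)
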