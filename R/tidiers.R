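# broom-style accessors for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a fitted concentration-response curve
#'
#' @param x A `cr_fit`.
#' @param ... Unused.
#' @return Tibble with one row per parameter (`term`, `estimate`).
#' @method tidy cr_fit
#' @export
tidy.cr_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$params),
    estimate = unname(x$params)
  )
}

#' One-row model summary of a fitted curve
#'
#' @param x A `cr_fit`.
#' @param ... Unused.
#' @return Tibble with `family_id`, `n_params`, `fit_score` (AICc),
#'   `residual_sd`, `converged`, `nobs`.
#' @method glance cr_fit
#' @export
glance.cr_fit <- function(x, ...) {
  tibble::tibble(
    family_id = x$family_id,
    n_params = x$family$n_params,
    fit_score = x$fit_score,
    residual_sd = x$residual_sd,
    converged = x$converged,
    nobs = x$n
  )
}

#' Fitted values and residuals for the training data
#'
#' @param x A `cr_fit`.
#' @param ... Unused.
#' @return The fit's data with `.fitted` and `.resid` columns.
#' @method augment cr_fit
#' @export
augment.cr_fit <- function(x, ...) {
  out <- x$data
  out$.fitted <- predict(x)
  out$.resid <- out$response - out$.fitted
  out
}

#' Tidy the comparisons of a step-down test
#'
#' @param x A `stepdown_result`.
#' @param ... Unused.
#' @return The `comparisons` tibble (group, raw and adjusted p, rejection).
#' @method tidy stepdown_result
#' @export
tidy.stepdown_result <- function(x, ...) x$comparisons

#' One-row summary of a step-down test
#'
#' @param x A `stepdown_result`.
#' @param ... Unused.
#' @return Tibble with `reference`, `alpha`, `n_comparisons`, `n_rejected`.
#' @method glance stepdown_result
#' @export
glance.stepdown_result <- function(x, ...) {
  tibble::tibble(
    reference = x$reference,
    alpha = x$alpha,
    n_comparisons = nrow(x$comparisons),
    n_rejected = sum(x$comparisons$rejected)
  )
}

#' Tidy a bootstrap confidence band
#'
#' @param x A `cr_band`.
#' @param ... Unused.
#' @return Tibble with `concentration_uM`, `fitted`, `lower`, `upper`.
#' @method tidy cr_band
#' @export
tidy.cr_band <- function(x, ...) {
  tibble::tibble(
    concentration_uM = x$grid,
    fitted = x$fitted,
    lower = x$lower,
    upper = x$upper
  )
}
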