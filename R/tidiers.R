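#' Tidy the fixed effects of a longitudinal network-metric model
#'
#' @param x an `rsn_lme` from [fit_rsn_lme()].
#' @param ... unused.
#' @return Tibble with one row per fixed-effect term: `term`, `estimate`,
#'   `std_error`, `df`, `p_value`.
#' @export
tidy.rsn_lme <- function(x, ...) {
  x$fixed
}

#' One-row model summary of a longitudinal network-metric model
#'
#' @param x an `rsn_lme` from [fit_rsn_lme()].
#' @param ... unused.
#' @return One-row tibble: `response`, `sigma_subject`, `sigma_resid`,
#'   `n_obs`, `n_subjects`, `converged`, `singular`, `df_method`.
#' @export
glance.rsn_lme <- function(x, ...) {
  tibble::tibble(
    response = x$response,
    sigma_subject = x$sigma_subject,
    sigma_resid = x$sigma_resid,
    n_obs = x$n_obs,
    n_subjects = x$n_subjects,
    converged = x$converged,
    singular = x$singular,
    df_method = x$df_method
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
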