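#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a joint logistic fit
#'
#' @param x A `cone_fit` object.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`.
#' @export
tidy.cone_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params), estimate = unname(x$params))
}

#' One-row summary of a joint logistic fit
#'
#' @param x A `cone_fit` object.
#' @param ... Unused.
#' @export
glance.cone_fit <- function(x, ...) {
  tibble::tibble(loss = x$loss, converged = x$converged,
                 n_restarts_used = x$n_restarts_used,
                 n_azimuths = nrow(x$counts))
}

#' Tidy a cone-width inference object
#'
#' Returns the pairwise condition contrasts as a tibble (estimates in
#' degrees, Wald-t intervals, unadjusted p-values).
#'
#' @param x A `cone_inference` object from [analyze_cone_widths()].
#' @param ... Unused.
#' @export
tidy.cone_inference <- function(x, ...) {
  x$contrasts
}

#' One-row summary of a cone-width inference object
#'
#' @param x A `cone_inference` object.
#' @param ... Unused.
#' @return A tibble with sample sizes, the model log-likelihood, and the
#'   condition likelihood-ratio test.
#' @export
glance.cone_inference <- function(x, ...) {
  cond <- x$lrt[x$lrt$effect == "condition", ]
  tibble::tibble(
    n_participants = x$n_participants,
    n_obs = x$n_obs,
    logLik = as.numeric(logLik(x$model)),
    condition_chi2 = cond$chi2,
    condition_df = cond$df,
    condition_p = cond$p_value
  )
}
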