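#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted trend model
#'
#' One row per fixed-effect term: estimate, standard error, type-III Wald
#' chi-square, degrees of freedom, p-value.
#'
#' @param x a `trend_fit`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.trend_fit <- function(x, ...) {
  dplyr::rename(x$wald, statistic = "chisq", std.error = "std_error",
                p.value = "p_value")
}

#' One-row summary of a fitted trend model
#'
#' @param x a `trend_fit`.
#' @param ... unused.
#' @return tibble: nobs, n_terms, logLik, AICc, variance components,
#'   marginal and conditional pseudo-R2, fitting method, convergence.
#' @export
glance.trend_fit <- function(x, ...) {
  tibble::tibble(
    nobs = x$n,
    n_terms = length(x$spec$fixed),
    logLik = x$loglik,
    AICc = x$aicc,
    sigma2_location = unname(x$varcomp["location"]),
    sigma2_species = unname(x$varcomp["species"]),
    sigma2_residual = unname(x$varcomp["residual"]),
    r2_marginal = x$pseudo_r2[["marginal"]],
    r2_conditional = x$pseudo_r2[["conditional"]],
    method = x$method,
    converged = x$converged)
}

#' Tidy a stepwise selection result
#'
#' The elimination path: one row per step with the dropped term and the
#' AICc after the drop (step 0 is the full model).
#'
#' @param x a `stepwise_fit`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.stepwise_fit <- function(x, ...) x$path

#' @export
glance.stepwise_fit <- function(x, ...) glance(x$fit)

#' Tidy life-history PCA scores
#'
#' @param x a `life_history_pca`.
#' @param ... unused.
#' @return tibble of per-species axis scores.
#' @export
tidy.life_history_pca <- function(x, ...) x$scores

#' @export
glance.life_history_pca <- function(x, ...) {
  tibble::tibble(axis = paste0("pc", seq_along(x$variance_explained)),
                 variance_explained = x$variance_explained)
}
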