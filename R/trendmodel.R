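#' Assemble the population-level analysis table
#'
#' Inner join of the per-population trend table, environmental change
#' rates, and per-species life-history scores. Rows with any missing
#' covariate are dropped and reported.
#'
#' @param lambdas tibble from [population_trends()] / [lambda_table()]
#'   (population_id, species, site, mean_lambda, ...).
#' @param env tibble from [env_change()] (population_id, delta_t, one
#'   column per cover class).
#' @param scores tibble with species and pc1 (e.g.
#'   `life_history_scores(...)$scores`).
#' @return tibble: population_id, mean_lambda, delta_t, pc1, the cover
#'   rate columns, species, location; dropped rows reported in the
#'   `dropped` attribute.
#' @export
assemble_model_frame <- function(lambdas, env, scores) {
  if (anyDuplicated(lambdas$population_id) ||
      anyDuplicated(env$population_id)) {
    abort("duplicate population_id")
  }
  if (anyDuplicated(scores$species)) abort("duplicate species in scores")
  frame <- dplyr::inner_join(
    dplyr::select(lambdas, "population_id", "species", "site",
                  "mean_lambda"),
    env, by = "population_id")
  frame <- dplyr::left_join(frame, dplyr::select(scores, "species", "pc1"),
                            by = "species")
  covars <- c("mean_lambda", "delta_t", "pc1",
              intersect(cover_classes(), names(frame)))
  ok <- complete.cases(frame[covars])
  dropped <- tibble::tibble(
    population_id = frame$population_id[!ok],
    reason = "missing covariate")
  missing_ids <- setdiff(union(lambdas$population_id, env$population_id),
                         frame$population_id)
  if (length(missing_ids)) {
    dropped <- dplyr::bind_rows(dropped, tibble::tibble(
      population_id = missing_ids, reason = "no matching row"))
  }
  out <- dplyr::rename(frame[ok, ], location = "site")
  out <- dplyr::relocate(out, "population_id", "mean_lambda", "delta_t",
                         "pc1")
  attr(out, "dropped") <- dropped
  out
}

#' Full fixed-effect specification of the trend model
#'
#' All main effects of warming rate, the fast-slow axis, and each cover
#' change rate, plus every two- and three-way interaction of warming and
#' the fast-slow axis with each other and with each cover class -- no
#' cover x cover interactions. With N cover classes this yields
#' (N + 2) main effects, (2N + 1) two-way and N three-way interactions.
#' Random intercepts for location and species.
#'
#' @param frame a model frame from [assemble_model_frame()]; cover classes
#'   are detected from its columns.
#' @return object of class `model_spec`: list with `fixed` (ordered term
#'   labels), `random` (grouping factors), `response`, `n_cover`.
#' @export
build_full_spec <- function(frame) {
  cls <- intersect(cover_classes(), names(frame))
  if (!all(c("delta_t", "pc1") %in% names(frame))) {
    abort("frame must contain delta_t and pc1")
  }
  fixed <- c("delta_t", "pc1", cls,
             "delta_t:pc1",
             paste0("pc1:", cls),
             paste0("delta_t:", cls),
             paste0("delta_t:pc1:", cls))
  new_model_spec(fixed, response = "mean_lambda",
                 random = c("location", "species"))
}

new_model_spec <- function(fixed, response = "mean_lambda",
                           random = c("location", "species")) {
  spec <- structure(list(fixed = fixed, random = random,
                         response = response),
                    class = "model_spec")
  check_marginality(spec)
  spec
}

term_vars <- function(term) strsplit(term, ":", fixed = TRUE)[[1]]

# every interaction's lower-order terms must be present
check_marginality <- function(spec) {
  for (term in spec$fixed) {
    vars <- term_vars(term)
    if (length(vars) < 2L) next
    for (k in seq_len(length(vars) - 1L)) {
      sub <- utils::combn(vars, k, paste, collapse = ":")
      present <- vapply(sub, function(s) {
        any(vapply(spec$fixed, function(f)
          setequal(term_vars(f), term_vars(s)), logical(1)))
      }, logical(1))
      if (!all(present)) {
        abort(sprintf("marginality violated: `%s` lacks parent `%s`",
                      term, sub[!present][1]))
      }
    }
  }
  invisible(spec)
}

#' @export
print.model_spec <- function(x, ...) {
  n_way <- vapply(x$fixed, function(t) length(term_vars(t)), integer(1))
  cat(sprintf(
    "<model_spec> %d fixed terms (%d main, %d two-way, %d three-way) + intercept\n",
    length(x$fixed), sum(n_way == 1), sum(n_way == 2), sum(n_way == 3)))
  cat("random intercepts:", paste(x$random, collapse = ", "), "\n")
  invisible(x)
}

#' @export
format.model_spec <- function(x, ...) spec_formula_text(x)

spec_formula_text <- function(spec) {
  rhs <- if (length(spec$fixed)) paste(spec$fixed, collapse = " + ")
         else "1"
  paste(spec$response, "~", rhs, "+",
        paste(sprintf("(1 | %s)", spec$random), collapse = " + "))
}

#' Fit the population-trend linear mixed model
#'
#' Linear mixed-effects model of the mean log10 rate of population change
#' with crossed random intercepts for location and species, fitted by
#' REML (final inference) or ML (for AICc comparisons of fixed-effect
#' structures).
#'
#' @param frame model frame from [assemble_model_frame()].
#' @param spec a `model_spec`; defaults to [build_full_spec()] of the
#'   frame.
#' @param method "REML" or "ML".
#' @param standardize center and scale the continuous covariates before
#'   fitting (default `FALSE`: coefficients stay on the raw scales).
#' @return object of class `trend_fit`: the lme4 fit plus the spec,
#'   per-term Wald table, variance components, AICc, and pseudo-R2.
#'   Non-convergence is reported in `$converged`, never silently.
#' @export
fit_lmm <- function(frame, spec = build_full_spec(frame),
                    method = c("REML", "ML"), standardize = FALSE) {
  method <- match.arg(method)
  for (g in spec$random) {
    if (length(unique(frame[[g]])) < 2L) {
      abort(sprintf("grouping factor `%s` needs at least 2 levels", g))
    }
  }
  if (standardize) {
    for (v in unique(unlist(lapply(spec$fixed, term_vars)))) {
      frame[[v]] <- as.numeric(scale(frame[[v]]))
    }
  }
  form <- as.formula(spec_formula_text(spec))
  fit <- suppressMessages(lme4::lmer(
    form, data = frame, REML = (method == "REML"),
    control = lme4::lmerControl(calc.derivs = FALSE,
                                check.conv.singular = "ignore",
                                check.scaleX = "ignore")))
  conv <- length(fit@optinfo$conv$lme4$messages %||% character(0)) == 0L
  if (!conv) warn("mixed-model fit did not converge cleanly")
  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomp <- setNames(vc$vcov, ifelse(vc$grp == "Residual", "residual",
                                      vc$grp))
  n <- nrow(frame)
  k <- length(lme4::fixef(fit)) + length(varcomp)
  structure(list(
    fit = fit, spec = spec, method = method, n = n, k = k,
    converged = conv,
    varcomp = varcomp,
    loglik = as.numeric(logLik(fit)),
    aicc = aicc_value(as.numeric(logLik(fit)), n, k),
    wald = wald_type3(fit),
    pseudo_r2 = pseudo_r2_components(fit, varcomp)
  ), class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit> %s, n = %d, k = %d, AICc = %.2f%s\n",
              x$method, x$n, x$k, x$aicc,
              if (x$converged) "" else " (NOT CONVERGED)"))
  print(x$wald, n = Inf)
  cat(sprintf("pseudo-R2: marginal %.3f, conditional %.3f\n",
              x$pseudo_r2[["marginal"]], x$pseudo_r2[["conditional"]]))
  invisible(x)
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1)`, where k counts fixed-effect
#' coefficients plus variance components (including the residual).
#'
#' @param object a `trend_fit`, or a log-likelihood value when `n` and `k`
#'   are given.
#' @param n,k sample size and parameter count (ignored for `trend_fit`).
#' @return a single number.
#' @export
aicc <- function(object, n = NULL, k = NULL) {
  if (inherits(object, "trend_fit")) {
    return(aicc_value(object$loglik, object$n, object$k))
  }
  aicc_value(as.numeric(object), n, k)
}

aicc_value <- function(loglik, n, k) {
  if (is.null(n) || is.null(k)) abort("n and k are required")
  if (n <= k + 1) abort("AICc undefined: need n > k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Type-III Wald chi-square tests
#'
#' Per-term chi-square statistics from the estimated fixed-effect
#' coefficients and their covariance matrix: for a term with coefficient
#' block b and covariance V, `chisq = b' V^-1 b` on as many degrees of
#' freedom as coefficients (for single-coefficient terms this is
#' `(estimate / SE)^2`). P-values from the chi-square reference
#' distribution.
#'
#' @param fit a `trend_fit` or an `lme4` fit.
#' @return tibble: term, estimate, std_error (single-df terms), chisq, df,
#'   p_value.
#' @export
wald_type3 <- function(fit) {
  if (inherits(fit, "trend_fit")) fit <- fit$fit
  b <- lme4::fixef(fit)
  V <- as.matrix(vcov(fit))
  asgn <- attr(model.matrix(fit), "assign")
  labels <- c("(Intercept)", attr(terms(fit), "term.labels"))
  rows <- lapply(sort(unique(asgn)), function(a) {
    idx <- which(asgn == a)
    Vi <- V[idx, idx, drop = FALSE]
    chi <- tryCatch(
      as.numeric(t(b[idx]) %*% solve(Vi) %*% b[idx]),
      error = function(e) NA_real_)
    tibble::tibble(
      term = labels[a + 1L],
      estimate = if (length(idx) == 1L) unname(b[idx]) else NA_real_,
      std_error = if (length(idx) == 1L) sqrt(Vi[1, 1]) else NA_real_,
      chisq = chi,
      df = length(idx),
      p_value = pchisq(chi, length(idx), lower.tail = FALSE))
  })
  out <- dplyr::bind_rows(rows)
  if (anyNA(out$chisq)) warn("singular covariance block in Wald test")
  out
}

#' Wald chi-square from an estimate and its standard error
#'
#' The single-coefficient case of the type-III Wald test:
#' `chisq = (estimate / std_error)^2` with a chi-square(1) p-value.
#'
#' @param estimate,std_error numeric vectors.
#' @return tibble: estimate, std_error, chisq, p_value.
#' @export
#' @examples
#' wald_chisq(-1.4974, 0.6943)
wald_chisq <- function(estimate, std_error) {
  chi <- (estimate / std_error)^2
  tibble::tibble(estimate = estimate, std_error = std_error, chisq = chi,
                 p_value = pchisq(chi, 1, lower.tail = FALSE))
}

pseudo_r2_components <- function(fit, varcomp) {
  X <- model.matrix(fit)
  var_fixed <- var(as.vector(X %*% lme4::fixef(fit)))
  total <- var_fixed + sum(varcomp)
  if (total <= .Machine$double.eps) abort("zero total variance")
  c(marginal = var_fixed / total,
    conditional = (var_fixed + sum(varcomp[names(varcomp) != "residual"])) /
      total)
}

#' Marginal and conditional pseudo-R2
#'
#' Variance explained by the fixed effects alone (marginal) and by fixed
#' plus random effects (conditional), as fractions of the sum of the
#' fixed-predictor variance, random-intercept variances, and residual
#' variance.
#'
#' @param fit a `trend_fit`.
#' @return named numeric vector with elements `marginal` and
#'   `conditional`.
#' @export
pseudo_r2 <- function(fit) {
  stopifnot(inherits(fit, "trend_fit"))
  fit$pseudo_r2
}

# terms that can be dropped without violating marginality
droppable_terms <- function(fixed) {
  fixed[vapply(fixed, function(t) {
    vt <- term_vars(t)
    !any(vapply(fixed, function(s) {
      vs <- term_vars(s)
      length(vs) > length(vt) && all(vt %in% vs)
    }, logical(1)))
  }, logical(1))]
}

#' Backward stepwise selection by AICc
#'
#' Starting from the full specification, repeatedly removes the single
#' droppable term (one that is not a parent of a retained interaction)
#' whose removal most decreases the AICc, until no removal decreases it.
#' Comparisons use ML fits; the final model is refitted with REML. Ties
#' are broken deterministically by dropping the term appearing later in
#' the specification order.
#'
#' @param frame model frame.
#' @param spec starting `model_spec` (default: the full specification).
#' @return object of class `stepwise_fit`: list with `fit` (final REML
#'   `trend_fit`), `spec` (final spec), and `path` (tibble of the
#'   elimination path: step, dropped, aicc).
#' @export
stepwise_aicc <- function(frame, spec = build_full_spec(frame)) {
  current <- spec
  cur_fit <- fit_lmm(frame, current, method = "ML")
  path <- tibble::tibble(step = 0L, dropped = NA_character_,
                         aicc = cur_fit$aicc)
  step_i <- 0L
  repeat {
    cands <- droppable_terms(current$fixed)
    if (!length(cands)) break
    trial <- purrr::map_dbl(cands, function(term) {
      sp <- new_model_spec(setdiff(current$fixed, term),
                           response = current$response,
                           random = current$random)
      fit_lmm(frame, sp, method = "ML")$aicc
    })
    best <- min(trial)
    if (best >= cur_fit$aicc) break
    # tie-break: later term in spec order
    drop_term <- cands[max(which(trial == best))]
    current <- new_model_spec(setdiff(current$fixed, drop_term),
                              response = current$response,
                              random = current$random)
    cur_fit <- fit_lmm(frame, current, method = "ML")
    step_i <- step_i + 1L
    path <- dplyr::bind_rows(path, tibble::tibble(
      step = step_i, dropped = drop_term, aicc = cur_fit$aicc))
  }
  structure(list(fit = fit_lmm(frame, current, method = "REML"),
                 spec = current, path = path),
            class = "stepwise_fit")
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat("<stepwise_fit>", nrow(x$path) - 1L, "terms eliminated; final:\n")
  print(x$fit)
  invisible(x)
}
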