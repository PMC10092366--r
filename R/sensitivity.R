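#' Refit the trend model across imputation-quality thresholds
#'
#' Re-applies the length/fit filter at each R-squared threshold, rebuilds
#' the analysis table, and refits the supplied (baseline-selected) model
#' specification. Raising the threshold can only shrink the retained set.
#'
#' @param imputed imputation table from [impute_populations()].
#' @param env environmental change table from [env_change()]; it should
#'   cover every population that can survive any threshold (compute it
#'   from the threshold-0 filtered set), otherwise lenient scenarios lose
#'   rows in the join.
#' @param scores life-history scores tibble (species, pc1).
#' @param spec the `model_spec` to refit in every scenario (the
#'   baseline-selected model); set `reselect = TRUE` to rerun the full
#'   backward AICc selection instead.
#' @param thresholds R-squared thresholds to scan.
#' @param min_length,window filter parameters as in
#'   [filter_populations()].
#' @param reselect rerun stepwise selection per scenario.
#' @return object of class `sensitivity_scan`: list with `summary`
#'   (tibble: threshold, n_populations, n_species, n_locations, aicc,
#'   marginal/conditional pseudo-R2, fitted flag) and `fits` (named list
#'   of `trend_fit`s). Scenarios with too few rows are flagged, not
#'   fatal.
#' @export
r2_threshold_scan <- function(imputed, env, scores, spec,
                              thresholds = c(0.3, 0.5, 0.7, 0.9),
                              min_length = 5L, window = c(1992L, 2018L),
                              reselect = FALSE) {
  fits <- list()
  rows <- lapply(thresholds, function(thr) {
    kept <- filter_populations(imputed, min_length = min_length,
                               r2_threshold = thr, window = window)
    lam <- lambda_table(kept)
    frame <- assemble_model_frame(lam, env, scores)
    fit <- tryCatch({
      if (reselect) stepwise_aicc(frame)$fit
      else fit_lmm(frame, spec, method = "REML")
    }, error = function(e) NULL)
    fits[[as.character(thr)]] <<- fit
    tibble::tibble(
      threshold = thr,
      n_populations = nrow(frame),
      n_species = length(unique(frame$species)),
      n_locations = length(unique(frame$location)),
      fitted = !is.null(fit),
      aicc = if (is.null(fit)) NA_real_ else fit$aicc,
      r2_marginal = if (is.null(fit)) NA_real_
                    else fit$pseudo_r2[["marginal"]],
      r2_conditional = if (is.null(fit)) NA_real_
                       else fit$pseudo_r2[["conditional"]])
  })
  structure(list(summary = dplyr::bind_rows(rows), fits = fits),
            class = "sensitivity_scan")
}

#' @export
print.sensitivity_scan <- function(x, ...) {
  cat("<sensitivity_scan>\n")
  print(x$summary)
  invisible(x)
}

#' Trim populations with extreme mean rates of change
#'
#' Removes rows of the analysis table whose mean log10 rate of change
#' falls below the lower and/or above the upper empirical quantile
#' (linear interpolation), the percentile-trimming robustness protocol.
#'
#' @param frame model frame with a `mean_lambda` column.
#' @param mode which tail(s) to drop.
#' @param q tail probability (default 0.025, i.e. the 2.5th/97.5th
#'   percentiles).
#' @return the trimmed frame; attribute `removed_fraction` records the
#'   fraction dropped.
#' @export
trim_extremes <- function(frame,
                          mode = c("drop_both", "drop_lower",
                                   "drop_upper"),
                          q = 0.025) {
  mode <- match.arg(mode)
  stopifnot(q >= 0, q < 0.5)
  if (q > 0 && nrow(frame) < 1 / q) {
    abort(sprintf("need at least %d rows to trim at q = %g",
                  ceiling(1 / q), q))
  }
  lo <- quantile(frame$mean_lambda, q, type = 7, names = FALSE)
  hi <- quantile(frame$mean_lambda, 1 - q, type = 7, names = FALSE)
  keep <- switch(mode,
                 drop_both = frame$mean_lambda >= lo &
                   frame$mean_lambda <= hi,
                 drop_lower = frame$mean_lambda >= lo,
                 drop_upper = frame$mean_lambda <= hi)
  if (q == 0) keep <- rep(TRUE, nrow(frame))
  out <- frame[keep, ]
  attr(out, "removed_fraction") <- 1 - mean(keep)
  out
}

#' Compare scenario fits against the baseline
#'
#' Per term and scenario: the estimate, whether its sign flipped relative
#' to the baseline, whether it is significant at `alpha`, and whether its
#' significance status changed.
#'
#' @param baseline a `trend_fit` (the baseline model).
#' @param scenarios named list of `trend_fit`s sharing the baseline's
#'   terms.
#' @param alpha significance level (default 0.05).
#' @return object of class `sensitivity_comparison`: tibble with one row
#'   per term x scenario.
#' @export
sensitivity_compare <- function(baseline, scenarios, alpha = 0.05) {
  base <- baseline$wald
  rows <- purrr::imap(scenarios, function(fit, name) {
    w <- dplyr::left_join(dplyr::select(base, "term",
                                        base_estimate = "estimate",
                                        base_p = "p_value"),
                          fit$wald, by = "term")
    tibble::tibble(
      scenario = name,
      term = w$term,
      estimate = w$estimate,
      p_value = w$p_value,
      sign_flip = sign(w$estimate) != sign(w$base_estimate) &
        !is.na(w$estimate),
      significant = !is.na(w$p_value) & w$p_value < alpha,
      significance_change = ((w$base_p < alpha) !=
                               (!is.na(w$p_value) & w$p_value < alpha)))
  })
  structure(dplyr::bind_rows(rows), class = c("sensitivity_comparison",
                                              "tbl_df", "tbl", "data.frame"))
}

#' Run the percentile-trimming sensitivity scenarios
#'
#' Fits the baseline specification on the three trimmed datasets (lower
#' tail dropped, upper tail dropped, both dropped) and compares them to
#' the baseline fit.
#'
#' @param frame baseline model frame.
#' @param fit baseline `trend_fit` whose specification is refitted.
#' @param q tail probability (default 0.025).
#' @return list with `fits` (named list including `baseline`), `counts`
#'   (rows per scenario), and `comparison` (a `sensitivity_comparison`).
#' @export
trim_scenarios <- function(frame, fit, q = 0.025) {
  modes <- c("drop_lower", "drop_upper", "drop_both")
  fits <- list(baseline = fit)
  counts <- c(baseline = nrow(frame))
  for (m in modes) {
    trimmed <- trim_extremes(frame, mode = m, q = q)
    fits[[m]] <- fit_lmm(trimmed, fit$spec, method = "REML")
    counts[[m]] <- nrow(trimmed)
  }
  list(fits = fits,
       counts = tibble::tibble(scenario = names(counts),
                               n_populations = unname(counts)),
       comparison = sensitivity_compare(fit, fits[modes]))
}
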