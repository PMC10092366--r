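#' Replace zero abundances
#'
#' Zeros in an abundance series are replaced by 1% of the arithmetic mean
#' of that population's non-zero abundances, so the series can be
#' log-transformed. Populations with no non-zero abundance are rejected.
#'
#' @param populations long tibble with columns population_id, year,
#'   abundance (`NA` = missing).
#' @return the same tibble with zeros replaced; non-zero values untouched.
#' @export
#' @examples
#' df <- tibble::tibble(population_id = "P1", year = 2000:2002,
#'                      abundance = c(0, 10, 30))
#' replace_zeros(df)$abundance # 0.2 10 30
replace_zeros <- function(populations) {
  stopifnot(all(c("population_id", "abundance") %in% names(populations)))
  if (any(populations$abundance < 0, na.rm = TRUE)) {
    abort("abundances must be non-negative")
  }
  dplyr::mutate(
    dplyr::group_by(populations, .data$population_id),
    abundance = {
      x <- .data$abundance
      nz <- x[!is.na(x) & x > 0]
      if (any(!is.na(x) & x == 0)) {
        if (length(nz) == 0L) {
          abort(paste0("no non-zero abundance in population ",
                       .data$population_id[1]))
        }
        x[!is.na(x) & x == 0] <- 0.01 * mean(nz)
      }
      x
    }
  ) |> dplyr::ungroup()
}

# impute one population's series; returns rows for every consecutive year
# between the first and last real record, plus fit metadata
impute_one <- function(years, abundance) {
  obs <- !is.na(abundance)
  n_real <- sum(obs)
  if (n_real < 2L) {
    return(list(values = NULL, method = "rejected", fit_r2 = NA_real_,
                n_real = n_real))
  }
  yr_obs <- years[obs]
  ab_obs <- abundance[obs]
  first <- min(yr_obs); last <- max(yr_obs)
  full_years <- seq(first, last)
  have <- match(full_years, yr_obs)
  if (!anyNA(have)) {
    return(list(
      values = tibble::tibble(year = full_years, abundance = ab_obs[have],
                              imputed = FALSE),
      method = "none", fit_r2 = NA_real_, n_real = n_real))
  }
  span <- last - first + 1L
  log_ab <- log10(ab_obs)
  dat <- data.frame(year = yr_obs, log_ab = log_ab)
  k <- min(ceiling(span / 2), n_real - 1L)
  fit <- NULL
  method <- NA_character_
  r2 <- NA_real_
  if (n_real >= 6L && k >= 3L) {
    fit <- tryCatch(
      mgcv::gam(log_ab ~ s(year, k = k), data = dat, method = "GCV.Cp"),
      error = function(e) NULL)
    if (!is.null(fit)) {
      method <- "gam"
      r2 <- summary(fit)$dev.expl
    }
  }
  if (is.null(fit)) {
    fit <- tryCatch(lm(log_ab ~ year, data = dat), error = function(e) NULL)
    if (is.null(fit) || anyNA(coef(fit))) {
      return(list(values = NULL, method = "failed", fit_r2 = NA_real_,
                  n_real = n_real))
    }
    method <- "linear"
    r2 <- suppressWarnings(summary(fit)$r.squared)
  }
  pred <- as.numeric(predict(fit, newdata = data.frame(year = full_years)))
  values <- 10^pred
  values[!is.na(have)] <- ab_obs[have[!is.na(have)]] # real records exact
  list(values = tibble::tibble(year = full_years, abundance = values,
                               imputed = is.na(have)),
       method = method, fit_r2 = r2, n_real = n_real)
}

#' Impute interior gaps in population time series
#'
#' Fits log10 abundance against year per population -- a simple linear
#' regression when fewer than six real observations are available,
#' otherwise a GAM with a penalized regression spline of year whose basis
#' dimension is half the series span (rounded up, capped at one less than
#' the number of real observations) -- and fills interior gaps with fitted
#' values. No extrapolation outside the first--last real record. Complete
#' series are passed through with `method = "none"`.
#'
#' @param populations long tibble (population_id, year, abundance, plus any
#'   metadata columns carried through); zeros must already be replaced.
#' @param window inclusive year interval to which records are restricted
#'   before imputation.
#' @return tibble with one row per population-year of the completed series:
#'   metadata columns, year, abundance, imputed (logical), method
#'   (none/linear/gam), fit_r2 (proportion of deviance explained for GAMs,
#'   R-squared for linear fits, `NA` for complete series), n_real.
#'   Populations with fewer than two real records in the window, or whose
#'   fit failed, appear only in the `exclusions` attribute.
#' @export
impute_populations <- function(populations, window = c(1992L, 2018L)) {
  stopifnot(all(c("population_id", "year", "abundance") %in%
                  names(populations)))
  pos <- populations$abundance
  if (any(pos <= 0, na.rm = TRUE)) {
    abort("non-positive abundance: run replace_zeros() first")
  }
  populations <- dplyr::filter(populations, .data$year >= window[1],
                               .data$year <= window[2])
  meta_cols <- setdiff(names(populations), c("year", "abundance"))
  meta <- dplyr::distinct(populations,
                          dplyr::across(dplyr::all_of(meta_cols)))
  split_pops <- split(populations, populations$population_id)
  out <- vector("list", length(split_pops))
  excl <- list()
  for (i in seq_along(split_pops)) {
    d <- split_pops[[i]]
    res <- impute_one(d$year, d$abundance)
    if (is.null(res$values)) {
      excl[[length(excl) + 1L]] <- tibble::tibble(
        population_id = d$population_id[1],
        reason = if (res$method == "failed") "imputation failed"
                 else "too few real records")
      next
    }
    res$values$population_id <- d$population_id[1]
    res$values$method <- res$method
    res$values$fit_r2 <- res$fit_r2
    res$values$n_real <- res$n_real
    out[[i]] <- res$values
  }
  values <- dplyr::bind_rows(out)
  if (nrow(values) > 0) {
    values <- dplyr::left_join(values, meta, by = "population_id")
    values <- dplyr::select(values, dplyr::all_of(meta_cols), "year",
                            "abundance", "imputed", "method", "fit_r2",
                            "n_real")
  }
  attr(values, "exclusions") <- dplyr::bind_rows(excl)
  values
}

#' Filter imputed series on length and imputation fit
#'
#' Retains populations with at least `min_length` consecutive values
#' (real + imputed) inside the window and, when imputation was needed, a
#' model fit of at least `r2_threshold`. Complete series pass the fit
#' filter automatically. Exclusion reasons are recorded per population.
#'
#' @param imputed output of [impute_populations()].
#' @param min_length minimum total series length (default 5).
#' @param r2_threshold minimum imputation R-squared (default 0.5).
#' @param window inclusive year interval.
#' @return the retained subset, with an `exclusions` attribute (tibble:
#'   population_id, reason) covering both earlier and new exclusions.
#' @export
filter_populations <- function(imputed, min_length = 5L,
                               r2_threshold = 0.5,
                               window = c(1992L, 2018L)) {
  excl_prev <- attr(imputed, "exclusions") %||% tibble::tibble()
  d <- dplyr::filter(imputed, .data$year >= window[1],
                     .data$year <= window[2])
  info <- dplyr::summarise(
    dplyr::group_by(d, .data$population_id),
    n_values = dplyr::n(),
    method = .data$method[1],
    fit_r2 = .data$fit_r2[1], .groups = "drop")
  info$reason <- dplyr::case_when(
    info$n_values < min_length ~ "too short",
    info$method != "none" & (is.na(info$fit_r2) |
                               info$fit_r2 < r2_threshold) ~
      "low imputation fit",
    TRUE ~ NA_character_)
  keep_ids <- info$population_id[is.na(info$reason)]
  out <- dplyr::filter(d, .data$population_id %in% keep_ids)
  excl <- dplyr::bind_rows(
    excl_prev,
    dplyr::select(dplyr::filter(info, !is.na(.data$reason)),
                  "population_id", "reason"))
  attr(out, "exclusions") <- excl
  out
}

#' Annual log10 rates of population change
#'
#' For a consecutive, positive abundance series, the annual rate is
#' `lambda_t = log10(n_t / n_{t-1})` for each adjacent pair of years.
#'
#' @param abundance numeric vector of positive abundances in year order.
#' @return numeric vector of length `length(abundance) - 1`.
#' @export
#' @examples
#' annual_lambda(c(10, 100)) # 1
annual_lambda <- function(abundance) {
  if (any(!is.finite(abundance)) || any(abundance <= 0)) {
    abort("abundances must be positive and finite (replace zeros first)")
  }
  if (length(abundance) < 2L) abort("need at least two values")
  log10(abundance[-1] / abundance[-length(abundance)])
}

#' Mean log10 rate of population change
#'
#' Arithmetic mean of the annual rates, i.e. the average over the
#' year-to-year transitions of the series.
#'
#' @param lambdas numeric vector of annual rates from [annual_lambda()].
#' @return a single number.
#' @export
mean_lambda <- function(lambdas) {
  if (length(lambdas) == 0L) abort("empty lambda vector")
  mean(lambdas)
}

#' Population trend table from raw series
#'
#' End-to-end trend estimation: zero replacement, gap imputation, quality
#' filtering, and per-population mean log10 rate of change.
#'
#' @param populations long tibble (population_id, species, site, latitude,
#'   longitude, year, abundance; `NA` = missing).
#' @param min_length,r2_threshold,window filtering parameters, see
#'   [filter_populations()].
#' @return tibble with one row per retained population: metadata,
#'   mean_lambda, n_years (series length), n_real, method, fit_r2,
#'   first_year, last_year; exclusions carried in the `exclusions`
#'   attribute.
#' @export
population_trends <- function(populations, min_length = 5L,
                              r2_threshold = 0.5,
                              window = c(1992L, 2018L)) {
  imputed <- impute_populations(replace_zeros(populations), window = window)
  kept <- filter_populations(imputed, min_length = min_length,
                             r2_threshold = r2_threshold, window = window)
  out <- lambda_table(kept)
  attr(out, "exclusions") <- attr(kept, "exclusions")
  out
}

#' Summarise filtered series into a per-population lambda table
#'
#' @param imputed a filtered imputation table (see [filter_populations()]).
#' @return tibble: one row per population with mean_lambda and metadata.
#' @export
lambda_table <- function(imputed) {
  meta_cols <- intersect(c("species", "site", "latitude", "longitude"),
                         names(imputed))
  dplyr::summarise(
    dplyr::group_by(imputed, .data$population_id),
    dplyr::across(dplyr::all_of(meta_cols), ~ .x[1]),
    mean_lambda = mean_lambda(annual_lambda(.data$abundance[order(.data$year)])),
    n_years = dplyr::n(),
    n_real = .data$n_real[1],
    method = .data$method[1],
    fit_r2 = .data$fit_r2[1],
    first_year = min(.data$year),
    last_year = max(.data$year),
    .groups = "drop")
}
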