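#' Geometric mean
#'
#' Mean on the log scale, back-transformed. Used to aggregate repeated trait
#' measurements for one species across source datasets.
#'
#' @param x numeric vector of strictly positive values; `NA`s are dropped.
#' @return a single number, or `NA` if no finite values remain.
#' @export
#' @examples
#' geometric_mean(c(2, 8)) # 4
geometric_mean <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  if (any(x <= 0)) abort("geometric mean requires strictly positive values")
  exp(mean(log(x)))
}

# stop with a message naming the offending field
assert_field <- function(ok, field, what) {
  if (!isTRUE(ok)) abort(sprintf("invalid `%s`: %s", field, what))
}

# OLS slope of y on x, closed form; NA-safe
ols_slope <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2L) return(NA_real_)
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}
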