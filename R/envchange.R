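#' Annual mean temperature from monthly values
#'
#' Per site and year, the arithmetic mean of the available monthly values
#' (12 expected). Years with more than two missing months are flagged;
#' empty years are excluded with a warning.
#'
#' @param temperature long tibble: site, year, month, temperature.
#' @return tibble: site, year, temperature (annual mean), n_months,
#'   flagged (logical, more than two months missing).
#' @export
annual_mean_temperature <- function(temperature) {
  stopifnot(all(c("site", "year", "temperature") %in% names(temperature)))
  ann <- dplyr::summarise(
    dplyr::group_by(temperature, .data$site, .data$year),
    n_months = sum(!is.na(.data$temperature)),
    temperature = mean(.data$temperature, na.rm = TRUE),
    .groups = "drop")
  empty <- ann$n_months == 0L
  if (any(empty)) {
    warn(sprintf("%d site-years with no monthly values excluded",
                 sum(empty)))
    ann <- ann[!empty, ]
  }
  ann$flagged <- ann$n_months < 10L
  dplyr::select(ann, "site", "year", "temperature", "n_months", "flagged")
}

#' Per-population temperature warming rate
#'
#' Ordinary least-squares slope of annual mean temperature on year,
#' restricted to each population's monitoring window, used as the average
#' annual rate of temperature change.
#'
#' @param annual annual temperature tibble from
#'   [annual_mean_temperature()].
#' @param windows tibble: population_id, site, first_year, last_year.
#' @return tibble: population_id, delta_t (degrees C per year), n_years.
#'   Populations with fewer than two annual values get `NA` and are listed
#'   in the `exclusions` attribute.
#' @export
temperature_trend <- function(annual, windows) {
  stopifnot(all(c("population_id", "site", "first_year", "last_year") %in%
                  names(windows)))
  res <- purrr::pmap(windows[c("population_id", "site", "first_year",
                               "last_year")], function(population_id, site,
                                                       first_year,
                                                       last_year) {
    d <- annual[annual$site == site & annual$year >= first_year &
                  annual$year <= last_year, ]
    tibble::tibble(population_id = population_id,
                   delta_t = if (nrow(d) >= 2L)
                     ols_slope(d$year, d$temperature) else NA_real_,
                   n_years = nrow(d))
  })
  out <- dplyr::bind_rows(res)
  attr(out, "exclusions") <- tibble::tibble(
    population_id = out$population_id[is.na(out$delta_t)],
    reason = "fewer than two annual temperature values")
  out
}

#' Default crosswalk from 14 simplified classes to the 8 final classes
#'
#' The packaged crosswalk maps each of the 14 simplified land-cover classes
#' (four tree, four shrub, and six other classes) fully into one of the 8
#' final classes, grouping all tree classes into forest and all shrub
#' classes into shrubs. Users may supply their own table with columns
#' code, class, fraction (fractions per code summing to 1).
#'
#' @return tibble: code, class, fraction.
#' @export
default_crosswalk <- function() {
  simplified <- c("broadleaf_evergreen_trees", "broadleaf_deciduous_trees",
                  "needleleaf_evergreen_trees", "needleleaf_deciduous_trees",
                  "broadleaf_evergreen_shrubs", "broadleaf_deciduous_shrubs",
                  "needleleaf_evergreen_shrubs", "needleleaf_deciduous_shrubs",
                  "natural_grass", "bare_soil", "cropland", "snow_ice",
                  "urban", "water")
  final <- c(rep("forest", 4), rep("shrubs", 4), "natural_grass",
             "bare_soil", "cropland", "snow_ice", "urban", "water")
  tibble::tibble(code = seq_along(simplified), class = final, fraction = 1)
}

validate_crosswalk <- function(crosswalk) {
  stopifnot(all(c("code", "class", "fraction") %in% names(crosswalk)))
  sums <- tapply(crosswalk$fraction, crosswalk$code, sum)
  if (any(abs(sums - 1) > 1e-6)) {
    abort("crosswalk fractions must sum to 1 per source code")
  }
  bad <- setdiff(unique(crosswalk$class), cover_classes())
  if (length(bad)) {
    abort(paste("unknown cover classes in crosswalk:",
                paste(bad, collapse = ", ")))
  }
  invisible(crosswalk)
}

#' A categorical land-cover grid in geographic coordinates
#'
#' Lightweight in-memory representation of a single-year categorical
#' raster: an integer matrix of land-cover codes (rows = north to south)
#' with a lon/lat extent (WGS84).
#'
#' @param codes integer matrix of land-cover codes; row 1 is the northern
#'   edge.
#' @param xmin,xmax,ymin,ymax extent in decimal degrees.
#' @return an object of class `landcover_grid`.
#' @export
landcover_grid <- function(codes, xmin, xmax, ymin, ymax) {
  stopifnot(is.matrix(codes), xmax > xmin, ymax > ymin)
  structure(list(codes = codes, xmin = xmin, xmax = xmax,
                 ymin = ymin, ymax = ymax),
            class = "landcover_grid")
}

# lon/lat of all pixel centers of a grid
grid_centers <- function(grid) {
  nr <- nrow(grid$codes); nc <- ncol(grid$codes)
  dx <- (grid$xmax - grid$xmin) / nc
  dy <- (grid$ymax - grid$ymin) / nr
  lon <- grid$xmin + (seq_len(nc) - 0.5) * dx
  lat <- grid$ymax - (seq_len(nr) - 0.5) * dy
  list(lon = lon, lat = lat)
}

#' Land-cover class fractions within a buffer
#'
#' Crosswalks each pixel's code into the 8 final classes and averages over
#' the pixels whose centers fall inside a geodesic circle around the
#' location (default radius 1 km).
#'
#' @param grid a [landcover_grid()].
#' @param latitude,longitude location in decimal degrees (WGS84).
#' @param crosswalk crosswalk tibble (code, class, fraction); defaults to
#'   [default_crosswalk()].
#' @param radius buffer radius in meters.
#' @return named numeric vector over [cover_classes()], summing to 1.
#' @export
buffer_fractions <- function(grid, latitude, longitude,
                             crosswalk = default_crosswalk(),
                             radius = 1000) {
  validate_crosswalk(crosswalk)
  if (longitude < grid$xmin || longitude > grid$xmax ||
      latitude < grid$ymin || latitude > grid$ymax) {
    abort("location outside raster extent")
  }
  ctr <- grid_centers(grid)
  # prune to a generous bounding box before geodesic distances
  dlat <- radius / 110574 * 1.5
  dlon <- radius / (111320 * max(cos(latitude * pi / 180), 0.01)) * 1.5
  cols <- which(ctr$lon >= longitude - dlon & ctr$lon <= longitude + dlon)
  rows <- which(ctr$lat >= latitude - dlat & ctr$lat <= latitude + dlat)
  if (!length(cols) || !length(rows)) {
    abort("no pixel centers inside the buffer")
  }
  pts <- expand.grid(row = rows, col = cols)
  d <- geosphere::distGeo(cbind(longitude, latitude),
                          cbind(ctr$lon[pts$col], ctr$lat[pts$row]))
  inside <- d <= radius
  if (!any(inside)) abort("no pixel centers inside the buffer")
  codes <- grid$codes[cbind(pts$row[inside], pts$col[inside])]
  counts <- table(codes)
  cw <- tidyr::pivot_wider(crosswalk, names_from = "class",
                           values_from = "fraction", values_fill = 0,
                           values_fn = sum)
  missing_codes <- setdiff(names(counts), as.character(cw$code))
  if (length(missing_codes)) {
    abort(paste("codes missing from crosswalk:",
                paste(missing_codes, collapse = ", ")))
  }
  frac <- setNames(numeric(length(cover_classes())), cover_classes())
  for (cl in intersect(cover_classes(), names(cw))) {
    contrib <- cw[[cl]][match(as.integer(names(counts)), cw$code)]
    frac[cl] <- sum(contrib * as.numeric(counts))
  }
  frac / sum(counts)
}

#' Per-class mean annual rate of land-cover change
#'
#' For each class, the arithmetic mean of successive annual differences of
#' the cover fraction -- equal to (last - first) / (years - 1). A linear
#' regression is deliberately not used: land cover changes directionally
#' without the strong inter-annual fluctuations of temperature.
#'
#' @param fractions tibble with columns year and one column per cover
#'   class (fractions of buffer area).
#' @param window optional inclusive year interval restricting the series.
#' @return named numeric vector of per-class rates (fraction of area per
#'   year).
#' @export
landcover_rate <- function(fractions, window = NULL) {
  if (!is.null(window)) {
    fractions <- dplyr::filter(fractions, .data$year >= window[1],
                               .data$year <= window[2])
  }
  if (nrow(fractions) < 2L) abort("need at least two annual fraction rows")
  fractions <- dplyr::arrange(fractions, .data$year)
  cls <- intersect(cover_classes(), names(fractions))
  vapply(cls, function(cl) mean(diff(fractions[[cl]])), numeric(1))
}

#' Per-population environmental change rates
#'
#' Combines the temperature warming slope and per-class land-cover change
#' rates over each population's monitoring window.
#'
#' @param windows tibble: population_id, site, first_year, last_year.
#' @param temperature monthly temperature tibble (site, year, month,
#'   temperature) or an annual table already averaged (site, year,
#'   temperature with attribute-free layout is detected by the absence of
#'   a month column).
#' @param landcover tibble: site, year, one column per cover class.
#' @return tibble: population_id, delta_t, and one rate column per cover
#'   class; populations lacking usable data carry `NA` and are listed in
#'   the `exclusions` attribute.
#' @export
env_change <- function(windows, temperature, landcover) {
  annual <- if ("month" %in% names(temperature)) {
    annual_mean_temperature(temperature)
  } else temperature
  tt <- temperature_trend(annual, windows)
  lc_years <- sort(unique(landcover$year))
  carried <- FALSE
  rates <- purrr::pmap(windows[c("population_id", "site", "first_year",
                                 "last_year")],
                       function(population_id, site, first_year,
                                last_year) {
    d <- landcover[landcover$site == site, ]
    want <- seq(first_year, last_year)
    have <- intersect(want, d$year)
    if (length(have) < length(want)) {
      # carry nearest available year for gaps in the raster record
      carried <<- TRUE
      idx <- vapply(want, function(y) which.min(abs(d$year - y)),
                    integer(1))
      d <- d[idx, ]
      d$year <- want
    } else {
      d <- d[d$year %in% want, ]
    }
    if (nrow(d) < 2L) {
      return(tibble::tibble(population_id = population_id))
    }
    r <- landcover_rate(d)
    tibble::tibble(population_id = population_id, !!!as.list(r))
  })
  rates <- dplyr::bind_rows(rates)
  if (carried) {
    warn("some window years missing from the land-cover record; nearest available year carried")
  }
  out <- dplyr::left_join(tt[c("population_id", "delta_t")], rates,
                          by = "population_id")
  bad <- !complete.cases(out)
  attr(out, "exclusions") <- tibble::tibble(
    population_id = out$population_id[bad],
    reason = "incomplete environmental record")
  out
}
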