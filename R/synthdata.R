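#' Land-cover classes used throughout the pipeline
#'
#' The eight aggregated land-cover classes: forest, shrubs, natural grass,
#' bare soil, cropland, snow/ice, urban, water.
#'
#' @return character vector of class labels (syntactic column names).
#' @export
cover_classes <- function() {
  c("forest", "shrubs", "natural_grass", "bare_soil",
    "cropland", "snow_ice", "urban", "water")
}

#' Default generating fixed-effect coefficients
#'
#' Named coefficient vector for the population-trend model's fixed effects:
#' intercept, temperature-change rate (`delta_t`), the fast--slow axis
#' (`pc1`), the eight land-cover change rates, and all their two- and
#' three-way interactions (no cover x cover terms). Defaults place non-zero
#' effects on the terms of the reduced model reported for the empirical
#' study (cropland and bare-soil rates, their interactions with `pc1`, and
#' the warming x bare-soil interaction); every other term is zero.
#'
#' @return named numeric vector of length 36 (intercept + 35 terms).
#' @export
default_beta <- function() {
  cls <- cover_classes()
  nm <- c("intercept", "delta_t", "pc1", cls,
          "delta_t:pc1",
          paste0("pc1:", cls),
          paste0("delta_t:", cls),
          paste0("delta_t:pc1:", cls))
  beta <- setNames(numeric(length(nm)), nm)
  beta["intercept"] <- 0.0025
  beta["delta_t"] <- 0.0246
  beta["pc1"] <- 0.0052
  beta["cropland"] <- -1.4974
  beta["bare_soil"] <- 5.1349
  beta["pc1:cropland"] <- 1.896
  beta["pc1:bare_soil"] <- 2.7376
  beta["delta_t:bare_soil"] <- -718.4483
  beta
}

#' Configuration for the synthetic study generator
#'
#' Bundles every knob of the generative model: study dimensions, the
#' observation window, missingness and zero-inflation rates, the generating
#' fixed-effect coefficients, random-effect and residual standard
#' deviations, and the strength of the fecundity--ageing trade-off that
#' induces the latent fast--slow axis.
#'
#' @param n_species,n_populations,n_sites study dimensions.
#' @param year_range inclusive year interval, length-2 integer vector.
#' @param missing_rate,zero_rate fractions in \[0, 1\]: probability that an
#'   interior observation is missing, and that an observed value is recorded
#'   as zero.
#' @param beta named coefficient vector as [default_beta()].
#' @param sigma_species,sigma_site,sigma_resid non-negative standard
#'   deviations of the species and site random intercepts and the
#'   population-level residual on the mean log10 annual rate of change.
#' @param tradeoff_strength non-negative scalar scaling the loading of the
#'   latent fast--slow axis on the life-history traits; 0 switches the
#'   trade-off off.
#' @param trait_noise sd of log-trait noise around the allometric +
#'   trade-off expectation.
#' @param trait_missing_rate fraction of trait cells masked as missing.
#' @param temp_slope_mean,temp_slope_sd distribution of true site warming
#'   slopes (degrees C per year).
#' @param temp_noise sd of monthly temperature noise (degrees C).
#' @param temp_seasonal_amp amplitude of the seasonal cycle (degrees C).
#' @param cover_rate_sd sd of the designed per-class annual cover change
#'   rates across sites (fraction of buffer area per year); either a
#'   single value or a named vector over [cover_classes()]. The defaults
#'   make cropland change the most variable class and snow/ice the least.
#' @param cover_noise sd of annual perturbations of cover fractions
#'   (renormalized to close to 1).
#' @param obs_noise sd of per-year observation noise on the log10 abundance
#'   step.
#' @param mean_series_length,sd_series_length distribution of series lengths
#'   (years), clipped to \[5, window span\].
#' @param seed integer seed; all generators are deterministic given it.
#' @return an object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(n_species = 120,
                       n_populations = 400,
                       n_sites = 150,
                       year_range = c(1992L, 2018L),
                       missing_rate = 0.2,
                       zero_rate = 0.02,
                       beta = default_beta(),
                       sigma_species = 0.04,
                       sigma_site = 0.03,
                       sigma_resid = 0.1,
                       tradeoff_strength = 1,
                       trait_noise = 0.3,
                       trait_missing_rate = 0,
                       temp_slope_mean = 0.02,
                       temp_slope_sd = 0.015,
                       temp_noise = 0.5,
                       temp_seasonal_amp = 8,
                       cover_rate_sd = c(forest = 0.004, shrubs = 0.002,
                                         natural_grass = 0.003,
                                         bare_soil = 0.0017,
                                         cropland = 0.0045,
                                         snow_ice = 0.0005, urban = 0.001,
                                         water = 0.001),
                       cover_noise = 0.002,
                       obs_noise = 0.05,
                       mean_series_length = 10,
                       sd_series_length = 4.2,
                       seed = 1L) {
  cfg <- list(
    n_species = as.integer(n_species),
    n_populations = as.integer(n_populations),
    n_sites = as.integer(n_sites),
    year_range = as.integer(year_range),
    missing_rate = missing_rate, zero_rate = zero_rate,
    beta = beta,
    sigma_species = sigma_species, sigma_site = sigma_site,
    sigma_resid = sigma_resid,
    tradeoff_strength = tradeoff_strength,
    trait_noise = trait_noise, trait_missing_rate = trait_missing_rate,
    temp_slope_mean = temp_slope_mean, temp_slope_sd = temp_slope_sd,
    temp_noise = temp_noise, temp_seasonal_amp = temp_seasonal_amp,
    cover_rate_sd = cover_rate_sd, cover_noise = cover_noise,
    obs_noise = obs_noise,
    mean_series_length = mean_series_length,
    sd_series_length = sd_series_length,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  assert_field(length(cfg$year_range) == 2L &&
                 diff(cfg$year_range) >= 4L,
               "year_range", "must span at least 5 years")
  for (f in c("missing_rate", "zero_rate", "trait_missing_rate")) {
    assert_field(is.numeric(cfg[[f]]) && cfg[[f]] >= 0 && cfg[[f]] <= 1,
                 f, "must be a fraction in [0, 1]")
  }
  for (f in c("sigma_species", "sigma_site", "sigma_resid",
              "tradeoff_strength", "trait_noise", "temp_noise",
              "cover_noise", "obs_noise")) {
    assert_field(is.numeric(cfg[[f]]) && length(cfg[[f]]) == 1L &&
                   cfg[[f]] >= 0, f, "must be a non-negative scalar")
  }
  assert_field(is.numeric(cfg$cover_rate_sd) && all(cfg$cover_rate_sd >= 0) &&
                 (length(cfg$cover_rate_sd) == 1L ||
                    all(cover_classes() %in% names(cfg$cover_rate_sd))),
               "cover_rate_sd",
               "must be a non-negative scalar or named vector over the cover classes")
  assert_field(cfg$n_species >= 4L, "n_species", "must be at least 4")
  assert_field(cfg$n_populations >= 1L, "n_populations", "must be positive")
  assert_field(cfg$n_sites >= 1L, "n_sites", "must be positive")
  assert_field(is.numeric(cfg$beta) && !is.null(names(cfg$beta)),
               "beta", "must be a named numeric vector")
  invisible(cfg)
}

# per-class sd vector for the designed cover change rates
cover_rate_sd_vec <- function(cfg) {
  if (length(cfg$cover_rate_sd) == 1L) {
    setNames(rep(cfg$cover_rate_sd, length(cover_classes())),
             cover_classes())
  } else cfg$cover_rate_sd[cover_classes()]
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_species, "species,", x$n_populations,
      "populations,", x$n_sites, "sites,",
      paste(x$year_range, collapse = "-"), "\n")
  invisible(x)
}

# trait generative model: log trait = allometric intercept + slope * log mass
#   + loading * tradeoff_strength * latent + noise
trait_allometry <- function() {
  tibble::tibble(
    trait = c("longevity", "maturity", "reproductive_events", "offspring"),
    intercept = c(0.6, -1.2, 0.6, 1.2),
    slope = c(0.18, 0.23, -0.12, -0.08),
    loading = c(-0.35, -0.35, 0.35, 0.35) # slow traits load negatively
  )
}

# nested taxonomy consistent with the tree: cut the cophenetic dendrogram
simulate_taxonomy <- function(tree) {
  n <- length(tree$tip.label)
  h <- stats::hclust(stats::as.dist(ape::cophenetic.phylo(tree)), "average")
  k_class <- min(3L, n)
  k_order <- min(max(3L, n %/% 12L), n)
  k_family <- min(max(6L, n %/% 5L), n)
  tibble::tibble(
    species = tree$tip.label,
    class = paste0("class_", stats::cutree(h, k_class)[tree$tip.label]),
    order = paste0("order_", stats::cutree(h, k_order)[tree$tip.label]),
    family = paste0("family_", stats::cutree(h, k_family)[tree$tip.label])
  )
}

#' Simulate species life-history traits and a phylogeny
#'
#' Draws a latent fast--slow axis per species and generates five
#' life-history traits (maximum longevity, age at sexual maturity, annual
#' reproductive events, offspring per event, body mass in grams) from a
#' body-mass allometry plus an opposite-signed loading of the latent axis
#' on ageing vs fecundity traits, together with a pure-birth ultrametric
#' phylogeny and a nested taxonomy.
#'
#' @param config a [sim_config()].
#' @return list with `traits` (tibble: species, the five traits, taxonomy),
#'   `tree` (an `ape::phylo`), and `truth` (tibble: species,
#'   latent_fastslow, log_mass).
#' @export
simulate_traits <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_species
  species <- sprintf("Species_%03d", seq_len(n))
  tree <- ape::rphylo(n, birth = 0.2, death = 0)
  tree$tip.label <- species
  tax <- simulate_taxonomy(tree)

  latent <- rnorm(n)
  log_mass <- rnorm(n, mean = 5, sd = 2) # grams, ln scale
  allo <- trait_allometry()
  traits <- tibble::tibble(species = species, body_mass = exp(log_mass))
  for (i in seq_len(nrow(allo))) {
    mu <- allo$intercept[i] + allo$slope[i] * log_mass +
      allo$loading[i] * config$tradeoff_strength * latent
    traits[[allo$trait[i]]] <- exp(mu + rnorm(n, sd = config$trait_noise))
  }
  traits <- traits[, c("species", "longevity", "maturity",
                       "reproductive_events", "offspring", "body_mass")]
  if (config$trait_missing_rate > 0) {
    for (tr in c("longevity", "maturity", "reproductive_events",
                 "offspring", "body_mass")) {
      mask <- runif(n) < config$trait_missing_rate
      traits[[tr]][mask] <- NA_real_
    }
  }
  traits <- dplyr::left_join(traits, tax, by = "species")
  list(traits = traits, tree = tree,
       truth = tibble::tibble(species = species, latent_fastslow = latent,
                              log_mass = log_mass))
}

#' Simulate per-site temperature and land-cover series
#'
#' Monthly temperature per site is a linear warming trend plus a seasonal
#' cycle and white noise; annual land-cover fractions follow a directional
#' linear path across the eight classes (closed to sum 1 each year) with
#' optional annual perturbations. True warming slopes and per-class change
#' rates are recorded for recovery tests.
#'
#' @param config a [sim_config()].
#' @return list with `sites` (site, latitude, longitude), `temperature`
#'   (site, year, month, temperature), `landcover` (site, year, one column
#'   per cover class), and `truth` (per-site `temp_slope` tibble and
#'   `cover_rates` tibble of designed per-class rates).
#' @export
simulate_environment <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  ns <- config$n_sites
  years <- seq(config$year_range[1], config$year_range[2])
  ny <- length(years)
  sites <- tibble::tibble(
    site = sprintf("S%03d", seq_len(ns)),
    latitude = runif(ns, -60, 70),
    longitude = runif(ns, -180, 180)
  )

  baseline <- rnorm(ns, 10, 8)
  slope <- rnorm(ns, config$temp_slope_mean, config$temp_slope_sd)
  grid <- tidyr::expand_grid(i = seq_len(ns), year = years, month = 1:12)
  phase <- ifelse(sites$latitude[grid$i] >= 0, 7, 1) # warmest month
  grid$temperature <- baseline[grid$i] +
    slope[grid$i] * (grid$year - years[1]) +
    config$temp_seasonal_amp * cos(2 * pi * (grid$month - phase) / 12) +
    rnorm(nrow(grid), sd = config$temp_noise)
  temperature <- tibble::tibble(site = sites$site[grid$i],
                                year = grid$year, month = grid$month,
                                temperature = grid$temperature)

  cls <- cover_classes()
  k <- length(cls)
  # directional drift: cropland/urban tend to expand, forest to contract
  drift_mean <- setNames(c(-0.001, 0, 0, 0.0003, 0.001, 0, 0.0003, 0), cls)
  cover_list <- vector("list", ns)
  rate_list <- vector("list", ns)
  for (s in seq_len(ns)) {
    f0 <- as.numeric(stats::rgamma(k, shape = c(4, 2, 3, 1, 3, 0.3, 1, 1)))
    f0 <- f0 / sum(f0)
    rate <- rnorm(k, drift_mean, cover_rate_sd_vec(config))
    rate <- rate - mean(rate) # closure: rates sum to 0
    # keep the linear path inside [0, 1]
    end <- f0 + rate * (ny - 1)
    shrink <- 1
    bad <- end < 0.001 | end > 0.999
    if (any(bad)) {
      shrink <- min(abs((f0[bad] - ifelse(rate[bad] < 0, 0.001, 0.999)) /
                          (rate[bad] * (ny - 1))))
      rate <- rate * max(0, min(1, shrink))
    }
    path <- outer(rep(1, ny), f0) + outer(seq_len(ny) - 1, rate)
    if (config$cover_noise > 0) {
      path <- path + matrix(rnorm(ny * k, sd = config$cover_noise), ny, k)
      path[path < 0] <- 0
    }
    path <- path / rowSums(path)
    colnames(path) <- cls
    cover_list[[s]] <- tibble::tibble(site = sites$site[s], year = years,
                                      tibble::as_tibble(path))
    # truth: realized rate of the designed (noiseless) closed path
    rate_list[[s]] <- tibble::tibble(site = sites$site[s], class = cls,
                                     rate = rate)
  }
  landcover <- dplyr::bind_rows(cover_list)
  truth <- list(
    temp_slope = tibble::tibble(site = sites$site, slope = slope),
    cover_rates = dplyr::bind_rows(rate_list)
  )
  list(sites = sites, temperature = temperature, landcover = landcover,
       truth = truth)
}

# linear predictor for one population from named beta and covariates
eta_from_beta <- function(beta, delta_t, pc1, rates) {
  cls <- names(rates)
  val <- beta[["intercept"]] + beta[["delta_t"]] * delta_t +
    beta[["pc1"]] * pc1 + beta[["delta_t:pc1"]] * delta_t * pc1
  for (cl in cls) {
    r <- rates[[cl]]
    val <- val + beta[[cl]] * r +
      beta[[paste0("pc1:", cl)]] * pc1 * r +
      beta[[paste0("delta_t:", cl)]] * delta_t * r +
      beta[[paste0("delta_t:pc1:", cl)]] * delta_t * pc1 * r
  }
  val
}

#' Simulate population abundance time series
#'
#' Each population is assigned a species and a site; its expected mean
#' log10 annual rate of change is the fixed-effect linear predictor
#' evaluated at the site's true environmental change rates and the species'
#' latent fast--slow value, plus species and site random intercepts and a
#' population-level residual. Abundance follows
#' `n_t = n_{t-1} * 10^(lambda + noise)`; missingness (interior years,
#' completely at random) and zeros are then injected.
#'
#' @param config a [sim_config()].
#' @param traits result of [simulate_traits()].
#' @param environment result of [simulate_environment()].
#' @return list with `populations` (long tibble: population_id, species,
#'   site, latitude, longitude, year, abundance with `NA` = missing) and
#'   `truth` (per-population tibble with the generating linear predictor
#'   `eta`, realized `lambda_true`, and the random effects).
#' @export
simulate_populations <- function(config, traits, environment) {
  validate_sim_config(config)
  set.seed(config$seed + 2L)
  np <- config$n_populations
  years <- seq(config$year_range[1], config$year_range[2])
  span <- length(years)

  sp_idx <- sample(config$n_species, np, replace = TRUE)
  site_idx <- sample(config$n_sites, np, replace = TRUE)
  u_species <- rnorm(config$n_species, sd = config$sigma_species)
  v_site <- rnorm(config$n_sites, sd = config$sigma_site)

  slope <- environment$truth$temp_slope$slope
  rates_wide <- tidyr::pivot_wider(environment$truth$cover_rates,
                                   names_from = "class",
                                   values_from = "rate")
  rates_wide <- rates_wide[match(environment$sites$site, rates_wide$site), ]

  len <- pmin(span, pmax(5L, round(rnorm(np, config$mean_series_length,
                                         config$sd_series_length))))
  start <- vapply(len, function(l) sample(span - l + 1L, 1L), integer(1))

  pop_rows <- vector("list", np)
  truth_rows <- vector("list", np)
  for (p in seq_len(np)) {
    s <- site_idx[p]; i <- sp_idx[p]
    rates <- as.list(rates_wide[s, cover_classes()])
    eta <- eta_from_beta(config$beta, slope[s],
                         traits$truth$latent_fastslow[i], rates)
    lam <- eta + u_species[i] + v_site[s] +
      rnorm(1, sd = config$sigma_resid)
    yrs <- years[start[p]:(start[p] + len[p] - 1L)]
    steps <- lam + rnorm(len[p] - 1L, sd = config$obs_noise)
    n0 <- 10^runif(1, 1, 3)
    abun <- n0 * 10^cumsum(c(0, steps))
    # interior MCAR missingness; first and last record always observed
    miss <- c(FALSE, runif(len[p] - 2L) < config$missing_rate, FALSE)
    zero <- !miss & runif(len[p]) < config$zero_rate
    abun[zero] <- 0
    abun[miss] <- NA_real_
    pop_rows[[p]] <- tibble::tibble(
      population_id = sprintf("P%04d", p),
      species = traits$traits$species[i],
      site = environment$sites$site[s],
      latitude = environment$sites$latitude[s],
      longitude = environment$sites$longitude[s],
      year = yrs, abundance = abun
    )
    truth_rows[[p]] <- tibble::tibble(
      population_id = sprintf("P%04d", p),
      species = traits$traits$species[i],
      site = environment$sites$site[s],
      eta = eta, lambda_true = lam,
      species_effect = u_species[i], site_effect = v_site[s]
    )
  }
  list(populations = dplyr::bind_rows(pop_rows),
       truth = dplyr::bind_rows(truth_rows),
       species_effects = u_species, site_effects = v_site)
}

#' Simulate a population-level analysis table directly
#'
#' Generative twin of the trend model at the level of the assembled
#' analysis table: site warming slopes and cover-change rates and the
#' species latent fast--slow axis are drawn from the same distributions
#' as the full study generator, and the response is the fixed-effect
#' linear predictor plus species and site random intercepts and residual
#' noise. Used for parameter-recovery and selection studies where the
#' series-level machinery is not under test.
#'
#' @param config a [sim_config()].
#' @return tibble shaped like [assemble_model_frame()]'s output
#'   (population_id, mean_lambda, delta_t, pc1, cover rate columns,
#'   species, location), with the generating `eta` in the `truth`
#'   attribute.
#' @export
simulate_model_frame <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed + 3L)
  np <- config$n_populations
  ns <- config$n_sites
  nsp <- config$n_species
  cls <- cover_classes()
  slope <- rnorm(ns, config$temp_slope_mean, config$temp_slope_sd)
  sds <- cover_rate_sd_vec(config)
  rates <- matrix(rnorm(ns * length(cls), sd = rep(sds, each = ns)),
                  ns, length(cls), dimnames = list(NULL, cls))
  rates <- rates - rowMeans(rates) # closed fractions: rates sum to 0
  latent <- rnorm(nsp)
  u <- rnorm(nsp, sd = config$sigma_species)
  v <- rnorm(ns, sd = config$sigma_site)
  sp <- sample(nsp, np, replace = TRUE)
  site <- sample(ns, np, replace = TRUE)
  eta <- vapply(seq_len(np), function(p) {
    eta_from_beta(config$beta, slope[site[p]], latent[sp[p]],
                  as.list(as.data.frame(rates)[site[p], ]))
  }, numeric(1))
  frame <- tibble::tibble(
    population_id = sprintf("P%04d", seq_len(np)),
    mean_lambda = eta + u[sp] + v[site] +
      rnorm(np, sd = config$sigma_resid),
    delta_t = slope[site],
    pc1 = latent[sp])
  for (cl in cls) frame[[cl]] <- rates[site, cl]
  frame$species <- sprintf("Species_%03d", sp)
  frame$location <- sprintf("S%03d", site)
  attr(frame, "truth") <- tibble::tibble(
    population_id = frame$population_id, eta = eta)
  frame
}

#' Simulate a complete synthetic study
#'
#' Runs the trait, environment, and population generators under one
#' configuration and collects their ground truth.
#'
#' @param config a [sim_config()].
#' @return an object of class `sim_study`: list with `populations`,
#'   `traits`, `tree`, `sites`, `temperature`, `landcover`, and `truth`
#'   (beta, latent axis, random effects, per-site environmental rates,
#'   per-population linear predictors).
#' @export
#' @examples
#' study <- simulate_study(sim_config(n_species = 10, n_populations = 20,
#'                                    n_sites = 8, seed = 42))
#' dplyr::glimpse(study$populations)
simulate_study <- function(config = sim_config()) {
  tr <- simulate_traits(config)
  env <- simulate_environment(config)
  pops <- simulate_populations(config, tr, env)
  structure(list(
    config = config,
    populations = pops$populations,
    traits = tr$traits,
    tree = tr$tree,
    sites = env$sites,
    temperature = env$temperature,
    landcover = env$landcover,
    truth = list(beta = config$beta,
                 latent_fastslow = tr$truth,
                 temp_slope = env$truth$temp_slope,
                 cover_rates = env$truth$cover_rates,
                 populations = pops$truth,
                 species_effects = pops$species_effects,
                 site_effects = pops$site_effects)
  ), class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat("<sim_study>", nrow(x$truth$populations), "populations,",
      length(x$tree$tip.label), "species,", nrow(x$sites), "sites\n")
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Populations as wide CSV (one column per year), traits and environment as
#' CSV, the phylogeny as Newick, and the ground truth as JSON.
#'
#' @param study a [simulate_study()] result.
#' @param dir output directory, created if needed.
#' @return invisibly, the named vector of written file paths.
#' @export
write_sim_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(populations = file.path(dir, "populations.csv"),
             traits = file.path(dir, "traits.csv"),
             tree = file.path(dir, "phylogeny.nwk"),
             temperature = file.path(dir, "temperature.csv"),
             landcover = file.path(dir, "landcover.csv"),
             truth = file.path(dir, "ground_truth.json"))
  wide <- tidyr::pivot_wider(study$populations,
                             names_from = "year",
                             values_from = "abundance",
                             names_sort = TRUE)
  utils::write.csv(wide, paths["populations"], row.names = FALSE, na = "")
  utils::write.csv(study$traits, paths["traits"], row.names = FALSE, na = "")
  ape::write.tree(study$tree, paths["tree"])
  utils::write.csv(study$temperature, paths["temperature"],
                   row.names = FALSE)
  utils::write.csv(study$landcover, paths["landcover"], row.names = FALSE)
  truth <- study$truth
  truth$beta <- as.list(truth$beta)
  jsonlite::write_json(truth, paths["truth"], dataframe = "columns",
                       digits = NA, auto_unbox = TRUE)
  invisible(paths)
}

#' Read populations from a wide CSV
#'
#' Inverse of the wide layout written by [write_sim_study()]: metadata
#' columns followed by one column per year, blank cells meaning missing.
#'
#' @param path CSV file path.
#' @return long tibble: population_id, species, site, latitude, longitude,
#'   year, abundance.
#' @export
read_populations_csv <- function(path) {
  wide <- utils::read.csv(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  meta_cols <- names(wide)[is.na(suppressWarnings(as.integer(names(wide))))]
  long <- tidyr::pivot_longer(tibble::as_tibble(wide),
                              cols = -dplyr::all_of(meta_cols),
                              names_to = "year", values_to = "abundance")
  long$year <- as.integer(long$year)
  dplyr::arrange(long, .data$population_id, .data$year)
}
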