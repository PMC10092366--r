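# shared fixtures for the test suite; everything is generated in code

# a small complete study used by several files
small_study <- function(seed = 7, n_species = 20, n_populations = 60,
                        n_sites = 15, ...) {
  simulate_study(sim_config(n_species = n_species,
                            n_populations = n_populations,
                            n_sites = n_sites, seed = seed, ...))
}

# long-format population tibble from year/abundance vectors
make_series <- function(years, abundance, id = "P1") {
  tibble::tibble(population_id = id, year = years, abundance = abundance)
}

# independent closed-form OLS slope oracle
ols_slope_oracle <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# a 6-taxon two-clade tree with a long stem between the clades
two_clade_tree <- function() {
  ape::read.tree(text = paste0(
    "(((a:1,b:1):1,c:2):10,((d:1,e:1):1,f:2):10);"))
}

# reduced specification matching the generator's non-zero effects
reduced_spec <- function() {
  fastslowpop:::new_model_spec(c("delta_t", "pc1", "cropland", "bare_soil",
                                 "pc1:cropland", "pc1:bare_soil",
                                 "delta_t:bare_soil"))
}

# betas for recovery studies: the generator's default pattern with effect
# sizes large enough to be estimable at n = 1000
recovery_beta <- function() {
  b <- default_beta()
  b["delta_t"] <- 0.3
  b["pc1"] <- 0.02
  b["cropland"] <- -2.5
  b["bare_soil"] <- 8
  b["pc1:cropland"] <- 1.9
  b["pc1:bare_soil"] <- 4
  b["delta_t:bare_soil"] <- -718
  b
}
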