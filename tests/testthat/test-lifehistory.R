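syn_table <- function() {
  tibble::tibble(
    raw_name = c("Falco_tinnunculus", "Falco_vespertinus",
                 "Buteo_vulgaris"),
    accepted = c("Falco_tinnunculus", "Falco_vespertinus", "Buteo_buteo"),
    class = "Aves", order = "Falconiformes",
    family = c("Falconidae", "Falconidae", "Accipitridae"))
}

test_that("taxonomy harmonization maps synonyms and reports the unmatched", {
  rec <- tibble::tibble(species = c("Falco_tinnunculus", "Buteo_vulgaris",
                                    "Unknown_species"),
                        longevity = c(15, 20, 5))
  out <- harmonize_taxonomy(rec, syn_table())
  expect_equal(out$species, c("Falco_tinnunculus", "Buteo_buteo"))
  expect_equal(out$family, c("Falconidae", "Accipitridae"))
  expect_equal(attr(out, "unmatched"), "Unknown_species")
  # conflicting mapping rejected
  bad <- dplyr::bind_rows(syn_table(),
                          dplyr::mutate(syn_table()[3, ],
                                        accepted = "Buteo_other"))
  expect_error(harmonize_taxonomy(rec, bad), "conflicting")
})

test_that("trait aggregation is a geometric mean and ignores source order", {
  rec <- tibble::tibble(species = "A", source = c("x", "y"),
                        longevity = c(2, 8), body_mass = c(100, NA))
  out <- aggregate_traits(rec)
  expect_equal(out$longevity, 4)
  expect_equal(out$body_mass, 100) # single value is itself
  rec3 <- tibble::tibble(species = "A", longevity = c(5, 5, 5))
  expect_equal(aggregate_traits(rec3)$longevity, 5)
  # permutation invariance across sources
  shuffled <- rec[c(2, 1), ]
  expect_equal(aggregate_traits(shuffled)$longevity, out$longevity)
  expect_error(aggregate_traits(tibble::tibble(species = "A",
                                               longevity = -1)),
               "non-positive")
})

test_that("eigenvector 1 separates two distant clades by sign", {
  tree <- two_clade_tree()
  ev <- phylo_eigenvectors(tree, n = 4)
  clade1 <- ev$ev1[match(c("a", "b", "c"), ev$species)]
  clade2 <- ev$ev1[match(c("d", "e", "f"), ev$species)]
  expect_true(all(sign(clade1) == sign(clade1[1])))
  expect_true(all(sign(clade2) == -sign(clade1[1])))
  # oracle: principal-coordinate analysis from ape on the same distances
  ref <- ape::pcoa(as.dist(ape::cophenetic.phylo(tree)))
  expect_equal(abs(ev$ev1), unname(abs(ref$vectors[ev$species, 1])),
               tolerance = 1e-8)
  expect_equal(abs(ev$ev2), unname(abs(ref$vectors[ev$species, 2])),
               tolerance = 1e-8)
})

test_that("species absent from the tree are flagged with undefined eigenvectors", {
  st <- simulate_traits(sim_config(n_species = 15, seed = 2))
  ev <- phylo_eigenvectors(st$tree, species = c(st$traits$species[1:3],
                                                "Species_999"))
  expect_equal(ev$in_tree, c(TRUE, TRUE, TRUE, FALSE))
  expect_true(all(is.na(ev$ev1[4])))
  expect_error(phylo_eigenvectors(ape::rtree(5), n = 10), "at least")
  lengthless <- ape::read.tree(text = "((a,b),(c,d));")
  expect_error(phylo_eigenvectors(lengthless, n = 2), "branch lengths")
})

test_that("imputation returns complete tables without touching observations", {
  sim <- simulate_traits(sim_config(n_species = 120, seed = 5,
                                    trait_missing_rate = 0.2))
  ev <- phylo_eigenvectors(sim$tree)
  out <- impute_traits(sim$traits, ev, seed = 1)
  traits <- c("longevity", "maturity", "reproductive_events", "offspring",
              "body_mass")
  expect_false(anyNA(out[traits]))
  for (tr in traits) {
    obs <- !is.na(sim$traits[[tr]])
    expect_identical(out[[tr]][obs], sim$traits[[tr]][obs])
    expect_identical(out[[paste0(tr, "_imputed")]], !obs)
  }
  # determinism under the recorded seed
  out2 <- impute_traits(sim$traits, ev, seed = 1)
  expect_identical(out[traits], out2[traits])
  # gap-free tables pass through unchanged
  full <- simulate_traits(sim_config(n_species = 20, seed = 6))$traits
  expect_equal(as.data.frame(impute_traits(full))[names(full)],
               as.data.frame(full))
})

test_that("random-forest imputation beats column medians on correlated traits", {
  sim <- simulate_traits(sim_config(n_species = 250, seed = 8,
                                    tradeoff_strength = 1.5,
                                    trait_noise = 0.2))
  truth <- sim$traits
  masked <- truth
  traits <- c("longevity", "maturity", "reproductive_events", "offspring",
              "body_mass")
  set.seed(99)
  for (tr in traits) {
    masked[[tr]][sample(250, 50)] <- NA # 20% per trait
  }
  ev <- phylo_eigenvectors(sim$tree)
  out <- impute_traits(masked, ev, seed = 3)
  nrmse <- function(pred, true, miss) {
    sqrt(mean((log(pred[miss]) - log(true[miss]))^2)) /
      sd(log(true[[1]])[miss] * 0 + log(true)[miss]) # per-trait scale
  }
  for (tr in traits) {
    miss <- is.na(masked[[tr]])
    err_rf <- sqrt(mean((log(out[[tr]][miss]) -
                           log(truth[[tr]][miss]))^2))
    med <- exp(median(log(masked[[tr]]), na.rm = TRUE))
    err_med <- sqrt(mean((log(med) - log(truth[[tr]][miss]))^2))
    expect_lt(err_rf, err_med)
  }
})

test_that("a species with no traits but valid taxonomy is fully imputed", {
  sim <- simulate_traits(sim_config(n_species = 60, seed = 9))
  traits <- sim$traits
  traits[1, c("longevity", "maturity", "reproductive_events", "offspring",
              "body_mass")] <- NA_real_
  out <- impute_traits(traits, phylo_eigenvectors(sim$tree), seed = 2)
  expect_false(anyNA(out[1, c("longevity", "body_mass")]))
  expect_true(out$longevity_imputed[1])
  # but a trait missing everywhere is rejected
  traits2 <- sim$traits
  traits2$offspring <- NA_real_
  expect_error(impute_traits(traits2), "entirely missing")
})

test_that("mass adjustment removes allometry exactly in the noise-free case", {
  sim <- simulate_traits(sim_config(n_species = 40, seed = 12,
                                    tradeoff_strength = 0,
                                    trait_noise = 0))
  res <- mass_adjust(sim$traits)
  for (tr in c("longevity", "maturity", "reproductive_events",
               "offspring")) {
    expect_lt(max(abs(res[[tr]])), 1e-6)
  }
})

test_that("adjusted traits are uncorrelated with log mass", {
  sim <- simulate_traits(sim_config(n_species = 200, seed = 14))
  res <- mass_adjust(sim$traits)
  lmass <- log(sim$traits$body_mass)
  for (tr in c("longevity", "offspring")) {
    # conditional residuals: orthogonality holds within group structure;
    # marginal correlation with mass must be near zero
    expect_lt(abs(cor(res[[tr]], lmass)), 0.1)
  }
  # noise-free allometry with no grouping: exact orthogonality
  n <- 100
  lm0 <- rnorm(n, 5, 2)
  flat <- tibble::tibble(
    species = paste0("s", 1:n),
    longevity = exp(0.5 + 0.2 * lm0 + rnorm(n, sd = 0.3)),
    maturity = exp(-1 + 0.25 * lm0 + rnorm(n, sd = 0.3)),
    reproductive_events = exp(0.5 - 0.1 * lm0 + rnorm(n, sd = 0.3)),
    offspring = exp(1 - 0.1 * lm0 + rnorm(n, sd = 0.3)),
    body_mass = exp(lm0))
  res0 <- mass_adjust(flat)
  for (tr in c("longevity", "maturity", "reproductive_events",
               "offspring")) {
    expect_lt(abs(cor(res0[[tr]], lm0)), 1e-6)
  }
})

test_that("a constant family offset does not reorder residuals within family", {
  sim <- simulate_traits(sim_config(n_species = 120, seed = 16))
  res1 <- mass_adjust(sim$traits)
  shifted <- sim$traits
  fam <- shifted$family == shifted$family[1]
  shifted$longevity[fam] <- shifted$longevity[fam] * exp(1)
  res2 <- mass_adjust(shifted)
  r1 <- res1$longevity[fam]
  r2 <- res2$longevity[fam]
  expect_equal(cor(r1, r2, method = "spearman"), 1, tolerance = 1e-6)
})

test_that("the PCA is oriented fast-positive with normalized variance", {
  sim <- simulate_traits(sim_config(n_species = 300, seed = 18,
                                    tradeoff_strength = 1.5,
                                    trait_noise = 0.15))
  pca <- fast_slow_pca(mass_adjust(sim$traits))
  expect_equal(sum(pca$variance_explained), 1, tolerance = 1e-12)
  expect_true(all(diff(pca$variance_explained) <= 1e-12))
  # dominant first axis under a strong latent trade-off
  expect_gt(pca$variance_explained[1], 0.5)
  # orientation: fecundity loads positive, ageing negative
  expect_gt(pca$loadings["offspring", 1], 0)
  expect_gt(pca$loadings["reproductive_events", 1], 0)
  expect_lt(pca$loadings["longevity", 1], 0)
  expect_lt(pca$loadings["maturity", 1], 0)
  # scores centered and orthogonal across axes
  sc <- as.matrix(pca$scores[paste0("pc", 1:4)])
  expect_lt(max(abs(colMeans(sc))), 1e-10)
  cv <- cov(sc)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-10)
  expect_error(
    fast_slow_pca(tibble::tibble(species = letters[1:5],
                                 longevity = 1,
                                 maturity = rnorm(5),
                                 reproductive_events = rnorm(5),
                                 offspring = rnorm(5))),
    "constant")
})

test_that("mirroring the latent axis flips score signs only", {
  sim <- simulate_traits(sim_config(n_species = 100, seed = 20,
                                    tradeoff_strength = 1.5,
                                    trait_noise = 0.1))
  pca <- fast_slow_pca(mass_adjust(sim$traits))
  mirrored <- sim$traits
  # swapping the ageing and fecundity trait roles mirrors the axis
  mirrored[c("longevity", "maturity", "reproductive_events",
             "offspring")] <-
    sim$traits[c("reproductive_events", "offspring", "longevity",
                 "maturity")]
  pca2 <- fast_slow_pca(mass_adjust(mirrored))
  expect_equal(abs(pca2$scores$pc1), abs(pca$scores$pc1),
               tolerance = 1e-6)
  expect_gt(cor(pca2$scores$pc1, -pca$scores$pc1), 0.999)
})

test_that("PC1 recovers a strong latent fast-slow axis", {
  cfg <- sim_config(n_species = 500, seed = 22, tradeoff_strength = 1.5,
                    trait_noise = 0.1)
  sim <- simulate_traits(cfg)
  pca <- fast_slow_pca(mass_adjust(sim$traits))
  truth <- simulate_traits(cfg)$truth
  rho <- cor(pca$scores$pc1, truth$latent_fastslow, method = "spearman")
  expect_gt(rho, 0.9)
})

test_that("the full trait pipeline runs from records to scores", {
  sim <- simulate_traits(sim_config(n_species = 80, seed = 24,
                                    trait_missing_rate = 0.15))
  pca <- life_history_scores(sim$traits, tree = sim$tree, seed = 4)
  expect_s3_class(pca, "life_history_pca")
  expect_equal(nrow(pca$scores), 80)
  expect_false(anyNA(pca$scores$pc1))
  expect_equal(nrow(glance(pca)), 4)
  expect_identical(tidy(pca), pca$scores)
})
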