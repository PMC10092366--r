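test_that("model frame assembly joins, drops incomplete rows, and reports", {
  lam <- tibble::tibble(population_id = c("P1", "P2", "P3"),
                        species = c("A", "A", "B"),
                        site = c("S1", "S2", "S1"),
                        mean_lambda = c(0.1, -0.1, 0))
  env <- tibble::tibble(population_id = c("P1", "P2", "P3"),
                        delta_t = c(0.01, 0.02, NA),
                        cropland = c(0.001, -0.001, 0))
  scores <- tibble::tibble(species = c("A", "B"), pc1 = c(1, -1))
  frame <- assemble_model_frame(lam, env, scores)
  expect_equal(nrow(frame), 2)
  expect_named(attr(frame, "dropped"), c("population_id", "reason"))
  expect_true("P3" %in% attr(frame, "dropped")$population_id)
  expect_equal(names(frame)[1:4],
               c("population_id", "mean_lambda", "delta_t", "pc1"))
  # complete overlap preserves rows; disjoint keys give an empty frame
  env_ok <- dplyr::mutate(env, delta_t = c(0.01, 0.02, 0.03))
  expect_equal(nrow(assemble_model_frame(lam, env_ok, scores)), 3)
  env_disjoint <- dplyr::mutate(env_ok,
                                population_id = c("X1", "X2", "X3"))
  empty <- assemble_model_frame(lam, env_disjoint, scores)
  expect_equal(nrow(empty), 0)
  expect_equal(nrow(attr(empty, "dropped")), 6)
  # missing pc1 drops the population
  scores_na <- tibble::tibble(species = c("A", "B"), pc1 = c(1, NA))
  f2 <- assemble_model_frame(lam, env_ok, scores_na)
  expect_false("P3" %in% f2$population_id)
  expect_error(assemble_model_frame(lam[c(1, 1), ], env, scores),
               "duplicate")
})

test_that("the full specification has the right combinatorial structure", {
  frame <- simulate_model_frame(sim_config(n_populations = 50,
                                           n_sites = 20, n_species = 10,
                                           seed = 1))
  spec <- build_full_spec(frame)
  expect_equal(length(spec$fixed), 35) # 10 main + 17 two-way + 8 three-way
  n_way <- vapply(spec$fixed,
                  function(t) length(strsplit(t, ":")[[1]]), integer(1))
  expect_equal(as.integer(table(n_way)), c(10L, 17L, 8L))
  # N = 1 cover class: 3 + 3 + 1 = 7 terms
  spec1 <- build_full_spec(frame[c("population_id", "mean_lambda",
                                   "delta_t", "pc1", "cropland",
                                   "species", "location")])
  expect_equal(length(spec1$fixed), 7)
  # no cover x cover interactions anywhere
  for (term in spec$fixed) {
    vars <- strsplit(term, ":")[[1]]
    expect_lte(sum(vars %in% cover_classes()), 1)
  }
  # marginality: building a spec with a missing parent fails
  expect_error(fastslowpop:::new_model_spec(c("pc1", "pc1:cropland")),
               "marginality")
})

test_that("AICc follows the small-sample correction formula", {
  # k = 3, n = 10: correction term 2*3*4/(10-3-1) = 4
  expect_equal(aicc(-5, n = 10, k = 3), 10 + 6 + 4)
  # converges to AIC as n grows
  expect_equal(aicc(-5, n = 1e9, k = 3), 16, tolerance = 1e-6)
  # strictly decreasing in n at fixed k and logLik
  ns <- c(10, 20, 50, 100, 1000)
  vals <- vapply(ns, function(n) aicc(-5, n = n, k = 3), numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_error(aicc(-5, n = 4, k = 3), "n > k")
})

test_that("with zero random-effect variance the fit matches OLS", {
  cfg <- sim_config(n_populations = 400, n_sites = 100, n_species = 80,
                    sigma_species = 0, sigma_site = 0, seed = 2,
                    beta = recovery_beta())
  frame <- simulate_model_frame(cfg)
  fit <- fit_lmm(frame, reduced_spec(), method = "REML")
  ols <- lm(mean_lambda ~ delta_t + pc1 + cropland + bare_soil +
              pc1:cropland + pc1:bare_soil + delta_t:bare_soil,
            data = frame)
  expect_lt(fit$varcomp[["species"]], 0.05 * fit$varcomp[["residual"]])
  expect_lt(fit$varcomp[["location"]], 0.05 * fit$varcomp[["residual"]])
  expect_equal(unname(lme4::fixef(fit$fit)), unname(coef(ols)),
               tolerance = 0.05)
})

test_that("duplicating every row shrinks standard errors, not estimates", {
  # with negligible random-effect variance the information doubles, so
  # estimates are stable and every standard error shrinks
  cfg <- sim_config(n_populations = 300, n_sites = 80, n_species = 60,
                    sigma_species = 0, sigma_site = 0,
                    seed = 3, beta = recovery_beta())
  frame <- simulate_model_frame(cfg)
  fit1 <- fit_lmm(frame, reduced_spec())
  copy <- dplyr::mutate(frame,
                        species = paste0(species, "_b"),
                        location = paste0(location, "_b"))
  doubled <- dplyr::bind_rows(frame, copy)
  doubled$population_id <- sprintf("P%04d", seq_len(nrow(doubled)))
  fit2 <- fit_lmm(doubled, reduced_spec())
  expect_equal(fit2$wald$estimate, fit1$wald$estimate, tolerance = 0.05)
  expect_true(all(fit2$wald$std_error < fit1$wald$std_error))
})

test_that("type-III Wald statistics match the car oracle", {
  skip_if_not_installed("car")
  cfg <- sim_config(n_populations = 300, n_sites = 80, n_species = 60,
                    seed = 4, beta = recovery_beta())
  frame <- simulate_model_frame(cfg)
  fit <- fit_lmm(frame, reduced_spec())
  ours <- fit$wald
  ref <- car::Anova(fit$fit, type = 3, test.statistic = "Chisq")
  ref_terms <- rownames(ref)
  for (i in seq_along(ref_terms)) {
    j <- match(ref_terms[i], ours$term)
    expect_equal(ours$chisq[j], ref$Chisq[i], tolerance = 1e-6)
    expect_equal(ours$p_value[j], ref$`Pr(>Chisq)`[i], tolerance = 1e-6)
  }
  # single-df chi-square equals the squared z statistic
  expect_equal(ours$chisq,
               (ours$estimate / ours$std_error)^2, tolerance = 1e-10)
})

test_that("pseudo-R2 behaves at the boundaries and orders correctly", {
  cfg <- sim_config(n_populations = 300, n_sites = 80, n_species = 60,
                    seed = 5, beta = recovery_beta())
  frame <- simulate_model_frame(cfg)
  fit <- fit_lmm(frame, reduced_spec())
  r2 <- pseudo_r2(fit)
  expect_gte(r2[["conditional"]], r2[["marginal"]])
  expect_true(all(r2 >= 0 & r2 <= 1))
  # intercept-only model with no random-effect variance: both near zero
  b0 <- default_beta(); b0[] <- 0
  cfg0 <- sim_config(n_populations = 300, n_sites = 80, n_species = 60,
                     sigma_species = 0, sigma_site = 0, seed = 6,
                     beta = b0)
  frame0 <- simulate_model_frame(cfg0)
  fit0 <- fit_lmm(frame0, fastslowpop:::new_model_spec(character(0)))
  expect_equal(unname(fit0$pseudo_r2), c(0, 0), tolerance = 0.02)
})

test_that("pseudo-R2 recovers a known variance decomposition", {
  b0 <- default_beta(); b0[] <- 0
  # response = species + site + residual variance only (no fixed signal):
  # conditional R2 should approach (0.04+0.03^2... ) computed below
  cfg <- sim_config(n_populations = 2000, n_sites = 200, n_species = 150,
                    sigma_species = 0.06, sigma_site = 0.05,
                    sigma_resid = 0.08, seed = 7, beta = b0)
  frame <- simulate_model_frame(cfg)
  fit <- fit_lmm(frame, fastslowpop:::new_model_spec(character(0)))
  expected_cond <- (0.06^2 + 0.05^2) / (0.06^2 + 0.05^2 + 0.08^2)
  expect_equal(fit$pseudo_r2[["conditional"]], expected_cond,
               tolerance = 0.12)
  expect_lt(fit$pseudo_r2[["marginal"]], 0.02)
})

test_that("backward AICc elimination respects marginality and the path is logged", {
  cfg <- sim_config(n_populations = 300, n_sites = 100, n_species = 60,
                    seed = 8, beta = recovery_beta())
  frame <- simulate_model_frame(cfg)
  frame <- frame[c("population_id", "mean_lambda", "delta_t", "pc1",
                   "cropland", "bare_soil", "species", "location")]
  sw <- stepwise_aicc(frame)
  # final spec is a subset of the full spec and still hierarchical
  full <- build_full_spec(frame)
  expect_true(all(sw$spec$fixed %in% full$fixed))
  expect_silent(fastslowpop:::check_marginality(sw$spec))
  # path: AICc decreases monotonically after step 0
  expect_true(all(diff(sw$path$aicc) < 0))
  # the final fit is REML
  expect_equal(sw$fit$method, "REML")
  expect_s3_class(tidy(sw), "tbl_df")
})

test_that("a full model already at minimal AICc is returned unchanged", {
  cfg <- sim_config(n_populations = 500, n_sites = 120, n_species = 80,
                    seed = 9, beta = recovery_beta(), sigma_resid = 0.02)
  frame <- simulate_model_frame(cfg)
  frame <- frame[c("population_id", "mean_lambda", "delta_t", "pc1",
                   "bare_soil", "species", "location")]
  # strong effects on every term of this one-class spec
  sw <- stepwise_aicc(frame)
  expect_true(all(c("delta_t", "bare_soil", "delta_t:bare_soil") %in%
                    sw$spec$fixed))
})

test_that("tidy and glance return the documented columns", {
  cfg <- sim_config(n_populations = 200, n_sites = 50, n_species = 40,
                    seed = 10)
  frame <- simulate_model_frame(cfg)
  fit <- fit_lmm(frame, reduced_spec())
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "df",
                     "p.value"))
  expect_equal(nrow(td), 8) # intercept + 7 terms
  gl <- glance(fit)
  expect_equal(gl$nobs, 200)
  expect_true(gl$r2_conditional >= gl$r2_marginal)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
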