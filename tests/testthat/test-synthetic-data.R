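# The generator must plant every property the pipeline is built to handle,
# with known ground truth and full seed determinism.

test_that("truth generation is deterministic and satisfies its invariants", {
  t1 <- generate_truth(k = 5, p_core = 39, seed = 7)
  t2 <- generate_truth(k = 5, p_core = 39, seed = 7)
  expect_identical(t1, t2)
  t3 <- generate_truth(k = 2, p_core = 6, seed = 3)
  expect_identical(t3, generate_truth(k = 2, p_core = 6, seed = 3))

  phi <- t1$factor_corr
  expect_equal(phi, t(phi))
  expect_equal(diag(phi), rep(1, 5))
  expect_true(all(abs(phi[upper.tri(phi)]) <= 0.4))
  expect_gt(min(eigen(phi, symmetric = TRUE)$values), 0)

  # communality + uniqueness = 1 under the oblique quadratic form
  h2 <- diag(t1$loadings %*% phi %*% t(t1$loadings))
  expect_equal(h2 + t1$uniquenesses, rep(1, 39), tolerance = 1e-9)
  expect_true(all(t1$uniquenesses > 0 & t1$uniquenesses <= 1))

  # simple structure: one primary loading >= 0.5 per variable, cross
  # loadings below 0.2, and at least 3 markers per factor
  primary <- apply(abs(t1$loadings), 1, which.max)
  expect_true(all(t1$loadings[cbind(1:39, primary)] >= 0.5))
  cross <- t1$loadings
  cross[cbind(1:39, primary)] <- 0
  expect_true(all(abs(cross) <= 0.2))
  expect_true(all(table(factor(primary, levels = 1:5)) >= 3))

  expect_equal(generate_truth(k = 1, p_core = 3, seed = 1)$factor_corr,
               matrix(1, 1, 1))
})

test_that("tract tables plant complements, low-CV columns and exact strata", {
  truth <- generate_truth(k = 2, p_core = 8, seed = 3, missing_rate = 0)
  with_strata <- generate_tract_table(truth, n_tracts = 300, n_states = 3,
                                      counties_per_state = 2, seed = 11,
                                      n_strata = 1, strata_size = 4)
  no_strata <- generate_tract_table(truth, n_tracts = 300, n_states = 3,
                                    counties_per_state = 2, seed = 11,
                                    n_strata = 0)
  expect_false(anyNA(with_strata$tracts))

  # complements are exact: x + (1 - x) = 1
  comps <- with_strata$catalog[with_strata$catalog$role == "complement", ]
  expect_gt(nrow(comps), 0)
  for (i in seq_len(nrow(comps))) {
    expect_equal(with_strata$tracts[[comps$variable[i]]] +
                   with_strata$tracts[[comps$complement_of[i]]],
                 rep(1, 300))
  }

  # planted low-CV column really is below the filter threshold
  lv <- with_strata$catalog$variable[with_strata$catalog$role == "low_cv"]
  st <- variable_stats(with_strata$tracts[lv])
  expect_true(all(st$cv < 0.06))

  # strata columns sum exactly to the parent they replaced (the parent is
  # visible in the run of the same seed with no strata planted)
  strata <- with_strata$catalog[with_strata$catalog$role == "stratum", ]
  parent <- unique(strata$parent)
  expect_length(parent, 1)
  expect_false(parent %in% names(with_strata$tracts))
  expect_equal(rowSums(with_strata$tracts[strata$variable]),
               no_strata$tracts[[parent]], tolerance = 1e-12)

  # the catalog covers every data column
  expect_setequal(with_strata$catalog$variable,
                  setdiff(names(with_strata$tracts), "GEOID"))
})

test_that("missingness lands at the configured MCAR rate", {
  truth <- generate_truth(k = 5, p_core = 39, seed = 5,
                          missing_rate = 0.0016)
  sim <- generate_tract_table(truth, n_tracts = 5000, n_states = 10,
                              counties_per_state = 2, seed = 9)
  frac <- mean(is.na(sim$tracts[setdiff(names(sim$tracts), "GEOID")]))
  expect_lt(abs(frac - 0.0016), 5e-4)

  none <- generate_truth(k = 2, p_core = 6, seed = 5, missing_rate = 0)
  sim0 <- generate_tract_table(none, 100, 2, 2, seed = 9)
  expect_false(anyNA(sim0$tracts))
})

test_that("identical seeds reproduce identical tables and geography", {
  truth <- generate_truth(k = 2, p_core = 6, seed = 2)
  a <- generate_tract_table(truth, 200, 4, 2, seed = 13)
  b <- generate_tract_table(truth, 200, 4, 2, seed = 13)
  expect_identical(a, b)

  g <- a$geography
  expect_false(any(duplicated(g$tract_id)))
  expect_true(all(nchar(g$tract_id) == 11))
  expect_identical(substr(g$tract_id, 1, 2), g$state_code)
  expect_identical(substr(g$tract_id, 3, 5), g$county_code)
})

test_that("core-column correlations converge to the generating covariance", {
  truth <- generate_truth(k = 2, p_core = 8, seed = 4,
                          transforms = "identity", missing_rate = 0)
  sim <- generate_tract_table(truth, n_tracts = 20000, n_states = 4,
                              counties_per_state = 2, seed = 21,
                              n_complements = 0, n_low_cv = 0, n_strata = 0)
  emp <- cor(as.matrix(sim$tracts[setdiff(names(sim$tracts), "GEOID")]))
  pop <- truth$loadings %*% truth$factor_corr %*% t(truth$loadings) +
    diag(truth$uniquenesses)
  expect_lt(max(abs(emp - pop)), 0.05)
})

test_that("outcome generation follows the configured logit-scale model", {
  truth <- generate_truth(k = 2, p_core = 6, seed = 6)
  truth$outcome_betas <- c(0, 0)
  truth$confounder_betas[] <- 0
  truth$state_sd <- truth$county_sd <- truth$noise_sd <- 0
  sim <- generate_tract_table(truth, 200, 4, 2, seed = 31)
  out <- generate_outcome(truth, sim$factor_draws, sim$geography, seed = 32)
  expect_equal(out$prevalence, rep(plogis(truth$intercept), 200))
  expect_true(all(out$prevalence > 0 & out$prevalence < 1))

  # a single strong factor effect dominates the logit of prevalence
  truth$outcome_betas <- c(-1, 0)
  big <- generate_tract_table(truth, 10000, 4, 2, seed = 33)
  out2 <- generate_outcome(truth, big$factor_draws, big$geography, seed = 34)
  expect_lte(cor(big$factor_draws[, 1], qlogis(out2$prevalence)), -0.99)

  # state random intercepts carry the configured variance
  truth$outcome_betas <- c(0, 0)
  truth$state_sd <- 0.5
  geo <- generate_tract_table(truth, 10000, 50, 4, seed = 35)
  out3 <- generate_outcome(truth, geo$factor_draws, geo$geography, seed = 36)
  state_means <- tapply(qlogis(out3$prevalence), out3$state, mean)
  expect_lt(abs(var(state_means) - 0.25) / 0.25, 0.2)

  expect_error(generate_outcome(truth, big$factor_draws[1:10, ],
                                big$geography, seed = 1),
               "rows")
})
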