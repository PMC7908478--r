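# Per-state smoothing splines and the mixed-model variance decomposition.

fake_geo <- function(n, states, tracts_per_state = n / states) {
  st <- sprintf("%02d", rep(seq_len(states), each = tracts_per_state))
  data.frame(
    GEOID = paste0(st, "001", sprintf("%06d", seq_len(n))),
    state = st, county = "001", stringsAsFactors = FALSE
  )
}

test_that("noise-free polynomial signals are fit exactly by the splines", {
  set.seed(30)
  n <- 180
  geo <- fake_geo(n, states = 3)
  x <- rnorm(n)
  scores <- data.frame(GEOID = geo$GEOID, factor_1 = x)
  out <- cbind(geo, prevalence = 0.3 + 0.05 * x + 0.01 * x^3)
  sp <- state_spline_r2(scores, out)
  expect_true(all(sp$by_state$r2 > 1 - 1e-6))
  expect_equal(sp$summary$n_states, 3)

  # pure noise yields near-zero median R^2
  set.seed(31)
  geo2 <- fake_geo(1000, states = 5)
  scores2 <- data.frame(GEOID = geo2$GEOID, factor_1 = rnorm(1000))
  out2 <- cbind(geo2, prevalence = runif(1000, 0.1, 0.3))
  sp2 <- state_spline_r2(scores2, out2)
  expect_lt(sp2$summary$median_r2, 0.05)

  # spline R^2 on a linear signal is at least the linear-regression R^2
  set.seed(32)
  out3 <- cbind(geo, prevalence = 0.3 + 0.02 * x + rnorm(n, sd = 0.01))
  sp3 <- state_spline_r2(scores, out3)
  for (st in unique(geo$state)) {
    idx <- geo$state == st
    lin <- summary(lm(out3$prevalence[idx] ~ x[idx]))$r.squared
    expect_gte(sp3$by_state$r2[sp3$by_state$state == st], lin - 1e-6)
  }
})

test_that("stronger factor effects earn higher median spline R^2", {
  set.seed(33)
  n <- 2000
  geo <- fake_geo(n, states = 10)
  f <- matrix(rnorm(n * 2), ncol = 2)
  scores <- data.frame(GEOID = geo$GEOID, factor_1 = f[, 1],
                       factor_4 = f[, 2])
  lp <- -2 - 0.8 * f[, 1] + 0.1 * f[, 2] + rnorm(n, sd = 0.3)
  out <- cbind(geo, prevalence = plogis(lp))
  sp <- state_spline_r2(scores, out)
  med <- setNames(sp$summary$median_r2, sp$summary$factor)
  expect_gt(med["factor_1"], med["factor_4"])

  # states below the size filter are excluded with a reason
  small <- rbind(out[1:5, ])
  small$state <- "99"
  small$GEOID <- paste0("99001", sprintf("%06d", 1:5))
  sp2 <- state_spline_r2(rbind(scores,
                               data.frame(GEOID = small$GEOID,
                                          factor_1 = rnorm(5),
                                          factor_4 = rnorm(5))),
                         rbind(out, small))
  expect_true(any(grepl("fewer than", sp2$excluded$reason)))
  expect_error(state_spline_r2(scores[1:5, ], out[1:5, ]),
               "size filter")
})

test_that("the mixed model recovers planted variance components", {
  truth <- generate_truth(k = 2, p_core = 6, seed = 40)
  truth$outcome_betas <- c(0, 0)
  truth$confounder_betas[] <- 0
  truth$state_sd <- 0.5
  truth$county_sd <- 0.2
  truth$noise_sd <- 0.3
  sim <- generate_tract_table(truth, n_tracts = 10000, n_states = 50,
                              counties_per_state = 4, seed = 41)
  out <- generate_outcome(truth, sim$factor_draws, sim$geography, seed = 42)
  # fit on the logit scale, where the generating model is exactly linear
  d <- data.frame(prevalence = qlogis(out$prevalence), state = out$state,
                  county = out$county)
  m <- fit_lme(d)
  expect_lt(abs(m$vc[["state"]] - 0.25) / 0.25, 0.3)
  expect_lt(abs(m$vc[["county"]] - 0.04) / 0.04, 0.3)
  expect_lt(abs(m$vc[["residual"]] - 0.09) / 0.09, 0.3)
  expect_equal(m$v_model, sum(m$vc))

  # a pure-noise fixed effect barely changes the model variance
  set.seed(43)
  d$junk <- rnorm(nrow(d))
  m2 <- fit_lme(d, "junk")
  expect_lt(abs(m2$v_model - m$v_model) / m$v_model, 0.01)

  expect_error(fit_lme(d[d$state == "01", ]), "2 states")
})

test_that("R2, unique variance, f2 and labels follow their definitions", {
  expect_equal(r2_from_variances(10, 10), 0)
  expect_equal(r2_from_variances(10, 2), 0.8)
  expect_equal(r2_from_variances(7.3, 0), 1)
  expect_error(r2_from_variances(0, 1))

  expect_equal(unique_variance(0.9037, 0.8376), 0.0661)
  expect_equal(unique_variance(0.8376, 0.8376), 0)
  expect_equal(unique_variance(0.42, 0.42), 0)

  expect_equal(cohens_f2(0.8587, 0.8376), (0.8587 - 0.8376) / (1 - 0.8587))
  expect_equal(round(cohens_f2(0.8587, 0.8376), 3), 0.149)
  expect_equal(cohens_f2(0.8376, 0.8376), 0)
  expect_equal(cohens_f2(0.5, 0), 1)
  expect_error(cohens_f2(1, 0.5))

  # step function with >= boundaries at 0.02 / 0.15 / 0.35
  expect_equal(classify_effect(c(0, 0.019999, 0.02, 0.15, 0.35, 0.6861)),
               c("none", "none", "small", "medium", "large", "large"))
})

test_that("adding fixed effects never decreases R2 under ML", {
  fx <- reference_fixture()
  out <- fx$study$outcome
  merged <- merge(fx$scores, out, by = "GEOID")
  v_null <- fit_lme(merged)$v_model
  terms <- c("conf_age", "conf_poverty", "factor_1", "factor_2")
  r2_prev <- 0
  for (i in seq_along(terms)) {
    r2 <- r2_from_variances(v_null,
                            suppressWarnings(
                              fit_lme(merged, terms[seq_len(i)])$v_model))
    expect_gte(r2, r2_prev - 1e-6)
    r2_prev <- r2
  }
})

test_that("decomposition isolates signal and reports null factors as null", {
  # outcome with zero factor effects: no factor explains unique variance
  truth <- generate_truth(k = 3, p_core = 9, seed = 44)
  truth$outcome_betas <- c(0, 0, 0)
  sim <- generate_tract_table(truth, n_tracts = 10000, n_states = 20,
                              counties_per_state = 4, seed = 45)
  out <- generate_outcome(truth, sim$factor_draws, sim$geography, seed = 46)
  scores <- data.frame(GEOID = sim$geography$tract_id,
                       factor_1 = sim$factor_draws[, 1],
                       factor_2 = sim$factor_draws[, 2],
                       factor_3 = sim$factor_draws[, 3])
  dec <- suppressWarnings(
    decomposition_report(out, scores, names(truth$confounder_betas)))
  per_factor <- dec[grepl("^Ma,[0-9]+$", dec$model), ]
  expect_true(all(per_factor$unique_variance < 0.01))

  # only factor 1 drives the outcome, confounders are pure noise:
  # f2 concentrates on factor 1
  truth2 <- generate_truth(k = 3, p_core = 9, seed = 47)
  truth2$outcome_betas <- c(1, 0, 0)
  truth2$conf_loadings[] <- 0
  sim2 <- generate_tract_table(truth2, n_tracts = 8000, n_states = 20,
                               counties_per_state = 4, seed = 48)
  out2 <- generate_outcome(truth2, sim2$factor_draws, sim2$geography,
                           seed = 49)
  scores2 <- data.frame(GEOID = sim2$geography$tract_id,
                        factor_1 = sim2$factor_draws[, 1],
                        factor_2 = sim2$factor_draws[, 2],
                        factor_3 = sim2$factor_draws[, 3])
  dec2 <- suppressWarnings(
    decomposition_report(out2, scores2, names(truth2$confounder_betas)))
  f2 <- setNames(dec2$f2, dec2$model)
  expect_gte(f2[["Ma,1"]], 5 * max(f2[["Ma,2"]], f2[["Ma,3"]]))
})

test_that("confounders anchored on a factor attenuate its f2, not its R2", {
  # the confounders are noisy images of factor 2 only, and they also drive
  # the outcome: bivariately factor 2 dominates, but after adjustment its
  # unique contribution drops below factor 1's - the ordering flips
  truth <- generate_truth(k = 2, p_core = 6, seed = 50)
  truth$outcome_betas <- c(0.6, 0.3)
  truth$conf_loadings[] <- 0
  truth$conf_loadings[, 2] <- c(1, 1, 1, 1, 1)
  sim <- generate_tract_table(truth, n_tracts = 8000, n_states = 20,
                              counties_per_state = 4, seed = 51)
  out <- generate_outcome(truth, sim$factor_draws, sim$geography, seed = 52)
  scores <- data.frame(GEOID = sim$geography$tract_id,
                       factor_1 = sim$factor_draws[, 1],
                       factor_2 = sim$factor_draws[, 2])
  sp <- state_spline_r2(scores, out)
  med <- setNames(sp$summary$median_r2, sp$summary$factor)
  dec <- suppressWarnings(
    decomposition_report(out, scores, names(truth$confounder_betas)))
  f2 <- setNames(dec$f2, dec$model)
  # bivariately the confounded factor ranks first ...
  expect_gt(med[["factor_2"]], med[["factor_1"]])
  # ... but its adjusted effect falls below the clean factor's
  expect_lt(f2[["Ma,2"]], f2[["Ma,1"]])
})
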