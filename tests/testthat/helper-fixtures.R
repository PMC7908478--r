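# Shared fixtures, built lazily and cached for the whole test run.

.fixture_env <- new.env(parent = emptyenv())

# Reference study: 5 factors, 39 core variables, 5000 tracts, 20 states,
# run through selection -> transform -> imputation -> EFA -> scores, with
# the estimated factors aligned to the generating loadings by name-matched
# Tucker congruence.
reference_fixture <- function() {
  if (is.null(.fixture_env$fx)) {
    study <- simulate_study(seed = 1)
    selection <- select_features(study$tracts, study$catalog)
    specs <- fit_transforms(selection$table)
    transformed <- knn_impute(apply_transforms(selection$table, specs))
    model <- fit_efa(transformed, k = 5)
    scores <- compute_scores(model, transformed)
    core <- sprintf("v%02d", seq_len(study$truth$p_core))
    alignment <- align_factors(model$loadings[core, ], study$truth$loadings)
    .fixture_env$fx <- list(
      study = study, selection = selection, specs = specs,
      transformed = transformed, model = model, scores = scores,
      core = core, alignment = alignment
    )
  }
  .fixture_env$fx
}

# Scores for the estimated factors reordered/signed to match the truth
# factors (column i corresponds to generating factor i).
truth_aligned_scores <- function(fx) {
  m <- as.matrix(fx$scores[setdiff(names(fx$scores), "GEOID")])
  m[, fx$alignment$perm, drop = FALSE] %*% diag(fx$alignment$signs)
}

# Small crafted two-factor loading structure used across factor-model tests.
two_factor_structure <- function() {
  lambda <- rbind(c(0.8, 0), c(0.7, 0), c(0.6, 0),
                  c(0, 0.7), c(0, 0.8), c(0, 0.6))
  phi <- matrix(c(1, 0.3, 0.3, 1), 2)
  psi <- 1 - diag(lambda %*% phi %*% t(lambda))
  r <- lambda %*% phi %*% t(lambda) + diag(psi)
  dimnames(r) <- list(paste0("x", 1:6), paste0("x", 1:6))
  list(lambda = lambda, phi = phi, psi = psi, r = r)
}
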