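# Synthetic tract-table generator with a known oblique factor structure.
#
# The generator is the test bed for the whole pipeline: every property the
# real ACS-style input possesses (skewed marginals driven by latent factors,
# redundant complement columns, low-variability columns, strata subgroups,
# sparse MCAR missingness, a state/county/tract hierarchy, and an outcome
# driven by the factors plus random intercepts and confounders) is planted
# here with known ground truth.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so generator calls do not disturb the
#' caller's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Menu of marginal skewing maps applied to the latent-normal core columns,
# with their inverses. The squaring map is shifted by +5 so that it stays
# monotone (hence invertible) over the effective range of a standard normal.
.skew_maps <- list(
  exp_half = list(fwd = function(x) exp(x / 2),
                  inv = function(y) 2 * log(y)),
  square   = list(fwd = function(x) (x + 5)^2,
                  inv = function(y) sqrt(y) - 5),
  logistic = list(fwd = function(x) stats::plogis(x - 2),
                  inv = function(y) stats::qlogis(y) + 2),
  identity = list(fwd = identity, inv = identity)
)

.conf_names <- c("conf_age", "conf_sex_ratio", "conf_black",
                 "conf_hispanic", "conf_poverty")

# The 13 variable groups used to label the catalog.
.var_groups <- c(
  "age", "race/ethnicity", "nativity/citizenship", "mobility",
  "transportation", "household type", "marital status", "education",
  "disability", "income", "employment", "residential conditions", "tenure"
)

#' Generate the ground truth of a synthetic study
#'
#' Draws a simple-structure oblique factor model: each of `p_core` variables
#' has one primary loading of at least 0.5 and cross-loadings below 0.2 in
#' absolute value; factor correlations are drawn uniformly in \[-0.4, 0.4\]
#' (the range observed for oblique neighborhood factors in practice) subject
#' to positive definiteness. Uniquenesses complete each variable's variance to
#' one, so the latent core columns have unit variance before skewing.
#'
#' The truth object also fixes the outcome model: per-factor effects on the
#' logit of prevalence (`outcome_betas`), confounder effects
#' (`confounder_betas`), random-intercept standard deviations for state and
#' county, a residual SD, and a baseline prevalence. Defaults emulate a study
#' in which the first factor has a strong protective effect, the second none,
#' and the remainder moderate effects.
#'
#' @param k number of latent factors (>= 1).
#' @param p_core number of core observed variables (>= 3k so every factor has
#'   at least three markers).
#' @param seed integer seed; identical seeds give identical truths.
#' @param transforms character vector of skew-map names from
#'   `c("exp_half", "square", "logistic", "identity")`, recycled round-robin
#'   across the core variables.
#' @param missing_rate fraction of cells set missing completely at random
#'   (must be < 0.05).
#' @param max_tries resampling budget for a positive-definite factor
#'   correlation draw.
#' @return An object of class `neighbor_truth`: a list with elements
#'   `loadings`, `factor_corr`, `uniquenesses`, `marginal_transforms`,
#'   `outcome_betas`, `confounder_betas`, `conf_loadings`, `intercept`,
#'   `state_sd`, `county_sd`, `noise_sd`, `missing_rate`, `k`, `p_core`.
#' @examples
#' truth <- generate_truth(k = 2, p_core = 6, seed = 1)
#' truth$factor_corr
#' @export
generate_truth <- function(k, p_core, seed,
                           transforms = c("exp_half", "square",
                                          "logistic", "identity"),
                           missing_rate = 0.0016,
                           max_tries = 100L) {
  stopifnot(k >= 1, p_core >= 3 * k, missing_rate >= 0, missing_rate < 0.05)
  transforms <- match.arg(transforms, names(.skew_maps), several.ok = TRUE)
  with_seed(seed, {
    phi <- .draw_factor_corr(k, max_tries)
    lambda <- .draw_simple_structure(p_core, k, phi)
    h2 <- diag(lambda %*% phi %*% t(lambda))
    psi <- 1 - h2

    betas <- numeric(k)
    betas[1] <- -0.8
    if (k >= 3) betas[3:k] <- rep(c(0.30, 0.35, 0.45), length.out = k - 2)

    # Confounders are noisy linear images of the factors (R^2 = 0.5 with the
    # factor space), each anchored to one factor, so they genuinely confound.
    anchor <- c(min(3, k), min(2, k), min(4, k), min(5, k), 1)
    sgn <- c(1, 1, 1, 1, -1)
    conf_load <- matrix(0, nrow = 5, ncol = k,
                        dimnames = list(.conf_names, NULL))
    for (m in 1:5) conf_load[m, anchor[m]] <- sgn[m]

    truth <- list(
      k = as.integer(k), p_core = as.integer(p_core),
      loadings = lambda, factor_corr = phi, uniquenesses = psi,
      marginal_transforms = rep(transforms, length.out = p_core),
      outcome_betas = betas,
      confounder_betas = c(conf_age = 0.25, conf_sex_ratio = 0.10,
                           conf_black = 0.20, conf_hispanic = 0.20,
                           conf_poverty = 0.45),
      conf_loadings = conf_load,
      intercept = stats::qlogis(0.12),
      state_sd = 0.15, county_sd = 0.10, noise_sd = 0.15,
      missing_rate = missing_rate
    )
    class(truth) <- "neighbor_truth"
    truth
  })
}

#' @noRd
.draw_factor_corr <- function(k, max_tries) {
  if (k == 1) return(matrix(1, 1, 1))
  for (i in seq_len(max_tries)) {
    phi <- diag(k)
    off <- stats::runif(k * (k - 1) / 2, -0.4, 0.4)
    phi[upper.tri(phi)] <- off
    phi <- phi + t(phi) - diag(diag(phi))
    diag(phi) <- 1
    if (min(eigen(phi, symmetric = TRUE, only.values = TRUE)$values) > 0.05)
      return(phi)
  }
  stop("could not draw a positive-definite factor correlation matrix in ",
       max_tries, " tries; reduce k or widen the eigenvalue margin")
}

#' @noRd
.draw_simple_structure <- function(p, k, phi) {
  lambda <- matrix(stats::runif(p * k, -0.12, 0.12), nrow = p)
  primary <- rep(seq_len(k), length.out = p)
  lambda[cbind(seq_len(p), primary)] <- stats::runif(p, 0.55, 0.80)
  # keep communalities (via the oblique quadratic form) bounded by shrinking
  # cross-loadings only, so the primary loading stays >= 0.5
  for (i in seq_len(p)) {
    for (iter in 1:10) {
      h <- drop(lambda[i, ] %*% phi %*% lambda[i, ])
      if (h <= 0.9) break
      keep <- lambda[i, primary[i]]
      lambda[i, ] <- lambda[i, ] * 0.5
      lambda[i, primary[i]] <- keep
    }
  }
  lambda
}

#' @export
print.neighbor_truth <- function(x, ...) {
  cat("Synthetic study truth:", x$k, "factors,", x$p_core, "core variables\n")
  cat("  skew maps:", paste(unique(x$marginal_transforms), collapse = ", "),
      "\n")
  cat("  outcome betas:", paste(round(x$outcome_betas, 2), collapse = ", "),
      "\n")
  cat("  random-intercept SDs: state", x$state_sd, "/ county", x$county_sd,
      "; residual", x$noise_sd, "\n")
  invisible(x)
}

#' Generate a synthetic tract table, geography, and variable catalog
#'
#' Draws factor scores `F ~ MVN(0, Phi)` and unit-variance latent normals
#' `Lambda F' + E`, applies each variable's skew map, then plants the
#' structures the selection stage must handle: complement columns (`1 - x`),
#' near-constant low-CV columns, and strata groups (a core column split into
#' additive subgroup shares that sum to the parent). Missing cells are planted
#' completely at random at `truth$missing_rate`. Tracts are assigned
#' round-robin to counties within states and keyed by an 11-digit synthetic
#' GEOID (2-digit state, 3-digit county, 6-digit tract; no real FIPS codes
#' implied).
#'
#' @param truth a `neighbor_truth` object.
#' @param n_tracts number of tracts (>= n_states * counties_per_state).
#' @param n_states,counties_per_state balanced geography dimensions.
#' @param seed integer seed.
#' @param n_complements,n_low_cv,n_strata how many complement columns,
#'   low-variability columns, and strata splits to plant.
#' @param strata_size subgroup columns per planted stratum.
#' @return list with `tracts` (data.frame, GEOID + variable columns),
#'   `catalog` (variable metadata data.frame), `geography` (tract_id,
#'   state_code, county_code), and `factor_draws` (n x k matrix of the true
#'   latent scores, for recovery tests and outcome generation).
#' @export
generate_tract_table <- function(truth, n_tracts, n_states,
                                 counties_per_state, seed,
                                 n_complements = 3L, n_low_cv = 1L,
                                 n_strata = 1L, strata_size = 4L) {
  stopifnot(inherits(truth, "neighbor_truth"),
            n_tracts >= n_states * counties_per_state,
            strata_size >= 2)
  p <- truth$p_core
  k <- truth$k
  n_complements <- min(n_complements, p)
  with_seed(seed, {
    geography <- .make_geography(n_tracts, n_states, counties_per_state)

    f <- matrix(stats::rnorm(n_tracts * k), ncol = k) %*%
      chol(truth$factor_corr)
    e <- matrix(stats::rnorm(n_tracts * p), ncol = p) %*%
      diag(sqrt(truth$uniquenesses), p)
    latent <- f %*% t(truth$loadings) + e

    core_names <- sprintf("v%02d", seq_len(p))
    core <- matrix(NA_real_, n_tracts, p, dimnames = list(NULL, core_names))
    for (j in seq_len(p)) {
      core[, j] <- .skew_maps[[truth$marginal_transforms[j]]]$fwd(latent[, j])
    }
    if (any(apply(core, 2, stats::sd) == 0))
      stop("degenerate skew map produced a constant core column")

    catalog <- data.frame(
      variable = core_names,
      group = rep(.var_groups, length.out = p),
      role = "core",
      complement_of = NA_character_,
      parent = NA_character_,
      combine_rule = NA_character_,
      weights = NA_character_,
      stringsAsFactors = FALSE
    )

    tracts <- as.data.frame(core)

    # strata: split chosen core columns into additive subgroup shares; the
    # parent column leaves the table and is recoverable only by combination
    strata_parents <- character(0)
    if (n_strata > 0) {
      pref <- which(truth$marginal_transforms == "logistic")
      cand <- c(pref, setdiff(seq_len(p), pref))
      cand <- setdiff(cand, seq_len(n_complements)) # keep complements simple
      strata_parents <- core_names[cand[seq_len(min(n_strata, length(cand)))]]
      for (parent in strata_parents) {
        g <- matrix(stats::rgamma(n_tracts * strata_size, shape = 2),
                    ncol = strata_size)
        w <- g / rowSums(g)
        subs <- w * tracts[[parent]]
        sub_names <- paste0(parent, "_s", seq_len(strata_size))
        colnames(subs) <- sub_names
        pgroup <- catalog$group[catalog$variable == parent]
        tracts[[parent]] <- NULL
        catalog <- catalog[catalog$variable != parent, ]
        tracts <- cbind(tracts, as.data.frame(subs))
        catalog <- rbind(catalog, data.frame(
          variable = sub_names, group = pgroup, role = "stratum",
          complement_of = NA_character_, parent = parent,
          combine_rule = "sum", weights = NA_character_,
          stringsAsFactors = FALSE
        ))
      }
    }

    if (n_complements > 0) {
      for (j in seq_len(n_complements)) {
        nm <- core_names[j]
        cnm <- paste0(nm, "_c")
        tracts[[cnm]] <- 1 - tracts[[nm]]
        catalog <- rbind(catalog, data.frame(
          variable = cnm, group = catalog$group[catalog$variable == nm],
          role = "complement", complement_of = nm, parent = NA_character_,
          combine_rule = NA_character_, weights = NA_character_,
          stringsAsFactors = FALSE
        ))
      }
    }

    if (n_low_cv > 0) {
      for (j in seq_len(n_low_cv)) {
        nm <- sprintf("lowvar%d", j)
        tracts[[nm]] <- stats::rnorm(n_tracts, mean = 1, sd = 0.005)
        catalog <- rbind(catalog, data.frame(
          variable = nm, group = .var_groups[(j - 1) %% 13 + 1],
          role = "low_cv", complement_of = NA_character_,
          parent = NA_character_, combine_rule = NA_character_,
          weights = NA_character_, stringsAsFactors = FALSE
        ))
      }
    }

    if (truth$missing_rate > 0) {
      m <- as.matrix(tracts)
      holes <- stats::runif(length(m)) < truth$missing_rate
      m[holes] <- NA_real_
      tracts <- as.data.frame(m)
    }

    tracts <- cbind(GEOID = geography$tract_id, tracts,
                    stringsAsFactors = FALSE)
    rownames(catalog) <- NULL
    list(tracts = tracts, catalog = catalog, geography = geography,
         factor_draws = f)
  })
}

#' @noRd
.make_geography <- function(n_tracts, n_states, counties_per_state) {
  states <- sprintf("%02d", seq_len(n_states))
  counties <- sprintf("%03d", seq_len(counties_per_state))
  pairs <- expand.grid(county = counties, state = states,
                       stringsAsFactors = FALSE)[, c("state", "county")]
  idx <- rep(seq_len(nrow(pairs)), length.out = n_tracts)
  data.frame(
    tract_id = paste0(pairs$state[idx], pairs$county[idx],
                      sprintf("%06d", seq_len(n_tracts))),
    state_code = pairs$state[idx],
    county_code = pairs$county[idx],
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic tract-level outcome table
#'
#' Prevalence of poor mental health per tract is generated on the logit scale
#' as baseline + factor effects + confounder effects + state and county random
#' intercepts + residual noise, then mapped through the inverse logit so all
#' prevalences lie in (0, 1). Confounders are noisy linear images of the
#' factors (shared R^2 of 0.5), standardized, so they genuinely confound the
#' factor-outcome relationship.
#'
#' @param truth a `neighbor_truth`.
#' @param factor_draws the n x k matrix of latent scores returned by
#'   [generate_tract_table()] (the same draws that produced the tract table).
#' @param geography the matching geography data.frame.
#' @param seed integer seed.
#' @return data.frame with GEOID, state, county, prevalence, and the five
#'   confounder columns.
#' @export
generate_outcome <- function(truth, factor_draws, geography, seed) {
  stopifnot(inherits(truth, "neighbor_truth"))
  n <- nrow(factor_draws)
  if (n != nrow(geography))
    stop("factor_draws has ", n, " rows but geography has ",
         nrow(geography), " rows")
  with_seed(seed, {
    a <- truth$conf_loadings
    # normalize rows so the factor part of each confounder has unit variance
    denom <- sqrt(diag(a %*% truth$factor_corr %*% t(a)))
    denom[denom == 0] <- 1 # all-zero row: confounder is pure noise
    a_n <- a / denom
    conf <- sqrt(0.5) * factor_draws %*% t(a_n) +
      sqrt(0.5) * matrix(stats::rnorm(n * nrow(a)), ncol = nrow(a))
    colnames(conf) <- rownames(a)

    u_state <- stats::rnorm(length(unique(geography$state_code)),
                            sd = truth$state_sd)
    names(u_state) <- unique(geography$state_code)
    county_key <- paste(geography$state_code, geography$county_code, sep = ":")
    u_county <- stats::rnorm(length(unique(county_key)),
                             sd = truth$county_sd)
    names(u_county) <- unique(county_key)

    lp <- truth$intercept +
      drop(factor_draws %*% truth$outcome_betas) +
      drop(conf %*% truth$confounder_betas[colnames(conf)]) +
      u_state[geography$state_code] +
      u_county[county_key] +
      stats::rnorm(n, sd = truth$noise_sd)

    data.frame(
      GEOID = geography$tract_id,
      state = geography$state_code,
      county = geography$county_code,
      prevalence = stats::plogis(lp),
      conf,
      stringsAsFactors = FALSE,
      row.names = NULL
    )
  })
}

#' Generate a complete synthetic study at the default conditions
#'
#' Convenience wrapper bundling [generate_truth()], [generate_tract_table()]
#' and [generate_outcome()]. Defaults reproduce the package's reference
#' fixture: 5 factors, 39 core variables, 5000 tracts in 20 states with 5
#' counties each.
#'
#' @param k,p_core,n_tracts,n_states,counties_per_state study dimensions.
#' @param seed integer seed driving all three generation stages.
#' @param ... passed on to [generate_truth()].
#' @return list with `truth`, `tracts`, `catalog`, `geography`,
#'   `factor_draws`, `outcome`.
#' @export
simulate_study <- function(k = 5, p_core = 39, n_tracts = 5000,
                           n_states = 20, counties_per_state = 5,
                           seed = 1, ...) {
  truth <- generate_truth(k = k, p_core = p_core, seed = seed, ...)
  sim <- generate_tract_table(truth, n_tracts = n_tracts,
                              n_states = n_states,
                              counties_per_state = counties_per_state,
                              seed = seed + 1)
  outcome <- generate_outcome(truth, sim$factor_draws, sim$geography,
                              seed = seed + 2)
  c(list(truth = truth, outcome = outcome), sim)
}

#' Write a simulated study to CSV/JSON artifacts
#'
#' Writes `tracts.csv`, `catalog.csv`, `outcome.csv` and `truth.json` into
#' `dir` (created if needed).
#'
#' @param study result of [simulate_study()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(study$tracts, file.path(dir, "tracts.csv"),
                   row.names = FALSE)
  utils::write.csv(study$catalog, file.path(dir, "catalog.csv"),
                   row.names = FALSE)
  utils::write.csv(study$outcome, file.path(dir, "outcome.csv"),
                   row.names = FALSE)
  truth <- study$truth
  truth$loadings <- unclass(truth$loadings)
  jsonlite::write_json(unclass(truth), file.path(dir, "truth.json"),
                       digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(dir)
}
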