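# Factor-outcome association: per-state cubic smoothing splines summarized
# by R-squared, and a linear mixed-model variance decomposition yielding
# unique variance and Cohen's f-squared per factor.

#' Merge factor scores with the outcome table on GEOID
#' @noRd
.merge_scores_outcome <- function(scores, outcome) {
  stopifnot("GEOID" %in% names(scores), "GEOID" %in% names(outcome))
  merged <- merge(as.data.frame(scores), outcome, by = "GEOID")
  if (nrow(merged) == 0) stop("no tracts shared between scores and outcome")
  merged
}

#' Per-state smoothing-spline fits of prevalence on factor scores
#'
#' For each factor and each state with at least `min_tracts` tracts, fits a
#' cubic smoothing spline of prevalence on the factor score with the
#' smoothing penalty chosen by generalized cross-validation, and computes
#' R^2 = 1 - SS_res / SS_tot. Per-factor fits are summarized by the median
#' and inter-quartile range of R^2 across states. States below the size
#' threshold, or whose spline cannot be fitted (fewer than four distinct
#' score values, or zero outcome variance), are excluded with a reason.
#'
#' @param scores `factor_scores` (GEOID + factor columns).
#' @param outcome outcome table with GEOID, state, prevalence.
#' @param min_tracts_per_state minimum tracts for a state to be fitted.
#' @return object of class `spline_summary`: list with `by_state`
#'   (data.frame: factor, state, n, r2), `summary` (data.frame: factor,
#'   n_states, median_r2, q25_r2, q75_r2), `excluded` (data.frame: factor,
#'   state, reason).
#' @export
state_spline_r2 <- function(scores, outcome, min_tracts_per_state = 20) {
  merged <- .merge_scores_outcome(scores, outcome)
  factors <- setdiff(names(scores), "GEOID")
  by_state <- excluded <- NULL
  states <- unique(merged$state)
  for (fac in factors) {
    for (st in states) {
      d <- merged[merged$state == st, c(fac, "prevalence")]
      n <- nrow(d)
      if (n < min_tracts_per_state) {
        excluded <- rbind(excluded, data.frame(
          factor = fac, state = st,
          reason = sprintf("fewer than %d tracts (%d)",
                           min_tracts_per_state, n)))
        next
      }
      r2 <- tryCatch({
        fit <- stats::smooth.spline(d[[fac]], d$prevalence, cv = FALSE)
        pred <- stats::predict(fit, d[[fac]])$y
        ss_tot <- sum((d$prevalence - mean(d$prevalence))^2)
        if (ss_tot == 0) stop("constant outcome")
        1 - sum((d$prevalence - pred)^2) / ss_tot
      }, error = function(e) e)
      if (inherits(r2, "error")) {
        excluded <- rbind(excluded, data.frame(
          factor = fac, state = st,
          reason = paste("spline fit failed:", conditionMessage(r2))))
      } else {
        by_state <- rbind(by_state, data.frame(
          factor = fac, state = st, n = n, r2 = r2))
      }
    }
  }
  if (is.null(by_state)) stop("no state passed the size filter")
  summ <- do.call(rbind, lapply(factors, function(fac) {
    r2s <- by_state$r2[by_state$factor == fac]
    data.frame(factor = fac, n_states = length(r2s),
               median_r2 = stats::median(r2s),
               q25_r2 = unname(stats::quantile(r2s, 0.25)),
               q75_r2 = unname(stats::quantile(r2s, 0.75)))
  }))
  structure(list(by_state = by_state, summary = summ,
                 excluded = if (is.null(excluded)) {
                   data.frame(factor = character(0), state = character(0),
                              reason = character(0))
                 } else {
                   excluded
                 }),
            class = "spline_summary")
}

#' @export
print.spline_summary <- function(x, ...) {
  cat("Per-state smoothing-spline fits (R^2 across states):\n")
  print(transform(x$summary,
                  median_r2 = round(median_r2, 3),
                  q25_r2 = round(q25_r2, 3),
                  q75_r2 = round(q75_r2, 3)),
        row.names = FALSE)
  if (nrow(x$excluded))
    cat(nrow(x$excluded), "factor-state fits excluded\n")
  invisible(x)
}

#' Fit a linear mixed model of prevalence with nested random intercepts
#'
#' Fits `prevalence ~ fixed effects + (1 | state) + (1 | state:county)` by
#' maximum likelihood (not REML, so variance comparisons across models with
#' different fixed effects are coherent). County is treated as nested within
#' state, as county codes are only unique within a state. A singular fit
#' (a variance component estimated at zero) produces a warning, not an
#' error.
#'
#' @param data merged data.frame with prevalence, state, county, and all
#'   requested covariate columns.
#' @param fixed_terms character vector of fixed-effect column names (may be
#'   empty: the null model).
#' @return list with `fit` (the lmerMod), `vc` (named variance components:
#'   state, county, residual), `v_model` (their sum), `fixed` (fixed-effect
#'   estimates).
#' @export
fit_lme <- function(data, fixed_terms = character(0)) {
  stopifnot(all(c("prevalence", "state", "county") %in% names(data)))
  if (length(unique(data$state)) < 2) stop("need at least 2 states")
  if (anyNA(data[c("prevalence", "state", "county", fixed_terms)]))
    stop("missing values in model columns")
  rhs <- paste(c(if (length(fixed_terms)) fixed_terms else "1",
                 "(1 | state)", "(1 | state:county)"), collapse = " + ")
  form <- stats::as.formula(paste("prevalence ~", rhs))
  fit <- lme4::lmer(form, data = data, REML = FALSE,
                    control = lme4::lmerControl(calc.derivs = FALSE,
                                                check.conv.singular = "ignore"))
  vc <- as.data.frame(lme4::VarCorr(fit))
  comp <- stats::setNames(vc$vcov, vc$grp)
  out <- c(state = unname(comp["state"]),
           county = unname(comp["state:county"]),
           residual = unname(comp["Residual"]))
  if (any(out < 1e-12))
    warning("singular fit: variance component(s) estimated at zero: ",
            paste(names(out)[out < 1e-12], collapse = ", "))
  list(fit = fit, vc = out, v_model = sum(out),
       fixed = lme4::fixef(fit))
}

#' R-squared from null and model variances
#'
#' `(V_null - V_model) / V_null`, where V is the total unexplained variance
#' (the sum of the estimated state, county and residual components).
#'
#' @param v_null,v_model total variance of the null and the fitted model.
#' @return unitless R^2.
#' @export
r2_from_variances <- function(v_null, v_model) {
  stopifnot(v_null > 0, v_model >= 0)
  (v_null - v_model) / v_null
}

#' Unique variance explained by a covariate
#'
#' The increment in model R^2 from adding the covariate:
#' `r2_with - r2_without`.
#'
#' @param r2_with,r2_without model R^2 with and without the covariate.
#' @return unitless increment.
#' @export
unique_variance <- function(r2_with, r2_without) {
  stopifnot(r2_with >= 0, r2_with <= 1, r2_without >= 0, r2_without <= 1)
  r2_with - r2_without
}

#' Cohen's f-squared local effect size
#'
#' `(r2_with - r2_without) / (1 - r2_with)`.
#'
#' @param r2_with,r2_without model R^2 with and without the covariate.
#' @return unitless effect size.
#' @export
cohens_f2 <- function(r2_with, r2_without) {
  if (any(r2_with >= 1)) stop("r2_with must be < 1")
  (r2_with - r2_without) / (1 - r2_with)
}

#' Classify a Cohen's f-squared effect size
#'
#' Thresholds: large for f^2 >= 0.35, medium for f^2 >= 0.15, small for
#' f^2 >= 0.02, otherwise none.
#'
#' @param f2 non-negative effect size(s).
#' @return character vector in `c("none", "small", "medium", "large")`.
#' @export
classify_effect <- function(f2) {
  stopifnot(all(f2 >= 0))
  ifelse(f2 >= 0.35, "large",
         ifelse(f2 >= 0.15, "medium",
                ifelse(f2 >= 0.02, "small", "none")))
}

#' Mixed-model variance decomposition across factor models
#'
#' Fits the null model (random intercepts only), the confounder-only model
#' Ma, one model per factor Ma,i (confounders + that factor), and the full
#' model Ma,1:k (confounders + all factors), all by maximum likelihood.
#' Each model's R^2 is computed against the null model's total variance;
#' unique variance and Cohen's f^2 for each factor (and for all factors
#' jointly) are computed against Ma, with effect-size labels attached.
#'
#' @param outcome outcome table (GEOID, state, county, prevalence,
#'   confounders).
#' @param scores `factor_scores` keyed by GEOID.
#' @param confounder_names character vector of confounder columns in
#'   `outcome`.
#' @param variance which variance enters the R^2 formula: `"total"`
#'   (default; the sum of state, county and residual components, so fixed
#'   effects at any level register) or `"residual"` (the residual component
#'   only).
#' @return object of class `variance_decomposition`: a data.frame with one
#'   row per model (model, label, v_model, variance_explained,
#'   unique_variance, f2, effect_label); attribute `v_null` holds the null
#'   model's total variance.
#' @export
decomposition_report <- function(outcome, scores, confounder_names,
                                 variance = c("total", "residual")) {
  variance <- match.arg(variance)
  merged <- .merge_scores_outcome(scores, outcome)
  factors <- setdiff(names(scores), "GEOID")
  missing_conf <- setdiff(confounder_names, names(merged))
  if (length(missing_conf))
    stop("confounder column(s) not found: ",
         paste(missing_conf, collapse = ", "))

  v_of <- function(m) {
    if (variance == "total") m$v_model else unname(m$vc["residual"])
  }
  v_null <- v_of(fit_lme(merged))
  fit_r2 <- function(terms) {
    r2_from_variances(v_null, v_of(fit_lme(merged, terms)))
  }

  r2_a <- fit_r2(confounder_names)
  rows <- data.frame(
    model = "Ma", label = "confounders only", v_model = NA_real_,
    variance_explained = r2_a, unique_variance = NA_real_, f2 = NA_real_,
    effect_label = NA_character_, stringsAsFactors = FALSE
  )
  for (i in seq_along(factors)) {
    r2_i <- fit_r2(c(confounder_names, factors[i]))
    uv <- unique_variance(r2_i, r2_a)
    f2 <- cohens_f2(r2_i, r2_a)
    rows <- rbind(rows, data.frame(
      model = sprintf("Ma,%d", i),
      label = paste("confounders +", factors[i]), v_model = NA_real_,
      variance_explained = r2_i, unique_variance = uv, f2 = f2,
      effect_label = classify_effect(max(f2, 0)), stringsAsFactors = FALSE
    ))
  }
  r2_all <- fit_r2(c(confounder_names, factors))
  uv <- unique_variance(r2_all, r2_a)
  f2 <- cohens_f2(r2_all, r2_a)
  rows <- rbind(rows, data.frame(
    model = sprintf("Ma,1:%d", length(factors)),
    label = "confounders + all factors", v_model = NA_real_,
    variance_explained = r2_all, unique_variance = uv, f2 = f2,
    effect_label = classify_effect(max(f2, 0)), stringsAsFactors = FALSE
  ))
  rows$v_model <- v_null * (1 - rows$variance_explained)
  structure(rows, v_null = v_null,
            class = c("variance_decomposition", "data.frame"))
}

#' @export
print.variance_decomposition <- function(x, digits = 4, ...) {
  cat("Mixed-model variance decomposition (V_null =",
      signif(attr(x, "v_null"), 4), "):\n")
  y <- as.data.frame(x)
  y$v_model <- NULL
  y$variance_explained <- round(y$variance_explained, digits)
  y$unique_variance <- round(y$unique_variance, digits)
  y$f2 <- round(y$f2, digits)
  print(y, row.names = FALSE)
  invisible(x)
}
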