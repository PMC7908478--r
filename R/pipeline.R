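# End-to-end orchestration with validated tabular I/O. GEOIDs are always
# strings: leading-zero state codes corrupt silently under numeric parsing.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with its default: the CV threshold
#' of the low-variability filter, the number of imputation neighbors, the
#' factor count, the bootstrap resample count, the effect-size thresholds,
#' the spline state-size filter, the variance definition for mixed-model
#' R^2, and the transform menu.
#'
#' @param cv_threshold coefficient-of-variation cutoff (default 0.06).
#' @param knn_k imputation neighbor count (default 10).
#' @param n_factors factor count (default 5).
#' @param n_boot bootstrap resamples (default 2000; 0 skips the bootstrap).
#' @param seed integer seed.
#' @param effect_thresholds small/medium/large f^2 cutpoints.
#' @param spline_min_tracts state-size filter for spline fits (default 20).
#' @param variance `"total"` or `"residual"` (see [decomposition_report()]).
#' @param transform_families candidate transform menu, in preference order.
#' @return object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(cv_threshold = 0.06, knn_k = 10, n_factors = 5,
                            n_boot = 2000, seed = 1,
                            effect_thresholds = c(small = 0.02,
                                                  medium = 0.15,
                                                  large = 0.35),
                            spline_min_tracts = 20,
                            variance = c("total", "residual"),
                            transform_families = .transform_families) {
  stopifnot(cv_threshold > 0, knn_k >= 1, n_factors >= 1, n_boot >= 0,
            spline_min_tracts > 0, all(effect_thresholds > 0))
  structure(list(
    cv_threshold = cv_threshold, knn_k = knn_k, n_factors = n_factors,
    n_boot = n_boot, seed = as.integer(seed),
    effect_thresholds = effect_thresholds,
    spline_min_tracts = spline_min_tracts,
    variance = match.arg(variance),
    transform_families = transform_families
  ), class = "pipeline_config")
}

#' Read and validate a tract table
#'
#' GEOIDs are parsed as 11-character zero-padded strings (never numeric);
#' all other columns are numeric with empty cells as missing. Duplicate or
#' malformed GEOIDs are rejected with the offending key or row named.
#'
#' @param path CSV path with a header including a GEOID column.
#' @return validated data.frame.
#' @export
read_tract_table <- function(path) {
  tab <- utils::read.csv(path, colClasses = c(GEOID = "character"),
                         check.names = FALSE)
  if (!"GEOID" %in% names(tab)) stop("no GEOID column in ", path)
  .validate_geoid(tab$GEOID)
  for (nm in setdiff(names(tab), "GEOID")) {
    if (!is.numeric(tab[[nm]])) {
      suppressWarnings(num <- as.numeric(tab[[nm]]))
      bad <- which(!is.na(tab[[nm]]) & tab[[nm]] != "" & is.na(num))
      if (length(bad))
        stop("non-numeric cell in column '", nm, "', row ", bad[1],
             ": '", tab[[nm]][bad[1]], "'")
      tab[[nm]] <- num
    }
  }
  tab
}

#' @noRd
.validate_geoid <- function(geoid) {
  bad <- which(!grepl("^[0-9]{11}$", geoid))
  if (length(bad))
    stop("malformed GEOID in row ", bad[1], ": '", geoid[bad[1]],
         "' (expected 11 digits)")
  dup <- geoid[duplicated(geoid)]
  if (length(dup))
    stop("duplicated GEOID: ", dup[1])
}

#' Read a variable catalog
#'
#' @param path CSV path with columns variable, group, role, complement_of,
#'   parent, combine_rule (and optionally weights).
#' @return validated catalog data.frame.
#' @export
read_catalog <- function(path) {
  cat_df <- utils::read.csv(path, colClasses = "character",
                            check.names = FALSE)
  need <- c("variable", "role")
  miss <- setdiff(need, names(cat_df))
  if (length(miss))
    stop("catalog is missing column(s): ", paste(miss, collapse = ", "))
  for (nm in c("complement_of", "parent", "combine_rule", "weights")) {
    if (!nm %in% names(cat_df)) cat_df[[nm]] <- NA_character_
    cat_df[[nm]][cat_df[[nm]] == ""] <- NA_character_
  }
  refs <- c(cat_df$complement_of, cat_df$parent)
  refs <- refs[!is.na(refs)]
  dangling <- setdiff(refs, c(cat_df$variable, cat_df$parent))
  if (length(dangling))
    stop("catalog reference(s) to unknown variable: ",
         paste(unique(dangling), collapse = ", "))
  cat_df
}

#' Read and validate an outcome table
#'
#' @param path CSV path with GEOID, state, county, prevalence and
#'   confounder columns.
#' @return validated data.frame (GEOID, state, county as strings).
#' @export
read_outcome_table <- function(path) {
  tab <- utils::read.csv(path, colClasses = c(GEOID = "character",
                                              state = "character",
                                              county = "character"),
                         check.names = FALSE)
  need <- c("GEOID", "state", "county", "prevalence")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("outcome table is missing column(s): ",
         paste(miss, collapse = ", "))
  .validate_geoid(tab$GEOID)
  bad <- which(substr(tab$GEOID, 1, 2) != tab$state |
                 substr(tab$GEOID, 3, 5) != tab$county)
  if (length(bad))
    stop("state/county codes inconsistent with GEOID in row ", bad[1])
  if (any(tab$prevalence < 0 | tab$prevalence > 1, na.rm = TRUE))
    stop("prevalence outside [0, 1]")
  tab
}

#' Tiny stable content hash (FNV-1a) for the manifest
#' @noRd
.fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 2166136261
  for (b in bytes) h <- bitwAnd(bitwXor(h, b) * 16777619, 0xFFFFFFFF)
  sprintf("%08x", h)
}

#' Run the full pipeline on tract, catalog and outcome files
#'
#' Executes selection, transformation, imputation, factor analysis, scoring,
#' the per-state spline summary and the mixed-model decomposition, writing
#' every intermediate artifact plus a `manifest.json` (config, config hash,
#' seed, row/column counts at each stage, timings) into a new run directory.
#' Identical config + inputs + seed reproduce identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param tract_table_path,catalog_path,outcome_path input CSV paths.
#' @param out_dir run directory; must not already exist (one directory per
#'   invocation, for auditability).
#' @return list with the stage results (`selection`, `specs`, `transformed`,
#'   `model`, `scores`, `splines`, `decomposition`, `bootstrap`,
#'   `manifest`), invisibly.
#' @export
run_pipeline <- function(config, tract_table_path, catalog_path,
                         outcome_path, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (dir.exists(out_dir))
    stop("run directory already exists: ", out_dir)
  dir.create(out_dir, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  stage_times <- c()
  tick <- function(label) {
    t1 <- proc.time()[["elapsed"]]
    stage_times[[label]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }

  tracts <- read_tract_table(tract_table_path)
  catalog <- read_catalog(catalog_path)
  outcome <- read_outcome_table(outcome_path)
  counts <- list(input = dim(tracts))
  tick("read")

  sel <- select_features(tracts, catalog, cv_threshold = config$cv_threshold)
  utils::write.csv(sel$table, file.path(out_dir, "selected.csv"),
                   row.names = FALSE)
  utils::write.csv(sel$log, file.path(out_dir, "selection_log.csv"),
                   row.names = FALSE)
  counts$selected <- dim(sel$table)
  tick("select")

  specs <- fit_transforms(sel$table, families = config$transform_families)
  transformed <- apply_transforms(sel$table, specs)
  transformed <- knn_impute(transformed, k = config$knn_k)
  utils::write.csv(transformed, file.path(out_dir, "transformed.csv"),
                   row.names = FALSE)
  jsonlite::write_json(lapply(specs, unclass),
                       file.path(out_dir, "transforms.json"),
                       auto_unbox = TRUE, digits = NA)
  counts$transformed <- dim(transformed)
  counts$missing_after_impute <- sum(is.na(transformed))
  tick("transform")

  model <- fit_efa(transformed, k = config$n_factors)
  diag_tab <- factor_diagnostics(transformed,
                                 k_max = min(config$n_factors + 2,
                                             nrow(model$loadings) - 1))
  utils::write.csv(
    data.frame(variable = rownames(model$loadings), model$loadings),
    file.path(out_dir, "loadings.csv"), row.names = FALSE)
  utils::write.csv(model$factor_corr, file.path(out_dir, "phi.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(
    eigenvalues = model$eigenvalues,
    variance_explained = model$variance_explained,
    cumulative_variance = model$cumulative_variance,
    rms_residual = model$rms_residual,
    offdiag_fit = model$offdiag_fit,
    kaiser_count = diag_tab$kaiser_count,
    scree_elbow = diag_tab$scree_elbow
  ), file.path(out_dir, "fit.json"), auto_unbox = TRUE, digits = NA)
  tick("factor")

  scores <- compute_scores(model, transformed)
  utils::write.csv(scores, file.path(out_dir, "scores.csv"),
                   row.names = FALSE)
  tick("score")

  boot <- NULL
  if (config$n_boot > 0) {
    boot <- bootstrap_loading_se(transformed, k = config$n_factors,
                                 n_boot = config$n_boot, seed = config$seed)
    utils::write.csv(
      data.frame(variable = rownames(boot$loading_se), boot$loading_se),
      file.path(out_dir, "bootstrap_se.csv"), row.names = FALSE)
    tick("bootstrap")
  }

  confounders <- grep("^conf_", names(outcome), value = TRUE)
  splines <- state_spline_r2(scores, outcome,
                             min_tracts_per_state = config$spline_min_tracts)
  utils::write.csv(splines$by_state,
                   file.path(out_dir, "spline_summary.csv"),
                   row.names = FALSE)
  decomp <- suppressWarnings(
    decomposition_report(outcome, scores, confounders,
                         variance = config$variance))
  utils::write.csv(as.data.frame(decomp),
                   file.path(out_dir, "decomposition.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(
    spline_summary = splines$summary,
    decomposition = as.data.frame(decomp),
    v_null = attr(decomp, "v_null")
  ), file.path(out_dir, "association_report.json"), auto_unbox = TRUE,
    digits = NA, dataframe = "rows")
  tick("associate")

  manifest <- list(
    config = unclass(config), config_hash = .fnv1a(unclass(config)),
    seed = config$seed, counts = counts, timings_sec = as.list(stage_times)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(selection = sel, specs = specs, transformed = transformed,
                 model = model, diagnostics = diag_tab, scores = scores,
                 splines = splines, decomposition = decomp,
                 bootstrap = boot, manifest = manifest))
}
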