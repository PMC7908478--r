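# Catalog-driven variable selection: redundancy removal, low-variability
# filtering, and strata combination. The pipeline order is
# drop_redundant -> filter_low_cv -> combine_strata; select_features() runs
# all three and concatenates their logs, which jointly account for every
# column removed.

#' @noRd
.data_cols <- function(table) setdiff(names(table), "GEOID")

#' @noRd
.check_catalog <- function(table, catalog) {
  cols <- .data_cols(table)
  miss <- setdiff(cols, catalog$variable)
  if (length(miss))
    stop("catalog does not cover column(s): ", paste(miss, collapse = ", "))
}

#' Remove catalog-declared redundant (complement) variables
#'
#' A variable is redundant when it is fully represented by another (the
#' archetype: a female share that is one minus the male share). Redundancy is
#' declared in the catalog (`role == "complement"` or a non-missing
#' `complement_of`), never auto-detected, so the analysis variable set cannot
#' silently change.
#'
#' @param table tract table (data.frame; a `GEOID` column, if present, is
#'   carried through untouched).
#' @param catalog variable catalog covering every data column, with columns
#'   `variable`, `role`, `complement_of`.
#' @return list with `table` (reduced) and `log` (data.frame: variable,
#'   action, detail).
#' @export
drop_redundant <- function(table, catalog) {
  .check_catalog(table, catalog)
  cat_sub <- catalog[catalog$variable %in% .data_cols(table), ]
  redundant <- cat_sub$variable[
    cat_sub$role == "complement" | !is.na(cat_sub$complement_of)]
  partner <- cat_sub$complement_of[match(redundant, cat_sub$variable)]
  # circular redundancy: the retained counterpart must itself be retained
  bad <- partner[!is.na(partner) & partner %in% redundant]
  if (length(bad))
    stop("circular redundancy: complement_of points at removed column(s): ",
         paste(unique(bad), collapse = ", "))
  log <- data.frame(
    variable = redundant,
    action = rep("redundant", length(redundant)),
    detail = ifelse(is.na(partner), "",
                    paste0("retained counterpart: ", partner)),
    stringsAsFactors = FALSE
  )
  list(table = table[, !(names(table) %in% redundant), drop = FALSE],
       log = log)
}

#' Coefficient of variation per column
#'
#' Sample standard deviation (n - 1 denominator) over the mean, computed on
#' raw values ignoring missing entries. Undefined (NA) when the mean is not
#' positive.
#'
#' @param table data.frame of numeric columns (GEOID ignored).
#' @return data.frame with variable, mean, sd, cv.
#' @export
variable_stats <- function(table) {
  cols <- .data_cols(table)
  m <- vapply(table[cols], function(x) mean(x, na.rm = TRUE), numeric(1))
  s <- vapply(table[cols], function(x) stats::sd(x, na.rm = TRUE), numeric(1))
  data.frame(variable = cols, mean = m, sd = s,
             cv = ifelse(m > 0, s / m, NA_real_),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Remove low-variability variables by coefficient of variation
#'
#' Columns whose CV (sd/mean on raw, untransformed values) falls below the
#' threshold carry almost no between-tract information and are dropped.
#' Columns with non-positive mean have no defined CV; they are never removed
#' by this rule and are logged as retained.
#'
#' @param table tract table.
#' @param threshold positive CV cutoff (default 0.06).
#' @return list with `table` and `log`.
#' @export
filter_low_cv <- function(table, threshold = 0.06) {
  if (length(.data_cols(table)) == 0) stop("empty table")
  stopifnot(threshold >= 0)
  st <- variable_stats(table)
  undef <- st$variable[is.na(st$cv)]
  drop <- st$variable[!is.na(st$cv) & st$cv < threshold]
  log <- rbind(
    data.frame(variable = drop, action = rep("low_cv", length(drop)),
               detail = sprintf("cv = %.4g < %.4g",
                                st$cv[match(drop, st$variable)], threshold),
               stringsAsFactors = FALSE),
    data.frame(variable = undef, action = rep("kept", length(undef)),
               detail = rep("cv-undefined, retained", length(undef)),
               stringsAsFactors = FALSE)
  )
  list(table = table[, !(names(table) %in% drop), drop = FALSE], log = log)
}

#' Combine strata subgroup columns into single statistics
#'
#' Each stratum group (catalog rows sharing a `parent`) is replaced by one
#' column named after the parent, using the group's `combine_rule`: `sum` for
#' proportion subgroups (e.g., share with a bachelor's degree or higher as the
#' sum of degree-level shares) or `weighted_mean` with bin weights (e.g., mean
#' age from age-band shares and band midpoints). A missing value in any
#' subgroup propagates to the combined value.
#'
#' @param table tract table.
#' @param catalog catalog with `role`, `parent`, `combine_rule` and optional
#'   `weights` (comma-separated numeric string) per stratum variable.
#' @return list with `table` and `log` (one row per absorbed subgroup column).
#' @export
combine_strata <- function(table, catalog) {
  cat_sub <- catalog[catalog$variable %in% .data_cols(table) &
                       catalog$role == "stratum" & !is.na(catalog$parent), ]
  log <- data.frame(variable = character(0), action = character(0),
                    detail = character(0), stringsAsFactors = FALSE)
  for (parent in unique(cat_sub$parent)) {
    members <- cat_sub[cat_sub$parent == parent, ]
    absent <- setdiff(members$variable, names(table))
    if (length(absent))
      stop("stratum group '", parent, "' is missing column(s): ",
           paste(absent, collapse = ", "))
    rule <- unique(members$combine_rule)
    rule <- rule[!is.na(rule)]
    if (length(rule) != 1)
      stop("stratum group '", parent,
           "' must declare exactly one combine_rule")
    sub <- as.matrix(table[members$variable])
    if (rule == "sum") {
      combined <- rowSums(sub) # NA propagates
    } else if (rule == "weighted_mean") {
      w <- .parse_weights(members$weights)
      if (length(w) != ncol(sub))
        stop("stratum group '", parent, "': ", length(w), " weights for ",
             ncol(sub), " subgroup columns")
      combined <- drop(sub %*% w) / rowSums(sub)
      combined[rowSums(sub) == 0] <- NA_real_
    } else {
      stop("unknown combine_rule '", rule, "' for stratum group '",
           parent, "'")
    }
    pos <- match(members$variable[1], names(table))
    table <- table[, !(names(table) %in% members$variable), drop = FALSE]
    # insert the combined column where the first subgroup sat
    table <- cbind(table[, seq_len(pos - 1), drop = FALSE],
                   stats::setNames(data.frame(combined), parent),
                   table[, seq(pos, length.out = ncol(table) - pos + 1),
                         drop = FALSE])
    log <- rbind(log, data.frame(
      variable = members$variable, action = "combined_into",
      detail = sprintf("%s (%s)", parent, rule), stringsAsFactors = FALSE))
  }
  list(table = table, log = log)
}

#' @noRd
.parse_weights <- function(w) {
  w <- w[!is.na(w)]
  if (!length(w)) stop("weighted_mean stratum group declares no weights")
  as.numeric(strsplit(w[1], ",")[[1]])
}

#' Run the full selection stage
#'
#' Applies [drop_redundant()], [filter_low_cv()] and [combine_strata()] in
#' that order and concatenates the three logs; the logged removals and
#' combinations account exactly for the difference between input and output
#' column counts.
#'
#' @inheritParams drop_redundant
#' @param cv_threshold CV cutoff passed to [filter_low_cv()].
#' @return list with `table` and `log`.
#' @export
select_features <- function(table, catalog, cv_threshold = 0.06) {
  s1 <- drop_redundant(table, catalog)
  s2 <- filter_low_cv(s1$table, threshold = cv_threshold)
  s3 <- combine_strata(s2$table, catalog)
  list(table = s3$table, log = rbind(s1$log, s2$log, s3$log))
}
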