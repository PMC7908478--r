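# Gaussianizing transformation and weighted k-nearest-neighbor imputation.
#
# Each variable gets a data-driven transform chosen from a small menu to
# minimize absolute sample skewness, is standardized, and missing values are
# then filled by inverse-distance-weighted averaging over the 10 nearest
# rows in the standardized space.

.transform_families <- c("identity", "log_shift", "sqrt", "logit",
                         "yeo_johnson")

#' Sample skewness of the non-missing values
#' @noRd
.skew <- function(x) e1071::skewness(x, na.rm = TRUE)

#' Yeo-Johnson transform and inverse
#' @noRd
.yj <- function(x, lambda) {
  pos <- !is.na(x) & x >= 0
  out <- x
  if (abs(lambda) > 1e-10) {
    out[pos] <- ((x[pos] + 1)^lambda - 1) / lambda
  } else {
    out[pos] <- log1p(x[pos])
  }
  if (abs(lambda - 2) > 1e-10) {
    out[!pos & !is.na(x)] <- -((1 - x[!pos & !is.na(x)])^(2 - lambda) - 1) /
      (2 - lambda)
  } else {
    out[!pos & !is.na(x)] <- -log1p(-x[!pos & !is.na(x)])
  }
  out
}

#' @noRd
.yj_inv <- function(y, lambda) {
  pos <- !is.na(y) & y >= 0
  out <- y
  if (abs(lambda) > 1e-10) {
    out[pos] <- (lambda * y[pos] + 1)^(1 / lambda) - 1
  } else {
    out[pos] <- expm1(y[pos])
  }
  if (abs(lambda - 2) > 1e-10) {
    out[!pos & !is.na(y)] <-
      1 - (1 - (2 - lambda) * y[!pos & !is.na(y)])^(1 / (2 - lambda))
  } else {
    out[!pos & !is.na(y)] <- 1 - exp(-y[!pos & !is.na(y)])
  }
  out
}

#' Forward-map a vector under a fitted family (no standardization)
#' @noRd
.family_fwd <- function(x, spec) {
  switch(spec$family,
    identity = x,
    log_shift = log(x + spec$shift),
    sqrt = sqrt(x),
    logit = stats::qlogis(pmin(pmax(x, spec$eps_lo), 1 - spec$eps_hi)),
    yeo_johnson = .yj(x, spec$lambda),
    stop("unknown transform family: ", spec$family)
  )
}

#' @noRd
.family_inv <- function(y, spec) {
  switch(spec$family,
    identity = y,
    log_shift = exp(y) - spec$shift,
    sqrt = y^2,
    logit = stats::plogis(y),
    yeo_johnson = .yj_inv(y, spec$lambda),
    stop("unknown transform family: ", spec$family)
  )
}

#' Fit Gaussianizing transforms for every column
#'
#' For each column the applicable candidate families are evaluated (logit
#' only for values within \[0, 1\]; sqrt only for non-negative values;
#' log-shift with shift `max(0, eps - min)` where `eps` is half the smallest
#' positive observed value; Yeo-Johnson with lambda optimized over
#' \[-3, 3\]), and the family minimizing the absolute sample skewness of the
#' transformed values is selected. A simplicity margin applies: the
#' earliest-listed family whose |skewness| comes within `tol` of the minimum
#' wins, so a marginal improvement never displaces a simpler (or exactly
#' inverse) transform. Standardization constants are recorded from the
#' transformed values.
#'
#' @param table tract table (data.frame; `GEOID` ignored).
#' @param families candidate families, in preference order.
#' @param tol simplicity margin on |skewness| (default 0.10).
#' @return object of class `transform_spec`: a named list of per-variable
#'   specs (family, parameters, pre/post skewness, mean, sd).
#' @export
fit_transforms <- function(table, families = .transform_families,
                           tol = 0.10) {
  families <- match.arg(families, .transform_families, several.ok = TRUE)
  cols <- .data_cols(table)
  specs <- lapply(cols, function(nm) {
    x <- table[[nm]]
    xs <- x[!is.na(x)]
    if (length(xs) < 10)
      stop("column '", nm, "' has fewer than 10 non-missing values")
    if (stats::sd(xs) == 0) stop("zero-variance column: ", nm)
    pos <- xs[xs > 0]
    eps <- if (length(pos)) min(pos) / 2 else 1e-3

    cand <- list()
    for (fam in families) {
      spec <- switch(fam,
        identity = list(family = "identity"),
        log_shift = list(family = "log_shift",
                         shift = max(0, eps - min(xs))),
        sqrt = if (min(xs) >= 0) list(family = "sqrt"),
        logit = if (min(xs) >= 0 && max(xs) <= 1) {
          up <- 1 - xs[xs < 1]
          list(family = "logit", eps_lo = eps,
               eps_hi = if (length(up)) min(up) / 2 else 1e-3)
        },
        yeo_johnson = {
          obj <- function(l) abs(.skew(.yj(xs, l)))
          opt <- stats::optimize(obj, c(-3, 3))
          list(family = "yeo_johnson", lambda = opt$minimum)
        }
      )
      if (!is.null(spec)) {
        spec$post_skewness <- abs(.skew(.family_fwd(xs, spec)))
        cand[[fam]] <- spec
      }
    }
    skews <- vapply(cand, `[[`, numeric(1), "post_skewness")
    best <- cand[[which(skews <= min(skews) + tol)[1]]]

    y <- .family_fwd(xs, best)
    best$pre_skewness <- .skew(xs)
    best$post_skewness <- .skew(y)
    best$mean <- mean(y)
    best$sd <- stats::sd(y)
    best
  })
  names(specs) <- cols
  structure(specs, class = "transform_spec")
}

#' @export
print.transform_spec <- function(x, ...) {
  fam <- vapply(x, `[[`, character(1), "family")
  cat("Transform specs for", length(x), "variables:\n")
  print(table(factor(fam, levels = .transform_families)))
  invisible(x)
}

#' Apply fitted transforms and standardize
#'
#' Maps every non-missing cell through its column's fitted family, then
#' centers and scales with the recorded constants; missing cells stay
#' missing. Values outside a family's domain (for example a proportion above
#' one under logit) raise an error naming the column and row.
#'
#' @param table tract table with the same columns the specs were fitted on.
#' @param specs a `transform_spec`.
#' @return data.frame of transformed standardized columns (GEOID carried
#'   through if present).
#' @export
apply_transforms <- function(table, specs) {
  cols <- .data_cols(table)
  if (!setequal(cols, names(specs)))
    stop("specs were fitted on different columns")
  out <- table
  for (nm in cols) {
    spec <- specs[[nm]]
    x <- table[[nm]]
    bad <- switch(spec$family,
      log_shift = which(x + spec$shift <= 0),
      sqrt = which(x < 0),
      logit = which(x < 0 | x > 1),
      integer(0)
    )
    bad <- bad[!is.na(x[bad])]
    if (length(bad))
      stop("value outside the ", spec$family, " domain in column '", nm,
           "', row ", bad[1], " (", x[bad[1]], ")")
    out[[nm]] <- (.family_fwd(x, spec) - spec$mean) / spec$sd
  }
  out
}

#' Invert fitted transforms
#'
#' De-standardizes and applies the inverse family map; exact for the
#' bijective families (identity, log-shift, sqrt on non-negatives,
#' Yeo-Johnson) and for logit away from the clipped edges.
#'
#' @param table transformed table as produced by [apply_transforms()].
#' @param specs the `transform_spec` used.
#' @return data.frame on the original scale.
#' @export
invert_transforms <- function(table, specs) {
  out <- table
  for (nm in .data_cols(table)) {
    spec <- specs[[nm]]
    out[[nm]] <- .family_inv(table[[nm]] * spec$sd + spec$mean, spec)
  }
  out
}

#' Weighted k-nearest-neighbor imputation
#'
#' For each missing cell, the k nearest rows are found by Euclidean distance
#' over the columns observed in both rows, rescaled by
#' `sqrt(n_columns / n_shared)` so that distances over few shared columns are
#' comparable to full-dimension distances. The imputed value is the
#' inverse-distance-weighted average (weights `1 / (distance + eps)`) of the
#' neighbors' observed values in that column; if none of the k neighbors has
#' the column observed, the column mean is used and a warning is raised.
#' Observed cells are never modified.
#'
#' @param x numeric matrix or data.frame of standardized columns (a `GEOID`
#'   column is carried through untouched).
#' @param k number of neighbors (default 10; must be < number of rows).
#' @param eps additive constant in the inverse-distance weights.
#' @return completed object of the same shape with zero missing cells.
#' @export
knn_impute <- function(x, k = 10, eps = 1e-8) {
  is_df <- is.data.frame(x)
  geoid <- NULL
  if (is_df && "GEOID" %in% names(x)) {
    geoid <- x$GEOID
    x <- x[setdiff(names(x), "GEOID")]
  }
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  stopifnot(k >= 1, k < nrow(m))
  obs <- !is.na(m)
  if (any(rowSums(obs) == 0)) stop("row(s) entirely missing")
  if (all(obs)) {
    out <- m
  } else {
    out <- m
    p <- ncol(m)
    m0 <- m
    m0[!obs] <- 0
    target_rows <- which(rowSums(!obs) > 0)
    fallbacks <- 0L
    col_means <- colMeans(m, na.rm = TRUE)
    for (i in target_rows) {
      oi <- obs[i, ]
      # squared differences over columns observed in both rows
      diff <- sweep(m0[, oi, drop = FALSE], 2, m0[i, oi], "-")
      both <- obs[, oi, drop = FALSE]
      diff[!both] <- 0
      shared <- rowSums(both)
      d2 <- rowSums(diff^2) * p / pmax(shared, 1)
      d <- sqrt(d2)
      d[shared == 0] <- Inf
      d[i] <- Inf
      nb <- order(d)[seq_len(k)]
      w <- 1 / (d[nb] + eps)
      for (j in which(!obs[i, ])) {
        has <- obs[nb, j]
        if (!any(has)) {
          out[i, j] <- col_means[j]
          fallbacks <- fallbacks + 1L
        } else {
          out[i, j] <- sum(w[has] * m[nb[has], j]) / sum(w[has])
        }
      }
    }
    if (fallbacks > 0)
      warning(fallbacks, " cell(s) fell back to the column mean: ",
              "no neighbor had the column observed")
  }
  if (is_df) {
    out <- as.data.frame(out)
    if (!is.null(geoid)) out <- cbind(GEOID = geoid, out,
                                      stringsAsFactors = FALSE)
  }
  out
}
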