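# Exploratory factor analysis: minimum-residual (ULS) extraction, direct
# oblimin (quartimin) rotation by oblique gradient projection, factor-number
# diagnostics, regression factor scores, and bootstrap loading standard
# errors with congruence-based factor alignment.

#' @noRd
.is_corr <- function(x) {
  is.matrix(x) && nrow(x) == ncol(x) &&
    max(abs(x - t(x))) < 1e-10 && max(abs(diag(x) - 1)) < 1e-10
}

#' @noRd
.input_corr <- function(x) {
  if (.is_corr(as.matrix(x))) {
    r <- as.matrix(x)
    if (is.null(colnames(r))) colnames(r) <- rownames(r) <-
        sprintf("V%d", seq_len(ncol(r)))
    list(r = r, n_obs = NA_integer_)
  } else {
    m <- as.matrix(if (is.data.frame(x)) x[setdiff(names(x), "GEOID")] else x)
    if (anyNA(m)) stop("input matrix has missing values; impute first")
    list(r = stats::cor(m), n_obs = nrow(m))
  }
}

#' Minres (ULS) extraction: loadings from the reduced correlation matrix
#' for a given vector of uniquenesses.
#' @noRd
.minres_loadings <- function(r, psi, k) {
  rr <- r
  diag(rr) <- 1 - psi
  e <- eigen(rr, symmetric = TRUE)
  ev <- pmax(e$values[seq_len(k)], 0)
  e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(ev), k)
}

#' Sum of squared off-diagonal residuals of R - Lambda Lambda'
#' @noRd
.minres_objective <- function(psi, r, k) {
  l <- .minres_loadings(r, psi, k)
  res <- r - tcrossprod(l)
  diag(res) <- 0
  sum(res^2) / 2
}

#' Quartimin criterion value and gradient (direct oblimin, gamma = 0)
#' @noRd
.quartimin_vgQ <- function(l) {
  l2 <- l^2
  k <- ncol(l)
  n <- matrix(1, k, k) - diag(k)
  x <- l2 %*% n
  list(f = sum(l2 * x) / 4, Gq = l * x)
}

#' Oblique gradient-projection rotation (Jennrich 2002) with the quartimin
#' criterion. The identity start can sit exactly on a saddle point for
#' perfectly balanced structures, so a fixed set of pseudo-random starts is
#' tried as well and the solution with the lowest criterion value wins;
#' the start set is deterministic, keeping fits reproducible.
#' @noRd
.oblimin_rotate <- function(a, maxit = 1000L, eps = 1e-6, n_starts = 10L) {
  k <- ncol(a)
  if (k == 1)
    return(list(loadings = a, phi = matrix(1, 1, 1), converged = TRUE))
  starts <- c(list(diag(k)), with_seed(285714L, lapply(
    seq_len(n_starts - 1),
    function(i) qr.Q(qr(matrix(stats::rnorm(k * k), k))))))
  best <- NULL
  for (t0 in starts) {
    cand <- tryCatch(.gpa_oblq(a, t0, maxit = maxit, eps = eps),
                     error = function(e) NULL)
    if (!is.null(cand) && (is.null(best) || cand$f < best$f - 1e-10))
      best <- cand
  }
  if (is.null(best)) stop("oblimin rotation failed from every start")
  best
}

#' One gradient-projection run from a given rotation start
#' @noRd
.gpa_oblq <- function(a, tmat, maxit = 1000L, eps = 1e-6) {
  k <- ncol(a)
  al <- 1
  l <- a %*% t(solve(tmat))
  vg <- .quartimin_vgQ(l)
  f <- vg$f
  g <- -t(t(l) %*% vg$Gq %*% solve(tmat))
  converged <- FALSE
  for (iter in seq_len(maxit)) {
    gp <- g - tmat %*% diag(colSums(tmat * g), k)
    s <- sqrt(sum(gp^2))
    if (s < eps) {
      converged <- TRUE
      break
    }
    al <- 2 * al
    for (i in 0:10) {
      x <- tmat - al * gp
      tmatt <- x %*% diag(1 / sqrt(colSums(x^2)), k)
      l <- a %*% t(solve(tmatt))
      vgt <- .quartimin_vgQ(l)
      if (vgt$f < f - 0.5 * s^2 * al) break
      al <- al / 2
    }
    tmat <- tmatt
    f <- vgt$f
    g <- -t(t(l) %*% vgt$Gq %*% solve(tmat))
  }
  list(loadings = l, phi = crossprod(tmat), converged = converged, f = f)
}

#' Fit an exploratory factor model (minres extraction, oblimin rotation)
#'
#' Uniquenesses are estimated by minimizing the sum of squared off-diagonal
#' residuals of the correlation matrix (minimum-residual / unweighted least
#' squares), with loadings from the leading eigenstructure of the reduced
#' correlation matrix. The unrotated solution is then rotated by direct
#' oblimin with gamma = 0 (quartimin) via oblique gradient projection,
#' yielding a pattern matrix and factor correlations. Factors are ordered by
#' descending variance explained and signed so each factor's largest-|loading|
#' entry is positive. Heywood cases (communality > 1) are clamped to 0.995
#' with a warning.
#'
#' @param x an n x p data matrix / data.frame (complete; a `GEOID` column is
#'   ignored) or a p x p correlation matrix.
#' @param k number of factors (1 <= k < p).
#' @param rotation `"oblimin"` (default) or `"none"`.
#' @param heywood `"clamp"` (default) or `"stop"`.
#' @return object of class `factor_model`: list with `loadings` (p x k
#'   pattern), `factor_corr`, `uniquenesses`, `communalities`, `eigenvalues`
#'   (of the observed correlation matrix), `variance_explained` (per-factor
#'   proportions), `cumulative_variance`, `rms_residual`, `offdiag_fit`,
#'   `rotation`, `extraction`, `r` (the correlation matrix), `n_obs`,
#'   `converged`.
#' @examples
#' r <- diag(5)
#' r[r == 0] <- 0.64
#' fit_efa(r, k = 1)$loadings
#' @export
fit_efa <- function(x, k, rotation = c("oblimin", "none"),
                    heywood = c("clamp", "stop")) {
  rotation <- match.arg(rotation)
  heywood <- match.arg(heywood)
  inp <- .input_corr(x)
  r <- inp$r
  p <- ncol(r)
  stopifnot(k >= 1, k < p)

  # start uniquenesses at 1 - squared multiple correlation
  smc <- tryCatch(1 - 1 / diag(solve(r)), error = function(e) rep(0.5, p))
  start <- pmin(pmax(1 - smc, 0.005), 1)
  opt <- stats::optim(start, .minres_objective, r = r, k = k,
                      method = "L-BFGS-B", lower = 0.005, upper = 1,
                      control = list(maxit = 1000, factr = 1e7))
  if (opt$convergence != 0)
    stop("minres extraction did not converge: code ", opt$convergence,
         " (", opt$message, ")")
  l0 <- .minres_loadings(r, opt$par, k)

  h2 <- rowSums(l0^2)
  if (any(h2 > 1)) {
    if (heywood == "stop")
      stop("Heywood case: communality > 1 for ",
           paste(rownames(r)[h2 > 1], collapse = ", "))
    warning("Heywood case: clamping ", sum(h2 > 1),
            " communality(ies) to 0.995")
    bad <- h2 > 1
    l0[bad, ] <- l0[bad, , drop = FALSE] * sqrt(0.995 / h2[bad])
    h2 <- rowSums(l0^2)
  }

  if (rotation == "oblimin") {
    rot <- .oblimin_rotate(l0)
    lambda <- rot$loadings
    phi <- rot$phi
    converged <- rot$converged
  } else {
    lambda <- l0
    phi <- diag(k)
    converged <- TRUE
  }

  # order by descending variance explained, sign so the largest-|loading|
  # entry of each pattern column is positive
  ss <- diag(phi %*% crossprod(lambda))
  ord <- order(ss, decreasing = TRUE)
  lambda <- lambda[, ord, drop = FALSE]
  phi <- phi[ord, ord, drop = FALSE]
  ss <- ss[ord]
  flip <- vapply(seq_len(k), function(j) {
    v <- lambda[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  lambda <- sweep(lambda, 2, flip, "*")
  phi <- diag(flip, k) %*% phi %*% diag(flip, k)

  dimnames(lambda) <- list(rownames(r), sprintf("factor_%d", seq_len(k)))
  dimnames(phi) <- list(colnames(lambda), colnames(lambda))
  psi <- 1 - h2
  names(psi) <- rownames(r)

  fitstats <- .residual_fit(r, lambda, phi)
  eigs <- eigen(r, symmetric = TRUE, only.values = TRUE)$values

  structure(list(
    loadings = lambda, factor_corr = phi, uniquenesses = psi,
    communalities = h2, eigenvalues = eigs,
    variance_explained = ss / p, cumulative_variance = sum(ss) / p,
    rms_residual = fitstats$rms, offdiag_fit = fitstats$fit,
    rotation = rotation, extraction = "minres",
    r = r, n_obs = inp$n_obs, converged = converged
  ), class = "factor_model")
}

#' Off-diagonal residual fit statistics
#' @noRd
.residual_fit <- function(r, lambda, phi) {
  rep_r <- lambda %*% phi %*% t(lambda)
  res <- r - rep_r
  off <- upper.tri(r)
  list(rms = sqrt(mean(res[off]^2)),
       fit = 1 - sum(res[off]^2) / sum(r[off]^2))
}

#' @export
print.factor_model <- function(x, digits = 2, ...) {
  k <- ncol(x$loadings)
  cat("Factor model:", x$extraction, "extraction,", x$rotation,
      "rotation,", k, "factor(s)\n")
  cat(sprintf("  variance explained: %s (cumulative %.2f)\n",
              paste(round(x$variance_explained, digits), collapse = ", "),
              x$cumulative_variance))
  cat(sprintf("  rms residual %.4f, off-diagonal fit %.4f\n",
              x$rms_residual, x$offdiag_fit))
  cat("\nPattern loadings (|loading| >= 0.3 shown):\n")
  l <- round(x$loadings, digits)
  ltxt <- ifelse(abs(x$loadings) >= 0.3, format(l), "")
  print(ltxt, quote = FALSE)
  if (k > 1) {
    cat("\nFactor correlations:\n")
    print(round(x$factor_corr, digits))
  }
  invisible(x)
}

#' Factor-number diagnostics
#'
#' Returns the eigenvalues of the observed correlation matrix, the Kaiser
#' count (number of eigenvalues >= 1), a scree-elbow suggestion (the point of
#' maximum acceleration — largest discrete second difference — of the
#' log-eigenvalue scree, minus one), and for each candidate k the fitted
#' model's cumulative variance, RMS off-diagonal residual, and off-diagonal
#' fit.
#'
#' @param x data matrix or correlation matrix (as in [fit_efa()]).
#' @param k_max largest factor count to fit (< p).
#' @return list with `eigenvalues`, `kaiser_count`, `scree_elbow`, and `fits`
#'   (data.frame: k, cumulative_variance, rms_residual, offdiag_fit).
#' @export
factor_diagnostics <- function(x, k_max) {
  inp <- .input_corr(x)
  r <- inp$r
  p <- ncol(r)
  stopifnot(k_max >= 1, k_max < p)
  eigs <- eigen(r, symmetric = TRUE, only.values = TRUE)$values

  kaiser <- sum(eigs >= 1)

  pos <- eigs[eigs > 1e-12]
  le <- log(pos)
  elbow <- NA_integer_
  if (length(le) >= 3) {
    acc <- le[-c(1, 2)] + le[seq_len(length(le) - 2)] -
      2 * le[-c(1, length(le))]
    if (any(acc > 0)) elbow <- which.max(acc) # acc[j-1] is curvature at j
  }

  fits <- do.call(rbind, lapply(seq_len(k_max), function(k) {
    fit <- suppressWarnings(fit_efa(r, k))
    data.frame(k = k, cumulative_variance = fit$cumulative_variance,
               rms_residual = fit$rms_residual,
               offdiag_fit = fit$offdiag_fit)
  }))
  list(eigenvalues = eigs, kaiser_count = kaiser, scree_elbow = elbow,
       fits = fits)
}

#' Regression (Thurstone) factor scores
#'
#' Scores are `X_std W` with weights `W = R^-1 Lambda Phi` (the structure
#' matrix premultiplied by the inverse correlation matrix). If R is singular
#' it is ridge-regularized with lambda = 1e-8 and a warning. The input is
#' standardized column-wise before scoring.
#'
#' @param model a `factor_model`.
#' @param x n x p data matrix or data.frame with the model's variables (a
#'   `GEOID` column, if present, keys the result rows).
#' @return object of class `factor_scores`: a data.frame with optional GEOID
#'   and one column per factor; attribute `scoring_method` =
#'   `"regression"`.
#' @export
compute_scores <- function(model, x) {
  stopifnot(inherits(model, "factor_model"))
  geoid <- NULL
  if (is.data.frame(x) && "GEOID" %in% names(x)) {
    geoid <- x$GEOID
    x <- x[setdiff(names(x), "GEOID")]
  }
  m <- as.matrix(x)
  if (anyNA(m)) stop("input matrix has missing values; impute first")
  vars <- rownames(model$loadings)
  if (!setequal(colnames(m), vars))
    stop("matrix columns do not match the model's variables")
  m <- m[, vars, drop = FALSE]
  m <- scale(m)

  s <- model$loadings %*% model$factor_corr
  w <- tryCatch(solve(model$r, s), error = function(e) {
    warning("singular correlation matrix; ridge-regularizing (1e-8)")
    solve(model$r + diag(1e-8, ncol(model$r)), s)
  })
  sc <- m %*% w
  colnames(sc) <- colnames(model$loadings)
  out <- as.data.frame(sc)
  if (!is.null(geoid)) out <- cbind(GEOID = geoid, out,
                                    stringsAsFactors = FALSE)
  structure(out, scoring_method = "regression", class = c("factor_scores",
                                                          "data.frame"))
}

#' Pearson correlations among factor scores
#'
#' @param scores a `factor_scores` (or any data.frame of score columns;
#'   `GEOID` ignored).
#' @return k x k Pearson correlation matrix with unit diagonal; entries
#'   involving a constant column are NA.
#' @export
score_correlations <- function(scores) {
  m <- as.matrix(scores[setdiff(names(scores), "GEOID")])
  if (nrow(m) < 3) stop("need at least 3 rows")
  const <- apply(m, 2, stats::sd) == 0
  rc <- suppressWarnings(stats::cor(m))
  rc[const, ] <- NA_real_
  rc[, const] <- NA_real_
  diag(rc) <- 1
  rc
}

#' Tucker congruence between two loading vectors or matrices
#'
#' Column-wise cosine similarity, the standard metric for matching factors
#' across solutions.
#'
#' @param a,b numeric vectors or p x k matrices (matched column-wise).
#' @return numeric vector of per-column congruence coefficients.
#' @export
tucker_congruence <- function(a, b) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  stopifnot(dim(a) == dim(b))
  colSums(a * b) / sqrt(colSums(a^2) * colSums(b^2))
}

#' Align the columns of a loading matrix to a reference
#'
#' Solves the column-assignment problem maximizing total |Tucker congruence|
#' (exhaustive search over the k! permutations; k <= 8), then flips signs so
#' congruence with the reference is positive.
#'
#' @param loadings p x k matrix to align.
#' @param reference p x k reference loadings.
#' @return list with `loadings` (aligned), `perm`, `signs`, `congruence`
#'   (per-factor, after alignment).
#' @export
align_factors <- function(loadings, reference) {
  k <- ncol(reference)
  stopifnot(ncol(loadings) == k, k <= 8)
  cmat <- matrix(0, k, k)
  for (j in seq_len(k))
    cmat[, j] <- tucker_congruence(
      loadings[, rep(j, k), drop = FALSE], reference)
  # cmat[i, j]: congruence of candidate column j with reference column i
  perms <- .permutations(k)
  tot <- apply(perms, 1, function(pp) sum(abs(cmat[cbind(seq_len(k), pp)])))
  best <- perms[which.max(tot), ]
  cong <- cmat[cbind(seq_len(k), best)]
  signs <- ifelse(cong < 0, -1, 1)
  aligned <- sweep(loadings[, best, drop = FALSE], 2, signs, "*")
  dimnames(aligned) <- dimnames(reference)
  list(loadings = aligned, perm = best, signs = signs,
       congruence = abs(cong))
}

#' All permutations of 1..k as rows
#' @noRd
.permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Bootstrap standard errors of factor loadings
#'
#' Resamples rows with replacement, refits the factor model, aligns each
#' resample's factors to the reference fit by maximum total |Tucker
#' congruence| with sign flips, and reports the standard deviation of each
#' aligned loading across resamples. Resamples whose fit fails are dropped
#' and counted; more than 5% dropped is an error.
#'
#' @param x n x p complete data matrix or data.frame.
#' @param k number of factors.
#' @param n_boot number of bootstrap resamples (default 2000).
#' @param seed integer seed; fixed seed gives identical results.
#' @return object of class `bootstrap_stability`: list with `loading_se`
#'   (p x k), `n_boot`, `n_dropped`, `alignment_congruence` (per-factor
#'   minimum and median across resamples).
#' @export
bootstrap_loading_se <- function(x, k, n_boot = 2000, seed = 1) {
  stopifnot(n_boot >= 2)
  if (is.data.frame(x)) x <- x[setdiff(names(x), "GEOID")]
  m <- as.matrix(x)
  ref <- fit_efa(m, k)
  with_seed(seed, {
    boots <- vector("list", n_boot)
    congs <- matrix(NA_real_, n_boot, k)
    dropped <- 0L
    for (b in seq_len(n_boot)) {
      idx <- sample.int(nrow(m), replace = TRUE)
      fit <- tryCatch(suppressWarnings(fit_efa(m[idx, , drop = FALSE], k)),
                      error = function(e) NULL)
      if (is.null(fit)) {
        dropped <- dropped + 1L
        next
      }
      al <- align_factors(fit$loadings, ref$loadings)
      boots[[b]] <- al$loadings
      congs[b, ] <- al$congruence
    }
    if (dropped > 0.05 * n_boot)
      stop(dropped, " of ", n_boot, " bootstrap resamples failed to fit")
    keep <- !vapply(boots, is.null, logical(1))
    arr <- simplify2array(boots[keep])
    se <- apply(arr, c(1, 2), stats::sd)
    dimnames(se) <- dimnames(ref$loadings)
    congs <- congs[keep, , drop = FALSE]
    structure(list(
      loading_se = se, n_boot = n_boot, n_dropped = dropped,
      alignment_congruence = data.frame(
        factor = colnames(ref$loadings),
        min = apply(congs, 2, min),
        median = apply(congs, 2, stats::median)
      )
    ), class = "bootstrap_stability")
  })
}

#' @export
print.bootstrap_stability <- function(x, ...) {
  cat("Bootstrap loading stability:", x$n_boot, "resamples (",
      x$n_dropped, "dropped )\n")
  cat("  max loading SE:", round(max(x$loading_se), 4), "\n")
  cat("  per-factor alignment congruence (min / median):\n")
  print(x$alignment_congruence, row.names = FALSE)
  invisible(x)
}
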