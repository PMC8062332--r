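#' Mean semantic distance across spaces
#'
#' The simple aggregate score: the arithmetic mean of the non-missing
#' per-space distances for a response, emitted only when at least
#' `min_spaces` spaces contributed.
#'
#' @param values numeric vector (or one row) of per-space distances, `NA`
#'   for missing.
#' @param min_spaces minimum number of non-missing distances required
#'   (default 1).
#' @return The mean, or `NA_real_`.
#' @export
semdis_mean <- function(values, min_spaces = 1L) {
  v <- as.numeric(values)
  ok <- !is.na(v)
  if (sum(ok) >= min_spaces && sum(ok) > 0L) mean(v[ok]) else NA_real_
}

#' Maximum-likelihood discrepancy of a one-factor model
#'
#' The ML fit function for a covariance structure `Sigma = lambda lambda' +
#' diag(psi)` against a sample covariance `S`:
#' `F = log|Sigma| + tr(S Sigma^-1) - log|S| - p`.
#' Non-negative, and exactly 0 when `S` equals the implied covariance.
#'
#' @param S p x p sample covariance matrix (positive definite).
#' @param loadings numeric vector of p loadings.
#' @param uniquenesses numeric vector of p positive uniquenesses.
#' @return The scalar discrepancy.
#' @export
fml_discrepancy <- function(S, loadings, uniquenesses) {
  p <- nrow(S)
  stopifnot(length(loadings) == p, length(uniquenesses) == p)
  Sigma <- tcrossprod(loadings) + diag(uniquenesses, p)
  cS <- chol(S)
  cSig <- chol(Sigma)
  ldS <- 2 * sum(log(diag(cS)))
  ldSig <- 2 * sum(log(diag(cSig)))
  ldSig + sum(diag(chol2inv(cSig) %*% S)) - ldS - p
}

#' Fit a one-factor maximum-likelihood model to per-space distances
#'
#' Estimates the single-factor model `x = lambda f + e` with factor
#' variance fixed at 1 and all loadings free, by minimizing the ML
#' discrepancy [fml_discrepancy()] between the sample covariance of the
#' per-space distances and the implied covariance
#' `lambda lambda' + diag(psi)`. The fit is on the covariance of the raw
#' distances (indicators are not standardized first). Rows containing any
#' missing value are removed listwise before fitting.
#'
#' Identification: factor variance 1, sign fixed by requiring the first
#' loading to be non-negative (factor sign is arbitrary). Initialization is
#' deterministic, from a principal-axis solution with squared-multiple-
#' correlation communality starts, so repeated fits are bit-stable.
#' Uniquenesses are optimized on the log scale, keeping them positive; a
#' solution pinned against the boundary (a Heywood case) or a failed
#' optimizer is flagged `converged = FALSE` and factor scores are withheld.
#'
#' @param X numeric matrix or data frame, n rows (responses) by p columns
#'   (spaces), p >= 3, n > p after listwise deletion.
#' @return An object of class `semdis_factor_model`: `space_names`,
#'   `loadings`, `uniquenesses`, `sample_mean`, `implied_covariance`,
#'   `discrepancy`, `converged`, `n_used`, `heywood`.
#' @export
fit_one_factor <- function(X) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("X must be numeric", call. = FALSE)
  p <- ncol(X)
  if (p < 3L)
    stop("one-factor model is under-identified with fewer than 3 ",
         "indicators (got ", p, ")", call. = FALSE)
  space_names <- colnames(X)
  if (is.null(space_names)) space_names <- paste0("V", seq_len(p))
  keep <- stats::complete.cases(X)
  X <- X[keep, , drop = FALSE]
  n <- nrow(X)
  if (n <= p)
    stop("need more complete rows (", n, ") than indicators (", p, ")",
         call. = FALSE)
  S <- stats::cov(X)
  xbar <- colMeans(X)

  model <- list(space_names = space_names, loadings = rep(NA_real_, p),
                uniquenesses = rep(NA_real_, p), sample_mean = xbar,
                implied_covariance = NULL, discrepancy = NA_real_,
                converged = FALSE, n_used = n, heywood = FALSE)
  class(model) <- "semdis_factor_model"

  # degenerate S (rank-deficient / non-PD): flag, no scores
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= max(ev) * 1e-10 || min(ev) <= 0) return(model)

  sds <- sqrt(diag(S))
  R <- stats::cov2cor(S)
  # principal-axis start: SMC communalities, first eigenpair of reduced R
  smc <- 1 - 1 / diag(solve(R))
  Rh <- R
  diag(Rh) <- pmin(pmax(smc, 0.05), 0.95)
  e1 <- eigen(Rh, symmetric = TRUE)
  l0_cor <- sqrt(max(e1$values[1], 0.1)) * e1$vectors[, 1]
  if (l0_cor[1] < 0) l0_cor <- -l0_cor
  l0 <- l0_cor * sds
  psi0 <- pmax(diag(S) - l0^2, 0.05 * diag(S))

  obj <- function(par) {
    lam <- par[1:p]
    psi <- exp(par[(p + 1):(2 * p)])
    f <- tryCatch(fml_discrepancy(S, lam, psi), error = function(e) NA_real_)
    if (!is.finite(f)) 1e10 else f
  }
  fit <- stats::nlminb(c(l0, log(psi0)), obj,
                       control = list(iter.max = 500, eval.max = 1000,
                                      abs.tol = 1e-12))
  lam <- fit$par[1:p]
  psi <- exp(fit$par[(p + 1):(2 * p)])
  if (lam[1] < 0) lam <- -lam

  heywood <- any(psi < 1e-6 * diag(S))
  # nlminb reports "false convergence" at machine-precision minima of a
  # near-zero objective; an exact fit (F ~ 0) is accepted regardless
  ok <- (fit$convergence == 0 || fit$objective < 1e-8) &&
    all(is.finite(lam)) && all(psi > 0) && !heywood
  model$loadings <- stats::setNames(lam, space_names)
  model$uniquenesses <- stats::setNames(psi, space_names)
  model$implied_covariance <- tcrossprod(lam) + diag(psi, p)
  dimnames(model$implied_covariance) <- list(space_names, space_names)
  model$discrepancy <- fit$objective
  model$heywood <- heywood
  model$converged <- ok
  model
}

#' @export
print.semdis_factor_model <- function(x, ...) {
  cat(sprintf("<one-factor model: %d indicators, n = %d, %s>\n",
              length(x$loadings), x$n_used,
              if (x$converged) "converged"
              else if (x$heywood) "Heywood case (not converged)"
              else "not converged"))
  if (all(is.finite(x$loadings))) {
    m <- cbind(loading = x$loadings, uniqueness = x$uniquenesses)
    print(round(m, 4))
  }
  invisible(x)
}

#' Regression (Thurstone) factor scores from a fitted one-factor model
#'
#' Per-response latent scores `f = lambda' Sigma^-1 (x - xbar)`, using the
#' model-implied covariance `Sigma` and the fitting-sample mean `xbar`.
#' Rows with any missing indicator receive `NA` (a response missing any
#' space cannot receive a factor score). The mean of emitted scores over
#' the fitted rows is 0 by construction.
#'
#' @param model a converged [fit_one_factor()] result.
#' @param X n x p matrix of per-space distances, columns in model order.
#' @return Numeric vector of length n with `NA` for incomplete rows.
#' @export
factor_scores <- function(model, X) {
  stopifnot(inherits(model, "semdis_factor_model"))
  if (!model$converged)
    stop("factor scores withheld: model did not converge", call. = FALSE)
  X <- as.matrix(X)
  p <- length(model$loadings)
  if (ncol(X) != p)
    stop("X has ", ncol(X), " columns but the model has ", p,
         " indicators", call. = FALSE)
  w <- solve(model$implied_covariance, model$loadings)  # Sigma^-1 lambda
  ctr <- sweep(X, 2, model$sample_mean)
  scores <- as.numeric(ctr %*% w)
  scores[!stats::complete.cases(X)] <- NA_real_
  scores
}

#' Append aggregate scores to a score table
#'
#' Adds `semdis_mean` (mean of non-missing per-space distances) and, when
#' requested and at least three spaces are registered, `semdis_factor`
#' (regression scores from a one-factor ML model fitted to the complete
#' rows of this table). Rows with any missing space get a mean (subject to
#' `min_spaces`) but no factor score.
#'
#' @param scores tibble from [score_table()].
#' @param emit subset of `c("mean", "factor")`.
#' @param min_spaces_for_mean minimum non-missing spaces for the mean.
#' @return `scores` with aggregate columns appended; when a factor model
#'   was fitted it is attached as attribute `"factor_model"`.
#' @export
aggregate_scores <- function(scores, emit = c("mean", "factor"),
                             min_spaces_for_mean = 1L) {
  emit <- match.arg(emit, c("mean", "factor"), several.ok = TRUE)
  cols <- distance_columns(scores)
  if (!length(cols)) stop("no `_dis` columns in `scores`", call. = FALSE)
  D <- as.matrix(scores[, cols, drop = FALSE])
  if ("mean" %in% emit)
    scores$semdis_mean <- apply(D, 1, semdis_mean,
                                min_spaces = min_spaces_for_mean)
  if ("factor" %in% emit) {
    if (length(cols) < 3L)
      stop("factor score requires >= 3 registered spaces (got ",
           length(cols), ")", call. = FALSE)
    model <- fit_one_factor(D)
    if (model$converged) {
      scores$semdis_factor <- factor_scores(model, D)
    } else {
      scores$semdis_factor <- NA_real_
      warning("one-factor model did not converge; semdis_factor withheld",
              call. = FALSE)
    }
    attr(scores, "factor_model") <- model
  }
  scores
}

#' Elaboration-bias diagnostic
#'
#' Pearson correlation between response word count (elaboration) and a
#' chosen semantic-distance score. Additive composition tends to penalize
#' longer responses (negative r); multiplicative composition tends to
#' reward them (positive r) -- this diagnostic makes the direction of the
#' bias visible for a scored table.
#'
#' @param scores tibble from [score_table()] (with aggregates appended if
#'   `which` names one).
#' @param which `"mean"`, `"factor"`, or a space name (matching a
#'   `<space>_dis` column).
#' @return List with `r` (Pearson correlation) and `n` (pairs used).
#' @export
elaboration_diagnostic <- function(scores, which = "mean") {
  col <- switch(which,
                mean = "semdis_mean",
                factor = "semdis_factor",
                paste0(which, "_dis"))
  if (!col %in% names(scores))
    stop("score column not found: ", col, call. = FALSE)
  wc <- scores$word_count
  y <- scores[[col]]
  ok <- !is.na(wc) & !is.na(y)
  if (sum(ok) < 3L)
    stop("need at least 3 non-missing (word_count, score) pairs",
         call. = FALSE)
  if (stats::var(wc[ok]) == 0)
    stop("word_count has zero variance; correlation undefined",
         call. = FALSE)
  list(r = stats::cor(wc[ok], y[ok]), n = sum(ok))
}

#' Aggregate response-level scores to the participant-by-item level
#'
#' Person-level indicators are the per-participant-per-item mean of the
#' response-level scores, the transparent default for building
#' subject-level creativity measures from trial-level distances.
#'
#' @param scores tibble with `id`, `item` and score columns.
#' @param cols columns to aggregate; default all `_dis` plus any
#'   `semdis_*` columns present.
#' @param fun aggregation function over non-missing values (default mean).
#' @return Tibble with one row per `id` x `item`.
#' @export
person_level <- function(scores, cols = NULL, fun = mean) {
  if (is.null(cols))
    cols <- c(distance_columns(scores),
              intersect(c("semdis_mean", "semdis_factor"), names(scores)))
  agg <- stats::aggregate(
    scores[, cols, drop = FALSE],
    by = list(id = scores$id, item = scores$item),
    FUN = function(v) if (all(is.na(v))) NA_real_ else fun(v[!is.na(v)]))
  tibble::as_tibble(agg[order(agg$id, agg$item), , drop = FALSE])
}
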