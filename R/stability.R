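# L1-regularized logistic modeling with stability selection.
#
# The objective is the sum of logistic losses over samples plus an L1
# penalty, min over (alpha, c) of
#   sum_l log(1 + exp(-y_l (x_l' alpha + c))) + lambda ||alpha||_1 ,
# with labels y in {-1, +1}. Fits are delegated to glmnet, whose binomial
# deviance is scaled by 1/n, so a penalty of `lambda` on the sum-loss scale
# corresponds to glmnet's `lambda / n`.

#' Configuration for L1 + stability-selection fits
#'
#' @param lambda_grid Optional vector of penalty values on the sum-loss
#'   scale; when `NULL` a 10-point grid is computed from the data, spanning
#'   three decades below the smallest lambda with empty support.
#' @param n_resamples Number of stability-selection resampling rounds
#'   (default 500).
#' @param subsample_fraction Fraction of samples drawn (without replacement,
#'   class-stratified) per round.
#' @param selection_threshold Minimum selection frequency for a feature to be
#'   retained.
#' @param n_lambda,lambda_min_ratio Grid size and span used when
#'   `lambda_grid` is computed from data.
#' @param selection_min_ratio Lower end (relative to the largest grid lambda)
#'   of the penalty region over which a feature counts as selected in a
#'   resampling round. Per-round supports must stay sparse for selection
#'   frequencies to be informative, so only the strongly penalized top of the
#'   path (default: one decade, 0.1) is used for counting; the full grid is
#'   still used for the CV-tuned predictive refit.
#' @param per_round_cap Maximum number of features counted as selected per
#'   round: the first `per_round_cap` features to enter the path (ties at one
#'   lambda all count). `NULL` (default) sizes the cap as
#'   `ceiling(sqrt(0.8 * p))`, which bounds the expected number of stably
#'   selected false positives at roughly one for thresholds above 0.5.
#' @param method `"stability"` (default) or `"plain"`: plain skips
#'   resampling and takes the support of a single 2-fold-CV-tuned L1 fit,
#'   useful for contrasting false-positive behaviour.
#' @param seed Integer seed controlling subsampling and fold assignment.
#' @return A list of class `l1_config`.
#' @export
l1_config <- function(lambda_grid = NULL, n_resamples = 500L,
                      subsample_fraction = 0.5, selection_threshold = 0.6,
                      n_lambda = 10L, lambda_min_ratio = 1e-3,
                      selection_min_ratio = 0.1, per_round_cap = NULL,
                      method = c("stability", "plain"), seed = 1L) {
  stopifnot(n_resamples >= 1L, subsample_fraction > 0, subsample_fraction <= 1,
            selection_threshold > 0, selection_threshold <= 1,
            selection_min_ratio > 0, selection_min_ratio <= 1)
  if (!is.null(lambda_grid) && !length(lambda_grid)) {
    stop("lambda grid must be non-empty", call. = FALSE)
  }
  structure(
    list(lambda_grid = lambda_grid, n_resamples = as.integer(n_resamples),
         subsample_fraction = subsample_fraction,
         selection_threshold = selection_threshold,
         n_lambda = as.integer(n_lambda), lambda_min_ratio = lambda_min_ratio,
         selection_min_ratio = selection_min_ratio,
         per_round_cap = if (!is.null(per_round_cap)) as.integer(per_round_cap),
         method = match.arg(method), seed = as.integer(seed)),
    class = "l1_config"
  )
}

# Smallest sum-loss-scale lambda with empty support, from the gradient of
# the logistic loss at alpha = 0 (intercept at the class log-odds).
lambda_max_sumloss <- function(X, y) {
  y01 <- (y + 1) / 2
  z <- y01 - mean(y01)
  max(abs(crossprod(X, z)))
}

lambda_grid_from_data <- function(X, y, n_lambda = 10L, min_ratio = 1e-3) {
  lmax <- lambda_max_sumloss(X, y)
  if (lmax <= 0) lmax <- 1
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = n_lambda))
}

# glmnet wants >= 2 columns; pad single-column designs with an all-zero
# column that can never be selected.
.pad1 <- function(X) {
  if (ncol(X) >= 2L) return(list(X = X, padded = FALSE))
  list(X = cbind(X, 0), padded = TRUE)
}

# Robust glmnet path fit: glmnet rejects designs whose usable predictors all
# have zero variance and classes with fewer than two members, both of which
# happen legitimately on small subsamples. Constant columns are dropped and
# coefficients mapped back to the input columns; NULL signals "no fit".
path_fit <- function(X, yf, lam_g, thresh = 1e-7) {
  p <- ncol(X)
  keep <- which(vapply(seq_len(p), function(j) {
    x <- X[, j]
    any(x != x[1L])
  }, logical(1)))
  if (!length(keep)) return(NULL)
  Xk <- X[, keep, drop = FALSE]
  padded <- ncol(Xk) < 2L
  if (padded) Xk <- cbind(Xk, 0)
  fit <- tryCatch(
    suppressWarnings(
      glmnet::glmnet(Xk, yf, family = "binomial", lambda = lam_g,
                     standardize = FALSE, thresh = thresh)
    ),
    error = function(e) NULL
  )
  if (is.null(fit) || ncol(fit$beta) != length(lam_g)) return(NULL)
  beta <- matrix(0, p, length(lam_g))
  beta[keep, ] <- as.matrix(fit$beta)[seq_along(keep), , drop = FALSE]
  list(beta = beta, a0 = as.numeric(fit$a0))
}

#' Fit one L1-regularized logistic regression
#'
#' Minimizes the sum-loss objective at a single penalty `lam` (sum-loss
#' scale). The solve runs down a short warm-start path ending at `lam` for
#' numerical stability.
#'
#' @param X Numeric design matrix (binary indicator features).
#' @param y Labels in `{-1, +1}`.
#' @param lam Penalty on the sum-loss scale (glmnet lambda times `n`).
#' @return A list: `weights` (may be exactly zero), `intercept`, `lambda`.
#' @export
fit_l1_logistic <- function(X, y, lam) {
  if (!ncol(X)) stop("empty design matrix", call. = FALSE)
  if (!any(y == 1L) || !any(y == -1L)) {
    stop("both classes must be present", call. = FALSE)
  }
  n <- nrow(X)
  pad <- .pad1(X)
  lam_g <- lam / n
  start <- max(lambda_max_sumloss(X, y) / n, lam_g * 10)
  path <- unique(sort(c(exp(seq(log(start), log(lam_g), length.out = 5L)),
                        lam_g), decreasing = TRUE))
  fit <- glmnet::glmnet(pad$X, factor(y, levels = c(-1, 1)),
                        family = "binomial", lambda = path,
                        standardize = FALSE, thresh = 1e-10)
  beta <- as.numeric(fit$beta[, ncol(fit$beta)])
  if (pad$padded) beta <- beta[1L]
  list(weights = beta, intercept = fit$a0[[length(fit$a0)]], lambda = lam)
}

# Deterministic 2-fold-CV choice of lambda and refit on the full data.
# (cv.glmnet insists on >= 3 folds, so the 2-fold internal loop is explicit.)
# Returns weights/intercept at the CV-selected grid lambda (sum-loss scale).
refit_cv <- function(X, y, lambda_grid, seed) {
  n <- nrow(X)
  lam_g <- sort(unique(lambda_grid / n), decreasing = TRUE)
  yf <- factor(y, levels = c(-1, 1))
  y01 <- (y + 1) / 2
  foldid <- with_seed(derive_seed(seed, 77L), stratified_folds(y, 2L))

  dev <- numeric(length(lam_g))
  scored <- FALSE
  for (f in 1:2) {
    tr <- foldid != f
    if (min(table(factor(y[tr], levels = c(-1, 1)))) < 2L) next
    pf <- path_fit(X[tr, , drop = FALSE], yf[tr], lam_g)
    if (is.null(pf)) next
    eta <- sweep(X[!tr, , drop = FALSE] %*% pf$beta, 2L, pf$a0, `+`)
    prob <- pmin(pmax(stats::plogis(eta), 1e-12), 1 - 1e-12)
    ll <- y01[!tr] * log(prob) + (1 - y01[!tr]) * log(1 - prob)
    dev <- dev - 2 * colSums(ll)
    scored <- TRUE
  }
  # degenerate folds: fall back to the middle of the grid
  k <- if (scored) which.min(dev) else as.integer(ceiling(length(lam_g) / 2))

  pf <- path_fit(X, yf, lam_g, thresh = 1e-9)
  if (is.null(pf)) {
    return(list(weights = rep(0, ncol(X)),
                intercept = stats::qlogis(mean(y01)),
                lambda = lam_g[k] * n))
  }
  list(weights = pf$beta[, k], intercept = pf$a0[k], lambda = lam_g[k] * n)
}

#' Feature selection by stability selection (or a plain L1 fit)
#'
#' For each resampling round a class-stratified half-sample (fraction
#' configurable) is drawn without replacement and an L1 path over the lambda
#' grid is fitted; a feature counts as selected in the round when its weight
#' is nonzero at any grid lambda. Features whose selection frequency reaches
#' `selection_threshold` form the selected set, and final coefficients come
#' from one 2-fold-CV-tuned refit on the full data restricted to that set.
#' With `method = "plain"` the selected set is simply the support of the
#' CV-tuned full-data fit (no resampling).
#'
#' @param X Binary design matrix.
#' @param y Labels in `{-1, +1}`.
#' @param cfg An [l1_config()].
#' @param descriptors Optional descriptor `data.frame` carried through to the
#'   result.
#' @return A list of class `stability_result`: `frequencies`, `selected`
#'   (column indices), `coefficients` (named, over the selected set),
#'   `intercept`, `lambda_grid`, `refit_lambda`, `descriptors`.
#' @export
stability_select <- function(X, y, cfg = l1_config(), descriptors = NULL) {
  if (!ncol(X)) stop("empty design matrix", call. = FALSE)
  if (is.null(cfg$lambda_grid)) {
    grid <- lambda_grid_from_data(X, y, cfg$n_lambda, cfg$lambda_min_ratio)
  } else {
    grid <- cfg$lambda_grid
  }
  if (!length(grid)) stop("empty lambda grid", call. = FALSE)
  n <- nrow(X)
  p <- ncol(X)
  yf <- factor(y, levels = c(-1, 1))
  lam_g <- sort(unique(grid / n), decreasing = TRUE)  # fixed across rounds

  if (cfg$method == "plain") {
    freq <- numeric(p)
    refit_all <- refit_cv(X, y, grid, cfg$seed)
    selected <- which(refit_all$weights != 0)
    freq[selected] <- 1
  } else {
    m <- ceiling(cfg$subsample_fraction * n)
    counts <- numeric(p)
    # selection region: strongly penalized top of the path only
    lam_sel <- lam_g[lam_g >= max(lam_g) * cfg$selection_min_ratio]
    if (!length(lam_sel)) lam_sel <- lam_g[1L]
    q <- cfg$per_round_cap %||% ceiling(sqrt(0.8 * p))
    with_seed(cfg$seed, {
      for (r in seq_len(cfg$n_resamples)) {
        idx <- stratified_sample(y, m)
        pf <- path_fit(X[idx, , drop = FALSE], yf[idx], lam_sel)
        if (is.null(pf)) next
        nz <- pf$beta != 0
        # path entry order; only the first q entrants count as selected
        entry <- rep(Inf, p)
        for (l in rev(seq_len(ncol(nz)))) entry[nz[, l]] <- l
        fin <- which(is.finite(entry))
        if (length(fin) > q) {
          cutoff <- sort(entry[fin], partial = q)[q]
          fin <- fin[entry[fin] <= cutoff]
        }
        counts[fin] <- counts[fin] + 1
      }
    })
    freq <- counts / cfg$n_resamples
    selected <- which(freq >= cfg$selection_threshold)
  }

  if (length(selected)) {
    refit <- refit_cv(X[, selected, drop = FALSE], y, grid, cfg$seed)
    coefs <- stats::setNames(refit$weights,
                             colnames(X)[selected] %||%
                               as.character(selected))
    intercept <- refit$intercept
    refit_lambda <- refit$lambda
  } else {
    coefs <- numeric(0)
    y01 <- (y + 1) / 2
    intercept <- stats::qlogis(mean(y01))
    refit_lambda <- NA_real_
  }

  structure(
    list(frequencies = freq, selected = selected, coefficients = coefs,
         intercept = intercept, lambda_grid = grid,
         refit_lambda = refit_lambda,
         descriptors = if (!is.null(descriptors)) {
           descriptors[seq_len(p), , drop = FALSE]
         }),
    class = "stability_result"
  )
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf(
    "stability_result: %d/%d features selected (max frequency %.2f)\n",
    length(x$selected), length(x$frequencies),
    if (length(x$frequencies)) max(x$frequencies) else 0
  ))
  invisible(x)
}

#' Rank features of a stability result
#'
#' Total order: selection frequency descending, then chi-squared p ascending,
#' then absolute refit coefficient descending, then descriptor label.
#'
#' @param res A `stability_result`.
#' @param pvals Per-feature chi-squared p-values aligned with
#'   `res$frequencies`.
#' @return Integer vector of feature indices, best first.
#' @export
rank_features <- function(res, pvals) {
  p <- length(res$frequencies)
  if (!p) stop("empty stability result", call. = FALSE)
  coef_full <- numeric(p)
  coef_full[res$selected] <- res$coefficients
  labels <- if (!is.null(res$descriptors)) res$descriptors$label else
    as.character(seq_len(p))
  order(-res$frequencies, pvals, -abs(coef_full), labels)
}

#' Export a stability result as CSV
#'
#' @param res A `stability_result` (with descriptors).
#' @param pvals Per-feature chi-squared p-values.
#' @param path Output file.
#' @export
write_stability_csv <- function(res, pvals, path) {
  p <- length(res$frequencies)
  coef_full <- numeric(p)
  coef_full[res$selected] <- res$coefficients
  tab <- data.frame(
    descriptor = if (!is.null(res$descriptors)) res$descriptors$label else
      as.character(seq_len(p)),
    frequency = res$frequencies,
    coefficient = coef_full,
    chi2_p = pvals,
    stringsAsFactors = FALSE
  )
  utils::write.csv(tab[order(-tab$frequency, tab$chi2_p), ], path,
                   row.names = FALSE)
  invisible(path)
}
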