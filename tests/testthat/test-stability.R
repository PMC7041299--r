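# L1 logistic fits, stability selection, feature ranking.

# sum-loss objective of the penalized logistic model
l1_objective <- function(X, y, w, c0, lam) {
  eta <- as.numeric(X %*% w + c0)
  sum(log1p(exp(-y * eta))) + lam * sum(abs(w))
}

# independent numeric minimizer: split w = u - v with u, v >= 0 so the
# penalty becomes linear and L-BFGS-B box constraints apply
oracle_l1_min <- function(X, y, lam) {
  p <- ncol(X)
  obj <- function(par) {
    u <- par[1:p]; v <- par[(p + 1):(2 * p)]; c0 <- par[2 * p + 1]
    eta <- as.numeric(X %*% (u - v) + c0)
    sum(log1p(exp(-y * eta))) + lam * sum(u + v)
  }
  grad <- function(par) {
    u <- par[1:p]; v <- par[(p + 1):(2 * p)]; c0 <- par[2 * p + 1]
    eta <- as.numeric(X %*% (u - v) + c0)
    s <- -y * stats::plogis(-y * eta)       # d loss / d eta
    gw <- as.numeric(crossprod(X, s))
    c(gw + lam, -gw + lam, sum(s))
  }
  fit <- stats::optim(rep(0, 2 * p + 1), obj, grad, method = "L-BFGS-B",
                      lower = c(rep(0, 2 * p), -Inf),
                      control = list(maxit = 500, factr = 1e3))
  fit$value
}

test_that("huge penalty shrinks all weights to zero, intercept to log-odds", {
  set.seed(41)
  X <- matrix(rbinom(200, 1, 0.4), nrow = 40)
  y <- rep(c(1L, -1L), each = 20)
  fit <- fit_l1_logistic(X, y, lam = 1e6)
  expect_equal(fit$weights, rep(0, 5))
  expect_equal(fit$intercept, qlogis(0.5), tolerance = 1e-6)
  y2 <- c(rep(1L, 30), rep(-1L, 10))
  fit2 <- fit_l1_logistic(X, y2, lam = 1e6)
  expect_equal(fit2$intercept, qlogis(0.75), tolerance = 1e-4)
})

test_that("weight sign follows the class direction at small penalty", {
  x <- c(rep(1, 20), rep(0, 20))
  y <- c(rep(1L, 20), rep(-1L, 20))
  fit <- fit_l1_logistic(cbind(x), y, lam = 1)
  expect_gt(fit$weights[1], 0)
  fit_neg <- fit_l1_logistic(cbind(x), -y, lam = 1)
  expect_lt(fit_neg$weights[1], 0)
})

test_that("solver objective matches an independent numeric minimizer", {
  set.seed(43)
  for (rep in 1:5) {
    X <- matrix(rbinom(100, 1, 0.5), nrow = 20)
    y <- ifelse(rbinom(20, 1, plogis(X[, 1] - X[, 2])) == 1, 1L, -1L)
    if (length(unique(y)) < 2) next
    lam <- runif(1, 0.5, 4)
    fit <- suppressWarnings(fit_l1_logistic(X, y, lam))  # tiny-n glmnet note
    ours <- l1_objective(X, y, fit$weights, fit$intercept, lam)
    best <- oracle_l1_min(X, y, lam)
    expect_equal(ours, best, tolerance = 1e-4)
  }
})

test_that("a label-identical feature is selected with frequency near 1", {
  set.seed(44)
  n <- 200
  y <- rep(c(1L, -1L), each = n / 2)
  signal <- as.integer(y == 1L)
  X <- cbind(signal, matrix(rbinom(n * 50, 1, 0.3), nrow = n))
  colnames(X) <- sprintf("f%d", 0:50)
  res <- stability_select(X, y, l1_config(n_resamples = 100L, seed = 2L))
  expect_gte(res$frequencies[1], 0.95)
  expect_true(1L %in% res$selected)
  expect_gt(res$coefficients[["f0"]], 0)
})

test_that("stability selection retains far fewer noise features than a plain path", {
  set.seed(45)
  n <- 200
  y <- rep(c(1L, -1L), each = n / 2)
  X <- matrix(rbinom(n * 50, 1, 0.3), nrow = n)
  res_st <- stability_select(X, y, l1_config(n_resamples = 100L, seed = 3L))
  # matched-lambda comparison: support of one full-data fit over the same
  # selection region of the path
  grid <- res_st$lambda_grid
  lam_sel <- grid[grid >= max(grid) * 0.1] / n
  fit <- glmnet::glmnet(X, factor(y, levels = c(-1, 1)), family = "binomial",
                        lambda = sort(lam_sel, decreasing = TRUE),
                        standardize = FALSE)
  plain_support <- sum(Matrix::rowSums(fit$beta != 0) > 0)
  expect_lt(length(res_st$selected), plain_support)
})

test_that("one full-sample round reduces to a single path fit's support", {
  set.seed(46)
  n <- 80
  y <- rep(c(1L, -1L), each = n / 2)
  X <- cbind(as.integer(y == 1L), matrix(rbinom(n * 5, 1, 0.4), nrow = n))
  cfg <- l1_config(n_resamples = 1L, subsample_fraction = 1,
                   selection_threshold = 1, selection_min_ratio = 1e-3,
                   per_round_cap = ncol(X), seed = 9L)
  res <- stability_select(X, y, cfg)
  grid <- res$lambda_grid
  fit <- glmnet::glmnet(X, factor(y, levels = c(-1, 1)), family = "binomial",
                        lambda = sort(grid / n, decreasing = TRUE),
                        standardize = FALSE)
  support <- unname(which(Matrix::rowSums(fit$beta != 0) > 0))
  expect_equal(res$selected, support)
})

test_that("identical seeds reproduce identical stability results", {
  set.seed(47)
  X <- matrix(rbinom(100 * 20, 1, 0.3), nrow = 100)
  y <- rep(c(1L, -1L), each = 50)
  r1 <- stability_select(X, y, l1_config(n_resamples = 40L, seed = 123L))
  r2 <- stability_select(X, y, l1_config(n_resamples = 40L, seed = 123L))
  expect_identical(r1$frequencies, r2$frequencies)
  expect_identical(r1$selected, r2$selected)
  expect_identical(r1$coefficients, r2$coefficients)
  r3 <- stability_select(X, y, l1_config(n_resamples = 40L, seed = 124L))
  expect_false(identical(r1$frequencies, r3$frequencies))
})

test_that("support size shrinks monotonically along the penalty path", {
  set.seed(48)
  n <- 150
  y <- rep(c(1L, -1L), each = n / 2)
  X <- cbind(as.integer(y == 1L) * rbinom(n, 1, 0.8),
             matrix(rbinom(n * 10, 1, 0.4), nrow = n))
  lams <- c(2, 8, 30, 120)
  sizes <- vapply(lams, function(l) {
    sum(fit_l1_logistic(X, y, l)$weights != 0)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("empty inputs and empty grids are contract errors", {
  X <- matrix(rbinom(40, 1, 0.5), nrow = 20)
  y <- rep(c(1L, -1L), 10)
  expect_error(stability_select(X[, 0, drop = FALSE], y, l1_config()),
               "empty design")
  expect_error(l1_config(lambda_grid = numeric(0)), "non-empty")
  expect_error(fit_l1_logistic(X, rep(1L, 20), 1), "both classes")
})

test_that("ranking follows frequency, then p, then |coefficient|", {
  res <- structure(
    list(frequencies = c(0.9, 0.4, 0.9, 0.9),
         selected = c(1L, 3L, 4L),
         coefficients = c(a = 0.2, c = -1.5, d = 0.7),
         intercept = 0,
         descriptors = data.frame(label = c("a", "b", "c", "d"))),
    class = "stability_result"
  )
  # freq ties 1,3,4 -> p breaks 3 (1e-8) ahead of {1, 4} (1e-3); |coef|
  # breaks 4 (0.7) ahead of 1 (0.2); feature 2 (freq 0.4) last
  pv <- c(1e-3, 1e-6, 1e-8, 1e-3)
  expect_equal(rank_features(res, pv), c(3L, 4L, 1L, 2L))
})

test_that("ranking equals a brute-force composite-key sort", {
  set.seed(51)
  for (rep in 1:10) {
    p <- 12
    freq <- round(runif(p, 0, 1), 1)      # force ties
    pv <- round(runif(p), 2)
    sel <- sort(sample.int(p, 5))
    coefs <- round(rnorm(5), 1)
    res <- structure(
      list(frequencies = freq, selected = sel,
           coefficients = setNames(coefs, sprintf("f%02d", sel)),
           descriptors = data.frame(label = sprintf("f%02d", 1:p))),
      class = "stability_result"
    )
    cf <- numeric(p); cf[sel] <- coefs
    key <- data.frame(a = -freq, b = pv, c = -abs(cf),
                      d = sprintf("f%02d", 1:p))
    oracle <- do.call(order, key)
    expect_equal(rank_features(res, pv), oracle)
  }
})

test_that("stability results export as descriptor/frequency CSV", {
  set.seed(52)
  X <- cbind(a = rep(c(1L, 0L), each = 20), b = rbinom(40, 1, 0.4))
  y <- rep(c(1L, -1L), each = 20)
  desc <- data.frame(label = c("rs1_Aa", "rs2_aa"))
  res <- stability_select(X, y, l1_config(n_resamples = 20L, seed = 5L),
                          descriptors = desc)
  path <- tempfile(fileext = ".csv")
  write_stability_csv(res, pvals = c(1e-6, 0.3), path)
  tab <- read.csv(path)
  expect_equal(names(tab), c("descriptor", "frequency", "coefficient",
                             "chi2_p"))
  expect_equal(tab$descriptor[1], "rs1_Aa")
})
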