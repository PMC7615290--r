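test_that("shrunk covariance interpolates between sample covariance and identity", {
  set.seed(1)
  x <- matrix(rnorm(200), 40, 5)
  xc <- sweep(x, 2, colMeans(x))
  S <- crossprod(xc) / nrow(x)
  expect_equal(shrunk_covariance(x, 0)$matrix, S, tolerance = 1e-12)
  expect_equal(shrunk_covariance(x, 1)$matrix,
               diag(sum(diag(S)) / 5, 5), tolerance = 1e-12)
  ## hand case: S = [[2,1],[1,2]], alpha = 0.5 -> [[2,0.5],[0.5,2]]
  u1 <- c(1, 1) / sqrt(2); u2 <- c(1, -1) / sqrt(2)
  X <- rbind(sqrt(6) * u1, -sqrt(6) * u1, sqrt(2) * u2, -sqrt(2) * u2)
  expect_equal(shrunk_covariance(X, 0)$matrix,
               matrix(c(2, 1, 1, 2), 2), tolerance = 1e-12)
  expect_equal(shrunk_covariance(X, 0.5)$matrix,
               matrix(c(2, 0.5, 0.5, 2), 2), tolerance = 1e-12)
  ## symmetry and alpha validation
  sym <- shrunk_covariance(x, 0.3)$matrix
  expect_lt(max(abs(sym - t(sym))), 1e-10)
  expect_error(shrunk_covariance(x, 1.2), "alpha")
  expect_error(shrunk_covariance(x[1, , drop = FALSE], 0), "2 samples")
})

test_that("binary LDA matches closed-form directions", {
  ## pooled S = [[1,0],[0,4]], delta mu = (1,1) -> w proportional to (1, 1/4)
  base <- rbind(c(sqrt(2), 0), c(-sqrt(2), 0), c(0, 2 * sqrt(2)),
                c(0, -2 * sqrt(2)))
  x <- rbind(base, sweep(base, 2, c(-1, -1)))
  y <- rep(c(1, 0), each = 4)
  fit <- fit_binary_lda(x, y, 0)
  expect_equal(fit$w[2] / fit$w[1], 0.25, tolerance = 1e-10,
               ignore_attr = TRUE)
  ## alpha = 1: scaled-identity whitening, w proportional to delta mu
  d <- two_class_data(20, 4, shift = c(1, 2, 0, -1), seed = 3)
  f1 <- fit_binary_lda(d$x, d$y, 1)
  dmu <- colMeans(d$x[d$y == 1, ]) - colMeans(d$x[d$y == 0, ])
  expect_equal(abs(cor(f1$w, dmu)), 1, tolerance = 1e-10)
  ## closed-form oracle on small problems
  for (s in 1:5) {
    d <- two_class_data(15, 3, shift = 0.5, seed = s)
    for (a in c(0, 0.4)) {
      fit <- fit_binary_lda(d$x, d$y, a)
      S <- cnvsig:::pooled_within_cov(d$x, d$y)
      sig <- (1 - a) * S + diag(a * sum(diag(S)) / 3, 3)
      oracle <- solve(sig, colMeans(d$x[d$y == 1, ]) -
                        colMeans(d$x[d$y == 0, ]))
      expect_equal(unname(fit$w), unname(oracle), tolerance = 1e-8)
    }
  }
  ## singular at alpha = 0 when features outnumber samples
  xs <- matrix(rnorm(10 * 20), 10, 20)
  expect_error(fit_binary_lda(xs, rep(c(0, 1), 5), 0), "alpha > 0")
})

test_that("LDA direction agrees with an independent reference implementation", {
  skip_if_not_installed("MASS")
  d <- two_class_data(40, 4, shift = 0.8, seed = 9)
  fit <- fit_binary_lda(d$x, d$y, 0)
  ref <- MASS::lda(d$x, grouping = d$y)
  expect_equal(abs(cor(fit$w, ref$scaling[, 1])), 1, tolerance = 1e-6)
})

test_that("MCC matches the prediction-label correlation on all small tables", {
  expect_equal(mcc(10, 5, 0, 0), 1)
  expect_equal(mcc(3, 0, 4, 0), 0)  # all predicted positive
  expect_equal(mcc(3, 4, 1, 2), 10 / sqrt(600))
  ## exhaustive enumeration, totals <= 6, against cor() of the label vectors
  for (tot in 1:6) {
    parts <- expand.grid(tp = 0:tot, tn = 0:tot, fp = 0:tot, fn = 0:tot)
    parts <- parts[rowSums(parts) == tot, ]
    for (i in seq_len(nrow(parts))) {
      p <- parts[i, ]
      truth <- c(rep(1, p$tp), rep(0, p$tn), rep(0, p$fp), rep(1, p$fn))
      pred <- c(rep(1, p$tp), rep(0, p$tn), rep(1, p$fp), rep(0, p$fn))
      oracle <- if (length(truth) < 2 || sd(truth) == 0 || sd(pred) == 0) 0
                else cor(pred, truth)
      expect_equal(mcc(p$tp, p$tn, p$fp, p$fn), oracle, tolerance = 1e-12)
    }
  }
  expect_error(mcc(-1, 0, 0, 1), "non-negative")
})

test_that("leave-one-out selection equals the brute-force oracle", {
  grid <- seq(0, 1, by = 0.1)
  naive_loo <- function(x, y, grid) {
    n <- nrow(x)
    vapply(grid, function(a) {
      pred <- rep(NA_integer_, n)
      for (i in seq_len(n)) {
        fit <- tryCatch(fit_binary_lda(x[-i, , drop = FALSE], y[-i], a),
                        error = function(e) NULL)
        if (is.null(fit)) return(-Inf)
        pred[i] <- predict(fit, x[i, , drop = FALSE])
      }
      mcc(sum(pred == 1 & y == 1), sum(pred == 0 & y == 0),
          sum(pred == 1 & y == 0), sum(pred == 0 & y == 1))
    }, numeric(1))
  }
  for (s in 1:4) {
    set.seed(s)
    n1 <- sample(5:12, 1); n0 <- sample(6:20, 1); p <- sample(3:10, 1)
    x <- matrix(rnorm((n1 + n0) * p), n1 + n0, p)
    y <- c(rep(1L, n1), rep(0L, n0))
    x[y == 1, ] <- x[y == 1, ] + 0.7
    fast <- loo_select_alpha(x, y, grid)
    slow <- naive_loo(x, y, grid)
    expect_equal(unname(fast$scores), slow, tolerance = 1e-9)
    expect_equal(fast$alpha, grid[which.max(slow)])
  }
})

test_that("selection tie-breaks to the smallest alpha and avoids singular fits", {
  ## perfectly separated, low dimensional: every alpha scores 1 -> 0 returned
  x <- cbind(c(rnorm(20, -5), rnorm(20, 5)), rnorm(40))
  y <- rep(c(0, 1), each = 20)
  sel <- loo_select_alpha(x, y)
  expect_equal(unname(sel$scores["0.0"]), 1)
  expect_equal(sel$alpha, 0)
  ## features >= samples: alpha = 0 excluded
  xs <- matrix(rnorm(16 * 30), 16, 30)
  sel2 <- loo_select_alpha(xs, rep(c(0, 1), 8))
  expect_identical(unname(sel2$scores["0.0"]), -Inf)
  expect_gt(sel2$alpha, 0)
})
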