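#' Shrinkage-regularized covariance estimate
#'
#' Convex interpolation between the maximum-likelihood (n divisor) sample
#' covariance S and a scaled identity with matched total variance:
#' `(1 - alpha) * S + alpha * (trace(S)/p) * I`. `alpha = 0` reproduces S,
#' `alpha = 1` the scaled identity; any `alpha > 0` yields an invertible
#' estimate, which is what makes linear discriminant analysis feasible when
#' regions outnumber subjects.
#'
#' @param x Samples x features matrix (>= 2 rows).
#' @param alpha Shrinkage intensity in `[0, 1]`.
#' @return Object of class `shrunk_covariance`: `alpha`, `matrix`.
#' @export
shrunk_covariance <- function(x, alpha) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 samples")
  check_alpha(alpha)
  xc <- sweep(x, 2L, colMeans(x))
  S <- crossprod(xc) / nrow(x)
  structure(list(alpha = alpha, matrix = shrink_matrix(S, alpha)),
            class = "shrunk_covariance")
}

check_alpha <- function(alpha) {
  if (length(alpha) != 1L || is.na(alpha) || alpha < 0 || alpha > 1) {
    stop("alpha must be a scalar in [0, 1]")
  }
}

shrink_matrix <- function(S, alpha) {
  p <- ncol(S)
  (1 - alpha) * S + diag(alpha * sum(diag(S)) / p, p)
}

## pooled within-class ML covariance (classes centered on their own means)
pooled_within_cov <- function(x, y) {
  xc <- x
  for (lv in unique(y)) {
    idx <- y == lv
    xc[idx, ] <- sweep(x[idx, , drop = FALSE], 2L,
                       colMeans(x[idx, , drop = FALSE]))
  }
  crossprod(xc) / nrow(x)
}

#' Fit a binary shrinkage-LDA model
#'
#' Gaussian linear discriminant with pooled within-class shrunk covariance:
#' discriminant direction `w = Sigma(alpha)^-1 (mu1 - mu0)`, class 1 assigned
#' when `w'x > w'(mu0 + mu1)/2 - log(pi1/pi0)` with empirical class priors.
#'
#' @param x Samples x features matrix.
#' @param y Binary labels (0/1, logical, or a 2-level factor whose second
#'   level is treated as the positive class).
#' @param alpha Shrinkage intensity in `[0, 1]`.
#' @return Object of class `binary_lda`: `w`, `mu0`, `mu1`, `alpha`,
#'   `priors`, `threshold`.
#' @export
fit_binary_lda <- function(x, y, alpha) {
  x <- as.matrix(x)
  y <- as_binary(y)
  check_alpha(alpha)
  if (length(unique(y)) != 2L) stop("both classes must be present")
  mu0 <- colMeans(x[y == 0L, , drop = FALSE])
  mu1 <- colMeans(x[y == 1L, , drop = FALSE])
  sigma <- shrink_matrix(pooled_within_cov(x, y), alpha)
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) {
    stop("singular shrunk covariance (alpha = ", alpha,
         "); use alpha > 0 when features outnumber samples")
  }
  w <- backsolve(ch, forwardsolve(t(ch), mu1 - mu0))
  names(w) <- colnames(x)
  priors <- c(mean(y == 0L), mean(y == 1L))
  structure(list(w = w, mu0 = mu0, mu1 = mu1, alpha = alpha,
                 priors = priors,
                 threshold = sum(w * (mu0 + mu1)) / 2 -
                   log(priors[2] / priors[1])),
            class = "binary_lda")
}

as_binary <- function(y) {
  if (is.factor(y)) as.integer(y == levels(y)[2L])
  else if (is.logical(y)) as.integer(y)
  else as.integer(y != 0)
}

#' @export
predict.binary_lda <- function(object, newdata, type = c("class", "score"),
                               ...) {
  type <- match.arg(type)
  score <- as.vector(as.matrix(newdata) %*% object$w)
  if (type == "score") score else as.integer(score > object$threshold)
}

#' @export
print.binary_lda <- function(x, ...) {
  cat("Binary shrinkage-LDA:", length(x$w), "features, alpha =", x$alpha,
      ", priors =", paste(signif(x$priors, 3), collapse = "/"), "\n")
  invisible(x)
}

#' Matthews correlation coefficient
#'
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`; by convention 0
#' when any denominator factor is zero (e.g. all predictions in one class).
#' Ranges over `[-1, 1]`, with +1 a perfect prediction, 0 chance level.
#'
#' @param tp,tn,fp,fn Non-negative confusion-matrix counts.
#' @return Scalar score.
#' @export
mcc <- function(tp, tn, fp, fn) {
  if (any(c(tp, tn, fp, fn) < 0)) stop("counts must be non-negative")
  tp <- as.numeric(tp); tn <- as.numeric(tn)
  fp <- as.numeric(fp); fn <- as.numeric(fn)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Leave-one-out shrinkage selection for binary LDA
#'
#' For each candidate shrinkage value, every in-bag sample is predicted by a
#' model fitted on the remaining samples; the pooled leave-one-out confusion
#' matrix is scored with the Matthews correlation coefficient and the best
#' alpha returned (ties broken toward the smallest alpha). Grid points where
#' the covariance is singular (alpha = 0 with features >= samples) score
#' `-Inf`. The left-out models are computed exactly via a rank-one downdate
#' of the pooled covariance in its eigenbasis, so the full grid costs little
#' more than a single eigendecomposition.
#'
#' @param x Samples x features matrix.
#' @param y Binary labels.
#' @param grid Candidate alphas (default `seq(0, 1, 0.1)`).
#' @return List with `alpha` (selected value) and `scores` (named MCC per
#'   grid point; `-Inf` marks singular fits).
#' @export
loo_select_alpha <- function(x, y, grid = seq(0, 1, by = 0.1)) {
  x <- as.matrix(x)
  y <- as_binary(y)
  if (length(unique(y)) != 2L) stop("both classes must be present")
  scores <- loo_mcc_scores(x, y, grid)
  list(alpha = grid[which.max(scores)],
       scores = stats::setNames(scores, format(grid)))
}

## Exact LOO via eigendecomposition + Sherman-Morrison rank-one downdate.
## Identity: with d = x_i - mu_c and m the size of i's class,
##   (n-1) * S(-i) = n * S - (m/(m-1)) d d'
## so Sigma_alpha(-i) = M - r d d' with M diagonal in the eigenbasis of S.
loo_mcc_scores <- function(x, y, grid) {
  n <- nrow(x); p <- ncol(x)
  n1 <- sum(y == 1L); n0 <- n - n1
  S <- pooled_within_cov(x, y)
  eg <- eigen(S, symmetric = TRUE)
  D <- pmax(eg$values, 0)
  Z <- x %*% eg$vectors
  mz0 <- colMeans(Z[y == 0L, , drop = FALSE])
  mz1 <- colMeans(Z[y == 1L, , drop = FALSE])
  trS <- sum(D)
  eps <- 1e-9 * max(trS / p, .Machine$double.xmin)
  A <- length(grid)
  tp <- fp <- tn <- fn <- numeric(A)
  valid <- rep(TRUE, A)
  scale_D <- D * (n / (n - 1))
  for (i in seq_len(n)) {
    ci <- y[i]
    m <- if (ci == 1L) n1 else n0
    if (m < 2L) next
    zi <- Z[i, ]
    d <- zi - (if (ci == 1L) mz1 else mz0)
    tri <- (n * trS - (m / (m - 1)) * sum(d^2)) / (n - 1)
    G <- outer(scale_D, 1 - grid) + outer(rep(tri / p, p), grid)
    r <- (1 - grid) * m / ((m - 1) * (n - 1))
    shift <- d / (m - 1)
    delta <- (mz1 - mz0) + (if (ci == 1L) -shift else shift)
    msum <- mz0 + mz1 - shift
    Ud <- d / G
    V <- delta / G
    denom <- 1 - r * colSums(d * Ud)
    bad <- (apply(G, 2L, min) <= eps) | (denom <= 1e-10)
    valid <- valid & !bad
    coefs <- r * colSums(d * V) / denom
    s_x <- colSums(V * zi) + coefs * colSums(Ud * zi)
    s_m <- (colSums(V * msum) + coefs * colSums(Ud * msum)) / 2
    n1p <- n1 - (ci == 1L); n0p <- n0 - (ci == 0L)
    pred <- s_x > s_m - log(n1p / n0p)
    pred[bad] <- NA
    if (ci == 1L) {
      tp <- tp + (pred %in% TRUE); fn <- fn + (pred %in% FALSE)
    } else {
      fp <- fp + (pred %in% TRUE); tn <- tn + (pred %in% FALSE)
    }
  }
  out <- vapply(seq_len(A), function(a) mcc(tp[a], tn[a], fp[a], fn[a]),
                numeric(1))
  out[!valid] <- -Inf
  out
}

## Multiclass analogue: pooled within-class covariance over K classes,
## leave-one-out pooled accuracy per alpha (used by the 2-D LDA embedding).
loo_accuracy_multiclass <- function(x, y, grid) {
  y <- as.integer(factor(y))
  K <- max(y)
  n <- nrow(x); p <- ncol(x)
  counts <- tabulate(y, K)
  S <- pooled_within_cov(x, y)
  eg <- eigen(S, symmetric = TRUE)
  D <- pmax(eg$values, 0)
  Z <- x %*% eg$vectors
  mz <- t(vapply(seq_len(K),
                 function(k) colMeans(Z[y == k, , drop = FALSE]),
                 numeric(p)))
  trS <- sum(D)
  eps <- 1e-9 * max(trS / p, .Machine$double.xmin)
  A <- length(grid)
  correct <- numeric(A)
  total <- numeric(A)
  valid <- rep(TRUE, A)
  scale_D <- D * (n / (n - 1))
  for (i in seq_len(n)) {
    ci <- y[i]
    m <- counts[ci]
    if (m < 2L) next
    zi <- Z[i, ]
    d <- zi - mz[ci, ]
    tri <- (n * trS - (m / (m - 1)) * sum(d^2)) / (n - 1)
    G <- outer(scale_D, 1 - grid) + outer(rep(tri / p, p), grid)
    r <- (1 - grid) * m / ((m - 1) * (n - 1))
    Ud <- d / G
    dUd <- colSums(d * Ud)
    denom <- 1 - r * dUd
    bad <- (apply(G, 2L, min) <= eps) | (denom <= 1e-10)
    valid <- valid & !bad
    zUd <- colSums(Ud * zi)
    disc <- matrix(-Inf, K, A)
    for (k in seq_len(K)) {
      mu_k <- mz[k, ]
      if (k == ci) mu_k <- mu_k - d / (m - 1)
      nk <- counts[k] - (k == ci)
      if (nk < 1L) next
      Vk <- mu_k / G
      ck <- r * colSums(d * Vk) / denom
      ## Sigma^-1 mu_k in eigenbasis: Vk + ck * Ud
      zSm <- colSums(Vk * zi) + ck * zUd
      mSm <- colSums(Vk * mu_k) + ck * colSums(Ud * mu_k)
      disc[k, ] <- zSm - mSm / 2 + log(nk / (n - 1))
    }
    pred <- max.col(t(disc), ties.method = "first")
    correct <- correct + (pred == ci)
    total <- total + 1
  }
  out <- correct / pmax(total, 1)
  out[!valid] <- -Inf
  out
}
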