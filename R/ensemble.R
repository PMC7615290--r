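#' Fit a bagged shrinkage-LDA intermediate phenotype
#'
#' The core estimator of the package. For one CNV group versus controls it
#' runs `B` stratified bootstrap iterations: carriers and controls are
#' resampled with replacement separately so in-bag class counts equal the
#' dataset's; the shrinkage intensity is selected per iteration by exact
#' leave-one-out search over `grid` scored with the Matthews correlation
#' coefficient (see [loo_select_alpha()]); a binary shrinkage-LDA is fitted
#' on the in-bag set and evaluated on the out-of-bag subjects. Each
#' discriminant is sign-aligned (multiplied by the sign of its Pearson
#' correlation with a reference map, conventionally the group's Cohen's d
#' map; zero correlation aligns to +1), unit-L2-normalized, and the aligned
#' discriminants are averaged into the signature `W` — the CNV-specific
#' intermediate phenotype. Per-region 2.5/97.5% bootstrap percentiles give a
#' significance mask (interval excluding zero). Bootstrap draws whose
#' out-of-bag set lacks a class are redrawn up to `max_redraw` times, then
#' recorded as invalid and excluded from the mean MCC.
#'
#' @param x Subjects x regions matrix of confound-adjusted volumes
#'   (carriers of one CNV plus controls).
#' @param y Binary labels: 1/TRUE for carriers, 0/FALSE for controls.
#' @param B Number of bootstrap iterations (default 100).
#' @param grid Shrinkage search grid (default `seq(0, 1, 0.1)`).
#' @param align_to Reference map for sign alignment (length = regions).
#'   Default: the carrier-minus-control mean-difference map of `x`.
#' @param seed Integer seed.
#' @param max_redraw Redraw budget for degenerate out-of-bag sets.
#' @param label Optional CNV label stored with the fit.
#' @return Object of class `bagged_lda` with elements `signature` (W, the
#'   averaged aligned unit-norm discriminant), `discriminants` (B x regions,
#'   aligned and unit-norm), `ci` (2 x regions bootstrap percentiles),
#'   `significant` (logical mask), `oob_mcc` (per iteration, NA when
#'   invalid), `mean_mcc`, `alpha` (per iteration), `n_invalid`, `label`.
#' @seealso [predict.bagged_lda()] for expression scoring,
#'   [permutation_null()] for the label-shuffling chance model.
#' @export
bagged_lda <- function(x, y, B = 100L, grid = seq(0, 1, by = 0.1),
                       align_to = NULL, seed = 1L, max_redraw = 10L,
                       label = NULL) {
  x <- as.matrix(x)
  y <- as_binary(y)
  idx1 <- which(y == 1L); idx0 <- which(y == 0L)
  if (length(idx1) < 2L || length(idx0) < 2L) {
    stop("need at least 2 carriers and 2 controls")
  }
  B <- as.integer(B)
  if (B < 1L) stop("B must be >= 1")
  if (is.null(align_to)) {
    align_to <- colMeans(x[idx1, , drop = FALSE]) -
      colMeans(x[idx0, , drop = FALSE])
  }
  if (length(align_to) != ncol(x)) {
    stop("align_to must have one value per region")
  }
  set.seed(as.integer(seed))
  p <- ncol(x)
  W_mat <- matrix(NA_real_, B, p, dimnames = list(NULL, colnames(x)))
  oob_mcc <- rep(NA_real_, B)
  alphas <- rep(NA_real_, B)
  n_invalid <- 0L
  for (b in seq_len(B)) {
    oob <- integer(0)
    ok <- FALSE
    for (try in seq_len(max_redraw + 1L)) {
      inbag <- c(idx1[sample.int(length(idx1), replace = TRUE)],
                 idx0[sample.int(length(idx0), replace = TRUE)])
      oob <- setdiff(c(idx1, idx0), inbag)
      if (length(unique(y[oob])) == 2L) { ok <- TRUE; break }
    }
    if (!ok) n_invalid <- n_invalid + 1L
    xb <- x[inbag, , drop = FALSE]
    yb <- y[inbag]
    sel <- loo_select_alpha(xb, yb, grid)
    fit <- fit_binary_lda(xb, yb, sel$alpha)
    alphas[b] <- sel$alpha
    if (ok) {
      pred <- predict(fit, x[oob, , drop = FALSE])
      yo <- y[oob]
      oob_mcc[b] <- mcc(sum(pred == 1L & yo == 1L), sum(pred == 0L & yo == 0L),
                        sum(pred == 1L & yo == 0L), sum(pred == 0L & yo == 1L))
    }
    w <- fit$w
    s <- sign(stats::cor(w, align_to))
    if (is.na(s) || s == 0) s <- 1
    W_mat[b, ] <- s * w / sqrt(sum(w^2))
  }
  W <- colMeans(W_mat)
  ci <- apply(W_mat, 2L, stats::quantile, probs = c(0.025, 0.975))
  significant <- as.vector(ci[1L, ] > 0 | ci[2L, ] < 0)
  structure(list(signature = W, discriminants = W_mat, ci = ci,
                 significant = significant, oob_mcc = oob_mcc,
                 mean_mcc = mean(oob_mcc, na.rm = TRUE),
                 alpha = alphas, n_invalid = n_invalid,
                 B = B, grid = grid, label = label,
                 n_carriers = length(idx1), n_controls = length(idx0),
                 seed = as.integer(seed)),
            class = "bagged_lda")
}

#' @export
print.bagged_lda <- function(x, ...) {
  cat("Bagged shrinkage-LDA intermediate phenotype",
      if (!is.null(x$label)) paste0("(", x$label, ")"), "\n")
  cat("  ", x$n_carriers, "carriers vs", x$n_controls, "controls;",
      x$B, "bootstrap iterations",
      if (x$n_invalid > 0) paste0("(", x$n_invalid, " invalid)"), "\n")
  cat("  mean out-of-bag MCC:", signif(x$mean_mcc, 3),
      "; significant coefficients:", sum(x$significant), "/",
      length(x$signature), "\n")
  invisible(x)
}

#' @export
summary.bagged_lda <- function(object, ...) {
  out <- list(label = object$label,
              mean_mcc = object$mean_mcc,
              mcc_range = range(object$oob_mcc, na.rm = TRUE),
              n_significant = sum(object$significant),
              n_regions = length(object$signature),
              alpha_table = table(object$alpha),
              n_invalid = object$n_invalid)
  class(out) <- "summary.bagged_lda"
  out
}

#' @export
print.summary.bagged_lda <- function(x, ...) {
  cat("Bagged shrinkage-LDA", if (!is.null(x$label)) paste0("(", x$label, ")"),
      "\n  mean OOB MCC", signif(x$mean_mcc, 3), " range",
      paste(signif(x$mcc_range, 3), collapse = " .. "), "\n")
  cat("  significant coefficients:", x$n_significant, "/", x$n_regions, "\n")
  cat("  selected shrinkage values:\n")
  print(x$alpha_table)
  invisible(x)
}

#' @export
coef.bagged_lda <- function(object, ...) object$signature

#' Expression scoring with a fitted intermediate phenotype
#'
#' The expression of the intermediate phenotype in a subject is the dot
#' product of the subject's (confound-adjusted) regional volumes with the
#' averaged signature vector — equivalently the average one-dimensional LDA
#' projection across the bootstrap ensemble.
#'
#' @param object A `bagged_lda` fit.
#' @param newdata Subjects x regions matrix, regions matching the fit.
#' @param ... Unused.
#' @return Numeric vector of expression scores.
#' @export
predict.bagged_lda <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$signature)) {
    stop("newdata must have one column per signature region")
  }
  nms <- names(object$signature)
  if (!is.null(nms) && !is.null(colnames(newdata)) &&
      !identical(colnames(newdata), nms)) {
    stop("region identifiers of newdata do not match the signature")
  }
  as.vector(newdata %*% object$signature)
}

## light-weight bagged fit returning only the mean out-of-bag MCC
bagged_mean_mcc <- function(x, y, B, grid, seed, max_redraw = 10L) {
  fit <- bagged_lda(x, y, B = B, grid = grid, seed = seed,
                    max_redraw = max_redraw)
  fit$mean_mcc
}

#' Label-permutation chance model for the bagged ensemble
#'
#' Repeats the full bagged procedure (including per-iteration shrinkage
#' selection) on label-shuffled data to build the empirical null
#' distribution of the mean out-of-bag MCC. Classification is deemed
#' above chance when the observed mean MCC exceeds the null's 97.5th
#' percentile.
#'
#' @param x,y As in [bagged_lda()].
#' @param B Bootstrap iterations of the observed model (used as default for
#'   `B_null`).
#' @param n_perm Number of label permutations (default 100).
#' @param grid Shrinkage grid.
#' @param seed Integer seed.
#' @param B_null Bootstrap iterations per permuted refit (default `B`).
#' @return Object of class `mcc_null`: `null_mcc` (length `n_perm`),
#'   `threshold` (97.5th percentile), `n_perm`, `B_null`.
#' @export
permutation_null <- function(x, y, B = 100L, n_perm = 100L,
                             grid = seq(0, 1, by = 0.1), seed = 1L,
                             B_null = B) {
  n_perm <- as.integer(n_perm)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  y <- as_binary(y)
  null_mcc <- numeric(n_perm)
  for (k in seq_len(n_perm)) {
    set.seed(derive_seed(seed, paste0("perm_shuffle_", k)))
    y_perm <- sample(y)
    null_mcc[k] <- bagged_mean_mcc(x, y_perm, B = B_null, grid = grid,
                                   seed = derive_seed(seed, paste0("perm_fit_", k)))
  }
  structure(list(null_mcc = null_mcc,
                 threshold = unname(stats::quantile(null_mcc, 0.975)),
                 n_perm = n_perm, B_null = as.integer(B_null)),
            class = "mcc_null")
}

#' @export
print.mcc_null <- function(x, ...) {
  cat("Permutation null:", x$n_perm, "label shuffles, B_null =", x$B_null,
      "; 97.5th percentile threshold =", signif(x$threshold, 3), "\n")
  invisible(x)
}

#' Per-network share of significant signature coefficients
#'
#' For each large-scale network: the fraction of its regions whose signature
#' coefficient is flagged significant by the bootstrap percentile interval.
#'
#' @param signature A `bagged_lda` fit (or logical mask of length regions).
#' @param atlas The matching `atlas_spec`.
#' @return Data frame with `network`, `n_regions`, `n_significant`,
#'   `fraction`.
#' @export
network_summary <- function(signature, atlas) {
  mask <- if (inherits(signature, "bagged_lda")) signature$significant
          else as.logical(signature)
  if (length(mask) != atlas$n_regions) {
    stop("signature length must equal the number of atlas regions")
  }
  K <- length(atlas$network_names)
  n_reg <- tabulate(atlas$network, K)
  n_sig <- vapply(seq_len(K),
                  function(k) sum(mask[atlas$network == k]), integer(1))
  data.frame(network = atlas$network_names,
             n_regions = n_reg, n_significant = n_sig,
             fraction = n_sig / n_reg)
}

#' Correlation between coefficient counts and classifier performance
#'
#' Pearson correlation across CNVs between the number of significant
#' signature coefficients and the mean out-of-bag MCC, with a two-sided
#' t-distribution p-value (df = n - 2).
#'
#' @param signatures List of >= 3 `bagged_lda` fits.
#' @return List with `r`, `p`, `n`.
#' @export
coeff_vs_performance <- function(signatures) {
  if (length(signatures) < 3L) stop("need at least 3 signatures")
  counts <- vapply(signatures, function(s) sum(s$significant), integer(1))
  perf <- vapply(signatures, function(s) s$mean_mcc, numeric(1))
  if (stats::sd(counts) == 0 || stats::sd(perf) == 0) {
    stop("correlation undefined: constant input")
  }
  n <- length(signatures)
  r <- stats::cor(counts, perf)
  tval <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tval), df = n - 2), n = n)
}
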