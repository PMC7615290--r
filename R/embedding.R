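#' Two-dimensional PCA embedding with post-hoc projection
#'
#' Principal component analysis fitted on one subject subset (e.g. all CNV
#' carriers) and applied to another (e.g. controls, projected post hoc).
#' Components are the top eigenvectors of the fit-population covariance;
#' coordinates are centered on fit-population means.
#'
#' @param x Subjects x regions matrix (confound-adjusted volumes).
#' @param fit_subjects Rows used to fit the components.
#' @param project_subjects Rows projected post hoc (default none).
#' @param n_comp Number of components (default 2).
#' @return Object of class `embedding`: `coords` (fit + projected subjects),
#'   `loadings`, `explained_var`, `fitted` (logical per row of `coords`),
#'   `method = "pca"`.
#' @export
pca_embedding <- function(x, fit_subjects, project_subjects = NULL,
                          n_comp = 2L) {
  x <- as.matrix(x)
  fit_subjects <- resolve_rows(x, fit_subjects)
  if (length(fit_subjects) < 3L) stop("need at least 3 fit subjects")
  xf <- x[fit_subjects, , drop = FALSE]
  ctr <- colMeans(xf)
  pc <- stats::prcomp(xf, center = TRUE, scale. = FALSE)
  if (pc$sdev[1L] <= 0) stop("degenerate input: no variance in fit subjects")
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  ## truncate to the available non-degenerate directions (>= 1)
  n_comp <- min(n_comp, max(1L, sum(pc$sdev > 1e-10 * pc$sdev[1L])))
  load <- pc$rotation[, seq_len(n_comp), drop = FALSE]
  co_fit <- pc$x[, seq_len(n_comp), drop = FALSE]
  coords <- co_fit
  fitted <- rep(TRUE, nrow(co_fit))
  if (!is.null(project_subjects)) {
    project_subjects <- resolve_rows(x, project_subjects)
    xp <- sweep(x[project_subjects, , drop = FALSE], 2L, ctr)
    coords <- rbind(coords, xp %*% load)
    fitted <- c(fitted, rep(FALSE, length(project_subjects)))
    rownames(coords) <- rownames(x)[c(fit_subjects, project_subjects)]
  }
  structure(list(coords = coords, loadings = load,
                 explained_var = ev[seq_len(n_comp)],
                 center = ctr, fitted = fitted, method = "pca"),
            class = "embedding")
}

#' Multiclass shrinkage-LDA embedding
#'
#' Low-dimensional representation explicitly maximizing separation among the
#' CNV classes: generalized eigenvectors of the between-class scatter
#' against the pooled within-class shrunk covariance (at most classes - 1
#' usable directions, truncated to `n_comp`). The shrinkage intensity is
#' selected by leave-one-out pooled accuracy over `grid`. Additional
#' subjects (e.g. controls) are projected post hoc after centering on the
#' fit-population grand mean.
#'
#' @param x Subjects x regions matrix.
#' @param labels Class labels for the fit subjects (>= 2 classes, each with
#'   >= 2 subjects).
#' @param fit_subjects Rows carrying `labels` (default: all rows).
#' @param project_subjects Rows projected post hoc.
#' @param grid Shrinkage search grid.
#' @param n_comp Requested dimensions (default 2; silently truncated to
#'   classes - 1).
#' @return Object of class `embedding` with `method = "lda"`, plus `alpha`
#'   (selected shrinkage) and `eigenvalues`.
#' @export
multiclass_lda_embedding <- function(x, labels, fit_subjects = NULL,
                                     project_subjects = NULL,
                                     grid = seq(0, 1, by = 0.1),
                                     n_comp = 2L) {
  x <- as.matrix(x)
  if (is.null(fit_subjects)) fit_subjects <- seq_len(nrow(x))
  fit_subjects <- resolve_rows(x, fit_subjects)
  xf <- x[fit_subjects, , drop = FALSE]
  y <- factor(labels)
  if (length(y) != nrow(xf)) stop("labels must match fit subjects")
  K <- nlevels(y)
  if (K < 2L || any(table(y) < 2L)) {
    stop("need >= 2 classes with >= 2 subjects each")
  }
  acc <- loo_accuracy_multiclass(xf, y, grid)
  alpha <- grid[which.max(acc)]
  Sw <- shrink_matrix(pooled_within_cov(xf, as.integer(y)), alpha)
  gm <- colMeans(xf)
  mu <- t(vapply(levels(y),
                 function(lv) colMeans(xf[y == lv, , drop = FALSE]),
                 numeric(ncol(xf))))
  nc <- as.vector(table(y))
  Md <- sweep(mu, 2L, gm)
  Sb <- crossprod(Md * sqrt(nc / nrow(xf)))
  ch <- tryCatch(chol(Sw), error = function(e) NULL)
  if (is.null(ch)) stop("singular within-class covariance; increase alpha")
  ## whiten: A = L^-T Sb L^-1 symmetric, eigenvectors map back via L^-1
  A <- backsolve(ch, t(backsolve(ch, t(Sb), transpose = TRUE)),
                 transpose = TRUE)
  eg <- eigen((A + t(A)) / 2, symmetric = TRUE)
  usable <- sum(eg$values > max(1e-10 * max(eg$values, 0), 1e-12))
  usable <- min(usable, K - 1L)
  if (usable < 1L) {
    stop("degenerate between-class scatter: class means coincide")
  }
  n_comp <- min(n_comp, usable)
  load <- backsolve(ch, eg$vectors[, seq_len(n_comp), drop = FALSE])
  colnames(load) <- paste0("LD", seq_len(n_comp))
  co_fit <- sweep(xf, 2L, gm) %*% load
  coords <- co_fit
  fitted <- rep(TRUE, nrow(co_fit))
  if (!is.null(project_subjects)) {
    project_subjects <- resolve_rows(x, project_subjects)
    xp <- sweep(x[project_subjects, , drop = FALSE], 2L, gm)
    coords <- rbind(coords, xp %*% load)
    fitted <- c(fitted, rep(FALSE, length(project_subjects)))
    rownames(coords) <- rownames(x)[c(fit_subjects, project_subjects)]
  }
  structure(list(coords = coords, loadings = load,
                 explained_var = NULL, center = gm, fitted = fitted,
                 alpha = alpha, eigenvalues = eg$values[seq_len(n_comp)],
                 method = "lda"),
            class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cat("2-D embedding (", x$method, "): ", sum(x$fitted), " fitted + ",
      sum(!x$fitted), " projected subjects, ", ncol(x$coords),
      " dimension(s)\n", sep = "")
  if (!is.null(x$explained_var)) {
    cat("  explained variance:",
        paste(signif(100 * x$explained_var, 3), collapse = "% / "), "%\n")
  }
  invisible(x)
}

#' @export
plot.embedding <- function(x, labels = NULL, ...) {
  if (ncol(x$coords) < 2L) {
    graphics::plot(x$coords[, 1L], rep(0, nrow(x$coords)),
                   xlab = colnames(x$coords)[1L], ylab = "", ...)
    return(invisible(x))
  }
  col <- if (is.null(labels)) ifelse(x$fitted, 1L, 8L)
         else as.integer(factor(labels))
  graphics::plot(x$coords[, 1L], x$coords[, 2L], col = col,
                 pch = ifelse(x$fitted, 16L, 1L),
                 xlab = colnames(x$coords)[1L],
                 ylab = colnames(x$coords)[2L], ...)
  invisible(x)
}
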