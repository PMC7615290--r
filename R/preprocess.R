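#' Residualize volumes on nuisance variables
#'
#' Per-region ordinary-least-squares adjustment for a configurable fixed
#' effect design. The design is specified by term names: any numeric column
#' of `confounds` may be named directly; `<name>2` adds the squared term
#' (e.g. `age2`); factor/character columns are expanded into indicator
#' columns (first level as reference). The model is fitted on `fit_subjects`
#' and its coefficients applied to all rows, so coefficients estimated in one
#' population can residualize another.
#'
#' @param volumes Subjects x regions numeric matrix.
#' @param confounds Data frame of per-subject nuisance variables, rows
#'   aligned with `volumes`.
#' @param design Character vector of term names (default
#'   `c("icv", "age", "age2", "sex", "site")`, the clinical recipe).
#' @param fit_subjects Row indices (or logical/rownames) used to fit the
#'   model; default all subjects.
#' @return List with `adjusted` (residual matrix, class `adjusted_volumes`)
#'   and `model` (class `confound_model`: coefficients k x regions, design
#'   column names, fit subset).
#' @export
adjust_confounds <- function(volumes, confounds,
                             design = c("icv", "age", "age2", "sex", "site"),
                             fit_subjects = NULL) {
  volumes <- as.matrix(volumes)
  if (nrow(volumes) != nrow(confounds)) {
    stop("volumes and confounds must have the same number of rows")
  }
  if (anyNA(confounds[, intersect(names(confounds), sub("2$", "", design)),
                      drop = FALSE])) {
    stop("missing confound values are not supported")
  }
  X <- build_design_matrix(confounds, design)
  if (is.null(fit_subjects)) fit_subjects <- seq_len(nrow(volumes))
  if (is.logical(fit_subjects)) fit_subjects <- which(fit_subjects)
  if (is.character(fit_subjects)) {
    fit_subjects <- match(fit_subjects, rownames(volumes))
  }
  Xf <- X[fit_subjects, , drop = FALSE]
  qx <- qr(Xf)
  if (qx$rank < ncol(Xf)) {
    bad <- colnames(Xf)[qx$pivot[(qx$rank + 1L):ncol(Xf)]]
    stop("collinear design columns: ", paste(bad, collapse = ", "))
  }
  coefs <- qr.coef(qx, volumes[fit_subjects, , drop = FALSE])
  resid <- volumes - X %*% coefs
  model <- structure(list(coefficients = coefs,
                          design = colnames(X),
                          terms = design,
                          fit_subjects = fit_subjects),
                     class = "confound_model")
  adjusted <- structure(resid, class = c("adjusted_volumes", "matrix", "array"),
                        design = colnames(X))
  list(adjusted = adjusted, model = model)
}

build_design_matrix <- function(confounds, design) {
  n <- nrow(confounds)
  cols <- list(intercept = rep(1, n))
  for (term in design) {
    base <- sub("2$", "", term)
    if (term %in% names(confounds)) {
      v <- confounds[[term]]
      squared <- FALSE
    } else if (grepl("2$", term) && base %in% names(confounds)) {
      v <- confounds[[base]]
      squared <- TRUE
    } else {
      stop("unknown design term: ", term)
    }
    if (is.factor(v) || is.character(v)) {
      v <- factor(v)
      if (nlevels(v) < 2L) {
        warning("design term '", term,
                "' has a single level and was dropped")
        next
      }
      mm <- stats::model.matrix(~v)[, -1, drop = FALSE]
      colnames(mm) <- paste0(term, "_", levels(v)[-1])
      for (j in seq_len(ncol(mm))) cols[[colnames(mm)[j]]] <- mm[, j]
    } else {
      cols[[term]] <- if (squared) as.numeric(v)^2 else as.numeric(v)
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- rownames(confounds)
  X
}

#' @export
print.confound_model <- function(x, ...) {
  cat("Confound model:", length(x$design), "design columns (",
      paste(x$design, collapse = ", "), ") fitted on",
      length(x$fit_subjects), "subjects,", ncol(x$coefficients), "regions\n")
  invisible(x)
}

#' Column z-scoring over a reference subset
#'
#' Centers and scales each region using the mean and sample standard
#' deviation (n - 1 divisor) computed over `over_subjects`; all rows are
#' transformed with those parameters. This matches the normalization used
#' before per-CNV effect-size computation, where the reference set is the
#' union of one CNV's carriers and the controls.
#'
#' @param volumes Subjects x regions numeric matrix.
#' @param over_subjects Row subset defining the normalization parameters
#'   (default: all rows); indices, logical, or rownames.
#' @return Matrix of the same shape, z-scored.
#' @export
zscore_columns <- function(volumes, over_subjects = NULL) {
  volumes <- as.matrix(volumes)
  if (is.null(over_subjects)) over_subjects <- seq_len(nrow(volumes))
  if (is.logical(over_subjects)) over_subjects <- which(over_subjects)
  if (is.character(over_subjects)) {
    over_subjects <- match(over_subjects, rownames(volumes))
  }
  if (length(over_subjects) < 2L) {
    stop("need at least 2 subjects in the normalization subset")
  }
  sub <- volumes[over_subjects, , drop = FALSE]
  mu <- colMeans(sub)
  sdv <- apply(sub, 2L, stats::sd)
  if (any(sdv <= 0)) {
    bad <- colnames(volumes)[sdv <= 0]
    if (is.null(bad)) bad <- which(sdv <= 0)
    stop("zero-variance region(s): ", paste(bad, collapse = ", "))
  }
  sweep(sweep(volumes, 2L, mu), 2L, sdv, "/")
}
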