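#' Score intermediate-phenotype expressions in a cohort
#'
#' Dot product of each subject's confound-adjusted volumes with each CNV
#' signature vector. Region identifiers must match between the volumes and
#' the signatures.
#'
#' @param volumes Subjects x regions matrix (adjusted).
#' @param signatures List of `bagged_lda` fits, or a matrix with one
#'   signature per row.
#' @return Matrix (subjects x signatures) of class `expression_scores`.
#' @export
score_expressions <- function(volumes, signatures) {
  volumes <- as.matrix(volumes)
  if (is.list(signatures)) {
    W <- t(vapply(signatures, function(s) {
      if (inherits(s, "bagged_lda")) s$signature else as.numeric(s)
    }, numeric(ncol(volumes))))
    nm <- names(signatures)
    labs <- vapply(signatures, function(s) {
      if (inherits(s, "bagged_lda") && !is.null(s$label)) s$label else ""
    }, character(1))
    if (is.null(nm) && all(nzchar(labs))) nm <- labs
    rownames(W) <- nm
    sig_names <- names(if (inherits(signatures[[1L]], "bagged_lda"))
      signatures[[1L]]$signature else signatures[[1L]])
  } else {
    W <- as.matrix(signatures)
    sig_names <- colnames(W)
  }
  if (ncol(W) != ncol(volumes)) {
    stop("region count mismatch between volumes and signatures")
  }
  if (!is.null(sig_names) && !is.null(colnames(volumes)) &&
      !identical(colnames(volumes), sig_names)) {
    stop("region identifiers of volumes do not match the signatures")
  }
  scores <- volumes %*% t(W)
  class(scores) <- c("expression_scores", class(scores))
  scores
}

#' Tukey interquartile-range outlier flags for expression scores
#'
#' Per signature column, values outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`
#' (quartiles by linear interpolation) are flagged; a subject flagged on any
#' column is excluded from all downstream phenome scans (union rule).
#'
#' @param scores Subjects x signatures matrix.
#' @param k Fence multiplier (default 1.5).
#' @return Logical vector (TRUE = outlier) with attribute `per_column`, the
#'   subjects x signatures flag matrix.
#' @export
tukey_filter <- function(scores, k = 1.5) {
  scores <- unclass(as.matrix(scores))
  if (nrow(scores) < 4L) stop("need at least 4 subjects")
  flags <- apply(scores, 2L, function(v) {
    q <- stats::quantile(v, c(0.25, 0.75), na.rm = TRUE)
    iqr <- q[2L] - q[1L]
    v < q[1L] - k * iqr | v > q[2L] + k * iqr
  })
  out <- rowSums(flags, na.rm = TRUE) > 0
  attr(out, "per_column") <- flags
  out
}

#' Two-sample bootstrap test for a difference in means
#'
#' The observed statistic is `mean(x) - mean(y)`. The null is enforced by
#' shifting both groups to the pooled mean; `B` within-group resamples give
#' the null distribution and the two-sided p-value
#' `(1 + #{|T_b| >= |T|}) / (B + 1)`.
#'
#' @param x,y Numeric group values (each >= 2).
#' @param B Bootstrap replicates (default 10000).
#' @param seed Integer seed.
#' @return Object of class `boot_mean_test`: `estimate`, `p`, `B`, `n1`,
#'   `n2`.
#' @export
bootstrap_mean_test <- function(x, y, B = 10000L, seed = 1L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) stop("both groups need >= 2 values")
  B <- as.integer(B)
  set.seed(as.integer(seed))
  obs <- mean(x) - mean(y)
  pooled <- mean(c(x, y))
  x0 <- x - mean(x) + pooled
  y0 <- y - mean(y) + pooled
  n1 <- length(x0); n2 <- length(y0)
  tb <- colMeans(matrix(sample(x0, n1 * B, replace = TRUE), n1, B)) -
    colMeans(matrix(sample(y0, n2 * B, replace = TRUE), n2, B))
  structure(list(estimate = obs,
                 p = (1 + sum(abs(tb) >= abs(obs))) / (B + 1),
                 B = B, n1 = n1, n2 = n2),
            class = "boot_mean_test")
}

#' @export
print.boot_mean_test <- function(x, ...) {
  cat("Two-sample bootstrap mean test: difference =", signif(x$estimate, 4),
      ", p =", signif(x$p, 3), " (", x$B, "replicates, n =", x$n1, "vs",
      x$n2, ")\n")
  invisible(x)
}

#' Phenome-wide association scan for one or all signature expressions
#'
#' For each phenotype: Pearson correlation with the expression score on
#' pairwise-complete cases (binary and ordinal phenotypes treated as numeric
#' scores, i.e. point-biserial / level-as-score), two-sided p from the t
#' distribution (df = n - 2), Bonferroni threshold `alpha / P_testable`, and
#' Benjamini-Hochberg FDR across the scan's testable phenotypes. Phenotypes
#' with fewer than `min_n` complete pairs, or without variation on the
#' complete cases, are marked untestable and excluded from the multiplicity
#' counts.
#'
#' @param scores Subjects x signatures matrix (already outlier-filtered, or
#'   pass `exclude`).
#' @param phenome A `phenome_table` (or plain subjects x phenotypes matrix).
#' @param alpha Significance level (default 0.05).
#' @param exclude Optional logical vector of subjects to drop (e.g.
#'   [tukey_filter()] flags).
#' @param min_n Minimum complete pairs per phenotype (default 10).
#' @return Named list (one per signature column) of `phewas_profile`
#'   objects: data frames with `phenotype`, `category`, `r`, `p`, `n`,
#'   `bonferroni`, `fdr`, `testable`, plus attributes `alpha` and
#'   `n_testable`.
#' @export
run_phewas <- function(scores, phenome, alpha = 0.05, exclude = NULL,
                       min_n = 10L) {
  scores <- unclass(as.matrix(scores))
  values <- if (inherits(phenome, "phenome_table")) phenome$values
            else as.matrix(phenome)
  category <- if (inherits(phenome, "phenome_table")) phenome$category
              else rep(1L, ncol(values))
  cat_names <- if (inherits(phenome, "phenome_table")) phenome$category_names
               else "all"
  if (nrow(values) != nrow(scores)) {
    stop("scores and phenome must cover the same subjects")
  }
  if (!is.null(exclude)) {
    scores <- scores[!exclude, , drop = FALSE]
    values <- values[!exclude, , drop = FALSE]
  }
  P <- ncol(values)
  K <- ncol(scores)
  snames <- colnames(scores)
  if (is.null(snames)) snames <- paste0("signature_", seq_len(K))
  pnames <- colnames(values)
  if (is.null(pnames)) pnames <- sprintf("phenotype_%04d", seq_len(P))

  r <- matrix(NA_real_, P, K)
  n_eff <- matrix(0L, P, K)
  for (q in seq_len(P)) {
    ok <- !is.na(values[, q])
    nq <- sum(ok)
    if (nq < min_n) next
    v <- values[ok, q]
    if (stats::sd(v) == 0) next
    sc <- scores[ok, , drop = FALSE]
    sds <- apply(sc, 2L, stats::sd)
    usable <- sds > 0
    if (any(usable)) {
      r[q, usable] <- as.vector(stats::cor(sc[, usable, drop = FALSE], v))
      n_eff[q, usable] <- nq
    }
  }
  tstat <- r * sqrt(pmax(n_eff - 2, 0) / pmax(1 - r^2, .Machine$double.eps))
  pval <- 2 * stats::pt(-abs(tstat), df = pmax(n_eff - 2, 1))

  out <- vector("list", K)
  names(out) <- snames
  for (k in seq_len(K)) {
    testable <- !is.na(r[, k])
    n_testable <- sum(testable)
    bon <- fdr <- rep(FALSE, P)
    if (n_testable > 0) {
      bon[testable] <- pval[testable, k] < alpha / n_testable
      fdr[testable] <- stats::p.adjust(pval[testable, k], "BH") < alpha
    }
    df <- data.frame(phenotype = pnames,
                     category = factor(cat_names[category],
                                       levels = cat_names),
                     r = r[, k], p = pval[, k], n = n_eff[, k],
                     bonferroni = bon, fdr = fdr, testable = testable,
                     stringsAsFactors = FALSE)
    attr(df, "alpha") <- alpha
    attr(df, "n_testable") <- n_testable
    attr(df, "signature") <- snames[k]
    class(df) <- c("phewas_profile", "data.frame")
    out[[k]] <- df
  }
  out
}

#' @export
print.phewas_profile <- function(x, ...) {
  cat("PheWAS profile (", attr(x, "signature"), "): ", nrow(x),
      " phenotypes, ", attr(x, "n_testable"), " testable; ",
      sum(x$bonferroni), " Bonferroni / ", sum(x$fdr), " FDR hits\n",
      sep = "")
  invisible(x)
}

#' Per-category ratio of significant associations
#'
#' For each phenome category, the number of Bonferroni-significant
#' associations divided by the number of (testable) phenotypes in the
#' category; categories without testable phenotypes are reported `NA`.
#'
#' @param profile A `phewas_profile`.
#' @return Data frame with `category`, `n_phenotypes`, `n_hits`, `ratio`.
#' @export
category_hit_ratio <- function(profile) {
  stopifnot(inherits(profile, "phewas_profile"))
  agg <- split(profile[profile$testable, c("bonferroni", "r")],
               profile$category[profile$testable])
  lv <- levels(profile$category)
  n_phen <- vapply(lv, function(cl) {
    nrow(agg[[cl]] %||% data.frame())
  }, integer(1))
  n_hit <- vapply(lv, function(cl) {
    a <- agg[[cl]]; if (is.null(a)) 0L else sum(a$bonferroni)
  }, integer(1))
  data.frame(category = lv, n_phenotypes = n_phen, n_hits = n_hit,
             ratio = ifelse(n_phen > 0, n_hit / n_phen, NA_real_))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Similarity of PheWAS profiles across CNVs
#'
#' Pairwise Pearson correlation between the per-phenotype correlation
#' vectors of two scans (restricted to phenotypes testable in both), with
#' significance from phenotype-label permutation (shuffling one profile's
#' phenotype order) and Benjamini-Hochberg FDR across pairs.
#'
#' @param profiles List of `phewas_profile`s over the same phenotype set.
#' @param n_perm Phenotype permutations per pair (default 1000).
#' @param seed Integer seed.
#' @return Object of class `map_similarity` (same shape as
#'   [similarity_matrix()]).
#' @export
profile_similarity <- function(profiles, n_perm = 1000L, seed = 1L) {
  K <- length(profiles)
  phen <- profiles[[1L]]$phenotype
  for (pr in profiles) {
    if (!identical(pr$phenotype, phen)) {
      stop("profiles must share the same phenotype set and order")
    }
  }
  Rv <- vapply(profiles, function(pr) pr$r, numeric(length(phen)))
  nm <- names(profiles)
  if (is.null(nm)) nm <- paste0("profile_", seq_len(K))
  colnames(Rv) <- nm
  r <- matrix(NA_real_, K, K, dimnames = list(nm, nm))
  diag(r) <- 1
  p <- matrix(NA_real_, K, K, dimnames = list(nm, nm))
  pairs <- which(upper.tri(r), arr.ind = TRUE)
  pvec <- numeric(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs[i, 1L]; b <- pairs[i, 2L]
    ok <- !is.na(Rv[, a]) & !is.na(Rv[, b])
    va <- Rv[ok, a]; vb <- Rv[ok, b]
    robs <- stats::cor(va, vb)
    set.seed(derive_seed(seed, paste0("profperm_", a, "_", b)))
    null <- replicate(n_perm, stats::cor(va, sample(vb)))
    pv <- (1 + sum(abs(null) >= abs(robs))) / (n_perm + 1)
    r[a, b] <- r[b, a] <- robs
    p[a, b] <- p[b, a] <- pv
    pvec[i] <- pv
  }
  pf <- stats::p.adjust(pvec, "BH")
  p_fdr <- matrix(NA_real_, K, K, dimnames = list(nm, nm))
  for (i in seq_len(nrow(pairs))) {
    p_fdr[pairs[i, 1L], pairs[i, 2L]] <-
      p_fdr[pairs[i, 2L], pairs[i, 1L]] <- pf[i]
  }
  structure(list(r = r, p = p, p_fdr = p_fdr,
                 mean_abs_r = mean(abs(r[upper.tri(r)])),
                 n_perm = as.integer(n_perm)),
            class = "map_similarity")
}

#' Per-category profile similarity matrices
#'
#' [profile_similarity()] restricted to each phenome category; categories
#' with fewer than 2 testable phenotypes are reported `NULL`.
#'
#' @param profiles List of `phewas_profile`s.
#' @return Named list of correlation matrices (or `NULL`).
#' @export
category_profile_similarity <- function(profiles) {
  lv <- levels(profiles[[1L]]$category)
  out <- vector("list", length(lv))
  names(out) <- lv
  for (cl in lv) {
    sel <- profiles[[1L]]$category == cl
    Rv <- vapply(profiles, function(pr) pr$r[sel], numeric(sum(sel)))
    keep <- stats::complete.cases(Rv)
    if (sum(keep) < 2L) next
    out[[cl]] <- stats::cor(Rv[keep, , drop = FALSE])
  }
  out
}

#' Phenotypes shared across multiple CNV scans
#'
#' Phenotypes Bonferroni-significant in at least `min_k` of the scans,
#' ordered by mean absolute correlation across all scans; also reports the
#' top phenotypes by mean absolute correlation regardless of significance.
#'
#' @param profiles List of `phewas_profile`s (same phenotype set).
#' @param min_k Minimum number of scans a phenotype must be significant in
#'   (1..number of scans).
#' @param n_top Size of the strongest-association table (default 10).
#' @return List with `shared` and `top` data frames.
#' @export
shared_hits <- function(profiles, min_k = 5L, n_top = 10L) {
  K <- length(profiles)
  if (min_k < 1L || min_k > K) {
    stop("min_k must lie between 1 and the number of scans (", K, ")")
  }
  phen <- profiles[[1L]]$phenotype
  hits <- rowSums(vapply(profiles, function(pr) pr$bonferroni,
                         logical(length(phen))))
  mean_abs_r <- rowMeans(abs(vapply(profiles, function(pr) pr$r,
                                    numeric(length(phen)))), na.rm = TRUE)
  base <- data.frame(phenotype = phen,
                     category = profiles[[1L]]$category,
                     n_significant = hits, mean_abs_r = mean_abs_r,
                     stringsAsFactors = FALSE)
  shared <- base[base$n_significant >= min_k, , drop = FALSE]
  shared <- shared[order(-shared$mean_abs_r), , drop = FALSE]
  top <- base[order(-base$mean_abs_r), , drop = FALSE]
  top <- utils::head(top, n_top)
  rownames(shared) <- rownames(top) <- NULL
  list(shared = shared, top = top)
}

#' Condition each expression column on the remaining signatures
#'
#' OLS-residualizes (with intercept) every expression column on the other
#' columns, isolating the variation unique to each CNV signature. The
#' operation is a projection: applying it twice changes nothing.
#'
#' @param scores Subjects x signatures matrix (>= 2 columns).
#' @return Residualized matrix of the same shape and class.
#' @export
condition_out <- function(scores) {
  cls <- class(scores)
  scores <- unclass(as.matrix(scores))
  K <- ncol(scores)
  if (K < 2L) stop("need at least 2 expression columns")
  out <- scores
  for (k in seq_len(K)) {
    X <- cbind(1, scores[, -k, drop = FALSE])
    ## rank-tolerant projection: the residual is well-defined even when the
    ## conditioning columns are collinear (e.g. duplicated signatures)
    out[, k] <- qr.resid(qr(X), scores[, k])
  }
  class(out) <- cls
  out
}

#' Brain-map versus phenome-profile convergence report
#'
#' Pairs the 28 off-diagonal absolute similarities of the volumetric
#' (Cohen's d map) similarity matrix with those of the PheWAS profile
#' similarity matrix, computes Lin's concordance between the two 28-vectors,
#' and counts the pairs whose phenotypic similarity exceeds the volumetric
#' one — the quantitative statement of "diverging brain maps, converging
#' phenome profiles".
#'
#' @param map_similarity,profile_similarity `map_similarity` objects over
#'   the same CNV order.
#' @return Object of class `convergence_report`: `rho_c`, `n_pairs`,
#'   `n_phenotypic_greater`, `mean_abs_map`, `mean_abs_profile`, `pairs`
#'   (data frame of paired absolute similarities).
#' @export
concordance_report <- function(map_similarity, profile_similarity) {
  Rm <- map_similarity$r
  Rp <- profile_similarity$r
  if (!identical(dim(Rm), dim(Rp))) stop("similarity matrices differ in size")
  ut <- upper.tri(Rm)
  am <- abs(Rm[ut]); ap <- abs(Rp[ut])
  idx <- which(ut, arr.ind = TRUE)
  nm <- rownames(Rm) %||% paste0("cnv_", seq_len(nrow(Rm)))
  pairs <- data.frame(cnv_a = nm[idx[, 1L]],
                      cnv_b = nm[idx[, 2L]],
                      map_abs_r = am, profile_abs_r = ap,
                      stringsAsFactors = FALSE)
  cc <- lin_ccc(am, ap)
  structure(list(rho_c = cc$rho_c, n_pairs = length(am),
                 n_phenotypic_greater = sum(ap > am),
                 mean_abs_map = mean(am), mean_abs_profile = mean(ap),
                 pairs = pairs),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat("Convergence report over", x$n_pairs, "CNV pairs\n")
  cat("  mean |map similarity| =", signif(x$mean_abs_map, 3),
      "; mean |profile similarity| =", signif(x$mean_abs_profile, 3), "\n")
  cat("  phenotypic > volumetric in", x$n_phenotypic_greater, "of",
      x$n_pairs, "pairs; Lin's rho_c =", signif(x$rho_c, 3), "\n")
  invisible(x)
}
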