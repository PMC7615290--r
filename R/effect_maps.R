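#' Per-region Cohen's d effect map
#'
#' Standardized mean difference per region between a carrier group and
#' controls: `d = (mean1 - mean2) / sqrt((s1^2 + s2^2) / 2)` with sample
#' (n - 1 divisor) standard deviations. Typically computed on
#' confound-adjusted, z-scored volumes.
#'
#' @param volumes Subjects x regions matrix (adjusted and z-scored).
#' @param carriers,controls Row subsets (indices, logical, or rownames).
#' @param group Optional label describing the carrier group.
#' @return Object of class `effect_map`: list with `d`, `mean1`, `mean2`,
#'   `sd1`, `sd2`, `n1`, `n2`, `group`.
#' @examples
#' v <- matrix(c(2, 4, 6, 1, 3, 5), ncol = 1)
#' cohens_d_map(v, carriers = 1:3, controls = 4:6)$d  # 0.5
#' @export
cohens_d_map <- function(volumes, carriers, controls, group = NULL) {
  volumes <- as.matrix(volumes)
  x1 <- volumes[resolve_rows(volumes, carriers), , drop = FALSE]
  x2 <- volumes[resolve_rows(volumes, controls), , drop = FALSE]
  if (nrow(x1) < 2L || nrow(x2) < 2L) {
    stop("both groups need at least 2 subjects")
  }
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  s1 <- apply(x1, 2L, stats::sd); s2 <- apply(x2, 2L, stats::sd)
  denom <- sqrt((s1^2 + s2^2) / 2)
  if (any(denom == 0)) {
    bad <- which(denom == 0)
    nm <- if (!is.null(colnames(volumes))) colnames(volumes)[bad] else bad
    stop("zero variance in both groups for region(s): ",
         paste(nm, collapse = ", "))
  }
  structure(list(d = (m1 - m2) / denom, mean1 = m1, mean2 = m2,
                 sd1 = s1, sd2 = s2, n1 = nrow(x1), n2 = nrow(x2),
                 group = group),
            class = "effect_map")
}

resolve_rows <- function(m, idx) {
  if (is.logical(idx)) which(idx)
  else if (is.character(idx)) match(idx, rownames(m))
  else idx
}

#' @export
print.effect_map <- function(x, ...) {
  cat("Effect-size map", if (!is.null(x$group)) paste0("(", x$group, ")"),
      ":", length(x$d), "regions, n =", x$n1, "vs", x$n2,
      "; mean |d| =", signif(mean(abs(x$d)), 3), "\n")
  invisible(x)
}

#' Lin's concordance correlation coefficient
#'
#' Agreement between two vectors: `rho_c = 2*s12 / (s1^2 + s2^2 +
#' (mean1 - mean2)^2)`, with population-form (n divisor) variances and
#' covariance. Equals 1 only for identical vectors and penalizes both
#' decorrelation and location/scale shifts; `|rho_c| <= |Pearson r|`.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return Object of class `concordance`: `rho_c`, `s12`, `s1_sq`, `s2_sq`,
#'   `mean_x`, `mean_y`.
#' @examples
#' lin_ccc(c(1, 2, 3), c(2, 3, 4))$rho_c  # 4/7
#' @export
lin_ccc <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    stop("x and y must have equal length >= 2")
  }
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  s1 <- mean((x - mx)^2); s2 <- mean((y - my)^2)
  if (s1 == 0 && s2 == 0) stop("concordance undefined: both vectors constant")
  s12 <- mean((x - mx) * (y - my))
  structure(list(rho_c = 2 * s12 / (s1 + s2 + (mx - my)^2),
                 s12 = s12, s1_sq = s1, s2_sq = s2,
                 mean_x = mx, mean_y = my),
            class = "concordance")
}

#' @export
print.concordance <- function(x, ...) {
  cat("Lin's concordance rho_c =", signif(x$rho_c, 4), "\n")
  invisible(x)
}

## Haar-uniform random rotation in SO(3): QR of a Gaussian matrix with the
## R-diagonal sign fix, then determinant correction.
random_rotation <- function() {
  qrm <- qr(matrix(stats::rnorm(9L), 3L))
  Q <- qr.Q(qrm) %*% diag(sign(diag(qr.R(qrm))))
  if (det(Q) < 0) Q[, 3L] <- -Q[, 3L]
  Q
}

#' Spin permutation test for the correlation of two parcel maps
#'
#' Spatial null for parcellated brain maps: for each permutation a uniform
#' random 3-D rotation is applied to all parcel centroids and each region is
#' reassigned the value of `map_b`'s region whose original centroid lies
#' nearest the rotated position (nearest-centroid rule; duplicated source
#' values are allowed). The null statistic is the Pearson correlation between
#' `map_a` and the spun `map_b`; the two-sided p-value is
#' `(1 + #{|r_null| >= |r_obs|}) / (n_perm + 1)`. Because rotations preserve
#' the spatial autocorrelation of the map, the test is calibrated for smooth
#' maps where a naive parametric test is not.
#'
#' @param map_a,map_b Numeric vectors, one value per atlas region.
#' @param atlas An `atlas_spec` supplying the spherical centroids.
#' @param n_perm Number of rotations (default 1000).
#' @param seed Integer seed.
#' @return List with `r_obs`, `p`, `null` (length `n_perm`), `n_perm`.
#' @export
spin_test <- function(map_a, map_b, atlas, n_perm = 1000L, seed = 1L) {
  stopifnot(inherits(atlas, "atlas_spec"))
  if (length(map_a) != atlas$n_regions || length(map_b) != atlas$n_regions) {
    stop("maps must have one value per atlas region")
  }
  if (stats::sd(map_a) == 0 || stats::sd(map_b) == 0) {
    stop("correlation undefined for a constant map")
  }
  n_perm <- as.integer(n_perm)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  set.seed(as.integer(seed))
  r_obs <- stats::cor(map_a, map_b)
  cent <- atlas$centroid
  null <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    rot <- cent %*% t(random_rotation())
    nearest <- max.col(rot %*% t(cent), ties.method = "first")
    spun <- map_b[nearest]
    null[b] <- if (stats::sd(spun) == 0) 0 else stats::cor(map_a, spun)
  }
  p <- (1 + sum(abs(null) >= abs(r_obs))) / (n_perm + 1)
  list(r_obs = r_obs, p = p, null = null, n_perm = n_perm)
}

#' Pairwise similarity of CNV brain maps with spin-permutation significance
#'
#' Pearson correlations between all map pairs, spin-test p-values per
#' off-diagonal pair, Benjamini-Hochberg FDR across the pairs, and the mean
#' absolute off-diagonal correlation ("average similarity").
#'
#' @param maps Matrix (n_maps x n_regions) or list of equal-length vectors;
#'   row/element names label the maps.
#' @param atlas The `atlas_spec` for the spin null.
#' @param n_perm Rotations per pair (default 1000).
#' @param seed Integer master seed (per-pair seeds are derived from it).
#' @return Object of class `map_similarity`: `r`, `p`, `p_fdr` (matrices),
#'   `mean_abs_r`, `n_perm`.
#' @export
similarity_matrix <- function(maps, atlas, n_perm = 1000L, seed = 1L) {
  if (is.list(maps)) maps <- do.call(rbind, maps)
  maps <- as.matrix(maps)
  K <- nrow(maps)
  if (ncol(maps) != atlas$n_regions) {
    stop("maps must have one column per atlas region")
  }
  nm <- rownames(maps)
  if (is.null(nm)) nm <- paste0("map_", seq_len(K))
  r <- stats::cor(t(maps))
  p <- matrix(NA_real_, K, K, dimnames = list(nm, nm))
  dimnames(r) <- list(nm, nm)
  pairs <- which(upper.tri(r), arr.ind = TRUE)
  pvec <- numeric(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs[i, 1L]; b <- pairs[i, 2L]
    st <- spin_test(maps[a, ], maps[b, ], atlas, n_perm = n_perm,
                    seed = derive_seed(seed, paste0("spin_", a, "_", b)))
    pvec[i] <- st$p
    p[a, b] <- p[b, a] <- st$p
  }
  pf <- stats::p.adjust(pvec, method = "BH")
  p_fdr <- matrix(NA_real_, K, K, dimnames = list(nm, nm))
  for (i in seq_len(nrow(pairs))) {
    p_fdr[pairs[i, 1L], pairs[i, 2L]] <- pf[i]
    p_fdr[pairs[i, 2L], pairs[i, 1L]] <- pf[i]
  }
  structure(list(r = r, p = p, p_fdr = p_fdr,
                 mean_abs_r = mean(abs(r[upper.tri(r)])),
                 n_perm = as.integer(n_perm)),
            class = "map_similarity")
}

#' @export
print.map_similarity <- function(x, ...) {
  cat("Map similarity:", nrow(x$r), "maps; mean |r| (off-diagonal) =",
      signif(x$mean_abs_r, 3), "\n")
  print(round(x$r, 2))
  invisible(x)
}
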