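#' Default phenome category assignment
#'
#' Phenotypes are partitioned into contiguous, near-equal category blocks so
#' that the simulator and any category-restricted coupling agree on which
#' phenotype belongs where.
#'
#' @param n_phenotypes Number of phenotypes P.
#' @param n_categories Number of categories (default 11).
#' @return Integer vector of length P with values in 1..n_categories.
#' @export
phenome_categories <- function(n_phenotypes, n_categories = 11L) {
  sort(rep_len(seq_len(n_categories), n_phenotypes))
}

phenome_category_names <- function(n_categories = 11L) {
  nm <- c("cognitive", "physical_general", "bone_density", "blood_assays",
          "cardiac", "mental_health", "early_life", "lifestyle",
          "sociodemographics", "medical_history", "environment")
  if (n_categories == 11L) nm else paste0("category_", seq_len(n_categories))
}

#' Generate ground-truth CNV signatures and phenome couplings
#'
#' Builds, for each of the 8 CNV groups, a spatially smooth, network-weighted,
#' zero-mean unit-norm effect map (`beta`). Within each locus the duplication
#' map is constructed as
#' `-mirror_rho * beta_del + sqrt(1 - mirror_rho^2) * e` with `e` an
#' independent smooth map orthogonalized against the deletion map, so the
#' deletion/duplication correlation equals `-mirror_rho` exactly (the mirror
#' effect). Phenome coupling rows are
#' `c * shared + (1 - c) * independent` with `c = pheno_convergence`, giving
#' pairwise row correlations `c^2 / (c^2 + (1-c)^2)` that increase
#' monotonically from 0 (c = 0) to 1 (c = 1); rows are rescaled to root-mean
#' square `coupling_strength`.
#'
#' @param atlas An `atlas_spec`.
#' @param n_phenotypes Number of phenome variables P (default 977).
#' @param theta Length-8 effect scales: the root-mean-square per-region
#'   carrier effect in standard-deviation units of the regional noise
#'   (default all 1); see [simulate_clinical()] for the exact injection.
#' @param mirror_rho Length-4 per-locus target anti-correlation in `[0, 1]`.
#' @param pheno_convergence Scalar in `[0, 1]`: cross-CNV similarity of the
#'   phenome coupling rows.
#' @param coupling_strength Root-mean-square magnitude of each coupling row.
#' @param n_categories Number of phenome categories (default 11).
#' @param active_categories Optional integer vector; couplings are zeroed
#'   outside these categories (default: all categories active).
#' @param network_focus Optional length-8 integer vector (NA = none): network
#'   whose regions get amplified weight in that CNV's map.
#' @param focus_gain Multiplicative gain for the focused network (default 4).
#' @param n_bumps,concentration Smooth-map parameters, see
#'   [random_smooth_map()].
#' @param network_weight_sd Log-sd of random per-network weights (default 0.6).
#' @param seed Integer seed.
#' @return An object of class `ground_truth` with elements `beta` (8 x
#'   n_regions), `theta`, `mirror_rho`, `gamma` (8 x P), `pheno_convergence`,
#'   `coupling_strength`, `category`, `category_names`.
#' @export
make_signatures <- function(atlas, n_phenotypes = 977L,
                            theta = rep(1, 8),
                            mirror_rho = c(0.3, 0.4, 0.4, 0.5),
                            pheno_convergence = 0.8,
                            coupling_strength = 0.1,
                            n_categories = 11L,
                            active_categories = NULL,
                            network_focus = NULL,
                            focus_gain = 4,
                            n_bumps = 6L, concentration = 12,
                            network_weight_sd = 0.6,
                            seed = 1L) {
  stopifnot(inherits(atlas, "atlas_spec"))
  theta <- rep_len(theta, 8L)
  mirror_rho <- rep_len(mirror_rho, 4L)
  if (any(mirror_rho < 0 | mirror_rho > 1)) {
    stop("mirror_rho must lie in [0, 1]")
  }
  if (length(pheno_convergence) != 1L ||
      pheno_convergence < 0 || pheno_convergence > 1) {
    stop("pheno_convergence must be a scalar in [0, 1]")
  }
  set.seed(as.integer(seed))
  R <- atlas$n_regions
  K <- length(atlas$network_names)
  labels <- cnv_labels()
  beta <- matrix(0, 8L, R, dimnames = list(labels, rownames(atlas$centroid)))

  weight_for <- function(cnv_idx) {
    w <- exp(stats::rnorm(K, 0, network_weight_sd))
    if (!is.null(network_focus) && !is.na(network_focus[cnv_idx])) {
      w[network_focus[cnv_idx]] <- w[network_focus[cnv_idx]] * focus_gain
    }
    w[atlas$network]
  }
  unit_centered <- function(v) {
    v <- v - mean(v)
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) stop("degenerate (constant) smooth map; increase n_bumps")
    v / nv
  }
  for (l in seq_len(4L)) {
    i_del <- 2L * l - 1L
    i_dup <- 2L * l
    a <- unit_centered(random_smooth_map(atlas, n_bumps, concentration) *
                         weight_for(i_del))
    e <- random_smooth_map(atlas, n_bumps, concentration) * weight_for(i_dup)
    e <- e - mean(e)
    e <- e - sum(e * a) * a
    ne <- sqrt(sum(e^2))
    if (ne < 1e-10) stop("degenerate orthogonal complement at locus ", l)
    e <- e / ne
    rho <- mirror_rho[l]
    beta[i_del, ] <- a
    beta[i_dup, ] <- -rho * a + sqrt(1 - rho^2) * e
  }

  P <- as.integer(n_phenotypes)
  category <- phenome_categories(P, n_categories)
  shared <- stats::rnorm(P)
  gamma <- matrix(0, 8L, P, dimnames = list(labels, NULL))
  cc <- pheno_convergence
  for (k in seq_len(8L)) {
    row <- cc * shared + (1 - cc) * stats::rnorm(P)
    if (!is.null(active_categories)) {
      row[!(category %in% active_categories)] <- 0
    }
    rms <- sqrt(mean(row^2))
    if (rms > 0) row <- row * coupling_strength / rms
    gamma[k, ] <- row
  }
  colnames(gamma) <- sprintf("phenotype_%04d", seq_len(P))

  structure(list(beta = beta,
                 theta = stats::setNames(theta, labels),
                 mirror_rho = stats::setNames(mirror_rho,
                                              unique(sub("_(del|dup)$", "", labels))),
                 gamma = gamma,
                 pheno_convergence = pheno_convergence,
                 coupling_strength = coupling_strength,
                 category = category,
                 category_names = phenome_category_names(n_categories),
                 seed = as.integer(seed)),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Ground truth: 8 CNV signatures over", ncol(x$beta), "regions,",
      ncol(x$gamma), "phenome couplings\n")
  cat("  theta:", paste(signif(x$theta, 3), collapse = " "), "\n")
  cat("  mirror_rho:", paste(x$mirror_rho, collapse = " "),
      " pheno_convergence:", x$pheno_convergence, "\n")
  invisible(x)
}
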