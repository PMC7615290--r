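#' Canonical CNV group labels
#'
#' The eight recurrent copy-number variants analysed throughout the package:
#' deletions and duplications at the 1q21.1, 15q11.2, 16p11.2 and 22q11.2
#' loci. Ordering is fixed (del before dup within each locus) and shared by
#' every simulator and analysis function.
#'
#' @return Character vector of length 8.
#' @export
cnv_labels <- function() {
  loci <- c("1q21.1", "15q11.2", "16p11.2", "22q11.2")
  as.vector(t(outer(loci, c("del", "dup"), paste, sep = "_")))
}

## locus index (1..4) for each of the 8 CNV groups
cnv_locus <- function() rep(1:4, each = 2L)

yeo7_names <- function() {
  c("visual", "somatomotor", "dorsal_attention", "salience_ventral_attention",
    "limbic", "frontoparietal", "default_mode")
}

#' Build a spherical parcellation with network labels
#'
#' Places `n_regions` parcel centroids on the unit sphere as a quasi-uniform
#' Fibonacci lattice and groups them into `n_networks` spatially contiguous
#' networks by nearest-seed-direction assignment (seed directions drawn
#' uniformly on the sphere). Empty networks are repaired by pulling in the
#' region closest to the network's seed direction, so every network holds at
#' least one region. This emulates the structure of a cortical parcel atlas
#' with a 7-network grouping at arbitrary resolution.
#'
#' @param n_regions Number of parcels (>= `n_networks`).
#' @param n_networks Number of networks (default 7; with 7 the conventional
#'   large-scale network names are attached).
#' @param seed Integer seed; the lattice is deterministic, the seed controls
#'   the network seed directions.
#' @return An object of class `atlas_spec`: list with `n_regions`,
#'   `network` (integer labels in 1..K), `centroid` (n x 3 matrix, unit
#'   rows), `network_names`.
#' @examples
#' atl <- make_atlas(100, 7, seed = 1)
#' table(atl$network)
#' @export
make_atlas <- function(n_regions, n_networks = 7L, seed = 1L) {
  n_regions <- as.integer(n_regions)
  n_networks <- as.integer(n_networks)
  if (n_networks < 1L || n_regions < n_networks) {
    stop("invalid design: need n_regions >= n_networks >= 1 (got ",
         n_regions, " regions, ", n_networks, " networks)")
  }
  cent <- fibonacci_sphere(n_regions)
  set.seed(as.integer(seed))
  dirs <- matrix(stats::rnorm(3L * n_networks), ncol = 3L)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  lab <- max.col(cent %*% t(dirs), ties.method = "first")
  ## repair: guarantee every network non-empty without emptying another
  for (k in seq_len(n_networks)) {
    if (any(lab == k)) next
    affinity <- as.vector(cent %*% dirs[k, ])
    counts <- tabulate(lab, n_networks)
    movable <- which(counts[lab] > 1L)
    cand <- movable[which.max(affinity[movable])]
    lab[cand] <- k
  }
  nm <- if (n_networks == 7L) yeo7_names() else
    paste0("network_", seq_len(n_networks))
  rn <- sprintf("region_%03d", seq_len(n_regions))
  dimnames(cent) <- list(rn, c("x", "y", "z"))
  structure(list(n_regions = n_regions, network = lab, centroid = cent,
                 network_names = nm),
            class = "atlas_spec")
}

## Fibonacci lattice on the unit sphere: deterministic, quasi-uniform.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 1
  z <- 1 - 2 * (i + 0.5) / n
  r <- sqrt(pmax(0, 1 - z^2))
  ga <- pi * (3 - sqrt(5))
  cent <- cbind(r * cos(ga * i), r * sin(ga * i), z)
  cent / sqrt(rowSums(cent^2))
}

#' @export
print.atlas_spec <- function(x, ...) {
  cat("Spherical atlas:", x$n_regions, "regions,",
      length(x$network_names), "networks\n")
  print(table(factor(x$network_names[x$network], levels = x$network_names)))
  invisible(x)
}

#' Smooth random map on an atlas sphere
#'
#' Sum of isotropic bumps exp(kappa * (cos(angle) - 1)) centred at random
#' directions with random signed amplitudes. Produces maps with genuine
#' spatial autocorrelation, which is what the spin-permutation null is
#' designed to respect.
#'
#' @param atlas An `atlas_spec`.
#' @param n_bumps Number of bumps summed (default 6).
#' @param concentration Bump concentration kappa; larger = more focal
#'   (default 12).
#' @param seed Integer seed, or `NULL` to draw from the current RNG stream.
#' @return Numeric vector of length `atlas$n_regions` (not normalized).
#' @export
random_smooth_map <- function(atlas, n_bumps = 6L, concentration = 12,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  ctr <- matrix(stats::rnorm(3L * n_bumps), ncol = 3L)
  ctr <- ctr / sqrt(rowSums(ctr^2))
  amp <- stats::rnorm(n_bumps)
  cosang <- atlas$centroid %*% t(ctr)
  as.vector(exp(concentration * (cosang - 1)) %*% amp)
}

## Deterministic derivation of stage seeds from a master seed, kept within
## 32-bit integer range.
derive_seed <- function(seed, stage) {
  chars <- utf8ToInt(as.character(stage))
  h <- sum(chars * seq_along(chars))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}
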