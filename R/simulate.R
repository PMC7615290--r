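#' Clinical cohort design (group sizes)
#'
#' Default per-group subject counts for the clinical cohort: carriers
#' 24, 15, 112, 146, 80, 69, 69, 19 for the 8 CNV groups (total 534) and 312
#' controls, optionally scaled by a common factor (minimum 2 per group).
#'
#' @param scale Multiplicative factor applied to every group size.
#' @return Named integer vector (8 CNV groups + `control`).
#' @export
clinical_design <- function(scale = 1) {
  sizes <- c(24, 15, 112, 146, 80, 69, 69, 19, 312)
  names(sizes) <- c(cnv_labels(), "control")
  out <- pmax(2L, as.integer(round(sizes * scale)))
  names(out) <- names(sizes)
  out
}

#' Population cohort design (carrier counts)
#'
#' Default carrier counts for the population cohort: 12, 14, 117, 155, 4, 7,
#' 5, 47 carriers of the 8 CNV groups plus 38,731 non-carriers (the published
#' demographic-table counts; their implied total fixes the default
#' `n_subjects`).
#'
#' @param n_subjects Total cohort size.
#' @param carrier_counts Named length-8 vector of carrier counts.
#' @return List with `n_subjects`, `carrier_counts`, `n_noncarriers`.
#' @export
population_design <- function(n_subjects = 39092L,
                              carrier_counts = c(12L, 14L, 117L, 155L,
                                                 4L, 7L, 5L, 47L)) {
  carrier_counts <- stats::setNames(as.integer(rep_len(carrier_counts, 8L)),
                                    cnv_labels())
  n_subjects <- as.integer(n_subjects)
  if (sum(carrier_counts) >= n_subjects) {
    stop("invalid design: carrier counts (", sum(carrier_counts),
         ") must sum to less than n_subjects (", n_subjects, ")")
  }
  list(n_subjects = n_subjects, carrier_counts = carrier_counts,
       n_noncarriers = n_subjects - sum(carrier_counts))
}

default_clinical_confounds <- function() {
  list(icv_mean = 1500, icv_sd = 120, icv_loading = 0.004,
       age_range = c(6, 64), age_loading = 0.02, age2_loading = -2e-4,
       sex_loading = 0.3, n_sites = 4L, site_sd = 0.3,
       site_prefix = "clinical_site_")
}

default_population_confounds <- function() {
  list(head_size_mean = 1450, head_size_sd = 110, head_size_loading = 0.004,
       bmi_mean = 27, bmi_sd = 4, bmi_loading = 0.02,
       motion_meanlog = -1.5, motion_sdlog = 0.5, motion_loading = -0.3,
       age_range = c(45, 80), age_loading = 0.01, sex_loading = 0.2,
       n_sites = 3L, site_sd = 0.3, site_prefix = "population_site_")
}

default_phenome_config <- function() {
  list(prop_binary = 0.25, prop_ordinal = 0.15, ordinal_levels = 4L,
       binary_quantile = 0.5, missing_rate = 0.05, max_missing = 0.2,
       noise_sd = 1)
}

merge_config <- function(defaults, user) {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) stop("unknown config entries: ",
                            paste(unknown, collapse = ", "))
  defaults[names(user)] <- user
  defaults
}

#' Simulate the multisite clinical cohort
#'
#' Volume of subject i in region j is
#' `baseline_j + site_offset + ICV/age/age^2/sex loadings + carrier effect +
#' Gaussian noise`, where the carrier effect for a subject in CNV group k is
#' `theta_k * sqrt(n_regions) * beta_kj`. Since the signature rows `beta_k`
#' are unit-L2-norm spatial patterns, the `sqrt(n_regions)` factor makes
#' `theta_k` the root-mean-square per-region effect in units of the regional
#' noise standard deviation: at `theta = 1` a typical region shifts by about
#' one noise SD, i.e. a regional Cohen's d of order 1.
#'
#' @param truth A `ground_truth`.
#' @param atlas The `atlas_spec` the truth was built on.
#' @param sizes Named group sizes as from [clinical_design()].
#' @param confound_cfg Optional list overriding entries of the default
#'   confound configuration (ICV/age/sex loadings, site count and spread).
#' @param noise_sd Regional noise SD (default 1).
#' @param seed Integer seed.
#' @return An object of class `clinical_cohort`: list with `volumes`
#'   (subjects x regions), `group` (factor, `control` + 8 CNV labels),
#'   `confounds` (data.frame: icv, age, sex, site).
#' @export
simulate_clinical <- function(truth, atlas, sizes = clinical_design(),
                              confound_cfg = NULL, noise_sd = 1, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"), inherits(atlas, "atlas_spec"))
  cfg <- merge_config(default_clinical_confounds(), confound_cfg)
  labels <- c(cnv_labels(), "control")
  if (is.null(names(sizes))) names(sizes) <- labels
  sizes <- sizes[labels]
  if (any(is.na(sizes)) || any(sizes < 2)) {
    stop("invalid design: every group (8 CNVs + control) needs size >= 2")
  }
  set.seed(as.integer(seed))
  n <- sum(sizes)
  R <- atlas$n_regions
  group <- factor(rep(labels, times = sizes), levels = c("control", cnv_labels()))

  icv <- stats::rnorm(n, cfg$icv_mean, cfg$icv_sd)
  age <- stats::runif(n, cfg$age_range[1], cfg$age_range[2])
  sex <- stats::rbinom(n, 1L, 0.5)
  site <- factor(paste0(cfg$site_prefix,
                        sample.int(cfg$n_sites, n, replace = TRUE)))
  site_offset <- matrix(stats::rnorm(cfg$n_sites * R, 0, cfg$site_sd),
                        cfg$n_sites, R)
  baseline <- stats::rnorm(R, 10, 1)

  vol <- matrix(baseline, n, R, byrow = TRUE) +
    site_offset[as.integer(site), , drop = FALSE] +
    (cfg$icv_loading * icv + cfg$age_loading * age +
       cfg$age2_loading * age^2 + cfg$sex_loading * sex)
  for (k in seq_len(8L)) {
    idx <- which(group == cnv_labels()[k])
    if (length(idx)) {
      eff <- truth$theta[k] * sqrt(R) * truth$beta[k, ]
      vol[idx, ] <- vol[idx, ] + matrix(eff, length(idx), R, byrow = TRUE)
    }
  }
  vol <- vol + matrix(stats::rnorm(n * R, 0, noise_sd), n, R)
  dimnames(vol) <- list(sprintf("clin_%04d", seq_len(n)), colnames(truth$beta))

  structure(list(volumes = vol, group = group,
                 confounds = data.frame(icv = icv, age = age, sex = sex,
                                        site = site,
                                        row.names = rownames(vol)),
                 sizes = sizes, seed = as.integer(seed)),
            class = "clinical_cohort")
}

#' @export
print.clinical_cohort <- function(x, ...) {
  cat("Clinical cohort:", nrow(x$volumes), "subjects x", ncol(x$volumes),
      "regions;", nlevels(x$confounds$site), "sites\n")
  print(table(x$group))
  invisible(x)
}

#' Simulate the population cohort with phenome
#'
#' Volumes follow the same generative model as [simulate_clinical()] but with
#' the population nuisance set (head size, body-mass index, head motion, age,
#' sex, site; site identifiers are distinct from the clinical cohort's).
#' Each subject's latent signature expression is
#' `t_i = (carrier effect + regional noise) . beta^T` (the part of the volume
#' profile that survives confound removal), and phenome values are
#' `y_iq = gamma[, q] . t_i + noise`. Binary phenotypes are thresholded at a
#' configurable latent quantile, ordinal phenotypes binned into
#' equal-probability levels, and missingness is applied completely at random.
#'
#' @param truth A `ground_truth`.
#' @param atlas The matching `atlas_spec`.
#' @param n_subjects Total cohort size.
#' @param carrier_counts Length-8 carrier counts (default: [population_design()]).
#' @param confound_cfg,phenome_cfg Optional overrides of the default
#'   configurations.
#' @param noise_sd Regional volume noise SD (default 1).
#' @param seed Integer seed.
#' @return Object of class `population_cohort`: `volumes`, `carrier_status`
#'   (factor `non_carrier` + 8 CNV labels), `confounds`, `phenome` (class
#'   `phenome_table`: `values` with NA for missing, `var_type`, `category`,
#'   `category_names`), `latent_expression` (N x 8 ground-truth doses).
#' @export
simulate_population <- function(truth, atlas, n_subjects = 39085L,
                                carrier_counts = NULL,
                                confound_cfg = NULL, phenome_cfg = NULL,
                                noise_sd = 1, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"), inherits(atlas, "atlas_spec"))
  cfg <- merge_config(default_population_confounds(), confound_cfg)
  pcfg <- merge_config(default_phenome_config(), phenome_cfg)
  if (pcfg$missing_rate > pcfg$max_missing) {
    stop("missing_rate exceeds configured maximum")
  }
  des <- if (is.null(carrier_counts)) population_design(n_subjects)
         else population_design(n_subjects, carrier_counts)
  N <- des$n_subjects
  R <- atlas$n_regions
  P <- ncol(truth$gamma)
  set.seed(as.integer(seed))

  status <- factor(rep(c("non_carrier", cnv_labels()),
                       times = c(des$n_noncarriers, des$carrier_counts)),
                   levels = c("non_carrier", cnv_labels()))
  status <- status[sample.int(N)]

  head_size <- stats::rnorm(N, cfg$head_size_mean, cfg$head_size_sd)
  bmi <- stats::rnorm(N, cfg$bmi_mean, cfg$bmi_sd)
  motion <- stats::rlnorm(N, cfg$motion_meanlog, cfg$motion_sdlog)
  age <- stats::runif(N, cfg$age_range[1], cfg$age_range[2])
  sex <- stats::rbinom(N, 1L, 0.5)
  site <- factor(paste0(cfg$site_prefix,
                        sample.int(cfg$n_sites, N, replace = TRUE)))
  site_offset <- matrix(stats::rnorm(cfg$n_sites * R, 0, cfg$site_sd),
                        cfg$n_sites, R)
  baseline <- stats::rnorm(R, 10, 1)

  ## signal part (carrier effect + regional noise): defines the latent dose
  signal <- matrix(stats::rnorm(N * R, 0, noise_sd), N, R)
  for (k in seq_len(8L)) {
    idx <- which(status == cnv_labels()[k])
    if (length(idx)) {
      eff <- truth$theta[k] * sqrt(R) * truth$beta[k, ]
      signal[idx, ] <- signal[idx, ] + matrix(eff, length(idx), R, byrow = TRUE)
    }
  }
  latent <- signal %*% t(truth$beta)
  colnames(latent) <- cnv_labels()

  vol <- matrix(baseline, N, R, byrow = TRUE) +
    site_offset[as.integer(site), , drop = FALSE] +
    (cfg$head_size_loading * head_size + cfg$bmi_loading * bmi +
       cfg$motion_loading * motion + cfg$age_loading * age +
       cfg$sex_loading * sex) + signal
  dimnames(vol) <- list(sprintf("pop_%05d", seq_len(N)), colnames(truth$beta))
  rownames(latent) <- rownames(vol)

  ## phenome: latent continuous values then type coercion + MCAR missingness
  y <- latent %*% truth$gamma +
    matrix(stats::rnorm(N * P, 0, pcfg$noise_sd), N, P)
  n_bin <- round(pcfg$prop_binary * P)
  n_ord <- round(pcfg$prop_ordinal * P)
  var_type <- rep("continuous", P)
  var_type[sample.int(P, n_bin + n_ord)] <-
    rep(c("binary", "ordinal"), c(n_bin, n_ord))
  for (q in seq_len(P)) {
    if (var_type[q] == "binary") {
      y[, q] <- as.numeric(y[, q] > stats::quantile(y[, q],
                                                    pcfg$binary_quantile))
    } else if (var_type[q] == "ordinal") {
      L <- pcfg$ordinal_levels
      br <- stats::quantile(y[, q], probs = seq(0, 1, length.out = L + 1))
      br[1] <- -Inf; br[L + 1] <- Inf
      y[, q] <- as.integer(cut(y[, q], breaks = unique(br),
                               labels = FALSE, include.lowest = TRUE))
    }
  }
  if (pcfg$missing_rate > 0) {
    y[matrix(stats::runif(N * P) < pcfg$missing_rate, N, P)] <- NA
  }
  dimnames(y) <- list(rownames(vol), colnames(truth$gamma))

  phenome <- structure(list(values = y, var_type = var_type,
                            category = truth$category,
                            category_names = truth$category_names),
                       class = "phenome_table")
  structure(list(volumes = vol, carrier_status = status,
                 confounds = data.frame(head_size = head_size, bmi = bmi,
                                        motion = motion, age = age, sex = sex,
                                        site = site, row.names = rownames(vol)),
                 phenome = phenome, latent_expression = latent,
                 design = des, seed = as.integer(seed)),
            class = "population_cohort")
}

#' @export
print.population_cohort <- function(x, ...) {
  cat("Population cohort:", nrow(x$volumes), "subjects x", ncol(x$volumes),
      "regions;", ncol(x$phenome$values), "phenotypes\n")
  print(table(x$carrier_status))
  invisible(x)
}

#' @export
print.phenome_table <- function(x, ...) {
  cat("Phenome table:", nrow(x$values), "subjects x", ncol(x$values),
      "phenotypes (", paste(table(x$var_type), names(table(x$var_type))),
      ")\n")
  invisible(x)
}
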