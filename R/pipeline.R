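#' Assemble a pipeline configuration
#'
#' Collects every tunable of the end-to-end run — atlas resolution, cohort
#' design, effect and coupling parameters, ensemble and permutation sizes,
#' significance levels — with desk-scale defaults (100 regions, the standard
#' clinical group sizes, a 4,000-subject population with 200 phenotypes)
#' chosen to keep a full run in the minutes range while preserving the class
#' imbalance and multiplicity structure of the full-scale design. Every
#' stochastic stage derives its own seed deterministically from the master
#' seed.
#'
#' @param seed Master seed.
#' @param ... Overrides for any default entry (unknown names are an error).
#' @return Object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_regions = 100L,
    n_networks = 7L,
    n_phenotypes = 200L,
    n_categories = 11L,
    theta = rep(1, 8),
    mirror_rho = c(0.3, 0.4, 0.4, 0.5),
    pheno_convergence = 0.8,
    coupling_strength = 0.1,
    clinical_sizes = clinical_design(),
    n_population = 4000L,
    population_carriers = pmax(2L, as.integer(round(
      c(12, 14, 117, 155, 4, 7, 5, 47) * 4000 / 39085))),
    B = 25L,
    B_null = 10L,
    n_perm_label = 20L,
    n_perm_spin = 199L,
    n_perm_profile = 199L,
    boot_replicates = 1999L,
    alpha = 0.05,
    grid = seq(0, 1, by = 0.1),
    min_n = 10L
  )
  user <- list(...)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) stop("unknown config entries: ",
                            paste(unknown, collapse = ", "))
  cfg[names(user)] <- user
  structure(cfg, class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Range and cross-field consistency checks. Violations are returned as
#' data (a character vector naming the offending fields), not raised as
#' errors.
#'
#' @param config A `pipeline_config`.
#' @return Character vector of violations; empty when the config is valid.
#' @export
validate_config <- function(config) {
  v <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  chk(config$n_regions >= config$n_networks && config$n_networks >= 1,
      "n_regions must be >= n_networks >= 1")
  chk(all(config$mirror_rho >= 0 & config$mirror_rho <= 1),
      "mirror_rho must lie in [0, 1]")
  chk(length(config$pheno_convergence) == 1 &&
        config$pheno_convergence >= 0 && config$pheno_convergence <= 1,
      "pheno_convergence must lie in [0, 1]")
  chk(all(config$clinical_sizes >= 2) && length(config$clinical_sizes) == 9,
      "clinical_sizes needs 9 entries, each >= 2")
  chk(sum(config$population_carriers) < config$n_population,
      "population carrier counts must sum to less than n_population")
  chk(all(config$grid >= 0 & config$grid <= 1) && length(config$grid) >= 1,
      "shrinkage grid must lie in [0, 1]")
  chk(config$alpha > 0 && config$alpha < 1, "alpha must lie in (0, 1)")
  chk(config$B >= 1, "B must be >= 1")
  chk(config$n_perm_label >= 1 && config$B_null >= 1,
      "label-permutation settings must be >= 1")
  chk(config$n_phenotypes >= config$n_categories,
      "n_phenotypes must be >= n_categories")
  chk(config$boot_replicates >= 1, "boot_replicates must be >= 1")
  v
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline config: seed", x$seed, "|", x$n_regions, "regions |",
      sum(x$clinical_sizes), "clinical subjects |", x$n_population,
      "population subjects x", x$n_phenotypes, "phenotypes | B =", x$B, "\n")
  viol <- validate_config(x)
  if (length(viol)) cat("  VIOLATIONS:", paste(viol, collapse = "; "), "\n")
  invisible(x)
}

#' Run the full pipeline and write its artifacts
#'
#' Executes simulate -> preprocess -> effect maps -> ensembles -> transfer
#' -> PheWAS -> convergence report, writing every artifact as a delimited
#' table (TSV) or JSON under `out_dir`, and returns a manifest listing each
#' output file with a content digest plus stage warnings (invalid bootstrap
#' iterations, untestable phenotypes, discarded outliers). Any stage error
#' aborts with the stage name; the partial manifest is still written.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Output directory (created if missing).
#' @return Object of class `run_manifest` (invisibly).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  viol <- validate_config(config)
  if (length(viol)) stop("invalid config: ", paste(viol, collapse = "; "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("cnvsig")),
                   seed = config$seed, started = format(Sys.time()),
                   stages = list(), files = list(), warnings = character(0))
  seed <- config$seed
  labels <- cnv_labels()
  finish <- function() {
    manifest$finished <- format(Sys.time())
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
               file.path(out_dir, "manifest.json"))
    structure(manifest, class = "run_manifest")
  }
  record <- function(stage, files) {
    manifest$stages[[stage]] <<- list(outputs = basename(files))
    for (f in files) {
      manifest$files[[basename(f)]] <<- unname(tools::md5sum(f))
    }
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      manifest$warnings <<- c(manifest$warnings,
                              paste0("stage '", stage, "' failed: ",
                                     conditionMessage(e)))
      finish()
      stop("pipeline aborted at stage '", stage, "': ",
           conditionMessage(e), call. = FALSE)
    })
  }

  ## --- simulate ---------------------------------------------------------
  atlas <- truth <- clinical <- population <- NULL
  run_stage("simulate", {
    atlas <- make_atlas(config$n_regions, config$n_networks,
                         seed = derive_seed(seed, "atlas"))
    truth <- make_signatures(atlas, n_phenotypes = config$n_phenotypes,
                              theta = config$theta,
                              mirror_rho = config$mirror_rho,
                              pheno_convergence = config$pheno_convergence,
                              coupling_strength = config$coupling_strength,
                              n_categories = config$n_categories,
                              seed = derive_seed(seed, "truth"))
    clinical <- simulate_clinical(truth, atlas, sizes = config$clinical_sizes,
                                   seed = derive_seed(seed, "clinical"))
    population <- simulate_population(truth, atlas,
                                       n_subjects = config$n_population,
                                       carrier_counts = config$population_carriers,
                                       seed = derive_seed(seed, "population"))
    files <- c(write_atlas_tsv(atlas, file.path(out_dir, "atlas.tsv")),
               write_truth_json(truth, file.path(out_dir, "ground_truth.json")),
               write_clinical_tsv(clinical, out_dir),
               write_population_tsv(population, out_dir))
    record("simulate", files)
  })

  ## --- preprocess -------------------------------------------------------
  adj_clin <- adj_pop <- NULL
  run_stage("preprocess", {
    adj_clin <- adjust_confounds(clinical$volumes, clinical$confounds,
                                  design = c("icv", "age", "age2", "sex",
                                             "site"))
    adj_pop <- adjust_confounds(population$volumes, population$confounds,
                                 design = c("head_size", "bmi", "motion",
                                            "age", "sex", "site"))
    f1 <- file.path(out_dir, "clinical_adjusted.tsv")
    f2 <- file.path(out_dir, "population_adjusted.tsv")
    write_matrix_tsv(adj_clin$adjusted, f1)
    write_matrix_tsv(adj_pop$adjusted, f2)
    record("preprocess", c(f1, f2))
  })

  ## --- effect maps ------------------------------------------------------
  d_maps <- map_sim <- NULL
  run_stage("effectmaps", {
    d_maps <- matrix(NA_real_, 8L, config$n_regions,
                      dimnames = list(labels, colnames(clinical$volumes)))
    controls <- clinical$group == "control"
    for (k in seq_len(8L)) {
      carriers <- clinical$group == labels[k]
      z <- zscore_columns(adj_clin$adjusted,
                          over_subjects = carriers | controls)
      d_maps[k, ] <- cohens_d_map(z, carriers, controls,
                                   group = labels[k])$d
    }
    map_sim <- similarity_matrix(d_maps, atlas, n_perm = config$n_perm_spin,
                                  seed = derive_seed(seed, "spin"))
    f1 <- file.path(out_dir, "cohens_d_maps.tsv")
    f2 <- file.path(out_dir, "map_similarity.tsv")
    write_matrix_tsv(d_maps, f1)
    write_matrix_tsv(map_sim$r, f2)
    record("effectmaps", c(f1, f2))
  })

  ## --- ensembles --------------------------------------------------------
  signatures <- NULL
  run_stage("fit", {
    controls <- clinical$group == "control"
    signatures <- vector("list", 8L)
    names(signatures) <- labels
    for (k in seq_len(8L)) {
      sel <- clinical$group == labels[k] | controls
      xk <- adj_clin$adjusted[sel, , drop = FALSE]
      yk <- as.integer(clinical$group[sel] == labels[k])
      fit <- bagged_lda(xk, yk, B = config$B, grid = config$grid,
                        align_to = d_maps[k, ],
                        seed = derive_seed(seed, paste0("bag_", labels[k])),
                        label = labels[k])
      nullk <- permutation_null(xk, yk, B = config$B,
                                n_perm = config$n_perm_label,
                                grid = config$grid,
                                seed = derive_seed(seed,
                                                   paste0("null_", labels[k])),
                                B_null = config$B_null)
      fit$null <- nullk
      signatures[[k]] <- fit
      if (fit$n_invalid > 0) {
        manifest$warnings <- c(manifest$warnings,
                                paste0(labels[k], ": ", fit$n_invalid,
                                       " invalid bootstrap iteration(s)"))
      }
    }
    f <- file.path(out_dir, "signatures.json")
    write_signatures_json(signatures, f)
    record("fit", f)
  })

  ## --- transfer ---------------------------------------------------------
  scores <- outliers <- NULL
  boot_tests <- list()
  run_stage("transfer", {
    scores <- score_expressions(adj_pop$adjusted, signatures)
    outliers <- tukey_filter(scores)
    manifest$warnings <- c(manifest$warnings,
                            paste0("tukey filter discarded ", sum(outliers),
                                   " participants"))
    for (k in seq_len(8L)) {
      carr <- population$carrier_status == labels[k]
      boot_tests[[labels[k]]] <- bootstrap_mean_test(
        scores[carr, k], scores[!carr, k], B = config$boot_replicates,
        seed = derive_seed(seed, paste0("boot_", labels[k])))
    }
    f <- file.path(out_dir, "expressions.tsv")
    write_matrix_tsv(unclass(scores), f)
    f2 <- file.path(out_dir, "expression_tests.tsv")
    utils::write.table(
      data.frame(cnv = labels,
                 mean_difference = vapply(boot_tests, `[[`, numeric(1),
                                          "estimate"),
                 p = vapply(boot_tests, `[[`, numeric(1), "p")),
      f2, sep = "\t", quote = FALSE, row.names = FALSE)
    record("transfer", c(f, f2))
  })

  ## --- phewas -----------------------------------------------------------
  profiles <- prof_sim <- NULL
  run_stage("phewas", {
    profiles <- run_phewas(scores, population$phenome, alpha = config$alpha,
                            exclude = outliers, min_n = config$min_n)
    untestable <- sum(!profiles[[1L]]$testable)
    if (untestable > 0) {
      manifest$warnings <- c(manifest$warnings,
                              paste0(untestable,
                                     " untestable phenotype(s) excluded"))
    }
    files <- character(0)
    for (k in seq_len(8L)) {
      f <- file.path(out_dir, paste0("phewas_", labels[k], ".tsv"))
      utils::write.table(as.data.frame(profiles[[k]]), f, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      files <- c(files, f)
    }
    prof_sim <- profile_similarity(profiles, n_perm = config$n_perm_profile,
                                    seed = derive_seed(seed, "profperm"))
    f2 <- file.path(out_dir, "profile_similarity.tsv")
    write_matrix_tsv(prof_sim$r, f2)
    record("phewas", c(files, f2))
  })

  ## --- report -----------------------------------------------------------
  run_stage("report", {
    report <- concordance_report(map_sim, prof_sim)
    shared <- shared_hits(profiles, min_k = min(5L, 8L))
    out <- list(
      rho_c = report$rho_c,
      n_pairs = report$n_pairs,
      n_phenotypic_greater = report$n_phenotypic_greater,
      mean_abs_map_similarity = report$mean_abs_map,
      mean_abs_profile_similarity = report$mean_abs_profile,
      mean_oob_mcc = vapply(signatures, `[[`, numeric(1), "mean_mcc"),
      null_threshold = vapply(signatures,
                              function(s) s$null$threshold, numeric(1)),
      bonferroni_hits = vapply(profiles,
                               function(p) sum(p$bonferroni), integer(1)),
      n_outliers_discarded = sum(outliers)
    )
    f <- file.path(out_dir, "convergence_report.json")
    writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE), f)
    f2 <- file.path(out_dir, "convergence_pairs.tsv")
    utils::write.table(report$pairs, f2, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    f3 <- file.path(out_dir, "shared_hits.tsv")
    utils::write.table(shared$shared, f3, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    record("report", c(f, f2, f3))
  })

  invisible(finish())
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Pipeline run (seed", x$seed, ") —", length(x$stages), "stages,",
      length(x$files), "artifacts\n")
  for (s in names(x$stages)) {
    cat("  ", s, ": ", paste(x$stages[[s]]$outputs, collapse = ", "), "\n",
        sep = "")
  }
  if (length(x$warnings)) {
    cat("  warnings:\n")
    for (w in x$warnings) cat("    -", w, "\n")
  }
  invisible(x)
}
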