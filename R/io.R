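## Plain-text artifact writers/readers: TSV for tables, JSON for models.
## Every file round-trips through the matching read_* function.

write_matrix_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m) %||% seq_len(nrow(m)),
                   as.data.frame(unclass(m)), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Write / read an atlas as TSV
#'
#' Columns: region, network (integer), network_name, x, y, z.
#' @param atlas An `atlas_spec`.
#' @param path Output file.
#' @return The path (write) or an `atlas_spec` (read).
#' @export
write_atlas_tsv <- function(atlas, path) {
  df <- data.frame(region = rownames(atlas$centroid),
                   network = atlas$network,
                   network_name = atlas$network_names[atlas$network],
                   x = atlas$centroid[, 1L], y = atlas$centroid[, 2L],
                   z = atlas$centroid[, 3L])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' @rdname write_atlas_tsv
#' @export
read_atlas_tsv <- function(path) {
  df <- utils::read.delim(path)
  cent <- as.matrix(df[, c("x", "y", "z")])
  rownames(cent) <- df$region
  nm <- unique(df[order(df$network), c("network", "network_name")])
  structure(list(n_regions = nrow(df), network = df$network,
                 centroid = cent, network_names = nm$network_name),
            class = "atlas_spec")
}

write_truth_json <- function(truth, path) {
  row_list <- function(m) {
    stats::setNames(lapply(seq_len(nrow(m)), function(i) unname(m[i, ])),
                    rownames(m))
  }
  out <- list(beta = row_list(truth$beta),
              theta = as.list(truth$theta),
              mirror_rho = as.list(truth$mirror_rho),
              gamma = row_list(truth$gamma),
              pheno_convergence = truth$pheno_convergence,
              coupling_strength = truth$coupling_strength,
              category = truth$category,
              category_names = truth$category_names,
              seed = truth$seed)
  writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA), path)
  path
}

write_clinical_tsv <- function(cohort, dir) {
  f1 <- write_matrix_tsv(cohort$volumes,
                         file.path(dir, "clinical_volumes.tsv"))
  f2 <- file.path(dir, "clinical_confounds.tsv")
  utils::write.table(data.frame(id = rownames(cohort$volumes),
                                cohort$confounds),
                     f2, sep = "\t", quote = FALSE, row.names = FALSE)
  f3 <- file.path(dir, "clinical_groups.tsv")
  utils::write.table(data.frame(id = rownames(cohort$volumes),
                                group = as.character(cohort$group)),
                     f3, sep = "\t", quote = FALSE, row.names = FALSE)
  c(f1, f2, f3)
}

write_population_tsv <- function(cohort, dir) {
  f1 <- write_matrix_tsv(cohort$volumes,
                         file.path(dir, "population_volumes.tsv"))
  f2 <- file.path(dir, "population_confounds.tsv")
  utils::write.table(data.frame(id = rownames(cohort$volumes),
                                cohort$confounds,
                                carrier_status = as.character(cohort$carrier_status)),
                     f2, sep = "\t", quote = FALSE, row.names = FALSE)
  f3 <- write_matrix_tsv(cohort$phenome$values,
                         file.path(dir, "population_phenome.tsv"))
  f4 <- file.path(dir, "population_phenome_meta.tsv")
  utils::write.table(
    data.frame(phenotype = colnames(cohort$phenome$values),
               var_type = cohort$phenome$var_type,
               category = cohort$phenome$category,
               category_name =
                 cohort$phenome$category_names[cohort$phenome$category]),
    f4, sep = "\t", quote = FALSE, row.names = FALSE)
  c(f1, f2, f3, f4)
}

#' Serialize fitted intermediate phenotypes to JSON
#'
#' Stores, per CNV signature: coefficients, bootstrap percentile intervals,
#' significance mask, per-iteration out-of-bag MCC and selected shrinkage,
#' and (when present) the label-permutation null distribution.
#'
#' @param signatures Named list of `bagged_lda` fits.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_signatures_json <- function(signatures, path) {
  ser <- lapply(signatures, function(s) {
    list(label = s$label, signature = as.list(s$signature),
         ci_lower = unname(s$ci[1L, ]), ci_upper = unname(s$ci[2L, ]),
         significant = s$significant, oob_mcc = s$oob_mcc,
         mean_mcc = s$mean_mcc, alpha = s$alpha, B = s$B,
         n_invalid = s$n_invalid, n_carriers = s$n_carriers,
         n_controls = s$n_controls, seed = s$seed,
         null_mcc = if (!is.null(s$null)) s$null$null_mcc,
         null_threshold = if (!is.null(s$null)) s$null$threshold)
  })
  writeLines(jsonlite::toJSON(ser, auto_unbox = TRUE, digits = NA, na = "null"),
             path)
  invisible(path)
}
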