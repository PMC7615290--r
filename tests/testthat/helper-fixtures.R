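## Shared small fixtures, built in code at test time.

tiny_atlas <- function(n_regions = 60L, seed = 7L) {
  make_atlas(n_regions, 7L, seed = seed)
}

## clinical cohort with one active carrier group and minimal others
one_group_sizes <- function(n_carriers, n_controls, group = 1L) {
  sizes <- stats::setNames(rep(2L, 9L), c(cnv_labels(), "control"))
  sizes[group] <- n_carriers
  sizes["control"] <- n_controls
  sizes
}

## matrix whose pooled within-class ML covariance and mean difference are known
two_class_data <- function(n_per = 30L, p = 5L, shift = 1, seed = 1L) {
  set.seed(seed)
  x <- matrix(stats::rnorm(2L * n_per * p), 2L * n_per, p)
  y <- rep(c(0L, 1L), each = n_per)
  x[y == 1L, ] <- x[y == 1L, ] + shift
  list(x = x, y = y)
}

## minimal stand-ins carrying the fields used by ensemble summaries
fake_signature <- function(n_sig, mean_mcc, p = 50L) {
  structure(list(significant = c(rep(TRUE, n_sig), rep(FALSE, p - n_sig)),
                 mean_mcc = mean_mcc),
            class = "bagged_lda")
}

## build a phewas_profile data frame directly (for pure table operations)
fake_profile <- function(r, p, bonferroni, category = NULL,
                         cat_names = c("a", "b")) {
  P <- length(r)
  if (is.null(category)) category <- rep_len(seq_along(cat_names), P)
  df <- data.frame(phenotype = sprintf("phenotype_%04d", seq_len(P)),
                   category = factor(cat_names[category], levels = cat_names),
                   r = r, p = p, n = rep(100L, P),
                   bonferroni = bonferroni, fdr = bonferroni,
                   testable = rep(TRUE, P), stringsAsFactors = FALSE)
  attr(df, "alpha") <- 0.05
  attr(df, "n_testable") <- P
  attr(df, "signature") <- "fake"
  class(df) <- c("phewas_profile", "data.frame")
  df
}
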