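test_that("single-iteration ensemble is one aligned unit-norm discriminant", {
  d <- two_class_data(15, 8, shift = 0.8, seed = 2)
  fit <- bagged_lda(d$x, d$y, B = 1, seed = 3)
  expect_equal(fit$signature, fit$discriminants[1, ])
  expect_equal(sum(fit$signature^2), 1, tolerance = 1e-12)
  ## aligned: non-negative correlation with the reference mean difference
  dmu <- colMeans(d$x[d$y == 1, ]) - colMeans(d$x[d$y == 0, ])
  expect_gte(cor(fit$signature, dmu), 0)
})

test_that("the ensemble is deterministic for a fixed seed", {
  d <- two_class_data(12, 6, shift = 0.6, seed = 4)
  f1 <- bagged_lda(d$x, d$y, B = 8, seed = 11)
  f2 <- bagged_lda(d$x, d$y, B = 8, seed = 11)
  expect_identical(f1$signature, f2$signature)
  expect_identical(f1$oob_mcc, f2$oob_mcc)
  expect_identical(f1$significant, f2$significant)
  f3 <- bagged_lda(d$x, d$y, B = 8, seed = 12)
  expect_false(identical(f1$signature, f3$signature))
})

test_that("signature recovery improves monotonically with effect size", {
  atl <- tiny_atlas(40)
  rec_at <- function(theta, s) {
    tr <- make_signatures(atl, n_phenotypes = 10, theta = rep(theta, 8),
                          seed = s)
    coh <- simulate_clinical(tr, atl, sizes = one_group_sizes(30, 60),
                             seed = 20 + s)
    adj <- adjust_confounds(coh$volumes, coh$confounds)
    sel <- coh$group %in% c(cnv_labels()[1], "control")
    fit <- bagged_lda(adj$adjusted[sel, ],
                      as.integer(coh$group[sel] == cnv_labels()[1]),
                      B = 10, seed = 30 + s)
    abs(cor(fit$signature, tr$beta[1, ]))
  }
  mean_rec <- vapply(c(0.25, 0.5, 1.0), function(th) {
    mean(vapply(1:5, function(s) rec_at(th, s), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_rec) > 0))
  expect_gt(mean_rec[3], 0.8)
})

test_that("pure-noise labels give near-nominal significant-coefficient rates", {
  set.seed(7)
  x <- matrix(rnorm(120 * 30), 120, 30)
  y <- rep(c(0, 1), each = 60)
  fit <- bagged_lda(x, y, B = 100, seed = 8)
  expect_lte(mean(fit$significant), 0.10)
  expect_lt(abs(fit$mean_mcc), 0.2)
})

test_that("permutation null reduces to its single value at n_perm = 1", {
  d <- two_class_data(10, 5, shift = 0.3, seed = 5)
  nl <- permutation_null(d$x, d$y, B = 3, n_perm = 1, seed = 6, B_null = 3)
  expect_equal(nl$threshold, nl$null_mcc)
  expect_length(nl$null_mcc, 1)
})

test_that("a planted effect clears the permutation-null threshold", {
  d <- two_class_data(25, 15, shift = 1.2, seed = 6)
  fit <- bagged_lda(d$x, d$y, B = 10, seed = 7)
  nl <- permutation_null(d$x, d$y, B = 10, n_perm = 10, seed = 8, B_null = 5)
  expect_gt(fit$mean_mcc, nl$threshold)
})

test_that("network summaries count significant coefficients per network", {
  atl <- tiny_atlas(70)
  K <- length(atl$network_names)
  ## degenerate masks
  ns0 <- network_summary(rep(FALSE, 70), atl)
  expect_equal(ns0$fraction, rep(0, K))
  mask3 <- atl$network == 3
  ns3 <- network_summary(mask3, atl)
  expect_equal(ns3$fraction, as.numeric(seq_len(K) == 3))
  expect_true(all(ns3$n_significant <= ns3$n_regions))
  expect_error(network_summary(rep(TRUE, 10), atl), "atlas regions")
})

test_that("signatures concentrated on one network dominate its fraction", {
  atl <- tiny_atlas(80)
  focus <- rep(NA_integer_, 8)
  focus[1] <- 5L
  tr <- make_signatures(atl, n_phenotypes = 10, network_focus = focus,
                        focus_gain = 8, seed = 10)
  coh <- simulate_clinical(tr, atl, sizes = one_group_sizes(40, 80),
                           seed = 11)
  adj <- adjust_confounds(coh$volumes, coh$confounds)
  sel <- coh$group %in% c(cnv_labels()[1], "control")
  fit <- bagged_lda(adj$adjusted[sel, ],
                    as.integer(coh$group[sel] == cnv_labels()[1]),
                    B = 15, seed = 12)
  ns <- network_summary(fit, atl)
  expect_equal(which.max(ns$fraction), 5L)
})

test_that("coefficient counts versus performance correlation behaves", {
  sigs <- list(fake_signature(5, 0.1), fake_signature(10, 0.2),
               fake_signature(20, 0.4), fake_signature(40, 0.8))
  cv <- coeff_vs_performance(sigs)
  expect_equal(cv$r, 1)
  expect_lt(cv$p, 1e-6)
  expect_error(coeff_vs_performance(sigs[1:2]), "at least 3")
  const <- list(fake_signature(5, 0.3), fake_signature(5, 0.3),
                fake_signature(5, 0.3))
  expect_error(coeff_vs_performance(const), "constant")
})

test_that("expression prediction is a linear region-matched projection", {
  d <- two_class_data(12, 6, shift = 0.5, seed = 13)
  colnames(d$x) <- paste0("region_", seq_len(ncol(d$x)))
  fit <- bagged_lda(d$x, d$y, B = 5, seed = 14)
  a <- d$x[1, , drop = FALSE]; b <- d$x[2, , drop = FALSE]
  expect_equal(predict(fit, 2 * a + 3 * b),
               2 * predict(fit, a) + 3 * predict(fit, b), tolerance = 1e-12)
  wrong <- d$x[, c(2, 1, 3:6)]
  expect_error(predict(fit, wrong), "region identifiers")
  expect_error(predict(fit, d$x[, 1:3]), "per signature region")
})
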