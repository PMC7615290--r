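test_that("expression scoring is a named, linear projection", {
  W <- matrix(rnorm(3 * 10), 3, 10,
              dimnames = list(cnv_labels()[1:3], paste0("region_", 1:10)))
  W <- W / sqrt(rowSums(W^2))
  v <- matrix(rnorm(50), 5, 10, dimnames = list(NULL, paste0("region_", 1:10)))
  sc <- score_expressions(v, W)
  expect_equal(unclass(sc), v %*% t(W), ignore_attr = TRUE)
  ## subject equal to the signature scores its squared norm (= 1)
  sc1 <- score_expressions(W[1, , drop = FALSE], W)
  expect_equal(unname(sc1[1, 1]), 1, tolerance = 1e-12)
  ## orthogonal volumes score zero
  orth <- W[2, ] - sum(W[2, ] * W[1, ]) * W[1, ]
  sc2 <- score_expressions(matrix(orth, 1, dimnames = list(NULL, colnames(W))), W)
  expect_equal(unname(sc2[1, 1]), 0, tolerance = 1e-12)
  ## linearity
  a <- v[1, , drop = FALSE]; b <- v[2, , drop = FALSE]
  expect_equal(score_expressions(2 * a + 3 * b, W),
               2 * score_expressions(a, W) + 3 * score_expressions(b, W),
               tolerance = 1e-12, ignore_attr = TRUE)
  bad <- v; colnames(bad) <- paste0("other_", 1:10)
  expect_error(score_expressions(bad, W), "region identifiers")
  expect_error(score_expressions(v[, 1:5], W), "region count")
})

test_that("Tukey fences flag gross outliers and spare regular values", {
  x <- matrix(c(1:8, 100), ncol = 1)
  fl <- tukey_filter(x)
  expect_identical(which(fl), 9L)
  ## constant column: nothing flagged
  expect_false(any(tukey_filter(matrix(5, 10, 1))))
  ## standard normal: roughly 0.7% flagged
  set.seed(1)
  frac <- mean(tukey_filter(matrix(rnorm(10000), ncol = 1)))
  expect_lt(abs(frac - 0.007), 0.004)
  ## union rule across columns
  m <- cbind(c(rep(0, 9), 50), c(50, rep(0, 9)))
  expect_identical(which(tukey_filter(m)), c(1L, 10L))
  expect_error(tukey_filter(matrix(1:3, ncol = 1)), "at least 4")
})

test_that("bootstrap mean test honours its null construction", {
  x <- c(1, 2, 3, 4, 5)
  bt <- bootstrap_mean_test(x, x, B = 199, seed = 1)
  expect_equal(bt$estimate, 0)
  expect_equal(bt$p, 1)
  ## p-value floor
  set.seed(2)
  bt2 <- bootstrap_mean_test(rnorm(50, 5), rnorm(50, 0), B = 199, seed = 3)
  expect_gte(bt2$p, 1 / 200)
  expect_lte(bt2$p, 0.01)
  expect_error(bootstrap_mean_test(1, c(1, 2)), ">= 2")
})

test_that("the phenome scan computes correlations, multiplicity and flags", {
  set.seed(4)
  N <- 600
  scores <- matrix(rnorm(N * 2), N, 2,
                   dimnames = list(NULL, c("sigA", "sigB")))
  class(scores) <- c("expression_scores", class(scores))
  P <- 40
  y <- matrix(rnorm(N * P), N, P, dimnames = list(NULL, sprintf("ph%02d", 1:P)))
  ## plant one strong coupling on signature 1
  y[, 5] <- 0.5 * scores[, 1] + sqrt(1 - 0.25) * rnorm(N)
  ## one untestable phenotype (too few complete pairs)
  y[10:N, 7] <- NA
  prof <- run_phewas(scores, y, alpha = 0.05)
  p1 <- prof[[1]]
  expect_false(p1$testable[7])
  expect_equal(attr(p1, "n_testable"), P - 1L)
  expect_true(p1$bonferroni[5])
  expect_equal(p1$r[5], 0.5, tolerance = 0.12)
  ## oracle check of r and p on a single phenotype
  ct <- cor.test(scores[, 1], y[, 3])
  expect_equal(p1$r[3], unname(ct$estimate), tolerance = 1e-12)
  expect_equal(p1$p[3], ct$p.value, tolerance = 1e-9)
  ## Bonferroni flags are a subset of FDR flags
  for (pr in prof) expect_true(all(!pr$bonferroni | pr$fdr))
  ## pairwise-complete n bookkeeping
  expect_equal(p1$n[1], N)
  y[1:50, 2] <- NA
  prof2 <- run_phewas(scores, y)
  expect_equal(prof2[[1]]$n[2], N - 50L)
})

test_that("category ratios aggregate Bonferroni hits", {
  pr <- fake_profile(r = c(0.5, 0.4, 0.01, 0.02),
                     p = c(1e-9, 1e-8, 0.5, 0.6),
                     bonferroni = c(TRUE, TRUE, FALSE, FALSE),
                     category = c(1, 1, 2, 2))
  ratios <- category_hit_ratio(pr)
  expect_equal(ratios$ratio, c(1, 0))
  ## no hits anywhere
  pr0 <- fake_profile(r = rep(0, 4), p = rep(0.9, 4),
                      bonferroni = rep(FALSE, 4), category = c(1, 1, 2, 2))
  expect_equal(category_hit_ratio(pr0)$ratio, c(0, 0))
  ## empty category reported as missing
  pr2 <- fake_profile(r = rep(0.1, 4), p = rep(0.5, 4),
                      bonferroni = rep(FALSE, 4), category = rep(1, 4))
  expect_true(is.na(category_hit_ratio(pr2)$ratio[2]))
})

test_that("profile similarity and shared hits behave on constructed scans", {
  set.seed(5)
  rvec <- rnorm(60) / 10
  prof_same <- list(a = fake_profile(rvec, rep(0.5, 60), rep(FALSE, 60)),
                    b = fake_profile(rvec, rep(0.5, 60), rep(FALSE, 60)),
                    c = fake_profile(rvec, rep(0.5, 60), rep(FALSE, 60)))
  ps <- profile_similarity(prof_same, n_perm = 49, seed = 6)
  expect_equal(unname(ps$r[upper.tri(ps$r)]), rep(1, 3), tolerance = 1e-12)
  expect_equal(ps$mean_abs_r, 1)
  mismatch <- fake_profile(rvec[1:59], rep(0.5, 59), rep(FALSE, 59))
  expect_error(profile_similarity(list(prof_same$a, mismatch)),
               "same phenotype set")
  ## shared hits
  bon <- rep(FALSE, 60); bon[3] <- TRUE
  profs <- replicate(8, fake_profile(rvec, rep(0.5, 60), bon),
                     simplify = FALSE)
  sh <- shared_hits(profs, min_k = 8)
  expect_equal(sh$shared$phenotype, "phenotype_0003")
  expect_equal(nrow(sh$top), 10)
  none <- replicate(8, fake_profile(rvec, rep(0.5, 60), rep(FALSE, 60)),
                    simplify = FALSE)
  expect_equal(nrow(shared_hits(none, min_k = 1)$shared), 0)
  expect_error(shared_hits(profs, min_k = 9), "between 1 and")
})

test_that("conditioning is an idempotent projection that isolates unique variance", {
  set.seed(7)
  ## orthogonal zero-mean columns are left unchanged
  Q <- qr.Q(qr(matrix(rnorm(100 * 4), 100, 4)))
  Q <- sweep(Q, 2, colMeans(Q))
  Q <- qr.Q(qr(Q))  # re-orthogonalize after centering
  r1 <- condition_out(Q)
  expect_equal(unclass(r1), Q, tolerance = 1e-10, ignore_attr = TRUE)
  ## duplicated column: its unique variance is zero
  x <- matrix(rnorm(300), 100, 3)
  xx <- cbind(x[, 1], x[, 1], x[, 2:3])
  res <- condition_out(xx)
  expect_lt(max(abs(res[, 1])), 1e-10)
  ## per-column projection property: each residual is orthogonal to the
  ## conditioning columns it was regressed on
  y <- matrix(rnorm(400), 100, 4)
  res_y <- condition_out(y)
  for (k in 1:4) {
    expect_lt(max(abs(crossprod(cbind(1, y[, -k]), res_y[, k]))), 1e-9)
  }
  expect_error(condition_out(x[, 1, drop = FALSE]), "at least 2")
})

test_that("the convergence report pairs and compares the two similarity structures", {
  r <- matrix(c(1, 0.3, -0.2, 0.3, 1, 0.5, -0.2, 0.5, 1), 3,
              dimnames = list(letters[1:3], letters[1:3]))
  sim <- structure(list(r = r, mean_abs_r = mean(abs(r[upper.tri(r)]))),
                   class = "map_similarity")
  rep_same <- concordance_report(sim, sim)
  expect_equal(rep_same$rho_c, 1)
  expect_equal(rep_same$n_phenotypic_greater, 0)
  r2 <- r; r2[upper.tri(r2)] <- r2[upper.tri(r2)] * 2
  r2[lower.tri(r2)] <- t(r2)[lower.tri(r2)]
  sim2 <- structure(list(r = r2), class = "map_similarity")
  rep2 <- concordance_report(sim, sim2)
  expect_equal(rep2$n_phenotypic_greater, 3)
  expect_equal(rep2$n_pairs, 3)
  ## both similarity sets constant: concordance undefined
  z <- structure(list(r = diag(3)), class = "map_similarity")
  expect_error(concordance_report(z, z), "constant")
})
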