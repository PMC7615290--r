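test_that("default designs reproduce the study group sizes", {
  sizes <- clinical_design()
  expect_equal(sum(sizes[cnv_labels()]), 534)
  expect_equal(unname(sizes["control"]), 312)
  des <- population_design()
  expect_equal(des$n_noncarriers, 38731)
  expect_equal(sum(des$carrier_counts), 361)
  expect_error(population_design(100, rep(20, 8)), "invalid design")
})

test_that("clinical simulation is deterministic and honours the design", {
  atl <- tiny_atlas(40)
  tr <- make_signatures(atl, n_phenotypes = 20, seed = 1)
  sizes <- clinical_design(0.1)
  a <- simulate_clinical(tr, atl, sizes = sizes, seed = 5)
  b <- simulate_clinical(tr, atl, sizes = sizes, seed = 5)
  expect_identical(a$volumes, b$volumes)
  expect_identical(a$group, b$group)
  expect_equal(as.vector(table(a$group)[names(sizes)]), unname(sizes))
  expect_false(anyNA(a$volumes))
  expect_gte(nlevels(a$confounds$site), 2)
  expect_error(simulate_clinical(tr, atl, sizes = one_group_sizes(1, 50)),
               "invalid design")
})

test_that("null effects give near-zero regional effect sizes", {
  atl <- tiny_atlas(100)
  tr <- make_signatures(atl, n_phenotypes = 10, theta = rep(0, 8), seed = 2)
  coh <- simulate_clinical(tr, atl, sizes = one_group_sizes(100, 100),
                           seed = 8)
  adj <- adjust_confounds(coh$volumes, coh$confounds)
  sel <- coh$group %in% c(cnv_labels()[1], "control")
  z <- zscore_columns(adj$adjusted, sel)
  dm <- cohens_d_map(z, coh$group == cnv_labels()[1],
                     coh$group == "control")
  expect_gte(mean(abs(dm$d) < 0.3), 0.95)
})

test_that("strong planted effects are recovered by the effect-size map", {
  atl <- tiny_atlas(100)
  cors <- vapply(1:5, function(s) {
    tr <- make_signatures(atl, n_phenotypes = 10, seed = s)
    coh <- simulate_clinical(tr, atl, sizes = one_group_sizes(50, 150),
                             seed = 100 + s)
    adj <- adjust_confounds(coh$volumes, coh$confounds)
    sel <- coh$group %in% c(cnv_labels()[1], "control")
    z <- zscore_columns(adj$adjusted, sel)
    dm <- cohens_d_map(z, coh$group == cnv_labels()[1],
                       coh$group == "control")
    cor(dm$d, tr$beta[1, ])
  }, numeric(1))
  expect_gt(mean(cors), 0.9)
})

test_that("mean absolute effect size scales linearly with theta", {
  atl <- tiny_atlas(60)
  thetas <- c(0.25, 0.5, 1.0)
  slopes <- vapply(1:3, function(s) {
    tr1 <- make_signatures(atl, n_phenotypes = 10, theta = rep(1, 8),
                           seed = s)
    expected_slope <- sqrt(atl$n_regions) * mean(abs(tr1$beta[1, ]))
    mean_d <- vapply(thetas, function(th) {
      tr <- make_signatures(atl, n_phenotypes = 10, theta = rep(th, 8),
                            seed = s)
      coh <- simulate_clinical(tr, atl, sizes = one_group_sizes(150, 250),
                               seed = 50 + s)
      adj <- adjust_confounds(coh$volumes, coh$confounds)
      sel <- coh$group %in% c(cnv_labels()[1], "control")
      z <- zscore_columns(adj$adjusted, sel)
      mean(abs(cohens_d_map(z, coh$group == cnv_labels()[1],
                            coh$group == "control")$d))
    }, numeric(1))
    unname(coef(lm(mean_d ~ thetas))[2]) / expected_slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 1), 0.15)
})

test_that("population simulation produces a well-formed phenome", {
  atl <- tiny_atlas(40)
  tr <- make_signatures(atl, n_phenotypes = 120, seed = 3)
  pop <- simulate_population(tr, atl, n_subjects = 4000,
                             carrier_counts = rep(10L, 8), seed = 4)
  ph <- pop$phenome
  expect_equal(dim(ph$values), c(4000L, 120L))
  bin <- which(ph$var_type == "binary")
  for (q in bin[1:3]) {
    vals <- ph$values[!is.na(ph$values[, q]), q]
    expect_true(all(vals %in% c(0, 1)))
    expect_equal(mean(vals), 0.5, tolerance = 0.03)
  }
  ord <- which(ph$var_type == "ordinal")[1]
  lv <- sort(unique(stats::na.omit(ph$values[, ord])))
  expect_identical(lv, as.numeric(seq_along(lv)))
  expect_lte(max(colMeans(is.na(ph$values))), 0.2)
  ## site identifiers are distinct from the clinical cohort's
  coh <- simulate_clinical(tr, atl, sizes = clinical_design(0.1), seed = 1)
  expect_length(intersect(levels(pop$confounds$site),
                          levels(coh$confounds$site)), 0)
})

test_that("null phenome couplings give uniform association p-values", {
  atl <- tiny_atlas(40)
  tr <- make_signatures(atl, n_phenotypes = 200, coupling_strength = 0,
                        seed = 5)
  pop <- simulate_population(tr, atl, n_subjects = 4000,
                             carrier_counts = rep(5L, 8), seed = 6)
  adj <- adjust_confounds(pop$volumes, pop$confounds,
                          design = c("head_size", "bmi", "motion", "age",
                                     "sex", "site"))
  scores <- score_expressions(adj$adjusted, tr$beta)
  prof <- run_phewas(scores, pop$phenome)
  pv <- prof[[1]]$p[prof[[1]]$testable]
  ks <- suppressWarnings(stats::ks.test(pv, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
})

test_that("latent expressions separate carriers from non-carriers", {
  atl <- tiny_atlas(60)
  tr <- make_signatures(atl, n_phenotypes = 20, seed = 9)
  pop <- simulate_population(tr, atl, n_subjects = 1000,
                             carrier_counts = rep(12L, 8), seed = 10)
  for (k in c(1, 4, 8)) {
    carr <- pop$carrier_status == cnv_labels()[k]
    expect_gt(mean(pop$latent_expression[carr, k]),
              mean(pop$latent_expression[!carr, k]))
  }
})
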