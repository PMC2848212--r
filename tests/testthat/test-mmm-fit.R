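test_that("null data give a near-zero intercept and tiny variances", {
  s <- small_study(n_areas = 80, seed = 37, sigma2_u = 0, sigma2_v = 0,
                   population_range = c(30000, 80000))
  f <- fit_poisson_mmm(s$observed, s$expected, s$syn$structure, "A")
  expect_equal(f$convergence, 0)
  expect_lt(abs(f$alpha), 3 * max(f$alpha_se, 0.02))
  expect_lt(unname(f$sigma2["u"]), 0.01)
  expect_lt(unname(f$sigma2["v"]), 0.05)
})

test_that("adding a constant to the offset shifts only the intercept", {
  s <- small_study(n_areas = 50, seed = 41)
  st <- s$syn$structure
  f1 <- fit_poisson_mmm(s$observed, s$expected, st, "A")
  f2 <- fit_poisson_mmm(s$observed, s$expected * exp(0.3), st, "A")
  expect_equal(f2$alpha, f1$alpha - 0.3, tolerance = 1e-3)
  expect_equal(f2$sigma2, f1$sigma2, tolerance = 1e-3)
  expect_equal(f2$log_likelihood, f1$log_likelihood, tolerance = 1e-4)
})

test_that("relabeling areas permutes predictions, not scalar estimates", {
  s <- small_study(n_areas = 40, seed = 43, sigma2_w = 0.1,
                   third_level = "asl")
  st <- s$syn$structure
  f1 <- fit_poisson_mmm(s$observed, s$expected, st, "B")
  set.seed(1); perm <- sample(40)
  xy <- as.matrix(s$syn$areas[perm, c("x", "y")])
  stp <- membership_structure(xy, s$cfg$neighbor_radius_km,
                              third_level = s$syn$areas$asl[perm])
  f2 <- fit_poisson_mmm(s$observed[perm], s$expected[perm], stp, "B")
  expect_equal(f2$alpha, f1$alpha, tolerance = 1e-5)
  expect_equal(f2$sigma2, f1$sigma2, tolerance = 1e-4)
  expect_equal(f2$log_likelihood, f1$log_likelihood, tolerance = 1e-5)
  expect_equal(f2$u, f1$u[perm], tolerance = 1e-3)
})

test_that("the spatial effect equals the explicit weighted sum", {
  s <- small_study(n_areas = 35, seed = 47)
  st <- s$syn$structure
  f <- fit_poisson_mmm(s$observed, s$expected, st, "A")
  pr <- predict_random_effects(f, st)
  v_loop <- vapply(seq_len(35), function(i) {
    sum(st$Z[i, ] * pr$v_star)
  }, numeric(1))
  expect_equal(pr$v, v_loop, tolerance = 1e-12)
  expect_equal(pr$v, f$v, tolerance = 1e-12)
})

test_that("a floored clustering variance refits at exactly zero", {
  # all areas mutually neighboring: the spatial effect is a single shared
  # intercept, indistinguishable from alpha, so sigma2_v collapses
  s <- small_study(n_areas = 30, seed = 53, sigma2_u = 0.3, sigma2_v = 0,
                   extent = c(20, 15), population_range = c(20000, 50000))
  f <- fit_poisson_mmm(s$observed, s$expected, s$syn$structure, "A")
  expect_true(f$clustering_variance_floored)
  expect_identical(unname(f$sigma2["v"]), 0)
  expect_true(is.na(f$sigma2_se["v"]))
  expect_equal(f$v_star, rep(0, 30))
  expect_equal(f$k, 2L)  # alpha + sigma2_u only
})

test_that("conditional modes shrink more where expected counts are small", {
  # areas with the same raw O/E ratio but very different E: the posterior
  # deviation is pulled toward zero hardest where the evidence is weakest
  n <- 40
  xy <- cbind(seq(0, by = 40, length.out = n), 0)  # all isolated
  st <- membership_structure(xy, 25)
  E <- rep(rep(c(2, 200), each = n / 4), 2)
  ratio <- rep(c(2, 0.5), each = n / 2)            # real heterogeneity
  O <- round(ratio * E)
  f <- fit_poisson_mmm(O, E, st, "A")
  dev_total <- abs(f$u + f$v)
  hi <- ratio == 2
  expect_lt(mean(dev_total[hi & E == 2]), mean(dev_total[hi & E == 200]))
  lo <- ratio == 0.5
  expect_lt(mean(dev_total[lo & E == 2]), mean(dev_total[lo & E == 200]))
})

test_that("variance Wald p-values follow the normal CDF", {
  expect_equal(wald_variance_pvalue(0, 1), 0.5)
  expect_equal(wald_variance_pvalue(1.645, 1), 0.05, tolerance = 1e-3)
  # one- vs two-sided on a tabulated heterogeneity estimate
  expect_equal(wald_variance_pvalue(0.0336, 0.0144, sides = 2), 0.0196,
               tolerance = 0.01)
  expect_equal(wald_variance_pvalue(0.0336, 0.0144, sides = 1), 0.0098,
               tolerance = 0.01)
  expect_true(is.na(wald_variance_pvalue(1, 0)))
})

test_that("AIC accounting and model ranking are consistent", {
  s <- small_study(n_areas = 40, seed = 59, sigma2_w = 0.3,
                   third_level = "asl", population_range = c(10000, 60000))
  st <- s$syn$structure
  fA <- fit_poisson_mmm(s$observed, s$expected, st, "A")
  fB <- fit_poisson_mmm(s$observed, s$expected, st, "B")
  if (!any(fA$floored)) expect_equal(fA$k, 3L)  # alpha, s2_u, s2_v
  if (!any(fB$floored)) expect_equal(fB$k, 4L)
  expect_equal(fA$aic, 2 * fA$k - 2 * fA$log_likelihood)

  # identical fit twice: identical AIC, stable sort
  fA2 <- fit_poisson_mmm(s$observed, s$expected, st, "A")
  expect_identical(fA$aic, fA2$aic)
  tab <- compare_models(fA, fB, fA2)
  expect_equal(tab$AIC, sort(tab$AIC))
  expect_s3_class(tab, "data.frame")

  # logLik method powers stats::AIC identically
  expect_equal(AIC(fA), fA$aic)

  # the third level can only improve the maximized likelihood
  expect_gte(fB$log_likelihood, fA$log_likelihood - 1e-4)

  # fits on different data refuse to be compared
  fX <- fit_poisson_mmm(s$observed + 1, s$expected, st, "A")
  expect_error(compare_models(fA, fX), "different data")
})

test_that("misspecified structures are refused", {
  s <- small_study(n_areas = 10, seed = 61)
  st <- s$syn$structure  # no third level
  expect_error(fit_poisson_mmm(s$observed, s$expected, st, "B"),
               "third-level")
  st2 <- membership_structure(as.matrix(s$syn$areas[, c("x", "y")]), 25,
                              third_level = seq_len(10))
  expect_error(fit_poisson_mmm(s$observed, s$expected, st2, "B"),
               "unidentifiable")
  expect_error(fit_poisson_mmm(s$observed, c(0, s$expected[-1]), st, "A"),
               "positive")
})
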