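test_that("config validation rejects impossible settings", {
  expect_error(synthetic_config(n_areas = 10, n_asl = 11), "n_asl")
  expect_error(synthetic_config(sigma2_u = -1), "sigma2_u")
  bad_risk <- default_stratum_risks(); bad_risk[1, 1] <- 1.2
  expect_error(synthetic_config(stratum_risk = bad_risk), "in \\(0, 1\\)")
  expect_error(generate_geography(synthetic_config(n_areas = 5, n_asl = 2,
                                                   n_risk_areas = 2,
                                                   region_extent = c(0, 0))),
               "rectangle too small")
})

test_that("a single area is its own district and its own neighborhood", {
  cfg <- synthetic_config(n_areas = 1, n_asl = 1, n_risk_areas = 1, seed = 2)
  syn <- simulate_area_table(cfg)
  expect_equal(nrow(syn$areas), 1L)
  expect_equal(length(unique(syn$areas$asl)), 1L)
  expect_equal(syn$structure$neighbor_sets[[1]], 1L)
})

test_that("risk areas are mutually exclusive", {
  cfg <- synthetic_config(n_areas = 40, n_risk_areas = 5, seed = 5,
                          region_extent = c(60, 60))
  geo <- generate_geography(cfg)
  # one label per area, and every label is a single risk area or none
  expect_equal(length(geo$risk_area), 40L)
  expect_true(all(grepl("^(RA[0-9]+|none)$", geo$risk_area)))
  # every assigned area lies within the radius of its nearest center, and
  # the assigned center is the nearest one (mutual exclusivity)
  seeds <- attr(geo, "risk_seeds")
  dr <- as.matrix(dist(cbind(geo$x, geo$y)))[, seeds, drop = FALSE]
  for (i in seq_len(40)) {
    if (geo$risk_area[i] == "none") {
      expect_gt(min(dr[i, ]), cfg$risk_area_radius_km)
    } else {
      k <- as.integer(sub("RA", "", geo$risk_area[i]))
      expect_lte(dr[i, k], cfg$risk_area_radius_km)
      expect_equal(k, unname(which.min(dr[i, ])))
    }
  }
})

test_that("fixing the seed fixes every output byte", {
  cfg <- synthetic_config(n_areas = 50, seed = 123)
  a <- simulate_area_table(cfg)
  b <- simulate_area_table(cfg)
  expect_identical(a$areas, b$areas)
  expect_identical(a$truth$u, b$truth$u)
  f1 <- tempfile(); f2 <- tempfile()
  write_area_table(a$areas, f1); write_area_table(b$areas, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("zero variances give unit relative risk everywhere", {
  syn <- simulate_area_table(synthetic_config(n_areas = 20, sigma2_u = 0,
                                              sigma2_v = 0, sigma2_w = 0,
                                              seed = 4))
  expect_equal(syn$truth$rr, rep(1, 20))
})

test_that("true relative risk equals exp(u + Zv* + w) and Poisson means are
           linear in the stratum populations", {
  syn <- simulate_area_table(synthetic_config(n_areas = 40, seed = 6,
                                              third_level = "asl"))
  tr <- syn$truth
  w_area <- unname(tr$w[as.integer(syn$structure$third_level)])
  expect_equal(tr$rr,
               exp(tr$u + as.vector(syn$structure$Z %*% tr$v_star) + w_area))

  # lambda_is = pop_is * risk_s * rr_i exactly: doubling any stratum
  # population doubles its Poisson mean
  cells <- as.vector(outer(c("M", "F"), mmsmooth:::AGE_TOKENS, paste, sep = "_"))
  pop <- as.matrix(syn$areas[, paste0("pop_", cells)])
  risks <- as.vector(synthetic_config()$stratum_risk)
  lambda <- pop * outer(tr$rr, risks)
  expect_equal(unname(as.matrix(tr$expected_strata)), unname(lambda))
})

test_that("realized counts match expected totals within sampling error", {
  syn <- simulate_area_table(synthetic_config(n_areas = 150, seed = 9,
                                              sigma2_u = 0.02, sigma2_v = 0.2,
                                              sigma2_w = 0))
  tot_lambda <- sum(syn$truth$expected_strata)
  tot_cases <- sum(syn$areas$cases)
  expect_lt(abs(tot_cases - tot_lambda) / sqrt(tot_lambda), 4)  # ~4 sd
})

test_that("variance of the realized spatial effect matches sigma2_v / n_i", {
  # oracle: direct simulation of the weighted sums under sigma2_v = 1
  cfg <- synthetic_config(n_areas = 200, sigma2_v = 1, seed = 31)
  geo <- generate_geography(cfg)
  st <- membership_structure(geo[, c("x", "y")], cfg$neighbor_radius_km)
  set.seed(99)
  reps <- 10000
  V <- matrix(rnorm(200 * reps), 200, reps)
  sums <- as.matrix(st$Z %*% V)
  emp_var <- apply(sums, 1, var)
  theo <- 1 / lengths(st$neighbor_sets)
  expect_lt(median(abs(emp_var - theo) / theo), 0.05)
  expect_equal(mean(emp_var), mean(theo), tolerance = 0.05)
})

test_that("extreme stratum rates are truncated with a warning", {
  risky <- matrix(0.9, 2, 8, dimnames = list(c("M", "F"), NULL))
  cfg <- synthetic_config(n_areas = 10, stratum_risk = risky, sigma2_u = 1,
                          n_asl = 2, n_risk_areas = 2, seed = 13)
  expect_warning(simulate_area_table(cfg), "truncated at 0.95")
})

test_that("area table CSV and long-format pivot round-trip", {
  syn <- simulate_area_table(synthetic_config(n_areas = 15, seed = 21))
  f <- tempfile(fileext = ".csv")
  write_area_table(syn$areas, f)
  back <- read_area_table(f)
  long <- area_table_to_strata(back)
  expect_equal(nrow(long), 15 * 16)
  agg <- tapply(long$cases, long$area_id, sum)
  expect_equal(as.numeric(agg[as.character(syn$areas$area_id)]),
               syn$areas$cases)
  expect_error(area_table_to_strata(back[, 1:5]), "lacks stratum columns")
})
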