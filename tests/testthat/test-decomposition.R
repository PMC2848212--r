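# The six tabulated model blocks from a published regional analysis, used
# as exogenous inputs: variance estimates with the regional summaries
# n_bar = 29.07, m_bar = 43.00 (districts) / 19.85 (risk areas).
replay_blocks <- list(
  lungA = list(sigma2_u = 0.0336, sigma2_v = 0.6940, sigma2_w = NULL,
               n_bar = 29.07, m_bar = NULL,
               v_area = 0.0239, w_area = NA, total = 0.0575,
               q_spatial = 41.57, q_third = NA),
  lungB = list(sigma2_u = 0.0402, sigma2_v = 0.2635, sigma2_w = 0.0218,
               n_bar = 29.07, m_bar = 43.00,
               v_area = 0.0091, w_area = 0.0005, total = 0.0498,
               q_spatial = 18.27, q_third = 1.00),
  lungC = list(sigma2_u = 0.0272, sigma2_v = 0.7179, sigma2_w = 0.0064,
               n_bar = 29.07, m_bar = 19.85,
               v_area = 0.0247, w_area = 0.0003, total = 0.0522,
               q_spatial = 47.32, q_third = 0.57),
  copdA = list(sigma2_u = 0.0722, sigma2_v = 2.1485, sigma2_w = NULL,
               n_bar = 29.07, m_bar = NULL,
               v_area = 0.0739, w_area = NA, total = 0.1461,
               q_spatial = 50.58, q_third = NA),
  copdB = list(sigma2_u = 0.0755, sigma2_v = 0.7946, sigma2_w = 0.0747,
               n_bar = 29.07, m_bar = 43.00,
               v_area = 0.0273, w_area = 0.0017, total = 0.1045,
               q_spatial = 26.12, q_third = 1.63),
  copdC = list(sigma2_u = 0.0722, sigma2_v = 2.1485, sigma2_w = 0.0000,
               n_bar = 29.07, m_bar = 19.85,
               v_area = 0.0739, w_area = 0.0000, total = 0.1461,
               q_spatial = 50.58, q_third = 0.00))

test_that("tabulated variance blocks reproduce every printed quotient", {
  for (nm in names(replay_blocks)) {
    b <- replay_blocks[[nm]]
    d <- decompose_variance(b$sigma2_u, b$sigma2_v, b$sigma2_w,
                            b$n_bar, b$m_bar, rounding = "paper_4dp")
    expect_equal(d$sigma2_v_per_area, b$v_area, info = nm)
    if (!is.null(b$sigma2_w)) {
      expect_equal(d$sigma2_w_per_area, b$w_area, info = nm)
      expect_equal(d$quota_third_pct, b$q_third, info = nm)
    }
    expect_equal(d$total, b$total, info = nm)
    expect_equal(d$quota_spatial_pct, b$q_spatial, info = nm)
  }
})

test_that("decomposition_table replays all blocks in one report", {
  inputs <- lapply(replay_blocks, function(b) {
    list(label = "model", sigma2_u = b$sigma2_u, sigma2_v = b$sigma2_v,
         sigma2_w = b$sigma2_w, n_bar = b$n_bar, m_bar = b$m_bar)
  })
  tab <- decomposition_table(inputs, rounding = "paper_4dp")
  expect_equal(unname(unlist(tab["sigma2_v_per_area", ])),
               vapply(replay_blocks, `[[`, numeric(1), "v_area"),
               ignore_attr = TRUE)
  expect_equal(unname(unlist(tab["total", ])),
               vapply(replay_blocks, `[[`, numeric(1), "total"),
               ignore_attr = TRUE)
  expect_equal(unname(unlist(tab["quota_spatial_pct", ])),
               vapply(replay_blocks, `[[`, numeric(1), "q_spatial"),
               ignore_attr = TRUE)
})

test_that("degenerate decompositions behave", {
  d0 <- decompose_variance(0.05, 0, NULL, 10)
  expect_equal(d0$quota_spatial_pct, 0)
  dz <- decompose_variance(0, 0, NULL, 10)
  expect_true(is.na(dz$quota_spatial))
  # all-zero block in a table
  tab <- decomposition_table(list(list(sigma2_u = 0, sigma2_v = 0,
                                       n_bar = 10)))
  expect_equal(tab["total", 1], 0)
  expect_error(decompose_variance(0.1, 0.1, 0.1, 10, m_bar = NULL), "m_bar")
})

test_that("unrounded quotas are monotone in sigma2_v and n_bar", {
  base <- decompose_variance(0.05, 0.5, NULL, 20)$quota_spatial
  expect_gt(decompose_variance(0.05, 0.6, NULL, 20)$quota_spatial, base)
  expect_lt(decompose_variance(0.05, 0.5, NULL, 25)$quota_spatial, base)
})

test_that("4-decimal intermediate rounding moves quotas by < 0.5 points", {
  for (b in replay_blocks) {
    d4 <- decompose_variance(b$sigma2_u, b$sigma2_v, b$sigma2_w,
                             b$n_bar, b$m_bar, rounding = "paper_4dp")
    dn <- decompose_variance(b$sigma2_u, b$sigma2_v, b$sigma2_w,
                             b$n_bar, b$m_bar, rounding = "none")
    expect_lt(abs(d4$quota_spatial_pct - 100 * dn$quota_spatial), 0.5)
  }
})

test_that("randomized inputs match an independent arithmetic recomputation", {
  set.seed(101)
  for (r in 1:25) {
    s2u <- runif(1, 0, 0.2); s2v <- runif(1, 0, 3); s2w <- runif(1, 0, 0.3)
    nb <- runif(1, 1, 50); mb <- runif(1, 1, 60)
    d <- decompose_variance(s2u, s2v, s2w, nb, mb, rounding = "paper_4dp")
    # spreadsheet-style recomputation
    va <- round(s2v / nb, 4); wa <- round(s2w / mb, 4)
    tot <- round(s2u, 4) + va + wa
    expect_equal(d$total, tot)
    expect_equal(d$quota_spatial_pct, round(100 * va / tot, 2))
    expect_equal(d$quota_third_pct, round(100 * wa / tot, 2))
    dn <- decompose_variance(s2u, s2v, s2w, nb, mb)
    expect_equal(dn$quota_spatial, (s2v / nb) / (s2u + s2v / nb + s2w / mb))
  }
})
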