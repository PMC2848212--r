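# Shared fixtures, built in code at test time.

# A balanced stratum table with identical admission probability p in every
# cell (useful null case for the risk-adjustment model).
flat_strata <- function(n_areas = 3, pop_per_cell = 1000, p = 0.1) {
  grid <- expand.grid(area_id = seq_len(n_areas), sex = c("M", "F"),
                      age_class = mmsmooth:::AGE_CLASSES,
                      stringsAsFactors = FALSE)
  grid$population <- pop_per_cell
  grid$cases <- round(p * pop_per_cell)
  grid
}

# Small, well-conditioned synthetic dataset plus its risk adjustment.
small_study <- function(n_areas = 60, seed = 11, sigma2_u = 0.05,
                        sigma2_v = 0.7, sigma2_w = 0,
                        third_level = "none", extent = c(120, 90),
                        population_range = c(2000, 50000), ...) {
  cfg <- synthetic_config(n_areas = n_areas, seed = seed,
                          sigma2_u = sigma2_u, sigma2_v = sigma2_v,
                          sigma2_w = sigma2_w, third_level = third_level,
                          region_extent = extent,
                          population_range = population_range,
                          n_asl = min(6L, n_areas),
                          n_risk_areas = min(12L, n_areas), ...)
  syn <- simulate_area_table(cfg)
  ra <- fit_risk_model(syn$strata)
  ord <- match(syn$areas$area_id, names(ra$expected))
  list(cfg = cfg, syn = syn, risk = ra,
       observed = as.numeric(ra$observed[ord]),
       expected = as.numeric(ra$expected[ord]),
       crude = crude_rate(sum(ra$observed), sum(syn$areas$population)))
}
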