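# Synthetic area tables with the exact statistical structure the smoothing
# models assume: stratified Poisson counts whose log relative risk is the sum
# of an unstructured municipality effect, a spatial multiple-membership
# effect and (optionally) a third-level group effect.

AGE_CLASSES <- c("0", "1-4", "5-14", "15-24", "25-44", "45-64", "65-74", ">74")
AGE_TOKENS  <- c("0", "1_4", "5_14", "15_24", "25_44", "45_64", "65_74", "75plus")
SEXES <- c("M", "F")

#' Default age-class population shares
#'
#' Shares of residents in the eight age classes (0, 1-4, 5-14, 15-24, 25-44,
#' 45-64, 65-74, >74), shaped like a contemporary southern-European
#' population pyramid. They sum to one.
#'
#' @return Named numeric vector of length 8.
#' @export
default_age_structure <- function() {
  stats::setNames(c(0.008, 0.035, 0.095, 0.105, 0.295, 0.255, 0.105, 0.102),
                  AGE_CLASSES)
}

#' Default per-stratum baseline admission probabilities
#'
#' Annual probabilities of hospitalization per resident by sex and age
#' class: rare overall, rising steeply with age, higher in males — the
#' pattern of chronic respiratory disease admissions. With the default age
#' structure the implied crude rate is about 25 per 10,000 residents.
#'
#' @return 2 x 8 numeric matrix (rows `M`, `F`; columns the age classes).
#' @export
default_stratum_risks <- function() {
  base <- c(4e-04, 1.6e-04, 4e-05, 4e-05, 8e-05, 1.2e-03, 6.6e-03, 1.5e-02)
  r <- rbind(M = 1.4 * base, F = 0.6 * base)
  colnames(r) <- AGE_CLASSES
  r
}

#' Configuration of the synthetic-data generator
#'
#' Bundles and validates every knob of the generator. The defaults emulate
#' the municipality structure of a region like Apulia: 258 areas in a
#' 200 x 150 km rectangle, highly skewed (log-uniform) population sizes, 6
#' contiguous health districts (ASL), 12 mutually exclusive 10-km
#' environmental risk areas, and a 25-km spatial-dependency radius.
#'
#' @param n_areas Number of municipalities.
#' @param region_extent Length-2 numeric: rectangle side lengths in km.
#' @param population_range Length-2: min/max residents per area; sizes are
#'   drawn log-uniformly, reproducing the strong small-area skew real
#'   municipal populations show.
#' @param stratum_risk 2 x 8 matrix of baseline admission probabilities per
#'   sex x age-class cell, all in (0, 1).
#' @param sigma2_u,sigma2_v,sigma2_w Non-negative variances of the
#'   heterogeneity, spatial (multiple-membership) and third-level random
#'   effects on the log relative-risk scale.
#' @param n_asl Number of health districts (contiguous spatial partition).
#' @param n_risk_areas Number of mutually exclusive environmental risk areas.
#' @param risk_area_radius_km Radius of each risk area (km); default 10.
#' @param neighbor_radius_km Spatial-dependency radius (km); default 25.
#' @param third_level Which grouping carries the generative third random
#'   effect w: the health districts (`"asl"`, default), the risk areas, or
#'   none.
#' @param age_structure Named shares of the eight age classes (sum 1).
#' @param sex_split Share of males in each area (default 0.49).
#' @param seed Integer seed; fixing it fixes every generated byte.
#' @return Object of class `"synthetic_config"` (a validated list).
#' @export
synthetic_config <- function(n_areas = 258, region_extent = c(200, 150),
                             population_range = c(500, 1e5),
                             stratum_risk = default_stratum_risks(),
                             sigma2_u = 0.05, sigma2_v = 0.7, sigma2_w = 0.05,
                             n_asl = 6, n_risk_areas = 12,
                             risk_area_radius_km = 10, neighbor_radius_km = 25,
                             third_level = c("asl", "risk_area", "none"),
                             age_structure = default_age_structure(),
                             sex_split = 0.49, seed = 1L) {
  third_level <- match.arg(third_level)
  stopifnot(n_areas >= 1, length(region_extent) == 2, all(region_extent >= 0),
            length(population_range) == 2, population_range[1] >= 1,
            population_range[2] >= population_range[1],
            sigma2_u >= 0, sigma2_v >= 0, sigma2_w >= 0,
            n_asl >= 1, n_asl <= n_areas,
            n_risk_areas >= 0, n_risk_areas <= n_areas,
            risk_area_radius_km > 0, neighbor_radius_km > 0,
            sex_split > 0, sex_split < 1)
  stratum_risk <- as.matrix(stratum_risk)
  if (!all(dim(stratum_risk) == c(2, 8))) {
    stop("`stratum_risk` must be a 2 x 8 matrix (sex x age class)")
  }
  if (any(stratum_risk <= 0) || any(stratum_risk >= 1)) {
    stop("stratum risks must lie strictly in (0, 1)")
  }
  if (abs(sum(age_structure) - 1) > 1e-8) stop("`age_structure` must sum to 1")
  structure(
    list(n_areas = as.integer(n_areas), region_extent = as.numeric(region_extent),
         population_range = as.numeric(population_range),
         stratum_risk = stratum_risk, sigma2_u = sigma2_u, sigma2_v = sigma2_v,
         sigma2_w = sigma2_w, n_asl = as.integer(n_asl),
         n_risk_areas = as.integer(n_risk_areas),
         risk_area_radius_km = risk_area_radius_km,
         neighbor_radius_km = neighbor_radius_km, third_level = third_level,
         age_structure = age_structure, sex_split = sex_split,
         seed = as.integer(seed)),
    class = "synthetic_config")
}

#' Generate synthetic municipality geography
#'
#' Draws area centroids uniformly in the configured rectangle, partitions
#' them into contiguous health districts (each area joins the nearest of
#' `n_asl` seed municipalities, a Voronoi-like partition mimicking real
#' administrative contiguity), and places `n_risk_areas` environmental risk
#' areas centred on randomly chosen municipalities: an area belongs to the
#' nearest risk centre if within `risk_area_radius_km`, else to none, so the
#' risk areas are mutually exclusive by construction. Voronoi cell surface
#' areas (km^2) stand in for municipal territory sizes.
#'
#' @param config A [synthetic_config()] object.
#' @return Object of class `"mm_geography"`: data frame with columns
#'   `area_id`, `x`, `y`, `asl`, `risk_area`, `surface_area`, plus
#'   attributes `"config"`, `"asl_seeds"` and `"risk_seeds"` (indices of
#'   the seed municipalities).
#' @export
generate_geography <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_areas
  ext <- config$region_extent
  if (n > 1 && (ext[1] <= 0 || ext[2] <= 0)) {
    stop("rectangle too small to place ", n, " distinct centroids: ",
         "both region_extent sides must be positive")
  }
  set.seed(config$seed)
  for (attempt in 1:10) {
    x <- stats::runif(n, 0, max(ext[1], 1e-9))
    y <- stats::runif(n, 0, max(ext[2], 1e-9))
    if (n == 1 || min(stats::dist(cbind(x, y))) > 0) break
    if (attempt == 10) {
      stop("rectangle too small to place ", n, " distinct centroids")
    }
  }
  xy <- cbind(x, y)

  asl_seeds <- sample.int(n, config$n_asl)
  asl <- paste0("ASL", apply(pdist2(xy, xy[asl_seeds, , drop = FALSE]), 1,
                             which.min))

  risk_area <- rep("none", n)
  risk_seeds <- integer(0)
  if (config$n_risk_areas > 0) {
    risk_seeds <- sample.int(n, config$n_risk_areas)
    dr <- pdist2(xy, xy[risk_seeds, , drop = FALSE])
    nearest <- apply(dr, 1, which.min)
    within <- dr[cbind(seq_len(n), nearest)] <= config$risk_area_radius_km
    risk_area[within] <- paste0("RA", nearest[within])
  }

  surface <- if (n == 1) prod(ext) else voronoi_polygons(xy, ext)$areas
  geo <- data.frame(area_id = seq_len(n), x = x, y = y, asl = asl,
                    risk_area = risk_area, surface_area = surface)
  attr(geo, "config") <- config
  attr(geo, "asl_seeds") <- asl_seeds
  attr(geo, "risk_seeds") <- risk_seeds
  class(geo) <- c("mm_geography", "data.frame")
  geo
}

pdist2 <- function(a, b) {
  # n x m Euclidean cross-distances
  sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2)
}

#' Generate stratified counts and the generating truth
#'
#' Simulates, for each municipality and each of the 16 sex x age strata,
#' Poisson admission counts with mean
#' `population * baseline_risk * exp(u_i + sum_j z_ij v*_j + w_k(i))`, where
#' `u`, `v*` and `w` are independent zero-mean normal draws with the
#' configured variances (all cross-covariances zero) and the weights `z_ij`
#' come from the 25-km multiple-membership structure of the centroids. The
#' generating effects are returned alongside the data so recovery can be
#' tested. If a stratum's per-person rate exceeds 0.95 it is truncated at
#' 0.95 with a warning (expected cases can otherwise exceed the population).
#'
#' @param geography An `"mm_geography"` object from [generate_geography()].
#' @param config The same [synthetic_config()] used for the geography.
#' @return List of class `"mm_synthesis"` with elements
#'   \describe{
#'     \item{areas}{wide per-area data frame: geography columns, total
#'       `population` and `cases`, and `pop_<sex>_<age>` /
#'       `cases_<sex>_<age>` stratum columns;}
#'     \item{strata}{long stratum table (`area_id`, `sex`, `age_class`,
#'       `population`, `cases`);}
#'     \item{truth}{the generating truth: config echo, realized `u`,
#'       `v_star`, `w`, per-area `v = Z v*`, true relative risk
#'       `rr = exp(u + v + w)`, and per-stratum expected counts;}
#'     \item{structure}{the `"membership_structure"` used for generation.}
#'   }
#' @export
generate_counts <- function(geography, config = attr(geography, "config")) {
  stopifnot(inherits(geography, "mm_geography"),
            inherits(config, "synthetic_config"))
  n <- nrow(geography)
  labels <- switch(config$third_level,
                   asl = geography$asl, risk_area = geography$risk_area,
                   none = NULL)
  struct <- membership_structure(geography[, c("x", "y")],
                                 radius_km = config$neighbor_radius_km,
                                 third_level = labels)
  set.seed(config$seed + 1L)

  pr <- config$population_range
  population <- round(exp(stats::runif(n, log(pr[1]), log(pr[2]))))

  u <- stats::rnorm(n, 0, sqrt(config$sigma2_u))
  v_star <- stats::rnorm(n, 0, sqrt(config$sigma2_v))
  v <- as.vector(struct$Z %*% v_star)
  if (is.null(struct$third_level)) {
    w_groups <- numeric(0)
    w <- rep(0, n)
  } else {
    w_groups <- stats::setNames(
      stats::rnorm(nlevels(struct$third_level), 0, sqrt(config$sigma2_w)),
      levels(struct$third_level))
    w <- unname(w_groups[as.integer(struct$third_level)])
  }
  rr <- exp(u + v + w)

  # per-area stratum populations: multinomial split over the 16 cells
  shares <- as.vector(outer(c(config$sex_split, 1 - config$sex_split),
                            config$age_structure))
  cells <- as.vector(outer(SEXES, AGE_TOKENS, paste, sep = "_"))
  pop_strata <- t(vapply(population,
                         function(p) as.vector(stats::rmultinom(1, p, shares)),
                         numeric(16)))
  colnames(pop_strata) <- cells

  base_risk <- rep(as.vector(config$stratum_risk), 1)  # M col-major: M,F x age
  rate <- outer(rr, base_risk)                         # n x 16 per-person rate
  if (any(rate > 0.95)) {
    warning("per-person admission rate exceeded 0.95 in ",
            sum(rate > 0.95), " strata; truncated at 0.95")
    rate[rate > 0.95] <- 0.95
  }
  lambda <- pop_strata * rate
  counts <- matrix(stats::rpois(length(lambda), as.vector(lambda)), nrow = n)
  colnames(counts) <- cells

  areas <- cbind(as.data.frame(geography),
                 population = population, cases = rowSums(counts))
  pops <- as.data.frame(pop_strata); names(pops) <- paste0("pop_", cells)
  cnts <- as.data.frame(counts); names(cnts) <- paste0("cases_", cells)
  areas <- cbind(areas, pops, cnts)

  strata <- data.frame(
    area_id = rep(geography$area_id, each = 16),
    sex = rep(rep(SEXES, 8), n),
    age_class = rep(rep(AGE_CLASSES, each = 2), n),
    population = as.vector(t(pop_strata)),
    cases = as.vector(t(counts)))

  truth <- list(config = config, u = u, v_star = v_star, w = w_groups,
                v = v, rr = rr, expected_strata = lambda)
  structure(list(areas = areas, strata = strata, truth = truth,
                 structure = struct),
            class = "mm_synthesis")
}

#' One-call synthetic area table
#'
#' Runs [generate_geography()] then [generate_counts()].
#'
#' @param config A [synthetic_config()].
#' @return The `"mm_synthesis"` list (see [generate_counts()]).
#' @export
simulate_area_table <- function(config = synthetic_config()) {
  generate_counts(generate_geography(config), config)
}

#' Write / read a stratified area table CSV
#'
#' The on-disk format is one row per municipality with `pop_<sex>_<age>` and
#' `cases_<sex>_<age>` columns for the 16 sex x age strata (age tokens `0`,
#' `1_4`, ..., `75plus`), plus `area_id`, centroid `x`/`y` (km), optional
#' `asl`, `risk_area` and `surface_area` columns.
#'
#' @param areas Wide per-area data frame (e.g. `$areas` of a synthesis).
#' @param file CSV path.
#' @return `write_area_table()` returns `file` invisibly;
#'   `read_area_table()` the data frame.
#' @export
write_area_table <- function(areas, file) {
  utils::write.csv(as.data.frame(areas), file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_area_table
#' @export
read_area_table <- function(file) {
  utils::read.csv(file, check.names = FALSE)
}

#' Pivot a wide area table to the long stratum table
#'
#' @param areas Wide per-area data frame with `pop_*`/`cases_*` columns.
#' @return Long data frame (`area_id`, `sex`, `age_class`, `population`,
#'   `cases`) suitable for [fit_risk_model()].
#' @export
area_table_to_strata <- function(areas) {
  cells <- as.vector(outer(SEXES, AGE_TOKENS, paste, sep = "_"))
  missing <- setdiff(c(paste0("pop_", cells), paste0("cases_", cells)),
                     names(areas))
  if (length(missing)) {
    stop("area table lacks stratum columns: ", paste(missing, collapse = ", "))
  }
  n <- nrow(areas)
  sex <- sub("_.*", "", cells)
  age <- AGE_CLASSES[match(sub("^[MF]_", "", cells), AGE_TOKENS)]
  data.frame(
    area_id = rep(areas$area_id, each = 16),
    sex = rep(sex, n),
    age_class = rep(age, n),
    population = as.vector(t(as.matrix(areas[, paste0("pop_", cells)]))),
    cases = as.vector(t(as.matrix(areas[, paste0("cases_", cells)]))))
}

#' Write the generating truth as a sidecar CSV
#'
#' @param synthesis An `"mm_synthesis"` object.
#' @param file CSV path.
#' @return `file`, invisibly.
#' @export
write_truth_table <- function(synthesis, file) {
  tr <- synthesis$truth
  df <- data.frame(area_id = synthesis$areas$area_id, u = tr$u,
                   v_star = tr$v_star, v = tr$v,
                   w = tr$w[as.integer(synthesis$structure$third_level)] %||% 0,
                   rr = tr$rr)
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a
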