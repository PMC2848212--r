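# Indirect standardization of small-area admission counts: a region-wide
# logistic model on sex and the eight age classes yields per-stratum
# admission probabilities, hence expected cases E_i per municipality and the
# risk-adjusted rate RAR_i = (O_i / E_i) * crude regional rate.

#' Fit the logistic risk-adjustment model
#'
#' Fits `logit(p) = intercept + sex + age_class` on the region-wide grouped
#' binomial data (the 16 sex x age cells pooled over areas; identical
#' coefficients to an individual-record fit), then computes each area's
#' expected cases `E_i = sum_s pop_is * p_hat_s`. Because the model contains
#' an intercept and is evaluated on its own training data, total expected
#' cases equal total observed cases. If the 16 cells are separated (some
#' cell fitted at probability 0 or 1), 0.5 is added to the cases and 0.5 to
#' the non-cases of every cell and the fit repeated, with a message.
#'
#' @param strata Long stratum table: columns `area_id`, `sex` (`"M"`/`"F"`),
#'   `age_class` (the eight classes), `population`, `cases`.
#' @return Object of class `"risk_adjustment"`: list with `model` (the
#'   `glm` fit), `cell_probs` (fitted probability per sex x age cell),
#'   `expected` (named `E_i` per area), `observed` (`O_i`), `c_statistic`,
#'   `wald` (global Wald statistic on sex + age coefficients, with df and
#'   p-value), and `continuity_corrected` flag.
#' @export
fit_risk_model <- function(strata) {
  strata <- validate_strata(strata)
  cells <- stats::aggregate(cbind(population, cases) ~ sex + age_class,
                            data = strata, FUN = sum)
  if (sum(cells$cases) == 0) stop("no events: all case counts are zero")
  if (sum(cells$cases) == sum(cells$population)) {
    stop("no non-events: every resident is a case")
  }
  cells$age_class <- factor(cells$age_class, levels = AGE_CLASSES)
  cells$sex <- factor(cells$sex, levels = SEXES)

  fit_once <- function(cs, pop) {
    stats::glm(cbind(cs, pop - cs) ~ sex + age_class, data = cells,
               family = stats::binomial())
  }
  corrected <- FALSE
  fit <- fit_once(cells$cases, cells$population)
  p <- stats::fitted(fit)
  if (any(p < 1e-10) || any(p > 1 - 1e-10) || !fit$converged) {
    message("separation across risk-adjustment cells: ",
            "adding 0.5 cases and 0.5 non-cases to every cell")
    corrected <- TRUE
    fit <- suppressWarnings(fit_once(cells$cases + 0.5, cells$population + 1))
    p <- stats::fitted(fit)
    if (!fit$converged) stop("risk-adjustment model did not converge")
  }

  key <- paste(cells$sex, cells$age_class)
  phat <- stats::setNames(p, key)
  strata$p <- phat[paste(strata$sex, strata$age_class)]
  expected <- tapply(strata$population * strata$p, strata$area_id, sum)
  expected <- stats::setNames(as.numeric(expected), names(expected))
  observed <- tapply(strata$cases, strata$area_id, sum)
  observed <- stats::setNames(as.numeric(observed), names(observed))

  cf <- stats::coef(fit); V <- stats::vcov(fit)
  idx <- setdiff(seq_along(cf), 1L)  # all but intercept
  wald_stat <- as.numeric(t(cf[idx]) %*% solve(V[idx, idx], cf[idx]))
  wald <- c(statistic = wald_stat, df = length(idx),
            p = stats::pchisq(wald_stat, length(idx), lower.tail = FALSE))

  structure(
    list(model = fit, cell_probs = phat,
         cells = cbind(cells, p = as.numeric(p)),
         expected = expected, observed = observed,
         c_statistic = c_statistic(p, cells$cases,
                                   cells$population - cells$cases),
         wald = wald, continuity_corrected = corrected),
    class = "risk_adjustment")
}

validate_strata <- function(strata) {
  need <- c("area_id", "sex", "age_class", "population", "cases")
  if (!all(need %in% names(strata))) {
    stop("`strata` needs columns: ", paste(need, collapse = ", "))
  }
  if (any(strata$cases > strata$population)) {
    stop("cases exceed population in some stratum")
  }
  if (any(strata$cases < 0) || any(strata$population < 0)) {
    stop("negative counts")
  }
  strata
}

#' @export
print.risk_adjustment <- function(x, ...) {
  cat("Risk adjustment (logistic, sex + 8 age classes)\n")
  cat(sprintf("  areas: %d  observed cases: %d  expected: %.2f\n",
              length(x$expected), sum(x$observed), sum(x$expected)))
  cat(sprintf("  c-statistic: %.3f\n", x$c_statistic))
  cat(sprintf("  global Wald: %.4f on %d df (p %s)\n", x$wald["statistic"],
              as.integer(x$wald["df"]), format.pval(x$wald["p"], digits = 3)))
  if (x$continuity_corrected) cat("  note: continuity-corrected cells\n")
  invisible(x)
}

#' Concordance (c-)statistic from grouped data
#'
#' The probability that a randomly chosen case has a higher fitted score
#' than a randomly chosen non-case, ties counting one half — the share of
#' all case/non-case pairs the model ranks correctly. Computed exactly from
#' grouped data by weighting every ordered pair of strata by
#' `cases_s * noncases_t`, equivalent to the individual-level statistic.
#'
#' @param scores Fitted probability (or any score) per stratum.
#' @param cases Number of cases per stratum.
#' @param noncases Number of non-cases per stratum.
#' @return Concordance in `[0, 1]`.
#' @export
c_statistic <- function(scores, cases, noncases) {
  stopifnot(length(scores) == length(cases), length(cases) == length(noncases))
  if (sum(cases) == 0 || sum(noncases) == 0) {
    stop("c-statistic needs at least one case and one non-case")
  }
  gt <- outer(scores, scores, ">")
  eq <- outer(scores, scores, "==")
  wt <- outer(cases, noncases)        # wt[s, t] = cases_s * noncases_t
  total <- sum(wt)
  (sum(wt * gt) + 0.5 * sum(wt * eq)) / total
}

#' Crude rate per `scale` residents
#'
#' @param cases Total observed cases.
#' @param population Total population at risk (> 0).
#' @param scale Reporting scale; default 10,000.
#' @param digits Reporting precision: the rate is truncated (not rounded)
#'   to this many decimals, the convention under which printed regional
#'   rates reproduce exactly from their case and population totals; use
#'   `NULL` for the full-precision value.
#' @return The rate per `scale` residents.
#' @examples
#' crude_rate(2591, 4071518)    # 6.36 per 10,000
#' crude_rate(10356, 4071518)   # 25.43 per 10,000
#' @export
crude_rate <- function(cases, population, scale = 1e4, digits = 2) {
  if (!is.numeric(population) || population <= 0) {
    stop("`population` must be positive")
  }
  r <- cases / population * scale
  if (is.null(digits)) r else trunc(r * 10^digits) / 10^digits
}

#' Risk-adjusted rate (RAR) per area
#'
#' Indirectly standardized rate: the ratio of observed to expected cases
#' times the crude regional rate, `RAR_i = (O_i / E_i) * crude`. Areas with
#' `E_i = 0` but `O_i > 0` get `NA` with a warning (the ratio is undefined);
#' areas with no observed cases get 0.
#'
#' @param observed Observed cases `O_i` per area.
#' @param expected Expected cases `E_i` per area from [fit_risk_model()].
#' @param crude Crude regional rate (per 10,000 by convention).
#' @return RAR per area, on the scale of `crude`.
#' @export
compute_rar <- function(observed, expected, crude) {
  stopifnot(length(observed) == length(expected))
  rar <- ifelse(observed == 0, 0, observed / expected * crude)
  bad <- expected <= 0 & observed > 0
  if (any(bad)) {
    warning(sum(bad), " area(s) with zero expected but positive observed ",
            "cases: RAR undefined (NA)")
    rar[bad] <- NA_real_
  }
  rar
}
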