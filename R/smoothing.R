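# Smoothed risk-adjusted rates: the model's fitted relative risk replaces
# the raw O/E ratio in the indirect-standardization formula, shrinking each
# municipality's rate toward the regional mean (heterogeneity term) and its
# neighborhood mean (clustering term).

#' Smoothed risk-adjusted rate (SRAR) per area
#'
#' `SRAR_i = exp(alpha + x_i beta + u_i + [Z v*]_i + w_k(i)) * crude`, the
#' model's fitted relative risk times the crude regional rate — the exact
#' smoothed analogue of `RAR_i = (O_i / E_i) * crude`, since the fitted
#' relative risk equals `mu_hat_i / E_i`. With `recenter = TRUE` the
#' intercept is dropped, pinning the regional level of the smoothed rates
#' at exactly the crude rate instead of the fitted level.
#'
#' @param fit A converged `"mmm_fit"`.
#' @param crude Crude regional rate (per 10,000 by convention).
#' @param recenter Drop the fitted intercept (default `FALSE`).
#' @return SRAR per area, on the scale of `crude`.
#' @export
compute_srar <- function(fit, crude, recenter = FALSE) {
  stopifnot(inherits(fit, "mmm_fit"))
  if (fit$convergence != 0) stop("fit did not converge; refusing to smooth")
  rr <- fit$fitted_rr
  if (recenter) rr <- rr / exp(fit$alpha)
  rr * crude
}

#' Assemble the per-area rates table
#'
#' Gathers observed and expected cases, population, optional surface area,
#' the RAR, one SRAR column per fitted model, the RAR-SRAR differences and
#' quintile classes for each rate column.
#'
#' @param observed,expected Per-area counts (see [compute_rar()]).
#' @param population Per-area population.
#' @param crude Crude regional rate.
#' @param fits Named list of converged `"mmm_fit"` objects (names become
#'   column suffixes, e.g. `list(A = fitA)` gives `srar_A`).
#' @param surface_area Optional per-area surface in km^2.
#' @param recenter Passed to [compute_srar()].
#' @return Data frame of class `"rates_table"` with columns `area_id`,
#'   `observed`, `expected`, `population`, (`surface_area`,) `rar`,
#'   `rar_q`, and per model `srar_<name>`, `diff_<name>` (= rar - srar),
#'   `srar_<name>_q`.
#' @export
rates_table <- function(observed, expected, population, crude, fits,
                        surface_area = NULL, recenter = FALSE) {
  stopifnot(is.list(fits), length(fits) >= 1)
  if (is.null(names(fits))) {
    names(fits) <- vapply(fits, `[[`, character(1), "variant")
  }
  out <- data.frame(area_id = seq_along(observed), observed = observed,
                    expected = expected, population = population)
  if (!is.null(surface_area)) out$surface_area <- surface_area
  out$rar <- compute_rar(observed, expected, crude)
  out$rar_q <- quintile_classify(out$rar)$class
  for (nm in names(fits)) {
    srar <- compute_srar(fits[[nm]], crude, recenter = recenter)
    out[[paste0("srar_", nm)]] <- srar
    out[[paste0("diff_", nm)]] <- out$rar - srar
    out[[paste0("srar_", nm, "_q")]] <- quintile_classify(srar)$class
  }
  class(out) <- c("rates_table", "data.frame")
  out
}

#' Profile the smoothing effect against area size
#'
#' Summarizes the absolute smoothing correction `|RAR - SRAR|` across
#' groups of municipality size — either resident population or territorial
#' surface area — and reports the rank (Spearman) correlation between the
#' correction and the size variable. Smoothing corrects small, unstable
#' areas the most, so this correlation is expected to be negative.
#'
#' @param rates A [rates_table()] data frame.
#' @param grouping `"population"` or `"surface_area"`.
#' @param model Which SRAR column to profile (name used in `fits`;
#'   default the first `diff_*` column).
#' @param n_groups Number of size bins (quantile cut; default 5).
#' @return List with `by_group` (data frame: group, size range, n, mean and
#'   sd of `|RAR - SRAR|`) and `spearman` (correlation of `|diff|` with the
#'   size variable; `NA` when all differences are zero).
#' @export
smoothing_effect_profile <- function(rates, grouping = c("population", "surface_area"),
                                     model = NULL, n_groups = 5) {
  grouping <- match.arg(grouping)
  if (!grouping %in% names(rates)) {
    stop("column `", grouping, "` is missing from the rates table")
  }
  diff_cols <- grep("^diff_", names(rates), value = TRUE)
  if (length(diff_cols) == 0L) stop("no `diff_*` column in the rates table")
  col <- if (is.null(model)) diff_cols[1] else paste0("diff_", model)
  if (!col %in% names(rates)) stop("no column `", col, "`")
  adiff <- abs(rates[[col]])
  size <- rates[[grouping]]

  br <- unique(stats::quantile(size, probs = seq(0, 1, length.out = n_groups + 1)))
  grp <- cut(size, breaks = br, include.lowest = TRUE)
  by_group <- data.frame(
    group = levels(grp),
    n = as.integer(table(grp)),
    mean_abs_diff = as.numeric(tapply(adiff, grp, mean)),
    sd_abs_diff = as.numeric(tapply(adiff, grp, stats::sd)))
  rho <- if (all(adiff == 0)) NA_real_ else
    suppressWarnings(stats::cor(adiff, size, method = "spearman"))
  list(by_group = by_group, spearman = rho, grouping = grouping, model = col)
}
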