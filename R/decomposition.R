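# Per-municipality variance decomposition. The total random variance for a
# municipality is sigma2_u + sigma2_v / n_bar (+ sigma2_w / m_bar), where
# n_bar is the mean number of municipalities in the spatial dependency
# neighborhoods and m_bar the mean number of municipalities per third-level
# group. sigma2_v / n_bar over the total is the "spatially structured
# variability quota".

#' Decompose the per-municipality random variance
#'
#' Computes the per-area contribution of each variance component, their
#' total, and the share (quota) of the total attributable to spatial
#' clustering and, when present, to the third level.
#'
#' `rounding = "paper_4dp"` rounds each per-area quotient
#' `sigma2_v / n_bar` and `sigma2_w / m_bar` to 4 decimals before summing
#' and forming quotas, reproducing how such tables are conventionally
#' printed and read back (quotas then reported as percentages to 2
#' decimals); `"none"` keeps full precision and is what real analyses
#' should use. The two differ by well under half a percentage point at
#' realistic magnitudes.
#'
#' @param sigma2_u Heterogeneity variance (>= 0).
#' @param sigma2_v Clustering (spatial) variance (>= 0).
#' @param sigma2_w Third-level variance, or `NULL` when the model has no
#'   third level.
#' @param n_bar Mean neighborhood size (>= 1).
#' @param m_bar Mean third-level group size (>= 1); required with
#'   `sigma2_w`.
#' @param rounding `"none"` (default) or `"paper_4dp"`.
#' @return Object of class `"variance_decomposition"`: list with
#'   `sigma2_u`, `sigma2_v_per_area`, `sigma2_w_per_area` (`NULL` if
#'   absent), `total`, fractional quotas `quota_spatial`, `quota_third`,
#'   `quota_heterogeneity`, percentage forms `quota_spatial_pct` /
#'   `quota_third_pct` (2 decimals), and the rounding mode. Quotas are `NA`
#'   when the total is zero.
#' @examples
#' # spatial share of total municipality-level variance
#' decompose_variance(0.0336, 0.6940, NULL, 29.07, rounding = "paper_4dp")
#' @export
decompose_variance <- function(sigma2_u, sigma2_v, sigma2_w = NULL,
                               n_bar, m_bar = NULL,
                               rounding = c("none", "paper_4dp")) {
  rounding <- match.arg(rounding)
  has_w <- !is.null(sigma2_w) && !is.na(sigma2_w)
  stopifnot(sigma2_u >= 0, sigma2_v >= 0, n_bar >= 1)
  if (has_w) {
    if (is.null(m_bar) || is.na(m_bar) || m_bar < 1) {
      stop("`m_bar` >= 1 is required when `sigma2_w` is present")
    }
    stopifnot(sigma2_w >= 0)
  }
  r4 <- function(x) if (rounding == "paper_4dp") round(x, 4) else x
  v_area <- r4(sigma2_v / n_bar)
  w_area <- if (has_w) r4(sigma2_w / m_bar) else NULL
  total <- r4(sigma2_u) + v_area + (w_area %||% 0)
  if (total > 0) {
    qs <- v_area / total
    qt <- if (has_w) w_area / total else NA_real_
    qh <- r4(sigma2_u) / total
  } else {
    qs <- qt <- qh <- NA_real_
  }
  structure(
    list(sigma2_u = sigma2_u, sigma2_v = sigma2_v,
         sigma2_w = if (has_w) sigma2_w else NULL,
         n_bar = n_bar, m_bar = if (has_w) m_bar else NULL,
         sigma2_v_per_area = v_area, sigma2_w_per_area = w_area,
         total = total,
         quota_spatial = qs, quota_third = qt, quota_heterogeneity = qh,
         quota_spatial_pct = round(100 * qs, 2),
         quota_third_pct = if (has_w) round(100 * qt, 2) else NA_real_,
         rounding = rounding),
    class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat("Per-municipality variance decomposition",
      sprintf("(rounding: %s)\n", x$rounding))
  cat(sprintf("  sigma2_u                 %.4f\n", x$sigma2_u))
  cat(sprintf("  sigma2_v / n_bar         %.4f  (sigma2_v %.4f, n_bar %.2f)\n",
              x$sigma2_v_per_area, x$sigma2_v, x$n_bar))
  if (!is.null(x$sigma2_w_per_area)) {
    cat(sprintf("  sigma2_w / m_bar         %.4f  (sigma2_w %.4f, m_bar %.2f)\n",
                x$sigma2_w_per_area, x$sigma2_w, x$m_bar))
  }
  cat(sprintf("  total                    %.4f\n", x$total))
  if (!is.na(x$quota_spatial)) {
    cat(sprintf("  spatially structured variability quota: %.2f%%\n",
                100 * x$quota_spatial))
    if (!is.null(x$sigma2_w_per_area)) {
      cat(sprintf("  third-level variability quota:          %.2f%%\n",
                  100 * x$quota_third))
    }
  } else {
    cat("  quotas undefined (zero total variance)\n")
  }
  invisible(x)
}

#' Variance-decomposition table across fitted models
#'
#' One column block per model, mirroring the conventional layout of
#' rate-smoothing reports: intercept, variance estimates with standard
#' errors and p-values, `n_bar`, `m_bar`, the per-area quotients
#' `sigma2_v/n_bar` and `sigma2_w/m_bar`, their total, the quotas and the
#' AIC. Accepts either `"mmm_fit"` objects (summaries taken from the fit)
#' or plain lists with fields `sigma2_u`, `sigma2_v`, optional `sigma2_w`,
#' `n_bar`, optional `m_bar`, optional `label`/`aic` — so printed estimates
#' from an external analysis can be replayed too.
#'
#' @param fits List of `"mmm_fit"` objects or plain input lists.
#' @param rounding Passed to [decompose_variance()].
#' @return Data frame, one row per quantity, one column per model.
#' @export
decomposition_table <- function(fits, rounding = c("none", "paper_4dp")) {
  rounding <- match.arg(rounding)
  stopifnot(is.list(fits), length(fits) >= 1)
  cols <- lapply(fits, function(f) {
    if (inherits(f, "mmm_fit")) {
      inp <- list(label = paste("Model", f$variant),
                  sigma2_u = unname(f$sigma2["u"]),
                  sigma2_v = unname(f$sigma2["v"]),
                  sigma2_w = if ("w" %in% names(f$sigma2)) unname(f$sigma2["w"]) else NULL,
                  n_bar = f$n_bar,
                  m_bar = if ("w" %in% names(f$sigma2)) f$m_bar else NULL,
                  aic = f$aic)
    } else inp <- f
    d <- decompose_variance(inp$sigma2_u, inp$sigma2_v, inp$sigma2_w,
                            inp$n_bar, inp$m_bar, rounding = rounding)
    c(sigma2_u = d$sigma2_u, sigma2_v = d$sigma2_v,
      sigma2_w = if (is.null(d$sigma2_w)) NA_real_ else d$sigma2_w,
      n_bar = d$n_bar, m_bar = if (is.null(d$m_bar)) NA_real_ else d$m_bar,
      sigma2_v_per_area = d$sigma2_v_per_area,
      sigma2_w_per_area = if (is.null(d$sigma2_w_per_area)) NA_real_ else d$sigma2_w_per_area,
      total = d$total,
      quota_spatial_pct = d$quota_spatial_pct,
      quota_third_pct = d$quota_third_pct,
      AIC = if (is.null(inp$aic)) NA_real_ else inp$aic)
  })
  labels <- vapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    if (inherits(f, "mmm_fit")) paste("Model", f$variant)
    else if (!is.null(f$label)) f$label else paste("model", i)
  }, character(1))
  out <- as.data.frame(cols, optional = TRUE)
  names(out) <- make.unique(labels)
  out
}
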