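# End-to-end orchestration: risk adjustment -> membership -> model fits ->
# variance decomposition -> smoothed rates -> quintile maps, with a plain-
# text run log. Every output is a pure function of (input table, options,
# seed).

#' Run the full rate-smoothing pipeline
#'
#' Executes, in order: synthetic-data generation (or CSV input), logistic
#' risk adjustment, multiple-membership structure construction, the Poisson
#' multilevel fits (Model A always; Model B when a health-district `asl`
#' column is present, Model C when a `risk_area` column is present —
#' missing columns skip the variant with a log line), variance
#' decomposition, SRAR computation, and quintile map export. All files are
#' written under `out_dir`; a `run.log` records the seed, package version,
#' stage progress and convergence flags.
#'
#' @param input Either a [synthetic_config()] (data are simulated) or the
#'   path of a stratified area-table CSV (see [write_area_table()]).
#' @param out_dir Output directory (created if needed).
#' @param radius_km Spatial-dependency radius in km (default 25).
#' @param variants Model variants to attempt (default `c("A","B","C")`).
#' @param seed Optional integer; overrides the config seed for synthetic
#'   input and seeds any stochastic step.
#' @param rounding Rounding mode for the decomposition report.
#' @param recenter Passed to [compute_srar()].
#' @param render Write PNG maps as well as GeoJSON (default `TRUE`).
#' @return Invisibly, a list with every intermediate object: `areas`,
#'   `risk`, `structure`, `fits`, `comparison`, `decomposition`, `rates`,
#'   `crude`, `log` (the log lines).
#' @export
run_pipeline <- function(input = synthetic_config(), out_dir = tempfile("mmsmooth_"),
                         radius_km = 25, variants = c("A", "B", "C"),
                         seed = NULL, rounding = "none", recenter = FALSE,
                         render = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  log_path <- file.path(out_dir, "run.log")
  say <- function(...) {
    line <- paste0(format(length(log_lines) + 1), ": ", sprintf(...))
    log_lines <<- c(log_lines, line)
    writeLines(log_lines, log_path)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      say("FAILED at stage [%s]: %s", name, conditionMessage(e))
      stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  say("mmsmooth %s pipeline start", as.character(utils::packageVersion("mmsmooth")))

  # --- input -----------------------------------------------------------
  synthesis <- NULL
  areas <- stage("input", {
    if (inherits(input, "synthetic_config")) {
      if (!is.null(seed)) input$seed <- as.integer(seed)
      say("synthetic input: %d areas, seed %d", input$n_areas, input$seed)
      synthesis <- simulate_area_table(input)
      write_area_table(synthesis$areas, file.path(out_dir, "area_table.csv"))
      write_truth_table(synthesis, file.path(out_dir, "truth.csv"))
      synthesis$areas
    } else {
      say("reading area table from %s", input)
      read_area_table(input)
    }
  })
  if (!is.null(seed)) set.seed(as.integer(seed))

  # --- risk adjustment --------------------------------------------------
  risk <- stage("risk_adjustment", {
    strata <- area_table_to_strata(areas)
    fit_risk_model(strata)
  })
  crude <- crude_rate(sum(risk$observed), sum(areas$population))
  say("risk adjustment: c-statistic %.3f, crude rate %.2f per 10,000",
      risk$c_statistic, crude)
  ord <- match(areas$area_id, names(risk$expected))
  expected <- as.numeric(risk$expected[ord])
  observed <- as.numeric(risk$observed[ord])
  utils::write.csv(
    data.frame(area_id = areas$area_id, observed = observed,
               expected = expected,
               rar = compute_rar(observed, expected, crude)),
    file.path(out_dir, "risk_adjustment.csv"), row.names = FALSE)
  writeLines(jsonlite::toJSON(list(
    c_statistic = risk$c_statistic,
    wald = as.list(risk$wald),
    coefficients = as.list(stats::coef(risk$model)),
    continuity_corrected = risk$continuity_corrected,
    crude_rate_per_10000 = crude), auto_unbox = TRUE, digits = 10, pretty = TRUE),
    file.path(out_dir, "risk_model.json"))

  # --- membership structures -------------------------------------------
  centroids <- stage("membership", {
    if (!all(c("x", "y") %in% names(areas))) {
      stop("area table has no centroid columns x/y")
    }
    as.matrix(areas[, c("x", "y")])
  })
  base_struct <- membership_structure(centroids, radius_km = radius_km)
  say("membership: n_bar %.2f at radius %.0f km", base_struct$n_bar, radius_km)
  write_membership_triplets(base_struct, file.path(out_dir, "weights.csv"))

  # --- model fits -------------------------------------------------------
  fits <- list()
  for (v in variants) {
    needed <- switch(v, A = NULL, B = "asl", C = "risk_area")
    if (!is.null(needed) && !needed %in% names(areas)) {
      say("model %s skipped: column `%s` absent from the area table", v, needed)
      next
    }
    st <- if (v == "A") base_struct else
      membership_structure(centroids, radius_km = radius_km,
                           third_level = areas[[needed]])
    fits[[v]] <- stage(paste0("fit_", v),
                       fit_poisson_mmm(observed, expected, st, variant = v))
    say("model %s: logLik %.2f, AIC %.1f, converged %s%s", v,
        fits[[v]]$log_likelihood, fits[[v]]$aic,
        fits[[v]]$convergence == 0,
        if (isTRUE(fits[[v]]$clustering_variance_floored))
          " (clustering variance floored at zero)" else "")
  }
  if (length(fits) == 0L) stop("no model variant could be fitted")

  comparison <- compare_models(fits)
  utils::write.csv(comparison, file.path(out_dir, "model_comparison.csv"),
                   row.names = FALSE)
  decomp <- decomposition_table(fits, rounding = rounding)
  utils::write.csv(cbind(quantity = rownames(decomp), decomp),
                   file.path(out_dir, "decomposition.csv"), row.names = FALSE)

  # --- smoothed rates ---------------------------------------------------
  rates <- stage("smoothing", {
    rates_table(observed, expected, areas$population, crude, fits,
                surface_area = areas$surface_area, recenter = recenter)
  })
  utils::write.csv(rates, file.path(out_dir, "rates.csv"), row.names = FALSE)

  # --- maps -------------------------------------------------------------
  stage("mapping", {
    extent <- c(max(areas$x), max(areas$y))
    overlay <- NULL
    if ("risk_area" %in% names(areas)) {
      centers <- areas[areas$risk_area != "none", , drop = FALSE]
      if (nrow(centers)) {
        # one representative point per risk area
        first <- !duplicated(centers$risk_area)
        overlay <- data.frame(x = centers$x[first], y = centers$y[first],
                              label = centers$risk_area[first])
      }
    }
    render_map(map_layer(areas$area_id, rates$rar, centroids = centroids,
                         extent = extent, overlay = overlay, name = "RAR"),
               file.path(out_dir, "map_rar"), png = render)
    for (nm in names(fits)) {
      render_map(map_layer(areas$area_id, rates[[paste0("srar_", nm)]],
                           centroids = centroids, extent = extent,
                           overlay = overlay, name = paste0("SRAR_", nm)),
                 file.path(out_dir, paste0("map_srar_", nm)), png = render)
    }
  })
  say("pipeline complete: %d model(s), outputs in %s",
      length(fits), normalizePath(out_dir))

  invisible(list(areas = areas, synthesis = synthesis, risk = risk,
                 structure = base_struct, fits = fits,
                 comparison = comparison, decomposition = decomp,
                 rates = rates, crude = crude, out_dir = out_dir,
                 log = log_lines))
}
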