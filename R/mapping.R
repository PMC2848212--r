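# Choropleth support: quintile classification of rates, map layers over
# synthetic Voronoi polygons (or centroid points as fallback), GeoJSON and
# PNG export with industrial-center overlays.

#' Quintile classification of area rates
#'
#' Class boundaries sit at the 20/40/60/80th percentiles of the finite
#' values (linear-interpolation quantile definition, `stats::quantile`
#' type 7); a value exactly on a boundary goes to the lower class, making
#' the classification deterministic under ties. With fewer distinct values
#' than classes the classes collapse (a message notes it); all-equal input
#' yields a single class.
#'
#' @param values Numeric rates, one per area; `NA`s propagate.
#' @return List with `class` (integer 1-5 per area) and `boundaries` (the
#'   four percentile cut points).
#' @export
quintile_classify <- function(values) {
  v <- as.numeric(values)
  if (all(!is.finite(v))) stop("no finite values to classify")
  b <- stats::quantile(v[is.finite(v)], probs = c(0.2, 0.4, 0.6, 0.8),
                       type = 7, names = FALSE)
  cl <- 1L + (v > b[1]) + (v > b[2]) + (v > b[3]) + (v > b[4])
  cl[!is.finite(v)] <- NA_integer_
  if (length(unique(cl[!is.na(cl)])) < 5L &&
      length(unique(v[is.finite(v)])) < 5L) {
    message("fewer than 5 distinct values: quintile classes collapsed")
  }
  list(class = as.integer(cl), boundaries = b)
}

#' Build a choropleth map layer
#'
#' Bundles per-area rates, their quintile classes and a geometry. Geometry
#' is, in order of preference: supplied `polygons`; Voronoi polygons of the
#' `centroids` clipped to `extent` (see [voronoi_polygons()]); or bare
#' centroid points (the render step warns and draws a point map).
#'
#' @param area_id Area identifiers.
#' @param values The rate to map (one per area).
#' @param centroids Optional two-column matrix of centroids (km).
#' @param polygons Optional list of two-column coordinate matrices.
#' @param extent Rectangle side lengths for the Voronoi construction.
#' @param overlay Optional data frame of overlay points (industrial centers
#'   and the like): columns `x`, `y`, optional `label`.
#' @param name Name of the rate column, used in titles and properties.
#' @return Object of class `"map_layer"`.
#' @export
map_layer <- function(area_id, values, centroids = NULL, polygons = NULL,
                      extent = NULL, overlay = NULL, name = "rate") {
  stopifnot(length(area_id) == length(values))
  if (is.null(polygons) && !is.null(centroids) && !is.null(extent)) {
    polygons <- voronoi_polygons(centroids, extent)$polygons
  }
  if (is.null(polygons) && is.null(centroids)) {
    stop("map layer needs polygons or centroids")
  }
  q <- quintile_classify(values)
  structure(list(area_id = area_id, values = values, name = name,
                 class = q$class, boundaries = q$boundaries,
                 polygons = polygons, centroids = centroids,
                 overlay = overlay),
            class = "map_layer")
}

#' Render a map layer to GeoJSON and PNG
#'
#' Writes `<file>.geojson` (polygon or point features carrying `area_id`,
#' the rate value and its quintile `class`; overlay points as point
#' features flagged `overlay`) and, unless `png = FALSE`, a `<file>.png`
#' choropleth shaded by quintile with the boundaries in the legend and the
#' overlay drawn as labelled triangles. Output is a pure function of the
#' layer: coordinates are written with fixed precision so reruns are
#' byte-identical.
#'
#' @param layer A [map_layer()].
#' @param file Output path without extension.
#' @param png Also write the PNG (default `TRUE`).
#' @return Invisibly, the GeoJSON path.
#' @export
render_map <- function(layer, file, png = TRUE) {
  stopifnot(inherits(layer, "map_layer"))
  point_fallback <- is.null(layer$polygons)
  if (point_fallback) {
    warning("no polygon geometry: falling back to a point map")
  }
  features <- lapply(seq_along(layer$area_id), function(i) {
    geom <- if (point_fallback) {
      list(type = "Point",
           coordinates = round(as.numeric(layer$centroids[i, ]), 6))
    } else {
      poly <- layer$polygons[[i]]
      ring <- rbind(poly, poly[1, , drop = FALSE])  # closed ring
      list(type = "Polygon",
           coordinates = list(lapply(seq_len(nrow(ring)), function(k)
             round(as.numeric(ring[k, ]), 6))))
    }
    list(type = "Feature", geometry = geom,
         properties = list(area_id = layer$area_id[i],
                           value = round(layer$values[i], 6),
                           class = layer$class[i]))
  })
  if (!is.null(layer$overlay)) {
    ov <- layer$overlay
    features <- c(features, lapply(seq_len(nrow(ov)), function(i) {
      list(type = "Feature",
           geometry = list(type = "Point",
                           coordinates = round(c(ov$x[i], ov$y[i]), 6)),
           properties = list(overlay = TRUE,
                             label = if ("label" %in% names(ov))
                               as.character(ov$label[i]) else paste0("center", i)))
    }))
  }
  gj <- list(type = "FeatureCollection", name = layer$name,
             features = features)
  geojson_path <- paste0(file, ".geojson")
  writeLines(jsonlite::toJSON(gj, auto_unbox = TRUE, digits = NA),
             geojson_path)

  if (png) {
    pal <- grDevices::hcl.colors(5, "YlOrRd", rev = TRUE)
    grDevices::png(paste0(file, ".png"), width = 900, height = 700)
    on.exit(grDevices::dev.off(), add = TRUE)
    xs <- if (point_fallback) layer$centroids[, 1] else
      unlist(lapply(layer$polygons, function(p) p[, 1]))
    ys <- if (point_fallback) layer$centroids[, 2] else
      unlist(lapply(layer$polygons, function(p) p[, 2]))
    graphics::plot(NA, xlim = range(xs), ylim = range(ys), asp = 1,
                   xlab = "km", ylab = "km",
                   main = paste("Quintile map of", layer$name))
    for (i in seq_along(layer$area_id)) {
      colr <- if (is.na(layer$class[i])) "grey80" else pal[layer$class[i]]
      if (point_fallback) {
        graphics::points(layer$centroids[i, 1], layer$centroids[i, 2],
                         pch = 21, bg = colr, cex = 1.4)
      } else {
        graphics::polygon(layer$polygons[[i]], col = colr, border = "grey40")
      }
    }
    if (!is.null(layer$overlay)) {
      graphics::points(layer$overlay$x, layer$overlay$y, pch = 17, cex = 1.6)
      if ("label" %in% names(layer$overlay)) {
        graphics::text(layer$overlay$x, layer$overlay$y,
                       layer$overlay$label, pos = 3, cex = 0.8)
      }
    }
    graphics::legend("topright",
                     legend = quintile_legend_labels(layer$boundaries),
                     fill = pal, title = "quintile", bty = "n")
  }
  invisible(geojson_path)
}

quintile_legend_labels <- function(b) {
  bb <- sprintf("%.2f", b)
  c(paste0("<= ", bb[1]),
    paste0("(", bb[1], ", ", bb[2], "]"),
    paste0("(", bb[2], ", ", bb[3], "]"),
    paste0("(", bb[3], ", ", bb[4], "]"),
    paste0("> ", bb[4]))
}
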