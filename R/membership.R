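#' Pairwise Euclidean distances between area centroids
#'
#' Distances between municipality centroids, in the same units as the
#' coordinates (kilometres throughout this package). Duplicate centroids are
#' permitted (their distance is zero) but flagged with a warning, since they
#' usually indicate a data problem upstream.
#'
#' @param centroids Two-column numeric matrix or data frame of centroid
#'   coordinates (x, y) in km, one row per area.
#' @return Symmetric numeric matrix of Euclidean distances with zero
#'   diagonal; row/column names taken from `rownames(centroids)` if present.
#' @examples
#' pairwise_distances(rbind(c(0, 0), c(3, 4)))
#' @export
pairwise_distances <- function(centroids) {
  xy <- as.matrix(centroids)
  if (!is.numeric(xy) || ncol(xy) != 2L) {
    stop("`centroids` must be a two-column numeric matrix of (x, y) in km")
  }
  if (anyNA(xy) || any(!is.finite(xy))) {
    stop("centroid coordinates must be finite")
  }
  d <- as.matrix(stats::dist(xy, method = "euclidean"))
  dimnames(d) <- if (is.null(rownames(centroids))) NULL else
    list(rownames(centroids), rownames(centroids))
  if (nrow(xy) > 1L && any(d[upper.tri(d)] == 0)) {
    warning("duplicate centroids detected (zero off-diagonal distance)")
  }
  d
}

#' Distance-radius neighbor sets
#'
#' The neighborhood of area i is the set of all areas whose centroid lies
#' within `radius_km` of i's centroid (closed ball: ties at exactly the
#' radius are included). By default the neighborhood includes area i itself,
#' which guarantees every neighborhood is non-empty and every row of the
#' derived weight matrix is well defined even for isolated areas;
#' `include_self = FALSE` is available for sensitivity analysis.
#'
#' @param distances Square symmetric distance matrix in km (see
#'   [pairwise_distances()]).
#' @param radius_km Positive radius in km; areas at distance <= radius are
#'   neighbors. Default 25, the median distance between neighboring
#'   municipalities in the regional geography the model was designed for.
#' @param include_self Logical; include area i in its own neighborhood
#'   (default `TRUE`).
#' @return List of integer vectors, one per area, of neighbor indices.
#' @export
build_neighborhoods <- function(distances, radius_km = 25, include_self = TRUE) {
  d <- as.matrix(distances)
  n <- nrow(d)
  if (n != ncol(d)) stop("`distances` must be square")
  if (max(abs(d - t(d))) > 1e-8) stop("`distances` must be symmetric")
  if (!is.numeric(radius_km) || length(radius_km) != 1L || radius_km <= 0) {
    stop("`radius_km` must be a single positive number")
  }
  nb <- lapply(seq_len(n), function(i) {
    s <- which(d[i, ] <= radius_km)
    if (!include_self) s <- setdiff(s, i)
    s
  })
  if (!include_self && any(lengths(nb) == 0L)) {
    stop("some areas have empty neighborhoods with include_self = FALSE; ",
         "increase the radius or keep self-inclusion")
  }
  names(nb) <- rownames(d)
  nb
}

#' Row-stochastic multiple-membership weight matrix
#'
#' Builds the weight matrix Z of the spatial multiple-membership structure:
#' `z[i, j] = 1 / |neighborhood(i)|` when j is a neighbor of i and 0
#' otherwise, so every row sums to one and the spatial effect of area i is
#' the equally-weighted mean of the latent effects of its neighborhood.
#'
#' @param neighbor_sets List of neighbor index vectors from
#'   [build_neighborhoods()].
#' @param n Number of areas (columns of Z); defaults to
#'   `length(neighbor_sets)`.
#' @return Sparse row-stochastic matrix of class `"dgCMatrix"`.
#' @export
build_weight_matrix <- function(neighbor_sets, n = length(neighbor_sets)) {
  if (length(neighbor_sets) == 0L) stop("`neighbor_sets` is empty")
  sizes <- lengths(neighbor_sets)
  if (any(sizes == 0L)) stop("empty neighbor set: every area needs >= 1 neighbor")
  i <- rep.int(seq_along(neighbor_sets), sizes)
  j <- unlist(neighbor_sets, use.names = FALSE)
  Matrix::sparseMatrix(i = i, j = j, x = 1 / sizes[i],
                       dims = c(length(neighbor_sets), n))
}

#' Assemble the full membership structure for the multilevel models
#'
#' Convenience constructor combining [pairwise_distances()],
#' [build_neighborhoods()] and [build_weight_matrix()], plus an optional
#' third hierarchical level (health-district or environmental-risk-area
#' labels) and the mean-size summaries used in the variance decomposition.
#'
#' @param centroids Two-column matrix/data frame of centroids in km.
#' @param radius_km Neighborhood radius in km (default 25).
#' @param third_level Optional vector of group labels (one per area), e.g.
#'   the health district (ASL) or the environmental risk area of each
#'   municipality. `NA` labels are grouped together as `"none"`.
#' @param include_self Passed to [build_neighborhoods()].
#' @param m_bar_convention How the mean third-level group size `m_bar` is
#'   computed: `"quotient"` (default) is the number of areas divided by the
#'   number of groups; `"area_weighted"` is the mean over areas of the size
#'   of their own group. The two agree when groups are equal-sized.
#' @return Object of class `"membership_structure"`: a list with
#'   `neighbor_sets`, `Z` (sparse row-stochastic matrix), `distances`,
#'   `third_level` (factor or `NULL`), `n_bar` (mean neighborhood size) and
#'   `m_bar` (mean group size, `NA` when no third level is supplied).
#' @export
membership_structure <- function(centroids, radius_km = 25, third_level = NULL,
                                 include_self = TRUE,
                                 m_bar_convention = c("quotient", "area_weighted")) {
  m_bar_convention <- match.arg(m_bar_convention)
  d <- pairwise_distances(centroids)
  nb <- build_neighborhoods(d, radius_km, include_self = include_self)
  Z <- build_weight_matrix(nb)
  tl <- NULL
  if (!is.null(third_level)) {
    if (length(third_level) != nrow(d)) {
      stop("`third_level` must have one label per area")
    }
    tl <- as.character(third_level)
    tl[is.na(tl)] <- "none"
    tl <- factor(tl)
  }
  structure(
    list(neighbor_sets = nb, Z = Z, distances = d, radius_km = radius_km,
         third_level = tl, n_bar = mean(lengths(nb)),
         m_bar = m_bar_from_labels(tl, m_bar_convention),
         m_bar_convention = m_bar_convention),
    class = "membership_structure"
  )
}

m_bar_from_labels <- function(labels, convention = "quotient") {
  if (is.null(labels)) return(NA_real_)
  labels <- droplevels(factor(labels))
  sizes <- table(labels)
  switch(convention,
         quotient      = length(labels) / nlevels(labels),
         area_weighted = mean(as.numeric(sizes[as.character(labels)])))
}

#' Mean neighborhood and group sizes of a membership structure
#'
#' Returns the summaries entering the per-municipality variance
#' decomposition: `n_bar`, the mean number of municipalities in the spatial
#' dependency neighborhoods, and `m_bar`, the mean number of municipalities
#' per third-level group (`NA` when the structure has no third level). Both
#' are reported to two decimals by the print method, matching how they are
#' conventionally tabulated.
#'
#' @param structure A `"membership_structure"` object.
#' @return Named numeric vector `c(n_bar = ..., m_bar = ...)`.
#' @export
summarize_membership <- function(structure) {
  stopifnot(inherits(structure, "membership_structure"))
  c(n_bar = structure$n_bar, m_bar = structure$m_bar)
}

#' @export
print.membership_structure <- function(x, ...) {
  n <- length(x$neighbor_sets)
  cat("Multiple-membership structure:", n, "areas, radius",
      x$radius_km, "km\n")
  cat(sprintf("  mean neighborhood size n_bar = %.2f\n", x$n_bar))
  if (!is.null(x$third_level)) {
    cat(sprintf("  third level: %d groups, mean group size m_bar = %.2f (%s)\n",
                nlevels(x$third_level), x$m_bar, x$m_bar_convention))
  } else {
    cat("  third level: absent (m_bar undefined)\n")
  }
  invisible(x)
}

#' Write the weight matrix and memberships as a sparse triplet CSV
#'
#' Audit export: one row per nonzero weight `(i, j, z_ij)`, plus an optional
#' companion CSV of third-level memberships.
#'
#' @param structure A `"membership_structure"` object.
#' @param file Path of the triplet CSV to write.
#' @param membership_file Optional path for the per-area third-level map.
#' @return Invisibly, the triplet data frame.
#' @export
write_membership_triplets <- function(structure, file, membership_file = NULL) {
  stopifnot(inherits(structure, "membership_structure"))
  tr <- Matrix::summary(structure$Z)
  df <- data.frame(i = tr$i, j = tr$j, z = tr$x)
  df <- df[order(df$i, df$j), , drop = FALSE]
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  if (!is.null(membership_file) && !is.null(structure$third_level)) {
    utils::write.csv(
      data.frame(area = seq_along(structure$third_level),
                 group = as.character(structure$third_level)),
      membership_file, row.names = FALSE, quote = FALSE)
  }
  invisible(df)
}
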