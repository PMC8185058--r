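# Pairwise distance / similarity matrices: community (Bray-Curtis),
# geographic (great-circle km) and environmental (log + z-score Euclidean).
# All are returned as labelled symmetric matrices with a zero diagonal,
# validated on construction.

as_distance_matrix <- function(values, labels = rownames(values)) {
  values <- as.matrix(values)
  if (is.null(labels)) stop("distance matrix needs labels")
  if (nrow(values) != ncol(values) || length(labels) != nrow(values))
    stop("distance matrix must be square with one label per row")
  dimnames(values) <- list(labels, labels)
  if (any(values < -1e-12)) stop("negative distances")
  if (max(abs(values - t(values))) > 1e-8) stop("distance matrix not symmetric")
  if (any(abs(diag(values)) > 1e-12)) stop("distance matrix diagonal not zero")
  values[values < 0] <- 0
  values <- (values + t(values)) / 2
  diag(values) <- 0
  class(values) <- c("distance_matrix", class(values))
  values
}

# off-diagonal pairs as a vector, row-major over the lower triangle
lower_pairs <- function(m) m[lower.tri(m)]

#' Bray-Curtis dissimilarity matrix
#'
#' \eqn{d(u,v) = \sum_i |u_i - v_i| / \sum_i (u_i + v_i)}. By default each
#' sample is first converted to relative abundances (the usual amplicon
#' convention when sample totals differ); `relative = FALSE` applies the
#' formula to raw counts.
#'
#' @param table abundance matrix, samples in rows.
#' @param relative normalize each sample to proportions first.
#' @return a `distance_matrix` with values in \[0, 1\].
#' @export
bray_curtis <- function(table, relative = TRUE) {
  table <- as.matrix(table)
  if (nrow(table) < 2L) stop("need at least two samples")
  totals <- rowSums(table)
  if (any(totals <= 0))
    stop("zero-total sample(s): ",
         paste(rownames(table)[totals <= 0], collapse = ", "))
  if (relative) table <- table / totals
  d <- as.matrix(vegan::vegdist(table, method = "bray"))
  as_distance_matrix(d, rownames(table))
}

#' Similarity from a normalized dissimilarity
#'
#' Elementwise `1 - d` (unit diagonal for a zero-diagonal dissimilarity),
#' as used for distance-decay plots of community similarity
#' (1 - Bray-Curtis). Only defined for values in \[0, 1\]; applying it
#' twice returns the input.
#'
#' @param matrix a `distance_matrix` with values in \[0, 1\].
#' @return matrix of similarities with the same labels, diagonal 1.
#' @export
similarity <- function(matrix) {
  m <- unclass(as.matrix(matrix))
  if (any(m > 1 + 1e-12))
    stop("similarity is only defined for normalized dissimilarities in [0, 1]")
  1 - m
}

#' Great-circle distance matrix (km)
#'
#' Haversine distances between sites on a sphere of radius 6371.0 km, the
#' standard choice for site-scale biogeography.
#'
#' @param coordinates data.frame or matrix with columns `latitude` and
#'   `longitude` in decimal degrees; row names (or a `site_id` column) label
#'   the sites.
#' @return a `distance_matrix` in kilometres.
#' @export
haversine_matrix <- function(coordinates) {
  coordinates <- as.data.frame(coordinates)
  labels <- if (!is.null(coordinates$site_id)) as.character(coordinates$site_id)
            else rownames(coordinates)
  lat <- coordinates$latitude
  lon <- coordinates$longitude
  if (is.null(lat) || is.null(lon))
    stop("coordinates need 'latitude' and 'longitude' columns")
  if (any(abs(lat) > 90)) stop("latitude outside [-90, 90]")
  if (any(abs(lon) > 360)) stop("longitude out of range")
  pts <- cbind(lon, lat)
  d <- geosphere::distm(pts, fun = function(p1, p2)
    geosphere::distHaversine(p1, p2, r = 6371000)) / 1000
  as_distance_matrix(d, labels)
}

#' Standardized environmental Euclidean distance
#'
#' Per-variable pipeline: every variable except pH is log(x + 1)
#' transformed, then every variable (pH included) is z-scored to mean 0 and
#' sd 1 across sites; the distance is Euclidean over the standardized
#' vectors. Variables with zero variance after transformation are dropped
#' with a warning.
#'
#' @param table an `env_table` or any data.frame with a `site_id` column and
#'   numeric variables.
#' @param variables variables to use; default all numeric environmental
#'   variables present.
#' @param log_vars variables to log(x + 1) transform; `NULL` (default)
#'   means every variable except pH, `character(0)` disables the transform
#'   (e.g. for an already-standardized gradient).
#' @return a `distance_matrix`.
#' @export
env_distance <- function(table, variables = NULL, log_vars = NULL) {
  df <- as.data.frame(table)
  labels <- if (!is.null(df$site_id)) as.character(df$site_id) else rownames(df)
  non_env <- c("site_id", "coordinates", "region", "peatland_type",
               "latitude", "longitude", "medium", "sample_id", "site")
  if (is.null(variables))
    variables <- setdiff(names(df)[vapply(df, is.numeric, TRUE)], non_env)
  missing <- setdiff(variables, names(df))
  if (length(missing))
    stop("variable(s) not in table: ", paste(missing, collapse = ", "))
  x <- as.matrix(df[variables])
  if (is.null(log_vars)) log_vars <- setdiff(variables, "pH")
  for (v in variables) {
    if (v %in% log_vars) {
      if (any(x[, v] < 0, na.rm = TRUE))
        stop("negative values in '", v, "' cannot be log(x + 1) transformed")
      x[, v] <- log(x[, v] + 1)
    }
  }
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance variable(s): ",
            paste(variables[sds == 0], collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
    if (ncol(x) == 0L) stop("no variables left after dropping zero variance")
  }
  z <- scale(x)
  d <- as.matrix(stats::dist(z, method = "euclidean"))
  as_distance_matrix(d, labels)
}

#' Mean pairwise off-diagonal value within a subset
#'
#' Arithmetic mean over the `n(n-1)/2` unordered pairs of the subset.
#'
#' @param matrix a square labelled matrix (distance or similarity).
#' @param subset labels to restrict to; default all.
#' @return a single numeric value.
#' @export
mean_pairwise <- function(matrix, subset = NULL) {
  m <- as.matrix(matrix)
  if (is.null(subset)) subset <- rownames(m)
  missing <- setdiff(subset, rownames(m))
  if (length(missing))
    stop("labels not in matrix: ", paste(missing, collapse = ", "))
  if (length(subset) < 2L) stop("need at least two labels")
  sub <- m[subset, subset]
  mean(sub[lower.tri(sub)])
}
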