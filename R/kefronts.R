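## Kinetic-energy fronts: percentile thresholding, domain-boundary overlap
## validation, K-means segmentation and per-pixel front occurrence.

#' Basin-wide kinetic-energy percentile threshold
#'
#' The q-th percentile of KE over all ocean cells and all months of the
#' reference period, with the linear-interpolation percentile convention
#' (\code{stats::quantile} type 7).
#'
#' @param KE a kinetic-energy \code{gridded_field}.
#' @param q percentile in (0, 100), default 50.
#' @return the threshold (m2/s2).
#' @export
ke_threshold <- function(KE, q = 50) {
  stopifnot(inherits(KE, "gridded_field"), q > 0, q < 100)
  vals <- matrix(KE$values, nrow = dim(KE$values)[1L])[, as.vector(KE$mask)]
  vals <- vals[!is.na(vals)]
  if (!length(vals)) stop_dm("all cells masked: no ocean KE values")
  unname(stats::quantile(vals, q / 100, type = 7))
}

#' Front mask from slot-mean kinetic energy
#'
#' Ocean cells whose time-mean KE over the (sliced) field exceeds the
#' threshold computed on the full reference period.
#'
#' @param KE the slot's kinetic-energy \code{gridded_field}.
#' @param threshold KE threshold from \code{\link{ke_threshold}}.
#' @return logical (lat x lon) matrix, \code{FALSE} on land.
#' @export
front_mask <- function(KE, threshold) {
  stopifnot(inherits(KE, "gridded_field"))
  meanKE <- colMeans(KE$values, dims = 1L)
  out <- !is.na(meanKE) & meanKE > threshold
  out & KE$mask
}

## One iteration of 3x3 (8-connected) binary dilation on a logical matrix.
dilate3x3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    src_r <- max(1L, 1L - di):min(nr, nr - di)
    src_c <- max(1L, 1L - dj):min(nc, nc - dj)
    out[src_r + di, src_c + dj] <- out[src_r + di, src_c + dj] |
      m[src_r, src_c]
  }
  out
}

#' Domain-boundary matrix
#'
#' Marks every ocean cell with at least one 4-neighbor carrying a different
#' domain label (background counts as its own label), then dilates the
#' result by one grid point with a 3x3 structuring element. By default,
#' cells whose only differing neighbor is land are not counted as boundary
#' (coastlines are not domain frontiers).
#'
#' @param label_map integer (lat x lon) label matrix (0 background, NA land),
#'   e.g. \code{domain_set$label_map}.
#' @param include_coast logical; count land contrast as boundary (default
#'   \code{FALSE}).
#' @return logical (lat x lon) boundary matrix, \code{FALSE} on land.
#' @export
boundary_matrix <- function(label_map, include_coast = FALSE) {
  nlat <- nrow(label_map); nlon <- ncol(label_map)
  raw <- matrix(FALSE, nlat, nlon)
  for (i in seq_len(nlat)) for (j in seq_len(nlon)) {
    a <- label_map[i, j]
    if (is.na(a)) next
    nb <- neighbors4(i, j, nlat, nlon)
    vals <- label_map[nb]
    differs <- !is.na(vals) & vals != a
    if (include_coast) differs <- differs | is.na(vals)
    if (any(differs)) raw[i, j] <- TRUE
  }
  dilate3x3(raw) & !is.na(label_map)
}

#' Fraction of domain boundary overlapping the KE fronts
#'
#' \code{|boundary AND front| / |boundary|}.
#'
#' @param boundary logical boundary matrix (\code{\link{boundary_matrix}}).
#' @param front logical front mask (\code{\link{front_mask}}).
#' @return fraction in [0, 1].
#' @export
overlap_fraction <- function(boundary, front) {
  if (!identical(dim(boundary), dim(front)))
    stop_dm("boundary and front grids differ")
  nb <- sum(boundary, na.rm = TRUE)
  if (nb == 0L) stop_dm("empty boundary matrix")
  sum(boundary & front, na.rm = TRUE) / nb
}

#' K-means segmentation of a kinetic-energy map
#'
#' One-dimensional K-means on the ocean-cell KE intensities (10 restarts,
#' seeded), with clusters relabeled in increasing centroid order; the
#' maximum-intensity cluster serves as the KE-front indicator.
#'
#' @param meanKE numeric (lat x lon) matrix of slot-mean KE (NA on land).
#' @param k number of clusters (default 4).
#' @param seed integer seed for the K-means restarts.
#' @return list: \code{cluster_map} (integer lat x lon, 1 = lowest energy),
#'   \code{centers} (increasing), \code{pixels} (per-cluster cell counts),
#'   \code{max_cluster_pixels}.
#' @export
kmeans_segment <- function(meanKE, k = 4L, seed = 1L) {
  stopifnot(is.matrix(meanKE), k >= 2L)
  ocean <- which(!is.na(meanKE))
  x <- meanKE[ocean]
  if (length(unique(x)) < k)
    stop_dm("fewer than k = %d distinct KE values (%d)", k, length(unique(x)))
  km <- with_local_seed(seed, stats::kmeans(x, centers = k, nstart = 10L,
                                            iter.max = 100L))
  ord <- order(km$centers)
  relab <- match(seq_len(k), ord)          # old label -> increasing rank
  cl <- relab[km$cluster]
  cluster_map <- matrix(NA_integer_, nrow(meanKE), ncol(meanKE))
  cluster_map[ocean] <- cl
  pixels <- tabulate(cl, nbins = k)
  list(cluster_map = cluster_map,
       centers = as.numeric(km$centers[ord]),
       pixels = pixels,
       max_cluster_pixels = pixels[k])
}

#' Per-pixel front occurrence count
#'
#' For each ocean cell, the number of months in the (sliced) field whose KE
#' exceeds the reference-period threshold.
#'
#' @param KE the slot's kinetic-energy \code{gridded_field}.
#' @param threshold KE threshold from \code{\link{ke_threshold}} over the
#'   full reference period.
#' @return integer (lat x lon) matrix of counts in \code{[0, months]}, NA on
#'   land.
#' @export
front_occurrence <- function(KE, threshold) {
  stopifnot(inherits(KE, "gridded_field"))
  counts <- colSums(KE$values > threshold, dims = 1L)
  counts[!KE$mask] <- NA_integer_
  mode(counts) <- "integer"
  counts
}

#' Per-cell correlation between two fields
#'
#' Pearson correlation of the two time series in every ocean cell, plus the
#' spatial mean and variance of the map over the defined cells. Cells where
#' either series has zero variance are excluded and counted.
#'
#' @param f1,f2 \code{gridded_field}s on the same grid and time axis.
#' @return list: \code{map} (lat x lon correlation matrix), \code{mean},
#'   \code{variance}, \code{n_excluded}.
#' @export
field_correlation_map <- function(f1, f2) {
  stopifnot(inherits(f1, "gridded_field"), inherits(f2, "gridded_field"))
  if (!same_grid(f1, f2) || !identical(f1$time, f2$time))
    stop_dm("fields must share grid and time axis")
  nlat <- length(f1$lat); nlon <- length(f1$lon)
  map <- matrix(NA_real_, nlat, nlon)
  excluded <- 0L
  for (i in seq_len(nlat)) for (j in seq_len(nlon)) {
    if (!f1$mask[i, j]) next
    a <- f1$values[, i, j]; b <- f2$values[, i, j]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      excluded <- excluded + 1L
      next
    }
    map[i, j] <- stats::cor(a, b)
  }
  vals <- map[!is.na(map)]
  list(map = map, mean = mean(vals),
       variance = if (length(vals) > 1L) stats::var(vals) else 0,
       n_excluded = excluded)
}
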