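# Independent brute-force oracles. These deliberately avoid the package's
# internal code paths: plain loops, explicit formulas, no shared helpers.

# Pearson correlation from first principles.
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
  sxy / sqrt(sxx * syy)
}

# Haversine great-circle distance (degrees in, metres out).
oracle_dist <- function(lat1, lon1, lat2, lon2) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad; dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  2 * 6378137 * asin(pmin(1, sqrt(a)))
}

# Local homogeneity by exhaustive loops: for each ocean cell, the K nearest
# ocean cells by great-circle distance (ties by (lat, lon) order), then the
# mean Pearson correlation over all unordered pairs of the neighborhood.
oracle_homogeneity <- function(field, K) {
  nlat <- length(field$lat); nlon <- length(field$lon)
  cells <- which(field$mask, arr.ind = TRUE)
  cells <- cells[order(cells[, 1], cells[, 2]), , drop = FALSE]
  n <- nrow(cells)
  out <- matrix(NA_real_, nlat, nlon)
  for (c1 in seq_len(n)) {
    d <- numeric(n)
    for (c2 in seq_len(n))
      d[c2] <- oracle_dist(field$lat[cells[c1, 1]], field$lon[cells[c1, 2]],
                           field$lat[cells[c2, 1]], field$lon[cells[c2, 2]])
    d[c1] <- Inf
    # same convention as the package: 1 cm distance resolution, then
    # (lat, lon) order
    nbr <- order(round(d, 2), seq_len(n))[seq_len(min(K, n - 1))]
    members <- c(c1, nbr)
    vals <- c()
    for (a in seq_along(members)) for (b in seq_along(members)) {
      if (a >= b) next
      xa <- field$values[, cells[members[a], 1], cells[members[a], 2]]
      xb <- field$values[, cells[members[b], 1], cells[members[b], 2]]
      if (sd(xa) > 0 && sd(xb) > 0)
        vals <- c(vals, oracle_pearson(xa, xb))
    }
    if (length(vals) && sd(field$values[, cells[c1, 1], cells[c1, 2]]) > 0)
      out[cells[c1, 1], cells[c1, 2]] <- mean(vals)
  }
  out
}

# Lagged cross-correlation by explicit shifting.
oracle_lagged_cor <- function(xa, xb, tau_max) {
  tt <- length(xa)
  out <- setNames(numeric(2 * tau_max + 1), -tau_max:tau_max)
  for (tau in -tau_max:tau_max) {
    pairs_a <- c(); pairs_b <- c()
    for (t in seq_len(tt)) {
      if (t + tau >= 1 && t + tau <= tt) {
        pairs_a <- c(pairs_a, xa[t]); pairs_b <- c(pairs_b, xb[t + tau])
      }
    }
    out[as.character(tau)] <- oracle_pearson(pairs_a, pairs_b)
  }
  out
}

# Kinetic energy by elementwise loop.
oracle_ke <- function(u, v) {
  out <- array(NA_real_, dim(u$values))
  d <- dim(u$values)
  for (t in seq_len(d[1])) for (i in seq_len(d[2])) for (j in seq_len(d[3]))
    out[t, i, j] <- 0.5 * (u$values[t, i, j]^2 + v$values[t, i, j]^2)
  out
}

# Type-7 (linear interpolation) percentile from the definition.
oracle_percentile <- function(x, q) {
  x <- sort(x)
  h <- (length(x) - 1) * q / 100 + 1
  lo <- floor(h)
  if (lo >= length(x)) return(x[length(x)])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

# Boundary matrix by direct set arithmetic: raw boundary cells, then the
# union of their 8-neighborhoods, restricted to non-land cells.
oracle_boundary <- function(label_map, include_coast = FALSE) {
  nlat <- nrow(label_map); nlon <- ncol(label_map)
  raw <- matrix(FALSE, nlat, nlon)
  for (i in seq_len(nlat)) for (j in seq_len(nlon)) {
    a <- label_map[i, j]
    if (is.na(a)) next
    for (s in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      ii <- i + s[1]; jj <- j + s[2]
      if (ii < 1 || ii > nlat || jj < 1 || jj > nlon) next
      b <- label_map[ii, jj]
      if ((is.na(b) && include_coast) || (!is.na(b) && b != a))
        raw[i, j] <- TRUE
    }
  }
  out <- raw
  for (i in seq_len(nlat)) for (j in seq_len(nlon)) {
    if (!raw[i, j]) next
    for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nlat && jj >= 1 && jj <= nlon) out[ii, jj] <- TRUE
    }
  }
  out & !is.na(label_map)
}

# Per-cell front occurrence by loop.
oracle_front_occurrence <- function(KE, threshold) {
  d <- dim(KE$values)
  out <- matrix(NA_integer_, d[2], d[3])
  for (i in seq_len(d[2])) for (j in seq_len(d[3])) {
    if (!KE$mask[i, j]) next
    cnt <- 0L
    for (t in seq_len(d[1]))
      if (KE$values[t, i, j] > threshold) cnt <- cnt + 1L
    out[i, j] <- cnt
  }
  out
}
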