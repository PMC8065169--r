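## Domain identification: cores of high local homogeneity are found on the
## anomaly field and grown/merged into spatially contiguous domains whose
## average pairwise cell correlation stays above the threshold delta.

## Per-grid geometry shared by the steps below: ocean-cell index table in
## deterministic (lat, lon) order, the K-nearest-neighbour lists by
## great-circle distance, and the 4-adjacency lists among ocean cells.
grid_geometry <- function(field, K) {
  oc <- which(field$mask, arr.ind = TRUE)
  ord <- order(oc[, 1L], oc[, 2L])
  oc <- oc[ord, , drop = FALSE]
  n <- nrow(oc)
  pts <- cbind(field$lon[oc[, 2L]], field$lat[oc[, 1L]])
  if (n > 1L) {
    dmat <- geosphere::distm(pts, fun = geosphere::distHaversine)
    diag(dmat) <- Inf
    k_eff <- min(K, n - 1L)
    nbr <- lapply(seq_len(n), function(i) {
      # deterministic: distance (1 cm resolution, so exactly equidistant
      # N/S neighbours tie robustly), then (lat, lon) order
      order(round(dmat[i, ], 2), seq_len(n))[seq_len(k_eff)]
    })
  } else nbr <- list(integer(0))
  cellid <- matrix(NA_integer_, length(field$lat), length(field$lon))
  cellid[oc] <- seq_len(n)
  adj <- lapply(seq_len(n), function(k) {
    nb <- neighbors4(oc[k, 1L], oc[k, 2L], length(field$lat),
                     length(field$lon))
    ids <- cellid[nb]
    sort(ids[!is.na(ids)])
  })
  list(idx = oc, nbr = nbr, adj = adj, cellid = cellid, n = n)
}

## Full ocean-cell correlation matrix; zero-variance cells give NA rows.
cell_cor <- function(series) {
  sds <- apply(series, 2L, stats::sd)
  C <- suppressWarnings(stats::cor(series))
  C[sds == 0, ] <- NA_real_
  C[, sds == 0] <- NA_real_
  C
}

#' Local homogeneity map
#'
#' For every ocean cell, the average pairwise Pearson correlation within the
#' neighborhood formed by the cell and its \code{K} nearest ocean neighbors
#' (great-circle distance; for \code{K = 4} on a regular grid this is the von
#' Neumann neighborhood away from coasts). Cells with a constant series are
#' undefined (\code{NA}) and are excluded from core detection.
#'
#' @param anoms a deseasonalized/detrended \code{gridded_field}.
#' @param K neighborhood size (>= 1), default 4.
#' @return a list of class \code{homogeneity_map}: \code{values} (lat x lon
#'   matrix, NA on land/undefined), \code{K}, plus the internal geometry
#'   reused by \code{\link{identify_domains}}.
#' @export
local_homogeneity <- function(anoms, K = 4L) {
  stopifnot(inherits(anoms, "gridded_field"), K >= 1L)
  os <- ocean_series(anoms)
  geo <- grid_geometry(anoms, K)
  C <- cell_cor(os$series)
  h <- rep(NA_real_, geo$n)
  for (i in seq_len(geo$n)) {
    mem <- c(i, geo$nbr[[i]])
    sub <- C[mem, mem]
    ut <- sub[upper.tri(sub)]
    ut <- ut[!is.na(ut)]
    if (length(ut) && !is.na(C[i, i])) h[i] <- mean(ut)
  }
  vals <- matrix(NA_real_, length(anoms$lat), length(anoms$lon))
  vals[geo$idx] <- h
  structure(list(values = vals, K = as.integer(K), h = h, geo = geo, C = C),
            class = "homogeneity_map")
}

#' Minimum significant correlation for a significance level
#'
#' The smallest Pearson correlation significant at two-sided level
#' \code{alpha} under a t-test with \code{T - 2} degrees of freedom:
#' \eqn{\delta = t^* / \sqrt{T - 2 + t^{*2}}}.
#'
#' @param alpha two-sided significance level in (0, 1).
#' @param T sample size (> 3).
#' @return the correlation threshold \eqn{\delta}.
#' @export
delta_from_alpha <- function(alpha, T) {
  stopifnot(alpha > 0, alpha < 1, T > 3)
  tstar <- stats::qt(1 - alpha / 2, df = T - 2)
  tstar / sqrt(T - 2 + tstar^2)
}

#' Find domain cores
#'
#' A core is an ocean cell whose local homogeneity strictly exceeds that of
#' every defined neighbor in its K-neighborhood and exceeds \code{delta}.
#'
#' @param H a \code{homogeneity_map}.
#' @param delta correlation threshold.
#' @return integer vector of core cell ids (in the map's internal ocean-cell
#'   ordering), possibly empty; the (lat, lon) indices are attached as
#'   \code{attr(, "idx")}.
#' @export
find_cores <- function(H, delta) {
  stopifnot(inherits(H, "homogeneity_map"))
  cores <- integer(0)
  for (i in seq_len(H$geo$n)) {
    hi <- H$h[i]
    if (is.na(hi) || hi <= delta) next
    nb <- H$h[H$geo$nbr[[i]]]
    nb <- nb[!is.na(nb)]
    if (!length(nb) || all(hi > nb)) cores <- c(cores, i)
  }
  attr(cores, "idx") <- H$geo$idx[cores, , drop = FALSE]
  cores
}

#' Identify spatially contiguous domains
#'
#' Each core seeds a domain. Domains are grown best-first: at every step the
#' (domain, adjacent unassigned ocean cell) pair with the largest resulting
#' average pairwise correlation is absorbed, provided that average stays at
#' or above \code{delta}; ties break by (lat, lon) index. After growth,
#' adjacent domains are merged (largest union average first) while the union
#' average pairwise correlation is at least \code{delta}. Cells claimed by no
#' domain remain background. Domains never overlap.
#'
#' @param anoms a deseasonalized/detrended \code{gridded_field}.
#' @param K neighborhood size for homogeneity/cores, default 4.
#' @param delta correlation threshold; either given directly (default 0.545,
#'   the midpoint of the 0.54-0.55 band typically targeted when calibrating
#'   per-slot significance levels) or derived via \code{\link{delta_from_alpha}}
#'   when \code{alpha} is supplied.
#' @param alpha optional significance level from which to derive \code{delta}.
#' @param H optional precomputed \code{homogeneity_map} (skips recomputation).
#' @return an object of class \code{domain_set}: \code{domains} (list of
#'   \code{list(id, cells, cores)} with \code{cells} a two-column (lat, lon)
#'   index matrix), \code{label_map} (integer lat x lon; 0 background, NA
#'   land), \code{delta}, \code{K}, \code{alpha}, \code{homogeneity}.
#' @export
identify_domains <- function(anoms, K = 4L, delta = 0.545, alpha = NULL,
                             H = NULL) {
  stopifnot(inherits(anoms, "gridded_field"))
  if (!is.null(alpha))
    delta <- delta_from_alpha(alpha, length(anoms$time))
  if (is.null(H)) H <- local_homogeneity(anoms, K)
  geo <- H$geo
  C <- H$C
  cores <- find_cores(H, delta)
  n <- geo$n

  assign <- integer(n)                      # 0 = background
  nd <- length(cores)
  if (nd == 0L) {
    return(finalize_domains(list(), anoms, geo, delta, K, alpha, H))
  }
  cells <- vector("list", nd)
  csum <- numeric(nd)                       # sum of pairwise correlations
  cs <- matrix(0, n, nd)                    # colsum of C over domain cells
  frontier <- vector("list", nd)
  active <- rep(TRUE, nd)
  best_score <- rep(-Inf, nd)
  best_cell <- rep(NA_integer_, nd)

  for (d in seq_len(nd)) {
    cells[[d]] <- cores[d]
    assign[cores[d]] <- d
    cs[, d] <- C[, cores[d]]
  }
  order_key <- function(ids) order(geo$idx[ids, 1L], geo$idx[ids, 2L])

  refresh <- function(d) {
    fr <- frontier[[d]]
    fr <- fr[assign[fr] == 0L]
    fr <- fr[!is.na(C[fr, cells[[d]][1L]])]  # exclude zero-variance cells
    frontier[[d]] <<- fr
    if (!length(fr)) {
      best_score[d] <<- -Inf; best_cell[d] <<- NA_integer_
      return(invisible())
    }
    m <- length(cells[[d]])
    sc <- (csum[d] + cs[fr, d]) / choose(m + 1L, 2L)
    top <- which(sc == max(sc))
    if (length(top) > 1L) top <- top[order_key(fr[top])[1L]]
    best_score[d] <<- sc[top]
    best_cell[d] <<- fr[top]
    invisible()
  }
  for (d in seq_len(nd)) {
    frontier[[d]] <- geo$adj[[cores[d]]]
    refresh(d)
  }

  ## global lazy best-first expansion
  repeat {
    live <- which(active)
    if (!length(live)) break
    d <- live[which.max(best_score[live])]
    if (!is.finite(best_score[d])) { active[d] <- FALSE; next }
    cell <- best_cell[d]
    if (assign[cell] != 0L) { refresh(d); next }  # stale cache: revalidate
    if (best_score[d] < delta) { active[d] <- FALSE; next }
    assign[cell] <- d
    csum[d] <- csum[d] + cs[cell, d]
    cells[[d]] <- c(cells[[d]], cell)
    cs[, d] <- cs[, d] + C[, cell]
    frontier[[d]] <- unique(c(frontier[[d]],
                              geo$adj[[cell]][assign[geo$adj[[cell]]] == 0L]))
    refresh(d)
  }

  ## merge adjacent domains while the union average correlation >= delta
  merged <- merge_domains(cells, csum, cs, assign, geo, C, delta)
  doms <- lapply(seq_along(merged$cells), function(d) {
    ids <- merged$cells[[d]]
    list(id = d, cells = geo$idx[ids, , drop = FALSE],
         cores = intersect(ids, cores))
  })
  finalize_domains(doms, anoms, geo, delta, K, alpha, H,
                   cell_ids = merged$cells)
}

merge_domains <- function(cells, csum, cs, assign, geo, C, delta) {
  nd <- length(cells)
  alive <- rep(TRUE, nd)
  adj_pairs <- function() {
    ps <- list()
    for (d in which(alive)) for (cell in cells[[d]]) {
      for (nb in geo$adj[[cell]]) {
        e <- assign[nb]
        if (e != 0L && e != d && alive[e] && d < e)
          ps[[paste(d, e)]] <- c(d, e)
      }
    }
    ps
  }
  union_avg <- function(a, b) {
    cross <- sum(cs[cells[[a]], b])
    na <- length(cells[[a]]); nb <- length(cells[[b]])
    (csum[a] + csum[b] + cross) / choose(na + nb, 2L)
  }
  repeat {
    ps <- adj_pairs()
    if (!length(ps)) break
    scores <- vapply(ps, function(p) union_avg(p[1L], p[2L]), 1)
    if (max(scores) < delta) break
    top <- which(scores == max(scores))[1L]
    a <- ps[[top]][1L]; b <- ps[[top]][2L]
    cross <- sum(cs[cells[[a]], b])
    csum[a] <- csum[a] + csum[b] + cross
    cells[[a]] <- c(cells[[a]], cells[[b]])
    cs[, a] <- cs[, a] + cs[, b]
    assign[assign == b] <- a
    alive[b] <- FALSE
  }
  keep <- which(alive)
  ## deterministic ids: order by the (lat, lon) of each domain's first cell
  firsts <- t(vapply(keep, function(d) {
    ij <- geo$idx[cells[[d]], , drop = FALSE]
    ij[order(ij[, 1L], ij[, 2L])[1L], ]
  }, c(0, 0)))
  keep <- keep[order(firsts[, 1L], firsts[, 2L])]
  list(cells = lapply(keep, function(d) sort(cells[[d]])))
}

finalize_domains <- function(doms, anoms, geo, delta, K, alpha, H,
                             cell_ids = NULL) {
  label <- matrix(0L, length(anoms$lat), length(anoms$lon))
  label[!anoms$mask] <- NA_integer_
  for (d in seq_along(doms)) label[doms[[d]]$cells] <- d
  structure(list(domains = doms, label_map = label, delta = delta,
                 K = as.integer(K), alpha = alpha,
                 homogeneity = H$values),
            class = "domain_set")
}

#' @export
print.domain_set <- function(x, ...) {
  sizes <- vapply(x$domains, function(d) nrow(d$cells), 1L)
  cat(sprintf("<domain_set> %d domains (delta = %.3f, K = %d)\n",
              length(x$domains), x$delta, x$K))
  if (length(sizes))
    cat("  sizes:", paste(sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Average pairwise correlation of a cell set
#'
#' Diagnostic used by the domain-set invariants: the mean Pearson correlation
#' over all unordered pairs of cells in a domain (1 for singletons).
#'
#' @param anoms the anomaly \code{gridded_field}.
#' @param cells two-column (lat, lon) index matrix.
#' @return the average pairwise correlation.
#' @export
domain_avg_correlation <- function(anoms, cells) {
  m <- nrow(cells)
  if (m < 2L) return(1)
  series <- vapply(seq_len(m), function(r)
    anoms$values[, cells[r, 1L], cells[r, 2L]], numeric(dim(anoms$values)[1L]))
  C <- stats::cor(series)
  mean(C[upper.tri(C)])
}
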