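## Per-time-slot ecoregionalization sweep and cross-slot summaries.

#' Pipeline configuration
#'
#' @param K homogeneity neighborhood size (default 4).
#' @param delta domain correlation threshold (default 0.545); ignored when
#'   \code{alpha} is given.
#' @param alpha optional significance level from which delta is derived
#'   per slot length (\code{\link{delta_from_alpha}}).
#' @param tau_max maximum network lag, months (default 12).
#' @param level network significance level (default 0.03).
#' @param dist reference distribution for the Bartlett statistic.
#' @param q front percentile (default 50).
#' @param kclust K-means cluster count (default 4).
#' @param seed integer seed (K-means restarts).
#' @param detrend_full detrend over the full record before slicing
#'   (default \code{TRUE}) rather than per slot.
#' @return a \code{pipeline_config} list.
#' @export
pipeline_config <- function(K = 4L, delta = 0.545, alpha = NULL,
                            tau_max = 12L, level = 0.03, dist = "t",
                            q = 50, kclust = 4L, seed = 1L,
                            detrend_full = TRUE) {
  structure(list(K = as.integer(K), delta = delta, alpha = alpha,
                 tau_max = as.integer(tau_max), level = level, dist = dist,
                 q = q, kclust = as.integer(kclust), seed = as.integer(seed),
                 detrend_full = detrend_full),
            class = "pipeline_config")
}

## Per-slot-length alpha table from the study calibration that keeps the
## minimum significant correlation near 0.54-0.55.
#' Significance level per slot length
#'
#' The calibrated per-slot-length significance levels used to keep the
#' minimum significant correlation for domain identification within a
#' fixed band across slot lengths: 6e-5 for 6-year slots, 2e-5 for 7,
#' 3e-6 for 8, and 1e-3 for a 4-year validation window.
#'
#' @param delta_years slot length in years (4, 6, 7 or 8).
#' @return the significance level alpha.
#' @export
alpha_for_slot_length <- function(delta_years) {
  tab <- c(`4` = 1e-3, `6` = 6e-5, `7` = 2e-5, `8` = 3e-6)
  a <- tab[as.character(delta_years)]
  if (is.na(a)) stop_dm("no calibrated alpha for %d-year slots", delta_years)
  unname(a)
}

#' Run the ecoregionalization pipeline on one time slot
#'
#' Slices the fields to the slot, deseasonalizes and detrends the SST
#' (detrending over the full record or per slot, per config), identifies
#' domains, infers the functional network, and computes the slot's KE
#' summaries (basin-mean KE, K-means max-intensity-cluster pixel count).
#'
#' @param sst,u,v \code{gridded_field}s covering the slot (u and v may be
#'   \code{NULL} to skip the KE summaries).
#' @param slot a \code{time_slot}.
#' @param cfg a \code{pipeline_config}.
#' @return an object of class \code{slot_result}: \code{slot},
#'   \code{domain_set}, \code{network}, \code{n_domains}, \code{mean_KE},
#'   \code{max_cluster_pixels}, \code{mean_KE_map}, \code{anoms}.
#' @export
run_slot <- function(sst, u = NULL, v = NULL, slot, cfg = pipeline_config()) {
  stopifnot(inherits(sst, "gridded_field"), inherits(slot, "time_slot"))
  if (!any(sst$mask)) stop_dm("slot %d-%d: empty ocean mask",
                              slot$yr_ini, slot$yr_end - 1L)
  pre <- deseasonalize(sst)
  anoms <- if (cfg$detrend_full) slice_field(detrend(pre), slot)
           else detrend(slice_field(pre, slot))
  delta <- if (!is.null(cfg$alpha))
    delta_from_alpha(cfg$alpha, length(anoms$time)) else cfg$delta
  dset <- identify_domains(anoms, K = cfg$K, delta = delta)
  net <- NULL
  if (length(dset$domains) >= 2L) {
    sig <- domain_signals(dset, anoms)
    net <- infer_network(sig, tau_max = cfg$tau_max, level = cfg$level,
                         dist = cfg$dist)
  }
  mean_KE <- NA_real_; mcp <- NA_integer_; meanKE_map <- NULL
  if (!is.null(u) && !is.null(v)) {
    KE <- kinetic_energy(slice_field(u, slot), slice_field(v, slot))
    mean_KE <- mean(matrix(KE$values, nrow = dim(KE$values)[1L])[,
                      as.vector(KE$mask)], na.rm = TRUE)
    meanKE_map <- colMeans(KE$values, dims = 1L)
    meanKE_map[!KE$mask] <- NA_real_
    seg <- try(kmeans_segment(meanKE_map, k = cfg$kclust, seed = cfg$seed),
               silent = TRUE)
    if (!inherits(seg, "try-error")) mcp <- seg$max_cluster_pixels
  }
  structure(list(slot = slot, domain_set = dset, network = net,
                 n_domains = length(dset$domains), mean_KE = mean_KE,
                 max_cluster_pixels = mcp, mean_KE_map = meanKE_map,
                 anoms = anoms),
            class = "slot_result")
}

#' @export
print.slot_result <- function(x, ...) {
  cat(sprintf("<slot_result> %d-%d: %d domains, mean KE %.4g\n",
              x$slot$yr_ini, x$slot$yr_end - 1L, x$n_domains, x$mean_KE))
  invisible(x)
}

#' Basin partition by split meridian
#'
#' Splits the ocean into named west/east subsets at a longitude.
#'
#' @param field any \code{gridded_field} carrying the grid.
#' @param split_lon dividing longitude (west: lon < split_lon).
#' @return named list of logical (lat x lon) masks.
#' @export
basin_partition <- function(field, split_lon) {
  west <- matrix(rep(field$lon < split_lon, each = length(field$lat)),
                 length(field$lat), length(field$lon)) & field$mask
  list(west = west, east = !west & field$mask)
}

slot_series <- function(results, fn) vapply(results, fn, 1)

cor_or_na <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    return(NA_real_)
  stats::cor(x[ok], y[ok])
}

#' Fragmentation versus mean kinetic energy
#'
#' Pearson correlation across time slots between the number of domains
#' (fragmentation) and the slot/basin mean surface KE, for the whole basin
#' and optionally per partition member (a domain is attributed to the member
#' holding the majority of its cells; member mean KE uses the member's
#' cells). Constant series yield \code{NA} with an explanatory flag.
#'
#' @param results list of \code{slot_result}s (>= 3).
#' @param partition optional named list of masks
#'   (\code{\link{basin_partition}}).
#' @return data.frame with columns \code{member}, \code{cc}, \code{n_slots},
#'   \code{flag}.
#' @export
fragmentation_vs_ke <- function(results, partition = NULL) {
  stopifnot(length(results) >= 3L)
  rows <- list()
  add <- function(member, x, y) {
    cc <- cor_or_na(x, y)
    rows[[length(rows) + 1L]] <<- data.frame(
      member = member, cc = cc, n_slots = length(x),
      flag = if (is.na(cc)) "undefined (constant or short series)" else "",
      stringsAsFactors = FALSE)
  }
  add("basin", slot_series(results, function(r) r$n_domains),
      slot_series(results, function(r) r$mean_KE))
  for (nm in names(partition)) {
    mk <- partition[[nm]]
    nd <- vapply(results, function(r) {
      sum(vapply(r$domain_set$domains, function(d) {
        inside <- mk[d$cells]
        mean(inside) > 0.5
      }, logical(1L)))
    }, 1)
    ke <- vapply(results, function(r) {
      if (is.null(r$mean_KE_map)) return(NA_real_)
      mean(r$mean_KE_map[mk], na.rm = TRUE)
    }, 1)
    add(nm, nd, ke)
  }
  do.call(rbind, rows)
}

#' Domain strength versus mean kinetic energy
#'
#' As \code{\link{fragmentation_vs_ke}}, with the slot series being the
#' spatial mean of the domain-strength map (each cell carries its domain's
#' strength) over the basin or partition member.
#'
#' @inheritParams fragmentation_vs_ke
#' @return data.frame with columns \code{member}, \code{cc}, \code{n_slots},
#'   \code{flag}.
#' @export
strength_vs_ke <- function(results, partition = NULL) {
  stopifnot(length(results) >= 3L)
  smap <- function(r) {
    m <- matrix(NA_real_, nrow(r$domain_set$label_map),
                ncol(r$domain_set$label_map))
    if (is.null(r$network)) return(m)
    st <- setNames(r$network$nodes$strength, r$network$nodes$id)
    for (d in r$domain_set$domains)
      m[d$cells] <- st[[as.character(d$id)]]
    m
  }
  maps <- lapply(results, smap)
  rows <- list()
  members <- c(list(basin = NULL), partition)
  for (nm in names(members)) {
    s <- vapply(seq_along(results), function(k) {
      m <- maps[[k]]
      if (!is.null(members[[nm]])) m[!members[[nm]]] <- NA_real_
      if (all(is.na(m))) NA_real_ else mean(m, na.rm = TRUE)
    }, 1)
    ke <- vapply(results, function(r) {
      if (is.null(members[[nm]]) || is.null(r$mean_KE_map)) r$mean_KE
      else mean(r$mean_KE_map[members[[nm]]], na.rm = TRUE)
    }, 1)
    cc <- cor_or_na(s, ke)
    rows[[length(rows) + 1L]] <- data.frame(
      member = nm, cc = cc, n_slots = length(s),
      flag = if (is.na(cc)) "undefined (constant or short series)" else "",
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

## Locate the domain containing a (lat, lon) point.
locate_domain <- function(result, lat, lon) {
  dset <- result$domain_set
  i <- which.min(abs(result$anoms$lat - lat))
  j <- which.min(abs(result$anoms$lon - lon))
  lab <- dset$label_map[i, j]
  if (is.na(lab)) stop_dm("point (%.2f, %.2f) is on land", lat, lon)
  if (lab == 0L) stop_dm("point (%.2f, %.2f) is in background", lat, lon)
  lab
}

#' Compare the connectivity of a focal domain across two runs
#'
#' Locates the domain containing \code{(lat, lon)} in each result, matches
#' domains across the two runs by spatial overlap (Jaccard >= 0.3), and
#' reports the focal domain's edges gained, lost and re-weighted.
#'
#' @param result1,result2 \code{slot_result}s on the same grid.
#' @param lat,lon coordinates of the focal point (degrees).
#' @param jaccard_min minimum Jaccard overlap to match counterpart domains
#'   (default 0.3).
#' @return data.frame with columns \code{counterpart1}, \code{counterpart2},
#'   \code{status} (\code{gained}/\code{lost}/\code{kept}), \code{w1},
#'   \code{w2}.
#' @export
compare_networks <- function(result1, result2, lat, lon, jaccard_min = 0.3) {
  if (!identical(dim(result1$domain_set$label_map),
                 dim(result2$domain_set$label_map)))
    stop_dm("results are on different grids")
  f1 <- locate_domain(result1, lat, lon)
  f2 <- locate_domain(result2, lat, lon)
  key <- function(cells, nlat) (cells[, 2L] - 1L) * nlat + cells[, 1L]
  nlat <- nrow(result1$domain_set$label_map)
  cells1 <- lapply(result1$domain_set$domains, function(d) key(d$cells, nlat))
  cells2 <- lapply(result2$domain_set$domains, function(d) key(d$cells, nlat))
  match12 <- vapply(seq_along(cells1), function(a) {
    jac <- vapply(cells2, function(b)
      length(intersect(cells1[[a]], b)) / length(union(cells1[[a]], b)), 1)
    if (!length(jac) || max(jac) < jaccard_min) NA_integer_
    else which.max(jac)
  }, 1L)
  edge_weights <- function(net, focal) {
    if (is.null(net) || !nrow(net$edges)) return(setNames(numeric(0), character(0)))
    e <- net$edges
    sel <- e$A == as.character(focal) | e$B == as.character(focal)
    e <- e[sel, , drop = FALSE]
    other <- ifelse(e$A == as.character(focal), e$B, e$A)
    setNames(e$w, other)
  }
  w1 <- edge_weights(result1$network, f1)
  w2 <- edge_weights(result2$network, f2)
  ## express run-1 partners in run-2 ids via the spatial matching
  part1_in2 <- vapply(names(w1), function(id)
    match12[as.integer(id)], 1L)
  rows <- list()
  for (k in seq_along(w1)) {
    cp2 <- part1_in2[k]
    nm2 <- if (!is.na(cp2)) as.character(cp2) else NA_character_
    if (!is.na(nm2) && nm2 %in% names(w2)) {
      rows[[length(rows) + 1L]] <- data.frame(
        counterpart1 = names(w1)[k], counterpart2 = nm2, status = "kept",
        w1 = unname(w1[k]), w2 = unname(w2[nm2]), stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        counterpart1 = names(w1)[k], counterpart2 = nm2, status = "lost",
        w1 = unname(w1[k]), w2 = NA_real_, stringsAsFactors = FALSE)
    }
  }
  matched2 <- stats::na.omit(vapply(rows, function(r) r$counterpart2, ""))
  for (nm2 in setdiff(names(w2), matched2)) {
    rows[[length(rows) + 1L]] <- data.frame(
      counterpart1 = NA_character_, counterpart2 = nm2, status = "gained",
      w1 = NA_real_, w2 = unname(w2[nm2]), stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(counterpart1 = character(0), counterpart2 = character(0),
                      status = character(0), w1 = numeric(0), w2 = numeric(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Write / read a domain set
#'
#' Label map plus per-domain metadata as JSON.
#'
#' @param dset a \code{domain_set}.
#' @param path file path.
#' @return \code{write_domains} returns \code{path} invisibly;
#'   \code{read_domains} the reconstructed \code{domain_set} (without the
#'   homogeneity map).
#' @export
write_domains <- function(dset, path) {
  lm <- dset$label_map
  lm[is.na(lm)] <- -1L
  obj <- list(dims = dim(lm), label_map = as.vector(lm),
              delta = dset$delta, K = dset$K, alpha = dset$alpha,
              domains = lapply(dset$domains, function(d)
                list(id = d$id, cells = unname(d$cells), cores = d$cores)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_domains
#' @export
read_domains <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  d <- as.integer(unlist(obj$dims))
  lm <- matrix(as.integer(unlist(obj$label_map)), d[1L], d[2L])
  lm[lm == -1L] <- NA_integer_
  doms <- lapply(obj$domains, function(x) {
    cells <- do.call(rbind, lapply(x$cells, function(r) as.integer(unlist(r))))
    colnames(cells) <- c("row", "col")
    list(id = as.integer(x$id), cells = cells,
         cores = as.integer(unlist(x$cores)))
  })
  structure(list(domains = doms, label_map = lm, delta = as.numeric(obj$delta),
                 K = as.integer(obj$K), alpha = obj$alpha,
                 homogeneity = NULL),
            class = "domain_set")
}
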