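#' Synthetic-field generator configuration
#'
#' Parameters of the seeded generator that emulates the statistical structure
#' the ecoregionalization analysis assumes: spatially contiguous regions whose
#' cells share an autocorrelated latent signal (optionally lag-coupled across
#' regions), a 12-month seasonal cycle, a linear warming trend, and velocity
#' jets aligned with region boundaries.
#'
#' @param nlat,nlon grid dimensions (>= 4).
#' @param n_years record length in years (>= 2); the time step is monthly.
#' @param n_regions number of planted regions.
#' @param ar1_coef lag-1 autocorrelation of each region's latent signal, in
#'   (0, 1). Default 0.5, a typical decorrelation scale of one to two months
#'   for mid-latitude monthly SST anomalies.
#' @param snr ratio of latent-signal standard deviation to the per-cell noise
#'   standard deviation (> 0).
#' @param seasonal_amp amplitude of the seasonal sinusoid, degrees C.
#' @param trend linear trend, degrees C per year.
#' @param land_fraction fraction of the grid occupied by a rectangular land
#'   block, in [0, 1). Default 0.
#' @param coverage_frac fraction of ocean cells covered by planted regions
#'   (>= 0.5). Default 0.9: ecoregion maps tile most of a basin, leaving a
#'   thin unassigned margin.
#' @param couplings optional list of lagged couplings between region latent
#'   signals; each element is \code{list(source=, target=, lag=, coef=)} with
#'   \code{source < target} and \code{lag} in months.
#' @param jet_speed speed amplitude of boundary jets, m/s. Default 0.3, the
#'   order of a mid-latitude boundary current.
#' @param lat0,lon0,dgrid grid origin (degrees) and spacing (degrees/cell).
#' @param seed integer seed; every generator call is deterministic given it.
#' @return a \code{synth_config} list, validated.
#' @export
synth_config <- function(nlat = 40L, nlon = 40L, n_years = 30L,
                         n_regions = 4L, ar1_coef = 0.5, snr = 5,
                         seasonal_amp = 4, trend = 0.03,
                         land_fraction = 0, coverage_frac = 0.9,
                         couplings = NULL, jet_speed = 0.3,
                         lat0 = 32, lon0 = 10, dgrid = 0.25, seed = 1L) {
  cfg <- list(nlat = as.integer(nlat), nlon = as.integer(nlon),
              n_years = as.integer(n_years), n_regions = as.integer(n_regions),
              ar1_coef = ar1_coef, snr = snr, seasonal_amp = seasonal_amp,
              trend = trend, land_fraction = land_fraction,
              coverage_frac = coverage_frac, couplings = couplings,
              jet_speed = jet_speed, lat0 = lat0, lon0 = lon0, dgrid = dgrid,
              seed = as.integer(seed))
  if (cfg$nlat < 4L || cfg$nlon < 4L) stop_dm("grid dimensions must be >= 4")
  if (cfg$n_years < 2L) stop_dm("n_years must be >= 2")
  if (!(cfg$snr > 0)) stop_dm("snr must be > 0")
  if (cfg$ar1_coef <= 0 || cfg$ar1_coef >= 1)
    stop_dm("ar1_coef must lie in (0, 1)")
  if (cfg$land_fraction < 0 || cfg$land_fraction >= 1)
    stop_dm("land_fraction must lie in [0, 1)")
  if (cfg$coverage_frac < 0.5 || cfg$coverage_frac > 1)
    stop_dm("coverage_frac must lie in [0.5, 1]")
  for (cp in cfg$couplings) {
    if (!all(c("source", "target", "lag", "coef") %in% names(cp)))
      stop_dm("each coupling needs source, target, lag, coef")
    if (cp$source >= cp$target)
      stop_dm("couplings must have source < target (acyclic ordering)")
  }
  class(cfg) <- "synth_config"
  cfg
}

synth_coords <- function(cfg) {
  list(lat = cfg$lat0 + (seq_len(cfg$nlat) - 1L) * cfg$dgrid,
       lon = cfg$lon0 + (seq_len(cfg$nlon) - 1L) * cfg$dgrid)
}

#' Generate planted ground truth
#'
#' Places \code{n_regions} disjoint 4-connected regions on the ocean grid by
#' seeded random breadth-first accretion from spread-out seed cells, until the
#' configured coverage fraction is reached, and traces velocity jets along
#' every shared boundary between adjacent regions.
#'
#' @param cfg a \code{synth_config}.
#' @return an object of class \code{ground_truth} with fields
#'   \code{label_map} (integer lat x lon matrix; 0 = background ocean,
#'   k > 0 = region k, NA = land), \code{mask}, \code{couplings},
#'   \code{jets} (list of \code{list(pair=, cells=, amp=)}; \code{cells} is a
#'   two-column (lat, lon) index matrix of the boundary band on both sides of
#'   the shared frontier), and \code{seed}.
#' @export
generate_truth <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_local_seed(cfg$seed + 101L, {
    nlat <- cfg$nlat; nlon <- cfg$nlon
    mask <- matrix(TRUE, nlat, nlon)
    if (cfg$land_fraction > 0) {
      # rectangular land block in the north-west corner
      nland <- round(cfg$land_fraction * nlat * nlon)
      w <- max(1L, round(sqrt(nland)))
      h <- max(1L, ceiling(nland / w))
      mask[seq_len(min(h, nlat)), seq_len(min(w, nlon))] <- FALSE
    }
    ocean <- which(mask, arr.ind = TRUE)
    n_ocean <- nrow(ocean)
    if (n_ocean < 4L * cfg$n_regions)
      stop_dm("grid too small to place %d disjoint regions (%d ocean cells)",
              cfg$n_regions, n_ocean)

    labels <- matrix(0L, nlat, nlon)
    labels[!mask] <- NA_integer_
    # spread-out seeds: rejection-sample for pairwise grid distance
    min_d <- max(2, 0.5 * sqrt(n_ocean / cfg$n_regions))
    seeds <- matrix(NA_integer_, 0L, 2L)
    tries <- 0L
    while (nrow(seeds) < cfg$n_regions) {
      cand <- ocean[sample.int(n_ocean, 1L), , drop = FALSE]
      ok <- nrow(seeds) == 0L ||
        all(sqrt(rowSums((seeds - matrix(cand, nrow(seeds), 2L,
                                         byrow = TRUE))^2)) >= min_d)
      tries <- tries + 1L
      if (tries > 2000L) min_d <- min_d * 0.9  # relax if crowded
      if (ok) seeds <- rbind(seeds, cand)
    }
    for (k in seq_len(cfg$n_regions))
      labels[seeds[k, 1L], seeds[k, 2L]] <- k

    # balanced random accretion: repeatedly grow the smallest region with a
    # nonempty frontier by one uniformly chosen frontier cell
    frontier <- vector("list", cfg$n_regions)
    sizes <- rep(1L, cfg$n_regions)
    enc <- function(ij) (ij[, 2L] - 1L) * nlat + ij[, 1L]
    dec <- function(id) cbind((id - 1L) %% nlat + 1L, (id - 1L) %/% nlat + 1L)
    for (k in seq_len(cfg$n_regions)) {
      nb <- neighbors4(seeds[k, 1L], seeds[k, 2L], nlat, nlon)
      ok <- mask[nb] & labels[nb] == 0L
      frontier[[k]] <- enc(nb[which(ok), , drop = FALSE])
    }
    target <- round(cfg$coverage_frac * n_ocean)
    total <- cfg$n_regions
    while (total < target) {
      open <- which(vapply(frontier, length, 1L) > 0L)
      if (!length(open)) break
      k <- open[which.min(sizes[open])]
      fr <- frontier[[k]]
      fr <- fr[labels[dec(fr)] == 0L & !is.na(labels[dec(fr)])]
      if (!length(fr)) { frontier[[k]] <- integer(0); next }
      pick <- fr[sample.int(length(fr), 1L)]
      pij <- dec(pick)
      labels[pij] <- k
      sizes[k] <- sizes[k] + 1L
      total <- total + 1L
      nb <- neighbors4(pij[1L], pij[2L], nlat, nlon)
      free <- !is.na(labels[nb]) & labels[nb] == 0L
      frontier[[k]] <- unique(c(setdiff(fr, pick),
                                enc(nb[which(free), , drop = FALSE])))
    }

    jets <- trace_jets(labels, cfg$jet_speed)
    structure(list(label_map = labels, mask = mask,
                   couplings = cfg$couplings %||% list(),
                   jets = jets, seed = cfg$seed),
              class = "ground_truth")
  })
}

## Jets: for each pair of 4-adjacent regions, the band of cells on either
## side of the shared frontier, carrying the jet speed amplitude.
trace_jets <- function(labels, jet_speed) {
  nlat <- nrow(labels); nlon <- ncol(labels)
  pairs <- list()
  for (i in seq_len(nlat)) for (j in seq_len(nlon)) {
    a <- labels[i, j]
    if (is.na(a) || a == 0L) next
    nb <- neighbors4(i, j, nlat, nlon)
    for (r in seq_len(nrow(nb))) {
      b <- labels[nb[r, 1L], nb[r, 2L]]
      if (is.na(b) || b == 0L || b == a) next
      key <- paste(min(a, b), max(a, b), sep = "-")
      pairs[[key]] <- rbind(pairs[[key]], c(i, j), nb[r, , drop = FALSE])
    }
  }
  lapply(names(pairs), function(key) {
    cells <- unique(pairs[[key]])
    colnames(cells) <- c("i", "j")
    list(pair = as.integer(strsplit(key, "-")[[1L]]),
         cells = cells, amp = jet_speed)
  })
}

## Latent region signals: unit-variance AR(1) series, lag-coupled per the
## planted couplings and re-standardized so within/cross correlations are
## controlled. An extended record absorbs burn-in and coupling lags.
latent_signals <- function(truth, cfg, n_months) {
  lags <- vapply(truth$couplings, function(cp) abs(cp$lag), 1)
  pad <- 120L + (if (length(lags)) max(lags) else 0L)
  phi <- cfg$ar1_coef
  base <- matrix(rnorm((n_months + pad) * cfg$n_regions,
                       sd = sqrt(1 - phi^2)),
                 n_months + pad, cfg$n_regions)
  for (t in 2:(n_months + pad))
    base[t, ] <- phi * base[t - 1L, ] + base[t, ]
  lat <- base
  for (cp in truth$couplings) {  # source < target: process in given order
    s <- lat[, cp$source]
    shifted <- c(rep(0, cp$lag), s)[seq_len(n_months + pad)]
    x <- lat[, cp$target] + cp$coef * shifted
    lat[, cp$target] <- x / sd(x)
  }
  lat[(pad + 1L):(pad + n_months), , drop = FALSE] /
    rep(apply(lat[(pad + 1L):(pad + n_months), , drop = FALSE], 2L, sd),
        each = n_months)
}

#' Generate a synthetic SST field
#'
#' Each planted-region cell receives its region's latent AR(1) signal plus
#' independent white noise of standard deviation \code{1/snr}, a shared
#' 12-month seasonal sinusoid, and a linear trend. Background ocean cells
#' receive independent unit-variance noise plus the same seasonal cycle and
#' trend. The region latent signals are attached as
#' \code{attr(field, "latents")} for recovery testing.
#'
#' @param truth a \code{ground_truth}.
#' @param cfg the matching \code{synth_config}.
#' @return a \code{gridded_field} of monthly SST (degC).
#' @export
generate_sst <- function(truth, cfg) {
  stopifnot(inherits(truth, "ground_truth"), inherits(cfg, "synth_config"))
  if (!identical(dim(truth$label_map), c(cfg$nlat, cfg$nlon)))
    stop_dm("truth grid does not match cfg grid")
  n_months <- 12L * cfg$n_years
  with_local_seed(cfg$seed + 202L, {
    lat_sig <- latent_signals(truth, cfg, n_months)
    seasonal <- cfg$seasonal_amp * sin(2 * pi * (seq_len(n_months) - 1L) / 12)
    tr <- (cfg$trend / 12) * (seq_len(n_months) - 1L)
    vals <- array(NA_real_, c(n_months, cfg$nlat, cfg$nlon))
    for (j in seq_len(cfg$nlon)) for (i in seq_len(cfg$nlat)) {
      k <- truth$label_map[i, j]
      if (is.na(k)) next
      core <- if (k > 0L) lat_sig[, k] + rnorm(n_months, sd = 1 / cfg$snr)
              else rnorm(n_months)
      vals[, i, j] <- core + seasonal + tr
    }
    crd <- synth_coords(cfg)
    out <- gridded_field(vals, monthly_dates(1987L, n_months),
                         crd$lat, crd$lon, truth$mask, units = "degC")
    attr(out, "latents") <- lat_sig
    out
  })
}

#' Generate synthetic velocity fields
#'
#' Background ocean cells carry a weak flow with a per-cell random base speed
#' around one tenth of the jet amplitude; jet-band cells carry the jet
#' amplitude directed along the local boundary orientation, with a
#' discretized cross-section decaying to half amplitude one cell and a
#' quarter amplitude two cells outside the core band. A small seeded
#' temporal noise is added to every ocean cell; land cells are zero.
#'
#' @param truth a \code{ground_truth}.
#' @param cfg the matching \code{synth_config}.
#' @return \code{list(u=, v=)} of \code{gridded_field}s (m/s).
#' @export
generate_velocity <- function(truth, cfg) {
  stopifnot(inherits(truth, "ground_truth"), inherits(cfg, "synth_config"))
  nlat <- cfg$nlat; nlon <- cfg$nlon
  n_months <- 12L * cfg$n_years
  with_local_seed(cfg$seed + 303L, {
    a <- cfg$jet_speed
    b <- a / 10
    speed <- matrix(0, nlat, nlon)
    ocean <- !is.na(truth$label_map)
    speed[ocean] <- b * runif(sum(ocean), 0.5, 1.5)
    theta <- matrix(runif(nlat * nlon, 0, 2 * pi), nlat, nlon)
    jetband <- matrix(FALSE, nlat, nlon)
    for (jet in truth$jets) {
      jetband[jet$cells] <- TRUE
      speed[jet$cells] <- jet$amp
    }
    # orient along the boundary: direction of the first same-band
    # 4-neighbour; fall back to zonal flow
    for (ij in which(jetband)) {
      i <- (ij - 1L) %% nlat + 1L; j <- (ij - 1L) %/% nlat + 1L
      nb <- neighbors4(i, j, nlat, nlon)
      on <- which(jetband[nb])
      theta[i, j] <- if (length(on))
        atan2(nb[on[1L], 1L] - i, nb[on[1L], 2L] - j) else 0
    }
    # discretized jet cross-section: half-amplitude flanks one cell outside
    # the core band, quarter-amplitude two cells outside
    flank1 <- dilate3x3(jetband) & !jetband & ocean
    flank2 <- dilate3x3(jetband | flank1) & !(jetband | flank1) & ocean
    speed[flank1] <- pmax(speed[flank1], a / 2)
    speed[flank2] <- pmax(speed[flank2], a / 4)
    u0 <- speed * cos(theta); v0 <- speed * sin(theta)
    uu <- array(0, c(n_months, nlat, nlon))
    vv <- array(0, c(n_months, nlat, nlon))
    noise_sd <- 0.05 * a
    for (t in seq_len(n_months)) {
      un <- matrix(rnorm(nlat * nlon, sd = noise_sd), nlat, nlon)
      vn <- matrix(rnorm(nlat * nlon, sd = noise_sd), nlat, nlon)
      uu[t, , ] <- ifelse(ocean, u0 + un, 0)
      vv[t, , ] <- ifelse(ocean, v0 + vn, 0)
    }
    crd <- synth_coords(cfg)
    tm <- monthly_dates(1987L, n_months)
    list(u = gridded_field(uu, tm, crd$lat, crd$lon, truth$mask, "m/s"),
         v = gridded_field(vv, tm, crd$lat, crd$lon, truth$mask, "m/s"))
  })
}

#' Write / read ground truth as JSON
#'
#' @param truth a \code{ground_truth}.
#' @param path file path.
#' @return \code{write_truth} returns \code{path} invisibly;
#'   \code{read_truth} the reconstructed object.
#' @export
write_truth <- function(truth, path) {
  lm <- truth$label_map
  lm[is.na(lm)] <- -1L  # land; JSON-safe
  obj <- list(
    dims = dim(truth$label_map),
    label_map = as.vector(lm),
    mask = as.vector(truth$mask),
    couplings = truth$couplings,
    jets = lapply(truth$jets, function(j)
      list(pair = j$pair, cells = unname(j$cells), amp = j$amp)),
    seed = truth$seed)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  d <- as.integer(unlist(obj$dims))
  jets <- lapply(obj$jets, function(j) {
    cells <- do.call(rbind, lapply(j$cells, function(r) as.integer(unlist(r))))
    colnames(cells) <- c("i", "j")
    list(pair = as.integer(unlist(j$pair)), cells = cells,
         amp = as.numeric(j$amp))
  })
  couplings <- lapply(obj$couplings, function(cp)
    list(source = as.integer(cp$source), target = as.integer(cp$target),
         lag = as.integer(cp$lag), coef = as.numeric(cp$coef)))
  lm <- matrix(as.integer(unlist(obj$label_map)), d[1L], d[2L])
  lm[lm == -1L] <- NA_integer_
  structure(list(label_map = lm,
                 mask = matrix(as.logical(unlist(obj$mask)), d[1L], d[2L]),
                 couplings = couplings, jets = jets,
                 seed = as.integer(obj$seed)),
            class = "ground_truth")
}
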