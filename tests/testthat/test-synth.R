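test_that("ground truth plants disjoint connected regions with boundary jets", {
  cfg <- synth_config(n_regions = 4L, nlat = 40L, nlon = 40L, seed = 7L)
  tr <- generate_truth(cfg)

  labs <- tr$label_map
  ocean <- !is.na(labs)
  expect_gte(sum(labs > 0, na.rm = TRUE) / sum(ocean), 0.5)
  expect_setequal(unique(labs[ocean & labs > 0]), 1:4)

  # 4-connectivity of each region by flood fill
  for (k in 1:4) {
    cells <- which(labs == k, arr.ind = TRUE)
    seen <- rep(FALSE, nrow(cells))
    keyset <- paste(cells[, 1], cells[, 2])
    queue <- 1L; seen[1L] <- TRUE
    while (length(queue)) {
      c0 <- cells[queue[1L], ]; queue <- queue[-1L]
      for (s in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        hit <- match(paste(c0[1] + s[1], c0[2] + s[2]), keyset)
        if (!is.na(hit) && !seen[hit]) { seen[hit] <- TRUE; queue <- c(queue, hit) }
      }
    }
    expect_true(all(seen), label = sprintf("region %d is 4-connected", k))
  }

  # every adjacent region pair contributes a jet (brute-force adjacency scan)
  adj <- c()
  for (i in 1:39) for (j in 1:40) {
    for (nb in list(labs[i + 1, j], if (j < 40) labs[i, j + 1])) {
      a <- labs[i, j]
      if (!is.null(nb) && !is.na(a) && !is.na(nb) && a > 0 && nb > 0 && a != nb)
        adj <- union(adj, paste(min(a, nb), max(a, nb)))
    }
  }
  jet_pairs <- vapply(tr$jets, function(j) paste(j$pair[1], j$pair[2]), "")
  expect_setequal(jet_pairs, adj)
  expect_true(all(vapply(tr$jets, function(j) nrow(j$cells) >= 1, TRUE)))
})

test_that("generator is deterministic and degenerate configs behave", {
  cfg <- synth_config(nlat = 12L, nlon = 12L, n_years = 3L, seed = 7L)
  t1 <- generate_truth(cfg); t2 <- generate_truth(cfg)
  expect_identical(t1, t2)
  expect_identical(generate_sst(t1, cfg)$values, generate_sst(t2, cfg)$values)
  v1 <- generate_velocity(t1, cfg); v2 <- generate_velocity(t1, cfg)
  expect_identical(v1$u$values, v2$u$values)

  one <- synth_config(nlat = 10L, nlon = 10L, n_years = 2L, n_regions = 1L,
                      land_fraction = 0, seed = 2L)
  tr1 <- generate_truth(one)
  expect_identical(sort(unique(tr1$label_map[tr1$label_map > 0])), 1L)
  expect_length(tr1$jets, 0L)

  expect_error(generate_truth(synth_config(nlat = 4L, nlon = 4L,
                                           n_regions = 12L, seed = 1L)),
               "too small")
})

test_that("cell series carry the planted signal, seasonality and trend", {
  # near-noiseless: one region's cells are almost perfectly correlated
  cfg <- synth_config(nlat = 8L, nlon = 8L, n_years = 4L, n_regions = 1L,
                      snr = 1e6, seasonal_amp = 0, trend = 0, seed = 5L)
  tr <- generate_truth(cfg)
  sst <- generate_sst(tr, cfg)
  cells <- which(tr$label_map == 1L, arr.ind = TRUE)[1:4, ]
  series <- vapply(1:4, function(r) sst$values[, cells[r, 1], cells[r, 2]],
                   numeric(48))
  expect_true(all(cor(series)[upper.tri(diag(4))] > 0.999999))

  # noiseless trend recovers the closed-form monthly slope
  cfg2 <- synth_config(nlat = 8L, nlon = 8L, n_years = 4L, n_regions = 1L,
                       snr = 1e6, seasonal_amp = 0, trend = 0.5, seed = 5L)
  sst2 <- generate_sst(generate_truth(cfg2), cfg2)
  diffs <- sst2$values[, 1, 1] - sst$values[, 1, 1]
  fit <- lm(diffs ~ seq_along(diffs))
  expect_equal(unname(coef(fit)[2]), 0.5 / 12, tolerance = 1e-8)

  # planted lagged coupling peaks at the planted lag in the latent signals
  cfg3 <- synth_config(nlat = 10L, nlon = 10L, n_years = 30L, n_regions = 2L,
                       snr = 10,
                       couplings = list(list(source = 1L, target = 2L,
                                             lag = 3L, coef = 0.8)),
                       seed = 11L)
  tr3 <- generate_truth(cfg3)
  lat3 <- attr(generate_sst(tr3, cfg3), "latents")
  r <- lagged_correlation(lat3[, 1], lat3[, 2], 6L)
  expect_identical(names(which.max(r)), "3")
})

test_that("within-region coherence decreases with noise and land is inert", {
  mean_cor <- function(snr) {
    cfg <- synth_config(nlat = 10L, nlon = 10L, n_years = 10L, n_regions = 1L,
                        snr = snr, seasonal_amp = 0, trend = 0, seed = 21L)
    tr <- generate_truth(cfg)
    sst <- generate_sst(tr, cfg)
    cells <- which(tr$label_map == 1L, arr.ind = TRUE)[1:10, ]
    series <- vapply(1:10, function(r) sst$values[, cells[r, 1], cells[r, 2]],
                     numeric(120))
    C <- cor(series)
    mean(C[upper.tri(C)])
  }
  cors <- c(mean_cor(0.5), mean_cor(2), mean_cor(10))
  expect_true(all(diff(cors) > 0))

  cfg <- synth_config(nlat = 12L, nlon = 12L, n_years = 3L,
                      land_fraction = 0.2, seed = 3L)
  tr <- generate_truth(cfg)
  sst <- generate_sst(tr, cfg)
  vel <- generate_velocity(tr, cfg)
  tt <- dim(sst$values)[1]
  land <- as.vector(!tr$mask)
  expect_true(all(is.na(matrix(sst$values, tt)[, land])))
  # land carries no flow: masked out of every downstream statistic
  uland <- matrix(vel$u$values, tt)[, land]
  expect_true(all(is.na(uland) | uland == 0))
  expect_true(all(is.na(matrix(vel$v$values, tt)[, land])))
})

test_that("jets dominate the background flow and show up in the KE tail", {
  cfg <- synth_config(nlat = 30L, nlon = 30L, n_years = 3L, n_regions = 3L,
                      seed = 9L)
  tr <- generate_truth(cfg)
  vel <- generate_velocity(tr, cfg)
  KE <- kinetic_energy(vel$u, vel$v)
  a <- cfg$jet_speed

  jet_cells <- unique(do.call(rbind, lapply(tr$jets, `[[`, "cells")))
  mean_speed <- sqrt(2 * colMeans(KE$values, dims = 1))
  expect_true(all(mean_speed[jet_cells] >= 5 * (1.5 * a / 10)))
  # KE on jet cells is a^2/2 up to the temporal-noise tolerance
  expect_equal(mean(colMeans(KE$values, dims = 1)[jet_cells]), a^2 / 2,
               tolerance = 0.05)

  fm <- front_mask(KE, ke_threshold(KE, 50))
  expect_gte(mean(fm[jet_cells]), 0.95)

  # no jets -> background speeds everywhere
  one <- synth_config(nlat = 10L, nlon = 10L, n_years = 2L, n_regions = 1L,
                      seed = 2L)
  tr1 <- generate_truth(one)
  vel1 <- generate_velocity(tr1, one)
  sp <- sqrt(vel1$u$values[1, , ]^2 + vel1$v$values[1, , ]^2)
  expect_true(all(sp < 5 * one$jet_speed / 10 + 0.2 * one$jet_speed))
})

test_that("ground truth and fields round-trip through their file formats", {
  cfg <- synth_config(nlat = 8L, nlon = 8L, n_years = 2L, n_regions = 2L,
                      land_fraction = 0.1, seed = 4L,
                      couplings = list(list(source = 1L, target = 2L,
                                            lag = 2L, coef = 0.5)))
  tr <- generate_truth(cfg)
  tf <- tempfile(fileext = ".json")
  write_truth(tr, tf)
  tr2 <- read_truth(tf)
  expect_identical(tr2$label_map, tr$label_map)
  expect_identical(tr2$mask, tr$mask)
  expect_equal(tr2$couplings, tr$couplings)
  expect_equal(length(tr2$jets), length(tr$jets))
  expect_equal(tr2$jets[[1]]$cells, tr$jets[[1]]$cells,
               ignore_attr = TRUE)

  sst <- generate_sst(tr, cfg)
  ff <- tempfile(fileext = ".json")
  write_field(sst, ff)
  sst2 <- read_field(ff)
  expect_equal(sst2$values, sst$values, tolerance = 1e-12)
  expect_identical(sst2$time, sst$time)
  expect_identical(sst2$mask, sst$mask)
})
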