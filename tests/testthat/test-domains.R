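test_that("local homogeneity matches the exhaustive pairwise oracle", {
  # 5x5 toy grid with an irregular mask, K = 4
  mask <- matrix(TRUE, 5, 5); mask[c(1, 25)] <- FALSE
  nf <- noise_field(120, 5, 5, seed = 13, mask = mask)
  H <- local_homogeneity(nf, K = 4L)
  expect_equal(H$values, oracle_homogeneity(nf, 4L), tolerance = 1e-12)

  # all cells sharing one series give homogeneity 1
  s <- rnorm(60)
  shared <- tiny_field(array(rep(s, 16), c(60, 4, 4)))
  Hs <- local_homogeneity(shared, K = 4L)
  expect_equal(unique(as.vector(Hs$values)), 1, tolerance = 1e-12)

  # independent white noise: homogeneity is near zero for T = 360
  wn <- noise_field(360, 5, 5, seed = 14)
  Hw <- local_homogeneity(wn, K = 4L)
  expect_lt(max(abs(Hw$values)), 3 / sqrt(360))
})

test_that("constant-series cells are undefined and never become cores", {
  vals <- array(rnorm(40 * 4 * 4), c(40, 4, 4))
  vals[, 2, 2] <- 1.5
  f <- tiny_field(vals)
  H <- local_homogeneity(f, K = 4L)
  expect_true(is.na(H$values[2, 2]))
  expect_false(any(attr(find_cores(H, -1), "idx")[, 1] == 2 &
                   attr(find_cores(H, -1), "idx")[, 2] == 2))
})

test_that("delta threshold follows the t-quantile inversion", {
  # numeric CDF-inversion oracle
  oracle_delta <- function(alpha, T) {
    f <- function(r) {
      tstat <- abs(r) * sqrt((T - 2) / (1 - r^2))
      2 * (1 - pt(tstat, df = T - 2)) - alpha
    }
    uniroot(f, c(1e-12, 1 - 1e-12), tol = 1e-14)$root
  }
  for (alpha in c(1e-3, 2e-5, 0.03)) {
    expect_equal(delta_from_alpha(alpha, 84), oracle_delta(alpha, 84),
                 tolerance = 1e-9)
  }
  expect_lt(delta_from_alpha(0.999, 100), 0.01)
  expect_gt(delta_from_alpha(1e-5, 84), delta_from_alpha(1e-3, 84))
})

test_that("cores are strict local maxima of homogeneity above delta", {
  # constant homogeneity: no strict maximum anywhere
  s <- rnorm(60)
  shared <- tiny_field(array(rep(s, 25), c(60, 5, 5)))
  H <- local_homogeneity(shared, K = 4L)
  expect_length(find_cores(H, 0.5), 0L)

  # a single peaked bump above delta yields exactly the peak
  H2 <- H
  bump <- matrix(0.1, 5, 5)
  bump[3, 3] <- 0.9; bump[c(2, 4), 3] <- 0.4; bump[3, c(2, 4)] <- 0.4
  H2$values <- bump
  H2$h <- bump[H2$geo$idx]
  cores <- find_cores(H2, 0.5)
  expect_identical(unname(attr(cores, "idx")[1, ]), c(3L, 3L))
  expect_length(cores, 1L)
})

test_that("planted regions are recovered as domains", {
  cfg <- synth_config(nlat = 24L, nlon = 24L, n_years = 15L, n_regions = 1L,
                      snr = 10, seed = 31L)
  tr <- generate_truth(cfg)
  anoms <- detrend(deseasonalize(generate_sst(tr, cfg)))
  dset <- identify_domains(anoms)
  expect_identical(length(dset$domains), 1L)
  expect_gte(jaccard_by_region(tr, dset), 0.9)

  # cores sit inside the planted region or hug its coast-like margin;
  # none arise in interior background noise
  H <- local_homogeneity(anoms, 4L)
  idx <- attr(find_cores(H, dset$delta), "idx")
  near_region <- deltamaps:::dilate3x3(tr$label_map == 1L)
  expect_true(all(near_region[idx]))
  expect_gte(sum(tr$label_map[idx] == 1L), 1L)

  # two independent regions give two non-overlapping domains
  cfg2 <- synth_config(nlat = 24L, nlon = 24L, n_years = 15L, n_regions = 2L,
                       snr = 10, seed = 32L)
  tr2 <- generate_truth(cfg2)
  dset2 <- identify_domains(detrend(deseasonalize(generate_sst(tr2, cfg2))))
  expect_identical(length(dset2$domains), 2L)
  lab <- dset2$label_map
  expect_true(all(table(lab[lab > 0]) > 0))
  expect_true(all(jaccard_by_region(tr2, dset2) >= 0.8))
})

test_that("domain-set invariants hold on every output", {
  cfg <- synth_config(nlat = 20L, nlon = 20L, n_years = 10L, n_regions = 3L,
                      seed = 17L)
  tr <- generate_truth(cfg)
  anoms <- detrend(deseasonalize(generate_sst(tr, cfg)))
  dset <- identify_domains(anoms)
  for (d in dset$domains) {
    # 4-connectivity
    cells <- d$cells
    seen <- rep(FALSE, nrow(cells)); seen[1] <- TRUE
    keyset <- paste(cells[, 1], cells[, 2])
    queue <- 1L
    while (length(queue)) {
      c0 <- cells[queue[1], ]; queue <- queue[-1]
      for (s in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        hit <- match(paste(c0[1] + s[1], c0[2] + s[2]), keyset)
        if (!is.na(hit) && !seen[hit]) { seen[hit] <- TRUE; queue <- c(queue, hit) }
      }
    }
    expect_true(all(seen))
    # average pairwise correlation above delta
    expect_gte(domain_avg_correlation(anoms, cells), dset$delta)
    # every domain traces back to at least one core, and all core cells
    # carry homogeneity above delta
    expect_gte(length(d$cores), 1L)
  }
  # every core cell in the map exceeds delta (cores are strict local maxima
  # above threshold by construction; cross-check through the stored map)
  H <- local_homogeneity(anoms, dset$K)
  core_idx <- attr(find_cores(H, dset$delta), "idx")
  expect_true(all(dset$homogeneity[core_idx] > dset$delta))
  # domains are pairwise disjoint: labels partition assigned cells
  sizes <- vapply(dset$domains, function(d) nrow(d$cells), 1L)
  expect_identical(sum(sizes), sum(dset$label_map > 0, na.rm = TRUE))
})

test_that("extreme thresholds and monotonicity behave", {
  cfg <- synth_config(nlat = 16L, nlon = 16L, n_years = 8L, n_regions = 2L,
                      seed = 19L)
  tr <- generate_truth(cfg)
  anoms <- detrend(deseasonalize(generate_sst(tr, cfg)))

  # delta = 1 on noisy data: domains are the bare cores
  H <- local_homogeneity(anoms, 4L)
  ds1 <- identify_domains(anoms, delta = 1 - 1e-12, H = H)
  expect_true(all(vapply(ds1$domains, function(d) nrow(d$cells), 1L) == 1L))

  # raising delta never increases the total domain area
  areas <- vapply(c(0.5, 0.7, 0.9, 0.99), function(dl)
    sum(identify_domains(anoms, delta = dl, H = H)$label_map > 0,
        na.rm = TRUE), 1)
  expect_true(all(diff(areas) <= 0))
})
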