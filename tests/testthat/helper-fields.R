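# Small field builders and shared fixtures, generated in code at test time.

# A tiny field from a values array with default coordinates.
tiny_field <- function(values, mask = NULL, lat0 = 35, lon0 = 10,
                       dgrid = 0.5, units = "degC") {
  d <- dim(values)
  gridded_field(values, monthly_dates(2000L, d[1]),
                lat0 + (seq_len(d[2]) - 1) * dgrid,
                lon0 + (seq_len(d[3]) - 1) * dgrid,
                mask = mask, units = units)
}

# Random field with iid normal cells.
noise_field <- function(n_months, nlat, nlon, seed = 1, mask = NULL) {
  set.seed(seed)
  tiny_field(array(rnorm(n_months * nlat * nlon), c(n_months, nlat, nlon)),
             mask = mask)
}

# Greedy per-region best-match Jaccard between planted regions and a
# recovered domain set.
jaccard_by_region <- function(truth, dset) {
  nlat <- nrow(truth$label_map)
  key <- function(cells) (cells[, 2] - 1) * nlat + cells[, 1]
  ks <- sort(unique(truth$label_map[!is.na(truth$label_map) &
                                    truth$label_map > 0]))
  rec <- lapply(dset$domains, function(d) key(d$cells))
  vapply(ks, function(k) {
    p <- which(truth$label_map == k)
    if (!length(rec)) return(0)
    max(vapply(rec, function(r)
      length(intersect(p, r)) / length(union(p, r)), 1))
  }, 1)
}

# Cached 20-seed recovery suite at the study conditions (4 planted regions,
# snr 5, 30 years monthly, 40 x 40 grid), shared across recovery and
# boundary-overlap tests.
.suite_cache <- new.env(parent = emptyenv())

recovery_suite <- function(n_seeds = 20L) {
  key <- paste0("suite", n_seeds)
  if (!is.null(.suite_cache[[key]])) return(.suite_cache[[key]])
  runs <- lapply(seq_len(n_seeds), function(s) {
    cfg <- synth_config(seed = s)
    tr <- generate_truth(cfg)
    anoms <- detrend(deseasonalize(generate_sst(tr, cfg)))
    dset <- identify_domains(anoms)
    list(cfg = cfg, truth = tr, dset = dset)
  })
  .suite_cache[[key]] <- runs
  runs
}

# Six-slot suite in which jet amplitude drives the number of planted
# regions: fragmentation and kinetic energy co-vary across slots.
fragmentation_suite <- function(base_seed = 100L) {
  key <- paste0("frag", base_seed)
  if (!is.null(.suite_cache[[key]])) return(.suite_cache[[key]])
  res <- lapply(1:6, function(k) {
    nreg <- k + 1L
    cfg <- synth_config(n_years = 7L, n_regions = nreg,
                        jet_speed = 0.3 * sqrt(1 + 0.05 * nreg),
                        seed = base_seed + k)
    tr <- generate_truth(cfg)
    vel <- generate_velocity(tr, cfg)
    run_slot(generate_sst(tr, cfg), vel$u, vel$v,
             time_slot(1987L, 7L), pipeline_config())
  })
  .suite_cache[[key]] <- res
  res
}
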