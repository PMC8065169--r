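# deltamaps

Connectivity-based ocean ecoregionalization from gridded
sea-surface-temperature (SST) anomaly fields.

Marine ecoregions — areas of relatively homogeneous ecosystem properties —
and the connectivity between them set the scale at which marine protected
areas, invasion pathways and larval dispersal should be assessed. Because
monthly SST anomalies at mid latitudes are dominated by advection, a
partition of an ocean basin into regions of coherent SST variability, plus
the lagged statistical links between those regions, is a low-cost proxy for
connectivity. `deltamaps` implements that analysis in the style of the
δ-MAPS family of climate-network methods, end to end:

* **Domain identification.** Each grid cell *i* carries a deseasonalized,
  detrended series *x_i(t)*. Its *local homogeneity* is the average pairwise
  Pearson correlation within the neighborhood of *i* and its *K* nearest
  ocean cells. Cells whose homogeneity is a strict local maximum above a
  threshold δ are *cores*; domains grow from cores best-first, absorbing the
  adjacent cell that keeps the domain's average pairwise correlation ≥ δ,
  and adjacent domains merge while the union stays above δ. The result is a
  set of spatially contiguous, disjoint domains (ecoregions).
* **Network inference.** Each domain *A* gets the latitude-weighted signal
  *X_A(t) = Σ_{i∈A} x_i(t) cos φ_i*. For every pair (*A*, *B*) the lagged
  correlations *r_AB(τ)*, τ ∈ [−τ_max, τ_max], are tested with a
  Bartlett-corrected statistic whose null variance
  *(1/(T−|τ|)) Σ_k ρ̂_A(k) ρ̂_B(k)* discounts the autocorrelation of both
  series. A link exists if any lag is significant; it is undirected if the
  significant-lag run contains τ = 0, directed *A*→*B* (resp. *B*→*A*) if
  strictly positive (negative). The weight is the covariance at the
  |r|-maximizing significant lag τ\*, and a domain's *strength* is the sum
  of |w| over its links.
* **Kinetic-energy fronts.** From velocity components, KE = ½(u² + v²).
  Fronts are cells whose slot-mean KE exceeds a basin-wide percentile of the
  full reference period; domain boundaries (dilated by one grid point) are
  validated by their overlap fraction with the fronts; a 4-cluster 1-D
  K-means segments the KE map and the maximum-intensity cluster's pixel
  count tracks front abundance; per-pixel front occurrences are counted
  month by month.
* **Time-slot sweep.** The whole analysis runs on sliding multi-year slots,
  yielding fragmentation (domain count) and strength series that are
  correlated with the basin's mean KE.
* **Synthetic generator.** Seeded fields with planted contiguous regions
  sharing lag-coupled AR(1) latent signals, seasonal cycle, trend, and
  velocity jets aligned with region boundaries — plus the ground truth
  needed to measure recovery.

## Worked example

```r
library(deltamaps)

cfg <- synth_config(nlat = 24L, nlon = 24L, n_years = 10L, n_regions = 3L,
                    snr = 5,
                    couplings = list(list(source = 1L, target = 2L,
                                          lag = 3L, coef = 0.7)),
                    seed = 2L)
truth <- generate_truth(cfg)
sst   <- generate_sst(truth, cfg)
vel   <- generate_velocity(truth, cfg)

anoms <- detrend(deseasonalize(sst))
dset  <- identify_domains(anoms, K = 4L, delta = 0.545)
dset
#> <domain_set> 3 domains (delta = 0.545, K = 4)
#>   sizes: 184, 186, 181

net <- infer_network(domain_signals(dset, anoms), tau_max = 12L, level = 0.03)
net$edges[, c("A", "B", "direction", "tau_star", "r", "w")]
#>   A B direction tau_star         r        w
#> 1 1 3      A->B        3 0.5780931 11029.32

KE <- kinetic_energy(vel$u, vel$v)
bm <- boundary_matrix(dset$label_map)
fm <- front_mask(KE, ke_threshold(KE, 50))
overlap_fraction(bm, fm)
#> [1] 0.719
```

The three planted regions come back as three domains of ~180 cells each.
The single planted coupling (region 1 driving region 2 at a 3-month lag
with coefficient 0.7) is recovered as one directed edge at τ\* = 3 with
r = 0.58 — domain ids are assigned by map position, so the planted region 2
is recovered domain 3 here. No spurious edge links the uncoupled pair. The
domain boundaries, where the generator plants velocity jets, overlap the
50th-percentile KE fronts at 0.72 — elevated well above the front's area
fraction, which is what validates SST-anomaly domains as current-bounded
ecoregions.

## Vignette

`vignettes/ecoregion-connectivity.Rmd` documents the model, its
assumptions, every tunable parameter with its default and rationale, what
the synthetic generator does and does not emulate, and the numerical design
choices (tie-breaks, truncations, degenerate inputs).
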