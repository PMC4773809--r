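# Shared fixtures and independent oracles used across test files.

# Small fully simulated dataset with injected PTCs + decoys, written to
# disk and reloaded, so tests exercise the real file formats.
make_small_run <- function(n_loci = 60, n_pops = 3, n_samples = 20,
                           F = 0.1, seed = 42, concordance = 1,
                           carrier_fraction = 0.25) {
  txdb <- simulate_transcripts(max(20, ceiling(n_loci / 3)), seed = seed)
  cfg <- sim_config(n_populations = n_pops,
                    samples_per_population = n_samples, n_loci = n_loci,
                    differentiation_F = F,
                    outgroup_concordance = concordance,
                    archaic_carrier_fraction = carrier_fraction,
                    seed = seed)
  ds <- simulate_populations(cfg)
  ds <- inject_ptc_variants(txdb, ds, seed = seed + 1)
  og <- simulate_outgroup_alleles(ds, concordance, seed = seed + 2)
  ar <- simulate_archaic_calls(ds, seed = seed + 3)
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  paths <- write_dataset(ds, txdb, og, ar, dir)
  list(txdb = txdb, ds = ds, og = og, ar = ar, paths = paths)
}

# Independent Weir-Cockerham oracle: two-level nested ANOVA on allele
# indicators computed directly from dosage vectors (mean squares ->
# variance components), an algebraically different route from the
# moment formulas in the package.
wc_theta_anova <- function(dos_by_pop) {
  n_i <- vapply(dos_by_pop, length, integer(1))
  r <- length(dos_by_pop)
  N <- sum(n_i)
  ybar <- sum(unlist(dos_by_pop)) / (2 * N)
  pop_means <- vapply(dos_by_pop, function(d) sum(d) / (2 * length(d)),
                      numeric(1))
  SSP <- sum(2 * n_i * (pop_means - ybar)^2)
  SSI <- sum(unlist(mapply(function(d, m) 2 * (d / 2 - m)^2,
                           dos_by_pop, pop_means, SIMPLIFY = FALSE)))
  SSG <- sum(unlist(dos_by_pop) == 1) * 0.5
  nc <- (N - sum(n_i^2) / N) / (r - 1)
  MSP <- SSP / (r - 1)
  MSI <- SSI / (N - r)
  MSG <- SSG / N
  cc <- MSG
  b <- (MSI - MSG) / 2
  a <- (MSP - MSI) / (2 * nc)
  a / (a + b + cc)
}

# Independent exact signed-rank oracle: walks subset sizes with combn()
# instead of enumerating sign matrices.
wilcoxon_exact_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  W_obs <- sum(rk[d > 0])
  W_all <- unlist(lapply(0:n, function(k) {
    if (k == 0) return(0)
    combn(n, k, FUN = function(ix) sum(rk[ix]))
  }))
  p_le <- sum(W_all <= W_obs + 1e-9) / 2^n
  p_ge <- sum(W_all >= W_obs - 1e-9) / 2^n
  min(1, 2 * min(p_le, p_ge))
}

dosage_to_counts <- function(dos_by_pop) {
  t(vapply(dos_by_pop, function(d) tabulate(d[!is.na(d)] + 1L, nbins = 3L),
           integer(3)))
}
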