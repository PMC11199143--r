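# Shared scenario scales and lazily cached fixtures.
#
# Desk scale keeps the per-bp mutation/recombination regime of the full
# default genome but on 1 Mb / 0.01 Morgan with a raised causal rate
# (theta = 4 N0 mu l = 64, ~400-500 causal SNPs per 250-diploid Reference
# sample), so trend suites run in minutes on one CPU. Tiny scale is for
# Monte-Carlo property tests of the simulator itself.

desk_config <- function(..., seed = 1) {
  demography_config(
    genome_length_bp = 1e6, genome_length_morgans = 0.01,
    causal_mutation_rate = 1.6e-9,
    n_sample_ref = 250, n_sample_bot = 250,
    seed = seed, ...
  )
}

tiny_config <- function(..., seed = 1) {
  demography_config(
    genome_length_bp = 3e5, genome_length_morgans = 0.003,
    causal_mutation_rate = 4e-9,
    n_sample_ref = 100, n_sample_bot = 100,
    seed = seed, ...
  )
}

# Expensive simulation products are computed once per test run and shared
# across test files (testthat sources helpers into the common test env).
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, expr, envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

fx_desk_dataset <- function() {
  fixture("desk_dataset", simulate_genotypes(desk_config(seed = 101)))
}

fx_tiny_dataset <- function() {
  fixture("tiny_dataset", simulate_genotypes(tiny_config(seed = 202)))
}

# Bottleneck-size sweep over the standard grid (desk scale).
fx_n_sweep <- function() {
  fixture("n_sweep", sweep_parameter(
    "N", c(8000, 4000, 2000, 1000, 500), desk_config(),
    R = 200, master_seed = 9001
  ))
}

# Split-time sweep. R = 500 because the statistic of
# interest is a variance: its relative Monte-Carlo error is sqrt(2/(R-1))
# per grid point (10% at R = 200, 6% at R = 500), and the near-linearity
# check needs the smaller one.
fx_t_sweep <- function() {
  fixture("t_sweep", sweep_parameter(
    "T", c(50, 200, 500), desk_config(),
    R = 500, master_seed = 9002
  ))
}

# Migration grid at two split times. T = 200 and 500: the
# no-migration heritability deficits there (~0.05 and ~0.10) are well above
# desk-scale Monte-Carlo noise, unlike T = 50 (~0.01).
fx_migration <- function() {
  fixture("migration", {
    grid <- expand.grid(T = c(200, 500), m = c(0, 0.01, 0.1))
    seeds <- derive_seeds(9003, nrow(grid))
    grid$mean_h2_bot <- NA_real_
    for (i in seq_len(nrow(grid))) {
      rec <- run_replicates(desk_config(T = grid$T[i], m = grid$m[i]),
                            R = 100, master_seed = seeds[i])
      grid$mean_h2_bot[i] <- summarize_replicates(rec)$mean_h2_bot
    }
    grid
  })
}

# Growth contrast: N = 1000 without growth, N = 1000
# at the printed rate g = 0.015, and the mild N = 8000 bottleneck. All
# three arms share one master seed, so replicate k uses the same ancestry
# and effect-size seeds in every arm (common random numbers) and the
# between-arm contrasts are paired.
fx_growth_trio <- function() {
  fixture("growth_trio", {
    arms <- list(
      small = desk_config(N = 1000, g = 0),
      grown = desk_config(N = 1000, g = 0.015),
      large = desk_config(N = 8000, g = 0)
    )
    lapply(arms, run_replicates, R = 500, master_seed = 9004)
  })
}

# Thresholding experiments run on a genome matched to the
# full-scale causal SNP count (theta = 160, ~1100 causal SNPs per
# Reference sample): the strict-quantile regime (n = 9 retains ~2 SNPs per
# trait) depends on the pooled SNP count, so the sweep-scale genome
# (theta = 64) would distort it.
threshold_config <- function(..., seed = 1) {
  demography_config(
    genome_length_bp = 2.5e6, genome_length_morgans = 0.025,
    causal_mutation_rate = 1.6e-9,
    n_sample_ref = 250, n_sample_bot = 250,
    seed = seed, ...
  )
}

fx_threshold_ve <- function() {
  fixture("threshold_ve", threshold_experiment(
    threshold_config(), n_values = c(1, 2, 3, 5, 7, 9), R = 200,
    mode = "variance_explained", master_seed = 9005, n_calibration = 200
  ))
}

# p-value mode companion, at reduced replication (qualitative comparison).
fx_threshold_pv <- function() {
  fixture("threshold_pv", threshold_experiment(
    threshold_config(), n_values = c(1, 3, 5), R = 100,
    mode = "p_value", master_seed = 9006, n_calibration = 100
  ))
}
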