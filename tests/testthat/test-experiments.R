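test_that("run_replicates is reproducible and carries full provenance", {
  cfg <- tiny_config()
  a <- run_replicates(cfg, R = 6, master_seed = 12)
  b <- run_replicates(cfg, R = 6, master_seed = 12)
  expect_identical(a, b)
  expect_false(anyDuplicated(a$seed_genotypes) > 0)
  expect_true(all(c("N0", "N", "T", "m", "g", "causal_mutation_rate",
                    "s", "h2_target", "master_seed") %in% names(a)))
  expect_true(all(a$status == "ok"))
  expect_equal(a$h2_ref, rep(0.5, 6), tolerance = 1e-12)
  # a different master seed gives different replicates
  expect_false(identical(a$h2_bot,
                         run_replicates(cfg, R = 6, master_seed = 13)$h2_bot))
})

test_that("empty-trait replicates are recorded as missing, not fatal", {
  cfg <- demography_config(genome_length_bp = 1000,
                           genome_length_morgans = 1e-5,
                           causal_mutation_rate = 1e-13,
                           n_sample_ref = 10, n_sample_bot = 10)
  tab <- run_replicates(cfg, R = 3, master_seed = 5)
  expect_identical(tab$status, rep("empty_trait", 3))
  expect_true(all(is.na(tab$h2_bot)))
})

test_that("sweep summaries are recomputable from the replicate records", {
  sw <- sweep_parameter("m", c(0, 0.05), tiny_config(), R = 8,
                        master_seed = 14, boot_B = 200)
  for (v in c(0, 0.05)) {
    sub <- sw$records[sw$records$value == v, ]
    smry <- sw$summary[sw$summary$value == v, ]
    re <- summarize_replicates(sub)
    expect_identical(re$mean_h2_bot, smry$mean_h2_bot)
    expect_identical(re$se_mean_h2_bot, smry$se_mean_h2_bot)
    expect_identical(re$var_h2_bot, smry$var_h2_bot)
    expect_lte(smry$var_ci_lower, smry$var_h2_bot)
    expect_gte(smry$var_ci_upper, smry$var_h2_bot)
  }
  # CSV round trip preserves the summary to write/read precision
  csv <- withr::local_tempfile(fileext = ".csv")
  write.csv(sw$records, csv, row.names = FALSE)
  back <- summarize_replicates(read.csv(csv)[read.csv(csv)$value == 0, ])
  expect_equal(back$mean_h2_bot,
               sw$summary$mean_h2_bot[sw$summary$value == 0])
})

test_that("a one-value sweep reduces to run_replicates", {
  cfg <- tiny_config()
  sw <- sweep_parameter("m", 0, cfg, R = 5, master_seed = 15, boot_B = 200)
  direct <- run_replicates(cfg, R = 5, master_seed = derive_seeds(15, 2)[1])
  expect_identical(sw$records$h2_bot, direct$h2_bot)
  expect_identical(sw$records$seed_genotypes, direct$seed_genotypes)
})

test_that("derive_seeds is deterministic, distinct and leaves the RNG alone", {
  expect_identical(derive_seeds(99, 10), derive_seeds(99, 10))
  s <- derive_seeds(99, 1000)
  expect_identical(anyDuplicated(s), 0L)
  expect_true(all(s >= 1 & s <= 2147483646))
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(derive_seeds(5, 5)); after <- runif(1)
  expect_identical(before, after)
})

test_that("threshold_experiment at n = 0 reduces to the identity line", {
  ex <- threshold_experiment(tiny_config(), n_values = 0, R = 12,
                             mode = "variance_explained", master_seed = 16,
                             n_calibration = 20)
  expect_equal(ex$records$h2_thresholded, ex$records$h2_simulated)
  expect_equal(ex$summary$r, 1)
  expect_equal(ex$summary$slope, 1)
  expect_equal(ex$summary$mean_fraction_retained, 1)
  expect_equal(ex$calibration$mean_fraction_retained, 1)
})

test_that("threshold_experiment is reproducible and tidily shaped", {
  args <- list(tiny_config(), n_values = c(1, 3), R = 6,
               mode = "variance_explained", master_seed = 17,
               n_calibration = 15)
  a <- do.call(threshold_experiment, args)
  b <- do.call(threshold_experiment, args)
  expect_identical(a$records, b$records)
  expect_identical(nrow(a$records), 12L) # R replicates x 2 exponents
  expect_true(all(c("n", "mode", "threshold_value", "n_snps_total",
                    "n_snps_retained", "h2_simulated", "h2_thresholded")
                  %in% names(a$records)))
  # stricter exponent, stricter cutoff, fewer SNPs kept
  expect_gt(a$summary$threshold_value[a$summary$n == 3],
            a$summary$threshold_value[a$summary$n == 1])
  expect_lte(a$summary$mean_fraction_retained[a$summary$n == 3],
             a$summary$mean_fraction_retained[a$summary$n == 1])
})
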