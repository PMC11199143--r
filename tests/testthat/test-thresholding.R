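test_that("variance_explained follows f(1-f) beta^2", {
  expect_equal(variance_explained(0.5, 2), 1)
  expect_equal(variance_explained(0, 100), 0)
  expect_equal(variance_explained(1, 100), 0)
  expect_equal(variance_explained(0.1, 1), 0.09)
  expect_equal(variance_explained(c(0.5, 0), c(2, 2)), c(1, 0))
  expect_error(variance_explained(-0.1, 1), "\\[0, 1\\]")
})

test_that("gwas_pvalues runs marginal regressions with stated conventions", {
  set.seed(1)
  X <- matrix(sample(0:2, 300, replace = TRUE), nrow = 100)
  X <- cbind(X, 1L) # monomorphic SNP
  y_noise <- rnorm(100)
  p <- gwas_pvalues(X, y_noise)
  expect_length(p, 4)
  expect_identical(p[4], 1)           # monomorphic convention
  expect_true(all(p >= 0 & p <= 1))

  # a SNP that determines the phenotype exactly is detected at p -> 0
  y_perfect <- 2 * X[, 1]
  expect_lt(gwas_pvalues(X[, 1, drop = FALSE], y_perfect)[1], 1e-12)

  expect_error(gwas_pvalues(X, rep(1, 100)), "constant")
  expect_error(gwas_pvalues(X[1:2, ], y_noise[1:2]), "3 individuals")
  expect_error(gwas_pvalues(X, y_noise[1:10]), "match")
})

test_that("null GWAS p-values are uniform", {
  # For a fixed genotype column and independent Gaussian phenotypes the
  # slope t-test is exact, so p-values are exactly U(0,1) across draws.
  ds <- fx_tiny_dataset()
  poly <- which(apply(ds$X_bot, 2, function(x) length(unique(x)) > 1))[1:2]
  for (j in poly) {
    p <- vapply(seq_len(400), function(k) {
      y <- simulate_phenotypes(rep(0, nrow(ds$X_bot)), Ve = 1, seed = 7000 + k)
      gwas_pvalues(ds$X_bot[, j, drop = FALSE], y)[1]
    }, numeric(1))
    expect_gt(suppressWarnings(ks.test(p, "punif")$p.value), 0.01)
  }
})

test_that("calibrate_threshold retains the top 1/2^n of the pool", {
  # normative example: 32 pooled scores, n = 5 keeps exactly the best one
  spec <- calibrate_threshold(1:32, threshold_spec("variance_explained", n = 5))
  expect_identical(spec$threshold_value, 32L)
  expect_identical(which(retained_snps(1:32, spec)), 32L)

  # p-value mode mirrors on the small side
  psp <- calibrate_threshold(seq(0.01, 0.32, by = 0.01),
                             threshold_spec("p_value", n = 5))
  expect_equal(psp$threshold_value, 0.01)
  expect_identical(sum(retained_snps(seq(0.01, 0.32, by = 0.01), psp)), 1L)

  # degenerate pool: every score equal, everything retained
  flat <- calibrate_threshold(rep(2.5, 40), threshold_spec("variance_explained", n = 3))
  expect_identical(flat$threshold_value, 2.5)
  expect_true(all(retained_snps(rep(2.5, 40), flat)))

  # n = 0 is the retain-everything threshold
  all_in <- calibrate_threshold(1:10, threshold_spec("variance_explained", n = 0))
  expect_true(all(retained_snps(1:10, all_in)))

  expect_error(calibrate_threshold(1:10, threshold_spec(n = 4)),
               "empty retention")
  expect_error(calibrate_threshold(numeric(0), threshold_spec(n = 1)),
               "non-empty")
  expect_error(retained_snps(1:5, threshold_spec(n = 1)), "not calibrated")
})

test_that("stricter thresholds retain nested SNP subsets", {
  set.seed(42)
  pool <- rexp(4096)
  scores <- rexp(300)
  prev <- rep(TRUE, 300)
  for (n in 1:6) {
    spec <- calibrate_threshold(pool, threshold_spec("variance_explained", n = n))
    keep <- retained_snps(scores, spec)
    expect_true(all(keep <= prev)) # subset of the looser threshold
    prev <- keep
  }
})

test_that("thresholded heritability collapses correctly at the extremes", {
  ds <- fx_tiny_dataset()
  arch <- trait_architecture(ds, seed = 51)
  spec <- calibrate_threshold(snp_scores(ds, arch),
                              threshold_spec("variance_explained", n = 0))
  out <- thresholded_heritability(ds, arch, spec)
  expect_equal(out$h2_thresholded, out$h2_simulated) # nothing filtered
  expect_identical(out$n_snps_retained, out$n_snps_total)

  spec$threshold_value <- max(snp_scores(ds, arch)) * 2
  none <- thresholded_heritability(ds, arch, spec)
  expect_identical(none$n_snps_retained, 0L)
  expect_identical(none$h2_thresholded, 0)
})

test_that("with decorrelated genotype columns thresholding cannot raise h2", {
  ds <- fx_tiny_dataset()
  # shuffle each bottleneck column independently to destroy linkage
  X_shuf <- ds$X_bot
  set.seed(7)
  for (j in seq_len(ncol(X_shuf))) X_shuf[, j] <- sample(X_shuf[, j])
  shuf <- genotype_dataset(ds$X_ref, X_shuf, ds$positions, ds$config)
  arch <- trait_architecture(shuf, seed = 61)
  scores <- snp_scores(shuf, arch)
  # Shuffling zeroes linkage only in expectation: residual empirical
  # cross-covariances between kept and dropped columns perturb Vg by
  # O(Vg / sqrt(n)), so the exact inequality holds up to a small slack.
  slack <- 0.01
  h2_thr <- numeric(0)
  for (n in 0:6) {
    spec <- calibrate_threshold(scores, threshold_spec("variance_explained", n = n))
    out <- thresholded_heritability(shuf, arch, spec)
    expect_lte(out$h2_thresholded, out$h2_simulated + slack)
    h2_thr <- c(h2_thr, out$h2_thresholded)
  }
  expect_true(all(diff(h2_thr) <= slack)) # non-increasing in n
})
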