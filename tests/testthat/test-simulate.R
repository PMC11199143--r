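# Monte-Carlo helpers over replicate batches of one scenario
batch_stat <- function(config, n_reps, master_seed, fun) {
  datasets <- simulate_genotype_batch(config, derive_seeds(master_seed, n_reps))
  vapply(datasets, function(ds) {
    if (inherits(ds, "driftherit_empty_trait")) NA_real_ else fun(ds)
  }, numeric(1))
}

test_that("allele_frequencies is the per-column mean count over 2", {
  expect_equal(allele_frequencies(matrix(0L, 3, 2)), c(0, 0))
  expect_equal(allele_frequencies(matrix(2L, 3, 2)), c(1, 1))
  expect_equal(allele_frequencies(cbind(c(0, 1, 1, 2))), 0.5)
  expect_error(allele_frequencies(matrix(numeric(0), 0, 0)), "non-empty")
  expect_error(allele_frequencies(matrix(c(0, 3), 1, 2)), "\\{0, 1, 2\\}")
})

test_that("simulated datasets satisfy their structural invariants", {
  ds <- fx_tiny_dataset()
  expect_true(all(ds$X_ref %in% 0:2))
  expect_true(all(ds$X_bot %in% 0:2))
  expect_identical(ds$f_ref, colSums(ds$X_ref) / (2 * nrow(ds$X_ref)))
  expect_identical(ds$f_bot, colSums(ds$X_bot) / (2 * nrow(ds$X_bot)))
  expect_true(all(ds$f_ref > 0 & ds$f_ref < 1))
  expect_true(all(ds$f_bot >= 0 & ds$f_bot <= 1))
  expect_true(all(diff(ds$positions) > 0))
  expect_identical(ds$L, ncol(ds$X_ref))
  expect_identical(dim(ds$X_ref), dim(ds$X_bot))
})

test_that("an identical configuration reproduces the dataset bit-identically", {
  cfg <- tiny_config(seed = 77)
  a <- simulate_genotypes(cfg)
  b <- simulate_genotypes(cfg)
  expect_identical(a$X_ref, b$X_ref)
  expect_identical(a$X_bot, b$X_bot)
  expect_identical(a$positions, b$positions)
  # a different seed gives a different genealogy
  c <- simulate_genotypes(tiny_config(seed = 78))
  expect_false(identical(a$positions, c$positions))
})

test_that("a scenario with no reference-segregating site signals an empty trait", {
  cfg <- demography_config(genome_length_bp = 1000,
                           genome_length_morgans = 1e-5,
                           causal_mutation_rate = 1e-13,
                           n_sample_ref = 10, n_sample_bot = 10, seed = 5)
  expect_error(simulate_genotypes(cfg), class = "driftherit_empty_trait")
  # batch interface records the condition instead of aborting
  out <- simulate_genotype_batch(cfg, c(5, 6))
  expect_s3_class(out[[1]], "driftherit_empty_trait")
})

test_that("T = 0 sample-frequency differences match binomial sampling noise", {
  # Both samples come from one panmictic population, so conditional on the
  # pooled frequency, Var(f_ref - f_bot) = f(1-f) (1/(2 n_ref) + 1/(2 n_bot)).
  # Restricted to pooled derived-allele count >= 20: the dataset is
  # ascertained on segregation in the reference sample, which distorts the
  # statistic at rare sites but is negligible for common ones.
  cfg <- tiny_config(T = 0)
  datasets <- simulate_genotype_batch(cfg, derive_seeds(4001, 200))
  num <- den <- 0
  for (ds in datasets) {
    if (inherits(ds, "driftherit_empty_trait")) next
    n1 <- 2 * nrow(ds$X_ref); n2 <- 2 * nrow(ds$X_bot)
    pooled <- (ds$f_ref * n1 + ds$f_bot * n2) / (n1 + n2)
    common <- pooled * (n1 + n2) >= 20 & (1 - pooled) * (n1 + n2) >= 20
    fbar <- pooled[common]
    num <- num + sum((ds$f_ref[common] - ds$f_bot[common])^2)
    den <- den + sum(fbar * (1 - fbar) * (1 / n1 + 1 / n2))
  }
  expect_gt(num / den, 0.9)
  expect_lt(num / den, 1.1)
})

test_that("stronger bottlenecks lose more reference SNPs", {
  lost <- function(ds) mean(ds$f_bot == 0)
  loss_500 <- mean(batch_stat(tiny_config(N = 500), 100, 4002, lost),
                   na.rm = TRUE)
  loss_1000 <- mean(batch_stat(tiny_config(N = 1000), 100, 4003, lost),
                    na.rm = TRUE)
  expect_gt(loss_500, loss_1000)
})

test_that("SNP loss in the bottleneck sample is non-decreasing in split time", {
  lost <- function(ds) mean(ds$f_bot == 0)
  loss <- vapply(c(50, 200, 500), function(T_split) {
    mean(batch_stat(tiny_config(T = T_split), 100, 4004 + T_split, lost),
         na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(loss) >= 0))
})

test_that("migration keeps bottleneck frequencies closer to the reference", {
  drift_gap <- function(ds) mean(abs(ds$f_ref - ds$f_bot))
  gap_m0 <- mean(batch_stat(tiny_config(m = 0), 100, 4005, drift_gap),
                 na.rm = TRUE)
  gap_m01 <- mean(batch_stat(tiny_config(m = 0.1), 100, 4006, drift_gap),
                  na.rm = TRUE)
  expect_lt(gap_m01, gap_m0)
})

test_that("datasets round-trip through the CSV + JSON serialisation", {
  ds <- fx_tiny_dataset()
  dir <- withr::local_tempdir()
  write_genotype_dataset(ds, dir, prefix = "rt")
  back <- read_genotype_dataset(dir, prefix = "rt")
  expect_equal(unname(back$X_ref), unname(ds$X_ref))
  expect_equal(unname(back$X_bot), unname(ds$X_bot))
  expect_equal(back$positions, ds$positions)
  expect_equal(back$f_ref, ds$f_ref)
  expect_equal(back$config$seed, ds$config$seed)
})

test_that("VCF and tree-sequence exports produce well-formed files", {
  ds <- fx_tiny_dataset()
  vcf <- withr::local_tempfile(fileext = ".vcf")
  export_vcf(ds, vcf)
  lines <- readLines(vcf)
  body <- lines[!startsWith(lines, "#")]
  expect_length(body, ds$L)
  fields <- strsplit(body[1], "\t")[[1]]
  expect_identical(length(fields), 9L + nrow(ds$X_ref) + nrow(ds$X_bot))
  pos <- as.numeric(vapply(strsplit(body, "\t"), `[`, character(1), 2))
  expect_true(all(diff(pos) > 0))

  trees <- withr::local_tempfile(fileext = ".trees")
  ds2 <- simulate_genotypes(tiny_config(seed = 301), trees_path = trees)
  expect_true(file.exists(trees) && file.size(trees) > 0)
  expect_s3_class(ds2, "genotype_dataset")
})
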