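#' Run independent (genealogy, trait) replicates
#'
#' Each replicate draws a fresh genealogy, fresh effect sizes and a fresh
#' environmental-variance calibration under the same demography. Seeds are
#' derived from `master_seed` with [derive_seeds()], so the same master seed
#' reproduces the table bit-identically. Replicates whose Reference sample
#' carries no segregating site are recorded as missing rows (`status =
#' "empty_trait"`), not fatal errors.
#'
#' @param config A [demography_config()].
#' @param R Number of replicates.
#' @param s Selection parameter for the trait architecture.
#' @param h2_target Target Reference heritability.
#' @param master_seed Integer master seed.
#' @param batch_size Replicates per coalescent backend invocation.
#' @param verbose Emit per-batch progress messages.
#' @return A data frame with one row per replicate: seeds, status, SNP
#'   count, variance components, heritabilities, and a full echo of the
#'   configuration, sufficient to regenerate any row.
#' @export
run_replicates <- function(config, R, s = -1, h2_target = 0.5,
                           master_seed = 1, batch_size = 100,
                           verbose = FALSE) {
  stopifnot(inherits(config, "demography_config"))
  check_scalar(R, "R")
  if (R < 1) stop_field("R", "must be >= 1")
  R <- as.integer(R)
  seeds <- matrix(derive_seeds(master_seed, 2L * R), ncol = 2)
  geno_seeds <- seeds[, 1]
  beta_seeds <- seeds[, 2]
  rows <- vector("list", R)
  batches <- split(seq_len(R), ceiling(seq_len(R) / batch_size))
  for (batch in batches) {
    datasets <- simulate_genotype_batch(config, geno_seeds[batch])
    if (verbose) {
      message(sprintf("replicates %d-%d of %d done", batch[1],
                      batch[length(batch)], R))
    }
    for (i in seq_along(batch)) {
      k <- batch[i]
      ds <- datasets[[i]]
      rows[[k]] <- if (inherits(ds, "driftherit_empty_trait")) {
        data.frame(replicate = k, seed_genotypes = geno_seeds[k],
                   seed_betas = beta_seeds[k], status = "empty_trait",
                   L = 0L, Vg_ref = NA_real_, Vg_bot = NA_real_,
                   h2_ref = NA_real_, h2_bot = NA_real_, Ve = NA_real_)
      } else {
        arch <- trait_architecture(ds, s = s, h2_target = h2_target,
                                   seed = beta_seeds[k])
        res <- evaluate_trait(ds, arch)
        cbind(data.frame(replicate = k, seed_genotypes = geno_seeds[k],
                         seed_betas = beta_seeds[k], status = "ok",
                         L = ds$L),
              as.data.frame(res))
      }
    }
  }
  out <- do.call(rbind, rows)
  echo <- data.frame(
    N0 = config$N0, N = config$N, T = config$T, m = config$m, g = config$g,
    genome_length_morgans = config$genome_length_morgans,
    genome_length_bp = config$genome_length_bp,
    causal_mutation_rate = config$causal_mutation_rate,
    n_sample_ref = config$n_sample_ref, n_sample_bot = config$n_sample_bot,
    s = s, h2_target = h2_target, master_seed = master_seed
  )
  cbind(out, echo[rep(1L, nrow(out)), , drop = FALSE], row.names = NULL)
}

#' Summarise a replicate table
#'
#' @param records Data frame from [run_replicates()] (possibly subset).
#' @return One-row data frame: replicate counts, mean and standard error of
#'   the mean of `h2_bot`, and its sample variance. Missing replicates are
#'   excluded and counted.
#' @export
summarize_replicates <- function(records) {
  h2 <- records$h2_bot[records$status == "ok"]
  data.frame(
    R = nrow(records),
    R_ok = length(h2),
    mean_h2_bot = mean(h2),
    se_mean_h2_bot = stats::sd(h2) / sqrt(length(h2)),
    var_h2_bot = stats::var(h2)
  )
}

#' Sweep one demographic parameter
#'
#' Runs [run_replicates()] at every value of one of `N`, `T`, `m`, `g`,
#' attaching per-value summaries and an empirical-bootstrap confidence
#' interval for the variance of the bottleneck heritability (the statistic
#' of interest when sweeping the split time).
#'
#' @param parameter One of `"N"`, `"T"`, `"m"`, `"g"`.
#' @param values Numeric vector of parameter values.
#' @param config Base [demography_config()]; the swept field is overwritten.
#' @param R Replicates per value.
#' @param master_seed Integer master seed; per-value seeds are derived.
#' @param s,h2_target Trait settings, as in [run_replicates()].
#' @param boot_B Bootstrap resamples for the variance CI.
#' @param ... Passed to [run_replicates()] (e.g. `batch_size`, `verbose`).
#' @return An object of class `sweep_result`: list with `parameter`,
#'   `records` (all replicate rows with `value` column) and `summary` (one
#'   row per value).
#' @export
sweep_parameter <- function(parameter = c("N", "T", "m", "g"), values,
                            config, R, master_seed = 1, s = -1,
                            h2_target = 0.5, boot_B = 1000, ...) {
  parameter <- match.arg(parameter)
  if (length(values) < 1) stop_field("values", "must be non-empty")
  value_seeds <- derive_seeds(master_seed, 2L * length(values))
  rec_list <- vector("list", length(values))
  sum_list <- vector("list", length(values))
  for (i in seq_along(values)) {
    cfg_args <- unclass(config)
    cfg_args[[parameter]] <- values[i]
    cfg <- do.call(demography_config, cfg_args)
    rec <- run_replicates(cfg, R, s = s, h2_target = h2_target,
                          master_seed = value_seeds[i], ...)
    rec <- cbind(parameter = parameter, value = values[i], rec)
    smry <- summarize_replicates(rec)
    ci <- bootstrap_variance_ci(rec$h2_bot[rec$status == "ok"], B = boot_B,
                                seed = value_seeds[length(values) + i])
    smry$var_ci_lower <- ci$lower
    smry$var_ci_upper <- ci$upper
    rec_list[[i]] <- rec
    sum_list[[i]] <- cbind(parameter = parameter, value = values[i], smry)
  }
  structure(
    list(parameter = parameter,
         records = do.call(rbind, rec_list),
         summary = do.call(rbind, sum_list)),
    class = "sweep_result"
  )
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Sweep over %s (%d values)\n", x$parameter,
              nrow(x$summary)))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' GWAS-detectability thresholding experiment
#'
#' Calibrates power thresholds at each quantile exponent `n` from an
#' independent calibration batch (pooled SNP scores over `n_calibration`
#' trait simulations sharing the demography), then generates `R` fresh
#' evaluation replicates and records simulated versus thresholded
#' heritability pairs, with per-`n` Pearson correlation (Fisher-z standard
#' error) and regression coefficient of the thresholded on the simulated
#' values. The calibration batch is never reused for evaluation, so the
#' threshold placement is independent of the scored traits.
#'
#' @param config A [demography_config()].
#' @param n_values Integer vector of quantile exponents.
#' @param R Evaluation replicates.
#' @param mode `"variance_explained"` or `"p_value"`.
#' @param master_seed Integer master seed.
#' @param n_calibration Calibration replicates (default 200).
#' @param s,h2_target Trait settings.
#' @param batch_size Replicates per backend invocation.
#' @param verbose Emit progress messages.
#' @return An object of class `threshold_experiment`: list with `records`
#'   (tidy data frame: one row per evaluation replicate per `n`), `summary`
#'   (per `n`: threshold value, mean retention, `r`, `se_r`, `slope`), and
#'   `calibration` (per `n`: threshold and mean per-trait fraction of SNPs
#'   retained over the calibration traits).
#' @export
threshold_experiment <- function(config, n_values, R,
                                 mode = c("variance_explained", "p_value"),
                                 master_seed = 1, n_calibration = 200,
                                 s = -1, h2_target = 0.5, batch_size = 50,
                                 verbose = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "demography_config"))
  if (length(n_values) < 1) stop_field("n_values", "must be non-empty")
  top <- derive_seeds(master_seed, 2)

  # -- calibration batch: pooled scores and per-trait score vectors --------
  cal_seeds <- matrix(derive_seeds(top[1], 3L * n_calibration), ncol = 3)
  cal_scores <- vector("list", n_calibration)
  batches <- split(seq_len(n_calibration),
                   ceiling(seq_len(n_calibration) / batch_size))
  for (batch in batches) {
    datasets <- simulate_genotype_batch(config, cal_seeds[batch, 1])
    for (i in seq_along(batch)) {
      k <- batch[i]
      ds <- datasets[[i]]
      if (inherits(ds, "driftherit_empty_trait")) next
      arch <- trait_architecture(ds, s = s, h2_target = h2_target,
                                 seed = cal_seeds[k, 2])
      cal_scores[[k]] <- snp_scores(ds, arch, mode = mode,
                                    seed = cal_seeds[k, 3])
    }
    if (verbose) message(sprintf("calibration %d/%d",
                                 batch[length(batch)], n_calibration))
  }
  cal_scores <- Filter(Negate(is.null), cal_scores)
  pool <- unlist(cal_scores, use.names = FALSE)
  specs <- lapply(n_values, function(n) {
    calibrate_threshold(pool, threshold_spec(mode, n = n,
                                             n_calibration = n_calibration))
  })
  calibration <- do.call(rbind, lapply(seq_along(n_values), function(j) {
    frac <- vapply(cal_scores,
                   function(sc) mean(retained_snps(sc, specs[[j]])),
                   numeric(1))
    data.frame(n = n_values[j], mode = mode,
               threshold_value = specs[[j]]$threshold_value,
               mean_fraction_retained = mean(frac))
  }))

  # -- evaluation batch: fresh traits scored against each threshold --------
  ev_seeds <- matrix(derive_seeds(top[2], 3L * R), ncol = 3)
  rows <- vector("list", R)
  batches <- split(seq_len(R), ceiling(seq_len(R) / batch_size))
  for (batch in batches) {
    datasets <- simulate_genotype_batch(config, ev_seeds[batch, 1])
    for (i in seq_along(batch)) {
      k <- batch[i]
      ds <- datasets[[i]]
      if (inherits(ds, "driftherit_empty_trait")) {
        rows[[k]] <- data.frame(
          replicate = k, n = n_values, mode = mode,
          threshold_value = vapply(specs, `[[`, numeric(1),
                                   "threshold_value"),
          n_snps_total = 0L, n_snps_retained = 0L,
          h2_simulated = NA_real_, h2_thresholded = NA_real_
        )
        next
      }
      arch <- trait_architecture(ds, s = s, h2_target = h2_target,
                                 seed = ev_seeds[k, 2])
      per_n <- lapply(specs, function(spec) {
        out <- thresholded_heritability(ds, arch, spec,
                                        seed = ev_seeds[k, 3])
        data.frame(replicate = k, n = spec$n, mode = mode,
                   threshold_value = out$threshold_value,
                   n_snps_total = out$n_snps_total,
                   n_snps_retained = out$n_snps_retained,
                   h2_simulated = out$h2_simulated,
                   h2_thresholded = out$h2_thresholded)
      })
      rows[[k]] <- do.call(rbind, per_n)
    }
    if (verbose) message(sprintf("evaluation %d/%d",
                                 batch[length(batch)], R))
  }
  records <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(n_values, function(n) {
    sub <- records[records$n == n & !is.na(records$h2_simulated), ]
    fit <- correlation_with_fisher_se(sub$h2_simulated, sub$h2_thresholded)
    data.frame(
      n = n, mode = mode,
      threshold_value = sub$threshold_value[1],
      mean_fraction_retained = mean(sub$n_snps_retained / sub$n_snps_total),
      r = fit$r, se_r = fit$se_r,
      slope = regression_coefficient(sub$h2_simulated, sub$h2_thresholded)
    )
  }))
  structure(
    list(records = records, summary = summary, calibration = calibration,
         config = config, master_seed = master_seed),
    class = "threshold_experiment"
  )
}

#' @export
print.threshold_experiment <- function(x, ...) {
  cat(sprintf("Thresholding experiment (%s mode, %d evaluation traits)\n",
              x$summary$mode[1], length(unique(x$records$replicate))))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
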