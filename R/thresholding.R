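#' Variance explained by a SNP
#'
#' `v_j = f_j (1 - f_j) beta_j^2`, the phenotypic variance a SNP explains
#' assuming independence from other SNPs; it proxies the power to detect the
#' SNP in a GWAS. Zero for SNPs lost (`f = 0`) or fixed (`f = 1`).
#'
#' @param f Frequency in `[0, 1]` (vectorised).
#' @param beta Effect size (vectorised, recycled against `f`).
#' @return `f * (1 - f) * beta^2`.
#' @examples
#' variance_explained(0.5, 2) # 1
#' @export
variance_explained <- function(f, beta) {
  if (!is.numeric(f) || any(!is.finite(f)) || any(f < 0 | f > 1)) {
    stop_field("f", "frequencies must lie in [0, 1]")
  }
  f * (1 - f) * beta^2
}

#' Marginal GWAS p-values
#'
#' Per-SNP two-sided p-value from simple linear regression of the phenotype
#' on the derived-allele count, one SNP at a time (no covariates, no
#' multiple-testing correction - the pooled power threshold replaces it).
#' SNPs monomorphic in the sample get `p = 1` by convention.
#'
#' @param X Genotype matrix of the population being scanned (individuals by
#'   SNPs).
#' @param y Phenotype vector, one entry per row of `X`.
#' @return Vector of p-values, one per SNP.
#' @export
gwas_pvalues <- function(X, y) {
  if (!is.matrix(X)) stop("X must be a matrix", call. = FALSE)
  n <- nrow(X)
  if (length(y) != n) stop("row counts of X and y must match", call. = FALSE)
  if (n < 3) stop("need at least 3 individuals for the slope t-test",
                  call. = FALSE)
  if (stats::sd(y) == 0) {
    stop("phenotype vector is constant; no association is testable",
         call. = FALSE)
  }
  yc <- y - mean(y)
  Xc <- sweep(X, 2, colMeans(X))
  Sxx <- colSums(Xc^2)
  Sxy <- drop(crossprod(Xc, yc))
  Syy <- sum(yc^2)
  p <- rep(1, ncol(X))
  ok <- Sxx > 0
  b <- Sxy[ok] / Sxx[ok]
  rss <- pmax(Syy - b * Sxy[ok], 0)
  df <- n - 2
  se <- sqrt(rss / df / Sxx[ok])
  tstat <- ifelse(se > 0, b / se, ifelse(b == 0, 0, Inf))
  p[ok] <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
  p
}

#' GWAS-detectability threshold specification
#'
#' Describes how SNPs are filtered to mimic limited detection power: scores
#' are either per-SNP variance explained (kept when large) or marginal GWAS
#' p-values (kept when small), and the cutoff retains the top `1/2^n`
#' fraction of a pooled score distribution built from `n_calibration`
#' independent trait simulations sharing the demography.
#'
#' `n = 0` is allowed as the degenerate "retain everything" threshold.
#'
#' @param mode `"variance_explained"` or `"p_value"`.
#' @param n Quantile exponent (non-negative integer): the top `1/2^n` of
#'   pooled scores is retained.
#' @param n_calibration Number of calibration replicates used to build the
#'   pool (default 200).
#' @return An object of class `threshold_spec`; `threshold_value` is `NA`
#'   until [calibrate_threshold()] is applied.
#' @export
threshold_spec <- function(mode = c("variance_explained", "p_value"),
                           n = 1, n_calibration = 200) {
  mode <- match.arg(mode)
  check_scalar(n, "n")
  check_scalar(n_calibration, "n_calibration")
  if (n < 0 || n != floor(n)) stop_field("n", "must be a non-negative integer")
  if (n_calibration < 2) stop_field("n_calibration", "must be >= 2")
  structure(
    list(mode = mode, n = as.integer(n),
         n_calibration = as.integer(n_calibration),
         threshold_value = NA_real_),
    class = "threshold_spec"
  )
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat(sprintf(
    "Threshold: mode %s, top 1/2^%d of pooled scores (%d calibration reps)",
    x$mode, x$n, x$n_calibration
  ))
  if (is.finite(x$threshold_value)) {
    cat(sprintf("; calibrated cutoff %.6g", x$threshold_value))
  } else {
    cat("; not calibrated")
  }
  cat("\n")
  invisible(x)
}

#' Calibrate a power threshold from pooled scores
#'
#' Sets the cutoff so that the top `1/2^n` of the pooled score distribution
#' is retained: the cutoff is the k-th most favourable pooled score with
#' `k = floor(length(pooled_scores) / 2^n)`, and retention uses a weak
#' inequality on the favourable side (`score >= cutoff` for variance
#' explained, `score <= cutoff` for p-values). With ties at the cutoff, the
#' retained set can exceed `k`; with all scores equal everything is
#' retained.
#'
#' @param pooled_scores Scores pooled with equal weight across all SNPs of
#'   all calibration replicates.
#' @param spec A [threshold_spec()].
#' @return The spec with `threshold_value` filled in.
#' @export
calibrate_threshold <- function(pooled_scores, spec) {
  stopifnot(inherits(spec, "threshold_spec"))
  if (length(pooled_scores) == 0) {
    stop("pooled_scores must be non-empty", call. = FALSE)
  }
  k <- floor(length(pooled_scores) / 2^spec$n)
  if (k < 1) {
    stop(sprintf(
      "empty retention: the top 1/2^%d of %d pooled scores contains no SNP",
      spec$n, length(pooled_scores)
    ), call. = FALSE)
  }
  spec$threshold_value <- if (spec$mode == "variance_explained") {
    sort(pooled_scores, decreasing = TRUE)[k]
  } else {
    sort(pooled_scores)[k]
  }
  spec
}

#' Which SNPs survive a calibrated threshold
#'
#' @param scores Per-SNP scores in the spec's mode.
#' @param spec A calibrated [threshold_spec()].
#' @return Logical vector: `TRUE` for retained SNPs.
#' @export
retained_snps <- function(scores, spec) {
  stopifnot(inherits(spec, "threshold_spec"))
  if (!is.finite(spec$threshold_value)) {
    stop("threshold_spec is not calibrated; run calibrate_threshold() first",
         call. = FALSE)
  }
  if (spec$mode == "variance_explained") {
    scores >= spec$threshold_value
  } else {
    scores <= spec$threshold_value
  }
}

#' Score SNPs for detectability in the bottleneck population
#'
#' Scores are computed where the GWAS would be run: variance explained uses
#' bottleneck-sample frequencies with the shared effect sizes; p-value mode
#' simulates a bottleneck phenotype (genetic values plus `N(0, Ve)` noise)
#' and runs the marginal GWAS.
#'
#' @param dataset A [genotype_dataset()].
#' @param arch The paired [trait_architecture()].
#' @param mode `"variance_explained"` or `"p_value"`.
#' @param seed Seed for the phenotype noise in p-value mode.
#' @return Numeric score vector, one per SNP.
#' @export
snp_scores <- function(dataset, arch,
                       mode = c("variance_explained", "p_value"),
                       seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "genotype_dataset"),
            inherits(arch, "trait_architecture"))
  if (length(arch$betas) != dataset$L) stop("SNP-set mismatch", call. = FALSE)
  if (mode == "variance_explained") {
    variance_explained(dataset$f_bot, arch$betas)
  } else {
    y_bot <- simulate_phenotypes(genetic_values(dataset$X_bot, arch$betas),
                                 arch$Ve, seed = seed)
    gwas_pvalues(dataset$X_bot, y_bot)
  }
}

#' Heritability before and after detectability thresholding
#'
#' Recomputes the bottleneck genetic variance using only the SNPs that
#' survive the calibrated power threshold, keeping the same effect sizes and
#' environmental variance, and returns it alongside the unthresholded
#' ("simulated") heritability. An empty retained set yields a thresholded
#' heritability of exactly 0 (reported, not an error).
#'
#' @param dataset A [genotype_dataset()].
#' @param arch The paired [trait_architecture()].
#' @param spec A calibrated [threshold_spec()].
#' @param seed Seed for phenotype noise in p-value mode scoring.
#' @return List with `h2_simulated`, `h2_thresholded`, `n_snps_total`,
#'   `n_snps_retained`, `threshold_value`.
#' @export
thresholded_heritability <- function(dataset, arch, spec, seed = NULL) {
  stopifnot(inherits(spec, "threshold_spec"))
  scores <- snp_scores(dataset, arch, mode = spec$mode, seed = seed)
  keep <- retained_snps(scores, spec)
  full <- evaluate_trait(dataset, arch)
  if (any(keep)) {
    Vg_kept <- pvar(genetic_values(dataset$X_bot[, keep, drop = FALSE],
                                   arch$betas[keep]))
    h2_thr <- heritability_from_variances(Vg_kept, arch$Ve)
  } else {
    h2_thr <- 0
  }
  list(
    h2_simulated = full$h2_bot,
    h2_thresholded = h2_thr,
    n_snps_total = dataset$L,
    n_snps_retained = sum(keep),
    threshold_value = spec$threshold_value
  )
}
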