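#' Per-SNP effect-size variance under frequency coupling
#'
#' Variance of the effect-size distribution for a SNP at derived-allele
#' frequency `f` under selection parameter `s`:
#' `sigma_beta^2 = [f (1 - f)]^s`. With `s = -1` (negative selection on the
#' trait) rare SNPs carry large effect-size variance; with `s = 0` effects
#' are frequency-independent.
#'
#' @param f Frequency (vectorised), strictly inside `(0, 1)`.
#' @param s Selection parameter.
#' @return `[f * (1 - f)]^s`.
#' @examples
#' effect_size_variance(0.5, -1) # 4
#' @export
effect_size_variance <- function(f, s) {
  check_scalar(s, "s")
  if (!is.numeric(f) || length(f) == 0) stop_field("f", "must be numeric")
  bad <- which(!is.finite(f) | f <= 0 | f >= 1)
  if (length(bad)) {
    stop_field("f", sprintf(
      "frequencies must lie strictly in (0, 1); offending SNP index %d (f = %g)",
      bad[1], f[bad[1]]
    ))
  }
  (f * (1 - f))^s
}

#' Draw frequency-coupled SNP effect sizes
#'
#' Independent draws `beta_j ~ N(0, [f_j (1 - f_j)]^s)` with frequencies
#' taken in the Reference population. Deterministic given `seed`; the
#' caller's RNG stream is untouched.
#'
#' @param f_ref Reference-sample frequencies, strictly in `(0, 1)`.
#' @param s Selection parameter (default `-1`).
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @return Numeric vector of effect sizes, one per SNP.
#' @export
draw_effect_sizes <- function(f_ref, s = -1, seed = NULL) {
  sd_beta <- sqrt(effect_size_variance(f_ref, s))
  with_seed(seed, stats::rnorm(length(f_ref), mean = 0, sd = sd_beta))
}

#' Genetic values of individuals
#'
#' The genetic component of the phenotype, `Y0_i = sum_j X_ij beta_j`.
#'
#' @param X Genotype matrix, individuals by SNPs.
#' @param betas Effect-size vector, one per SNP column.
#' @return Numeric vector of per-individual genetic values.
#' @export
genetic_values <- function(X, betas) {
  if (!is.matrix(X)) stop("X must be a matrix", call. = FALSE)
  if (ncol(X) != length(betas)) {
    stop(sprintf("dimension mismatch: %d SNP columns but %d effect sizes",
                 ncol(X), length(betas)), call. = FALSE)
  }
  drop(X %*% betas)
}

#' Calibrate environmental variance for a target heritability
#'
#' The unique `Ve` satisfying `h2 = Vg / (Vg + Ve)` given the Reference
#' genetic variance: `Ve = Vg * (1 - h2) / h2`. Calibration is done once in
#' the Reference population and the same `Ve` is reused unchanged in the
#' bottlenecked population (constant-environment assumption).
#'
#' @param Vg_ref Genetic variance in the Reference sample, `> 0`.
#' @param h2_target Target Reference heritability in `(0, 1)` (default 0.5).
#' @return Environmental variance `Ve`.
#' @examples
#' calibrate_Ve(2, 0.5) # 2
#' @export
calibrate_Ve <- function(Vg_ref, h2_target = 0.5) {
  check_scalar(Vg_ref, "Vg_ref")
  check_scalar(h2_target, "h2_target")
  if (h2_target <= 0 || h2_target >= 1) {
    stop_field("h2_target", "must lie strictly in (0, 1)")
  }
  if (Vg_ref <= 0) {
    stop("trait is uncalibratable: no genetic variance in the Reference ",
         "sample (Vg_ref = 0)", call. = FALSE)
  }
  Vg_ref * (1 - h2_target) / h2_target
}

#' Simulate phenotypes from genetic values
#'
#' `y_i = genetic_value_i + e_i` with environmental noise
#' `e_i ~ N(0, Ve)` i.i.d.
#'
#' @param genetic_values Numeric vector of genetic values.
#' @param Ve Environmental variance, `>= 0`.
#' @param seed Integer seed, or `NULL`.
#' @return Phenotype vector of the same length.
#' @export
simulate_phenotypes <- function(genetic_values, Ve, seed = NULL) {
  check_scalar(Ve, "Ve")
  if (Ve < 0) stop_field("Ve", "must be >= 0")
  n <- length(genetic_values)
  genetic_values + with_seed(seed, stats::rnorm(n, mean = 0, sd = sqrt(Ve)))
}

#' Overlay a trait architecture on a genotype dataset
#'
#' Draws one realisation of the polygenic architecture: effect sizes from
#' the frequency-coupled prior using Reference frequencies, the empirical
#' Reference genetic variance, and the environmental variance calibrated so
#' that Reference heritability equals `h2_target`. Effect sizes are drawn
#' once per trait and shared by both populations.
#'
#' @param dataset A [genotype_dataset()].
#' @param s Selection parameter (default `-1`).
#' @param h2_target Target Reference heritability (default 0.5).
#' @param seed Integer seed for the effect-size draw, or `NULL`.
#' @return An object of class `trait_architecture`: list with `betas`, `s`,
#'   `Ve`, `h2_target`, `Vg_ref` and `L`.
#' @export
trait_architecture <- function(dataset, s = -1, h2_target = 0.5, seed = NULL) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  betas <- draw_effect_sizes(dataset$f_ref, s = s, seed = seed)
  Vg_ref <- pvar(genetic_values(dataset$X_ref, betas))
  Ve <- calibrate_Ve(Vg_ref, h2_target)
  structure(
    list(betas = betas, s = s, Ve = Ve, h2_target = h2_target,
         Vg_ref = Vg_ref, L = dataset$L),
    class = "trait_architecture"
  )
}

#' @export
print.trait_architecture <- function(x, ...) {
  cat(sprintf(
    "Trait architecture: %d causal SNPs, s = %g; Vg_ref = %.4g, Ve = %.4g (h2 target %.3g)\n",
    x$L, x$s, x$Vg_ref, x$Ve, x$h2_target
  ))
  invisible(x)
}

#' Serialise a trait architecture alongside its SNPs
#'
#' Writes `<prefix>_arch.csv` (position, f_ref, beta) and
#' `<prefix>_arch.json` (s, Ve, h2_target, Vg_ref).
#'
#' @param arch A [trait_architecture()].
#' @param dataset The paired [genotype_dataset()].
#' @param dir Output directory.
#' @param prefix File name prefix.
#' @return Invisibly, the two file paths.
#' @export
write_trait_architecture <- function(arch, dataset, dir, prefix = "trait") {
  stopifnot(inherits(arch, "trait_architecture"),
            inherits(dataset, "genotype_dataset"))
  if (arch$L != dataset$L) stop("SNP-set mismatch", call. = FALSE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv <- file.path(dir, paste0(prefix, "_arch.csv"))
  js <- file.path(dir, paste0(prefix, "_arch.json"))
  utils::write.csv(
    data.frame(position = dataset$positions, f_ref = dataset$f_ref,
               beta = arch$betas),
    csv, row.names = FALSE
  )
  jsonlite::write_json(
    list(s = arch$s, Ve = arch$Ve, h2_target = arch$h2_target,
         Vg_ref = arch$Vg_ref, L = arch$L),
    js, auto_unbox = TRUE, digits = NA
  )
  invisible(c(csv, js))
}
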