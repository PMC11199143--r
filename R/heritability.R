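#' Heritability from variance components
#'
#' `h2 = Vg / (Vg + Ve)`, the proportion of phenotypic variance that is
#' genetic.
#'
#' @param Vg Genetic variance, `>= 0`.
#' @param Ve Environmental variance, `>= 0`; `Vg + Ve` must be positive.
#' @return Heritability in `[0, 1]`. Vectorised over `Vg`.
#' @examples
#' heritability_from_variances(1, 1) # 0.5
#' @export
heritability_from_variances <- function(Vg, Ve) {
  if (!is.numeric(Vg) || !is.numeric(Ve)) {
    stop("Vg and Ve must be numeric", call. = FALSE)
  }
  if (any(Vg < 0)) stop_field("Vg", "must be >= 0")
  if (any(Ve < 0)) stop_field("Ve", "must be >= 0")
  if (any(Vg + Ve <= 0)) {
    stop("Vg + Ve must be positive (no phenotypic variance at all)",
         call. = FALSE)
  }
  Vg / (Vg + Ve)
}

#' Evaluate a trait in both populations
#'
#' Computes genetic values with the shared effect sizes in the Reference and
#' Bottlenecked samples, their empirical (population-convention) variances,
#' and both heritabilities under the single Reference-calibrated `Ve`. SNPs
#' lost or fixed in the bottleneck sample contribute no variance there (a
#' fixed SNP shifts the mean only, which is irrelevant to `h2`).
#'
#' @param dataset A [genotype_dataset()].
#' @param arch A paired [trait_architecture()] (same SNP set).
#' @return An object of class `heritability_result`: list with `Vg_ref`,
#'   `Vg_bot`, `h2_ref`, `h2_bot`, `Ve`.
#' @export
evaluate_trait <- function(dataset, arch) {
  stopifnot(inherits(dataset, "genotype_dataset"),
            inherits(arch, "trait_architecture"))
  if (length(arch$betas) != dataset$L) {
    stop(sprintf("SNP-set mismatch: dataset has %d SNPs, architecture %d",
                 dataset$L, length(arch$betas)), call. = FALSE)
  }
  Vg_ref <- pvar(genetic_values(dataset$X_ref, arch$betas))
  Vg_bot <- pvar(genetic_values(dataset$X_bot, arch$betas))
  structure(
    list(
      Vg_ref = Vg_ref,
      Vg_bot = Vg_bot,
      h2_ref = heritability_from_variances(Vg_ref, arch$Ve),
      h2_bot = heritability_from_variances(Vg_bot, arch$Ve),
      Ve = arch$Ve
    ),
    class = "heritability_result"
  )
}

#' @export
print.heritability_result <- function(x, ...) {
  cat(sprintf("Heritability: reference %.4f, bottleneck %.4f (Ve = %.4g)\n",
              x$h2_ref, x$h2_bot, x$Ve))
  cat(sprintf("  Vg: reference %.4g, bottleneck %.4g\n", x$Vg_ref, x$Vg_bot))
  invisible(x)
}

#' @export
as.data.frame.heritability_result <- function(x, ...) {
  data.frame(Vg_ref = x$Vg_ref, Vg_bot = x$Vg_bot, h2_ref = x$h2_ref,
             h2_bot = x$h2_bot, Ve = x$Ve)
}
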