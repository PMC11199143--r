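#' Bootstrap confidence interval for a variance
#'
#' Resamples the input with replacement `B` times, computes the (sample)
#' variance of each resample, and forms a confidence interval for the
#' variance. The default flavour is the empirical/basic bootstrap pivot,
#' `[2 vhat - q_{1-a/2}, 2 vhat - q_{a/2}]` where `q` are quantiles of the
#' bootstrap variance distribution; the percentile interval
#' `[q_{a/2}, q_{1-a/2}]` is available as an alternative.
#'
#' @param values Numeric vector of at least two values.
#' @param B Number of bootstrap resamples (default 1000, minimum 100).
#' @param alpha Coverage complement (default 0.05 for a 95% CI).
#' @param seed Integer seed, or `NULL`.
#' @param type `"basic"` (empirical pivot) or `"percentile"`.
#' @return An object of class `bootstrap_ci`: list with `point_estimate`,
#'   `lower`, `upper`, `B`, `alpha`, `seed`, `type`. A constant input gives
#'   the degenerate interval `[0, 0]` with a warning.
#' @export
bootstrap_variance_ci <- function(values, B = 1000, alpha = 0.05, seed = NULL,
                                  type = c("basic", "percentile")) {
  type <- match.arg(type)
  if (length(values) < 2) stop("need at least two values", call. = FALSE)
  check_scalar(B, "B")
  check_scalar(alpha, "alpha")
  if (B < 100) stop_field("B", "must be >= 100")
  if (alpha <= 0 || alpha >= 1) stop_field("alpha", "must be in (0, 1)")
  v_hat <- stats::var(values)
  if (v_hat == 0) {
    warning("constant input: degenerate confidence interval [0, 0]")
    return(structure(
      list(point_estimate = 0, lower = 0, upper = 0, B = as.integer(B),
           alpha = alpha, seed = seed, type = type),
      class = "bootstrap_ci"
    ))
  }
  n <- length(values)
  boot <- with_seed(seed, {
    vapply(seq_len(B),
           function(b) stats::var(values[sample.int(n, n, replace = TRUE)]),
           numeric(1))
  })
  q <- stats::quantile(boot, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  ci <- if (type == "basic") c(2 * v_hat - q[2], 2 * v_hat - q[1]) else q
  structure(
    list(point_estimate = v_hat, lower = ci[1], upper = ci[2],
         B = as.integer(B), alpha = alpha, seed = seed, type = type),
    class = "bootstrap_ci"
  )
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat(sprintf("Variance %.6g, %g%% %s bootstrap CI [%.6g, %.6g] (B = %d)\n",
              x$point_estimate, 100 * (1 - x$alpha), x$type, x$lower,
              x$upper, x$B))
  invisible(x)
}

#' Pearson correlation with a Fisher-z standard error
#'
#' Computes the Pearson correlation `r` and its standard error through the
#' variance-stabilising Fisher transform: `z = atanh(r)`,
#' `se_z = 1 / sqrt(n - 3)`, back-transformed to the correlation scale as
#' `(tanh(z + se_z) - tanh(z - se_z)) / 2`. At the boundary `|r| = 1` the
#' back-transformed standard error is reported as 0.
#'
#' @param x,y Numeric vectors of equal length `>= 4`, both non-constant.
#' @return List with `r`, `se_r`, `se_z`, `n`.
#' @export
correlation_with_fisher_se <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 4) stop("need at least 4 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input: correlation undefined", call. = FALSE)
  }
  r <- stats::cor(x, y)
  # collinear input accumulates ~1e-16 of floating error; snap to the boundary
  if (1 - abs(r) < 1e-12) r <- sign(r)
  se_z <- 1 / sqrt(n - 3)
  se_r <- if (abs(r) >= 1) 0 else {
    z <- atanh(r)
    (tanh(z + se_z) - tanh(z - se_z)) / 2
  }
  list(r = r, se_r = se_r, se_z = se_z, n = n)
}

#' Ordinary least-squares slope
#'
#' Slope of the simple regression of `y` on `x`, equal to
#' `cor(x, y) * sd(y) / sd(x)`.
#'
#' @param x Predictor, non-constant, length `>= 3`.
#' @param y Response, same length.
#' @return The slope.
#' @export
regression_coefficient <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0) stop("constant x: slope undefined", call. = FALSE)
  stats::cov(x, y) / stats::var(x)
}
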