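# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random number stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

# Population variance (divide by n). Genetic variances follow this convention
# throughout: Var(.) is taken over the simulated sample and n is large.
pvar <- function(x) {
  mean((x - mean(x))^2)
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_scalar <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_field(field, "must be a single finite number")
  }
  invisible(x)
}

#' Derive per-replicate seeds from a master seed
#'
#' Seeds are drawn without replacement from `1:(2^31 - 2)` under the master
#' seed, so a batch of replicates is reproducible, free of collisions, and
#' safe to run in parallel. The draw is isolated from the caller's RNG state.
#'
#' @param master_seed Single integer master seed.
#' @param n Number of seeds to derive.
#' @return Integer vector of `n` distinct seeds in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(master_seed, n) {
  check_scalar(master_seed, "master_seed")
  check_scalar(n, "n")
  if (n < 1) stop_field("n", "must be >= 1")
  with_seed(master_seed, sample.int(2147483646L, as.integer(n)))
}
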