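#' Demographic scenario configuration
#'
#' Bundles every demographic and genomic parameter of one simulation
#' scenario: an ancestral population of diploid size `N0` splits `T`
#' generations ago into a Reference population of constant size `N0` and a
#' Bottlenecked population founded at size `N`, which may grow exponentially
#' at per-generation rate `g` and receive a fraction `m` of migrants per
#' generation from the Reference population.
#'
#' The genome is a single chromosome of `genome_length_morgans` genetic map
#' length realised on `genome_length_bp` base pairs with a uniform
#' recombination rate. Causal mutations arise under the infinite-sites model
#' at rate `causal_mutation_rate` per base pair per generation; this is
#' already scaled so that every simulated SNP is causal (a polygenicity
#' fraction folded into the rate, not modelled separately).
#'
#' @param N0 Diploid size of the Reference (and ancestral) population.
#' @param N Diploid founding size of the Bottlenecked population at the
#'   split.
#' @param T Split time in generations before present.
#' @param m Per-generation migration fraction from the Reference into the
#'   Bottlenecked population (forward time), in `[0, 1]`.
#' @param g Per-generation exponential growth rate of the Bottlenecked
#'   population after founding, so its present-day size is `N * exp(g * T)`.
#' @param genome_length_morgans Genetic map length in Morgans.
#' @param genome_length_bp Physical genome length in base pairs.
#' @param causal_mutation_rate Causal mutation rate per bp per generation.
#' @param n_sample_ref,n_sample_bot Diploid sample sizes drawn from each
#'   population at the present day; silently capped at the respective
#'   present-day population size.
#' @param seed Integer random seed in `[1, 2^31 - 2]`; identical
#'   configurations (including seed) give bit-identical datasets.
#' @return An object of class `demography_config`.
#' @seealso [build_demography()], [simulate_genotypes()]
#' @examples
#' cfg <- demography_config(N = 1000, T = 200, seed = 7)
#' cfg
#' @export
demography_config <- function(N0 = 10000,
                              N = 1000,
                              T = 200,
                              m = 0,
                              g = 0,
                              genome_length_morgans = 0.1,
                              genome_length_bp = 1e7,
                              causal_mutation_rate = 4e-10,
                              n_sample_ref = 500,
                              n_sample_bot = 500,
                              seed = 1) {
  for (f in c("N0", "N", "T", "m", "g", "genome_length_morgans",
              "genome_length_bp", "causal_mutation_rate",
              "n_sample_ref", "n_sample_bot", "seed")) {
    check_scalar(get(f), f)
  }
  if (N0 < 1) stop_field("N0", "population size must be >= 1")
  if (N < 1) stop_field("N", "population size must be >= 1")
  if (T < 0) stop_field("T", "split time must be >= 0")
  if (m < 0 || m > 1) stop_field("m", "migration fraction must be in [0, 1]")
  if (g < 0) stop_field("g", "growth rate must be >= 0")
  if (genome_length_morgans <= 0) {
    stop_field("genome_length_morgans", "must be > 0")
  }
  if (genome_length_bp <= 0) stop_field("genome_length_bp", "must be > 0")
  if (causal_mutation_rate <= 0) {
    stop_field("causal_mutation_rate", "must be > 0")
  }
  if (n_sample_ref < 1) stop_field("n_sample_ref", "must be >= 1")
  if (n_sample_bot < 1) stop_field("n_sample_bot", "must be >= 1")
  if (seed < 1 || seed > 2147483646) {
    stop_field("seed", "must be an integer in [1, 2^31 - 2]")
  }
  n_sample_ref <- min(n_sample_ref, floor(N0))
  n_sample_bot <- min(n_sample_bot, floor(N * exp(g * T)))
  structure(
    list(
      N0 = N0, N = N, T = T, m = m, g = g,
      genome_length_morgans = genome_length_morgans,
      genome_length_bp = genome_length_bp,
      causal_mutation_rate = causal_mutation_rate,
      n_sample_ref = as.integer(n_sample_ref),
      n_sample_bot = as.integer(n_sample_bot),
      seed = as.integer(seed)
    ),
    class = "demography_config"
  )
}

#' @export
print.demography_config <- function(x, ...) {
  cat("Demography configuration\n")
  cat(sprintf("  Reference:    N0 = %g diploids (constant)\n", x$N0))
  cat(sprintf(
    "  Bottleneck:   N = %g founded %g generations ago; g = %g (present size %.4g)\n",
    x$N, x$T, x$g, bottleneck_present_size(x)
  ))
  cat(sprintf("  Migration:    m = %g (Reference -> Bottleneck, forward time)\n",
              x$m))
  cat(sprintf("  Genome:       %g Morgans on %g bp; causal mu = %g /bp/gen\n",
              x$genome_length_morgans, x$genome_length_bp,
              x$causal_mutation_rate))
  cat(sprintf("  Samples:      %d + %d diploids; seed %d\n",
              x$n_sample_ref, x$n_sample_bot, x$seed))
  invisible(x)
}

#' Exponential growth fold change
#'
#' Fold change `exp(g * T)` of a population growing at per-generation rate
#' `g` over `T` generations. With `g = 0.015` and `T = 200` a founding
#' population grows by a factor of nearly 20.
#'
#' @param g Per-generation growth rate, `>= 0`.
#' @param T Number of generations, `>= 0`.
#' @return The dimensionless fold change `exp(g * T)`.
#' @examples
#' growth_factor(0.015, 200) # ~20
#' @export
growth_factor <- function(g, T) {
  check_scalar(g, "g")
  check_scalar(T, "T")
  if (g < 0) stop_field("g", "must be >= 0")
  if (T < 0) stop_field("T", "must be >= 0")
  exp(g * T)
}

#' Present-day size of the bottlenecked population
#'
#' @param config A [demography_config()].
#' @return `N * exp(g * T)` diploids.
#' @export
bottleneck_present_size <- function(config) {
  stopifnot(inherits(config, "demography_config"))
  config$N * growth_factor(config$g, config$T)
}

#' Build the two-population split demography
#'
#' Turns a [demography_config()] into an explicit demographic model
#' description: population sizes and growth rates by epoch, the split event,
#' and the migration regime. This description is what the coalescent backend
#' instantiates; it is also convenient for inspection and testing.
#'
#' With `T = 0` the model degenerates to a single panmictic population of
#' size `N0` from which both samples are drawn.
#'
#' @param config A [demography_config()].
#' @return An object of class `demography_model`: a list with elements
#'   `populations` (data frame of name, present-day size, growth rate),
#'   `split_time`, `migration` (forward-time Reference to Bottleneck
#'   fraction), and `recomb_rate_per_bp`.
#' @export
build_demography <- function(config) {
  stopifnot(inherits(config, "demography_config"))
  if (config$T > 0) {
    populations <- data.frame(
      name = c("REF", "BOT", "ANC"),
      initial_size = c(config$N0, bottleneck_present_size(config), config$N0),
      growth_rate = c(0, config$g, 0),
      stringsAsFactors = FALSE
    )
  } else {
    populations <- data.frame(
      name = "ANC", initial_size = config$N0, growth_rate = 0,
      stringsAsFactors = FALSE
    )
  }
  structure(
    list(
      populations = populations,
      split_time = config$T,
      migration = list(
        forward_rate = config$m,
        forward_direction = "REF -> BOT",
        backward_lineage_movement = "BOT -> REF"
      ),
      recomb_rate_per_bp = config$genome_length_morgans / config$genome_length_bp,
      config = config
    ),
    class = "demography_model"
  )
}

#' @export
print.demography_model <- function(x, ...) {
  cat("Two-population split demography\n")
  print(x$populations, row.names = FALSE)
  cat(sprintf("  split %g generations ago; forward migration %s at m = %g\n",
              x$split_time, x$migration$forward_direction,
              x$migration$forward_rate))
  cat(sprintf("  uniform recombination %g per bp per generation\n",
              x$recomb_rate_per_bp))
  invisible(x)
}
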