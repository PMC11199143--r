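#' Sampled genotype dataset for one scenario
#'
#' Container for the diploid genotype matrices sampled from the Reference
#' and Bottlenecked populations, restricted to the `L` sites segregating in
#' the Reference sample (sites private to the bottleneck carry no trait
#' effect and are dropped). Entries are derived-allele counts in
#' `{0, 1, 2}`.
#'
#' @param X_ref,X_bot Integer matrices, individuals by SNPs, same columns.
#' @param positions Numeric vector of strictly increasing site coordinates
#'   (0-based, continuous, as placed by infinite-sites mutation).
#' @param config The [demography_config()] that produced the data.
#' @return An object of class `genotype_dataset` with elements `X_ref`,
#'   `X_bot`, `f_ref`, `f_bot`, `positions`, `L`, `config`. Frequencies are
#'   per-column derived-allele frequencies of each sample; `f_ref` is
#'   strictly inside `(0, 1)` by construction, `f_bot` may touch 0 (lost) or
#'   1 (fixed).
#' @export
genotype_dataset <- function(X_ref, X_bot, positions, config = NULL) {
  if (!is.matrix(X_ref) || !is.matrix(X_bot)) {
    stop("X_ref and X_bot must be matrices", call. = FALSE)
  }
  if (ncol(X_ref) != ncol(X_bot)) {
    stop("X_ref and X_bot must have the same SNP columns", call. = FALSE)
  }
  if (length(positions) != ncol(X_ref)) {
    stop("positions length must equal the SNP count", call. = FALSE)
  }
  if (length(positions) > 1 && any(diff(positions) <= 0)) {
    stop("positions must be strictly increasing", call. = FALSE)
  }
  bad <- function(X) length(X) && !all(X %in% 0:2)
  if (bad(X_ref) || bad(X_bot)) {
    stop("genotype entries must be derived-allele counts in {0, 1, 2}",
         call. = FALSE)
  }
  f_ref <- allele_frequencies(X_ref)
  f_bot <- allele_frequencies(X_bot)
  if (length(f_ref) && any(f_ref <= 0 | f_ref >= 1)) {
    stop("every SNP must segregate in the Reference sample", call. = FALSE)
  }
  structure(
    list(X_ref = X_ref, X_bot = X_bot, f_ref = f_ref, f_bot = f_bot,
         positions = as.numeric(positions), L = ncol(X_ref), config = config),
    class = "genotype_dataset"
  )
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf(
    "Genotype dataset: %d causal SNPs; %d reference + %d bottleneck diploids\n",
    x$L, nrow(x$X_ref), nrow(x$X_bot)
  ))
  lost <- mean(x$f_bot == 0)
  fixed <- mean(x$f_bot == 1)
  cat(sprintf("  bottleneck sample: %.1f%% of SNPs lost, %.1f%% fixed\n",
              100 * lost, 100 * fixed))
  invisible(x)
}

#' Derived-allele frequencies of a genotype matrix
#'
#' @param X Matrix of diploid derived-allele counts in `{0, 1, 2}`,
#'   individuals in rows, SNPs in columns.
#' @return Per-SNP frequency: column sum divided by twice the row count.
#' @examples
#' allele_frequencies(rbind(c(0, 2), c(1, 2))) # 0.25, 1
#' @export
allele_frequencies <- function(X) {
  if (!is.matrix(X) || nrow(X) == 0L) {
    stop("X must be a non-empty genotype matrix", call. = FALSE)
  }
  if (length(X) && !all(X %in% 0:2)) {
    stop("genotype entries must be in {0, 1, 2}", call. = FALSE)
  }
  colMeans(X) / 2
}

empty_trait_error <- function(config) {
  structure(
    class = c("driftherit_empty_trait", "error", "condition"),
    list(
      message = paste0(
        "no sites segregate in the Reference sample (seed ", config$seed,
        "); the scenario yields an empty trait - increase ",
        "causal_mutation_rate or genome_length_bp"
      ),
      call = NULL
    )
  )
}

# Locate the python interpreter carrying msprime. Overridable through the
# DRIFTHERIT_PYTHON environment variable.
python_binary <- function() {
  override <- Sys.getenv("DRIFTHERIT_PYTHON", "")
  if (nzchar(override)) return(override)
  path <- Sys.which("python")
  if (!nzchar(path)) path <- Sys.which("python3")
  if (!nzchar(path)) {
    stop("no `python` interpreter found on the PATH; the coalescent backend ",
         "requires python with msprime and numpy", call. = FALSE)
  }
  path
}

backend_script <- function() {
  path <- system.file("python", "msprime_backend.py", package = "driftherit")
  if (!nzchar(path)) {
    # devtools::load_all() keeps inst/ unflattened
    path <- system.file("inst", "python", "msprime_backend.py",
                        package = "driftherit")
  }
  if (!nzchar(path)) stop("msprime backend script not found", call. = FALSE)
  path
}

backend_replicate_spec <- function(config, id, trees_path = NULL) {
  list(
    id = id,
    seed = config$seed,
    N0 = config$N0, N = config$N, T = config$T,
    m = config$m, g = config$g,
    genome_length_bp = config$genome_length_bp,
    recomb_rate_per_bp = config$genome_length_morgans / config$genome_length_bp,
    mu = config$causal_mutation_rate,
    n_ref = config$n_sample_ref, n_bot = config$n_sample_bot,
    trees_path = trees_path
  )
}

read_backend_replicate <- function(out_dir, id, config) {
  meta <- scan(file.path(out_dir, paste0("rep", id, ".meta")),
               what = integer(), quiet = TRUE)
  n_sites <- meta[1]; n_ref <- meta[2]; n_bot <- meta[3]
  if (n_sites == 0L) stop(empty_trait_error(config))
  positions <- scan(file.path(out_dir, paste0("rep", id, ".pos")),
                    what = double(), quiet = TRUE)
  raw <- readBin(file.path(out_dir, paste0("rep", id, ".geno")),
                 what = "integer", n = (n_ref + n_bot) * n_sites,
                 size = 1L, signed = FALSE)
  M <- matrix(raw, nrow = n_ref + n_bot, ncol = n_sites, byrow = TRUE)
  X_ref <- M[seq_len(n_ref), , drop = FALSE]
  X_bot <- M[n_ref + seq_len(n_bot), , drop = FALSE]
  # Keep only sites segregating in the Reference sample: the trait model is
  # undefined at f in {0, 1} and effects are defined in the Reference
  # population, then transferred.
  f_ref <- colMeans(X_ref) / 2
  keep <- f_ref > 0 & f_ref < 1
  if (!any(keep)) stop(empty_trait_error(config))
  genotype_dataset(
    X_ref = X_ref[, keep, drop = FALSE],
    X_bot = X_bot[, keep, drop = FALSE],
    positions = positions[keep],
    config = config
  )
}

#' Simulate genotype datasets for a batch of seeds
#'
#' Runs the coalescent backend once for a whole batch of replicates sharing
#' a demography but carrying distinct seeds, which amortises interpreter
#' start-up when generating hundreds of replicates.
#'
#' @param config A [demography_config()]; its own `seed` is ignored in
#'   favour of `seeds`.
#' @param seeds Integer vector of distinct seeds, one per replicate (see
#'   [derive_seeds()]).
#' @return A list of [genotype_dataset()] objects, one per seed. Replicates
#'   with no Reference-segregating site are returned as the error condition
#'   object (class `driftherit_empty_trait`) in that slot rather than
#'   aborting the batch.
#' @export
simulate_genotype_batch <- function(config, seeds) {
  stopifnot(inherits(config, "demography_config"))
  if (length(seeds) < 1) stop("seeds must be non-empty", call. = FALSE)
  if (anyDuplicated(seeds)) stop("seeds must be distinct", call. = FALSE)
  out_dir <- tempfile("driftherit_batch")
  dir.create(out_dir)
  on.exit(unlink(out_dir, recursive = TRUE), add = TRUE)
  configs <- lapply(seeds, function(s) {
    cfg <- config
    cfg$seed <- as.integer(s)
    cfg
  })
  reps <- lapply(seq_along(configs), function(k) {
    backend_replicate_spec(configs[[k]], id = k)
  })
  batch_file <- file.path(out_dir, "batch.json")
  jsonlite::write_json(
    list(out_dir = out_dir, replicates = reps),
    batch_file, auto_unbox = TRUE, digits = NA, null = "null"
  )
  status <- system2(python_binary(), c(backend_script(), batch_file),
                    stdout = TRUE, stderr = TRUE)
  code <- attr(status, "status")
  if (!is.null(code) && code != 0) {
    stop("coalescent backend failed:\n", paste(status, collapse = "\n"),
         call. = FALSE)
  }
  lapply(seq_along(configs), function(k) {
    tryCatch(
      read_backend_replicate(out_dir, k, configs[[k]]),
      driftherit_empty_trait = function(e) e
    )
  })
}

#' Simulate one genotype dataset
#'
#' Generates genealogies for the split demography of `config` with the
#' msprime coalescent simulator, superimposes infinite-sites mutations, and
#' returns the sampled diploid genotype matrices of both populations
#' restricted to sites segregating in the Reference sample. Identical
#' `config` (including `seed`) yields a bit-identical dataset.
#'
#' @param config A [demography_config()].
#' @param trees_path Optional path; when given, the underlying tree sequence
#'   is also dumped in the standard `.trees` format.
#' @return A [genotype_dataset()].
#' @examples
#' \dontrun{
#' ds <- simulate_genotypes(demography_config(seed = 42))
#' ds
#' }
#' @export
simulate_genotypes <- function(config, trees_path = NULL) {
  stopifnot(inherits(config, "demography_config"))
  if (is.null(trees_path)) {
    out <- simulate_genotype_batch(config, config$seed)[[1]]
    if (inherits(out, "driftherit_empty_trait")) stop(out)
    return(out)
  }
  out_dir <- tempfile("driftherit_sim")
  dir.create(out_dir)
  on.exit(unlink(out_dir, recursive = TRUE), add = TRUE)
  spec <- backend_replicate_spec(config, id = 1L, trees_path = trees_path)
  batch_file <- file.path(out_dir, "batch.json")
  jsonlite::write_json(
    list(out_dir = out_dir, replicates = list(spec)),
    batch_file, auto_unbox = TRUE, digits = NA, null = "null"
  )
  status <- system2(python_binary(), c(backend_script(), batch_file),
                    stdout = TRUE, stderr = TRUE)
  code <- attr(status, "status")
  if (!is.null(code) && code != 0) {
    stop("coalescent backend failed:\n", paste(status, collapse = "\n"),
         call. = FALSE)
  }
  read_backend_replicate(out_dir, 1L, config)
}

#' Serialise a genotype dataset to CSV matrices plus a JSON sidecar
#'
#' Writes `<prefix>_ref.csv` and `<prefix>_bot.csv` (individuals by SNPs,
#' columns named by position) and `<prefix>_meta.json` holding the
#' configuration, positions and sample frequencies.
#'
#' @param dataset A [genotype_dataset()].
#' @param dir Output directory (created if missing).
#' @param prefix File name prefix.
#' @return Invisibly, the three file paths.
#' @export
write_genotype_dataset <- function(dataset, dir, prefix = "dataset") {
  stopifnot(inherits(dataset, "genotype_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  snp_names <- sprintf("snp_%g", dataset$positions)
  paths <- file.path(dir, paste0(prefix, c("_ref.csv", "_bot.csv",
                                           "_meta.json")))
  for (i in 1:2) {
    X <- if (i == 1) dataset$X_ref else dataset$X_bot
    colnames(X) <- snp_names
    utils::write.csv(X, paths[i], row.names = FALSE)
  }
  jsonlite::write_json(
    list(config = unclass(dataset$config), positions = dataset$positions,
         f_ref = dataset$f_ref, f_bot = dataset$f_bot, L = dataset$L),
    paths[3], auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}

#' Read a genotype dataset written by [write_genotype_dataset()]
#'
#' @inheritParams write_genotype_dataset
#' @return A [genotype_dataset()].
#' @export
read_genotype_dataset <- function(dir, prefix = "dataset") {
  meta <- jsonlite::read_json(
    file.path(dir, paste0(prefix, "_meta.json")), simplifyVector = TRUE
  )
  config <- if (!is.null(meta$config)) {
    do.call(demography_config, meta$config[names(meta$config) %in%
                                             names(formals(demography_config))])
  }
  read_mat <- function(tag) {
    M <- as.matrix(utils::read.csv(file.path(dir, paste0(prefix, tag)),
                                   check.names = FALSE))
    dimnames(M) <- NULL
    M
  }
  genotype_dataset(read_mat("_ref.csv"), read_mat("_bot.csv"),
                   positions = meta$positions, config = config)
}

#' Export a genotype dataset as VCF
#'
#' Minimal diploid VCFv4.2 export with the derived allele as ALT and
#' unphased GT fields; Reference-sample individuals come first. Continuous
#' infinite-sites coordinates are converted to 1-based integer positions
#' (ties after flooring are shifted up by one to keep positions unique and
#' increasing).
#'
#' @param dataset A [genotype_dataset()].
#' @param path Output file path (plain text `.vcf`).
#' @return Invisibly, `path`.
#' @export
export_vcf <- function(dataset, path) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  pos <- floor(dataset$positions) + 1
  if (length(pos) > 1) {
    for (j in 2:length(pos)) if (pos[j] <= pos[j - 1]) pos[j] <- pos[j - 1] + 1
  }
  gt <- function(x) c("0/0", "0/1", "1/1")[x + 1L]
  ids <- c(sprintf("ref_%d", seq_len(nrow(dataset$X_ref))),
           sprintf("bot_%d", seq_len(nrow(dataset$X_bot))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=driftherit",
    sprintf("##contig=<ID=1,length=%d>",
            as.integer(max(dataset$config$genome_length_bp, max(pos)))),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")
  ), con)
  M <- rbind(dataset$X_ref, dataset$X_bot)
  for (j in seq_len(dataset$L)) {
    writeLines(paste(c("1", format(pos[j], scientific = FALSE),
                       sprintf("snp%d", j), "A", "T", ".", "PASS", ".",
                       "GT", gt(M[, j])), collapse = "\t"), con)
  }
  invisible(path)
}
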