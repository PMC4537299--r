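#' All 64 DNA codons
#'
#' Codon names in the fixed order used throughout the package (the order of
#' the standard genetic code table).
#'
#' @return character vector of 64 codons.
#' @export
allCodons <- function() names(Biostrings::GENETIC_CODE)

#' Standard genetic code as codon -> amino acid
#'
#' @return named character vector; stop codons map to `"*"`.
#' @export
geneticCode <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

stopCodons <- function() names(geneticCode())[geneticCode() == "*"]

#' Run configuration
#'
#' Bundles the thresholds and simulation budgets used across the package.
#' Defaults follow the reliability thresholds and Monte Carlo schedule used
#' for the yeast analysis the method was developed on.
#'
#' @param min_reads minimum summed (over replicates) reads per assay for a
#'   segment to be considered reliable (default 128).
#' @param min_segment_codons minimum segment length in codons (default 20).
#' @param n_length_groups number of equal-content length groups for the error
#'   model (default 10).
#' @param footprint_L ribosome footprint size in codons (default 10).
#' @param burn_in_terminations terminations before statistics start (default 1000).
#' @param max_burn_events cap on burn-in events for near-zero-flux genes
#'   (default 1e8).
#' @param max_steps cap on post-burn-in state-changing events (default 1e7).
#' @param first_check_step step of the first convergence check (default 5e5).
#' @param check_interval steps between convergence checks (default 1e6).
#' @param epsilon convergence threshold on the absolute change of segment-mean
#'   occupancies between checks (default 1e-3).
#' @param sigma_floor lower bound on estimated group sigma (default 1e-3).
#' @param proposed_scale_lnC proposed scaling factor on the natural-log axis
#'   (ln C-tilde), used to turn root-segment density ratios into occupancy
#'   targets for initiation-rate approximation.
#' @param rng_seed master RNG seed.
#' @return a `RunConfig` list.
#' @export
runConfig <- function(min_reads = 128L, min_segment_codons = 20L,
                      n_length_groups = 10L, footprint_L = 10L,
                      burn_in_terminations = 1000L, max_burn_events = 1e8,
                      max_steps = 1e7, first_check_step = 5e5,
                      check_interval = 1e6, epsilon = 1e-3,
                      sigma_floor = 1e-3,
                      proposed_scale_lnC = NA_real_, rng_seed = 1L) {
  cfg <- list(min_reads = as.integer(min_reads),
              min_segment_codons = as.integer(min_segment_codons),
              n_length_groups = as.integer(n_length_groups),
              footprint_L = as.integer(footprint_L),
              burn_in_terminations = as.integer(burn_in_terminations),
              max_burn_events = as.numeric(max_burn_events),
              max_steps = as.numeric(max_steps),
              first_check_step = as.numeric(first_check_step),
              check_interval = as.numeric(check_interval),
              epsilon = as.numeric(epsilon),
              sigma_floor = as.numeric(sigma_floor),
              proposed_scale_lnC = as.numeric(proposed_scale_lnC),
              rng_seed = as.integer(rng_seed))
  stopifnot(cfg$min_reads > 0, cfg$min_segment_codons > 0,
            cfg$n_length_groups > 0, cfg$footprint_L >= 1,
            cfg$epsilon > 0, cfg$sigma_floor > 0)
  class(cfg) <- "RunConfig"
  cfg
}

#' Read a run configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param path YAML file.
#' @return a `RunConfig` list.
#' @export
readRunConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(runConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  do.call(runConfig, vals)
}

# Deterministic per-gene seed stream: a polynomial hash of the gene id folded
# with the master seed, reduced below 2^31 so it is a valid R seed. Guarantees
# batch results independent of gene order and degree of parallelism.
# All arithmetic stays below 2^53 and is therefore exact in doubles.
deriveSeed <- function(master_seed, gene_id) {
  m <- 2147483629
  h <- as.numeric(master_seed) %% m
  for (b in utf8ToInt(as.character(gene_id)))
    h <- (h * 131 + b) %% m
  as.integer(h %% (m - 1) + 1)
}
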