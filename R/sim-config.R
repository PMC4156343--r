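#' Simulation configuration for a diverged diploid resequencing experiment
#'
#' Bundles every parameter of the synthetic-data generator: a reference
#' genome with block-wise GC heterogeneity, a target genome diverged from it
#' by substitutions (with a transition/transversion bias) and short indels,
#' within-individual heterozygosity with a configurable class mix, planted
#' perfect SSR loci and repeat-library elements, and paired-end reads with a
#' linear quality-decay error profile.
#'
#' Defaults describe a low-coverage bird resequencing experiment: 120 bp
#' paired-end reads at 5.41x coverage from a ~325 bp library (biological
#' insert 205 bp after subtracting two 60 bp adapters), a target diverged
#' ~5% from the guide genome, heterozygosity 1e-3 with Ts/Tv 2.
#'
#' @param seed integer seed driving every random choice of the generator.
#' @param genome_length reference length in bases.
#' @param isochore_block_length length of each constant-GC block.
#' @param isochore_gc_levels GC fractions the blocks are drawn from.
#' @param divergence_rate substitutions per site between reference and target.
#' @param indel_rate shared indel events per site between reference and target.
#' @param indel_length_geometric_p geometric parameter for indel lengths
#'   (length = 1 + rgeom(p), so mean 1/p).
#' @param heterozygosity heterozygous events per site between the two
#'   target haplotypes.
#' @param tstv_ratio expected transition/transversion count ratio for
#'   substitutions.
#' @param het_class_mix named probabilities over variant classes
#'   `SNV`, `deletion`, `insertion`, `MNV`, `replacement`.
#' @param ssr_densities named vector, planted SSR loci per Mb for motif
#'   lengths "2".."6".
#' @param repeat_library `NULL` (two random 400 bp elements, 10 copies each,
#'   are generated) or a data.frame with columns `seq` and `copies`.
#' @param read_length read length in bases.
#' @param insert_mean,insert_sd insert-size distribution (bases).
#' @param coverage expected fold coverage (total read bases / genome length).
#' @param error_rate_start,error_rate_end per-base error rate at the first
#'   and last sequencing cycle (linear in between).
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              genome_length = 5e6,
                              isochore_block_length = 5e4,
                              isochore_gc_levels = c(0.35, 0.45, 0.55, 0.65),
                              divergence_rate = 0.05,
                              indel_rate = 1e-3,
                              indel_length_geometric_p = 0.5,
                              heterozygosity = 1e-3,
                              tstv_ratio = 2.0,
                              het_class_mix = c(SNV = 0.70, deletion = 0.15,
                                                insertion = 0.07, MNV = 0.05,
                                                replacement = 0.03),
                              ssr_densities = c(`2` = 40, `3` = 20, `4` = 10,
                                                `5` = 5, `6` = 5),
                              repeat_library = NULL,
                              read_length = 120L,
                              insert_mean = 205,
                              insert_sd = 30,
                              coverage = 5.41,
                              error_rate_start = 1e-4,
                              error_rate_end = 1e-3) {
  cfg <- list(seed = as.integer(seed),
              genome_length = as.integer(genome_length),
              isochore_block_length = as.integer(isochore_block_length),
              isochore_gc_levels = isochore_gc_levels,
              divergence_rate = divergence_rate,
              indel_rate = indel_rate,
              indel_length_geometric_p = indel_length_geometric_p,
              heterozygosity = heterozygosity,
              tstv_ratio = tstv_ratio,
              het_class_mix = het_class_mix,
              ssr_densities = ssr_densities,
              repeat_library = repeat_library,
              read_length = as.integer(read_length),
              insert_mean = insert_mean,
              insert_sd = insert_sd,
              coverage = coverage,
              error_rate_start = error_rate_start,
              error_rate_end = error_rate_end)
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  stopifnot(cfg$genome_length > 0)
  rates <- c(cfg$divergence_rate, cfg$indel_rate, cfg$heterozygosity,
             cfg$indel_length_geometric_p, cfg$error_rate_start,
             cfg$error_rate_end)
  if (any(rates < 0 | rates > 1))
    stop("all rates must lie in [0, 1]")
  if (any(cfg$isochore_gc_levels <= 0 | cfg$isochore_gc_levels >= 1))
    stop("isochore_gc_levels must lie in (0, 1)")
  if (cfg$genome_length < 10 * cfg$isochore_block_length)
    stop("genome_length must be at least 10 x isochore_block_length")
  if (cfg$coverage <= 0) stop("coverage must be positive")
  if (cfg$read_length > cfg$insert_mean)
    stop("read_length must not exceed insert_mean")
  mix <- cfg$het_class_mix
  if (!all(c("SNV", "deletion", "insertion", "MNV", "replacement") %in%
           names(mix)) || abs(sum(mix) - 1) > 1e-6)
    stop("het_class_mix must be named probabilities summing to 1")
  if (!identical(sort(names(cfg$ssr_densities)), c("2", "3", "4", "5", "6")))
    stop("ssr_densities must be named by motif lengths 2..6")
  invisible(cfg)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("simulation_config:\n")
  cat(sprintf("  genome %s bp, %d-bp isochore blocks at GC {%s}\n",
              format(x$genome_length, big.mark = ","),
              x$isochore_block_length,
              paste(x$isochore_gc_levels, collapse = ", ")))
  cat(sprintf("  divergence %.3g subs/site (+%.3g indels/site), het %.3g/site, Ts/Tv %.2g\n",
              x$divergence_rate, x$indel_rate, x$heterozygosity, x$tstv_ratio))
  cat(sprintf("  reads: %d bp PE, insert %.0f +/- %.0f bp, coverage %.2fx, error %.3g-%.3g\n",
              x$read_length, x$insert_mean, x$insert_sd, x$coverage,
              x$error_rate_start, x$error_rate_end))
  invisible(x)
}

#' Construct a genome sequence with annotations
#'
#' Lightweight container for a named sequence over `{A,C,G,T,N}` plus
#' interval annotations (isochore blocks, planted SSRs, planted repeats).
#'
#' @param name sequence identifier.
#' @param sequence character scalar.
#' @param annotations data.frame with columns `start`, `end` (1-based,
#'   inclusive), `kind`, `payload`.
#' @return an object of class `genome_sequence`.
#' @export
genome_sequence <- function(name, sequence,
                            annotations = data.frame(start = integer(),
                                                     end = integer(),
                                                     kind = character(),
                                                     payload = character())) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nrow(annotations) &&
      (any(annotations$start < 1) || any(annotations$end > nchar(sequence))))
    stop("annotation intervals must lie within the sequence")
  structure(list(name = name, sequence = sequence,
                 annotations = annotations),
            class = "genome_sequence")
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat(sprintf("genome_sequence '%s': %s bp, %d annotations\n", x$name,
              format(nchar(x$sequence), big.mark = ","),
              nrow(x$annotations)))
  invisible(x)
}

# accept either a genome_sequence or a plain character scalar
as_sequence <- function(x) {
  if (inherits(x, "genome_sequence")) x$sequence
  else if (is.character(x) && length(x) == 1L) x
  else stop("expected a genome_sequence or a single character string")
}
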