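#' SSR scan parameters
#'
#' Minimum tandem-repeat counts per motif length for a perfect SSR locus:
#' 6 repeats for 2-mers, 4 for 3-mers, and 3 for 4-, 5- and 6-mers.
#'
#' @param min_repeats named integer vector over motif lengths "2".."6".
#' @return object of class `ssr_params`.
#' @export
ssr_params <- function(min_repeats = c(`2` = 6L, `3` = 4L, `4` = 3L,
                                       `5` = 3L, `6` = 3L)) {
  if (!identical(sort(names(min_repeats)), c("2", "3", "4", "5", "6")))
    stop("min_repeats must be named by motif lengths 2..6")
  if (any(min_repeats < 2)) stop("repeat thresholds must be at least 2")
  structure(list(min_repeats = min_repeats[c("2", "3", "4", "5", "6")]),
            class = "ssr_params")
}

#' Find perfect SSR loci
#'
#' Scans for maximal perfect tandem repeats of 2-6 bp motifs whose repeat
#' count meets the motif-length threshold.  A run is reported once, under
#' the leftmost phase of its primitive motif (a motif that is itself a
#' tandem of a shorter motif is never reported).  Non-ACGT characters
#' (N, IUPAC codes) terminate runs; scanning is case-insensitive.
#'
#' @param x sequences: character vector (named), [genome_sequence()],
#'   `contig_set`, or `consensus_assembly`.
#' @param params an [ssr_params()].
#' @return data.frame of loci: `seq_name`, `start`, `end` (1-based,
#'   inclusive; `end - start + 1 = motif_length * repeats`), `motif`,
#'   `motif_length`, `repeats`.
#' @export
find_ssrs <- function(x, params = ssr_params()) {
  seqs <- as_named_seqs(if (inherits(x, "consensus_assembly"))
    setNames(x$seq, x$name) else x)
  out <- lapply(seq_along(seqs), function(i) {
    df <- ssr_scan_cpp(toupper(seqs[[i]]),
                       as.integer(params$min_repeats))
    if (nrow(df)) cbind(seq_name = names(seqs)[i], df,
                        stringsAsFactors = FALSE)
    else NULL
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(seq_name = character(), start = integer(),
                      end = integer(), motif = character(),
                      motif_length = integer(), repeats = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$seq_name, res$start), , drop = FALSE]
}

#' SSR density per motif length
#'
#' Number of loci per Mb for each motif length, using non-N assembly bases
#' as the denominator so that assemblies with very different %N remain
#' comparable.
#'
#' @param loci data.frame from [find_ssrs()].
#' @param assembly_length_non_n denominator in bases (non-N assembly
#'   length, or total read bases in raw-read mode).
#' @return named numeric vector of loci per Mb for motif lengths 2..6.
#' @export
ssr_density <- function(loci, assembly_length_non_n) {
  if (assembly_length_non_n <= 0)
    stop("assembly_length_non_n must be positive")
  counts <- table(factor(loci$motif_length, levels = 2:6))
  dens <- as.numeric(counts) / (assembly_length_non_n / 1e6)
  setNames(dens, paste0(2:6, "mer"))
}
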