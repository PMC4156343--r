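#' Consensus-calling parameters
#'
#' @param min_coverage minimum depth for a base call; positions below it
#'   (or with no base evidence at all) become `N`.  The study design uses
#'   thresholds of 1, 2 and 5.
#' @param alt_fraction minimum fraction of total depth supporting an
#'   alternative allele for an IUPAC ambiguity call (inclusive).
#' @param alt_min_reads minimum reads supporting the alternative allele
#'   (inclusive).
#' @return an object of class `consensus_params`.
#' @export
consensus_params <- function(min_coverage = 1L, alt_fraction = 0.10,
                             alt_min_reads = 2L) {
  p <- list(min_coverage = as.integer(min_coverage),
            alt_fraction = alt_fraction,
            alt_min_reads = as.integer(alt_min_reads))
  stopifnot(p$min_coverage >= 1, p$alt_fraction > 0, p$alt_fraction < 0.5,
            p$alt_min_reads >= 1)
  class(p) <- "consensus_params"
  p
}

#' Call a reference-anchored consensus from a pileup
#'
#' Per reference position: depth (base counts + deletion evidence) below
#' `min_coverage` gives `N`; otherwise the majority base is emitted, unless
#' a second allele reaches both `alt_min_reads` reads and `alt_fraction` of
#' the total depth, in which case the IUPAC two-base code of majority and
#' alternative is emitted.  Both thresholds are inclusive ("at least").
#' Ambiguity is limited to two alleles; ties between alternatives resolve
#' to the allele with the higher summed base quality, then alphabetically.
#' The consensus has exactly the reference length; indel evidence does not
#' change it (insertions are reported separately by the variant caller).
#'
#' @param pileup a `refguide_pileup` from [build_pileup()].
#' @param params a [consensus_params()].
#' @return object of class `consensus_assembly`: `name`, `seq` (consensus
#'   string over A,C,G,T,R,Y,S,W,K,M,N), `depth` (coverage track), and the
#'   parameters used.
#' @export
call_consensus <- function(pileup, params = consensus_params()) {
  stopifnot(inherits(pileup, "refguide_pileup"))
  res <- consensus_cpp(pileup$counts_fwd, pileup$counts_rev, pileup$del,
                       pileup$qual_sum, params$min_coverage,
                       params$alt_fraction, params$alt_min_reads)
  structure(list(name = paste0(pileup$ref_name, "_cons",
                               params$min_coverage, "x"),
                 seq = res$seq, depth = res$depth, params = params,
                 ref_name = pileup$ref_name),
            class = "consensus_assembly")
}

#' @export
print.consensus_assembly <- function(x, ...) {
  comp <- consensus_composition(x)
  cat(sprintf("consensus_assembly '%s': %s bp, %.2f%% N (min coverage %d)\n",
              x$name, format(nchar(x$seq), big.mark = ","),
              100 * comp$fractions[["N"]], x$params$min_coverage))
  invisible(x)
}

#' Base composition of a consensus assembly
#'
#' Fractions of `N`, of each unambiguous base, and of each IUPAC ambiguity
#' code, all relative to total assembly length (they sum to 1).
#'
#' @param assembly a `consensus_assembly`, [genome_sequence()], or character
#'   scalar.
#' @return list with `fractions` (named numeric), `pct_n`,
#'   `pct_ambiguous`, and `length`.
#' @export
consensus_composition <- function(assembly) {
  s <- if (inherits(assembly, "consensus_assembly")) assembly$seq
       else as_sequence(assembly)
  if (nchar(s) == 0) stop("empty assembly")
  bytes <- charToRaw(s)
  chars <- c("A", "C", "G", "T", "N", names(.IUPAC_BASES))
  counts <- vapply(chars, function(ch)
    sum(bytes == charToRaw(ch)), numeric(1))
  other <- length(bytes) - sum(counts)
  fr <- counts / length(bytes)
  list(fractions = fr,
       pct_n = unname(100 * fr[["N"]]),
       pct_ambiguous = unname(100 * sum(fr[names(.IUPAC_BASES)])),
       other = other,
       length = length(bytes))
}

#' Write the coverage track of a consensus assembly
#'
#' Four-column BED-style text (sequence, start, end, depth) with 0-based
#' half-open intervals, run-length encoded.
#'
#' @param assembly a `consensus_assembly`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_coverage_track <- function(assembly, path) {
  r <- rle(assembly$depth)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  write.table(data.frame(assembly$name, starts, ends, r$values),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
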