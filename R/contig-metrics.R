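#' Split an assembly at long poly-N runs
#'
#' Maximal runs of at least `split_threshold` consecutive `N`s are removed;
#' the flanking segments become contigs that retain their source
#' coordinates.  Shorter N runs stay inside contigs.  Contigs below
#' `min_contig_length` are dropped.
#'
#' @param assembly a `consensus_assembly`, [genome_sequence()], or (named)
#'   character vector of sequences.
#' @param split_threshold minimum N-run length that triggers a split.
#' @param min_contig_length contigs shorter than this are discarded.
#' @return object of class `contig_set`: data.frame `contigs` with columns
#'   `seq_name`, `start`, `end` (1-based, inclusive, in source coordinates),
#'   `length`, `sequence`, plus the split parameters and conservation
#'   bookkeeping (`removed_n`, `dropped_short`).
#' @export
split_on_n_runs <- function(assembly, split_threshold = 500L,
                            min_contig_length = 1L) {
  seqs <- as_named_seqs(
    if (inherits(assembly, "consensus_assembly"))
      setNames(assembly$seq, assembly$name) else assembly)
  if (!length(seqs) || !sum(nchar(seqs))) stop("empty assembly")
  out <- vector("list", length(seqs))
  removed_n <- 0L
  dropped <- 0L
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    L <- nchar(s)
    g <- if (split_threshold > L) -1L else
      gregexpr(sprintf("N{%d,}", split_threshold), s)[[1]]
    if (g[1] == -1L) {
      starts <- 1L
      ends <- L
    } else {
      nstart <- as.integer(g)
      nlen <- attr(g, "match.length")
      removed_n <- removed_n + sum(nlen)
      starts <- c(1L, nstart + nlen)
      ends <- c(nstart - 1L, L)
    }
    keep <- ends >= starts
    starts <- starts[keep]; ends <- ends[keep]
    if (!length(starts)) { out[[i]] <- NULL; next }
    lens <- ends - starts + 1L
    short <- lens < min_contig_length
    dropped <- dropped + sum(lens[short])
    starts <- starts[!short]; ends <- ends[!short]
    if (!length(starts)) { out[[i]] <- NULL; next }
    out[[i]] <- data.frame(seq_name = names(seqs)[i], start = starts,
                           end = ends, length = ends - starts + 1L,
                           sequence = substring(s, starts, ends),
                           stringsAsFactors = FALSE)
  }
  contigs <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(contigs))
    contigs <- data.frame(seq_name = character(), start = integer(),
                          end = integer(), length = integer(),
                          sequence = character(), stringsAsFactors = FALSE)
  structure(list(contigs = contigs,
                 split_threshold = as.integer(split_threshold),
                 min_contig_length = as.integer(min_contig_length),
                 source_length = sum(nchar(seqs)),
                 removed_n = removed_n, dropped_short = dropped),
            class = "contig_set")
}

#' @export
print.contig_set <- function(x, ...) {
  cat(sprintf("contig_set: %d contigs, %s bp total (split at N>=%d)\n",
              nrow(x$contigs),
              format(sum(x$contigs$length), big.mark = ","),
              x$split_threshold))
  invisible(x)
}

#' N50 of a set of contig lengths
#'
#' The largest length L such that contigs of length >= L together cover at
#' least half of the total assembly length (sorted-descending cumulative
#' convention).
#'
#' @param lengths numeric vector of positive contig lengths.
#' @return the N50, as a single number.
#' @export
n50 <- function(lengths) {
  if (!length(lengths)) stop("n50 of an empty length list is undefined")
  if (any(lengths <= 0)) stop("contig lengths must be positive")
  s <- sort(lengths, decreasing = TRUE)
  cum <- cumsum(s)
  s[which(cum >= sum(s) / 2)[1]]
}

#' Fold coverage of a genome
#'
#' Total sequenced bases divided by genome size, reported to two decimals.
#'
#' @param total_bases total sequenced bases.
#' @param genome_size genome size in bases.
#' @return fold coverage, rounded to 2 decimals.
#' @export
fold_coverage <- function(total_bases, genome_size) {
  if (any(genome_size <= 0)) stop("genome size must be positive")
  round(total_bases / genome_size, 2)
}

#' Contig length histogram over log-spaced bins
#'
#' @param lengths contig lengths.
#' @param breaks bin edges; default follows the conventional log-spaced
#'   assembly bins.
#' @return named integer vector of counts per bin.
#' @export
length_histogram <- function(lengths,
                             breaks = c(0, 200, 500, 1000, 2000, 5000,
                                        10000, Inf)) {
  h <- hist(pmin(lengths, max(breaks[is.finite(breaks)]) + 1),
            breaks = breaks, plot = FALSE, right = FALSE)
  setNames(h$counts,
           paste0("[", breaks[-length(breaks)], ",", breaks[-1], ")"))
}

#' Contiguity report for a contig set
#'
#' @param contigs a `contig_set`.
#' @param assembly optional source assembly, used for %N (computed over the
#'   unsplit assembly).
#' @param genome_size optional genome size for fold coverage.
#' @param total_bases optional total sequenced bases for fold coverage.
#' @return list of class `contiguity_report` with `n_contigs`,
#'   `total_length`, `n50`, `max_length`, `pct_n`, `length_histogram`, and
#'   `fold_coverage` (NA unless both `total_bases` and `genome_size` given).
#' @export
contiguity_report <- function(contigs, assembly = NULL, genome_size = NULL,
                              total_bases = NULL) {
  lens <- contigs$contigs$length
  pct_n <- if (!is.null(assembly))
    consensus_composition(assembly)$pct_n else NA_real_
  fc <- if (!is.null(genome_size) && !is.null(total_bases))
    fold_coverage(total_bases, genome_size) else NA_real_
  structure(list(n_contigs = length(lens),
                 total_length = sum(lens),
                 n50 = if (length(lens)) n50(lens) else NA_real_,
                 max_length = if (length(lens)) max(lens) else NA_real_,
                 pct_n = pct_n,
                 length_histogram = length_histogram(lens),
                 fold_coverage = fc),
            class = "contiguity_report")
}

#' @export
print.contiguity_report <- function(x, ...) {
  cat(sprintf("contigs: %d  total: %s bp  N50: %s  max: %s  %%N: %s\n",
              x$n_contigs, format(x$total_length, big.mark = ","),
              format(x$n50, big.mark = ","),
              format(x$max_length, big.mark = ","),
              ifelse(is.na(x$pct_n), "-", sprintf("%.2f", x$pct_n))))
  invisible(x)
}

#' Fraction of contig bases masked by a repeat library
#'
#' Simplified repeat-content estimate: every local seed-and-extend match of
#' a library element (same unit-cost model as read mapping) with at least
#' `min_match` aligned reference bases and identity at least `min_identity`
#' masks its interval; overlapping matches are merged before computing
#' coverage.
#'
#' @param contigs a `contig_set`, [genome_sequence()], or character vector.
#' @param library character vector of repeat element sequences.
#' @param min_match minimum matched bases.
#' @param min_identity minimum identity of an accepted match.
#' @param params a [mapping_params()] supplying the unit costs.
#' @return masked fraction of total contig bases, in `[0, 1]`.
#' @export
repeat_library_content <- function(contigs, library, min_match = 50L,
                                   min_identity = 0.8,
                                   params = mapping_params()) {
  if (!length(library)) stop("repeat library must be non-empty")
  seqs <- as_named_seqs(if (inherits(contigs, "contig_set")) contigs
                        else contigs)
  total <- sum(nchar(seqs))
  masked <- 0
  for (s in seqs) {
    m <- match_library_cpp(toupper(s), toupper(library),
                           params$seed_length, params$band_fraction,
                           params$mismatch_cost, params$insertion_cost,
                           params$deletion_cost, as.integer(min_match),
                           min_identity, 10000L)
    if (!nrow(m)) next
    ir <- IRanges::reduce(IRanges::IRanges(m$start, m$end))
    masked <- masked + sum(IRanges::width(ir))
  }
  masked / total
}
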