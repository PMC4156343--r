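#' Simulate paired-end reads from a diploid genome
#'
#' Fragments are drawn uniformly from a random haplotype (0.5/0.5); insert
#' length is Normal(`insert_mean`, `insert_sd`) truncated to at least
#' `read_length`; mate 1 is the forward strand at the fragment's left end
#' and mate 2 the reverse complement of its right end.  The per-base error
#' rate is linearly interpolated from `error_rate_start` (first cycle) to
#' `error_rate_end` (last cycle), and the quality string encodes the true
#' per-base error as PHRED+33.  The number of pairs is chosen so that total
#' read bases approximate `coverage * genome_length`.
#'
#' @param hap_a,hap_b the two target haplotypes ([genome_sequence()] or
#'   character).
#' @param config a [simulation_config()].
#' @return list of class `read_set`: `r1`, `r2` (character vectors), `qual`
#'   (the shared per-cycle quality string), `names`, and `truth` (data.frame
#'   with source haplotype, 1-based fragment start on that haplotype, and
#'   insert length per pair).
#' @export
simulate_reads <- function(hap_a, hap_b, config) {
  validate_simulation_config(config)
  sa <- as_sequence(hap_a)
  sb <- as_sequence(hap_b)
  rl <- config$read_length
  if (nchar(sa) < rl || nchar(sb) < rl)
    stop("haplotypes shorter than the read length")
  n_pairs <- round(config$coverage * config$genome_length / (2 * rl))
  if (n_pairs < 1)
    stop("coverage too low: zero read pairs would be generated")
  with_stage_seed(config$seed, 3L, {
    res <- simulate_reads_cpp(sa, sb, n_pairs, rl,
                              config$insert_mean, config$insert_sd,
                              config$error_rate_start, config$error_rate_end)
    structure(list(
      r1 = as.character(res$r1), r2 = as.character(res$r2),
      qual = res$qual,
      names = sprintf("frag%07d", seq_len(n_pairs)),
      truth = data.frame(hap = res$hap, start = res$start,
                         insert = res$insert)), class = "read_set")
  })
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set: %s pairs of %d bp reads\n",
              format(length(x$r1), big.mark = ","), nchar(x$r1[1])))
  invisible(x)
}

#' Write sequences as FASTA
#'
#' @param x a [genome_sequence()], a named character vector, or a
#'   `contig_set`.
#' @param path output file.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  seqs <- as_named_seqs(x)
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(set))
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

# coerce the containers used around the package to named sequences
as_named_seqs <- function(x) {
  if (inherits(x, "genome_sequence")) {
    setNames(x$sequence, x$name)
  } else if (inherits(x, "contig_set")) {
    setNames(x$contigs$sequence,
             sprintf("%s:%d-%d", x$contigs$seq_name, x$contigs$start,
                     x$contigs$end))
  } else if (inherits(x, "consensus_assembly")) {
    setNames(x$seq, x$name)
  } else if (is.character(x)) {
    if (is.null(names(x))) names(x) <- sprintf("seq%d", seq_along(x))
    x
  } else stop("cannot interpret object of class ", class(x)[1],
              " as sequences")
}

#' Write paired reads as two FASTQ files
#'
#' Mate suffixes `/1` and `/2` are appended to the read names.
#'
#' @param reads a `read_set` from [simulate_reads()].
#' @param prefix output path prefix; files `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq` are written.
#' @return character vector of the two paths, invisibly.
#' @export
write_fastq_pair <- function(reads, prefix) {
  paths <- paste0(prefix, c("_1.fastq", "_2.fastq"))
  for (m in 1:2) {
    seqs <- if (m == 1) reads$r1 else reads$r2
    qs <- Biostrings::BStringSet(rep(reads$qual, length(seqs)))
    set <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(seqs),
      Biostrings::PhredQuality(qs))
    names(set) <- paste0(reads$names, "/", m)
    Biostrings::writeQualityScaledXStringSet(set, paths[m])
  }
  invisible(paths)
}

#' Read paired FASTQ files as a read set
#'
#' @param path1,path2 FASTQ files for mate 1 and mate 2.
#' @return a `read_set` (without simulation truth).
#' @export
read_fastq_pair <- function(path1, path2) {
  # metadata-column drop on coercion is expected and harmless here
  s1 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path1))
  s2 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path2))
  if (length(s1) != length(s2))
    stop("mate files differ in read count")
  structure(list(
    r1 = unname(as.character(s1)), r2 = unname(as.character(s2)),
    qual = unname(as.character(Biostrings::quality(s1))[1]),
    qual1 = unname(as.character(Biostrings::quality(s1))),
    qual2 = unname(as.character(Biostrings::quality(s2))),
    names = sub("/[12]$", "", sub("\\s.*$", "", names(s1))),
    truth = NULL), class = "read_set")
}

#' Write the simulation truth as a TSV table
#'
#' One row per planted event with columns `pos` (reference coordinate,
#' 1-based), `kind`, `ref_allele`, `alt_allele`, `class`.
#'
#' @param truth a `simulation_truth`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  div <- truth$divergence_sites
  het <- truth$het_sites
  ssr <- truth$planted_ssrs
  reps <- truth$repeat_intervals
  rows <- rbind(
    data.frame(pos = div$pos, kind = "divergence",
               ref_allele = div$ref_base, alt_allele = div$target_base,
               class = "substitution", stringsAsFactors = FALSE),
    data.frame(pos = het$pos, kind = "het", ref_allele = het$allele_a,
               alt_allele = het$allele_b, class = het$class,
               stringsAsFactors = FALSE),
    data.frame(pos = ssr$pos, kind = "ssr", ref_allele = ssr$motif,
               alt_allele = as.character(ssr$repeats), class = "ssr",
               stringsAsFactors = FALSE),
    data.frame(pos = reps$start, kind = "repeat",
               ref_allele = as.character(reps$end),
               alt_allele = as.character(reps$element), class = "repeat",
               stringsAsFactors = FALSE))
  rows <- rows[order(rows$pos), ]
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
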