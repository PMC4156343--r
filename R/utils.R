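#' @useDynLib refguide, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rgeom sd ks.test dbinom setNames
#' @importFrom graphics hist
#' @importFrom utils head write.table
NULL

# bases as raw byte lookup used by the vectorised sequence builders
.BASES <- c("A", "C", "G", "T")
.BASE_RAW <- charToRaw("ACGT")

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(revcomp_cpp(as.character(x)))
}

# IUPAC two-base ambiguity codes, keyed by sorted base pair
.IUPAC2 <- c(AG = "R", CT = "Y", CG = "S", AT = "W", GT = "K", AC = "M")
.IUPAC_BASES <- list(R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                     W = c("A", "T"), K = c("G", "T"), M = c("A", "C"))

iupac_code <- function(a, b) {
  key <- paste(sort(c(a, b)), collapse = "")
  code <- .IUPAC2[key]
  if (is.na(code)) stop("no IUPAC code for pair ", key)
  unname(code)
}

# transition partner of each base
.TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

is_transition <- function(a, b) {
  .TRANSITION[a] == b
}

#' Number of non-N bases in sequences
#'
#' @param x character vector of sequences.
#' @return total count of A/C/G/T (and IUPAC two-base) characters, i.e.
#'   everything except `N`.
#' @export
non_n_length <- function(x) {
  sum(nchar(x)) - sum(vapply(gregexpr("N", x, fixed = TRUE), function(g) {
    if (g[1] == -1L) 0L else length(g)
  }, integer(1)))
}

# run `code` under a deterministic RNG stream derived from (seed, stage),
# restoring the caller's RNG state afterwards
with_stage_seed <- function(seed, stage, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed((as.integer(seed) * 97L + as.integer(stage)) %% .Machine$integer.max)
  force(code)
}

# draw n random bases with per-base GC probability gc (vectorised over gc)
random_bases <- function(n, gc) {
  is_gc <- runif(n) < gc
  first <- runif(n) < 0.5
  idx <- ifelse(is_gc, ifelse(first, 3L, 2L), ifelse(first, 1L, 4L))
  rawToChar(.BASE_RAW[idx])
}

phred_to_error <- function(q) 10^(-q / 10)
error_to_phred <- function(e) -10 * log10(pmax(e, 1e-6))
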