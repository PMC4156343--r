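#' Windowed GC profile of an assembly
#'
#' Non-overlapping windows of `window_size` bases are tiled from the start
#' of each contig (the remainder is discarded; windows never span contig
#' boundaries).  Windows with an N fraction above `max_n_fraction` are
#' discarded; GC is computed over the non-N bases of each retained window.
#' The reported spread is the sample standard deviation (n - 1) of window
#' GC values.
#'
#' @param x sequences: `contig_set`, [genome_sequence()], character vector,
#'   or `consensus_assembly`.
#' @param window_size window size in bases.
#' @param max_n_fraction maximum tolerated N fraction per window.
#' @return object of class `gc_profile`: `window_size`, `gc_values`, `sd`,
#'   `n_windows`, and `status` ("ok" or "insufficient windows"; with fewer
#'   than 2 usable windows `sd` is NA rather than a silent zero).
#' @export
gc_profile <- function(x, window_size, max_n_fraction = 0.2) {
  if (window_size <= 0) stop("window_size must be positive")
  seqs <- as_named_seqs(if (inherits(x, "consensus_assembly"))
    setNames(x$seq, x$name) else x)
  gc_all <- numeric(0)
  for (s in seqs) {
    L <- nchar(s)
    nw <- L %/% window_size
    if (nw == 0) next
    b <- charToRaw(toupper(substr(s, 1L, nw * window_size)))
    is_gc <- b == charToRaw("G") | b == charToRaw("C")
    is_at <- b == charToRaw("A") | b == charToRaw("T")
    cg <- c(0, cumsum(is_gc))
    ca <- c(0, cumsum(is_at))
    edges <- seq(0L, nw * window_size, by = window_size)
    gcw <- diff(cg[edges + 1L])
    atw <- diff(ca[edges + 1L])
    nn <- window_size - gcw - atw     # N and other ambiguity codes
    keep <- nn / window_size <= max_n_fraction & (gcw + atw) > 0
    gc_all <- c(gc_all, (gcw / (gcw + atw))[keep])
  }
  structure(list(window_size = window_size, gc_values = gc_all,
                 sd = if (length(gc_all) >= 2) sd(gc_all) else NA_real_,
                 n_windows = length(gc_all),
                 status = if (length(gc_all) >= 2) "ok"
                          else "insufficient windows"),
            class = "gc_profile")
}

#' @export
print.gc_profile <- function(x, ...) {
  cat(sprintf("gc_profile: %d windows of %d bp, mean GC %.4f, sd %.5f\n",
              x$n_windows, x$window_size,
              if (x$n_windows) mean(x$gc_values) else NA, x$sd))
  invisible(x)
}

#' GC standard deviation across window sizes, against the homogeneous null
#'
#' Computes the windowed GC standard deviation for each window size and
#' compares it to the homogeneous-genome expectation, under which the
#' standard deviation halves as the window size quadruples:
#' `sd_null(w) = sd(w0) * sqrt(w0 / w)`, anchored at the smallest usable
#' window size.  The ratio `sd / sd_null` ("excess") quantifies isochore
#' structure: ~1 for a compositionally homogeneous genome, >1 when GC varies
#' regionally.
#'
#' @param x sequences (as for [gc_profile()]).
#' @param window_sizes at least two window sizes in bases; the study's
#'   ladder is 3, 5, 10, 20, 80, 160 and 320 kb.
#' @param max_n_fraction per-window N tolerance.
#' @return data.frame with `window_size`, `sd`, `n_windows`, `sd_null`,
#'   `excess`.
#' @export
sd_scaling_curve <- function(x, window_sizes = c(3000, 5000, 10000, 20000,
                                                 80000, 160000, 320000),
                             max_n_fraction = 0.2) {
  if (length(window_sizes) < 2)
    stop("at least two window sizes are required")
  window_sizes <- sort(window_sizes)
  profs <- lapply(window_sizes, function(w)
    gc_profile(x, w, max_n_fraction))
  out <- data.frame(window_size = window_sizes,
                    sd = vapply(profs, function(p) p$sd, numeric(1)),
                    n_windows = vapply(profs, function(p) p$n_windows,
                                       numeric(1)))
  anchor <- which(!is.na(out$sd))[1]
  if (is.na(anchor)) {
    out$sd_null <- NA_real_
    out$excess <- NA_real_
    return(out)
  }
  w0 <- out$window_size[anchor]
  out$sd_null <- out$sd[anchor] * sqrt(w0 / out$window_size)
  out$excess <- out$sd / out$sd_null
  out
}

#' Compare full and subsampled window GC distributions
#'
#' Draws `reduced_n` windows without replacement from a profile and
#' compares the subsample against the full set with a two-sample
#' Kolmogorov-Smirnov test (asymptotic p-value), reproducibly from `seed`.
#' This is the sampling experiment used to ask whether a reduced window
#' sample still represents the genome-wide GC distribution.
#'
#' @param full a `gc_profile`.
#' @param reduced_n subsample size (positive, at most `n_windows`).
#' @param seed integer seed for the subsample.
#' @return list with `D`, `p_value`, `n_full`, `n_reduced`, and the
#'   subsampled values.
#' @export
compare_window_samples <- function(full, reduced_n, seed = 1L) {
  stopifnot(inherits(full, "gc_profile"))
  if (reduced_n <= 0) stop("reduced_n must be positive")
  if (reduced_n > full$n_windows)
    stop("reduced_n exceeds the number of windows")
  sub <- with_stage_seed(seed, 7L,
    sample(full$gc_values, reduced_n, replace = FALSE))
  ks <- suppressWarnings(ks.test(full$gc_values, sub, exact = FALSE))
  list(D = unname(ks$statistic), p_value = ks$p.value,
       n_full = full$n_windows, n_reduced = reduced_n, subsample = sub)
}
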