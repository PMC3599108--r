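#' Frequency-of-frequencies spectrum of a corpus
#'
#' Counts every term of the chosen token layer and maps each occurrence
#' count `f` to the number of terms occurring exactly `f` times. Under
#' Zipf's law this spectrum is dominated by hapaxes and decays as a power
#' law; copy-paste redundancy moves mass from `f = 1` into mid-range
#' counts, producing a secondary peak. The spectrum is also coarsened into
#' log2 bins `[2^k, 2^(k+1))`, which is where peak detection operates.
#'
#' @param corpus An `ehr_corpus`.
#' @param layer `"word"` or `"concept"`; defaults to the corpus layer.
#' @return An object of class `frequency_spectrum`: `term_counts` (named
#'   counts), `spectrum` (data frame `f`, `n_terms`), `log2_bins` (data
#'   frame `k`, `lo`, `hi`, `n_terms`, covering `k = 0 ..
#'   floor(log2(max f))` including empty bins), `total_tokens`.
#' @export
frequency_spectrum <- function(corpus, layer = NULL) {
  stopifnot(inherits(corpus, "ehr_corpus"))
  if (is.null(layer)) layer <- corpus$layer
  toks <- unlist(lapply(corpus$documents, doc_tokens, layer = layer),
                 use.names = FALSE)
  if (!length(toks)) stop("corpus has no tokens on layer ", layer)
  counts <- table(toks)
  spec_tab <- table(as.integer(counts))
  spectrum <- data.frame(f = as.integer(names(spec_tab)),
                         n_terms = as.integer(spec_tab), row.names = NULL)
  kmax <- floor(log2(max(spectrum$f)))
  k <- 0:kmax
  bin_of <- floor(log2(spectrum$f))
  n_bin <- vapply(k, function(kk) sum(spectrum$n_terms[bin_of == kk]), 0L)
  log2_bins <- data.frame(k = k, lo = 2^k, hi = 2^(k + 1L), n_terms = n_bin)
  structure(list(term_counts = stats::setNames(as.integer(counts),
                                               names(counts)),
                 spectrum = spectrum, log2_bins = log2_bins,
                 total_tokens = length(toks), layer = layer),
            class = "frequency_spectrum")
}

#' @export
print.frequency_spectrum <- function(x, ...) {
  cat(sprintf("<frequency_spectrum (%s): %d types, %d tokens, max f = %d>\n",
              x$layer, sum(x$spectrum$n_terms), x$total_tokens,
              max(x$spectrum$f)))
  invisible(x)
}

#' Shape diagnostics of a frequency spectrum
#'
#' Fits a log-log slope to the spectrum (unweighted least squares of
#' `log2(n_terms)` on `log2(f)` over non-empty cells; a Zipfian corpus
#' gives a clearly negative slope) and scans the log2 bins for a secondary
#' peak: the first bin `b >= 2` whose count exceeds the previous bin's.
#' The peak is unset exactly when the bin counts are non-increasing after
#' the first bin — the shape of a redundancy-free corpus. Detection runs
#' on log2 bins rather than raw counts to suppress small-count jitter.
#'
#' @param spectrum A [frequency_spectrum()].
#' @return An object of class `spectrum_diagnostics`: `zipf_slope` (`NA`
#'   when fewer than two spectrum cells exist), `monotone_fraction`
#'   (fraction of adjacent log2-bin pairs that are non-increasing) and
#'   `secondary_peak` (the `k` of the offending bin `[2^k, 2^(k+1))`, or
#'   `NA`).
#' @export
spectrum_shape <- function(spectrum) {
  stopifnot(inherits(spectrum, "frequency_spectrum"))
  sp <- spectrum$spectrum
  slope <- if (nrow(sp) >= 2L)
    unname(stats::coef(stats::lm(log2(sp$n_terms) ~ log2(sp$f)))[2L])
  else NA_real_
  bins <- spectrum$log2_bins$n_terms
  if (length(bins) >= 2L) {
    diffs <- diff(bins)
    monotone_fraction <- mean(diffs <= 0)
    rising <- which(diffs > 0)
    secondary_peak <- if (length(rising))
      spectrum$log2_bins$k[rising[1L] + 1L] else NA_integer_
  } else {
    monotone_fraction <- 1
    secondary_peak <- NA_integer_
  }
  structure(list(zipf_slope = slope, monotone_fraction = monotone_fraction,
                 secondary_peak = secondary_peak),
            class = "spectrum_diagnostics")
}

#' @export
print.spectrum_diagnostics <- function(x, ...) {
  cat(sprintf("<spectrum_diagnostics: slope %s, monotone fraction %.2f, secondary peak %s>\n",
              if (is.na(x$zipf_slope)) "NA" else sprintf("%.2f", x$zipf_slope),
              x$monotone_fraction,
              if (is.na(x$secondary_peak)) "none"
              else sprintf("[%d,%d)", 2^x$secondary_peak,
                           2^(x$secondary_peak + 1L))))
  invisible(x)
}
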