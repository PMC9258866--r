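# sizeprof: per-sample size histograms, three-bin proportions and cohort
# medians. The three bins partition 1..600 bp as short = [1,49],
# mid = [50,150], long = [151,600]: "< 50 bp" is read strictly, "50 to
# 150 bp" inclusive on both ends, "> 150 bp" strictly, which is the only
# reading under which the three phrases partition the lengths.

SIZE_SUPPORT <- 600L
BIN_SHORT_MAX <- 49L
BIN_MID_MAX <- 150L

#' Fragment-size histogram
#'
#' Counts fragments per length 1..600 bp.
#'
#' @param frags A `fragments` data.frame (see [read_fragments()]).
#' @return A `size_histogram`: list with `counts` (named integer vector over
#'   lengths 1..600) and `total`.
#' @export
size_histogram <- function(frags) {
  if (is.null(frags) || nrow(frags) == 0L) {
    ucfrag_error("size_histogram: empty fragment set", "ucfrag_empty_sample_error")
  }
  len <- frags$length
  if (any(len < 1L | len > SIZE_SUPPORT)) {
    ucfrag_error(sprintf("size_histogram: fragment length outside 1..%d", SIZE_SUPPORT),
                 "ucfrag_record_error")
  }
  counts <- tabulate(len, nbins = SIZE_SUPPORT)
  names(counts) <- as.character(seq_len(SIZE_SUPPORT))
  structure(list(counts = counts, total = sum(counts)), class = "size_histogram")
}

#' @export
print.size_histogram <- function(x, ...) {
  nz <- which(x$counts > 0)
  cat(sprintf("<size_histogram> %d fragments, lengths %d..%d bp\n",
              x$total, min(nz), max(nz)))
  invisible(x)
}

#' Three-bin size proportions
#'
#' Fractions of fragments with length < 50 bp (`p_short`), 50..150 bp
#' (`p_mid`) and > 150 bp (`p_long`). The three fractions sum to 1.
#'
#' @param hist A [size_histogram()].
#' @return Named numeric vector `c(p_short, p_mid, p_long)`.
#' @export
size_bins <- function(hist) {
  stopifnot(inherits(hist, "size_histogram"))
  if (hist$total == 0L) {
    ucfrag_error("size_bins: histogram has zero total", "ucfrag_empty_sample_error")
  }
  cnt <- hist$counts
  c(p_short = sum(cnt[1:BIN_SHORT_MAX]) / hist$total,
    p_mid = sum(cnt[(BIN_SHORT_MAX + 1L):BIN_MID_MAX]) / hist$total,
    p_long = sum(cnt[(BIN_MID_MAX + 1L):SIZE_SUPPORT]) / hist$total)
}

#' Per-bin medians over a cohort of size-bin vectors
#'
#' Elementwise median of `c(p_short, p_mid, p_long)` across samples. Note
#' that medians of compositional vectors need not sum to 1.
#'
#' @param samples List of vectors as returned by [size_bins()].
#' @return Named numeric vector of per-bin medians.
#' @export
cohort_median_bins <- function(samples) {
  stopifnot(length(samples) >= 1L)
  m <- do.call(rbind, samples)
  apply(m, 2L, stats::median)
}

#' Median size profile over a cohort
#'
#' Per-length median of per-sample length frequencies; the per-length
#' medians define the cohort's median size curve.
#'
#' @param samples List of [size_histogram()] objects.
#' @return Numeric vector of length 600: median frequency per length.
#' @export
median_size_profile <- function(samples) {
  stopifnot(length(samples) >= 1L)
  freq <- vapply(samples, function(h) h$counts / h$total, numeric(SIZE_SUPPORT))
  out <- apply(freq, 1L, stats::median)
  names(out) <- as.character(seq_len(SIZE_SUPPORT))
  out
}

#' Export a size histogram as a TSV
#'
#' Columns: length, count, frequency.
#'
#' @param hist A [size_histogram()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_size_tsv <- function(hist, path) {
  stopifnot(inherits(hist, "size_histogram"))
  df <- data.frame(length = seq_len(SIZE_SUPPORT),
                   count = as.integer(hist$counts),
                   frequency = hist$counts / hist$total)
  write_hashed_tsv(df, path, "#length\tcount\tfrequency")
}
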