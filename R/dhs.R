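# dhs: fragment-end density around DHS centers and the within-DHS end
# proportion.
#
# "Within the DHSs" is operationalised as within +-1 kb of a DHS center
# (half-open: [center - window, center + window)). Both ends of every
# fragment are pooled: the end positions of a fragment [start, end) are
# start and end - 1. Each end is assigned to its NEAREST center, so
# overlapping windows of adjacent DHSs never double-count an end.

# End positions (chrom, pos) of a fragment table: upstream terminal base
# and last covered base.
fragment_ends <- function(frags) {
  data.frame(chrom = rep(frags$chrom, 2L),
             pos = c(frags$start, frags$end - 1L),
             stringsAsFactors = FALSE)
}

# Signed offset of each end from its nearest DHS center on the same chrom;
# NA when the chrom carries no DHS.
nearest_center_offset <- function(ends, dhs) {
  off <- rep(NA_integer_, nrow(ends))
  ivs <- dhs$intervals
  for (ch in unique(ends$chrom)) {
    centers <- dhs$centers[ivs$chrom == ch]
    if (length(centers) == 0L) next
    centers <- sort(centers)
    sel <- which(ends$chrom == ch)
    p <- ends$pos[sel]
    idx <- findInterval(p, centers)
    lo <- pmax(idx, 1L)
    hi <- pmin(idx + 1L, length(centers))
    d_lo <- abs(p - centers[lo])
    d_hi <- abs(p - centers[hi])
    nearest <- ifelse(d_lo <= d_hi, centers[lo], centers[hi])
    off[sel] <- p - nearest
  }
  off
}

#' Fragment-end density profile around DHS centers
#'
#' Both ends of every fragment contribute. An end at genomic position p
#' within `[center - window, center + window)` of its nearest DHS center is
#' assigned to offset bin `floor((p - center) / bin_width)`; counts are
#' aggregated over all DHSs and divided by the median bin count.
#'
#' @param frags A `fragments` data.frame.
#' @param dhs A [dhs_set()].
#' @param window Half-window around each center in bp (default 1000).
#' @param bin_width Bin width in bp (default 10; must divide `window`).
#' @return A `dhs_profile` data.frame with columns `bin_start` (offset of
#'   the bin's left edge, -window .. window - bin_width), `count` and
#'   `density`; attributes carry window, bin width and end totals.
#' @export
end_density_profile <- function(frags, dhs, window = 1000L, bin_width = 10L) {
  stopifnot(inherits(dhs, "dhs_set"), nrow(frags) > 0L)
  if (window %% bin_width != 0L) {
    ucfrag_error("end_density_profile: window must be a multiple of bin_width",
                 "ucfrag_record_error")
  }
  ends <- fragment_ends(frags)
  off <- nearest_center_offset(ends, dhs)
  inw <- !is.na(off) & off >= -window & off < window
  nb <- as.integer(2L * window / bin_width)
  bin <- off[inw] %/% bin_width
  counts <- tabulate(bin + window %/% bin_width + 1L, nbins = nb)
  med <- stats::median(counts)
  if (med <= 0) {
    ucfrag_error("end_density_profile: median bin count is zero (data too sparse)",
                 "ucfrag_sparse_data_error")
  }
  prof <- data.frame(bin_start = seq(-window, window - bin_width, by = bin_width),
                     count = counts,
                     density = counts / med)
  structure(prof,
            window = window, bin_width = bin_width,
            n_ends = nrow(ends), n_ends_in_window = sum(inw),
            class = c("dhs_profile", "data.frame"))
}

#' Normalized end density at the central bin
#'
#' @param profile A [end_density_profile()] result.
#' @return Density of the bin whose left edge is offset 0.
#' @export
central_density <- function(profile) {
  stopifnot(inherits(profile, "dhs_profile"))
  profile$density[profile$bin_start == 0L]
}

#' Proportion of fragment ends within the DHSs
#'
#' Fraction of fragment ends (both ends pooled) lying within `window` bp of
#' their nearest DHS center. With `size_range = c(lo, hi)` fragments with
#' length outside \[lo, hi\] are excluded first (the size-selected variant).
#'
#' @param frags A `fragments` data.frame.
#' @param dhs A [dhs_set()].
#' @param window Half-window in bp (default 1000).
#' @param size_range Optional length bounds `c(lo, hi)` in bp, inclusive.
#' @return Fraction in \[0, 1\].
#' @export
dhs_end_proportion <- function(frags, dhs, window = 1000L, size_range = NULL) {
  stopifnot(inherits(dhs, "dhs_set"))
  if (!is.null(size_range)) {
    stopifnot(length(size_range) == 2L)
    frags <- frags[frags$length >= size_range[1] & frags$length <= size_range[2], ,
                   drop = FALSE]
  }
  if (nrow(frags) == 0L) {
    ucfrag_error("dhs_end_proportion: no fragments left after size filter",
                 "ucfrag_empty_sample_error")
  }
  ends <- fragment_ends(frags)
  off <- nearest_center_offset(ends, dhs)
  mean(!is.na(off) & off >= -window & off < window)
}

#' Per-sample within-DHS proportions and group medians
#'
#' @param samples Named list of `fragments` data.frames.
#' @param dhs A [dhs_set()].
#' @param window,size_range Passed to [dhs_end_proportion()].
#' @param groups Optional character vector (one group label per sample).
#' @return List with `per_sample` (data.frame sample/group/proportion) and
#'   `medians` (overall, or one per group when `groups` is given).
#' @export
cohort_dhs <- function(samples, dhs, window = 1000L, size_range = NULL,
                       groups = NULL) {
  stopifnot(length(samples) >= 1L)
  ids <- names(samples) %||% as.character(seq_along(samples))
  props <- vapply(seq_along(samples), function(i) {
    tryCatch(dhs_end_proportion(samples[[i]], dhs, window, size_range),
             ucfrag_error = function(e) {
               ucfrag_error(sprintf("sample '%s': %s", ids[i], conditionMessage(e)),
                            class(e)[1])
             })
  }, numeric(1))
  df <- data.frame(sample = ids,
                   group = if (is.null(groups)) NA_character_ else groups,
                   proportion = props, stringsAsFactors = FALSE)
  medians <- if (is.null(groups)) {
    c(all = stats::median(props))
  } else {
    tapply(props, groups, stats::median)
  }
  list(per_sample = df, medians = medians)
}

#' Export a DHS profile as a TSV
#'
#' Columns: offset (bin left edge), count, density.
#'
#' @param profile A [end_density_profile()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dhs_profile_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "dhs_profile"))
  write_hashed_tsv(as.data.frame(profile), path, "#offset\tcount\tdensity")
}
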