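# endmotif: 4-mer end-motif spectra from fragment ends against the
# reference genome, rankings, T-end fraction, top-k sets, rank concordance
# and the subject-level motif-ratio metric.
#
# Orientation convention: both fragment ends contribute, and every motif is
# reported as the 5'->3' sequence entering the fragment. The upstream end
# motif is the reference bases [start, start+k); the downstream end motif is
# the reverse complement of the reference bases [end-k, end). Windows
# containing N are skipped and counted, not imputed.

BASES <- c("A", "C", "G", "T")

#' All k-mers over A/C/G/T in lexicographic order
#'
#' @param k Motif length.
#' @return Character vector of the 4^k motifs, sorted A < C < G < T.
#' @export
all_motifs <- function(k = 4L) {
  grid <- do.call(expand.grid, c(rep(list(BASES), k),
                                 list(stringsAsFactors = FALSE)))
  sort(do.call(paste0, grid[, seq_len(k), drop = FALSE]))
}

#' End-motif spectrum of a fragment sample
#'
#' Extracts the k-mer at each fragment end (see module conventions above)
#' and tabulates motif frequencies over the 4^k motifs.
#'
#' @param frags A `fragments` data.frame.
#' @param genome Named character vector of reference sequences (as returned
#'   by [read_fasta()] or [make_genome()]).
#' @param k Motif length (default 4).
#' @return A `motif_spectrum`: list with `freq` (named numeric over the 4^k
#'   motifs, summing to 1), `n_ends` and `n_skipped` (N-containing windows).
#' @export
end_motifs <- function(frags, genome, k = 4L) {
  stopifnot(is.data.frame(frags), nrow(frags) > 0L, is.character(genome))
  if (is.null(names(genome))) names(genome) <- "chr1"
  motifs <- character(0)
  for (ch in unique(frags$chrom)) {
    if (!ch %in% names(genome)) {
      ucfrag_error(sprintf("end_motifs: chrom '%s' not in genome", ch),
                   "ucfrag_coordinate_error")
    }
    sel <- frags$chrom == ch
    s <- frags$start[sel]
    e <- frags$end[sel]
    glen <- nchar(genome[[ch]])
    if (any(s < 0L) || any(e > glen) || any(e - s < k)) {
      ucfrag_error(sprintf(
        "end_motifs: fragment out of bounds or shorter than k on '%s'", ch),
        "ucfrag_coordinate_error")
    }
    up <- substring(genome[[ch]], s + 1L, s + k)
    down_win <- substring(genome[[ch]], e - k + 1L, e)
    down <- rev_fixed(chartr("ACGTN", "TGCAN", down_win), k)
    motifs <- c(motifs, up, down)
  }
  skip <- grepl("[^ACGT]", motifs)
  n_skipped <- sum(skip)
  lv <- all_motifs(k)
  counts <- table(factor(motifs[!skip], levels = lv))
  n_ends <- length(motifs) - n_skipped
  if (n_ends <= 0L) {
    ucfrag_error("end_motifs: no ends left after N-window skipping",
                 "ucfrag_empty_sample_error")
  }
  freq <- stats::setNames(as.numeric(counts) / n_ends, lv)
  structure(list(freq = freq, n_ends = n_ends, n_skipped = n_skipped),
            class = "motif_spectrum")
}

#' @export
print.motif_spectrum <- function(x, ...) {
  top <- sort(x$freq, decreasing = TRUE)[1:5]
  cat(sprintf("<motif_spectrum> %d ends (%d N-skipped); top motifs: %s\n",
              x$n_ends, x$n_skipped,
              paste(sprintf("%s=%.3f", names(top), top), collapse = " ")))
  invisible(x)
}

#' Rank motifs by descending frequency
#'
#' Ties are broken lexicographically (A < C < G < T); rank 1 is the most
#' frequent motif.
#'
#' @param spectrum A [end_motifs()] spectrum.
#' @return A `motif_ranking`: list with `order` (motifs in rank order) and
#'   `rank` (named integer, motif -> 1..4^k).
#' @export
rank_motifs <- function(spectrum) {
  stopifnot(inherits(spectrum, "motif_spectrum"))
  if (spectrum$n_ends <= 0L) {
    ucfrag_error("rank_motifs: spectrum has no ends", "ucfrag_empty_sample_error")
  }
  nm <- names(spectrum$freq)
  ord <- order(-spectrum$freq, nm)
  order_motifs <- nm[ord]
  rank <- stats::setNames(match(nm, order_motifs), nm)
  structure(list(order = order_motifs, rank = rank), class = "motif_ranking")
}

#' Fraction of ends whose motif begins with T
#'
#' @param spectrum A [end_motifs()] spectrum.
#' @return Numeric scalar in \[0, 1\].
#' @export
t_end_fraction <- function(spectrum) {
  stopifnot(inherits(spectrum, "motif_spectrum"))
  if (spectrum$n_ends <= 0L) {
    ucfrag_error("t_end_fraction: spectrum has no ends", "ucfrag_empty_sample_error")
  }
  sum(spectrum$freq[startsWith(names(spectrum$freq), "T")])
}

#' Top-k motif set of a ranking
#'
#' @param ranking A [rank_motifs()] ranking.
#' @param k Set size (default 25).
#' @return Character vector of the k top-ranked motifs.
#' @export
top_k_set <- function(ranking, k = 25L) {
  stopifnot(inherits(ranking, "motif_ranking"))
  n <- length(ranking$order)
  if (k < 1L || k > n) {
    ucfrag_error(sprintf("top_k_set: k must be in 1..%d", n), "ucfrag_record_error")
  }
  ranking$order[seq_len(k)]
}

#' Rank concordance between two motif rankings
#'
#' Returns the per-motif rank pairs and the two discordance sets: motifs in
#' the top `top` of one ranking but at rank `top + 1` or lower in the other.
#'
#' @param rank_a,rank_b Two [rank_motifs()] rankings over the same motifs.
#' @param top Top-rank threshold (default 10).
#' @return List with `pairs` (data.frame motif/rank_a/rank_b),
#'   `top_a_only` and `top_b_only` (character vectors).
#' @export
rank_concordance <- function(rank_a, rank_b, top = 10L) {
  stopifnot(inherits(rank_a, "motif_ranking"), inherits(rank_b, "motif_ranking"))
  nm <- names(rank_a$rank)
  if (!setequal(nm, names(rank_b$rank))) {
    ucfrag_error("rank_concordance: rankings cover different motif sets",
                 "ucfrag_record_error")
  }
  ra <- rank_a$rank[nm]
  rb <- rank_b$rank[nm]
  pairs <- data.frame(motif = nm, rank_a = as.integer(ra),
                      rank_b = as.integer(rb), stringsAsFactors = FALSE)
  list(pairs = pairs,
       top_a_only = nm[ra <= top & rb > top],
       top_b_only = nm[rb <= top & ra > top])
}

#' Motif-set frequency ratio
#'
#' Ratio of the spectrum mass over one motif set to the mass over another;
#' used as the subject-level end-motif metric with the top-25 sets learned
#' from wild-type and Dnase1-knockout reference spectra. The sets are used
#' verbatim (shared motifs may appear in both).
#'
#' @param spectrum A [end_motifs()] spectrum.
#' @param set_wt,set_ko Nonempty character vectors of motifs.
#' @return Numeric scalar: mass(set_wt) / mass(set_ko).
#' @export
motif_ratio <- function(spectrum, set_wt, set_ko) {
  stopifnot(inherits(spectrum, "motif_spectrum"))
  if (length(set_wt) == 0L || length(set_ko) == 0L) {
    ucfrag_error("motif_ratio: motif sets must be nonempty", "ucfrag_record_error")
  }
  nm <- names(spectrum$freq)
  if (!all(set_wt %in% nm) || !all(set_ko %in% nm)) {
    ucfrag_error("motif_ratio: unknown motif in set", "ucfrag_record_error")
  }
  den <- sum(spectrum$freq[set_ko])
  if (den <= 0) {
    ucfrag_error("motif_ratio: zero denominator mass", "ucfrag_degenerate_spectrum_error")
  }
  sum(spectrum$freq[set_wt]) / den
}

#' Export a motif spectrum as a TSV
#'
#' Columns: motif, frequency, rank.
#'
#' @param spectrum A [end_motifs()] spectrum.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motif_tsv <- function(spectrum, path) {
  rk <- rank_motifs(spectrum)
  df <- data.frame(motif = names(spectrum$freq),
                   frequency = as.numeric(spectrum$freq),
                   rank = as.integer(rk$rank))
  write_hashed_tsv(df, path, "#motif\tfrequency\trank")
}
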