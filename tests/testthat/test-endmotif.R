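test_that("end motifs are the 5'->3' sequences entering the fragment", {
  g <- c(chr1 = "TTTTACGT")
  fr <- fragments("chr1", 0, 8)
  sp <- end_motifs(fr, g)
  # upstream motif TTTT; downstream = revcomp("ACGT") = "ACGT" (palindrome)
  expect_equal(sp$n_ends, 2L)
  expect_equal(sp$freq[["TTTT"]], 0.5)
  expect_equal(sp$freq[["ACGT"]], 0.5)
  expect_equal(sum(sp$freq), 1)
})

test_that("N-containing windows are skipped, the other end still counts", {
  g <- c(chr1 = "ACGTAANNNN")
  fr <- fragments("chr1", 0, 10)
  sp <- end_motifs(fr, g)
  expect_equal(sp$n_skipped, 1L)
  expect_equal(sp$n_ends, 1L)
  expect_equal(sp$freq[["ACGT"]], 1)
})

test_that("out-of-bounds fragments raise coordinate errors", {
  g <- c(chr1 = "ACGTACGTAC")
  expect_error(end_motifs(fragments("chr1", 5, 12), g),
               class = "ucfrag_coordinate_error")
  expect_error(end_motifs(fragments("chr2", 0, 8), g),
               class = "ucfrag_coordinate_error")
})

test_that("spectrum equals the exhaustive dictionary count on toy genomes", {
  for (seed in c(3, 17, 91)) {
    g <- toy_genome(2000, seed)
    fr <- random_fragments(g, 50, seed = seed + 1)
    sp <- end_motifs(fr, g)
    expect_equal(sp$freq, oracle_end_motifs(fr, g), tolerance = 1e-12)
  }
})

test_that("revcomp is an involution on all 256 motifs", {
  m <- all_motifs(4)
  expect_identical(revcomp(revcomp(m)), m)
})

test_that("ranking is by descending frequency with lexicographic ties", {
  rk <- rank_motifs(uniform_spectrum())
  expect_equal(rk$order[1], "AAAA")
  expect_equal(rk$rank[["AAAA"]], 1L)
  expect_identical(rk$order, all_motifs(4))

  freq <- setNames(rep(0, 256), all_motifs(4))
  freq["TGTG"] <- 1
  rk <- rank_motifs(spectrum_from_freq(freq))
  expect_equal(rk$order[1], "TGTG")

  # brute-force stable sort oracle on random spectra
  for (seed in 1:3) {
    set.seed(seed)
    freq <- setNames(stats::rexp(256), all_motifs(4))
    freq <- freq / sum(freq)
    rk <- rank_motifs(spectrum_from_freq(freq))
    ord <- names(sort(-freq))  # base sort is stable; names pre-sorted
    expect_identical(rk$order, ord)
  }
})

test_that("t_end_fraction sums the 64 T-leading motifs", {
  expect_equal(t_end_fraction(uniform_spectrum()), 0.25)
  freq <- setNames(rep(0, 256), all_motifs(4))
  freq["TTTT"] <- 1
  expect_equal(t_end_fraction(spectrum_from_freq(freq)), 1.0)
})

test_that("top_k_set returns the first k motifs with the tie rule", {
  rk <- rank_motifs(uniform_spectrum())
  expect_identical(top_k_set(rk, 256), all_motifs(4))
  expect_identical(top_k_set(rk, 1), "AAAA")
  expect_error(top_k_set(rk, 0), class = "ucfrag_record_error")
  expect_error(top_k_set(rk, 257), class = "ucfrag_record_error")
})

test_that("rank_concordance returns pairs and the two discordance sets", {
  rk <- rank_motifs(uniform_spectrum())
  rc <- rank_concordance(rk, rk)
  expect_length(rc$top_a_only, 0L)
  expect_length(rc$top_b_only, 0L)
  expect_equal(nrow(rc$pairs), 256L)

  # reversed ranking: the top 10 of one are the bottom 10 of the other
  set.seed(4)
  freq <- setNames(stats::rexp(256), all_motifs(4))
  spA <- spectrum_from_freq(freq)
  spB <- spectrum_from_freq(max(freq) + min(freq) - freq)
  rc <- rank_concordance(rank_motifs(spA), rank_motifs(spB))
  expect_length(rc$top_a_only, 10L)
  expect_length(rc$top_b_only, 10L)
  expect_identical(sort(rc$top_a_only), sort(top_k_set(rank_motifs(spA), 10)))
})

test_that("motif_ratio is set-mass ratio with a degenerate-denominator error", {
  sp <- uniform_spectrum()
  top <- all_motifs(4)[1:25]
  expect_equal(motif_ratio(sp, top, top), 1.0)

  freq <- setNames(rep(0, 256), all_motifs(4))
  freq["AAAA"] <- 1
  sp1 <- spectrum_from_freq(freq)
  expect_error(motif_ratio(sp1, "AAAA", "CCCC"),
               class = "ucfrag_degenerate_spectrum_error")
  expect_error(motif_ratio(sp, character(0), top), class = "ucfrag_record_error")
  expect_equal(motif_ratio(sp1, "AAAA", c("AAAA", "CCCC")), 1.0)
})
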