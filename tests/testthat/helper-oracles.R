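# Independent oracles and shared fixtures. The oracles deliberately avoid
# the code paths they check: motif counting is dictionary-based with a
# strsplit reverse complement, AUC is pair counting, and the Mann-Whitney
# p-value is enumeration with explicit pair comparison.

oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    chars <- rev(strsplit(s, "")[[1]])
    paste(vapply(chars, function(b) {
      switch(b, A = "T", C = "G", G = "C", T = "A", "N")
    }, character(1)), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# dictionary-count end-motif spectrum on a toy genome
oracle_end_motifs <- function(frags, genome, k = 4) {
  counts <- new.env()
  n_ends <- 0L
  for (i in seq_len(nrow(frags))) {
    g <- genome[[frags$chrom[i]]]
    s <- frags$start[i]
    e <- frags$end[i]
    up <- substr(g, s + 1, s + k)
    down <- oracle_revcomp(substr(g, e - k + 1, e))
    for (m in c(up, down)) {
      if (grepl("N", m, fixed = TRUE)) next
      counts[[m]] <- (if (is.null(counts[[m]])) 0L else counts[[m]]) + 1L
      n_ends <- n_ends + 1L
    }
  }
  freq <- setNames(numeric(4^k), all_motifs(k))
  for (m in ls(counts)) freq[m] <- counts[[m]] / n_ends
  freq
}

# AUC by brute-force pair counting
oracle_auc <- function(scores, labels, positive) {
  case <- scores[labels == positive]
  ctrl <- scores[labels != positive]
  tot <- 0
  for (a in case) for (b in ctrl) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(case) * length(ctrl))
}

# exact two-sided Mann-Whitney p by enumerating label assignments with
# explicit pair comparison (min-U convention)
oracle_mw_p <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x)
  u_of <- function(a, b) {
    u <- 0
    for (ai in a) for (bi in b) u <- u + (ai > bi) + 0.5 * (ai == bi)
    min(u, length(a) * length(b) - u)
  }
  obs <- u_of(x, y)
  idx <- utils::combn(length(pool), n1)
  hits <- 0
  for (j in seq_len(ncol(idx))) {
    if (u_of(pool[idx[, j]], pool[-idx[, j]]) <= obs + 1e-9) hits <- hits + 1
  }
  hits / ncol(idx)
}

# random toy genome as a plain string vector
toy_genome <- function(len, seed, name = "chr1") {
  set.seed(seed)
  g <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  setNames(g, name)
}

random_fragments <- function(genome, n, seed, min_len = 10L, max_len = 60L) {
  set.seed(seed)
  glen <- nchar(genome[[1]])
  len <- sample(min_len:max_len, n, replace = TRUE)
  start <- vapply(len, function(l) sample.int(glen - l, 1L) - 1L, integer(1))
  fragments(rep(names(genome)[1], n), start, start + len)
}

# uniform-spectrum and custom-frequency motif_spectrum constructors
uniform_spectrum <- function(k = 4) {
  structure(list(freq = setNames(rep(1 / 4^k, 4^k), all_motifs(k)),
                 n_ends = 4^k, n_skipped = 0L),
            class = "motif_spectrum")
}

spectrum_from_freq <- function(freq) {
  structure(list(freq = freq / sum(freq), n_ends = 1000L, n_skipped = 0L),
            class = "motif_spectrum")
}

# Shared large-scale synthetic world (10 Mb genome, default DHS set,
# calibrated presets), built once per test run.
.world_cache <- new.env(parent = emptyenv())

acceptance_world <- function() {
  if (is.null(.world_cache$world)) {
    genome <- make_genome(1e7, 0.42, seed = 0)
    dhs <- make_dhs(genome, seed = 10)
    presets <- lapply(setNames(nm = ucfrag_presets()), function(p) {
      calibrate_preset(ucfrag_preset(p), dhs)
    })
    .world_cache$world <- list(genome = genome, dhs = dhs, presets = presets)
  }
  .world_cache$world
}
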