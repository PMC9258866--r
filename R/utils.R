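# Internal helpers shared across modules.

# Classed error so callers can distinguish format errors from coordinate
# errors etc. programmatically (tests rely on the classes).
ucfrag_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "ucfrag_error")))
}

ucfrag_warning <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "ucfrag_warning")))
}

# Evaluate `code` under a fixed seed without disturbing the caller's RNG
# stream. seed = NULL leaves the RNG alone.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Truncated normal via inverse-CDF; exact for the quantile grid R uses and
# deterministic under a fixed seed.
rtnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over the alphabet A/C/G/T/N.
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of the same length.
#' @examples
#' revcomp(c("ACGT", "TTTA"))
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

# Fast fixed-width string reversal used on large motif vectors: all strings
# must have exactly `k` characters.
rev_fixed <- function(x, k) {
  cols <- lapply(seq(k, 1L), function(i) substring(x, i, i))
  do.call(paste0, cols)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# TSV with a single '#'-prefixed header line, tab separators, no quoting,
# trailing newline (the package's canonical on-disk table form)
write_hashed_tsv <- function(df, path, header) {
  writeLines(header, path)
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE, quote = FALSE,
                     append = TRUE, na = "NA")
  invisible(path)
}
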