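# jagged: the Jagged Index-Unmethylated (JI-U).
#
# JI-U = (M1 - M2) / M1 * 100, where M1 is the pooled CpG methylation
# density of the 30 bases proximal to fragments' 5' ends and M2 the same
# for the 3' ends. End repair fills 5'-protruding (jagged) ends with
# unmethylated cytosines, so apparent methylation drops near the 3'-proximal
# read end; the higher the JI-U, the more jagged the ends. Densities are
# pooled counts (sum calls across fragments, then divide), not means of
# per-fragment ratios: per-fragment CpG counts are tiny.

#' Construct a pooled methylation-call table
#'
#' @param m1_meth,m1_total Methylated and total CpG calls within 30 bases of
#'   the 5' end, pooled over fragments.
#' @param m2_meth,m2_total Same for the 3' end.
#' @param calls Optional raw per-call data.frame (kept for round-tripping).
#' @return A `meth_call_table`.
#' @export
meth_call_table <- function(m1_meth, m1_total, m2_meth, m2_total, calls = NULL) {
  vals <- c(m1_meth, m1_total, m2_meth, m2_total)
  if (any(vals < 0) || m1_meth > m1_total || m2_meth > m2_total) {
    ucfrag_error("meth_call_table: need 0 <= meth <= total for both ends",
                 "ucfrag_record_error")
  }
  structure(list(m1_meth = m1_meth, m1_total = m1_total,
                 m2_meth = m2_meth, m2_total = m2_total,
                 calls = calls),
            class = "meth_call_table")
}

#' Aggregate raw methylation calls into a pooled table
#'
#' @param calls Data.frame with columns fragment_id, end_tag
#'   (`five_prime`/`three_prime`), offset (0..29) and call (`M`/`U`).
#' @return A [meth_call_table()] retaining `calls`.
#' @export
meth_call_table_from_calls <- function(calls) {
  stopifnot(is.data.frame(calls),
            all(c("fragment_id", "end_tag", "offset", "call") %in% names(calls)))
  five <- calls$end_tag == "five_prime"
  meth_call_table(
    m1_meth = sum(five & calls$call == "M"),
    m1_total = sum(five),
    m2_meth = sum(!five & calls$call == "M"),
    m2_total = sum(!five),
    calls = calls
  )
}

#' @export
print.meth_call_table <- function(x, ...) {
  cat(sprintf("<meth_call_table> 5' end: %d/%d M; 3' end: %d/%d M\n",
              x$m1_meth, x$m1_total, x$m2_meth, x$m2_total))
  invisible(x)
}

#' Methylation densities at the two fragment ends
#'
#' @param table A [meth_call_table()].
#' @return Named numeric vector `c(M1, M2)`, both in \[0, 1\].
#' @export
methylation_densities <- function(table) {
  stopifnot(inherits(table, "meth_call_table"))
  if (table$m1_total <= 0 || table$m2_total <= 0) {
    ucfrag_error("methylation_densities: zero CpG calls at one end",
                 "ucfrag_insufficient_cpg_error")
  }
  c(M1 = table$m1_meth / table$m1_total,
    M2 = table$m2_meth / table$m2_total)
}

#' Jagged Index-Unmethylated
#'
#' `JI-U = (M1 - M2) / M1 * 100`; requires M1 > 0.
#'
#' @param table A [meth_call_table()].
#' @return JI-U in percent (at most 100).
#' @export
ji_u <- function(table) {
  d <- methylation_densities(table)
  if (d[["M1"]] <= 0) {
    ucfrag_error("ji_u: M1 is zero, index undefined", "ucfrag_undefined_index_error")
  }
  (d[["M1"]] - d[["M2"]]) / d[["M1"]] * 100
}

#' Per-sample JI-U values and cohort median
#'
#' @param samples Named (or unnamed) list of [meth_call_table()] objects.
#' @return List with `values` (named numeric) and `median`.
#' @export
cohort_ji_u <- function(samples) {
  stopifnot(length(samples) >= 1L)
  ids <- names(samples) %||% as.character(seq_along(samples))
  values <- vapply(seq_along(samples), function(i) {
    tryCatch(ji_u(samples[[i]]), ucfrag_error = function(e) {
      ucfrag_error(sprintf("sample '%s': %s", ids[i], conditionMessage(e)),
                   class(e)[1])
    })
  }, numeric(1))
  names(values) <- ids
  list(values = values, median = stats::median(values))
}
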