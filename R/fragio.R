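# fragio: on-disk formats with fixed coordinate conventions.
#
# All coordinates are 0-based half-open (BED native). A fragment of length
# L starting at s covers bases s .. s+L-1; its two end positions are s (the
# upstream, plus-strand 5' end) and s+L-1 (the last covered base). Every
# reader is total over its stated format: any accepted file re-serialises
# to an equivalent file.

# Fragments longer than this are dropped at read time (standard insert
# filter for paired-end libraries).
MAX_FRAGMENT_LENGTH <- 600L

#' Read a FASTA file
#'
#' Reads a (multi-record) FASTA file into a named character vector of
#' uppercase base strings. Sequence names are taken from the header line up
#' to the first whitespace. Only the alphabet A/C/G/T/N is accepted.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one uppercase string per record.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    ucfrag_error(sprintf("FASTA file not found: %s", path), "ucfrag_format_error")
  }
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) {
      ucfrag_error(sprintf("malformed FASTA '%s': %s", path, conditionMessage(e)),
                   "ucfrag_format_error")
    }
  )
  if (length(seqs) == 0L) {
    ucfrag_error(sprintf("empty FASTA file: %s", path), "ucfrag_format_error")
  }
  af <- Biostrings::alphabetFrequency(seqs)
  allowed <- c("A", "C", "G", "T", "N")
  bad <- rowSums(af[, setdiff(colnames(af), allowed), drop = FALSE])
  if (any(bad > 0)) {
    ucfrag_error(sprintf("FASTA '%s': sequence '%s' contains bases outside A/C/G/T/N",
                         path, names(seqs)[which(bad > 0)[1]]),
                 "ucfrag_format_error")
  }
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  if (any(!nzchar(names(out)))) {
    ucfrag_error(sprintf("FASTA '%s': empty sequence name", path), "ucfrag_format_error")
  }
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of base strings.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  x <- Biostrings::DNAStringSet(toupper(seqs))
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

new_dhs_set <- function(intervals, genome_length = NA_integer_) {
  intervals <- intervals[order(intervals$chrom, intervals$start), , drop = FALSE]
  rownames(intervals) <- NULL
  structure(
    list(
      intervals = intervals,
      centers = (intervals$start + intervals$end) %/% 2L
    ),
    genome_length = genome_length,
    class = "dhs_set"
  )
}

#' Construct a DHS interval set
#'
#' Intervals are 0-based half-open and get sorted by (chrom, start). The
#' center of each interval is the floor midpoint `(start + end) %/% 2`.
#'
#' @param chrom Character vector of sequence names.
#' @param start,end Integer vectors of 0-based half-open coordinates.
#' @return A `dhs_set`: list with `intervals` (data.frame chrom/start/end)
#'   and `centers` (integer, aligned with the sorted intervals).
#' @export
dhs_set <- function(chrom, start, end) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(!nzchar(chrom))) ucfrag_error("empty chrom name", "ucfrag_record_error")
  if (any(start < 0L) || any(end <= start)) {
    ucfrag_error("invalid interval: need start >= 0 and end > start",
                 "ucfrag_record_error")
  }
  new_dhs_set(data.frame(chrom = as.character(chrom), start = start, end = end,
                         stringsAsFactors = FALSE))
}

#' @export
print.dhs_set <- function(x, ...) {
  cat(sprintf("<dhs_set> %d intervals on %d sequence(s)\n",
              nrow(x$intervals), length(unique(x$intervals$chrom))))
  invisible(x)
}

#' Read DHS intervals from a BED file
#'
#' Accepts BED3+ (extra columns ignored, `#`/track/browser lines skipped).
#' Records with negative coordinates or `start >= end` raise a record-level
#' error naming the offending line.
#'
#' @param path Path to a BED file.
#' @return A [dhs_set()].
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) {
    ucfrag_error(sprintf("BED '%s': no interval records", path), "ucfrag_format_error")
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols < 3L)) {
    ucfrag_error(sprintf("BED '%s' line %d: fewer than 3 tab-separated columns",
                         path, lineno[which(ncols < 3L)[1]]),
                 "ucfrag_format_error")
  }
  chrom <- vapply(parts, `[`, character(1), 1L)
  s_chr <- vapply(parts, `[`, character(1), 2L)
  e_chr <- vapply(parts, `[`, character(1), 3L)
  bad_int <- !grepl("^-?[0-9]+$", s_chr) | !grepl("^-?[0-9]+$", e_chr)
  if (any(bad_int)) {
    ucfrag_error(sprintf("BED '%s' line %d: non-integer coordinate",
                         path, lineno[which(bad_int)[1]]),
                 "ucfrag_record_error")
  }
  start <- as.integer(s_chr)
  end <- as.integer(e_chr)
  bad <- start < 0L | end <= start
  if (any(bad)) {
    ucfrag_error(sprintf("BED '%s' line %d: invalid interval [%d, %d)",
                         path, lineno[which(bad)[1]],
                         start[which(bad)[1]], end[which(bad)[1]]),
                 "ucfrag_record_error")
  }
  dhs_set(chrom, start, end)
}

#' Write a DHS set to BED3
#'
#' @param dhs A [dhs_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(dhs, path) {
  stopifnot(inherits(dhs, "dhs_set"))
  data.table::fwrite(dhs$intervals[, c("chrom", "start", "end")], path,
                     sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

new_fragments <- function(chrom, start, end) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start),
                   end = as.integer(end),
                   stringsAsFactors = FALSE)
  df$length <- df$end - df$start
  class(df) <- c("fragments", "data.frame")
  df
}

#' Construct a fragment table
#'
#' @param chrom,start,end Vectors of coordinates (0-based half-open).
#' @return A `fragments` data.frame with columns chrom, start, end, length.
#' @export
fragments <- function(chrom, start, end) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(start < 0L) || any(end <= start)) {
    ucfrag_error("invalid fragment: need start >= 0 and end > start",
                 "ucfrag_record_error")
  }
  new_fragments(chrom, start, end)
}

#' Read aligned fragments from a BED3-style TSV
#'
#' One fragment per line (chrom, 0-based start, half-open end); a single
#' optional header line starting with `#` is skipped. Fragments with length
#' outside 1..600 bp are dropped and counted; the drop count is reported via
#' a message and stored in the `n_dropped` attribute.
#'
#' @param path Path to a fragment TSV.
#' @param max_length Upper insert-size bound (default 600 bp).
#' @return A `fragments` data.frame (chrom, start, end, length).
#' @export
read_fragments <- function(path, max_length = MAX_FRAGMENT_LENGTH) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) {
    ucfrag_error(sprintf("fragment file '%s': no records", path), "ucfrag_format_error")
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3L)) {
    ucfrag_error(sprintf("fragment file '%s' line %d: fewer than 3 columns",
                         path, lineno[which(lengths(parts) < 3L)[1]]),
                 "ucfrag_format_error")
  }
  chrom <- vapply(parts, `[`, character(1), 1L)
  s_chr <- vapply(parts, `[`, character(1), 2L)
  e_chr <- vapply(parts, `[`, character(1), 3L)
  bad_int <- !grepl("^-?[0-9]+$", s_chr) | !grepl("^-?[0-9]+$", e_chr)
  if (any(bad_int)) {
    ucfrag_error(sprintf("fragment file '%s' line %d: non-integer coordinate",
                         path, lineno[which(bad_int)[1]]),
                 "ucfrag_parse_error")
  }
  start <- as.integer(s_chr)
  end <- as.integer(e_chr)
  bad <- start < 0L | end <= start
  if (any(bad)) {
    ucfrag_error(sprintf("fragment file '%s' line %d: invalid fragment [%d, %d)",
                         path, lineno[which(bad)[1]],
                         start[which(bad)[1]], end[which(bad)[1]]),
                 "ucfrag_record_error")
  }
  len <- end - start
  drop <- len > max_length | len < 1L
  n_dropped <- sum(drop)
  if (n_dropped > 0L) {
    message(sprintf("read_fragments: dropped %d of %d fragments outside 1..%d bp",
                    n_dropped, length(len), max_length))
  }
  out <- new_fragments(chrom[!drop], start[!drop], end[!drop])
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write fragments to a BED3-style TSV
#'
#' @param frags A `fragments` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(frags, path) {
  stopifnot(is.data.frame(frags))
  write_hashed_tsv(frags[, c("chrom", "start", "end")], path,
                   "#chrom\tstart\tend")
}

VALID_END_TAGS <- c("five_prime", "three_prime")
JAGGED_WINDOW <- 30L

#' Read a per-fragment methylation-call table
#'
#' TSV with columns fragment_id, end_tag (`five_prime`/`three_prime`),
#' offset (0-based bp distance from that end, 0..29) and call (`M`/`U`),
#' plus one `#`-prefixed header line. Calls are pooled into a
#' [meth_call_table()]; the raw calls are retained in the `$calls` field.
#'
#' @param path Path to a methylation-call TSV.
#' @return A `meth_call_table`.
#' @export
read_meth_calls <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) {
    ucfrag_error(sprintf("methylation-call file '%s': no records", path),
                 "ucfrag_format_error")
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 4L)) {
    ucfrag_error(sprintf("methylation-call file '%s' line %d: fewer than 4 columns",
                         path, lineno[which(lengths(parts) < 4L)[1]]),
                 "ucfrag_format_error")
  }
  frag <- vapply(parts, `[`, character(1), 1L)
  end_tag <- vapply(parts, `[`, character(1), 2L)
  off_chr <- vapply(parts, `[`, character(1), 3L)
  call <- vapply(parts, `[`, character(1), 4L)
  bad_tag <- !(end_tag %in% VALID_END_TAGS)
  if (any(bad_tag)) {
    ucfrag_error(sprintf("methylation-call file '%s' line %d: unknown end_tag '%s'",
                         path, lineno[which(bad_tag)[1]], end_tag[which(bad_tag)[1]]),
                 "ucfrag_parse_error")
  }
  bad_call <- !(call %in% c("M", "U"))
  if (any(bad_call)) {
    ucfrag_error(sprintf("methylation-call file '%s' line %d: unknown call token '%s'",
                         path, lineno[which(bad_call)[1]], call[which(bad_call)[1]]),
                 "ucfrag_parse_error")
  }
  bad_off <- !grepl("^[0-9]+$", off_chr)
  if (any(bad_off)) {
    ucfrag_error(sprintf("methylation-call file '%s' line %d: non-integer offset",
                         path, lineno[which(bad_off)[1]]),
                 "ucfrag_parse_error")
  }
  offset <- as.integer(off_chr)
  oob <- offset >= JAGGED_WINDOW
  if (any(oob)) {
    ucfrag_error(sprintf(
      "methylation-call file '%s' line %d: offset %d outside 0..%d",
      path, lineno[which(oob)[1]], offset[which(oob)[1]], JAGGED_WINDOW - 1L),
      "ucfrag_parse_error")
  }
  calls <- data.frame(fragment_id = frag, end_tag = end_tag,
                      offset = offset, call = call, stringsAsFactors = FALSE)
  meth_call_table_from_calls(calls)
}

#' Write methylation calls to TSV
#'
#' Accepts either a raw calls data.frame (fragment_id, end_tag, offset,
#' call) or a `meth_call_table` that retains its `$calls`.
#'
#' @param x Calls data.frame or `meth_call_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_meth_calls <- function(x, path) {
  calls <- if (inherits(x, "meth_call_table")) x$calls else x
  if (is.null(calls)) {
    ucfrag_error("no per-call rows available to write", "ucfrag_format_error")
  }
  write_hashed_tsv(calls[, c("fragment_id", "end_tag", "offset", "call")],
                   path, "#fragment_id\tend_tag\toffset\tcall")
}
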