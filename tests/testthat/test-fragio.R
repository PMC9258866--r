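test_that("read_fasta parses records, folds case and takes names to first whitespace", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1 some description", "ACGT"), f)
  g <- read_fasta(f)
  expect_identical(g, c(chr1 = "ACGT"))

  writeLines(c(">a", "ac", "gt", ">b", "NNNN"), f)
  g <- read_fasta(f)
  expect_identical(g, c(a = "ACGT", b = "NNNN"))
})

test_that("read_fasta rejects empty files and foreign alphabets", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(0), f)
  expect_error(read_fasta(f), class = "ucfrag_format_error")
  writeLines(c(">x", "ACGR"), f)
  expect_error(read_fasta(f), class = "ucfrag_format_error")
})

test_that("FASTA round-trips through write_fasta/read_fasta", {
  f <- withr::local_tempfile(fileext = ".fa")
  for (seed in 1:3) {
    g <- c(toy_genome(137, seed, "s1"), toy_genome(64, seed + 10, "s2"))
    write_fasta(g, f)
    expect_identical(read_fasta(f), g)
  }
})

test_that("read_bed computes floor-midpoint centers and sorts intervals", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t300", f)
  d <- read_bed(f)
  expect_equal(d$centers, 200L)

  writeLines("chr1\t100\t301", f)
  expect_equal(read_bed(f)$centers, 200L)  # floor of 200.5

  writeLines(c("chr2\t50\t80\textra\tcols", "chr1\t500\t600", "chr1\t10\t30"), f)
  d <- read_bed(f)
  expect_equal(d$intervals$chrom, c("chr1", "chr1", "chr2"))
  expect_equal(d$intervals$start, c(10L, 500L, 50L))
})

test_that("read_bed reports record-level errors with line numbers", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t30", "chr1\t300\t200"), f)
  expect_error(read_bed(f), "line 2", class = "ucfrag_record_error")
  writeLines(c("chr1\t-5\t30"), f)
  expect_error(read_bed(f), class = "ucfrag_record_error")
  writeLines(c("chr1\tten\t30"), f)
  expect_error(read_bed(f), class = "ucfrag_record_error")
})

test_that("read_fragments filters the insert size and counts drops", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#chrom\tstart\tend",
               "chr1\t10\t176",
               "chr1\t1000\t1700",
               "chr1\t0\t46"), f)
  expect_message(fr <- read_fragments(f), "dropped 1 of 3")
  expect_equal(nrow(fr), 2L)
  expect_equal(attr(fr, "n_dropped"), 1L)
  expect_equal(fr$length, c(166L, 46L))
})

test_that("read_fragments flags parse errors with line numbers", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chr1\t10\t20", "chr1\tx\t30"), f)
  expect_error(read_fragments(f), "line 2", class = "ucfrag_parse_error")
})

test_that("fragment tables round-trip bit-exactly", {
  f <- withr::local_tempfile(fileext = ".tsv")
  g <- toy_genome(5000, 7)
  fr <- random_fragments(g, 200, seed = 8)
  write_fragments(fr, f)
  back <- read_fragments(f)
  expect_equal(back$chrom, fr$chrom)
  expect_equal(back$start, fr$start)
  expect_equal(back$end, fr$end)
  # and the serialization is canonical: writing again gives identical bytes
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_fragments(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("read_meth_calls aggregates per end and validates tokens", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#fragment_id\tend_tag\toffset\tcall",
               "f1\tfive_prime\t0\tM",
               "f1\tfive_prime\t12\tM",
               "f2\tfive_prime\t3\tM",
               "f2\tfive_prime\t29\tM"), f)
  tab <- read_meth_calls(f)
  expect_equal(tab$m1_meth, 4L)
  expect_equal(tab$m1_total, 4L)
  expect_equal(tab$m2_total, 0L)

  writeLines(c("f1\tfive_prime\t30\tM"), f)
  expect_error(read_meth_calls(f), "offset 30", class = "ucfrag_parse_error")
  writeLines(c("f1\tmiddle\t3\tM"), f)
  expect_error(read_meth_calls(f), class = "ucfrag_parse_error")
  writeLines(c("f1\tfive_prime\t3\tX"), f)
  expect_error(read_meth_calls(f), class = "ucfrag_parse_error")
})

test_that("methylation calls round-trip through write_meth_calls", {
  calls <- data.frame(
    fragment_id = c("f1", "f1", "f2", "f2"),
    end_tag = c("five_prime", "three_prime", "five_prime", "three_prime"),
    offset = c(0L, 5L, 12L, 29L),
    call = c("M", "U", "M", "M"),
    stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_meth_calls(calls, f)
  back <- read_meth_calls(f)
  expect_equal(back$calls, calls)
  expect_equal(back$m1_meth, 2L)
  expect_equal(back$m2_meth, 1L)
  expect_equal(back$m2_total, 2L)
})
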