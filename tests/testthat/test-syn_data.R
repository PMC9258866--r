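test_that("make_genome is deterministic, respects GC and injects N blocks", {
  g1 <- make_genome(20000, seed = 1)
  g2 <- make_genome(20000, seed = 1)
  expect_identical(g1, g2)
  expect_false(identical(g1, make_genome(20000, seed = 2)))

  g <- make_genome(1e5, gc = 0.42, seed = 3)
  bases <- strsplit(g[[1]], "")[[1]]
  gc_emp <- mean(bases %in% c("C", "G"))
  se <- sqrt(0.42 * 0.58 / 1e5)
  expect_lt(abs(gc_emp - 0.42), 3 * se)

  gn <- make_genome(2000, seed = 4, n_blocks = list(c(100, 50)))
  expect_equal(substr(gn[[1]], 101, 150), strrep("N", 50))
  expect_false(grepl("N", substr(gn[[1]], 1, 100)))
  expect_error(make_genome(500), class = "ucfrag_parameter_error")
})

test_that("make_dhs packs spaced windows with the advertised coverage", {
  g <- make_genome(1e6, seed = 5)
  d <- make_dhs(g, n = 75, seed = 6)
  expect_equal(nrow(d$intervals), 75L)
  expect_true(all(diff(sort(d$centers)) >= 4000))
  expect_true(all(d$centers >= 1500 & d$centers <= 1e6 - 1500))
  expect_equal(attr(d, "coverage_1kb"), 75 * 2000 / 1e6)
  expect_identical(make_dhs(g, n = 75, seed = 6)$centers, d$centers)
  expect_error(make_dhs(g, n = 500, seed = 1), class = "ucfrag_parameter_error")
})

test_that("calibration resolves p_dhs, sigma_dhs and jagged_q from targets", {
  w <- acceptance_world()
  g <- attr(w$dhs, "coverage_1kb")
  cal <- w$presets$mouse_wt
  expect_equal(cal$p_dhs, (0.189 - g) / (1 - g), tolerance = 1e-12)
  expect_equal(cal$p_dhs, 0.0459, tolerance = 1e-3)

  # the closed form reproduces the central-density target at the solved sigma
  for (p in names(w$presets)) {
    cal <- w$presets[[p]]
    prof <- expected_dhs_profile(cal$sigma_dhs, cal$p_dhs, cal,
                                 nrow(w$dhs$intervals), 1e7)
    expect_lt(abs(prof$central_density - cal$center_density_target), 0.1)
  }

  # jagged_q: degenerate target forces L == 0; targets invert exactly
  expect_equal(calibrate_jagged_q(0), 0)
  q <- calibrate_jagged_q(28.2)
  expect_equal(100 * q * (1 - q^30) / (1 - q) / 30, 28.2, tolerance = 1e-6)

  # unreachable central-density target is a calibration error
  bad <- ucfrag_preset("mouse_wt")
  bad$center_density_target <- 1000
  expect_error(calibrate_preset(bad, w$dhs), class = "ucfrag_calibration_error")
})

test_that("simulated fragments recover mixture masses and end-base law", {
  w <- acceptance_world()
  cal <- w$presets$mouse_dnase1_ko
  fr <- simulate_fragments(cal, w$genome, w$dhs, 30000, seed = 7)
  expect_true(all(fr$start >= 0 & fr$end <= nchar(w$genome[[1]])))
  expect_true(all(fr$length >= 20 & fr$length <= 600))

  b <- size_bins(size_histogram(fr))
  se <- sqrt(0.3 * 0.7 / 30000)
  expect_lt(abs(b[["p_short"]] - cal$size_masses[["short"]]), 3 * se)
  expect_lt(abs(b[["p_long"]] - cal$size_masses[["long"]]), 3 * se)

  sp <- end_motifs(fr, w$genome)
  se_t <- sqrt(0.25 * 0.75 / (2 * 30000))
  expect_lt(abs(t_end_fraction(sp) - cal$p_t), 3 * se_t + 1e-3)

  expect_identical(simulate_fragments(cal, w$genome, w$dhs, 500, seed = 8),
                   simulate_fragments(cal, w$genome, w$dhs, 500, seed = 8))
})

test_that("p_dhs = 0 gives a flat profile and proportion near g", {
  w <- acceptance_world()
  null <- w$presets$mouse_wt
  null$p_dhs <- 0
  fr <- simulate_fragments(null, w$genome, w$dhs, 30000, seed = 9)
  g <- attr(w$dhs, "coverage_1kb")
  se <- sqrt(g * (1 - g) / (2 * 30000))
  expect_lt(abs(dhs_end_proportion(fr, w$dhs) - g), 3.5 * se)
})

test_that("simulated methylation calls obey the jagged-end model", {
  p <- ucfrag_preset("mouse_wt")
  p$jagged_q <- 0
  calls <- simulate_meth_calls(p, 5000, seed = 10)
  expect_true(all(calls$offset >= 0 & calls$offset <= 29))
  expect_true(all(calls$end_tag %in% c("five_prime", "three_prime")))
  # no fill-in: both ends share the methylation law, JI-U ~ 0
  expect_lt(abs(ji_u(meth_call_table_from_calls(calls))), 3)

  p$jagged_q <- 0.85
  expected <- 100 * (0.85 * (1 - 0.85^30) / (1 - 0.85)) / 30
  calls <- simulate_meth_calls(p, 20000, seed = 11)
  expect_lt(abs(ji_u(meth_call_table_from_calls(calls)) - expected), 1.5)
})

test_that("simulate_cohort draws the requested groups deterministically", {
  coh <- simulate_cohort(seed = 12)
  expect_equal(sum(coh$label == "control"), 46L)
  expect_equal(sum(coh$label == "cancer"), 39L)
  expect_identical(coh, simulate_cohort(seed = 12))

  flat <- simulate_cohort(n_control = 400, n_cancer = 400,
                          effect = c(dhs_prop = 0, ji_u = 0,
                                     motif_ratio = 0, concentration = 0),
                          seed = 13)
  expect_lt(abs(auc(flat$dhs_prop, flat$label)$auc_case_high - 0.5), 0.05)
})

test_that("generator writes outputs with provenance sidecars", {
  w <- acceptance_world()
  out <- withr::local_tempdir()
  simulate_fragments(w$presets$mouse_wt, w$genome, w$dhs, 200, seed = 14,
                     write_to = out)
  expect_true(file.exists(file.path(out, "fragments.tsv")))
  prov <- jsonlite::read_json(file.path(out, "fragments.provenance.json"))
  expect_equal(prov$seed, 14)
  expect_equal(prov$preset$name, "mouse_wt")
  expect_true(!is.null(prov$counters$n_match_failures))
})
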