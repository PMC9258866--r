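test_that("mann_whitney_u reports min-U and the exact enumeration p-value", {
  res <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(res$U, 0)
  expect_equal(res$p_value, 1 / 3)
  expect_equal(res$method, "exact")
})

test_that("identical samples give p = 1 with a degenerate warning", {
  expect_warning(res <- mann_whitney_u(c(2, 2), c(2, 2, 2)),
                 class = "ucfrag_degenerate_test_warning")
  expect_equal(res$p_value, 1)
})

test_that("exact p matches the enumeration oracle on random splits", {
  set.seed(9)
  for (i in 1:4) {
    vals <- round(stats::rnorm(8), 1)  # rounding forces occasional ties
    x <- vals[1:3]
    y <- vals[4:8]
    expect_equal(mann_whitney_u(x, y)$p_value, oracle_mw_p(x, y))
  }
})

test_that("the large-sample branch matches the tie-corrected normal test", {
  set.seed(10)
  x <- round(stats::rnorm(20), 1)
  y <- round(stats::rnorm(25, 0.4), 1)
  res <- mann_whitney_u(x, y)
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(res$method, "normal_tie_corrected")
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("auc matches brute-force pair counting and handles orientation", {
  scores <- c(0.1, 0.8, 0.2, 0.9)
  labels <- c("control", "control", "cancer", "cancer")
  res <- auc(scores, labels)
  expect_equal(res$auc_case_high, 0.75)
  expect_equal(res$auc, 0.75)
  expect_equal(res$direction, "case_high")
  expect_equal(res$auc_case_high, oracle_auc(scores, labels, "cancer"))

  # perfect separation and the flipped direction
  expect_equal(auc(c(1, 2, 3, 4), c("a", "a", "b", "b"))$auc, 1.0)
  flip <- auc(c(4, 3, 2, 1), c("a", "a", "b", "b"))
  expect_equal(flip$auc, 1.0)
  expect_equal(flip$direction, "case_low")
  expect_error(auc(1:4, rep("a", 4)), class = "ucfrag_class_error")
})

test_that("auc equals U / (n1 n2) and is monotone-invariant", {
  set.seed(12)
  scores <- round(stats::rnorm(30), 1)
  labels <- rep(c("control", "cancer"), 15)
  res <- auc(scores, labels)
  mw <- mann_whitney_u(scores[labels == "cancer"], scores[labels == "control"])
  expect_equal(res$auc_case_high, mw$U_x / (15 * 15))
  expect_equal(auc(exp(scores), labels)$auc_case_high, res$auc_case_high)
  expect_equal(auc(rank(scores), labels)$auc_case_high, res$auc_case_high)
})

test_that("random scores on balanced labels give AUC near 0.5", {
  set.seed(13)
  scores <- stats::rnorm(2000)
  labels <- rep(c("control", "cancer"), 1000)
  expect_lt(abs(auc(scores, labels)$auc_case_high - 0.5), 0.03)
})

test_that("loo_svm separates well-separated clusters and not shuffled ones", {
  set.seed(14)
  n <- 20
  df <- data.frame(
    id = sprintf("s%02d", 1:(2 * n)),
    label = factor(rep(c("control", "cancer"), each = n),
                   levels = c("control", "cancer")),
    f1 = c(stats::rnorm(n, 0), stats::rnorm(n, 4)),
    f2 = c(stats::rnorm(n, 0), stats::rnorm(n, 4)))
  res <- loo_svm(df, c("f1", "f2"))
  expect_gt(res$auc, 0.95)
  expect_named(res$decision_values, df$id)

  df$label <- sample(df$label)
  res0 <- loo_svm(df, c("f1", "f2"))
  expect_lt(abs(res0$auc - 0.5), 0.25)
})

test_that("loo_svm names the subject when a fold loses a class", {
  df <- data.frame(id = c("a", "b", "c"),
                   label = c("control", "control", "cancer"),
                   f1 = c(0, 1, 5))
  expect_error(loo_svm(df, "f1"), "c", class = "ucfrag_fold_error")
})

test_that("loo_cutoffs are Youden-optimal, stable and within range", {
  scores <- c(0, 0.1, 0.2, 0.3, 2.0, 2.1, 2.2, 2.3)
  labels <- rep(c("control", "cancer"), each = 4)
  res <- loo_cutoffs(scores, labels)
  expect_length(res$cutoffs, 8L)
  expect_true(all(res$cutoffs >= min(scores) & res$cutoffs <= max(scores)))
  # the class gap is 0.3..2.0; every training fold should cut inside it
  expect_true(all(res$cutoffs > 0.3 & res$cutoffs < 2.0))
  expect_lt(res$sd, (2.0 - 0.3) / 4)

  const <- loo_cutoffs(rep(1, 6), rep(c("control", "cancer"), 3))
  expect_equal(const$sd, 0)
  expect_equal(unique(const$cutoffs), 1)
})

test_that("normalize_concentration derives the ratio and logs exclusions", {
  df <- data.frame(id = c("a", "b"), label = c("control", "cancer"),
                   dhs_prop = c(0.2, 0.1), ji_u = c(28, 30),
                   motif_ratio = c(1, 1.1), conc = c(10, 8),
                   creatinine = c(2, NA))
  expect_message(out <- normalize_concentration(df), "1 subject")
  expect_equal(out$conc_per_creatinine, c(5, NA))
  expect_equal(attr(out, "n_excluded"), 1L)

  # AUC remains computable on the creatinine subset
  coh <- simulate_cohort(seed = 99)
  coh <- suppressMessages(normalize_concentration(coh))
  sub <- coh[!is.na(coh$conc_per_creatinine), ]
  expect_true(is.finite(auc(sub$conc_per_creatinine, sub$label)$auc))
})

test_that("subject feature tables round-trip through TSV", {
  coh <- simulate_cohort(n_control = 10, n_cancer = 8, seed = 3)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_subject_features(coh, f)
  back <- read_subject_features(f)
  expect_equal(as.character(back$label), as.character(coh$label))
  expect_equal(back$dhs_prop, coh$dhs_prop, tolerance = 1e-12)
  expect_equal(back$creatinine, coh$creatinine, tolerance = 1e-12)
})
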