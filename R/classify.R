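# classify: subject-level features, Mann-Whitney tests, ROC/AUC,
# leave-one-out linear SVM and per-iteration Youden cutoffs.

#' Read a subject feature table
#'
#' TSV with a single `#`-prefixed header line and columns id, label,
#' dhs_prop, ji_u, motif_ratio, conc, creatinine (creatinine may be `NA`).
#'
#' @param path Path to the TSV.
#' @return A `subject_features` data.frame; `label` is a factor with levels
#'   control < cancer.
#' @export
read_subject_features <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#")) {
    ucfrag_error(sprintf("subject file '%s': missing '#' header line", path),
                 "ucfrag_format_error")
  }
  cols <- strsplit(sub("^#", "", first), "\t", fixed = TRUE)[[1]]
  df <- utils::read.table(path, sep = "\t", skip = 1L, header = FALSE,
                          col.names = cols, stringsAsFactors = FALSE,
                          na.strings = "NA")
  need <- c("id", "label", "dhs_prop", "ji_u", "motif_ratio", "conc", "creatinine")
  if (!all(need %in% names(df))) {
    ucfrag_error(sprintf("subject file '%s': missing columns %s", path,
                         paste(setdiff(need, names(df)), collapse = ", ")),
                 "ucfrag_format_error")
  }
  if (!all(df$label %in% c("control", "cancer"))) {
    ucfrag_error(sprintf("subject file '%s': labels must be control/cancer", path),
                 "ucfrag_parse_error")
  }
  df$label <- factor(df$label, levels = c("control", "cancer"))
  class(df) <- c("subject_features", "data.frame")
  df
}

#' Write a subject feature table
#'
#' @param features A `subject_features` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_subject_features <- function(features, path) {
  cols <- c("id", "label", "dhs_prop", "ji_u", "motif_ratio", "conc", "creatinine")
  df <- as.data.frame(features)[, cols]
  df$label <- as.character(df$label)
  write_hashed_tsv(df, path, paste0("#", paste(cols, collapse = "\t")))
}

#' Mann-Whitney U test
#'
#' Reports the min-U statistic (`min(U_x, U_y)`, ties counted half) and a
#' two-sided p-value: exact enumeration of all label assignments when
#' `length(x) + length(y) <= 12` (so ties are handled exactly), otherwise
#' the normal approximation with tie correction (no continuity correction).
#'
#' @param x,y Numeric samples.
#' @param exact_max Combined size up to which the exact enumeration is used.
#' @return List with `U` (min-U), `U_x` (number of (x, y) pairs with
#'   x > y, ties half), `p_value` and `method`.
#' @export
mann_whitney_u <- function(x, y, exact_max = 12L) {
  if (length(x) == 0L || length(y) == 0L) {
    ucfrag_error("mann_whitney_u: both samples must be nonempty",
                 "ucfrag_empty_sample_error")
  }
  n1 <- length(x); n2 <- length(y)
  if (length(unique(c(x, y))) == 1L) {
    ucfrag_warning("mann_whitney_u: all values identical; p = 1",
                   "ucfrag_degenerate_test_warning")
    return(list(U = n1 * n2 / 2, U_x = n1 * n2 / 2, p_value = 1,
                method = "degenerate"))
  }
  u_stat <- function(xv, yv) {
    # U_x = #{x_i > y_j} + 0.5 #{x_i == y_j}, via midranks
    r <- rank(c(xv, yv))
    sum(r[seq_along(xv)]) - length(xv) * (length(xv) + 1) / 2
  }
  u_x <- u_stat(x, y)
  u_min <- min(u_x, n1 * n2 - u_x)
  if (n1 + n2 <= exact_max) {
    pool <- c(x, y)
    idx <- utils::combn(n1 + n2, n1)
    us <- apply(idx, 2L, function(ii) {
      ux <- u_stat(pool[ii], pool[-ii])
      min(ux, n1 * n2 - ux)
    })
    p <- mean(us <= u_min + 1e-9)
    method <- "exact"
  } else {
    n <- n1 + n2
    ties <- table(c(x, y))
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    z <- (u_x - n1 * n2 / 2) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal_tie_corrected"
  }
  list(U = u_min, U_x = u_x, p_value = min(p, 1), method = method)
}

#' Area under the ROC curve
#'
#' Rank-statistic AUC: the probability that a random case scores above a
#' random control, ties counted half. The oriented AUC (>= 0.5) is reported
#' together with its direction; `auc_case_high` is the unoriented value.
#'
#' @param scores Numeric scores.
#' @param labels Two-class labels (factor or character).
#' @param positive Label of the case class; defaults to `"cancer"` when
#'   present, otherwise the last factor level.
#' @return List with `auc` (oriented, >= 0.5), `direction`
#'   (`"case_high"`/`"case_low"`), `auc_case_high`, `n_case`, `n_control`.
#' @export
auc <- function(scores, labels, positive = NULL) {
  labels <- as.character(labels)
  lv <- sort(unique(labels))
  if (length(lv) != 2L) {
    ucfrag_error("auc: need exactly two classes in labels", "ucfrag_class_error")
  }
  if (is.null(positive)) positive <- if ("cancer" %in% lv) "cancer" else lv[2]
  case <- labels == positive
  n1 <- sum(case); n0 <- sum(!case)
  r <- rank(scores)
  a <- (sum(r[case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(auc = max(a, 1 - a),
       direction = if (a >= 0.5) "case_high" else "case_low",
       auc_case_high = a,
       n_case = n1, n_control = n0)
}

# z-score parameters from a training matrix; zero-variance columns get
# scale 1 so they pass through unchanged.
zscore_fit <- function(m) {
  mu <- colMeans(m)
  sd <- apply(m, 2L, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(mu = mu, sd = sd)
}

zscore_apply <- function(m, fit) {
  sweep(sweep(m, 2L, fit$mu, "-"), 2L, fit$sd, "/")
}

#' Leave-one-out linear-SVM classification
#'
#' For each held-out subject, z-score standardisation is fitted on the
#' training fold, a linear-kernel SVM (C = 1) is trained, and the held-out
#' decision value recorded; the ROC/AUC is computed on the pooled
#' out-of-fold decision values, oriented so that higher = case.
#'
#' @param features A `subject_features` data.frame (or any data.frame with
#'   a `label` column and numeric feature columns).
#' @param feature_names Character vector of feature columns to use.
#' @param cost SVM cost parameter (default 1).
#' @return List with `decision_values` (named by subject id), `labels`,
#'   `auc` (unoriented, case-high) and `auc_result` (full [auc()] output).
#' @export
loo_svm <- function(features, feature_names, cost = 1) {
  df <- as.data.frame(features)
  n <- nrow(df)
  if (n < 3L) {
    ucfrag_error("loo_svm: need at least 3 subjects", "ucfrag_class_error")
  }
  stopifnot(all(feature_names %in% names(df)))
  lab <- factor(as.character(df$label), levels = c("control", "cancer"))
  if (any(is.na(lab))) {
    ucfrag_error("loo_svm: labels must be control/cancer", "ucfrag_class_error")
  }
  x <- as.matrix(df[, feature_names, drop = FALSE])
  if (anyNA(x)) {
    ucfrag_error("loo_svm: missing values in selected features", "ucfrag_class_error")
  }
  ids <- if ("id" %in% names(df)) as.character(df$id) else as.character(seq_len(n))
  dec <- numeric(n)
  for (i in seq_len(n)) {
    tr_lab <- droplevels(lab[-i])
    if (nlevels(tr_lab) < 2L) {
      ucfrag_error(sprintf(
        "loo_svm: training fold for subject '%s' lacks a class", ids[i]),
        "ucfrag_fold_error")
    }
    zs <- zscore_fit(x[-i, , drop = FALSE])
    fit <- e1071::svm(zscore_apply(x[-i, , drop = FALSE], zs), lab[-i],
                      kernel = "linear", cost = cost, scale = FALSE)
    pr <- stats::predict(fit, zscore_apply(x[i, , drop = FALSE], zs),
                         decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    # libsvm signs the decision value toward the first training label;
    # normalise so higher = cancer using the column name "A/B" (positive = A)
    pos_class <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
    dec[i] <- if (pos_class == "cancer") dv[1, 1] else -dv[1, 1]
  }
  names(dec) <- ids
  res <- auc(dec, lab, positive = "cancer")
  list(decision_values = dec, labels = lab,
       auc = res$auc_case_high, auc_result = res)
}

# Youden-optimal threshold on (scores, case indicator): maximises
# sensitivity + specificity - 1 over midpoints between adjacent distinct
# scores (case assumed high); the lowest maximiser is returned.
youden_cutoff <- function(scores, case) {
  s <- sort(unique(scores))
  cand <- if (length(s) == 1L) s else (s[-length(s)] + s[-1]) / 2
  j <- vapply(cand, function(th) {
    sens <- mean(scores[case] > th)
    spec <- mean(scores[!case] <= th)
    sens + spec - 1
  }, numeric(1))
  cand[which.max(j)]
}

#' Per-iteration cutoffs of a leave-one-out analysis
#'
#' For each leave-one-out fold the Youden-optimal threshold (maximum
#' sensitivity + specificity - 1) is computed on the training fold; the
#' per-iteration cutoffs quantify how stable the decision threshold is.
#' Scores are assumed oriented case-high (as [loo_svm()] decision values
#' are); set `positive` to match the case label.
#'
#' @param scores Numeric subject scores.
#' @param labels Two-class labels.
#' @param positive Case label (defaults as in [auc()]).
#' @return List with `cutoffs` (one per fold), `min`, `max`, `sd`.
#' @export
loo_cutoffs <- function(scores, labels, positive = NULL) {
  labels <- as.character(labels)
  lv <- sort(unique(labels))
  if (length(lv) != 2L) {
    ucfrag_error("loo_cutoffs: need exactly two classes", "ucfrag_class_error")
  }
  if (is.null(positive)) positive <- if ("cancer" %in% lv) "cancer" else lv[2]
  case <- labels == positive
  n <- length(scores)
  if (n < 3L) ucfrag_error("loo_cutoffs: need at least 3 subjects", "ucfrag_class_error")
  cuts <- vapply(seq_len(n), function(i) {
    if (length(unique(case[-i])) < 2L) {
      ucfrag_error(sprintf("loo_cutoffs: training fold %d lacks a class", i),
                   "ucfrag_fold_error")
    }
    youden_cutoff(scores[-i], case[-i])
  }, numeric(1))
  list(cutoffs = cuts, min = min(cuts), max = max(cuts), sd = stats::sd(cuts))
}

#' Creatinine-normalized concentration feature
#'
#' Adds `conc_per_creatinine = conc / creatinine`. Subjects with missing or
#' non-positive creatinine get `NA` in the derived feature only; their count
#' is reported via a message and the `n_excluded` attribute.
#'
#' @param features A `subject_features` data.frame.
#' @return The data.frame with the added column.
#' @export
normalize_concentration <- function(features) {
  df <- features
  ok <- !is.na(df$creatinine) & df$creatinine > 0
  df$conc_per_creatinine <- ifelse(ok, df$conc / df$creatinine, NA_real_)
  n_excl <- sum(!ok)
  if (n_excl > 0L) {
    message(sprintf(
      "normalize_concentration: %d subject(s) without usable creatinine excluded from the derived feature",
      n_excl))
  }
  attr(df, "n_excluded") <- n_excl
  df
}

#' ROC points from scores and labels
#'
#' Sensitivity/specificity at every distinct threshold (case assumed high).
#'
#' @param scores Numeric scores.
#' @param labels Two-class labels.
#' @param positive Case label (defaults as in [auc()]).
#' @return Data.frame with columns threshold, sensitivity, specificity.
#' @export
roc_points <- function(scores, labels, positive = NULL) {
  labels <- as.character(labels)
  lv <- sort(unique(labels))
  if (length(lv) != 2L) {
    ucfrag_error("roc_points: need exactly two classes", "ucfrag_class_error")
  }
  if (is.null(positive)) positive <- if ("cancer" %in% lv) "cancer" else lv[2]
  case <- labels == positive
  th <- c(-Inf, sort(unique(scores)), Inf)
  data.frame(
    threshold = th,
    sensitivity = vapply(th, function(t) mean(scores[case] >= t), numeric(1)),
    specificity = vapply(th, function(t) mean(scores[!case] < t), numeric(1))
  )
}
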