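# syn_data: seeded synthetic genome, DHS set, genotype-preset fragment
# samples, methylation-call tables and human-like cohort feature tables.
#
# The generator is first-class: its defaults ARE the study conditions, and
# every preset carries published-median targets that calibrate the free
# sampling parameters so the pipeline can be verified by parameter
# recovery:
#   * size-bin masses are mixture weights over components with disjoint
#     hard supports aligned to the size bins, so bin fractions equal the
#     weights exactly;
#   * p_dhs (probability an end pair is DHS-placed) is solved from the
#     within-DHS proportion target given the realized window coverage g;
#   * sigma_dhs (SD of the truncated-Gaussian placement around a center)
#     is solved by bisection on a closed-form expected end-density profile;
#   * jagged_q (geometric fill-in length parameter) is solved so that the
#     expected JI-U matches the preset target.

SIZE_COMPONENTS <- list(
  short = list(mean = 46, sd = 8, lower = 20L, upper = 49L),
  mid = list(mean = 100, sd = 25, lower = 50L, upper = 150L),
  long = list(lower = 151L, upper = 600L,
              mix = list(list(w = 0.7, mean = 165, sd = 15),
                         list(w = 0.2, mean = 330, sd = 20),
                         list(w = 0.1, mean = 500, sd = 30)))
)

PRESETS <- list(
  mouse_wt = list(
    name = "mouse_wt",
    size_masses = c(short = 0.161, mid = 0.753, long = 0.086),
    p_t = 0.270,
    dhs_prop_target = 0.189,
    center_density_target = 1.71,
    ji_u_target = 28.2
  ),
  mouse_dnase1l3_ko = list(
    name = "mouse_dnase1l3_ko",
    size_masses = c(short = 0.161, mid = 0.753, long = 0.086),
    p_t = 0.278,
    dhs_prop_target = 0.193,
    center_density_target = 1.81,
    ji_u_target = 31.1
  ),
  mouse_dnase1_ko = list(
    name = "mouse_dnase1_ko",
    # short and long carry the published medians; the mid bin takes the
    # compositional remainder (per-sample compositions must sum to 1,
    # published per-bin medians over samples need not)
    size_masses = c(short = 0.299, mid = 0.451, long = 0.250),
    p_t = 0.248,
    dhs_prop_target = 0.238,
    center_density_target = 4.28,
    ji_u_target = 17.8
  )
)

PRESET_COMMON <- list(m_cpg = 0.75, cpg_density = 1 / 15)

#' Names of the built-in genotype presets
#'
#' @return Character vector of preset names.
#' @export
ucfrag_presets <- function() names(PRESETS)

#' Fetch a genotype preset
#'
#' Each preset holds the size-mixture masses, end-base T probability,
#' within-DHS proportion target, central-density target and expected JI-U
#' for one genotype, plus the shared CpG model (`m_cpg = 0.75`,
#' `cpg_density = 1/15`). Sampling parameters `p_dhs`, `sigma_dhs` and
#' `jagged_q` are resolved by [calibrate_preset()].
#'
#' @param name One of [ucfrag_presets()].
#' @return A `ucfrag_preset` list.
#' @export
ucfrag_preset <- function(name) {
  if (!name %in% names(PRESETS)) {
    ucfrag_error(sprintf("unknown preset '%s' (available: %s)", name,
                         paste(names(PRESETS), collapse = ", ")),
                 "ucfrag_parameter_error")
  }
  structure(c(PRESETS[[name]], PRESET_COMMON), class = "ucfrag_preset")
}

#' @export
print.ucfrag_preset <- function(x, ...) {
  cat(sprintf("<ucfrag_preset> %s: size masses (%.3f, %.3f, %.3f), p_T %.3f\n",
              x$name, x$size_masses[1], x$size_masses[2], x$size_masses[3], x$p_t))
  if (!is.null(x$p_dhs)) {
    cat(sprintf("  calibrated: p_dhs %.4f, sigma_dhs %.1f bp, jagged_q %.4f\n",
                x$p_dhs, x$sigma_dhs, x$jagged_q))
  }
  invisible(x)
}

#' Generate a synthetic single-chromosome genome
#'
#' I.i.d. bases at the stated GC content, no Ns by default; `n_blocks`
#' injects N runs (a list of `c(start, length)` pairs, 0-based) for
#' motif-window skipping tests. Deterministic per seed.
#'
#' @param length Genome length in bp (default 10 Mb).
#' @param gc GC content (default 0.42).
#' @param seed Integer seed.
#' @param n_blocks Optional list of `c(start, length)` N-block specs.
#' @return Named character vector `c(chr1 = <sequence>)`.
#' @export
make_genome <- function(length = 1e7, gc = 0.42, seed = NULL, n_blocks = NULL) {
  if (length < 1000) {
    ucfrag_error("make_genome: length must be >= 1 kb", "ucfrag_parameter_error")
  }
  length <- as.integer(length)
  prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  g <- with_seed(seed, {
    idx <- sample.int(4L, length, replace = TRUE, prob = prob)
    rawToChar(charToRaw("ACGT")[idx])
  })
  if (!is.null(n_blocks)) {
    for (blk in n_blocks) {
      s <- blk[1]; l <- blk[2]
      stopifnot(s >= 0, s + l <= length)
      substr(g, s + 1L, s + l) <- strrep("N", l)
    }
  }
  c(chr1 = g)
}

#' Place a synthetic DHS interval set
#'
#' `n` intervals of fixed width, centers at least `min_spacing` apart and at
#' least `margin` bp from the chromosome ends. The realized coverage of
#' +-1 kb windows is stored in the `coverage_1kb` attribute (about 0.15 at
#' the defaults on a 10 Mb genome). Deterministic per seed.
#'
#' @param genome Named character vector (single chromosome used).
#' @param n Number of DHSs (default 750).
#' @param width Interval width in bp (default 400).
#' @param min_spacing Minimum center spacing in bp (default 4000).
#' @param margin Minimum distance of centers from chromosome ends.
#' @param seed Integer seed.
#' @return A [dhs_set()] with attributes `coverage_1kb` and `genome_length`.
#' @export
make_dhs <- function(genome, n = 750L, width = 400L, min_spacing = 4000L,
                     margin = 1500L, seed = NULL) {
  glen <- nchar(genome[[1]])
  a <- margin
  b <- glen - margin
  span <- (b - a) - (n - 1) * min_spacing
  if (span <= 0) {
    ucfrag_error(sprintf(
      "make_dhs: cannot place %d centers with %d bp spacing on a %d bp genome",
      n, min_spacing, glen), "ucfrag_parameter_error")
  }
  centers <- with_seed(seed, {
    u <- sort(stats::runif(n, 0, span))
    as.integer(floor(a + u + (seq_len(n) - 1L) * min_spacing))
  })
  dhs <- dhs_set(chrom = rep(names(genome)[1], n),
                 start = centers - width %/% 2L,
                 end = centers + width %/% 2L)
  attr(dhs, "genome_length") <- glen
  attr(dhs, "coverage_1kb") <- dhs_window_coverage(dhs, glen, window = 1000L)
  dhs
}

# Fraction of the genome covered by the union of +-window windows around
# the DHS centers (clipped to [0, genome_length)).
dhs_window_coverage <- function(dhs, genome_length, window = 1000L) {
  lo <- pmax(sort(dhs$centers) - window, 0L)
  hi <- pmin(sort(dhs$centers) + window, genome_length)
  # merge overlaps
  covered <- 0
  cur_lo <- lo[1]; cur_hi <- hi[1]
  if (length(lo) > 1L) {
    for (i in 2:length(lo)) {
      if (lo[i] <= cur_hi) {
        cur_hi <- max(cur_hi, hi[i])
      } else {
        covered <- covered + (cur_hi - cur_lo)
        cur_lo <- lo[i]; cur_hi <- hi[i]
      }
    }
  }
  covered <- covered + (cur_hi - cur_lo)
  covered / genome_length
}

# Discrete pmf of integer fragment lengths under a preset's size mixture
# (components truncated-normal, integer-rounded).
length_pmf <- function(preset) {
  len <- SIZE_COMPONENTS$short$lower:SIZE_COMPONENTS$long$upper
  p <- numeric(length(len))
  disc <- function(mean, sd, lower, upper) {
    k <- lower:upper
    m <- stats::pnorm(k + 0.5, mean, sd) - stats::pnorm(k - 0.5, mean, sd)
    m / sum(m)
  }
  cs <- SIZE_COMPONENTS$short
  p[len >= cs$lower & len <= cs$upper] <-
    p[len >= cs$lower & len <= cs$upper] +
    preset$size_masses[["short"]] * disc(cs$mean, cs$sd, cs$lower, cs$upper)
  cm <- SIZE_COMPONENTS$mid
  p[len >= cm$lower & len <= cm$upper] <-
    p[len >= cm$lower & len <= cm$upper] +
    preset$size_masses[["mid"]] * disc(cm$mean, cm$sd, cm$lower, cm$upper)
  cl <- SIZE_COMPONENTS$long
  sel <- len >= cl$lower & len <= cl$upper
  for (sub in cl$mix) {
    p[sel] <- p[sel] +
      preset$size_masses[["long"]] * sub$w * disc(sub$mean, sub$sd, cl$lower, cl$upper)
  }
  list(len = len, p = p / sum(p))
}

# Distribution of the +-1 bp end-base matching shift under an i.i.d.
# genome. Candidate offsets are searched in the order 0, +1, -1, +2, -2,
# ...; conditional on the drawn target-base pair, each candidate position
# matches independently with probability pi_gen(b_up) * pi_gen(b_down)
# (complementation preserves the genome base law), so the shift is
# geometric in search order; the marginal kernel is the mixture over the
# 16 target pairs. Residual mass after 2*max_shift+1 candidates is
# accepted as-is at shift 0.
end_match_kernel <- function(p_t, gc, max_shift = 100L) {
  pi_end <- c(A = (1 - p_t) / 3, C = (1 - p_t) / 3, G = (1 - p_t) / 3, T = p_t)
  pi_gen <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  d_order <- c(0L, as.vector(rbind(seq_len(max_shift), -seq_len(max_shift))))
  prob <- stats::setNames(numeric(length(d_order)), as.character(d_order))
  q_bar <- 0
  for (bu in names(pi_end)) {
    for (bd in names(pi_end)) {
      w <- pi_end[[bu]] * pi_end[[bd]]
      q <- pi_gen[[bu]] * pi_gen[[bd]]
      prob <- prob + w * q * (1 - q)^(seq_along(d_order) - 1L)
      prob["0"] <- prob["0"] + w * (1 - q)^length(d_order)
      q_bar <- q_bar + w * q
    }
  }
  d <- (-max_shift):max_shift
  list(d = d, p = as.numeric(prob[as.character(d)]), q = q_bar)
}

# shifted accumulation convolution of two discrete pmfs on integer supports
conv_pmf <- function(xs, xp, ys, yp) {
  lo <- min(xs) + min(ys)
  hi <- max(xs) + max(ys)
  out <- numeric(hi - lo + 1L)
  for (j in seq_along(ys)) {
    idx <- (xs + ys[j]) - lo + 1L
    out[idx] <- out[idx] + xp * yp[j]
  }
  list(s = lo:hi, p = out)
}

#' Closed-form expected DHS end-density profile
#'
#' Deterministic expectation of [end_density_profile()] under the
#' generator's model: a fraction `p_dhs` of fragments has its midpoint at a
#' rounded truncated-Gaussian(0, sigma, +-window) offset from a DHS center,
#' the rest are uniform; each fragment contributes its two end positions
#' (`-floor(L/2)` and `ceil(L/2) - 1` relative to the midpoint, L from the
#' preset's length mixture), convolved with the analytic distribution of
#' the end-base matching shift. Used as the calibration oracle for
#' `sigma_dhs` and as an independent check of the empirical profile.
#'
#' @param sigma Placement SD in bp.
#' @param p_dhs DHS placement probability.
#' @param preset A `ucfrag_preset` (for the length mixture and p_T).
#' @param n_dhs Number of DHSs.
#' @param genome_length Genome length in bp.
#' @param gc Genome GC content.
#' @param window,bin_width As in [end_density_profile()].
#' @return List with `bin_start`, `density`, `mass_per_end` (expected
#'   in-window probability mass per bin per end), `q_window` (probability a
#'   DHS-placed end stays within its window) and `central_density`.
#' @export
expected_dhs_profile <- function(sigma, p_dhs, preset, n_dhs, genome_length,
                                 gc = 0.42, window = 1000L, bin_width = 10L) {
  lp <- length_pmf(preset)
  # integer rounded truncated normal on -window..window
  t <- (-window):window
  z <- stats::pnorm(window, 0, sigma) - stats::pnorm(-window, 0, sigma)
  pt <- (stats::pnorm(pmin(t + 0.5, window), 0, sigma) -
           stats::pnorm(pmax(t - 0.5, -window), 0, sigma)) / z
  # end offsets relative to midpoint: -floor(L/2) and ceil(L/2)-1
  a_val <- -(lp$len %/% 2L)
  b_val <- lp$len - 1L - lp$len %/% 2L
  pa <- tapply(lp$p, a_val, sum)
  pb <- tapply(lp$p, b_val, sum)
  up <- conv_pmf(t, pt, as.integer(names(pa)), as.numeric(pa))
  dn <- conv_pmf(t, pt, as.integer(names(pb)), as.numeric(pb))
  lo <- min(up$s, dn$s); hi <- max(up$s, dn$s)
  mix <- numeric(hi - lo + 1L)
  mix[up$s - lo + 1L] <- mix[up$s - lo + 1L] + 0.5 * up$p
  mix[dn$s - lo + 1L] <- mix[dn$s - lo + 1L] + 0.5 * dn$p
  ker <- end_match_kernel(preset$p_t, gc)
  sm <- conv_pmf(lo:hi, mix, ker$d, ker$p)
  keep <- sm$s >= -window & sm$s < window
  offs <- sm$s[keep]
  mass <- sm$p[keep]
  q_window <- sum(mass)
  nb <- as.integer(2L * window / bin_width)
  bin <- offs %/% bin_width
  mass_bin <- as.numeric(tapply(mass, factor(bin, levels = seq(-window %/% bin_width,
                                                               window %/% bin_width - 1L)),
                                sum))
  mass_bin[is.na(mass_bin)] <- 0
  per_end <- p_dhs * mass_bin + (1 - p_dhs) * bin_width * n_dhs / genome_length
  dens <- per_end / stats::median(per_end)
  bin_start <- seq(-window, window - bin_width, by = bin_width)
  list(bin_start = bin_start, density = dens, mass_per_end = per_end,
       q_window = q_window,
       central_density = dens[bin_start == 0L])
}

# expected capped-geometric fill-in length: L ~ Geom(jagged_q) on {0,1,...}
# (P(L=k) = (1-q) q^k) capped at `cap`; E[min(L, cap)] = q(1-q^cap)/(1-q)
expected_capped_geom <- function(q, cap = 30L) {
  if (q <= 0) return(0)
  q * (1 - q^cap) / (1 - q)
}

#' Solve the jagged-end geometric parameter from a JI-U target
#'
#' Under the generator's model (fill-in bases always unmethylated, interior
#' CpGs methylated with a common probability) the expected JI-U is
#' `100 * E[min(L, 30)] / 30` with `L ~ Geom(q)` capped at 30, independent
#' of the methylation level. This inverts that identity.
#'
#' @param ji_u_target Expected JI-U in percent (0 <= target < 100).
#' @return The geometric parameter `q` in \[0, 1).
#' @export
calibrate_jagged_q <- function(ji_u_target) {
  if (ji_u_target < 0 || ji_u_target >= 100) {
    ucfrag_error("calibrate_jagged_q: target must be in [0, 100)",
                 "ucfrag_calibration_error")
  }
  if (ji_u_target == 0) return(0)
  e_target <- JAGGED_WINDOW * ji_u_target / 100
  stats::uniroot(function(q) expected_capped_geom(q, JAGGED_WINDOW) - e_target,
                 lower = 1e-9, upper = 1 - 1e-9, tol = 1e-10)$root
}

#' Resolve a preset's sampling parameters from its targets
#'
#' Performs the three calibrations described for the generator:
#' `p_dhs = (P_target - g) / (1 - g)` from the within-DHS proportion target
#' and the realized window coverage `g`; `sigma_dhs` by bisection on the
#' closed-form [expected_dhs_profile()] so the expected central-bin density
#' matches the center-density target (the larger-sigma, decreasing branch
#' is used); and `jagged_q` so that `E[min(L, 30)] = 30 * JI-U_target / 100`.
#'
#' @param preset A `ucfrag_preset`.
#' @param dhs A [make_dhs()] DHS set (provides the coverage g).
#' @param genome_length Genome length in bp; defaults to the DHS set's
#'   `genome_length` attribute.
#' @param gc Genome GC content.
#' @param window,bin_width Profile geometry.
#' @return The preset with added fields `p_dhs`, `sigma_dhs`, `jagged_q`,
#'   `g`, `q_window` and `calibrated = TRUE`.
#' @export
calibrate_preset <- function(preset, dhs, genome_length = NULL, gc = 0.42,
                             window = 1000L, bin_width = 10L) {
  stopifnot(inherits(preset, "ucfrag_preset"), inherits(dhs, "dhs_set"))
  genome_length <- genome_length %||% attr(dhs, "genome_length")
  if (is.null(genome_length) || is.na(genome_length)) {
    ucfrag_error("calibrate_preset: genome_length unknown", "ucfrag_parameter_error")
  }
  g <- dhs_window_coverage(dhs, genome_length, window)
  p_dhs <- (preset$dhs_prop_target - g) / (1 - g)
  if (p_dhs < 0 || p_dhs > 1) {
    ucfrag_error(sprintf(
      "calibrate_preset: DHS proportion target %.3f infeasible at coverage g = %.3f",
      preset$dhs_prop_target, g), "ucfrag_calibration_error")
  }
  n_dhs <- nrow(dhs$intervals)
  f <- function(s) {
    expected_dhs_profile(s, p_dhs, preset, n_dhs, genome_length, gc,
                         window, bin_width)$central_density
  }
  grid <- exp(seq(log(5), log(800), length.out = 40))
  vals <- vapply(grid, f, numeric(1))
  target <- preset$center_density_target
  if (max(vals) < target) {
    ucfrag_error(sprintf(
      "calibrate_preset: central-density target %.2f unreachable (max %.2f over sigma grid)",
      target, max(vals)), "ucfrag_calibration_error")
  }
  # bisect on the decreasing branch right of the grid maximum
  i_max <- which.max(vals)
  j <- i_max
  while (j < length(grid) && vals[j + 1] >= target) j <- j + 1
  if (j == length(grid)) {
    ucfrag_error("calibrate_preset: no sigma bracket on decreasing branch",
                 "ucfrag_calibration_error")
  }
  sigma <- stats::uniroot(function(s) f(s) - target,
                          lower = grid[j], upper = grid[j + 1],
                          tol = 1e-3)$root
  jq <- calibrate_jagged_q(preset$ji_u_target)
  out <- preset
  out$p_dhs <- p_dhs
  out$sigma_dhs <- sigma
  out$jagged_q <- jq
  out$g <- g
  out$q_window <- expected_dhs_profile(sigma, p_dhs, preset, n_dhs,
                                       genome_length, gc, window,
                                       bin_width)$q_window
  out$calibrated <- TRUE
  out
}

# draw n integer lengths from a preset's size mixture
sample_lengths <- function(preset, n) {
  comp <- sample.int(3L, n, replace = TRUE, prob = preset$size_masses)
  len <- integer(n)
  cs <- SIZE_COMPONENTS$short
  ns <- sum(comp == 1L)
  if (ns > 0) {
    len[comp == 1L] <- pmin(pmax(as.integer(round(
      rtnorm(ns, cs$mean, cs$sd, cs$lower, cs$upper))), cs$lower), cs$upper)
  }
  cm <- SIZE_COMPONENTS$mid
  nm <- sum(comp == 2L)
  if (nm > 0) {
    len[comp == 2L] <- pmin(pmax(as.integer(round(
      rtnorm(nm, cm$mean, cm$sd, cm$lower, cm$upper))), cm$lower), cm$upper)
  }
  cl <- SIZE_COMPONENTS$long
  nl <- sum(comp == 3L)
  if (nl > 0) {
    ws <- vapply(cl$mix, `[[`, numeric(1), "w")
    sub <- sample.int(length(cl$mix), nl, replace = TRUE, prob = ws)
    ll <- integer(nl)
    for (si in seq_along(cl$mix)) {
      nsub <- sum(sub == si)
      if (nsub > 0) {
        ll[sub == si] <- pmin(pmax(as.integer(round(
          rtnorm(nsub, cl$mix[[si]]$mean, cl$mix[[si]]$sd, cl$lower, cl$upper))),
          cl$lower), cl$upper)
      }
    }
    len[comp == 3L] <- ll
  }
  len
}

#' Simulate a fragment sample from a calibrated preset
#'
#' Per fragment: the length is drawn from the preset's size mixture; with
#' probability `p_dhs` the fragment midpoint is a rounded
#' truncated-Gaussian(0, sigma_dhs, +-1 kb) offset from a uniformly chosen
#' DHS center, otherwise uniform on the genome; the fragment is then shifted
#' by up to +-100 bp (candidates searched 0, +1, -1, ...) until both
#' terminal reference bases match bases drawn independently from the
#' end-base law (first base T with probability `p_t`, the remainder split
#' equally over A/C/G; the downstream target applies to the 5'->3' motif
#' entering the fragment, i.e. the complement of the last covered base).
#' Unmatched fragments after the bounded search are accepted as-is and
#' counted. Deterministic per seed.
#'
#' @param preset A [calibrate_preset()]-resolved preset (or any preset with
#'   `p_dhs`, `sigma_dhs` set; `p_dhs = 0` gives the uniform null).
#' @param genome Named character vector (single chromosome used).
#' @param dhs A [dhs_set()].
#' @param n Number of fragments.
#' @param seed Integer seed.
#' @param write_to Optional output directory: writes `fragments.tsv` and a
#'   `fragments.provenance.json` sidecar (preset, resolved parameters,
#'   seed, counters).
#' @return A `fragments` data.frame with counter attributes `n_redraws` and
#'   `n_match_failures`.
#' @export
simulate_fragments <- function(preset, genome, dhs, n, seed = NULL,
                               write_to = NULL) {
  stopifnot(inherits(preset, "ucfrag_preset"))
  if (is.null(preset$p_dhs) || is.null(preset$sigma_dhs)) {
    ucfrag_error("simulate_fragments: preset not calibrated (run calibrate_preset)",
                 "ucfrag_parameter_error")
  }
  gstr <- genome[[1]]
  glen <- nchar(gstr)
  graw <- charToRaw(gstr)
  centers <- dhs$centers
  out <- with_seed(seed, {
    len <- sample_lengths(preset, n)
    is_dhs <- stats::runif(n) < preset$p_dhs
    mid <- integer(n)
    nd <- sum(is_dhs)
    if (nd > 0) {
      ctr <- centers[sample.int(length(centers), nd, replace = TRUE)]
      toff <- as.integer(round(rtnorm(nd, 0, preset$sigma_dhs, -1000, 1000)))
      mid[is_dhs] <- ctr + toff
    }
    nu <- n - nd
    if (nu > 0) {
      mid[!is_dhs] <- as.integer(floor(stats::runif(nu, 0, glen)))
    }
    start <- mid - len %/% 2L
    end <- start + len
    # redraw out-of-bounds placements (uniform part only can go out)
    n_redraws <- 0L
    repeat {
      bad <- which(start < 0L | end > glen)
      if (length(bad) == 0L) break
      n_redraws <- n_redraws + length(bad)
      mid_new <- as.integer(floor(stats::runif(length(bad), 0, glen)))
      start[bad] <- mid_new - len[bad] %/% 2L
      end[bad] <- start[bad] + len[bad]
    }
    # terminal-base matching by bounded +-1 bp shifts
    base_set <- c("T", "A", "C", "G")
    pb <- c(preset$p_t, rep((1 - preset$p_t) / 3, 3))
    b_up <- base_set[sample.int(4L, n, replace = TRUE, prob = pb)]
    b_down <- base_set[sample.int(4L, n, replace = TRUE, prob = pb)]
    up_raw <- charToRaw(paste(b_up, collapse = ""))
    # motif at the downstream end is the revcomp, so its first base matches
    # b_down iff the last covered base is the complement of b_down
    down_raw <- charToRaw(chartr("ACGT", "TGCA", paste(b_down, collapse = "")))
    d_order <- c(0L, as.vector(rbind(seq_len(100L), -seq_len(100L))))
    rem <- seq_len(n)
    shift <- integer(n)
    placed <- logical(n)
    for (d in d_order) {
      if (length(rem) == 0L) break
      p1 <- start[rem] + d + 1L        # 1-based index of upstream base
      p2 <- start[rem] + d + len[rem]  # 1-based index of last covered base
      i1 <- pmin(pmax(p1, 1L), glen)   # clamped for safe indexing only
      i2 <- pmin(pmax(p2, 1L), glen)
      ok <- p1 >= 1L & p2 <= glen &
        graw[i1] == up_raw[rem] &
        graw[i2] == down_raw[rem]
      hit <- rem[ok]
      shift[hit] <- d
      placed[hit] <- TRUE
      rem <- rem[!ok]
    }
    n_match_failures <- length(rem)  # accepted as-is at shift 0
    start <- start + shift
    end <- end + shift
    fr <- new_fragments(rep(names(genome)[1], n), start, end)
    attr(fr, "n_redraws") <- n_redraws
    attr(fr, "n_match_failures") <- n_match_failures
    fr
  })
  if (!is.null(write_to)) {
    dir.create(write_to, recursive = TRUE, showWarnings = FALSE)
    write_fragments(out, file.path(write_to, "fragments.tsv"))
    write_provenance(file.path(write_to, "fragments.provenance.json"),
                     preset, seed,
                     counters = list(n_redraws = attr(out, "n_redraws"),
                                     n_match_failures = attr(out, "n_match_failures")),
                     n = n)
  }
  out
}

#' Simulate a methylation-call table from a calibrated preset
#'
#' Per fragment and per end, CpG offsets within the 30-bp terminal window
#' are a Bernoulli(`cpg_density`) process over offsets 0..29. Calls at the
#' 5' end are methylated with probability `m_cpg`. At the 3' end a fill-in
#' length `L ~ Geom(jagged_q)` capped at 30 is drawn per fragment; calls at
#' offsets `< L` are forced U (end repair fills jagged 5' overhangs with
#' unmethylated bases), the rest methylated with probability `m_cpg`.
#'
#' @param preset A preset with `jagged_q` resolved (see [calibrate_preset()]).
#' @param n_fragments Number of fragments.
#' @param seed Integer seed.
#' @param write_to Optional output directory for `meth_calls.tsv` and its
#'   provenance sidecar.
#' @return Raw calls data.frame (fragment_id, end_tag, offset, call);
#'   aggregate with [meth_call_table_from_calls()].
#' @export
simulate_meth_calls <- function(preset, n_fragments, seed = NULL,
                                write_to = NULL) {
  stopifnot(inherits(preset, "ucfrag_preset"))
  if (is.null(preset$jagged_q)) {
    ucfrag_error("simulate_meth_calls: preset not calibrated (jagged_q missing)",
                 "ucfrag_parameter_error")
  }
  n <- n_fragments
  w <- JAGGED_WINDOW
  calls <- with_seed(seed, {
    qj <- preset$jagged_q
    L <- if (qj <= 0) integer(n) else pmin(stats::rgeom(n, prob = 1 - qj), w)
    mk_end <- function(tag) {
      keep <- stats::runif(n * w) < preset$cpg_density
      frag <- rep(seq_len(n), each = w)[keep]
      off <- rep(0:(w - 1L), times = n)[keep]
      meth <- stats::runif(length(frag)) < preset$m_cpg
      call <- ifelse(meth, "M", "U")
      if (tag == "three_prime") {
        call[off < L[frag]] <- "U"
      }
      data.frame(fragment_id = sprintf("f%06d", frag), end_tag = tag,
                 offset = off, call = call, stringsAsFactors = FALSE)
    }
    rbind(mk_end("five_prime"), mk_end("three_prime"))
  })
  calls <- calls[order(calls$fragment_id, calls$end_tag, calls$offset), ]
  rownames(calls) <- NULL
  if (!is.null(write_to)) {
    dir.create(write_to, recursive = TRUE, showWarnings = FALSE)
    write_meth_calls(calls, file.path(write_to, "meth_calls.tsv"))
    write_provenance(file.path(write_to, "meth_calls.provenance.json"),
                     preset, seed, counters = list(), n = n_fragments)
  }
  calls
}

# Baseline (control-group) feature means/SDs for the synthetic cohort.
# Means echo the mouse wild-type medians where a counterpart exists
# (dhs_prop ~ 0.19, ji_u ~ 28); concentration/creatinine are plausible
# urine values; SDs are chosen so the default standardized shifts give the
# published single-feature AUCs.
COHORT_BASELINE <- list(
  means = c(dhs_prop = 0.19, ji_u = 28, motif_ratio = 1.05,
            concentration = 6, creatinine = 10),
  sds = c(dhs_prop = 0.015, ji_u = 3, motif_ratio = 0.06,
          concentration = 4, creatinine = 4)
)

# Default standardized cancer-minus-control shifts: chosen so the expected
# single-feature AUCs Phi(|delta|/sqrt(2)) match the published values
# (dhs 0.83 with cancer lower, jaggedness/motifs 0.80, concentration 0.58).
COHORT_DEFAULT_EFFECT <- c(dhs_prop = -1.35, ji_u = 1.19,
                           motif_ratio = 1.19, concentration = 0.29)

#' Simulate a two-group subject feature table
#'
#' Per-subject features are drawn from group Gaussians: the control group
#' at the baseline means/SDs, the cancer group shifted by
#' `effect * sd` per feature (negative `dhs_prop` shift = cancer lower).
#' Creatinine is missing at the per-group rates seen in the reference
#' cohort subset (8/46 controls, 18/39 cancer). Deterministic per seed.
#'
#' @param n_control,n_cancer Group sizes (defaults 46 and 39).
#' @param effect Named numeric vector of standardized shifts for
#'   dhs_prop, ji_u, motif_ratio, concentration.
#' @param seed Integer seed.
#' @param baseline List with `means` and `sds` (see defaults).
#' @param missing_creatinine Per-group missingness rates
#'   `c(control =, cancer =)`.
#' @return A `subject_features` data.frame (id, label, dhs_prop, ji_u,
#'   motif_ratio, conc, creatinine).
#' @export
simulate_cohort <- function(n_control = 46L, n_cancer = 39L,
                            effect = COHORT_DEFAULT_EFFECT,
                            seed = NULL,
                            baseline = COHORT_BASELINE,
                            missing_creatinine = c(control = 8 / 46,
                                                   cancer = 18 / 39)) {
  stopifnot(all(is.finite(effect)))
  eff <- COHORT_DEFAULT_EFFECT * 0
  eff[names(effect)] <- effect
  mu <- baseline$means
  sd <- baseline$sds
  with_seed(seed, {
    n <- n_control + n_cancer
    label <- factor(rep(c("control", "cancer"), c(n_control, n_cancer)),
                    levels = c("control", "cancer"))
    shift <- ifelse(label == "cancer", 1, 0)
    draw <- function(feat) {
      stats::rnorm(n, mu[[feat]] + shift * eff[[feat]] * sd[[feat]], sd[[feat]])
    }
    dhs_prop <- pmin(pmax(draw("dhs_prop"), 0.001), 0.999)
    jiu <- draw("ji_u")
    ratio <- pmax(draw("motif_ratio"), 0.01)
    conc <- pmax(draw("concentration"), 0.1)
    creat <- pmax(stats::rnorm(n, mu[["creatinine"]], sd[["creatinine"]]), 0.2)
    miss_p <- ifelse(label == "cancer", missing_creatinine[["cancer"]],
                     missing_creatinine[["control"]])
    creat[stats::runif(n) < miss_p] <- NA_real_
    df <- data.frame(id = sprintf("S%03d", seq_len(n)),
                     label = label,
                     dhs_prop = dhs_prop, ji_u = jiu, motif_ratio = ratio,
                     conc = conc, creatinine = creat,
                     stringsAsFactors = FALSE)
    class(df) <- c("subject_features", "data.frame")
    df
  })
}

# JSON provenance sidecar written next to generator outputs
write_provenance <- function(path, preset, seed, counters, n) {
  resolved <- preset[!vapply(preset, is.function, logical(1))]
  jsonlite::write_json(
    list(preset = resolved, seed = seed, n = n, counters = counters,
         package_version = as.character(utils::packageVersion("ucfrag"))),
    path, auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
  invisible(path)
}
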