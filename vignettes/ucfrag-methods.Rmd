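---
title: "Models and methods behind ucfrag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ucfrag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`ucfrag` analyses the fragmentation features of urinary cell-free DNA
(ucfDNA): fragment sizes, 4-mer end motifs, jagged (5'-protruding) ends
quantified through bisulfite methylation, and fragment-end density around
DNase I hypersensitive sites (DHSs). This vignette documents the models
and conventions the package commits to, the calibrated synthetic-data
generator, and the numerical choices that were genuinely open.

## Coordinate and format conventions

All genomic coordinates are 0-based half-open (BED native). A fragment of
length $L$ starting at $s$ covers bases $s \dots s+L-1$; its two *end
positions* are $s$ (the upstream, plus-strand 5' terminus) and $s+L-1$
(the last covered base). Fragments with insert size above 600 bp or below
1 bp are dropped at read time, with the drop count surfaced so totals stay
auditable. Readers are total over their formats: every accepted file
re-serialises to an equivalent canonical file (sorted intervals, tabs, a
single `#` header line), which the round-trip tests assert.

## Size profiling

Histograms are counted over the support 1–600 bp. The three size bins
partition that support as short $=[1,49]$, mid $=[50,150]$,
long $=[151,600]$: "below 50 bp" is read strictly, "50 to 150 bp"
inclusive on both ends, "above 150 bp" strictly — the only reading under
which the three phrases partition the lengths, so the three fractions sum
to exactly 1 per sample. Cohort summaries are elementwise medians (mean of
the central pair for even cohort sizes); note that medians of
compositional vectors need not sum to 1, which is why per-genotype
published bin medians cannot all be matched by any single sample (see the
generator section).

## End motifs

Both fragment ends contribute to the spectrum, and every motif is
reported as the 5'→3' k-mer *entering* the fragment: the upstream motif is
the reference bases $[s, s+k)$ and the downstream motif is the reverse
complement of $[e-k, e)$. This matches the 5'-orientation convention of
the cfDNA end-motif literature; the pooling is per *end*, not per
fragment, so a fragment contributes up to two motifs. Windows containing N
are skipped and counted, never imputed. Rankings break frequency ties
lexicographically (A<C<G<T), making top-k sets deterministic. The
subject-level motif metric is the ratio of spectrum mass over two top-25
motif sets (learned from wild-type and Dnase1-knockout reference spectra);
the sets are used verbatim — motifs shared between the two sets stay in
both, since no exclusion rule is defined for the source metric.

## Jagged-end index

The Jagged Index-Unmethylated is

$$\mathrm{JI\text{-}U} = \frac{M_1 - M_2}{M_1} \times 100\%,$$

where $M_1$ and $M_2$ are the CpG methylation densities of the 30 bases
proximal to the 5' and 3' fragment ends. End repair fills 5' overhangs
with unmethylated cytosines, depressing apparent methylation near the
3'-proximal read end, so larger JI-U means more jagged ends. Densities are
*pooled* counts (sum methylated and total calls across fragments, then
divide) rather than means of per-fragment ratios: per-fragment CpG counts
within a 30-bp window are tiny (about two at the modelled CpG density),
so per-fragment ratios would be dominated by small-denominator noise.
Pooling also makes JI-U exactly invariant to scaling all four counts.
Calls at offsets ≥ 30 are rejected at parse time. Raw bisulfite read
processing (trimming, alignment, conversion QC) is out of scope; the
methylation-call table is the contract.

## DHS end density

"Within the DHSs" is operationalised as within ±1 kb of a DHS center
(floor midpoint of the interval), half-open on the right, for both the
density profile and the proportion metric — one definition for mouse and
human analyses. Both ends of every fragment are pooled, and each end is
assigned to its *nearest* center, so overlapping windows of adjacent DHSs
cannot double-count an end. The profile uses 10-bp bins (the source
figures plot a visually continuous curve without stating resolution) and
divides each bin count by the median count over all 200 bins in the ±1 kb
window; with a peak much narrower than the window the median sits on the
background, and by construction the median of the normalized densities is
1. A zero median raises a sparse-data error rather than an infinite
profile. The proportion variant accepts an inclusive fragment-size filter
(e.g. 130–160 bp) applied before counting ends.

## Classification

* **Mann-Whitney U**: the min-U convention with ties counted half. For
  combined sample sizes up to 12 the two-sided p-value is computed by
  exhaustive enumeration of all label assignments (exact under ties);
  beyond that, the normal approximation with tie correction and no
  continuity correction.
* **AUC**: the rank statistic, equal to the probability a random case
  outranks a random control with ties counted half; the identity
  $\mathrm{AUC} = U/(n_1 n_2)$ is asserted in the tests. Results report
  both the raw case-high value and the oriented value (≥ 0.5) with its
  direction flag.
* **LOO-SVM**: one subject held out per fold; z-score standardisation is
  fitted on the training fold only and applied to the held-out subject; a
  linear-kernel SVM with $C = 1$ is trained per fold; pooled out-of-fold
  decision values give the ROC. Kernel, cost and scaling are unreported
  for the reference analysis, so linear + standardisation was chosen as
  the minimal defensible configuration and is recorded in run manifests.
  Decision-value signs are normalised per fold from the trained model's
  class labelling so that higher always means case.
* **Cutoffs**: per leave-one-out iteration the Youden-optimal threshold
  (maximum sensitivity + specificity − 1) on the training fold, searched
  over midpoints between adjacent distinct scores with the lowest
  maximiser on ties. Youden's rule is an assumption — the source tables
  report per-iteration cutoffs without naming the rule.
* **Creatinine normalisation** adds concentration/creatinine as a derived
  feature; subjects without usable creatinine are excluded from that
  feature only, with the exclusion count logged.

## The synthetic-data generator

The generator's defaults *are* the study conditions; they are calibrated
once to published genotype medians and not tuned afterwards.

**Fragment sizes.** Lengths are drawn from a three-component mixture with
disjoint hard supports aligned to the size bins: short
$\sim \mathcal N(46, 8^2)$ truncated to $[20, 49]$; mid
$\sim \mathcal N(100, 25^2)$ truncated to $[50, 150]$; long a
$0.7/0.2/0.1$ ladder of $\mathcal N(165, 15^2)$, $\mathcal N(330, 20^2)$,
$\mathcal N(500, 30^2)$ truncated to $[151, 600]$ (the 46-bp and 165-bp
modes echo the two major peaks of nuclease-deficient urine, and the
ladder the mono-/di-/tri-nucleosomal pattern). Because supports are
disjoint and aligned to the bins, expected bin fractions equal the
mixture weights exactly — the size targets carry no calibration error.
The Dnase1-knockout preset sets the short and long weights to the
published medians (0.299, 0.250) and gives the mid bin the compositional
remainder 0.451 rather than the published mid median 39.9%: per-bin
medians over samples are not compositionally consistent for any single
sample, and the short/long bins carry the headline fold-changes.

**End bases.** Each fragment draws two target terminal bases from the
end-base law (T with probability $p_T$, the rest split equally), one for
each end; the downstream target applies to the 5'→3' motif entering the
fragment, i.e. to the complement of the last covered base. The fragment
is then shifted by whole base pairs (candidates searched in the order
$0, +1, -1, \dots, \pm 100$) until both terminal bases match; failures
after 201 candidates are accepted as-is and counted. Matching *both* ends
is deliberate: the end-motif metrics pool both ends, so calibrating only
the upstream base would leave the pooled T-fraction roughly halfway
between $p_T$ and the genome's A frequency and miss the targets by up to
two percentage points. The bounded local search preserves the size and
placement laws to first order (joint acceptance probability ≈ 0.06 per
candidate position, so the typical shift is a few bp), and the
acceptance-failure counter keeps the approximation auditable.

**DHS placement.** With probability `p_dhs` a fragment's midpoint is
placed at a rounded truncated-Gaussian$(0, \sigma, \pm 1\mathrm{kb})$
offset from a uniformly chosen DHS center; otherwise uniformly on the
genome. Calibration solves

1. `p_dhs` $= (P_{\mathrm{target}} - g)/(1 - g)$, where $g$ is the
   realized coverage of the ±1 kb windows (0.15 at the defaults: 750
   DHSs × 2 kb on 10 Mb) — uniform fragments land in windows with
   probability $g$, so this makes the expected within-DHS end proportion
   equal the target;
2. $\sigma$ by bisection on a closed-form expected profile so that the
   expected central-bin density equals the central-density target. The
   closed form composes (i) the integer-rounded truncated-Gaussian
   midpoint offset, (ii) the discrete length mixture acting through the
   end offsets $-\lfloor L/2\rfloor$ and $\lceil L/2\rceil - 1$, and
   (iii) the analytic distribution of the end-base matching shift under
   an i.i.d. genome (a mixture over the 16 target-base pairs of
   geometrics in search order), then applies the same median-of-bins
   normalisation as the empirical profile. Central density is not
   monotone in $\sigma$ (a very tight placement puts ends in a ring at
   $\pm L/2$, not the center), so the solver bisects on the decreasing,
   larger-$\sigma$ branch;
3. the jagged fill-in parameter from the identity below.

**Jagged ends.** Per fragment a fill-in length
$L \sim \mathrm{Geom}(q)$ on $\{0, 1, \dots\}$ capped at 30 is drawn. CpG
positions arise as a Bernoulli(1/15) process over offsets 0–29 at each
end; 5'-end calls are methylated with probability $m_{\mathrm{CpG}} =
0.75$, and 3'-end calls at offsets below $L$ are forced unmethylated.
Under this model the expected JI-U is $100\,E[\min(L, 30)]/30$,
*independent of* $m_{\mathrm{CpG}}$ — the tests verify this invariance at
$m_{\mathrm{CpG}} \in \{0.5, 0.75, 0.9\}$ — and
$E[\min(L,30)] = q(1-q^{30})/(1-q)$ inverts in closed form to calibrate
$q$ from a JI-U target.

**Cohorts.** Subject features are drawn from group Gaussians; the cancer
group is shifted by a standardized effect per feature, with defaults
chosen so the expected single-feature AUCs $\Phi(\delta/\sqrt 2)$ match
the published values (within-DHS proportion 0.83 with cancer lower,
jaggedness and motif ratio 0.80, concentration 0.58). Group sizes default
to 46 controls and 39 cancer subjects; the source reports both (46, 39)
and (39, 46) in different places, and the package flags rather than
resolves this. Creatinine is missing at the subset rates of the reference
cohort (8/46 controls, 18/39 cancer). The per-sample variability model is
the package's own choice — no between-sample dispersion model is
published.

## What the synthetic tests do and do not show

The generator emulates the *calibrated summary statistics* of real
ucfDNA — bin masses, end-base composition, window-level DHS enrichment,
pooled jaggedness — on an i.i.d. genome. It does not emulate genome
sequence structure (repeats, CpG islands, real DHS landscapes),
nucleosome-phased cutting (the 10-bp periodicity), correlated features
within a subject, PCR duplicates or bisulfite conversion error. Passing
recovery tests therefore demonstrates that the *pipeline computes its
statistics correctly at realistic scale*, not that the generator is a
biological simulator: full 4-mer rankings on the synthetic genome, for
example, reflect genome composition beyond the calibrated first base and
will not reproduce real motif tables.

## Problem sizes and determinism

Recovery checks use one sample per condition at the scale the presets
were calibrated for: 200,000 fragments for size, motif and DHS metrics
and 50,000 fragments for methylation-call tables, on a 10 Mb genome with
750 DHSs; classifier properties use cohorts of 85 (default), 500 (null
LOO-SVM) and 1,000 (AUC–$\Phi$ identity) subjects. Every stochastic
function takes an explicit seed, restores the caller's RNG state, and is
bit-reproducible per seed at the level of record content; generator
outputs carry a JSON provenance sidecar (preset, resolved parameters,
seed, counters).

## Known limitations

* The nearest-center rule for overlapping DHS windows is exercised only
  lightly: the synthetic DHS set guarantees ≥ 4 kb spacing, so real,
  densely clustered DHS landscapes stress it more than the tests do.
* The median normalisation uses all bins of the ±1 kb window; if the true
  enrichment were nearly as wide as the window, the median would sit on
  the peak shoulder and compress densities toward 1.
* JI-U assumes CpG-context calls only and a shared 30-bp window at both
  ends; read-pair geometry effects are outside the call-table contract.
* SVM hyperparameters for the reference combined classifier are
  unreported; combined-classifier results on real data are not expected
  to be bit-reproducible, only qualitatively similar.
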