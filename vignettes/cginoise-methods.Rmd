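---
title: "Methods: mean-adjusted expression noise and the CpG-island screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mean-adjusted expression noise and the CpG-island screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its statistical machinery:
the model behind each stage, the assumptions it rests on, the parameters
that matter and why their defaults are what they are, what the synthetic
data emulate (and deliberately do not), and the numerical decisions taken
where more than one reasonable choice existed.

## 1. From counts to mean-adjusted noise

### Filtering and normalization

Cells with fewer than 100,000 total counts (`min_total`) are removed —
the strict `<` boundary keeps a cell at exactly the threshold — along
with any cells flagged as bad. Genes detected in fewer than 1% of cells
(`min_cell_fraction`, applied as a `>=` keep-rule so a gene at exactly 1%
survives) are removed per dataset. Cell size factors come from the
pooling/deconvolution estimator (via scran), rescaled to geometric mean
1 so that normalized scales are comparable across datasets; deconvolution
needs at least 20 cells and falls back to library-size factors, with a
warning, below that. We delegate to scran rather than re-implementing the
ring-pool system: it is the reference implementation of the
deconvolution estimator, and the fallback, rescaling and validation
around it live in this package. Negative or non-finite factor estimates
are replaced per cell by library-size factors, again with a warning.

### The coefficient of variation and its expected value

Per gene, `gene_moments()` reports `mu`, the log2 of the mean normalized
count, and a squared coefficient of variation. Two scales are available:

- `cv2_on = "normalized"` (default): the sample variance of the
  normalized counts over the squared mean normalized count. This is the
  classic count-scale CV², the scale on which the technical expectation
  of an overdispersed count model has the clean form
  CV² ≈ 1/mean + dispersion.
- `cv2_on = "log2"`: the sample variance of `log2(c/s + pseudocount)`
  over `mu`². On this scale the technical component decays roughly as
  1/μ² — *outside* the reciprocal-in-μ family fitted below — so the
  residualization cannot fully remove the mean trend. The option is
  retained for comparability, but the count scale is the default
  precisely because the package's own mean-adjustment test (uncorrelated
  residuals under an effect-free generator) holds there and not on the
  log2 scale.

The mean–CV² curve `E[CV²] = a0 + a1/μ` is fitted by a gamma-family GLM
with identity link over fit-eligible genes (`mu > mu_floor`, CV² > 0,
at least 50 genes). The gamma family encodes multiplicative error —
the sampling spread of a variance-like statistic scales with its
expectation — and the identity link keeps the reciprocal parametrisation
exact. Free coefficients are fitted rather than pinning (a0, a1) to any
fixed values: a frozen curve cannot adapt across datasets with different
depths and dispersions. `mu_floor = 0.1` (log2 units) keeps `1/μ`
bounded; genes below the floor keep their CV² but get no residual.
Starting values come from an ordinary least-squares fit, shifted if they
would imply non-positive fitted means; IRLS runs to a relative tolerance
of 1e−8 with a 100-iteration cap, and non-convergence is surfaced as a
warning plus a flag on the returned object, never silently.

The mean-adjusted noise is the absolute residual
`rCV² = |CV² − E[CV²]|`. Because of the gamma error structure, the
*spread* of residuals also grows with the expected CV²; the
mean-adjustment property (rCV² uncorrelated with μ) therefore holds when
per-gene baseline dispersion differences dominate the residual, which is
the regime of real data and of the default generator, and it is verified
by simulation in the test suite rather than assumed.

## 2. The robust feature screen

Each feature column is regressed on rCV², individually and jointly,
with Huber M-estimation (tuning constant k = 1.345, the conventional
95%-Gaussian-efficiency choice; Tukey bisquare behind a flag), scale
estimated by the normal-consistent MAD, IRLS tolerance 1e−8, 200
iterations. rCV² is long-tailed, and a least-squares fit would hand a
few extreme genes control of the coefficients; the Huber loss behaves
like least squares in the bulk and like the median in the tail.
Coefficients are tested two-sided against zero with n − p degrees of
freedom. No multiple-testing correction is applied across features by
default — each feature is reported with its own p-value, as the screen
is exploratory — with an optional Benjamini–Hochberg column.

Continuous features are z-scored before regression (`<name>_z` columns
from `build_feature_table()`), so coefficients are per-standard-
deviation and comparable across features. Zero-variance columns are
flagged and left unstandardized. Rows with any missing value are dropped
listwise per model, so univariate models may legitimately use different
gene sets. Rank-deficient designs are rejected with the collinear
columns named. An exact interpolating fit has zero residual scale, which
the underlying IRLS mislabels as non-convergence; the package detects
this case and reports it as converged.

`subset_refit()` reruns the screens on the complement of an exclusion
list (for instance, a developmentally co-regulated programme) and
tabulates before/after coefficients, refusing exclusions that remove
more than 90% of genes.

## 3. Annotations

Promoters span −1 kb to +500 bp around the TSS, strand-aware: on the
plus strand the TSS is the gene start, on the minus strand the gene end,
and the interval is mirrored. Coordinates are 0-based half-open
throughout (BED-native); GTF's 1-based closed records are converted on
read and write. Promoters running past position 0 are clipped and
flagged. For multi-transcript genes the TSS comes from the gene record's
5′-most position and structure features (total exon length, exon count,
mean exon length) from the longest annotated transcript — "transcript
length" is per-transcript exon sum, not the union of exons.

A promoter is CpG-island-positive at ≥1 bp overlap; with several
candidate islands the maximal-overlap island wins and exact ties go to
the longer island. The same rule assigns islands to peak positions
within a 500-bp centred window. GC content is the G+C fraction over
unambiguous bases only (Ns excluded from numerator and denominator).
Motif counts and TATA-box classifications are accepted as optional
precomputed columns rather than being scanned in-package.

## 4. Promoter chromatin classes

ChIP and matched input libraries are counted in non-overlapping 200-bp
windows, depth-normalized to counts-per-million, and converted to
`log2((chip + 1)/(input + 1))`. Promoter signal is the unweighted mean
over overlapping windows per replicate, then the mean over replicates
(replicates are matched 1:1 to their inputs by tag).

H3K4me3 distributions over promoters are bimodal, so the threshold is
the local minimum of a Gaussian KDE (Silverman bandwidth, 512-point
grid) — specifically the lowest interior minimum between the two largest
modes, a rule that is insensitive to minor density ripples. H3K27me3 is
long-tailed without a usable minimum, so its threshold is the mean
signal. A mark is called when the signal strictly exceeds 1.5× its
threshold; both marks = bivalent, one = active or repressed, neither =
low (kept explicit rather than silently merged). Log2 enrichments can
make a threshold non-positive, in which case multiplying by 1.5 *lowers*
the bar; the package warns rather than second-guessing the caller.
Unimodal H3K4me3 densities are rejected with a pointer to the manual
threshold override. At least 200 promoters are required before density
estimation is attempted.

`category_regression()` puts rCV² on indicator columns for
active/bivalent/low (repressed as reference) plus z-scored island size
in one robust fit, separating the chromatin-state effect from the
island-size effect.

## 5. Time courses and the ranked-pair sign test

Fold changes between consecutive time points are either supplied
(moderated estimates from an external differential-expression fit are
accepted as-is) or computed naively as
`log2((mean_t2 + 1)/(mean_t1 + 1))` with replicates averaged. CAGE
features must be detected in more than 75% of samples, RNA-seq genes
must average more than 5 counts; both boundaries exclusive.

The enrichment question — do the earliest responders carry shorter
islands? — is answered by ranking island-bearing genes by descending
fold change separately in the early and the late comparison, pairing the
r-th early gene with the r-th late gene for r = 1..250 (`top_n`), and
counting pairs whose early island is strictly smaller. Exact size ties
are excluded, the standard sign-test treatment of zero differences. The
one-tailed p-value is the exact binomial tail
P(Bin(n, ½) ≥ k). Rank-matched pairing is used because it is the
reading under which the procedure *is* a paired-sample sign test; the
test suite verifies the equivalence against an independently coded
oracle, and that swapping the early/late arguments maps k to n − k and
flips the reported direction. Genes without an island are excluded
before ranking, so `top_n` always refers to island-bearing genes.

Response labels come from a per-gene Wilcoxon rank-sum test between
unstimulated and stimulated cells on library-size-normalized expression
(a distribution-free default that needs no dispersion model), BH
correction at FDR 0.05, and the sign of a pseudocount-shrunken fold
change. `noise_vs_response()` then summarizes pre-stimulation CV² (or
rCV²) per 0.5-kb island-size bin and label, and runs one-tailed
two-sample Kolmogorov–Smirnov tests with the alternative fixed as
"up-regulated genes are stochastically noisier"; bins with fewer than 3
genes are reported as missing rather than as unstable means. A non-island
stratum is computed alongside as a contrast.

## 6. What the synthetic data emulate

The generator produces every input the pipeline reads, with recorded
ground truth, under one statistical picture of a single-cell experiment:

- **Counts** are negative binomial, gene means log-normal
  (`meanlog = log 50`, `sdlog = 1` — deep, full-length-style libraries:
  2,000 such genes give cells of roughly 10^5 total counts, matching the
  cell filter they are meant to pass), cell scaling factors log-normal
  with geometric mean 1 (`sdlog = 0.2`).
- **Dispersion** is a per-gene log-normal *baseline* (median 0.15,
  sdlog 0.6, independent of all features) plus, for a ~30% minority of
  genes, a right-skewed *biological excess* (median 0.4, sdlog 0.8).
  Planted feature effects act on the excess channel only — on its log
  magnitude and on the log-odds of carrying it at all. This mixture is
  the load-bearing design decision. Real noise distributions have a
  bulk of genes near a baseline trend with a minority of highly variable
  genes above it; a fitted mean curve then hugs the bulk, residuals are
  one-sided, and the absolute residual is monotone in the biological
  excess. A generator in which *every* gene's dispersion shifts with the
  features instead pushes damped genes through and below the fitted
  curve, where taking the absolute value folds them upward and a
  median-focused robust fit reads a damping effect with the wrong sign.
  The mixture is both the more faithful picture of real data and the
  geometry under which the method is designed to operate. With
  `noisy_fraction = 0` and `floor_sd = 0` the generator collapses to an
  exact constant-dispersion NB, which is what the moment-identity tests
  use.
- **Planted effects** (defaults): island size damps the excess at
  −1 per kb on the log scale; bivalent promoters carry a 4× excess;
  early responders an e-fold excess. Zeroing all three gives the null
  generator used for calibration.
- **Annotations** place one gene per 12-kb slot on synthetic
  chromosomes, islands (log-normal sizes, truncated to 200 bp–10 kb,
  ~60% of promoters) centred on the TSS so each island overlaps its own
  promoter and no other — which is what makes planted island sizes
  exactly recoverable by the overlap rule, a round-trip the tests
  exploit. Exon structures are drawn and written to GTF so the
  structure features round-trip too.
- **Chromatin** signals are bimodal at the promoter level (H3K4me3
  modes 0 and 4 at SD 0.4; H3K27me3 exponential background vs a
  Gaussian elevated mode), with 200-bp windows and window-level noise.
- **Time series** draw per-comparison log2 fold changes N(0, 1), with
  the earliest comparison boosted by `effect` for genes whose island is
  below the median island size.

Deliberately *not* emulated: read-level data, UMI collapsing, doublets,
batch effects, expression-dependent detection dropout, correlated genes,
and chromatin-expression coupling beyond the planted class effects.
Passing tests on these generators therefore demonstrates the statistical
machinery — calibration, power against planted effects, oracle
equivalence, determinism — not biological generalization to any real
dataset.

## 7. Numerical choices and problem sizes

Degenerate inputs are rejected with named errors rather than propagated:
empty filters, zero-count cells, rank-deficient designs, unimodal
H3K4me3 densities, all-tie enrichment instances, fewer than 3 time
points, fewer than 3 cells for a variance estimate. Sample variances use
the n − 1 denominator everywhere. The `0.5^8 ≈ 0.0039` closed form of
the 8-of-8 sign test and a brute-force binomial summation serve as exact
anchors for the enrichment tail.

The test suite runs the heavier property checks at fixed seeds and
deliberate desk scales, chosen so the whole suite stays fast while the
asymptotics are already visible: 2,000 genes × 500 cells for the
mean-adjustment check, 2,000 × 150–200 for the 100-seed power and
calibration loops of the screen and the category regression, 500
promoters for classifier recovery, 200–1,000 replicates for the
enrichment oracle, calibration and power loops, and an 800-gene ×
200-cell demo bundle for the byte-identity check of the end-to-end
pipeline. `scripts/acceptance.R` recomputes the same quantities at the
same scales (with 25-seed loops where the suite uses 100) from a single
command-line seed.

## 8. Known limitations

- The absolute residual inherits the gamma error structure: where
  expected CV² varies strongly and baseline dispersion variation is
  small (very shallow data, or a near-degenerate dispersion
  distribution), rCV² re-acquires a mean trend. The mean-adjustment
  simulation is the guard; on real data, inspecting
  `plot_mean_cv2()` before interpreting screen coefficients is the
  practical equivalent.
- The reciprocal-in-μ curve is a working approximation, not a
  derivation, for log-scale means; its adequacy is dataset-dependent.
- The KDE-valley threshold assumes genuine H3K4me3 bimodality; shallow
  or unbalanced modes need the manual override.
- The rank-matched pairing of the enrichment test is one defensible
  reading of a ranked-proportion comparison; `top_n` is exposed so the
  full-list variant can be run, and direction plus effect size should be
  read together with the p-value.
- Wilcoxon-based response labels ignore the count nature of the data;
  for real datasets a dedicated single-cell DE method can replace them —
  the labels are an input contract, not a dependency.
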