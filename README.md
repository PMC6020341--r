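# cginoise

Gene expression noise — the cell-to-cell variability of a gene's
transcript level among otherwise identical cells — is not random across
the genome: promoter architecture shapes it. `cginoise` implements, as a
tested and reusable R pipeline, an analysis of how promoter features, and
CpG islands in particular, associate with expression noise in single-cell
RNA-seq data, and of how short CpG islands behave in stimulation time
courses. It is aimed at computational biologists who want to run the
noise screen on their own count matrices and annotations, or to study the
statistical behaviour of the method itself on synthetic data with known
ground truth.

## The statistic at the core

For a filtered, size-factor-normalized count matrix (genes *i*, cells
*j*, counts *c<sub>ij</sub>*, deconvolution size factors *s<sub>j</sub>*)
the per-gene noise is the squared coefficient of variation
CV²<sub>i</sub> = σ̂²<sub>i</sub>/mean², with

μ<sub>i</sub> = log₂( (1/m) Σ<sub>j</sub> c<sub>ij</sub>/s<sub>j</sub> ).

CV² falls with expression because counting itself is noisy, so a
reciprocal curve

E[CV²<sub>i</sub>] = a₀ + a₁/μ<sub>i</sub>

is fitted across genes with a gamma generalized linear model (identity
link) — the Brennecke-style parametrisation, with a gamma family because
CV² is a variance-like, χ²-flavoured quantity. The **residual CV²**

rCV²<sub>i</sub> = | CV²<sub>i</sub> − E[CV²<sub>i</sub>] |

is the mean-adjusted noise. Each genomic feature *X* (CpG-island
presence and size, GC content, gene structure, chromatin marks) is then
regressed on rCV² with a robust (Huber M-estimator) linear model —
rCV² is long-tailed, and the median's breakdown point of 0.5 keeps a
handful of extreme genes from steering the coefficients — and each
β is tested against 0 with a t-test, univariately and in a joint
multivariate model.

Around that core the package provides: promoter definition (−1 kb/+500 bp
around the TSS, strand-aware), CpG-island assignment by maximal overlap,
H3K4me3/H3K27me3 promoter fold-enrichment with
active/repressed/bivalent/low classification (KDE-valley and mean
thresholds, 1.5× rule), and a ranked-pair sign test asking whether the
earliest-responding genes after stimulation carry *shorter* CpG islands
than later responders (exact one-tailed binomial tail against a 50:50
null). A synthetic-data module generates every input with planted ground
truth.

## Worked example

Simulate a 2,000-gene × 200-cell matrix in which larger CpG islands damp
the biological dispersion, compute noise, and screen island size against
it:

```r
library(cginoise)

sim <- simulate_counts(n_genes = 2000, n_cells = 200, sim_config(), seed = 1)
res <- compute_noise(sim$counts, min_total = 1000, method = "library")
res$fit
#> mean-CV2 gamma GLM fit: E[CV2] = 0.37 + 0.7958 / mu  (n = 2000, converged in 2 iter)

features <- tibble::tibble(
  gene_id = sim$truth$gene_id,
  cgi_size_bp_z = as.numeric(scale(sim$truth$cgi_size_bp))
)
univariate_screen(res$noise, features, columns = "cgi_size_bp_z")
#>         feature model_kind     beta      se t_stat p_value    n significant
#> 1 cgi_size_bp_z univariate -0.00678 0.00319  -2.12  0.0339 2000        TRUE
```

The fitted curve (a₀ = 0.37, a₁ = 0.80) is the expected CV² at each
expression level; the negative, significant β on standardized island
size recovers the planted effect: genes with larger islands are less
noisy than their expression level predicts. `plot_mean_cv2(res$noise)`
draws the mean-CV² cloud with the fitted curve, and `plot_screen()`
plots screen coefficients. A full demo — counts, GTF, BED, bedGraph and
time-series files with a README of the planted truth — is written by
`make_demo(seed = 1, out_dir = "demo")` and analysed end to end by
`run_pipeline(read_run_config("demo/config.json"))`.

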