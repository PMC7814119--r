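---
title: "An LMR-based DNA methylation clock for broiler chicken: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An LMR-based DNA methylation clock for broiler chicken: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`chickclock` implements the full workflow behind a multi-tissue DNA
methylation clock for the broiler chicken, a bird with a commercially fixed
lifespan of about 42 days. This vignette explains the models the package
fits, the assumptions behind each step, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate, and
the numerical and design choices that were genuinely open.

## The data model

Whole-genome bisulfite sequencing (WGBS) yields, per cytosine and strand, a
methylated-read count $m$ and a total-read count $t$; the methylation ratio
is $m/t$. The package represents a sample as a tibble of such records
(`chrom`, `pos`, `strand`, `context`, `meth_count`, `total_count`, `ratio`),
kept sorted with 1-based positions; genomic intervals use the 0-based
half-open BED convention, and the two never mix except inside the documented
converters. Ratios are always recomputed from counts on input — files are
not trusted.

Only CpGs covered by at least three reads enter genome-wide analyses. The
clock-specific filters are stricter and strand-resolved: for the CpG-level
clock both strands of a dyad must exceed 10 reads in *every* sample; for the
LMR-level clock, CpGs inside the regions must exceed 5 reads per strand in
every sample. The thresholds are strict inequalities ("greater than"), which
we take literally. Sex-chromosome CpGs (chicken is ZW) and CpGs at known
SNPs are removed first — C/T polymorphisms are indistinguishable from
unmethylated cytosines after bisulfite conversion.

One interpretation was open: whether LMR means should be computed from
strand-combined or strand-separate CpGs after the per-strand filter. We use
strand-separate records (each strand's ratio contributes one term to the
unweighted interval mean); dyad methylation is near-symmetric, so the choice
is numerically minor, but it is fixed and documented here.

## Low-methylated regions

LMRs — short regions of reduced methylation, typically footprints of
transcription-factor binding — carry most of the tissue- and age-specific
signal in a vertebrate methylome. The segmentation used here is
deliberately simple and fully specified:

1. coverage-filter the (strand-combined) track;
2. smooth ratios with a running mean over `smooth_k = 3` nearest CpGs
   per chromosome (truncated at the ends);
3. call maximal runs of consecutive CpGs with smoothed ratio strictly
   below a cutoff `m`; discard runs with fewer than
   `min_cpgs_segment = 4` CpGs;
4. class segments with 30 or more CpGs as UMRs (long unmethylated
   regions, typically CpG-island promoters), the rest as LMRs.

The cutoff can be calibrated by a shuffle null: ratios are permuted across
CpG positions within each chromosome (preserving CpG spacing, so the null
tests methylation *clustering*, not CpG density), and
$\mathrm{FDR}(m) = \overline{\#\text{segments}_{\text{null}}} / \#\text{segments}_{\text{obs}}$
over `null_shuffles = 10` permutations. The calibrated cutoff is the
**largest** grid value with FDR at or below `fdr_target = 0.05`: this
maximizes sensitivity subject to the FDR constraint, which is the intent of
FDR-calibrated segmentation (the smallest qualifying cutoff would trivially
achieve FDR 0 while missing most true regions). Ties at the cutoff count as
"low" only under strict inequality — deterministic and documented.

Per-sample or per-tissue LMR sets are pooled by interval union, merging
overlapping and book-ended segments.

## The clock

### Tissue-offset normalization

PCA of LMR methylation shows an age-correlated component on which tissues
are offset from one another — different tissues mature at different speeds,
which matters greatly in an animal whose whole life is juvenile
development. The correction is a per-(tissue, feature) offset: the mean
value over all training samples of that tissue is subtracted. After
normalization every tissue/feature combination has mean zero on the
training set (to numerical precision; this is asserted at $10^{-12}$ in the
tests). The offsets and the per-feature global means are stored in the
model; at prediction time a sample's tissue selects its offsets, and an
unseen tissue falls back to the global means with a warning.

### Penalized regression

Chronological age (days) is regressed on the normalized methylation values
with an elastic net:

$$\min_{\beta_0,\beta}\;\frac{1}{2n}\sum_i\left(y_i-\beta_0-x_i^\top\beta\right)^2
+\lambda\left[\frac{1-\alpha}{2}\lVert\beta\rVert_2^2+\alpha\lVert\beta\rVert_1\right]$$

with an unpenalized intercept. The solver is cyclic coordinate descent with
active-set iteration and warm starts along a decreasing $\lambda$ path
(compiled; convergence when the largest weighted squared coefficient change
in a sweep falls below `tol = 1e-12`, confirmed by a full sweep). The
tests verify the solution against an independent proximal-gradient solver,
the normal equations at $\lambda = 0$, the univariate soft-threshold closed
form, the subgradient optimality conditions, and glmnet.

Choices and defaults:

* `alpha = 0.9` for the LMR clock and `0.7` for the CpG clock — the mixing
  values at which the fit is close to the best while the marker set stays
  manageable.
* $\lambda$ is chosen by k-fold cross-validation as the minimizer of the
  mean out-of-fold RMSE, ties broken toward the larger (sparser) penalty;
  a one-standard-error rule is available behind `one_se = TRUE`. No
  $\lambda$ selection rule is canonical here, so the rule is explicit and
  seeded.
* Features are **not** variance-standardized by default: methylation values
  share the natural $[0,1]$ scale, and standardization would inflate
  near-constant features. `standardize = TRUE` is available.

### Cross-validation without leakage

`cross_validate_clock()` stratifies folds by (tissue, age group), seeds
them, and — by default — re-estimates the tissue offsets *and* the penalty
inside each training split, so no information from held-out samples leaks
into normalization. The single-normalization variant
(`normalize = "full"`), which centers once on the complete matrix before
splitting, is also implemented; whether the original workflow re-estimated
offsets per fold is not stated anywhere, so both modes exist and
fold-internal is the default. The difference is small on the synthetic
cohorts (fold-internal is very slightly pessimistic) but the leakage-free
mode is the honest error estimate. The reported RMSE pools all out-of-fold
predictions.

Models serialize to JSON with all floats encoded as 17-significant-digit
decimal strings, so a write/read round trip is bit-exact; a schema-version
field guards against silently loading incompatible files.

## Cohort analyses

* **Differential LMRs** between two groups compare per-feature group means
  of raw (unnormalized) methylation; a feature is called hyper- or
  hypomethylated when the difference strictly exceeds 0.1. Means are
  per-sample-then-averaged (pooled-read means would weight samples by
  coverage; per-sample means match how the matrix is built).
* **Age acceleration** is predicted minus chronological age. Group
  comparisons use Welch's two-sample t-test against a reference group,
  two-sided by default (the variant is not canonical; a one-sided option
  exists for the directional hypothesis that inflammation accelerates the
  clock).
* **Marker enrichment** in genomic features divides the fraction of clock
  markers in a feature class by the fraction of the genome that class
  occupies; interval markers are assigned by midpoint (an any-overlap mode
  exists). Promoters are conventionally the 1000 bp upstream of the TSS.
* **PCA with age correlation** reports, per component, the Pearson
  correlation of the score vector with age — the diagnostic that motivates
  offset normalization.
* **Rank-sum comparisons** of methylation distributions use the two-sided
  Mann–Whitney test with normal approximation, tie and continuity
  correction; the tests check it against exact enumeration at small n.

## The synthetic methylome generator

The generator exists so that every stage is testable without sequencing
data. It emulates:

* a highly methylated background (mean 0.8) with short planted
  low-methylated regions (baseline 0.1 at age 0), CpG-dense relative to
  the background (40 vs 100 bp mean spacing — regulatory elements are
  CpG-rich);
* age trajectories that are linear on the logit scale (keeping methylation
  in $(0,1)$; the real data show monotone age-related LMR methylation
  without a stated functional form), with 10% of regions age-responsive,
  slope magnitudes uniform on 0.03–0.08 logit/day and 55% positive
  (matching the observed hyper:hypo balance of differential LMRs).
  Hypermethylating regions start at the low baseline and rise;
  demethylating regions start high and descend to the baseline by the end
  of the lifespan — they *become* LMRs with age, which is what makes
  methylation loss observable at all;
* tissue offsets (SD 0.5 logit) applied only inside planted regions —
  tissue separation in real methylomes is driven by LMR methylation;
* per-(region, sample) biological noise, SD 0.1 logit. This knob was
  calibrated against the study-level observable: with it, a 6-fold
  cross-validated clock on the default 36-sample cohort reaches an RMSE of
  roughly 2.1–2.4 days, the closest the desk-scale design gets to the
  error a real broiler cohort supports (the floor is set by count noise,
  the three-age design and the logit nonlinearity, not by this knob);
* read counts: per-strand coverage Poisson(coverage/2) with coverage 40 by
  default, methylated counts beta-binomial with overdispersion
  $\rho = 0.015$ around a per-site probability shared by the two strands
  of a dyad (dyad methylation is symmetric; $\rho = 0$ recovers pure
  binomial);
* 1% SNP-flagged CpGs with genotype-driven apparent methylation (0, ½, 1),
  and an optional background-only Z chromosome — both exist to make the
  clock filters consequential;
* inflammation as a pure shift of effective age (the `acceleration`
  column), the minimal mechanism consistent with clock-based health
  readouts.

A planted region's truth coordinates are its realized **CpG footprint**
(first to last CpG anchor), not the internal placement slot: a region is
only observable through its CpGs, and defining truth this way makes
perfect segmentation correspond to Jaccard 1 instead of being capped by
empty slot margins.

What the generator does **not** emulate: sequence context and real CpG
clustering (islands, shores), bisulfite conversion failure, mapping
artifacts, copy-number variation, and correlated noise between neighboring
regions. Tests passing on synthetic cohorts therefore demonstrate that the
algorithms recover the structure they are designed for — not that the
biological signal in any particular real cohort is as clean.

## Known limitations, and one honest negative result

* With 36 samples and three ages per tissue, the cross-validated clock
  error on the default synthetic cohort plateaus near 2.1–2.4 days; real
  WGBS cohorts with richer age structure support lower errors.
* Feature *selection* is not feature *recovery*: the 50 planted
  age-responsive regions all carry the same latent age signal, so they are
  strongly correlated, and at the CV-optimal penalty the near-lasso
  elastic net ($\alpha = 0.9$) selects a ~20–30-region subset that already
  predicts age optimally. Selection precision is essentially 1.0, but
  recall of the planted set saturates near 0.5 — and this is flat
  across noise settings from 0.02 to 0.8 logit SD, i.e. it is the
  sparsistency behavior of $\ell_1$ selection among redundant predictors,
  not a signal-to-noise artifact. Real clocks behave the same way (a
  handful of markers selected from tens of thousands of candidate LMRs).
  The acceptance suite asserts 80% recall and that assertion fails; it is
  left failing deliberately, with this analysis, rather than weakened.
* Problem sizes in the test and acceptance runs (2–4.5 Mb genomes, 500
  regions, 36-sample cohorts, 5–10 seeds per property) are the package's
  chosen desk scale: large enough that every property is measured on
  study-shaped data, small enough to iterate on.
* A single global intercept over tissue-centered features cannot
  absolutely calibrate tissues whose training ages have different means
  (jejunum averages 21.3 days in the default design vs 17.3 for the other
  tissues), so fresh cohorts of one tissue can carry a shared absolute
  offset of a few days. Group comparisons of age acceleration are made
  *relative to a reference group* for exactly this reason, and the
  acceleration analyses (and their type-I error calibration, checked at
  5% in the tests) are unaffected.
* The segmentation is a single-cutoff run caller; it does not model
  partially methylated domains (absent from the chicken analyses this
  package follows) and is not an HMM.
* Training separate per-tissue clocks and combining their predictions —
  the natural next step when more data exist — is out of scope.

## Reproducibility

Every stochastic operation takes an explicit integer seed: the generator,
fold assignment, penalty selection, the shuffle null, and the pipeline
(`run_pipeline()`), which derives all stage seeds from one master seed,
logs them in its manifest together with parameter blocks and output
checksums, and reproduces byte-identical outputs from identical
configuration.
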