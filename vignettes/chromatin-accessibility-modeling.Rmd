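---
title: "Modeling chromatin accessibility from chromatin features in DHSs"
author: "chromaccess developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling chromatin accessibility from chromatin features in DHSs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(chromaccess)
```

# The model and its assumptions

DNase I hypersensitive sites (DHSs) are nucleosome-depleted regions
whose continuous DNase-seq signal quantifies chromatin accessibility.
`chromaccess` treats accessibility prediction as a regression problem
over DHS regions: for region $i$ the target $y_i$ is the aggregated
DNase-seq signal in that region, and the predictors $x_{ij}$ are the
identically aggregated ChIP-seq signals of chromatin features $j$
(histone modifications and transcription factor binding). Two
aggregations are supported and always applied to predictors and target
alike:

* **max** — the maximum per-base signal over the region;
* **avg** — the base-weighted mean, with uncovered bases contributing
  zero.

The working assumptions are those of the underlying analysis design:
regions are taken exactly as the DHS peaks provide them (no resizing,
merging or flanking windows); signal is piecewise constant with
bedGraph semantics and exactly zero where no segment covers a base;
and signals enter the models untransformed (an optional `log1p` switch
exists but is off by default, since no transform is part of the
reference procedure).

## Prediction power

Models are evaluated by $k$-fold cross-validation (default $k = 10$):
the regions are randomly partitioned into $k$ folds of near-equal size
(differing by at most one), each fold is predicted by a model trained
on the other $k-1$, and the out-of-fold predictions are **pooled**
before scoring. The score is

$$ R^2 = \mathrm{cor}(\hat y, y)^2, \qquad R = +\sqrt{R^2}, $$

the squared Pearson correlation of the pooled predicted-vs-observed
scatter. This is deliberately *not* $1 - SSE/SST$: the reference
procedure plots pooled predictions against observations and reports
the coefficient of determination of the least-squares line through
that scatter, which is exactly the squared correlation. Consequences:
$R^2 \in [0, 1]$ by construction, and the measure is invariant under
positive affine transforms of either argument. Degenerate cases: a
constant observed vector is an error (the correlation is undefined); a
model that produces constant predictions is scored $R^2 = 0$ with a
warning, since such a model carries no ranking information.

## The regression models

Two algorithms are provided through one interface
(`fit_model()` / `kfold_cv()`):

* **lm** — ordinary least squares with intercept. Rank-deficient fits
  keep the QR solution with aliased coefficients set to zero.
* **svr** — epsilon-insensitive support vector regression with a
  radial-basis kernel. No SVM library is available as a dependency in
  the target environment, so the dual problem is solved by a
  sequential-minimal-optimization (SMO) solver written for this
  package (`src/svr_smo.cpp`), using libsvm-style second-order
  working-set selection and the standard stopping rule (maximal KKT
  violation below `tol`, default `1e-3`).

SVR hyperparameter defaults reproduce the defaults of the widely used
libsvm-backed R interface that the reference analysis employed: cost
$C = 1$, insensitivity $\varepsilon = 0.1$, kernel width
$\gamma = 1/\text{(number of features)}$, and standardization of
predictors and target on the **training fold only** (validation data
are transformed with training-fold statistics; predictions are mapped
back to target units). Standardization of constant columns maps them
to zeros rather than dividing by a zero standard deviation. No
hyperparameter tuning is performed inside cross-validation because
none is part of the reference procedure; all parameters are
configurable through `model_config()`.

The solver is verified two independent ways in the test suite: against
an exact solution of the same dual QP computed with `quadprog` on
small instances, and against frozen reference predictions computed
with scikit-learn's libsvm-backed SVR on a fixture regenerated from a
fixed seed.

## Redundancy analysis

`evaluate_combinations()` fits every $k$-feature subset
($k \in \{1,2,3\}$ by default; $\binom{33}{3} = 5456$ three-feature
models for the full design) and the all-feature model, **reusing one
fold partition across all subsets** so that subset comparisons are not
confounded by fold-assignment noise. The top set keeps combinations
with $R > 0.9 \cdot R_{\text{full}}$ — a strict inequality on $R$, not
$R^2$. Exhaustive SVR evaluation of thousands of subsets is expensive,
so the exhaustive stage defaults to the linear model
(`combo_model` in `pipeline_config()`); the algorithm is configurable
when the full SVR sweep is wanted.

Feature enrichment within the top set uses the canonical
hypergeometric construction: the null treats the $N$ top models as a
uniform draw from the $M = \binom{F}{k}$ enumerated models, of which
$K = \binom{F-1}{k-1}$ contain a given feature, and reports the
upper-tail probability $P(X \ge x)$ (enrichment only — depletion is
not flagged). The reference analysis states only "hypergeometric
test"; the model-draw universe and one-sidedness used here are the
standard reading of its counts, and are what the exhaustive-
enumeration oracle in the tests checks. Raw p-values are thresholded
at 0.01 to match the reference criterion; Benjamini–Hochberg adjusted
values are reported alongside for modern practice.

`sample_size_curve()` repeats the whole CV procedure on random region
subsamples of increasing size (500 replicates per size by default, as
in the reference sample-size analysis; test and pipeline runs use
fewer replicates purely for runtime, which changes only the precision
of the reported mean/sd, not the procedure).

# The synthetic world

The generator exists so that every pipeline stage can be exercised and
falsified without external tracks. Its structure mirrors what the
analysis assumes about real data:

* **Regions.** `n_dhs` non-overlapping regions on one synthetic
  chromosome, lengths uniform in `dhs_length_range` (default
  200–1000 bp), placed via random gap spacings (uniform, collision-free
  by construction). Each region carries a latent accessibility
  $a_i \sim \mathrm{LogNormal}(\mu, \sigma)$ (defaults $\mu = 2$,
  $\sigma = 0.8$: non-negative, right-skewed, like sequencing signal).
* **Tracks.** Within region $i$ every track is one unimodal staircase
  bump. The bump is a discretized triangle whose apex segment equals
  the sampled height $h_i$ *exactly* and whose total integral equals
  $h_i w_i / 2$ *exactly* (the flank segments are rescaled to
  compensate for the apex discretization), so per-region max reads
  $h_i$ cleanly while per-region avg equals
  $h_i w_i / (2 \ell_i)$ — diluted by the bump-width/region-length
  ratio $w_i/\ell_i$, which is drawn independently per region and per
  track (default 0.3–0.9). This randomized dilution is what makes max
  aggregation the better readout *by construction*, reproducing the
  direction of the reference max-vs-avg comparison.
* **Heights.** The DNase height is $a_i e^{\epsilon}$,
  $\epsilon \sim N(0, \texttt{dnase\_noise\_sd}^2)$. Feature $j$'s
  height is $s_j u_{ij}^{\beta_j} e^{\epsilon_{ij}}$,
  $\epsilon_{ij} \sim N(0, \tau_j^2)$, with effective latent
  $u_{ij} = \lambda_j a_i + (1 - \lambda_j) b_{ij}$ mixing the shared
  accessibility latent with a feature-private log-normal draw.
  $\lambda_j$ (`latent_share`) is the single redundancy knob: several
  features with high $\lambda$ are informative *and* mutually
  redundant. $\beta_j = 0$ gives a pure-noise feature.
* **Peaks.** Each of `n_peaks` peaks lands fully inside a uniformly
  chosen DHS with probability `p_in_dhs`, otherwise uniformly
  (base-weighted) in an inter-DHS gap without touching any DHS, so the
  observed localization percentage is binomially concentrated around
  the configured rate.
* **Background.** Optional low flat bumps between DHSs
  (`background_height > 0`), off by default: the analysis only reads
  signal inside DHSs, so background exercises I/O realism only.

## The two named configurations

`default_paper_like_config()` echoes the 33-feature design of the
reference dataset: 10 HMs and 23 TFs; a few strongly informative,
highly shared features (the H3k4me2/H3k4me3/H3k9ac analogues,
calibrated so their one-feature prediction power lands near 0.6–0.7 at
$n = 2000$); many moderately informative redundant features; several
weakly informative ones (H3k9me3/H3k36me3/ZNF274 analogues, one-feature
power roughly 0.2–0.35); and one pure-noise feature (SIX5 analogue,
$\beta = 0$) so null behaviour is testable. In-DHS peak probabilities
spread over 0.06–0.82 with the TF class mean (≈0.58) above the HM
class mean (≈0.45), matching the direction of the reference
localization result. Peak counts default to 2000 per feature — far
fewer than real ChIP-seq peak sets (tens of thousands per feature) —
because localization percentages are rate-governed; at 2000 peaks the
binomial standard error is about 1.1 percentage points, which is all
the tests need.

Because the default world's feature links are nearly linear on the
latent scale and its signals heavy-tailed, the linear model is highly
competitive with SVR there: a linear world cannot demonstrate a kernel
advantage. `nonlinear_table1_config()` is the stated world for the
qualitative model-comparison check: convex power links
($\beta \approx 2.2$–$2.8$, low noise, high latent share,
$\sigma = 0.5$), so accessibility is a monotone *saturating* function
of feature signal. There the RBF SVR genuinely outperforms the linear
model, and max beats avg for both algorithms — the direction of every
cell in the reference four-way comparison.

## What a green test does and does not establish

The synthetic world reproduces the *statistical structure* the
analysis assumes (a shared latent, monotone noisy links, controlled
localization rates, redundancy). It does not emulate read-level
artefacts, mappability or GC bias, peak-caller behaviour, chromosome
structure, or the actual ENCODE H1hesc signal distributions. Green
property tests therefore establish that the pipeline measures what it
claims to measure on data with known ground truth — not that the
original study's numeric values (e.g. its $R^2$ of 0.58/0.66 or its
110 top combinations) are recovered, which would require the original
tracks that carry no accession IDs.

# Numerical and design choices

* **Coordinates** are 0-based half-open (BED/bedGraph native) at every
  interface; wiggle input (1-based, per the UCSC standard) is
  converted on read. Internally a 1-based `GRanges` carries the
  intervals so Bioconductor interval machinery does the overlap work.
* **"Any amount of overlap"** means at least one shared base under
  half-open arithmetic; touching intervals do not overlap. A peak
  overlapping several DHSs counts once.
* **Overlapping bedGraph segments are an error**, not summed: bedGraph
  forbids overlap and silent summation would mask corruption.
  Negative signal values are likewise rejected.
* **Class means are unweighted** across features (each feature
  contributes one percentage regardless of peak count), matching a
  per-feature-percentage reading of the reference localization
  summary.
* **Zero-signal features are retained** as constant columns (they
  standardize to zeros) so subset-enumeration counts never change
  silently.
* **Sampling** of regions is uniform without replacement;
  `sample_regions()` with `n` at least the row count returns the
  matrix unchanged.
* **Ties** in combination ranking are broken lexicographically by the
  sorted, slash-joined feature names, making all tables deterministic.
* **Seeds.** Every stage draws from a named substream
  (`derive_seed(master, stage)`), so re-running one stage never
  perturbs another's randomness; all derived seeds stay below
  $2^{31}$.
* **Serialization.** Tables are tab-separated text with headers;
  combination tables carry `R_full` in a comment header so the
  top-set/enrichment steps can be re-run from the file alone. Configs
  round-trip through JSON (the target environment ships no YAML
  package for R; JSON preserves the contract).
* **Empty top sets** (possible at $k = 1$ with a strict threshold) are
  a valid outcome: the pipeline skips the enrichment table instead of
  failing, while `feature_enrichment()` itself still rejects empty
  input as specified.

# Known limitations

* BigWig/BigBed binary formats are not read; inputs are BED,
  bedGraph and text wiggle.
* Strand is ignored throughout (all intervals are strandless), and
  chromosome sizes are not validated against an assembly.
* The exhaustive subset search is limited to $k \le 3$ by design; no
  greedy or stepwise selection is offered.
* No significance procedure is attached to differences between cells
  of the model-comparison table, because none is defined in the
  reference procedure.
* The SMO solver targets dense problems of a few thousand training
  rows (the scale of this analysis); it precomputes the kernel matrix
  and does not implement shrinking or caching for much larger inputs.
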