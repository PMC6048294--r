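---
title: "Constrained ordination of T cell transcriptomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constrained ordination of T cell transcriptomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sc4a)
```

## The model

Correspondence analysis treats a nonnegative gene-by-sample table
$X \in \mathbb{R}^{p \times m}$ as a contingency table. With grand total
$n$, row masses $r_i$ and column masses $c_j$, the residual abundance
matrix is $P = X/n - r c^\top$ and its chi-square standardization is
$S = D_r^{-1/2} P D_c^{-1/2}$, whose squared Frobenius norm is the total
inertia of the table (the chi-square statistic over $n$). Distances
between column scores of the SVD of $S$ reproduce chi-square distances
between column profiles, which is what makes the ordination a faithful
map of compositional similarity between samples.

Canonical correspondence analysis (CCA) restricts this ordination to the
part of $S$ explained by external row covariates $Z \in \mathbb{R}^{p
\times k}$ (standardized to mean 0, variance 1). Genes act as the
"sites" at which expression is measured, and each covariate — for
example the log2 fold change between activated and resting T cells — is
an environmental gradient in ter Braak's sense. The weighted
least-squares projector is

$$Q = D_r^{1/2} Z (Z^\top D_r Z)^{-1} Z^\top D_r^{1/2}, \qquad
  S^* = Q S,$$

and the SVD $S^* = U D_\alpha V^\top$ yields eigenvalues
$\lambda_j = \alpha_j^2$ on $J = \min(p-1, m-1, k)$ axes. Sample scores
are the column principal coordinates $D_c^{-1/2} V D_\alpha$; gene
scores are the weighted averages $G_{wa} = D_r^{-1} P V D_\alpha^{-1}$
(without the $D_\alpha^{-1}$ factor when $k = 1$), which project the
abundance residuals onto the constrained axes. Biplot arrows are Pearson
correlations between the mass-weighted covariates and the left singular
vectors, so variables, samples and genes share one interpretable map.
This CCA is distinct from canonical *correlation* analysis, which
maximizes cross-covariance between two data sets rather than
constraining a chi-square ordination.

Three numerical conventions matter and are fixed here:

* **Sample-score metric.** A literal transcription of the sample-score
  formula with $D_r^{-1/2}$ is not dimensionally conformable ($V$ has
  $m$ rows); the package uses the standard constrained-ordination column
  principal coordinates $D_c^{-1/2} V D_\alpha$, and exposes
  `cca_sample_scores()` with `site`, `species` and `symmetric` scalings
  for users who want the other conventions.
* **Biplot weighting.** The covariate is carried into the chi-square
  metric as $d_n = D_r^{1/2} z_n$ — the same weighting in which the
  singular vectors live — before correlating with $u_j$. This is the
  unique choice under which the one-variable biplot value is *exactly*
  $\pm 1$ (because $u_1 \propto D_r^{1/2} z$), which the scoring system
  relies on. Weighting by $D_r$ itself leaves a residual of order
  $10^{-3}$ on typical tables.
* **Axis orientation.** SVD axes are sign-fixed by making the
  largest-magnitude entry of each $u_j$ positive, so repeated runs and
  plots are bit-reproducible. The one-dimensional activation score,
  Axis 1 sample score times the $\pm 1$ biplot value, is therefore
  orientation-free; negating the covariate negates the score, which is
  the correct semantics ("high score = positively correlated with the
  variable as given").

Rank-deficient $Z$ is handled by a pseudo-inverse with a singular-value
cutoff at $10^{-10}$ of the leading singular value, with a collinearity
warning. Axes whose singular value falls below $10^{-9}$ of the leading
one are treated as null; a fully degenerate constrained space yields an
empty ($J = 0$) solution rather than an error.

## Explanatory variables

Variables are built from differential contrasts: genes passing
FDR $< 0.01$ (Benjamini–Hochberg) and $|\log_2 \mathrm{FC}| > 1$ carry
their log2 fold change, all other genes carry 0, and the column is then
standardized. Zeroing rather than dropping non-selected genes keeps $Z$
row-aligned with the full matrix, which the regression requires; a
`top_n` option additionally restricts to the smallest p-values, since
published analyses often cap the list. The default test is Welch's
t-test; `method = "moderated"` uses limma's empirical-Bayes moderated
t-statistic, which is the method of record for microarray contrasts of
this kind and markedly more powerful at 2–3 replicates per group.

## SC4A: single-cell combinatorial CCA

For unannotated single-cell data the orientation flips: cells are rows
("sites") and genes are columns, so the weighted-average scores become
per-cell scores and the column scores become gene scores. Explanatory
variables are now *genes of the data set itself*, which removes
between-experiment variation from the regression; the chosen columns
are removed from the analysed matrix so a variable can never explain
itself.

The procedure has three steps:

1. **Preliminary ordination** with external activation/resting
   signatures identifies putative populations; cells are labelled
   activated (Axis 1 activation score $> 0$; exact zeros count as
   resting) and marker-positive (expression $> 0$), giving the four-way
   activated/resting × FOXP3$^{\pm}$ labels. Candidate genes are ranked
   per population by cosine similarity between the gene's score vector
   and the population centroid, keeping 5–10 per population (at most 25
   total — the tournament is quadratic in candidates).
2. **Combinatorial tournament.** Every unordered candidate pair becomes
   the $k = 2$ explanatory set of a CCA. In the first two axes of each
   pairwise solution, the angle between a gene's biplot arrow and a
   population's centroid (computed as
   $\operatorname{atan2}(|u \times v|, u \cdot v)$) decides the pair's
   winner for that population, ties breaking to the lexicographically
   smaller gene id. A per-gene F1 comes from the classification rule
   *predict a cell as target-population iff its score vector is closer
   in angle to this gene's arrow than to the competitor's and its
   projection on the arrow is positive*. The rule uses only quantities
   the method already defines (arrows, scores, angles); it is isolated
   in one place so alternatives can be swapped. Genes are ranked per
   population by mean F1 (ties by mean angle) and, separately, by mean
   angle; when the two rankings disagree the package surfaces both and
   requires an explicit preference rather than guessing — choosing the
   immunologically meaningful gene is a human decision.
3. **Final solution** with the selected genes (one per population) as
   explanatory variables; duplicates collapse with a warning.

## Lineages and pseudotime

Per-cell scores of the final solution are clustered with a Gaussian
mixture fitted by EM (mclust; BIC selects the component count and
covariance model when a range is given). A minimum spanning tree over
the cluster centroids — Prim's algorithm with a lexicographic tie-break
so the tree is reproducible — is rooted at a fixed cluster or at the
centroid best aligned with a named arrow (the resting/CCR7 pole in the
motivating analyses). Each root-to-leaf path is a lineage; clusters of
MST degree $\ge 3$ on $\ge 2$ lineages are bifurcation points. Cells of
a lineage's clusters are orthogonally projected onto the piecewise
linear curve through its centroids, and pseudotime is arc length from
the root rescaled to $[0, 1]$ per lineage (the units are arbitrary;
only the ordering is meaningful). This is a deliberate simplification
of simultaneous principal curves (Slingshot): it is fully specifiable,
deterministic, and exact on cells lying near the centroid skeleton, at
the cost of not smoothing curvature within segments.

Module trajectories z-score each member gene across cells
(zero-variance genes contribute 0), sum the z-scores per cell, and
summarise the sum in equal-width pseudotime bins. Quadrant gates count
cells against per-gene thresholds defaulting to the valley of the
kernel density between the outermost modes, mirroring how empirical
gates are drawn on density plots.

## What the synthetic data emulate — and what they do not

The generators are the package's study conditions, not tuning knobs.

* `simulate_bulk_contrast()` draws per-gene baseline log2 means from a
  normal distribution (log-normal intensities, microarray-like),
  Gaussian replicate noise of SD 0.5 on the log2 scale, three
  replicates per group, and shifts 200 of 1000 genes by four noise SDs
  with alternating sign. The 20% induced fraction is mid-range for a
  17-hour anti-CD3/CD28 activation contrast, which remodels a large
  part of the T-cell transcriptome; it also gives the prescribed
  detection calibration (≥ 95% sensitivity at BH 0.01) a proper design
  margin — the expected sensitivity is ~96%, against ~92% if only 5% of
  genes were induced, because the BH threshold adapts to the number of
  true signals.
* `simulate_single_cells()` plants four equal populations (500 cells,
  300 genes by default), each with one exclusive marker (negative
  binomial mean 30 inside, essentially silent outside), four decoys
  that leak into one other population, and a 15-gene program block
  elevated 4-fold in the population. The program block matters: a
  population distinguished by a single gene is not a transcriptional
  state, and without it the F1 ranking honestly prefers decoys because
  sibling populations collapse onto the same region of score space.
  Gradient genes follow the activation level, or latent time when a
  trajectory is configured. Counts are negative binomial with
  dispersion 0.3, so dropout-like zeros arise from the count model.
  Trajectories place cells around chain or Y-shaped cluster skeletons
  (Gaussian scatter, SD 0.25) with the latent time recorded as the arc
  position along the branch.

Not emulated: batch effects, doublets, ambient RNA, platform-specific
intensity artefacts, and library-size variation beyond what the count
model induces. Passing tests on these fixtures therefore demonstrate
the *algorithmic* properties (recovery, calibration, invariances), not
robustness to the full messiness of public single-cell data.

## Problem sizes and defaults

The shipped checks use 500 cells × 300 genes for the tournament (20
candidates → 190 pairwise fits; each fit costs one $k \times m$ SVD via
the orthonormal basis of $D_r^{1/2}Z$, never a $p \times p$ projector),
20 seeded replicates for the recovery properties, and 50 for the
calibration properties. These sizes make every property measurable with
comfortable statistical margins while a full run stays in the
one-minute range on a laptop-class machine.

Key defaults, with units and rationale:

| parameter | default | why |
|---|---|---|
| intensity floor | $\log_2 10 \approx 3.32$ (log2 units) | values below an intensity of 10 are treated as absence; applied per entry, genes left all-zero are dropped |
| DEG filters | FDR $< 0.01$, $|\mathrm{log_2FC}| > 1$ | the selection rule for signature genes |
| gate threshold | 0 (log scale), strict $>$ | any positive expression counts as marker-positive |
| variance/max gene filter | 10th percentile of each distribution | removes only jointly flat *and* low genes (conjunction) |
| outlier removal | PCA (centered), k-means $k = 2$, drop smallest cluster, max 20% of cells | auditable via the attrition report; refuses silent mass deletion |
| candidates per population | 5 (≤ 25 total) | tournament cost is quadratic |
| mixture components | BIC over a range, overridable | the component count is rarely known a priori |
| pseudotime bins | 10 | resolution of the module curves |

## Known limitations

* The piecewise-linear pseudotime underestimates arc length where the
  true manifold curves within a segment, and cells beyond the terminal
  centroids saturate at 0 or 1.
* The F1 classification rule is one defensible reading of an
  under-determined scoring step; the tournament reports both rankings
  precisely because the rule is not canonical.
* In-silico gating with a threshold of zero is sensitive to dropout:
  marker-negative calls conflate true absence with failed capture.
* With fewer than three replicates per group only fold changes are
  reported; no variance model is fitted from one observation.
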