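---
title: "Aligning mammary transcriptomes to a developmental atlas: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning mammary transcriptomes to a developmental atlas: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mammatlas)
```

## The analysis in one paragraph

`mammatlas` places heterogeneous mammary transcriptomes — droplet
single-cell profiles of normal (NM) and conditionally reprogrammed (CR)
human cells, mouse pregnancy-series cells, and bulk tumour profiles — onto
a single mouse developmental reference atlas, and then asks developmental
questions of all of them at once: how embryonic-like is each cell
(*arrow-of-time pseudotime*), which cells co-express lineage-discordant
marker pairs (*hybrid luminal/basal and epithelial/mesenchymal states*),
and how strongly each cell expresses an embryonic-stem-cell program
(*ESC score*). Every analytical claim the package makes is validated
against a synthetic branching-atlas generator with planted ground truth.

## The pipeline, stage by stage

1. **QC** (`qc_filter`): cells with a mitochondrial count fraction above
   `max_mito_frac` (default 0.05) or fewer than `min_genes` (default 200)
   detected genes are removed. Both bounds are strict in the removal
   direction: a cell at exactly 5% mitochondrial reads, or exactly 200
   genes, is kept. Mitochondrial genes are recognised by a configurable
   symbol prefix (default `"MT-"`), since annotation conventions differ
   across references.
2. **Feeder-cell removal** (`remove_feeder_cells`): CR cultures are grown
   on irradiated mouse fibroblasts, which contaminate the cell suspension.
   In a mixed-species reference their transcripts map to mouse genes, so a
   cell whose mouse-prefixed count fraction exceeds `max_mouse_frac`
   (default 0.5) is called a feeder and dropped; the mouse genes are then
   removed from the gene list. A per-cell fraction rule is used because it
   is reproducible without a clustering step: genuine feeder cells are
   nearly pure mouse, so any threshold well away from 0 and 1 gives the
   same answer.
3. **Normalisation** (`lognormalize`, `normalize_batches`): the standard
   global log-normalisation `log(1 + count / total * scale)`. Within one
   dataset `scale = 1e4`. Across batches, `normalize_batches` uses a
   single shared scale equal to the smallest per-batch median library
   size, which rescales every batch to the depth of the shallowest one
   before the nonlinear log step — the depth-matching role that
   multi-batch normalisation plays in this analysis family.
4. **Downsampling** (`downsample`): the reference atlas is downsampled to
   1000 cells with stage proportions preserved by largest-remainder
   rounding (so the target is hit exactly); the pregnancy series instead
   takes an equal 250 cells per stage. Sampling is seeded and without
   replacement.
5. **Alignment genes** (`corgi_select`): a randomized gene-subset
   selector. Each round samples `subset_size` genes with probability
   proportional to their weights and scores the subset by the shared
   structure it induces:
   `score = w1 * mean(variance explained by the top 2 PCs in each
   dataset) + w2 * (fraction of cells in a cross-dataset mutual
   nearest-neighbour pair)`. Weights of sampled genes are multiplied by
   `1 + alpha` when the score beats the running *median* of past scores
   (median, not mean, for robustness to score outliers) and by
   `1 - alpha` otherwise; after `n_iterations` rounds the top `n_selected`
   genes are kept. The scoring functional is this package's own concrete
   choice: it rewards subsets that are simultaneously low-dimensional
   within datasets and mixing across them, which is exactly the property
   the downstream 2-D projection needs. Defaults: `alpha = 0.05`,
   `subset_size = 200`, `n_iterations = 2000`, `n_selected = 1000`, all
   configurable (the test suite uses smaller, faster settings with the
   same structure).
6. **MNN correction** (`find_mnn_pairs`, `correct_query`, `project_all`):
   after cosine normalisation, cells r (reference) and q (query) form a
   mutual nearest-neighbour pair iff each lies within the other's k
   nearest cross-dataset neighbours (k = 20). Each pair contributes a
   difference vector `ref - query`; a query cell's correction is the
   Gaussian-kernel-weighted average of all pair differences, weights
   `exp(-d^2 / sigma^2)` over distances to the paired query cells.
   `sigma = 0.3` on the unit sphere, i.e. a squared bandwidth of ~0.1 —
   the smoothing scale of the published MNN algorithm. This matters: with
   a much narrower kernel each query cell snaps onto its individual
   nearest pair, the corrected dataset collapses into clumps, and
   batch-mixing diagnostics deteriorate rather than improve. Queries are
   corrected **independently** against the fixed reference, never chained
   through one another, so results do not depend on the order or
   composition of the query list; bulk profiles go through the identical
   path with one column per sample.
7. **Embedding and pseudotime** (`fit_reference_pca`, `embed_cells`,
   `fit_arrow`, `pseudotime`): the 2-D PCA is fit on the (corrected)
   reference only and frozen; queries are passively projected, so query
   composition can never warp the atlas. The arrow of time is the unit
   vector from the embryonic-stage centroid to the adult-stage centroid,
   with origin at the overall reference centroid; pseudotime is the dot
   product of origin-centred coordinates with that vector. More negative
   means more embryonic-like, and 0 sits at the atlas centroid. The
   centroid-difference definition is parameter-free; a discriminant
   (LDA-like) direction was considered and rejected as adding a covariance
   estimate without changing the qualitative geometry.
8. **Group contrasts** (`compare_groups`): a Gaussian linear model of
   pseudotime on group indicators; with two groups this is algebraically
   the pooled-variance t-test, which the suite asserts to 1e-9.
9. **Hybrid states** (`classify_hybrids`): a cell is a "high expressor"
   of a marker when its log-normalised expression reaches the 50th
   percentile of that marker over all analysed cells *and* is nonzero.
   KRT18+/KRT14+ cells are luminal/basal (L/B) doubles, EPCAM+/VIM+ cells
   epithelial/mesenchymal (E/M) doubles, and cells high in all four are
   quadruple positives — by construction members of both double sets,
   which the code asserts on every call. EPCAM is the default epithelial
   marker for its high expression; CDH1 can be substituted via
   configuration. Triple-positive combinations are computable via custom
   marker configurations but not reported by default.
10. **ESC score** (`esc_score`): the fraction of a cell's *raw* counts
    falling on an embryonic-stem-cell gene set — raw, because the score
    is defined as a proportion of reads, and per-cell proportions are
    invariant to the normalisation that follows.
11. **Plumbing DE** (`simple_de`, `signature_overlap`): a per-gene
    Wilcoxon rank-sum test with BH correction and a pseudocounted log2
    fold change, used only to feed signature-overlap tallies (e.g. the
    200-gene EMT hallmark set against quad-hybrid markers). It is
    deliberately the simplest defensible DE, not a mixed-model method.

`run_pipeline` executes these stages in order from a single validated
configuration; every stochastic stage draws its seed as a hash of the
global seed and the stage name, so adding a stage never perturbs the
randomness of earlier ones, and the run manifest records checksums that
are bitwise reproducible across reruns.

## Design of the synthetic atlas generator

The generator (`generate_reference`, `generate_query`, `generate_bulk`)
is first-class, tested code: it defines the conditions under which the
pipeline's guarantees are stated.

**Latent structure.** Each cell has a latent time t in [0, 1] drawn
uniformly within its stage's window (E16, E18, P4, Adult for the
reference; nulliparous/gestation/lactation/post-involution windows for
the pregnancy series, where gestation revisits mid-developmental times).
Cells develop along a common path until `branch_time = 0.6`, then commit
to a luminal or basal lineage with equal probability.

**Gene programs.** 460 genes split into epithelial (40, led by EPCAM),
mesenchymal (40, VIM), luminal keratin (40, KRT18), basal keratin (40,
KRT14), embryonic-stem (100), housekeeping (80) and pure-noise (120)
programs. A gene's log relative expression is
`base + loading * activation(cell)`; counts are negative-binomial
(dispersion 0.1, typical of UMI data) around library-size-scaled per-cell
proportions, with log-normal library sizes around 3500 UMIs. Program
loadings are 2.2–3.0 natural-log units, i.e. a 3–4.5 log2-fold dynamic
range, in line with canonical marker genes.

Three design points came out of building this generator and are worth
recording:

* **The embryonic program must decay across the whole life course**
  (activation `1 - t`), not just until the branch point. If it bottoms
  out at the branch, the post-branch time signal is carried only by the
  keratin ramps, which are antisymmetric between lineages and cancel in
  the lineage-averaged geometry — pseudotime then cannot order P4 vs
  adult cells. A monotone global maturation axis is also the
  biologically expected behaviour of embryonic gene expression.
* **Canonical markers need an abundant baseline** (their head genes get
  an elevated base mean). Percentile-threshold calls on a marker sampled
  at a handful of UMIs per cell drown in counting noise; the real
  markers are among the most abundant transcripts in their cell types,
  and the epithelial marker was chosen in this analysis family precisely
  for its high expression.
* **Compositional renormalisation eats into planted effects.** A
  quadruple hybrid activates four programs at once, inflating its total
  expected expression; because UMI counts are proportions of a library,
  this deflates each individual marker's share. Planted hybrids
  therefore activate their programs at 1.4x the lineage maximum — an
  over-expression effect size that survives the denominator and leaves
  the four-marker co-expression, not any single extreme marker, as the
  distinguishing feature.

**Batch effects and contaminants.** Queries add i.i.d. gene-wise Gaussian
log-fold offsets (sd 0.5) — exactly the additive structure MNN correction
is designed to remove. A configurable fraction of query cells are feeder
cells expressing only mouse-prefixed genes (including `mm10-Gapdh`).
Stem-like cells (full embryonic-program activation regardless of age)
and hybrid cells are planted with per-stage fractions; the CR analogue
raises both, the pregnancy-series analogue concentrates E/M hybrids in
gestation.

**What the generator does not emulate** — and hence what passing tests do
*not* show about real data: doublets, cell-cycle structure, ambient RNA,
zero inflation beyond the negative binomial, spatial effects, nonlinear
(gene-specific, cell-state-dependent) batch distortions, and the real
subtype composition of bulk tumour cohorts. Recovery statements are
statements about data whose generative assumptions match the model above.

## Numerical choices and degenerate inputs

* Percentiles use the linear-interpolation definition (R type 7), so the
  median of (1, 2, 3, 4) is 2.5.
* The 50th-percentile marker thresholds are computed over **all** cells
  of the analysed (post-downsampling) set, zeros included, with an
  additional nonzero requirement. For sparse markers whose median is 0,
  dropping that guard makes every cell "high" — a documented degeneracy
  the default avoids. Thresholds are per analysed dataset.
* kNN ties break toward the smaller cell index; PCA component signs are
  fixed so each component's largest-magnitude loading is positive; both
  make results bitwise reproducible.
* Constant genes get pseudotime correlation 0 with a flag, keeping
  rankings total; the DE fold change uses a 1e-9 pseudocount; a zero
  fold change counts as "up" in overlap splits so the up/down tally is a
  partition.
* `project_all` clamps k below the size of small queries (e.g. a
  handful of bulk samples) instead of refusing; `find_mnn_pairs` itself
  stays strict.
* Kernel underflow in the correction (a query cell far from every pair)
  falls back to the single nearest pair rather than dividing by zero.

## Problem sizes and what the suite enforces

The validation suite runs the generator at the study's own scale — a
1000-cell four-stage reference, 500–1000-cell queries, 460–500 gene
panels — and enforces, among others: Spearman correlation of at least
0.9 between pseudotime and planted latent time with strictly increasing
stage means; sensitivity and specificity of at least 0.8 for planted
quadruple hybrids; a one-sided rank-sum p below 0.001 separating planted
stem cells on the ESC score; the gestation dip-and-recover pseudotime
arc with the E/M hybrid peak at gestation; exact agreement of the MNN
search with a quadratic brute-force oracle; recovery of a constant
batch shift to below 1e-6; and at least 2x-over-chance recovery of
planted-structure genes by the subset selector. The gene-subset
selector's test configuration (50 planted among 500 genes, 300
iterations of 50-gene subsets) keeps the full suite under half a minute
on one CPU while preserving the algorithm's structure.

## Known limitations

* Pseudotime lives in an arbitrary 2-D PC plane; its units are not
  comparable across differently fit references, and a 2-D linear
  projection cannot represent trajectories that fold back on themselves.
* The centroid arrow mixes in lineage signal whenever adult lineages are
  unbalanced in the reference; the frozen-reference design prevents
  queries from amplifying this but does not remove it.
* MNN correction assumes shared populations between reference and query;
  a query population absent from the reference will be dragged onto its
  nearest (wrong) reference neighbourhood.
* The percentile-based hybrid definition is relative to the analysed
  cell set: proportions are comparable within one analysis, not across
  datasets thresholded separately.
* `simple_de` ignores per-individual correlation; it is plumbing for
  overlap tallies, not a replacement for mixed-model DE.
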