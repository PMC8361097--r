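---
title: "Methods: signatures, latent-time transfer, ligand-receptor scoring and cellular niches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signatures, latent-time transfer, ligand-receptor scoring and cellular niches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichemap)
```

nichemap implements a connected set of procedures for studying how a tumor
cell population shapes its microenvironment, across three modalities:
single-nucleus RNA-seq (snSeq) of tumors and normal epithelium, spot-based
spatial transcriptomics on a hexagonal array, and multiplexed antibody
imaging at single-cell resolution. This vignette describes each model, its
assumptions, the tunable parameters, and the design decisions taken where
the procedure was genuinely open.

## Preprocessing

**Hashtag recovery.** Multiplexed snSeq samples carry hashtag oligos (HTOs).
Initial demultiplexing calls (singlet / doublet / negative) are an input;
`demux_recover()` re-examines initial negatives and reassigns a cell to a
hashtag when its counts exceed the per-hashtag minimum for *exactly one*
hashtag. Doublets are never reassigned; a negative passing two thresholds
stays removed. This recovers real cells lost to over-conservative initial
calling without touching ambiguous ones.

**Nuclei QC.** `qc_filter_nuclei()` removes nuclei with a mitochondrial UMI
fraction *strictly above* 0.10 (a cell at exactly 10% is retained), then
trims the top and bottom 5% of the survivors by unique-gene count and by
total UMI. The two percentile rules are applied jointly to the same
surviving set: the order of the two tails is unspecified in common practice
and a joint application is order-free. Cells exactly at a percentile
boundary are retained (minimal-removal reading). Mitochondrial fractions
are always computed on raw counts. Note that percentile-tail trimming is a
one-shot operation: re-applying it to its own output trims fresh tails, so
only the absolute-threshold rules are idempotent.

**Spot QC.** `qc_filter_spots()` keeps spots with ≥ 1,250 total UMI and a
mitochondrial fraction below 10%, then drops genes detected in fewer than 4
surviving spots.

## Differential expression and signatures

`de_rank_genes()` scores each gene with the two-sided, tie-corrected
Wilcoxon rank-sum z statistic of one group against all other cells in
scope (one-vs-all), the standard marker statistic for single-cell data.
Log2 fold changes are computed on expm1-ed means of log-normalized
expression with a 1e-9 pseudocount; Benjamini–Hochberg adjustment is
applied within each group's gene list. Normalization (`normalize_log()`)
is counts-per-10,000 followed by natural `log(1+x)`.

`derive_subtype_signatures()` takes each group's top 200 genes by score.
A gene reaching several top lists is assigned only to the group where its
score is highest, so signatures within a compartment are disjoint.

`coexpression_modules()` filters genes by DE (FDR ≤ 0.05, |log2FC| ≥ 0.3),
then requires at least 5 correlation partners at |Pearson r| ≥ 0.4, and
partitions survivors by hierarchical clustering of their correlation
profiles (Euclidean distance). The linkage (complete) and the cut are not
dictated by the procedure's definition; when no module count is supplied
the cut maximizing the mean silhouette width over 2–10 modules is used.

Two gene-set scores are provided. `score_cells_binned()` compares the mean
expression of a signature to control genes sampled from the same
mean-expression bins (25 bins, 50 controls per gene), removing
expression-level bias. `score_samples_ssgsea()` is a single-sample,
rank-weighted running-sum enrichment statistic (weight exponent 0.25,
running-sum integral normalized by the number of non-signature genes); it
depends on expression only through ranks, hence is invariant to monotone
transforms. `quartile_stratify()` groups samples by empirical score
quartiles for downstream survival-style contrasts (the survival fitting
itself is out of scope).

## Latent-time transfer

Normal epithelium carries a latent differentiation time on [0, 1]
(estimated upstream; an input here). `select_latent_genes()` ranks genes
per normal sample by Pearson correlation with latent time and keeps the
top 500 with r ≥ 0.3, unioned across samples. The threshold is applied to
the *signed* correlation by default — the literal reading of a "minimum
correlation" — with `use_absolute = TRUE` available.

`transfer_latent_time()` assigns each tumor cell the latent time of the
normal cell minimizing the L1 distance of log-normalized expression over
the latent gene list (genes missing from either matrix are dropped with a
message; ties break to the lowest normal-cell index, making the transfer
deterministic). Inherited times therefore never extrapolate beyond the
normal cohort's range. `interval_signatures()` bins tumor cells into 5
equal-width intervals of inherited time and derives disjoint top-200
signatures per interval with the same cross-list tie-breaking as above.

## Receptor activity and ligand-receptor interactions

Receptor activity summarizes downstream pathway engagement rather than
receptor expression: for receptor *r* and cell *c*,
activity(c, r) = mean over the receptor's signature genes *g* of
|x(c, g) − μ_bg(g)|, where μ_bg is the gene's mean over all cells of *c*'s
broad compartment. Receptors with fewer than 5 signature genes are
excluded (`build_receptor_signatures()`). Signature gene lists are taken
directly from the prior table; the package does not walk signaling graphs
to assemble them, because the activity definition only needs the lists.
Backgrounds are pooled across samples by default (per-sample backgrounds
can be obtained by calling `receptor_activity()` per sample). The
deviation is computed on log-normalized expression, consistent with the
surrounding analyses.

Interaction calling proceeds in four stages, orchestrated by
`call_interactions()`:

1. **Available ligands** — one-vs-all DE of ligand genes within the
   sender's broad compartment; thresholds log2FC ≥ 0.5, BH p ≤ 0.05,
   expressed in ≥ 10% of sender cells (all boundaries inclusive).
2. **Active receptors** — the same rank-sum machinery applied to the
   receptor-activity matrix within the receiver compartment; thresholds
   log2FC ≥ 0.25, BH p ≤ 0.05, receptor gene expressed in ≥ 10% of
   receivers. Because activities are on a linear scale, their fold change
   is the plain log2 ratio of group means (no expm1 back-transform).
3. **Spatial co-expression** — a pair survives if, in at least one spatial
   sample, ≥ 25% of spots expressing the ligand (UMI > 0) also express the
   receptor (UMI > 0); the 25% boundary is inclusive.
4. **Potential and transparency** — interaction potential is the product
   of mean ligand expression over sender cells and mean receptor activity
   over receiver cells; rendering transparency is
   min(0.9, 1 − (potential / potential_max)²), so the strongest ribbon
   drawn together with its peers is opaque and none exceeds 90%
   transparency.

## Hexagonal ring profiles and concurrence

Spots live on an array frame in which the second coordinate is doubled
(`hex_grid()`), so x + y has constant parity and the six immediate
neighbors of (x, y) are (x ± 1, y ± 1) and (x, y ± 2). `hex_ring()`
implements the ring-index formula in exactly this printed form: ring *k*
contributes the six offsets (x ± (k+1), y ± (k+1)) and (x, y ± (k+2)).
For k ≥ 1 with odd k the two axial offsets (x, y ± (k+2)) leave the parity
lattice; such positions are flagged and treated as missing, never
zero-filled, and a `full_ring = TRUE` mode provides the complete 6(k+1)
hexagonal ring for users who want exhaustive coverage.

`reference_spots()` takes the top 5th percentile of a module score (ties
at the cutoff included). `ring_profile()` averages a gene's log-normalized
expression over existing ring spots, then over references;
`ring_profile_matrix()` z-scores profiles across modules per ring index
for display. `concurrence_test()` contrasts spots in the top and bottom
5% of a module score, classifies each spot's gene expression as top-5%
versus bottom-95%, and applies a one-sided Fisher exact test for
enrichment.

## Imaging: typing, niches, diversity, proximity

**Masks.** `expand_masks()` grows each nucleus by up to a radius without
overlap: contested pixels go to the nearest nucleus, so boundaries between
adjacent cells are equidistant. `ring_percentage()` reports, per nucleus
and marker, the percentage of pixels in the band just outside the nuclear
contour (default width 3 px, configurable — the band width is a free
parameter) with intensity strictly greater than 20. Surface-positive cells
show ring-like signal; neighbors that merely clip a positive cell's signal
do not, which is the feature's purpose.

**Typing.** `gate_training_set()` applies declarative intensity/ring-%
gates conjunctively per class and discards cells matching several classes.
`balance_classes()` caps each class at 2,500 training cells by uniform
subsampling. `knn_classify()` robust-scales features (median/IQR fitted on
training), then assigns the modal label among the k nearest training
cells — k = 200 for broad typing and k = 100 for T-cell subsets by
convention — with uniform weights and deterministic label-order
tie-breaking. The class roster is entirely config-driven (the gates you
pass define it). `rescue_classify()` runs 10 rounds of kNN (k = 20) on
per-round balanced subsamples (≤ 500 per class) and takes the majority
label across rounds; rescues into designated immune classes are rejected
and removed rather than relabeled.

**Niches.** `neighborhood_profiles()` tallies, for every cell, the
fraction of each broad type among its ≤ 10 nearest neighbors within 200
image units *plus the cell itself* (11 cells when 10 neighbors exist;
fewer when the distance cap bites). `select_k_niches()` clusters profiles
with k-means for each candidate k, splits cells half/half, fits one
1-vs-all logistic classifier per cluster (ridge penalty, λ = 0.01) on the
training half and reports the mean rank-based (Mann–Whitney) AUC on the
holdout; k = 1 is degenerate and skipped. `detect_niches()` performs the
final k-means and labels each niche by the broad types with the largest
positive classifier coefficients. k-means uses Hartigan–Wong with 10
random restarts under a fixed seed — restart stabilization serving the
role of a careful initialization. `merge_niches()` merges an explicitly
named pair (the real-data merge is a judgment call, so the interface is
explicit) or all pairs above a centroid-correlation threshold.

**Statistics.** Niche diversity is the Shannon entropy
S = −Σ P(xᵢ) log P(xᵢ) of the subtype frequencies over unique member
cells, in natural log (so S ranges from 0 for a pure niche to log n for n
equally frequent subtypes). `subtype_enrichment()` runs two-sided Fisher
tests of (in niche) × (is subtype); `marker_enrichment()` compares a
marker's intensity on one subtype inside a niche versus the same subtype
elsewhere (two-sided Wilcoxon; sides with < 3 cells are skipped).
`proximity_analysis()` computes, per spot, the median distance from each
query cell to its nearest target cell (a cell is never its own nearest
target) and compares two query subtypes across spot-level medians with a
Mann–Whitney test; only spots with ≥ 25 cells of every type examined are
evaluated. Distances are raw image coordinates throughout.

## The synthetic-data generators

Every analysis stage is exercised on generated data with planted ground
truth, so the package is testable end to end without external downloads.
The generators emulate the *statistical structure* the methods assume:

- `generate_tumor_cohort()`: negative-binomial UMI counts (mean 0.8,
  dispersion 2 — typical sparse nuclei data) for six subtypes across an
  epithelial and a fibroblast compartment, 200 cells each; 10 planted
  markers per subtype at log2FC 3 (subtype-defining genes are strong,
  near on/off markers); mitochondrial genes scaled per cell to a 2–8%
  fraction; an HTO table with 82% singlets, 8% doublets, 6% recoverable
  negatives and 4% true negatives.
- `generate_normal_cohort()`: uniform latent times; 50 time genes whose
  means rise six-fold across the axis with a milder residual dispersion
  (the time trend absorbs most of their biological variance), giving
  count–time correlations around 0.5–0.7. Gene-level baselines are drawn
  under a separate `base_seed` so distinct cohorts share them, as cells of
  one tissue do.
- `generate_visium()`: a parity-constrained hexagonal grid; 20
  housekeeping genes carry spot totals that straddle the 1,250-UMI
  boundary while the remaining genes are sparse; a contiguous ~5% region
  carries an elevated module program with co-elevated companion genes;
  `region_genes`/`anti_genes` plant spatially concordant or discordant
  gene pairs.
- `generate_codex()`: cells scattered over cores divided into niche bands
  with configured broad-type compositions; one high identity marker per
  broad type; a CD49a-like channel elevated on CD8 T cells inside the
  tumor niche by `marker_shift` intensity units.
- `generate_lr_prior()`: ligand-receptor pairs with signature gene lists,
  10% of receptors deliberately under the 5-gene minimum.

What the generators do **not** emulate: batch and sample effects, ambient
RNA, doublet expression profiles (HTO classes are planted directly),
segmentation errors, spatial autocorrelation beyond the planted regions,
and marker spillover between adjacent cells. Passing tests therefore
demonstrate correctness of the procedures and recoverability of planted
structure under idealized noise — not robustness to every artifact of
real tissue data.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: constant scores in quartile or
reference-spot selection warn; empty latent-gene lists, empty priors and
empty matrices error; empty niches and undersized test sides are skipped
with warnings. All stochastic steps (control-gene sampling, class
balancing, k-means, train/holdout splits) take explicit seeds, and every
generator is byte-reproducible under a fixed seed.

The test suite and the acceptance script run the pipeline at deliberately
compact sizes — 1,200-cell cohorts, 30×30 spot grids, 5,000-cell imaging
tables — chosen so the full suite completes in well under a minute while
every recovery statistic (niche ARI ≥ 0.8, latent-time Spearman ≥ 0.8,
marker top-ranking) retains a comfortable margin over its threshold at
these sample sizes.

## Known limitations

- The printed ring formula yields six axial positions per ring index, not
  the full hexagonal ring; we implement it as printed (with `full_ring`
  opt-in) and surface the count of parity-invalid positions.
- Receptor activity's absolute-deviation form cannot distinguish
  activation from suppression; with few subtypes per compartment the
  background mean sits between them and fold changes compress.
- ssGSEA scores are comparable within a cohort scored together, not
  across cohorts.
- kNN typing inherits the gating's class definitions; classes absent from
  the gates cannot be predicted.
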