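---
title: "Methods: co-segregation, similarity and luminosity analysis of a discordant-twin family"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-segregation, similarity and luminosity analysis of a discordant-twin family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinscope)
```

## The study design

twinscope implements the analysis pipeline for a particular, and particularly
informative, family design in reading-disability research: a nuclear family
of two parents, a pair of dizygotic twins discordant for specific reading
disability (SRD — exactly one twin affected), and an older sibling who is
also affected. Genotypes are available for all five members; structural MRI
morphometry for the three siblings. The discordant twins are the core
contrast: risk factors that track affection status within this family should
be *shared by the two affected siblings and differ in the unaffected twin*,
despite the twins' matched age and environment.

Three analysis families are implemented, plus a synthetic-data generator
that makes all of them testable without access to any protected subject
data.

## Genotype QC and co-segregation filtering

Array genotyping assigns each call a per-genotype confidence score (a
GenCall-style score in [0, 1]). QC is applied per sample: every call with a
score **less than or equal to 0.15** is set missing — such calls sit too far
from their cluster centroid to be trusted. The boundary is inclusive by
definition, and `apply_gencall_qc()` treats it that way; a test pins the
behaviour at 0.15 exactly.

The filter chain is fixed and order-sensitive:

1. **QC** (`apply_gencall_qc()`): mask low-confidence calls.
2. **Invariant removal** (`drop_family_invariant_snps()`): a SNP identical
   in all five family members carries no within-family information and is
   removed. SNPs with a missing call in any family member are removed too:
   a partially-missing SNP cannot be certified variable. Both counts are
   recorded.
3. **Pattern match** (`find_cosegregating_snps()`): a SNP co-segregates
   when the two affected siblings share a genotype and the unaffected
   twin's genotype differs from that shared genotype. Genotypes are
   compared as unordered allele multisets — array data are unphased, so
   `A/G` equals `G/A`. SNPs missing in any of the three siblings are
   excluded rather than imputed (conservative, and it keeps the planted
   ground truth exactly recoverable).

Parents enter step 2 (the design reads "invariant across the family"
literally) but not step 3, which is defined on the three siblings only.
Per-gene and per-functional-class tallies are computed from annotations, and
the proportion of pattern-matching SNPs among variable SNPs is compared
between the 28-gene reading panel and a genome background processed
identically (`background_comparison()`).

Gene assignment (`annotate_snps()`) is interval containment with an optional
flank, resolved to the nearest gene midpoint when intervals overlap. A
supplied functional-class annotation column is always honoured; the
interval-based fallback (gene body → intronic, flank only → intergenic) is
approximate and labelled as such. The default panel ships **synthetic**
interval coordinates (a deterministic layout), because the package performs
no external annotation-database queries; real analyses should read measured
coordinates from a BED-derived TSV (`read_gene_panel()`, which converts
half-open BED starts to the 1-based inclusive convention used throughout).

## Pairwise ICC of regional morphometry

Similarity of sibling morphometry is summarised by pairwise intraclass
correlations over regional averages, once across a whole-cortex
parcellation and once across the reading-related subset (fusiform, inferior
parietal, banks of the superior temporal sulcus, pars opercularis, pars
triangularis, supramarginal, transverse temporal).

Design choices the underlying study description leaves open, and how this
package resolves them:

* **ICC form.** Default `ICC(2,1)` — two-way random effects, absolute
  agreement, single measure. The siblings are interchangeable measurements
  of the same regional anatomy, so a constant offset between siblings
  *should* count against similarity. `ICC(1,1)` and `ICC(3,1)` are
  selectable, and every report prints the form used.
* **Items.** Each (ROI, hemisphere) average is one item; hemispheres are
  not averaged together, preserving asymmetry information in the item
  vector. With the 7-region reading set this gives 14 items per ICC.
* **Degenerate inputs.** Zero variance across items makes every ICC form
  undefined; this raises a classed error rather than returning a number.
  Fewer than 3 items is an error as well.

The implementation computes the classical ANOVA mean squares directly
(closed form for *n* items × 2 raters); tests verify all three forms against
an independent `stats::aov`-based oracle and check the exact identities
(self-ICC = 1; a constant shift leaves `ICC(3,1)` at 1 while lowering
`ICC(2,1)`).

## Asymmetry indices

Lateralization is measured per subject, ROI and phenotype as

$$AI = \frac{L - R}{(L + R)/2},$$

positive for leftward asymmetry, negative for rightward, bounded in
(−2, 2) for positive inputs, antisymmetric under hemisphere swap and
invariant to common rescaling. Direction is classified with a tolerance:
|AI| ≤ ε counts as symmetric, with ε = 0.01 by default — indices of that
magnitude are far below anatomical meaningfulness for these phenotypes —
and configurable everywhere it is used. The asymmetry report covers the
reading regions plus the superior temporal gyrus, whose thickness asymmetry
is of particular interest in this design.

## The luminosity-composite technique

The novel image-level comparison works directly on template-space binary
ROI masks:

1. **Slice** (`slice_mask()`): each 3D mask is cut into 2D binary slices
   along each anatomical axis (sagittal = x, coronal = y, axial = z on an
   RAS+ grid — the axis convention is fixed because slicing must be
   unambiguous). Only slices containing the ROI are kept, in anatomical
   order; realistic masks yield roughly 30–70 slices per axis.
2. **Composite** (`build_composite()`): the slices are opacity-layered into
   one grayscale image. The package uses the explicit rule
   `luminosity = min(255, round(255 · c / alpha_ref))`, where `c` counts
   the slices in which a pixel is foreground. Linear count scaling is the
   simplest rule that makes brighter pixels mean "present in more slices",
   and it makes the brute-force per-voxel projection oracle exact. The
   standardization constant `alpha_ref` is the maximum slice count over
   subjects for one (ROI, axis) — shared, so luminosities are comparable
   between subjects whose brains differ in size or scanner position. An
   `alpha_ref` below the stack size is rejected (it would saturate
   asymmetrically).
3. **Distribution** (`extract_distribution()`): the multiset of foreground
   pixel luminosities. Background (zero-luminosity) pixels are excluded by
   default — they encode mask footprint, not thickness — with an
   `include_zero` dialect available.
4. **Q–Q comparison** (`qq_compare()`): quantiles of two distributions are
   matched at levels k/(n+1), k = 1..99, with linear interpolation between
   order statistics (`stats::quantile` type 7; the grid and rule are fixed
   so curves are reproducible). Two constructions are used: the three
   inter-sibling pairs per ROI (twin–twin as the within-family baseline,
   the SRD pair, and the TD-twin/older-sibling pair), and intra-subject
   ROI pairs over all combinations within the ventral (2 ROIs → 1 pair),
   frontal (3 → 3) and dorsal (6 → 15) reading pathways. Axes are analyzed
   separately and never mixed.

The **divergence score** — mean absolute quantile difference divided by the
255 luminosity range — is an artifact addition: the underlying visual
technique reads Q–Q plots by eye, but a scalar is required for testable,
automated comparison. It is 0 exactly when the matched quantiles coincide,
symmetric in its arguments, and reported as such (clearly separated from
the raw curves) in all outputs. `most_similar_pair()` labels the minimal
divergence pair per ROI, breaking ties toward the twin–twin baseline and
flagging the tie with its margin.

Composites are written as 8-bit grayscale PNG, byte-deterministically.
Binary slices are assumed throughout (no anti-aliased mask edges).

## The synthetic-family generator

`sim_config()` fixes every data-generating choice; any artifact regenerated
from the same config is byte-identical. The defaults are the reference
case family's study conditions:

* **Genotypes**: an 800-SNP panel over the 28 reading genes with 14.5%
  family-invariant SNPs (leaving 684 variable) and exactly 79 planted
  co-segregation SNPs; a 2000-SNP genome background planted at the same
  rate (the case family's panel proportion was consistent with its genome
  background); per-call missingness 1% (typical array no-call rates).
  Children's genotypes are built from one transmitted allele per parent, so
  trios are Mendel-consistent by construction (verified by an independent
  brute-force checker). Every non-planted, non-invariant SNP is generated
  by rejection so that it is *neither* invariant *nor* pattern-matching:
  the planted set is therefore recoverable exactly (set equality) when
  missingness is zero.
* **Morphometry**: sibling-pair similarity targets default to the case's
  reading-region ICCs (SRD 0.76 > twins 0.66 > TD-OS 0.54 for thickness;
  0.99/0.97/0.95 volume; 0.99/0.96/0.95 area). The generator plants the
  *empirical* inter-sibling correlation matrix exactly: latent item vectors
  are mean-centred, orthonormalized and mixed through a pivoted Cholesky
  root of the target matrix (the pivoted factorization also handles
  rank-deficient targets such as correlations of exactly 1). Independent
  Gaussian measurement noise (`noise_sd`, default 0.05 standardized units)
  is added afterwards. A sampling-based generator was rejected by a design
  calculation: at 14 reading-set items, iid sampling at the case ICC values
  recovers the planted full ordering in only about half of simulations —
  the planted truth would not be a usable test oracle. Exact planting makes
  ordering recovery a property of the pipeline rather than of sampling
  luck, at the cost of realism in the item-level sampling distribution
  (real ICC estimates fluctuate more than simulated ones; tests calibrated
  on this generator say nothing about the sampling error of real data).
  Where an asymmetry index *a* is planted for a (subject, ROI, phenotype)
  cell, the hemisphere values are replaced by the exact solution
  L = m(1 + a/2), R = m(1 − a/2) around the cell's generated mean, so the
  index round-trips to machine precision. Asymmetry overrides take
  precedence over similarity planting in the affected cells.
* **Masks**: connected ellipsoid slabs on a shared 96³ RAS+ grid with
  per-axis nonzero slice counts drawn from [30, 70] and forced exactly (the
  semi-axes are set just under the requested half-extents). Per-subject
  shape similarity is planted through relative scale offsets
  (`mask_profile`) plus N(0, 0.02) size jitter; base counts are drawn with
  enough headroom that every subject's scaled count stays inside the range,
  because boundary clamping would silently erase the planted structure.
  Ellipsoids do not mimic cortical geometry — for comparing luminosity
  *distributions* the essential structure is a smooth solid with
  controllable extent per axis, and slabs keep the projection oracle
  tractable; conclusions about real cortical shapes are out of scope.

## Problem sizes and numerical choices

The test suite and the acceptance script run on these sizes: genotype
tables of 100–1,000 SNPs (the brute-force co-segregation oracle is run up
to 1,000); composites checked against the per-voxel projection oracle on
8³–16³ masks; quantiles against a sorted-sample oracle on samples of
371–1,000 values; recovery studies use 200 simulated cohorts each — the
ICC-ordering study on the 14-item reading set at the default (case-study)
similarity targets, the mask study on one ROI with planted offsets
(0, +0.05, −0.15) for (affected twin, older sibling, TD twin) and the
default jitter. Observed recovery in development runs was 100% for the ICC
ordering and 95–98% for the mask pairing across seeds.

Numerical conventions: coordinates are 1-based inclusive (VCF convention;
BED input is converted on read and the conversion logged); genotypes are
stored allele-sorted so equality ignores order and phase; ICC confidence
intervals use the F-based forms for ICC(1,1)/ICC(3,1) and the
Shrout–Fleiss approximation for ICC(2,1); divergence ties in
`most_similar_pair()` break toward the twin–twin baseline and are flagged.

## Known limitations

* Three siblings cannot support significance tests across pairs; the
  pipeline deliberately reports descriptive ICCs, indices and divergences
  without cross-pair inference.
* The synthetic generator plants no linkage disequilibrium, no realistic
  allele-frequency spectrum, and no cortical geometry; it exists to make
  the pipeline's logic testable, not to emulate biology.
* The interval-based functional-class fallback is approximate; supply a
  precomputed annotation column for real data.
* Whether luminosity axes should ever be pooled is left to the user; the
  package analyzes them separately (a pooled run is a sequence of per-axis
  runs).
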