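---
title: "Quantifying monogenic OR expression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying monogenic OR expression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tandemor)
```

## The scientific problem

Insect odorant receptor (OR) genes sit in tandem arrays of head-to-tail
paralogs, yet each olfactory sensory neuron (OSN) translates only one
"chosen" OR. tandemor implements the quantifications by which this
singularity can be established from genomic and imaging data: the geometry
of tandem arrays, the coverage signature of transcriptional readthrough
past polyadenylation sites, antisense transcription and bidirectional
promoters, the single-cell "staircase" of chosen-plus-downstream OR
coexpression with antisense lncRNA coupling, and nuclear-versus-cytoplasmic
RNA-FISH signal classification. A seeded synthetic-data module generates
inputs with the statistical structure each analysis assumes, together with
ground truth, so the whole pipeline is testable without external datasets.

## Genome annotation and tandem arrays

Annotations are held as a tibble of gene records with exon and CDS interval
list-columns. Coordinates are 0-based half-open internally and converted at
the GFF3/GTF boundary (1-based inclusive on disk). OR status is not a GFF
concept, so `read_annotation()` assigns biotypes by configurable rules: an
explicit OR id list, an id regex, and the `gene_biotype` attribute for
lncRNAs.

`detect_tandem_arrays()` chains ORs whose inter-gene gap is at most
`max_gap` (default 10 kb) regardless of strand, so inverted members remain
in their array; inversions in real arrays show that membership must be
strand-agnostic, and 10 kb is the conventional chaining distance for
insect OR clusters. The gap is measured against the running maximum end
coordinate, which makes the chaining exactly equivalent to the transitive
closure of the pairwise gap relation even for nested or overlapping gene
models (tested against a brute-force closure oracle). An array's strand is
the modal member strand; an exact tie falls back to the first member with a
warning. Pseudogenes count as members but are excluded from the
antisense-overlap denominators, which we restrict to non-pseudogene
genes of each class; the denominator is a genuine modelling choice and is
documented rather than hidden.

Gene pairs for the coverage analyses pass four filters: coding-sequence
length of both members in [100 bp, 10 kb], same strand, intergenic distance
in [50 bp, 10 kb], and neither gene nor the intergenic interval overlapping
any other annotated gene on either strand. OR pairs are enumerated
exhaustively; non-OR pairs are a seeded uniform sample of matching size.
Because the no-overlap filter forbids any gene inside the intergenic
interval, valid pairs are always genomically adjacent, which the
implementation exploits; the test suite checks it against a full
quadratic-enumeration oracle.

## Stranded coverage and relative coverage

Coverage tracks are dense per-base, per-strand read-depth vectors read from
stranded bedGraph pairs. For each gene pair we compute base-weighted mean
coverage over upstream/downstream exons and introns and over the entire
intergenic span, on the sense and antisense strands, and normalize
everything to the mean sense-strand coverage of the upstream gene's exons.
This relative coverage is scale-free (invariant to global depth), equals 1
for the upstream exons by construction, and is undefined when the
normalizer is zero — such pairs are excluded and counted rather than
imputed. The "intergenic span" is the genomic interval between the two
genes regardless of strand; strand enters only through sense/antisense
labeling. Group differences between OR and non-OR pairs use two-sided
Wilcoxon rank-sum tests with Benjamini–Hochberg correction across the
tested features.

## Promoter windows from capped-small-RNA start sites

Because OR UTR annotations are unreliable, OR promoter windows are
anchored at the first CDS; other genes use the annotated TSS. A window is
the `window_bp` (default 1000) bases immediately upstream of the anchor; a
read at position p belongs to a "+"-strand gene's window iff
1 ≤ anchor − p ≤ `window_bp`, mirrored for "−", and its reported distance
is anchor − p, so distances run from 1 to `window_bp` inclusive and the
anchor base itself is outside the window. Sense and
antisense reads are counted over the same genomic interval, and a window is
bidirectional when both strands reach `min_reads` (default 1, the most
literal reading of "has reads on both strands"; the threshold is exposed
because any larger floor is a judgement call). Reads are never double-counted within a
window, but a read may legitimately fall into two genes' overlapping
windows. Offset histograms are read-weighted; the sense/antisense contrast
is summarized by weighted medians.

## Single-cell analysis

Cells are kept as neurons when at least 2 of the 5 marker genes have UMI
≥ 2. Counts are scaled per cell to a target sum of 10,000 and transformed
with natural `log1p`, so `sum(expm1(values))` equals the target for every
non-empty cell (relative tolerance 1e-6 in the tests). The chosen OR is the
per-cell argmax over OR genes; ties break toward the lowest genomic
coordinate and are flagged; any tie rule would do, but it must be
deterministic and visible. Staircase matrices
restrict to cells whose chosen OR lies in one array, order cells by the
genomic position of their chosen OR and columns by genomic position, and
optionally subset by detectable (>0) expression of a named lncRNA.

Each nested antisense lncRNA is paired with three role ORs: the nearest OR
upstream of it in array direction (the gene its transcription silences),
the nearest OR downstream (the "chosen" OR whose bidirectional promoter
produces the lncRNA), and the OR after that. Distances are measured from
the chosen OR's TSS to the lncRNA 3' end and binned at 2.5, 5 and 10 kb.
Pearson correlations between lncRNA and role-OR expression are computed
across cells whose chosen OR is the paired OR, per lncRNA (minimum 3 cells;
constant vectors are skipped because r is undefined), and summarized per
role as the mean of per-lncRNA r with a one-sample t-test against zero.
A pooled mode concatenates cells across lncRNAs within a distance bin,
matching the scatter-plot style of aggregate figures; the per-lncRNA mode
matches the per-transcript summary. The switch statistic is the fraction of
cells detecting exactly one of {lncRNA, upstream OR} above a threshold
(default >0).

## RNA-FISH quantification

The imaging pipeline operates on (y, x, z, channel) stacks with a
designated DAPI channel at 90 nm/px and 1 µm z-steps:

1. **Depth correction** multiplies each non-DAPI slice by
   max_z(mean DAPI)/mean DAPI(z); DAPI itself is untouched. The reference
   statistic is the per-slice mean, with the "maximum across slices" read
   as the maximum of those means.
2. **Signal segmentation** subtracts a Gaussian background (sigma 100 px,
   clipped at zero), applies the geometric Triangle threshold to the
   residual (implemented from the histogram construction: a line from the
   peak to the far end of the longer tail, threshold at the maximal
   histogram-to-line distance over 256 bins), and drops 8-connected
   components under 12 px. Thresholding is per slice per channel by default; per-slice and
   per-stack scopes are both defensible, so the scope is configurable.
3. **Cytoplasm rings** dilate each nucleus by a Euclidean disk of radius
   3 px (~270 nm) and subtract the nucleus; pixels claimed by two rings or
   lying in any nucleus are removed from all claimants. Disjointness is
   enforced pixel-exactly and property-tested.
4. **ROI quantification** records, per nuclear ROI and ring, the
   per-channel mean of the background-subtracted, signal-masked intensity.
   The default `mask_mode = "zeroed"` lets non-signal pixels contribute 0
   while the denominator stays the full ROI area, so blank ROIs score 0;
   `masked_only` and `unmasked` are provided because segmentation and
   quantification can be combined in several defensible ways. Geometry (area, centroid, moment eccentricity) comes from
   the label masks.
5. **Normalization** maps nuclear and cytoplasmic means through the 0.001
   and 0.999 quantiles of the *nuclear* means, per image and channel;
   values outside [0, 1] are kept: the quantiles define a reference
   range, not a clip.
6. **Classification**: a chosen cell needs normalized nuclear signal
   > 0.75, normalized cytoplasmic signal > 0.2, nuclear area 400–900 px,
   cytoplasmic area > 100 px, and eccentricity < 0.8. Localization is
   "nuclear" at nuclear > 0.1 and "nuclear+cytoplasmic" only if nuclear
   status holds and cytoplasmic > 0.2 (the conditional "also"); chosen
   therefore always implies nuclear+cytoplasmic.

Nucleus segmentation itself is an injected backend. The built-in fallback
(DAPI smoothing, Otsu, watershed on the distance transform) exists to
exercise the pipeline on synthetic data and makes no claim of biological
fidelity; real analyses would inject a trained model adapter. Replicate
summaries are reported as proportions with t-distribution 95% confidence
intervals, never raw counts, because per-slice ROIs may double-count cells
across adjacent z-planes.

## What the generators emulate

- `gen_annotation()`: head-to-tail OR arrays (4 arrays of 5–8 ORs, 2 kb
  genes, 1–3 kb gaps) with optional inversions, antisense lncRNAs whose 3'
  ends sit at 2, 4 or 8 kb from a designated chosen OR's TSS (cycled so all
  distance bins are populated; the 3' end may fall inside the upstream OR
  body, which is how the annotated antisense-overlap fraction arises
  naturally), flanking non-OR genes on both strands, isolated filter-passing
  non-OR pairs, 5 neuron markers, and 20 housekeeping genes. Loci are
  separated by 15 kb, above the chaining gap.
- `gen_coverage()`: uniform promoter-rate depth over each pair's genes
  (rates uniform in 10–30 reads/nt); OR pairs additionally get sense depth
  decaying exponentially past the upstream 3' end at 0.3/kb and antisense
  depth at half the promoter rate; Poisson noise per base. The intergenic
  relative coverage of an isolated pair then has the closed form
  (1 − e^(−λL))/(λL), which the acceptance checks recover within
  Monte-Carlo error.
- `gen_tss()`: one sense peak per gene at 200 ± 30 bp upstream of the
  anchor and, for a deterministically sampled fraction (default 0.34) of
  genes, an antisense peak at 500 ± 30 bp; Poisson read counts (mean 20),
  or exact counts in the noiseless mode used for exact-recovery checks.
- `gen_counts()`: each cell draws one array and one chosen OR, and a
  Gamma(4, 4) activity factor scales the whole cascade: chosen OR mean 100,
  downstream ORs decaying by e^(−1.5) per rank, the promoter's lncRNA mean
  30. The OR immediately upstream of an active lncRNA leaks with mean
  20 · e^(−coupling · l/30), independent of the activity factor, so that at
  coupling 0 the lncRNA and upstream OR are uncorrelated while positive
  coupling yields the negative-upstream/positive-downstream signature and,
  at strong coupling, a switch-like XOR regime. Housekeeping genes (20 ×
  mean 200) carry the bulk of the library so the OR cascade is a
  realistically small fraction of total UMI; without them, target-sum
  normalization induces compositional correlations that swamp the signal.
- `gen_stack()`: 256×256 px fields, 4 slices, 9 disk nuclei per slice with
  radii 12–16 px (areas inside the 400–900 px gate), multiplicative 0.85
  per-slice attenuation applied to all channels, a bright subnuclear
  expression domain covering 35% (chosen) or 17.5% (nuclear-only) of the
  nucleus, ring puncta for chosen cells only, 1 px Gaussian blur, constant
  background and Poisson noise.

The generators do **not** emulate: mapping artifacts and multimapping,
ambient RNA or doublets, batch effects, anisotropic PSFs, segmentation
errors (truth masks are exact disks), irregular nuclear shapes, or
chromosome-scale genome organization. Passing tests therefore demonstrate
that the quantification operations recover known structure under their own
assumptions, not that those assumptions hold in any particular real
dataset.

## Numerical choices and problem sizes

Natural log for `log1p` (recorded in the matrix metadata); quantile type 7
(R default) for the normalization quantiles; 256 histogram bins for the
Triangle threshold; 8-connectivity for components; exact Euclidean disk
offsets for dilation (so ring tests can use a per-pixel distance oracle);
Wilcoxon tests use exact p-values where R's default does. Default problem
sizes were chosen to give stable statistics at interactive runtimes: 20
Monte-Carlo seeds with 50 pairs per group for coverage recovery, ~200 genes
for TSS medians, 1000 cells for chosen-OR recovery, 20 lncRNAs × 500 cells
for correlation signs (with the coupling-free null averaged over 20 seeds
of 1000 cells), and 10 stacks of 36 ROIs for imaging class recovery.

## Known limitations

Dense coverage vectors assume desk-scale chromosomes (fine for the
synthetic genome; a real genome would want RLE tracks). The gene-pair
enumeration assumes the no-overlap filter, so it would miss hypothetical
valid non-adjacent pairs if that filter were relaxed. The correlation
module pairs each lncRNA with a single upstream/chosen/downstream triple
derived from annotation geometry; promoters with several interleaved
lncRNAs keep only the nearest pairing. The imaging pipeline is 2-D per
slice by design and does not link ROIs across z, accepting the double
counting that proportion-based reporting tolerates.
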