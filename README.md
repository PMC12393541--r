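# tandemor

Quantification pipeline for studying how olfactory sensory neurons (OSNs)
achieve **monogenic odorant receptor (OR) expression** from tandem gene
arrays. Ant OR genes sit in head-to-tail arrays of dozens of paralogs, yet
each neuron translates a single "chosen" OR. The package implements the
analyses that establish this at the RNA level — for genomics, single-cell
and imaging data alike — plus seeded synthetic-data generators with ground
truth so every stage is testable offline.

## What it computes

1. **Tandem-array geometry** (`detect_tandem_arrays`, `flanking_genes`,
   `nested_lncrnas`, `antisense_lncrna_overlap`): ORs are chained into
   arrays when inter-gene gaps are ≤ 10 kb, strand-agnostically (inverted
   members stay in their array); arrays get flanking non-OR genes per side
   and strand class, and nested antisense lncRNAs with nearest-OR TSS
   distances.
2. **Readthrough and antisense coverage** (`sample_gene_pairs`,
   `pair_relative_coverage`, `compare_groups`): gene pairs filtered on CDS
   length (100 bp–10 kb), same strand, intergenic distance (50 bp–10 kb)
   and isolation; per-feature mean stranded coverage normalized to the
   upstream gene's sense exon mean,

   `rel_cov(feature) = mean_cov(feature) / mean_cov(upstream exons, sense)`,

   compared OR vs non-OR with Wilcoxon rank-sum tests and
   Benjamini–Hochberg correction. High OR intergenic relative coverage is
   the signature of RNA polymerase II reading through the polyadenylation
   site.
3. **Bidirectional promoters** (`window_assign`, `bidirectional_fraction`,
   `peak_offset_histogram`): capped-small-RNA 5′ ends assigned to the 1 kb
   window upstream of each gene's anchor (first CDS for ORs, annotated TSS
   otherwise); windows with reads on both strands are bidirectional, and
   antisense peaks sit farther upstream than sense peaks.
4. **Single-cell chosen-OR analysis** (`filter_neurons`,
   `normalize_counts`, `assign_chosen_or`, `staircase_matrix`,
   `lnc_or_correlation`, `switch_fraction`): marker-based neuron filtering
   (≥ 2 of 5 markers at UMI ≥ 2), per-cell normalization to 10,000 counts
   with log1p, chosen OR = per-cell argmax over ORs, staircase matrices of
   chosen-plus-downstream coexpression, and Pearson correlation of nested
   antisense lncRNAs with their upstream / chosen / downstream ORs by
   promoter distance (≤ 2.5, 2.5–5, 5–10 kb bins).
5. **RNA-FISH quantification** (`depth_correct`, `segment_signal`,
   `cytoplasm_rings`, `quantify_rois`, `normalize_signals`,
   `classify_chosen`, `classify_localization`): DAPI-referenced depth
   correction, Gaussian-background subtraction (σ = 100 px) with Triangle
   thresholding and < 12 px object removal, 3 px cytoplasm rings with
   contested-pixel exclusion, robust 0.001/0.999 nuclear-quantile
   normalization shared with the cytoplasm, and the chosen-cell gates
   (nuclear > 0.75, cytoplasmic > 0.2, nuclear area 400–900 px,
   cytoplasmic area > 100 px, eccentricity < 0.8) plus
   nuclear / nuclear+cytoplasmic localization calls.
6. **Synthetic data** (`gen_annotation`, `gen_coverage`, `gen_tss`,
   `gen_counts`, `gen_stack`): seeded generators that emulate each data
   type's structure and return ground truth (per-cell chosen promoter,
   per-ROI class) for recovery testing.

See `vignettes/methods.Rmd` for the models, parameter meanings and design
decisions.

## Worked example

The numbered drivers under `analysis/` run each stage end to end on
synthetic data and write tables under `results/`. For example:

```sh
$ Rscript analysis/01_tandem_arrays.R
Detected 4 tandem arrays (25 ORs) and 0 singleton ORs
Antisense lncRNA overlap: 24% of ORs vs 0% of non-ORs
8 antisense lncRNAs nested within arrays

$ Rscript analysis/02_readthrough.R
OR pairs: 7, non-OR pairs: 7
Median intergenic relative coverage: OR 0.801 vs non-OR 0.000
Rank-sum p = 0.00106

$ Rscript analysis/05_single_cell.R
Chosen-OR recovery: 99.5% of 1000 cells
Staircase matrix for the first array: 274 cells x 5 ORs
Per-lncRNA mean r: upstream -0.80, chosen 0.92, downstream 0.84
Switch (XOR) fraction in the <=2.5 kb bin: 6%

$ Rscript analysis/06_fish_quantification.R
Classified 36 ROIs; class recovery 100.0%
```

Reading the numbers: OR gene pairs keep substantial intergenic coverage
relative to the upstream gene (0.80) while non-OR pairs drop to ~0 —
transcription runs through OR intergenic regions. In the single-cell
stage, the per-cell argmax recovers the generator's true chosen promoter
in 99.5% of 1000 cells, and nested lncRNA expression is negatively
correlated with the upstream OR but positively with the chosen and
downstream ORs, the asymmetry expected of a bidirectional promoter that
silences upstream neighbors. The imaging pipeline assigns every synthetic
ROI its true class (chosen / nuclear-only / negative) through the full
depth-correct → segment → ring → normalize → classify chain.

Equivalent one-call entry points exist in R via
`run_workflow("readthrough" | "antisense" | "tss" | "staircase" |
"lnc_correlation" | "fish" | "demo", default_config(seed, out_dir))`.

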