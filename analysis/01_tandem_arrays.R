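#!/usr/bin/env Rscript
# Stage 1: genome geometry. Build the synthetic annotation, detect OR tandem
# arrays, find their flanking non-OR genes, and measure how often genes are
# overlapped by antisense lncRNAs (ORs vs other genes).

suppressMessages(library(tandemor))
seed <- 1L
out <- "results/01_tandem_arrays"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

ga <- gen_annotation(seed = seed)
ann <- ga$annotation
write_annotation_gff3(ann, file.path(out, "synthetic_annotation.gff3"))

arr <- detect_tandem_arrays(ann, max_gap = 10000)
cat(sprintf("Detected %d tandem arrays (%d ORs) and %d singleton ORs\n",
            nrow(arr$arrays), sum(arr$arrays$n_or), length(arr$singletons)))

# arrays as BED6 (0-based half-open, as BED wants)
bed <- with(arr$arrays, data.frame(chrom, as.integer(start), as.integer(end),
                                   array_id, n_or, majority_strand))
write.table(bed, file.path(out, "arrays.bed"), sep = "\t", quote = FALSE,
            row.names = FALSE, col.names = FALSE)

flanks <- dplyr::bind_rows(lapply(seq_len(nrow(arr$arrays)), function(i) {
  fl <- flanking_genes(arr$arrays[i, ], ann)
  tibble::tibble(array_id = arr$arrays$array_id[i],
                 upstream_same = fl$upstream_same,
                 upstream_opposite = fl$upstream_opposite,
                 downstream_same = fl$downstream_same,
                 downstream_opposite = fl$downstream_opposite)
}))
write.table(flanks, file.path(out, "flanking_genes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

ov <- antisense_lncrna_overlap(ann)
cat(sprintf("Antisense lncRNA overlap: %.0f%% of ORs vs %.0f%% of non-ORs\n",
            100 * ov$frac_OR, 100 * ov$frac_nonOR))
write.table(ov$per_gene, file.path(out, "antisense_overlap.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

nested <- dplyr::bind_rows(lapply(seq_len(nrow(arr$arrays)), function(i)
  nested_lncrnas(arr$arrays[i, ], ann)))
cat(sprintf("%d antisense lncRNAs nested within arrays\n", nrow(nested)))
write.table(nested, file.path(out, "nested_lncrnas.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
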