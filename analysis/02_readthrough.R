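#!/usr/bin/env Rscript
# Stage 2: transcriptional readthrough. Sample filtered OR and non-OR gene
# pairs, simulate stranded coverage with downstream readthrough decay for OR
# pairs, and compare intergenic relative coverage between the groups
# (Wilcoxon rank-sum). High OR intergenic relative coverage is the
# signature of polymerase reading through the polyadenylation site.

suppressMessages(library(tandemor))
res <- run_workflow("readthrough",
                    default_config(seed = 1L, out_dir = "results/02_readthrough"))
cat(sprintf("OR pairs: %d, non-OR pairs: %d\n",
            res$n_or_pairs, res$n_nonor_pairs))
cat(sprintf("Median intergenic relative coverage: OR %.3f vs non-OR %.3f\n",
            res$median_intergenic_relcov_or,
            res$median_intergenic_relcov_nonor))
cat(sprintf("Rank-sum p = %.3g\n", res$p_intergenic))
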