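#' Generate synthetic capped-small-RNA start-site tracks
#'
#' Each target gene gets a sense TSS peak at `sense_offset` bp upstream of
#' its anchor (jittered by `offset_sd`). A deterministically sampled
#' fraction `bidir_fraction` of the genes additionally gets an antisense
#' peak at the larger `antisense_offset`, emulating twin sense/antisense
#' initiation with the antisense start farther upstream. Read counts per
#' peak are Poisson(`reads_per_gene`), or exactly `reads_per_gene` with
#' `noise = "none"`.
#'
#' @param ann a [genome_annotation()]
#' @param gene_ids genes to give promoter signal (default: all non-lncRNA)
#' @param sense_offset,antisense_offset mean peak distances to the anchor,
#'   bp (defaults 200 and 500)
#' @param offset_sd Gaussian jitter of the peak position (default 30)
#' @param reads_per_gene expected reads per peak (default 20)
#' @param bidir_fraction fraction of genes with an antisense peak
#'   (default 0.34)
#' @param noise "poisson" or "none"
#' @param seed integer seed
#' @return list(track = `coverage_track` of 5'-end counts, truth = tibble
#'   gene_id, bidirectional, sense_offset, antisense_offset)
#' @export
gen_tss <- function(ann, gene_ids = NULL, sense_offset = 200,
                    antisense_offset = 500, offset_sd = 30,
                    reads_per_gene = 20, bidir_fraction = 0.34,
                    noise = c("poisson", "none"), seed = 1L) {
  noise <- match.arg(noise)
  withr::local_seed(seed)
  if (is.null(gene_ids)) gene_ids <- ann$gene_id[ann$biotype != "lncRNA"]
  sub <- ann[match(gene_ids, ann$gene_id), ]
  anchors <- gene_anchors(sub)
  n <- nrow(sub)
  n_bidir <- round(bidir_fraction * n)
  bidir <- rep(FALSE, n)
  bidir[sample(n, n_bidir)] <- TRUE
  track <- coverage_track(chrom_lengths(ann))
  window_max <- 1000
  clampi <- function(x) pmin(window_max, pmax(1, round(x)))
  so <- clampi(rnorm(n, sense_offset, offset_sd))
  ao <- clampi(rnorm(n, antisense_offset, offset_sd))
  deposit <- function(chrom, strand, pos, count) {
    if (count <= 0) return()
    track[[chrom]][[strand]][pos + 1] <<-
      track[[chrom]][[strand]][pos + 1] + count
  }
  for (i in seq_len(n)) {
    g <- sub[i, ]; a <- anchors[i]
    cnt <- function() if (noise == "poisson") rpois(1, reads_per_gene) else reads_per_gene
    if (g$strand == "+") {
      deposit(g$chrom, "+", a - so[i], cnt())
      if (bidir[i]) deposit(g$chrom, "-", a - ao[i], cnt())
    } else {
      deposit(g$chrom, "-", a + so[i], cnt())
      if (bidir[i]) deposit(g$chrom, "+", a + ao[i], cnt())
    }
  }
  list(track = track,
       truth = tibble::tibble(gene_id = sub$gene_id, bidirectional = bidir,
                              sense_offset = so, antisense_offset = ao),
       params = list(sense_offset = sense_offset,
                     antisense_offset = antisense_offset,
                     bidir_fraction = bidir_fraction,
                     reads_per_gene = reads_per_gene, seed = seed))
}
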