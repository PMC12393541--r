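#' Capped-small-RNA start-site track
#'
#' Single-nucleotide 5'-end read counts per strand. Reuses the dense
#' [coverage_track()] container; values are non-negative integers giving the
#' number of read 5' ends at each position.
#'
#' @name tss_track
NULL

#' Assign TSS reads to promoter windows
#'
#' For each gene, counts 5'-end reads in the `window_bp` bases immediately
#' upstream of its anchor (first CDS for ORs, annotated TSS otherwise, via
#' [gene_anchors()]). A read at position p falls in the window of a
#' "+"-strand anchor a iff 1 <= a - p <= window_bp (mirrored for "-");
#' its distance to the anchor is a - p. Sense reads are on the gene's
#' strand, antisense on the opposite strand; the same genomic window is
#' searched for both. Windows truncated at a chromosome edge are flagged.
#'
#' @param track a `coverage_track` of 5'-end counts
#' @param ann a [genome_annotation()]
#' @param gene_ids genes to score (default all)
#' @param window_bp window size upstream of the anchor (default 1000)
#' @param min_reads reads per strand required to call a window bidirectional
#' @return tibble: gene_id, strand, anchor, window_start, window_end,
#'   sense_count, antisense_count, sense_positions, antisense_positions
#'   (list-columns of distances, one entry per read), bidirectional,
#'   truncated
#' @export
window_assign <- function(track, ann, gene_ids = NULL, window_bp = 1000,
                          min_reads = 1) {
  if (is.null(gene_ids)) gene_ids <- ann$gene_id
  sub <- ann[match(gene_ids, ann$gene_id), ]
  anchors <- gene_anchors(sub)
  cl <- attr(track, "chrom_lengths")
  rows <- lapply(seq_len(nrow(sub)), function(i) {
    g <- sub[i, ]; a <- anchors[i]
    if (g$strand == "+") {
      ws <- max(0, a - window_bp); we <- a            # positions [ws, we)
    } else {
      ws <- a + 1; we <- min(cl[[g$chrom]], a + window_bp + 1)
    }
    truncated <- (we - ws) < window_bp
    grab <- function(strand) {
      if (we <= ws) return(numeric(0))
      v <- track[[g$chrom]][[strand]][(ws + 1):we]
      pos <- ws + which(v > 0) - 1
      counts <- v[v > 0]
      d <- if (g$strand == "+") a - pos else pos - a
      keep <- d >= 1 & d <= window_bp
      rep(d[keep], counts[keep])
    }
    sense <- grab(g$strand)
    anti <- grab(other_strand(g$strand))
    tibble::tibble(gene_id = g$gene_id, strand = g$strand, anchor = a,
                   window_start = ws, window_end = we,
                   sense_count = length(sense), antisense_count = length(anti),
                   sense_positions = list(sense), antisense_positions = list(anti),
                   bidirectional = length(sense) >= min_reads && length(anti) >= min_reads,
                   truncated = truncated)
  })
  dplyr::bind_rows(rows)
}

#' Fraction of genes with bidirectional promoter windows
#' @param results output of [window_assign()]
#' @param gene_ids optional subset of genes
#' @return fraction in [0, 1]
#' @export
bidirectional_fraction <- function(results, gene_ids = NULL) {
  if (!is.null(gene_ids)) results <- results[results$gene_id %in% gene_ids, ]
  if (nrow(results) == 0) stopf("no genes in group")
  mean(results$bidirectional)
}

#' Read-weighted histogram of TSS distances to the anchor
#'
#' Pools per-read distances across genes for one orientation and bins them.
#'
#' @param results output of [window_assign()]
#' @param orientation "sense" or "antisense"
#' @param binwidth bin width in bp
#' @return tibble: bin_start, bin_end, count
#' @export
peak_offset_histogram <- function(results, orientation = c("sense", "antisense"),
                                  binwidth = 50) {
  orientation <- match.arg(orientation)
  col <- paste0(orientation, "_positions")
  d <- unlist(results[[col]], use.names = FALSE)
  if (length(d) == 0)
    return(tibble::tibble(bin_start = numeric(0), bin_end = numeric(0),
                          count = integer(0)))
  bin <- floor((d - 1) / binwidth)
  tab <- table(bin)
  tibble::tibble(bin_start = as.numeric(names(tab)) * binwidth + 1,
                 bin_end = (as.numeric(names(tab)) + 1) * binwidth,
                 count = as.integer(tab))
}

#' Median read distance to anchor per orientation
#' @param results output of [window_assign()]
#' @return named vector c(sense =, antisense =) of read-weighted medians
#' @export
peak_offset_medians <- function(results) {
  c(sense = median(unlist(results$sense_positions, use.names = FALSE)),
    antisense = median(unlist(results$antisense_positions, use.names = FALSE)))
}
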