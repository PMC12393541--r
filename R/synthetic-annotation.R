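#' Generate a synthetic genome annotation with OR tandem arrays
#'
#' Lays out head-to-tail OR tandem arrays with configurable inversions,
#' antisense lncRNAs nested upstream-adjacent to designated ORs, flanking
#' non-OR genes on both strands of each array, a set of isolated non-OR gene
#' pairs that satisfy the gene-pair filters, and neuron marker genes.
#' Everything is placed on one synthetic chromosome with inter-locus spacing
#' well above the array-chaining gap.
#'
#' The returned truth records, per lncRNA, the role ORs of its bidirectional
#' promoter (upstream / chosen / downstream) and the chosen-OR-TSS to
#' lncRNA-3'-end distance; per array, the member ORs in transcription order;
#' and the flanking gene ids.
#'
#' @param seed integer seed
#' @param n_arrays number of tandem arrays (default 4)
#' @param array_size_range inclusive range of ORs per array (default c(5, 8))
#' @param gene_len OR gene length in bp (default 2000)
#' @param gap_range range of intra-array intergenic gaps in bp
#'   (default c(1000, 3000))
#' @param inversion_rate probability an OR is inverted (default 0; the
#'   emulated arrays are predominantly head-to-tail)
#' @param lnc_per_array nested antisense lncRNAs per array (default 2)
#' @param lnc_gap_choices candidate chosen-OR-TSS to lncRNA-3'-end distances
#'   (bp), cycled over lncRNAs so all distance bins are populated
#' @param flank_genes add flanking non-OR genes around each array
#' @param n_nonor_pairs isolated non-OR pairs passing the filters (default 30)
#' @param n_markers neuron marker genes (default 5)
#' @param locus_spacing spacing between independent loci in bp (default
#'   15000, above the array-chaining gap)
#' @param n_housekeeping housekeeping genes carrying the bulk of each
#'   cell's library (default 20)
#' @return list(annotation = [genome_annotation()], truth = list)
#' @export
gen_annotation <- function(seed = 1L, n_arrays = 4,
                           array_size_range = c(5, 8), gene_len = 2000,
                           gap_range = c(1000, 3000), inversion_rate = 0,
                           lnc_per_array = 2,
                           lnc_gap_choices = c(2000, 4000, 8000),
                           flank_genes = TRUE, n_nonor_pairs = 30,
                           n_markers = 5, n_housekeeping = 20,
                           locus_spacing = 15000) {
  stopifnot(array_size_range[1] >= 2, gene_len > 400,
            gap_range[1] > 200, inversion_rate >= 0, inversion_rate <= 1)
  withr::local_seed(seed)
  chrom <- "chrS"
  rows <- list(); pos <- 10000
  truth_lnc <- list(); truth_arr <- list(); truth_flank <- list()
  or_i <- 0L; lnc_i <- 0L; g_i <- 0L
  add_gene <- function(id, strand, start, end, biotype, with_cds = TRUE) {
    cds <- if (with_cds)
      matrix(c(start + 150, end - 150), 1, 2, dimnames = list(NULL, c("start", "end")))
    else matrix(numeric(0), 0, 2)
    rows[[length(rows) + 1]] <<- tibble::tibble(
      gene_id = id, chrom = chrom, strand = strand, start = start, end = end,
      exons = list(matrix(c(start, end), 1, 2, dimnames = list(NULL, c("start", "end")))),
      cds = list(cds), biotype = biotype, pseudogene = FALSE)
  }
  lnc_gap_i <- 0L
  for (a in seq_len(n_arrays)) {
    size <- resample(seq(array_size_range[1], array_size_range[2]), 1)
    arr_strand <- "+"
    starts <- numeric(size); ids <- character(size); strands <- character(size)
    if (flank_genes) {
      # upstream flanks (before the array): same and opposite strand
      g_i <- g_i + 1L
      up_same <- sprintf("G%03d", g_i)
      add_gene(up_same, "+", pos, pos + 1500, "other"); pos <- pos + 1500 + 3000
      g_i <- g_i + 1L
      up_opp <- sprintf("G%03d", g_i)
      add_gene(up_opp, "-", pos, pos + 1500, "other"); pos <- pos + 1500 + 3000
    }
    # designate lncRNA-bearing promoters up front so the intergenic gap
    # before each designated chosen OR is widened to fit its lncRNA at the
    # assigned promoter distance
    chosen_idx <- if (size > 2)
      sort(sample(2:(size - 1), min(lnc_per_array, size - 2))) else integer(0)
    lnc_gap <- setNames(numeric(length(chosen_idx)), as.character(chosen_idx))
    for (ci in chosen_idx) {
      lnc_gap_i <- lnc_gap_i + 1L
      lnc_gap[as.character(ci)] <-
        lnc_gap_choices[(lnc_gap_i - 1) %% length(lnc_gap_choices) + 1]
    }
    lnc_len <- 1200
    arr_start <- pos
    for (k in seq_len(size)) {
      or_i <- or_i + 1L
      ids[k] <- sprintf("OR%03d", or_i)
      strands[k] <- if (runif(1) < inversion_rate) "-" else arr_strand
      starts[k] <- pos
      add_gene(ids[k], strands[k], pos, pos + gene_len, "OR")
      pos <- pos + gene_len
      if (k < size) {
        gap_next <- resample(seq(gap_range[1], gap_range[2]), 1)
        if (as.character(k + 1) %in% names(lnc_gap))
          # widen only enough that the lncRNA 3' end stays within the
          # upstream OR body or the gap (antisense transcripts routinely
          # overlap the upstream OR, as in real annotations)
          gap_next <- max(gap_next,
                          lnc_gap[as.character(k + 1)] + 250 - gene_len)
        pos <- pos + gap_next
      }
    }
    arr_end <- pos
    # antisense lncRNAs: 3' end `d` bp upstream of the designated chosen
    # OR's first-CDS TSS, transcribed antisense toward the upstream OR
    for (ci in chosen_idx) {
      lnc_i <- lnc_i + 1L
      d <- lnc_gap[as.character(ci)]
      lid <- sprintf("LNC%03d", lnc_i)
      chosen_tss <- starts[ci] + 150          # first CDS of the chosen OR
      # antisense ("-") transcript: 3' end is the low-coordinate end, placed
      # `d` bp upstream of the chosen OR's TSS
      l_start <- chosen_tss - d
      l_end <- min(l_start + lnc_len, starts[ci] - 50)
      if (l_start <= starts[ci - 1] + 100 || l_end - l_start < 200)
        next                                  # does not fit; skip
      add_gene(lid, "-", l_start, l_end, "lncRNA", with_cds = FALSE)
      truth_lnc[[length(truth_lnc) + 1]] <- tibble::tibble(
        lncrna_id = lid, array_id = sprintf("A%03d", a),
        upstream_or = ids[ci - 1], chosen_or = ids[ci],
        downstream_or = if (ci < size) ids[ci + 1] else NA_character_,
        distance = d)
    }
    if (flank_genes) {
      pos <- pos + 3000
      g_i <- g_i + 1L
      dn_same <- sprintf("G%03d", g_i)
      add_gene(dn_same, "+", pos, pos + 1500, "other"); pos <- pos + 1500 + 3000
      g_i <- g_i + 1L
      dn_opp <- sprintf("G%03d", g_i)
      add_gene(dn_opp, "-", pos, pos + 1500, "other"); pos <- pos + 1500 + 3000
      truth_flank[[length(truth_flank) + 1]] <- tibble::tibble(
        array_id = sprintf("A%03d", a), upstream_same = up_same,
        upstream_opposite = up_opp, downstream_same = dn_same,
        downstream_opposite = dn_opp)
    }
    truth_arr[[length(truth_arr) + 1]] <- tibble::tibble(
      array_id = sprintf("A%03d", a), chrom = chrom, strand = arr_strand,
      start = arr_start, end = arr_end, or_ids = list(ids))
    pos <- pos + locus_spacing                # break chaining between loci
  }
  # isolated non-OR pairs satisfying the gene-pair filters
  for (p in seq_len(n_nonor_pairs)) {
    st <- sample(c("+", "-"), 1)
    len1 <- sample(800:3000, 1); len2 <- sample(800:3000, 1)
    gap <- sample(100:8000, 1)
    g_i <- g_i + 1L; id1 <- sprintf("G%03d", g_i)
    add_gene(id1, st, pos, pos + len1, "other"); pos <- pos + len1 + gap
    g_i <- g_i + 1L; id2 <- sprintf("G%03d", g_i)
    add_gene(id2, st, pos, pos + len2, "other"); pos <- pos + len2 + locus_spacing
  }
  markers <- character(n_markers)
  for (k in seq_len(n_markers)) {
    markers[k] <- sprintf("MARK%d", k)
    add_gene(markers[k], "+", pos, pos + 1200, "other"); pos <- pos + 1200 + locus_spacing
  }
  # housekeeping genes carry the bulk of each cell's library so that the OR
  # cascade is a realistically small fraction of total UMI
  housekeeping <- character(n_housekeeping)
  for (k in seq_len(n_housekeeping)) {
    housekeeping[k] <- sprintf("HK%03d", k)
    add_gene(housekeeping[k], "+", pos, pos + 1500, "other")
    pos <- pos + 1500 + locus_spacing
  }
  genes <- dplyr::bind_rows(rows)
  ann <- genome_annotation(genes, setNames(pos + 10000, chrom))
  truth <- list(
    seed = seed,
    arrays = dplyr::bind_rows(truth_arr),
    lnc = if (length(truth_lnc) > 0) dplyr::bind_rows(truth_lnc) else NULL,
    flanks = if (length(truth_flank) > 0) dplyr::bind_rows(truth_flank) else NULL,
    markers = markers,
    housekeeping = housekeeping,
    params = list(n_arrays = n_arrays, array_size_range = array_size_range,
                  gene_len = gene_len, gap_range = gap_range,
                  inversion_rate = inversion_rate,
                  lnc_per_array = lnc_per_array))
  list(annotation = ann, truth = truth)
}
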