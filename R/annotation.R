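#' Genome annotation container
#'
#' A `genome_annotation` is a tibble of gene records (one row per gene) with
#' list-columns holding exon and CDS intervals, plus a `chrom_lengths`
#' attribute. All coordinates are 0-based half-open internally; GFF3/GTF
#' files (1-based inclusive) are converted at the I/O boundary.
#'
#' Columns: `gene_id`, `chrom`, `strand` ("+"/"-"), `start`, `end`,
#' `exons` (list of 2-column matrices), `cds` (list, possibly 0-row),
#' `biotype` ("OR", "lncRNA", "other"), `pseudogene` (logical).
#'
#' @param genes tibble with the columns above
#' @param chrom_lengths named numeric vector of chromosome lengths (bp)
#' @return a `genome_annotation` tibble
#' @export
genome_annotation <- function(genes, chrom_lengths) {
  stopifnot(is.data.frame(genes))
  required <- c("gene_id", "chrom", "strand", "start", "end",
                "exons", "cds", "biotype", "pseudogene")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols) > 0)
    stopf("annotation is missing columns: %s", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(genes$gene_id))
    stopf("gene_ids are not unique")
  if (!all(genes$strand %in% c("+", "-")))
    stopf("strand must be '+' or '-'")
  bad <- genes$chrom[!genes$chrom %in% names(chrom_lengths)]
  if (length(bad) > 0)
    stopf("genes on chromosomes absent from chrom_lengths: %s",
          paste(unique(bad), collapse = ", "))
  if (any(genes$end > chrom_lengths[genes$chrom]))
    stopf("gene span exceeds chromosome length")
  if (any(genes$start < 0) || any(genes$end <= genes$start))
    stopf("gene spans must be non-empty with start >= 0")
  out <- tibble::as_tibble(genes)
  attr(out, "chrom_lengths") <- chrom_lengths
  class(out) <- c("genome_annotation", class(out))
  out
}

#' @export
chrom_lengths <- function(ann) attr(ann, "chrom_lengths")

# keep the class/attribute through subsetting done inside this package
reannotate <- function(genes, ann) {
  genome_annotation(as.data.frame(genes), chrom_lengths(ann))
}

#' Read a GFF3/GTF annotation
#'
#' Parses gene/exon/CDS features with rtracklayer and assigns biotypes by
#' configurable rules: a gene is an OR if its id is in `or_ids` or matches
#' `or_regex`; a lncRNA if its `gene_biotype`/`biotype` attribute equals
#' "lncRNA" or the id matches `lnc_regex`; otherwise "other". Pseudogene
#' status is taken from a `pseudo`/`pseudogene` attribute or `pseudo_ids`.
#'
#' @param path GFF3 or GTF file (extension decides the dialect)
#' @param biotype_rules list with optional elements `or_ids`, `or_regex`,
#'   `lnc_regex`, `pseudo_ids`
#' @param chrom_lengths optional named vector; defaults to the maximum
#'   observed end per chromosome
#' @return a [genome_annotation()]
#' @export
read_annotation <- function(path, biotype_rules = list(), chrom_lengths = NULL) {
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  fmt <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf" else "gff3"
  gr <- tryCatch(rtracklayer::import(path, format = fmt),
                 error = function(e) stopf("failed to parse %s: %s", path, conditionMessage(e)))
  if (length(gr) == 0) {
    return(genome_annotation(empty_gene_table(), chrom_lengths %||% numeric(0)))
  }
  md <- S4Vectors::mcols(gr)
  strands <- as.character(GenomicRanges::strand(gr))
  keep <- strands %in% c("+", "-")
  if (any(!keep)) {
    warnf("%d records with unknown strand rejected", sum(!keep))
    gr <- gr[keep]; md <- md[keep, , drop = FALSE]; strands <- strands[keep]
  }
  types <- tolower(as.character(md$type))
  get_attr <- function(nm) if (nm %in% names(md)) as.character(md[[nm]]) else rep(NA_character_, length(gr))
  ids <- if (fmt == "gtf") get_attr("gene_id") else {
    id <- get_attr("ID")
    ifelse(is.na(id), get_attr("gene_id"), sub("^gene[-:]", "", id))
  }
  parents <- if (fmt == "gtf") get_attr("gene_id") else {
    p <- get_attr("Parent")
    sub("^gene[-:]", "", ifelse(is.na(p) | p == "", get_attr("gene_id"), p))
  }
  is_gene <- types %in% c("gene", "pseudogene", "ncrna_gene")
  gene_idx <- which(is_gene)
  if (length(gene_idx) == 0) {
    # GTF files without explicit gene rows: derive spans from transcripts/exons
    gene_idx <- which(!duplicated(parents))
    ids[gene_idx] <- parents[gene_idx]
  }
  bt_attr <- get_attr("gene_biotype")
  bt_attr2 <- get_attr("biotype")
  rows <- lapply(gene_idx, function(i) {
    gid <- ids[i]
    child <- which(parents == gid & !is_gene)
    exon_rows <- child[types[child] == "exon"]
    cds_rows <- child[types[child] == "cds"]
    # transcripts as intermediaries: pull their exon/CDS children too
    tx_ids <- ids[child[types[child] %in% c("mrna", "transcript", "lnc_rna", "lncrna")]]
    if (length(tx_ids) > 0) {
      sub <- which(parents %in% tx_ids)
      exon_rows <- c(exon_rows, sub[types[sub] == "exon"])
      cds_rows <- c(cds_rows, sub[types[sub] == "cds"])
    }
    to_iv <- function(rowidx) {
      if (length(rowidx) == 0) return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("start", "end"))))
      iv <- cbind(start = GenomicRanges::start(gr)[rowidx] - 1,
                  end = GenomicRanges::end(gr)[rowidx])
      interval_union(iv)
    }
    exons <- to_iv(exon_rows)
    span <- c(GenomicRanges::start(gr)[i] - 1, GenomicRanges::end(gr)[i])
    if (nrow(exons) == 0) exons <- matrix(span, 1, 2, dimnames = list(NULL, c("start", "end")))
    list(gene_id = gid,
         chrom = as.character(GenomicRanges::seqnames(gr))[i],
         strand = strands[i],
         start = span[1], end = span[2],
         exons = exons, cds = to_iv(cds_rows),
         bt = if (!is.na(bt_attr[i])) bt_attr[i] else bt_attr2[i],
         is_pseudo = types[i] == "pseudogene")
  })
  genes <- tibble::tibble(
    gene_id = vapply(rows, `[[`, "", "gene_id"),
    chrom = vapply(rows, `[[`, "", "chrom"),
    strand = vapply(rows, `[[`, "", "strand"),
    start = vapply(rows, `[[`, 0, "start"),
    end = vapply(rows, `[[`, 0, "end"),
    exons = lapply(rows, `[[`, "exons"),
    cds = lapply(rows, `[[`, "cds"),
    biotype = "other",
    pseudogene = vapply(rows, `[[`, FALSE, "is_pseudo")
  )
  bt <- vapply(rows, function(r) r$bt %||% NA_character_, "")
  genes$biotype[!is.na(bt) & tolower(bt) %in% c("lncrna", "lnc_rna")] <- "lncRNA"
  if (!is.null(biotype_rules$lnc_regex))
    genes$biotype[grepl(biotype_rules$lnc_regex, genes$gene_id)] <- "lncRNA"
  if (!is.null(biotype_rules$or_regex))
    genes$biotype[grepl(biotype_rules$or_regex, genes$gene_id)] <- "OR"
  if (!is.null(biotype_rules$or_ids))
    genes$biotype[genes$gene_id %in% biotype_rules$or_ids] <- "OR"
  if (!is.null(biotype_rules$pseudo_ids))
    genes$pseudogene[genes$gene_id %in% biotype_rules$pseudo_ids] <- TRUE
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(genes$end, genes$chrom, max)
    chrom_lengths <- setNames(as.numeric(chrom_lengths), names(chrom_lengths))
  }
  genes <- genes[order(genes$chrom, genes$start, genes$gene_id), ]
  genome_annotation(genes, chrom_lengths)
}

empty_gene_table <- function() {
  tibble::tibble(gene_id = character(0), chrom = character(0),
                 strand = character(0), start = numeric(0), end = numeric(0),
                 exons = list(), cds = list(), biotype = character(0),
                 pseudogene = logical(0))
}

#' Write a genome annotation to GFF3
#'
#' Inverse of [read_annotation()]: emits gene, exon and CDS rows with
#' `gene_biotype` attributes, converting back to 1-based inclusive
#' coordinates. Output row order is deterministic (chrom, start, gene_id).
#'
#' @param ann a [genome_annotation()]
#' @param path output file
#' @export
write_annotation_gff3 <- function(ann, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  cl <- chrom_lengths(ann)
  for (ch in names(cl))
    writeLines(sprintf("##sequence-region %s 1 %d", ch, as.integer(cl[[ch]])), con)
  ord <- order(ann$chrom, ann$start, ann$gene_id)
  for (i in ord) {
    g <- ann[i, ]
    ftype <- if (g$pseudogene) "pseudogene" else "gene"
    writeLines(sprintf("%s\ttandemor\t%s\t%d\t%d\t.\t%s\t.\tID=%s;gene_biotype=%s",
                       g$chrom, ftype, g$start + 1, g$end, g$strand,
                       g$gene_id, g$biotype), con)
    ex <- g$exons[[1]]
    for (j in seq_len(nrow(ex)))
      writeLines(sprintf("%s\ttandemor\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                         g$chrom, ex[j, 1] + 1, ex[j, 2], g$strand, g$gene_id), con)
    cd <- g$cds[[1]]
    for (j in seq_len(nrow(cd)))
      writeLines(sprintf("%s\ttandemor\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s",
                         g$chrom, cd[j, 1] + 1, cd[j, 2], g$strand, g$gene_id), con)
  }
  invisible(path)
}

#' Transcription start anchor of a gene
#'
#' Strand-aware 5'-most position. `mode = "annotated"` uses the gene span;
#' `mode = "first_cds"` uses the CDS (the convention for OR genes, whose UTR
#' annotations are unreliable). For a "+" gene this is the minimum start; for
#' a "-" gene the maximum end (both as 0-based boundary coordinates).
#'
#' @param gene one-row slice of a [genome_annotation()]
#' @param mode "annotated" or "first_cds"
#' @return numeric position
#' @export
anchor_tss <- function(gene, mode = c("annotated", "first_cds")) {
  mode <- match.arg(mode)
  if (mode == "first_cds") {
    cds <- gene$cds[[1]]
    if (is.null(cds) || nrow(cds) == 0)
      stopf("gene %s has no CDS; cannot anchor at first_cds", gene$gene_id)
    if (gene$strand == "+") min(cds[, 1]) else max(cds[, 2])
  } else {
    if (gene$strand == "+") gene$start else gene$end
  }
}

# vectorised anchors for a whole annotation; ORs at first CDS, others annotated
gene_anchors <- function(ann, or_mode = "first_cds") {
  vapply(seq_len(nrow(ann)), function(i) {
    g <- ann[i, ]
    mode <- if (g$biotype == "OR" && or_mode == "first_cds" &&
                !is.null(g$cds[[1]]) && nrow(g$cds[[1]]) > 0) "first_cds" else "annotated"
    anchor_tss(g, mode)
  }, 0)
}

#' Detect tandem arrays of OR genes
#'
#' Chains OR genes (pseudogenes included) into arrays when the gap between
#' consecutive ORs on a chromosome is at most `max_gap`, irrespective of
#' strand, so inverted members stay in their array. The array strand is the
#' modal member strand; an exact tie falls back to the first member's strand
#' with a warning.
#'
#' @param ann a [genome_annotation()]
#' @param max_gap maximum inter-OR gap in bp (default 10 kb)
#' @return list with `arrays` (tibble: array_id, chrom, majority_strand,
#'   start, end, n_or, or_ids list-column) and `singletons` (character ids)
#' @export
detect_tandem_arrays <- function(ann, max_gap = 10000) {
  ors <- ann[ann$biotype == "OR", ]
  arrays <- list(); singles <- character(0); k <- 0L
  for (ch in sort(unique(ors$chrom))) {
    g <- ors[ors$chrom == ch, ]
    g <- g[order(g$start, g$gene_id), ]
    if (nrow(g) == 0) next
    # gap to the running maximum end so nested/overlapping members chain
    # exactly as a transitive closure of pairwise gap <= max_gap would
    gap <- g$start[-1] - cummax(g$end)[-nrow(g)]
    grp <- cumsum(c(0, as.integer(gap > max_gap)))
    for (gi in unique(grp)) {
      members <- g[grp == gi, ]
      if (nrow(members) < 2) { singles <- c(singles, members$gene_id); next }
      k <- k + 1L
      tab <- table(members$strand)
      maj <- names(tab)[which.max(tab)]
      if (length(tab) == 2 && tab[1] == tab[2]) {
        maj <- members$strand[1]
        warnf("array %d: strand tie, using first member's strand (%s)", k, maj)
      }
      arrays[[k]] <- tibble::tibble(
        array_id = sprintf("A%03d", k), chrom = ch, majority_strand = maj,
        start = min(members$start), end = max(members$end),
        n_or = nrow(members), or_ids = list(members$gene_id))
    }
  }
  list(arrays = if (k > 0) dplyr::bind_rows(arrays) else
         tibble::tibble(array_id = character(0), chrom = character(0),
                        majority_strand = character(0), start = numeric(0),
                        end = numeric(0), n_or = integer(0), or_ids = list()),
       singletons = singles)
}

#' Nearest non-OR genes flanking an array or singleton OR
#'
#' Finds the nearest non-OR gene on each genomic side of the span, split by
#' strand relative to the array's majority strand. "Upstream"/"downstream"
#' follow the transcription direction of the majority strand, so for a
#' "-"-strand array the gene at lower coordinates is downstream.
#'
#' @param span list/row with `chrom`, `majority_strand`, `start`, `end`
#' @param ann a [genome_annotation()]
#' @return named list (upstream_same, upstream_opposite, downstream_same,
#'   downstream_opposite) of gene_id or NA when absent
#' @export
flanking_genes <- function(span, ann) {
  cand <- ann[ann$biotype != "OR" & ann$chrom == span$chrom, ]
  left <- cand[cand$end <= span$start, ]
  right <- cand[cand$start >= span$end, ]
  nearest <- function(side, strand_class) {
    want <- if (strand_class == "same") span$majority_strand else other_strand(span$majority_strand)
    g <- side[side$strand == want, ]
    if (nrow(g) == 0) return(NA_character_)
    d <- pmax(span$start - g$end, g$start - span$end)
    g$gene_id[which.min(d)]
  }
  if (span$majority_strand == "+") {
    list(upstream_same = nearest(left, "same"),
         upstream_opposite = nearest(left, "opposite"),
         downstream_same = nearest(right, "same"),
         downstream_opposite = nearest(right, "opposite"))
  } else {
    list(upstream_same = nearest(right, "same"),
         upstream_opposite = nearest(right, "opposite"),
         downstream_same = nearest(left, "same"),
         downstream_opposite = nearest(left, "opposite"))
  }
}

cds_length <- function(gene) interval_width(gene$cds[[1]])

# all candidate same-strand ordered pairs with their filter verdicts
gene_pair_candidates <- function(ann, cds_len_bounds, intergenic_bounds) {
  out <- list(); k <- 0L
  for (ch in sort(unique(ann$chrom))) {
    sub <- ann[ann$chrom == ch, ]
    sub <- sub[order(sub$start, sub$gene_id), ]
    for (st in c("+", "-")) {
      g <- sub[sub$strand == st, ]
      if (nrow(g) < 2) next
      for (i in seq_len(nrow(g) - 1)) {
        a <- g[i, ]; b <- g[i + 1, ]   # a genomically left of b
        gap_start <- a$end; gap_end <- b$start
        if (gap_end <= gap_start) next
        len <- gap_end - gap_start
        if (len < intergenic_bounds[1] || len > intergenic_bounds[2]) next
        cl_a <- cds_length(a); cl_b <- cds_length(b)
        if (cl_a < cds_len_bounds[1] || cl_a > cds_len_bounds[2]) next
        if (cl_b < cds_len_bounds[1] || cl_b > cds_len_bounds[2]) next
        others <- sub[!(sub$gene_id %in% c(a$gene_id, b$gene_id)), ]
        if (nrow(others) > 0) {
          hit_a <- intervals_overlap(a$start, a$end, others$start, others$end)
          hit_b <- intervals_overlap(b$start, b$end, others$start, others$end)
          hit_g <- intervals_overlap(gap_start, gap_end, others$start, others$end)
          if (any(hit_a | hit_b | hit_g)) next
        }
        # transcription order: on "+" left gene is upstream, on "-" right is
        up <- if (st == "+") a else b
        dn <- if (st == "+") b else a
        both_or <- up$biotype == "OR" && dn$biotype == "OR"
        neither_or <- up$biotype != "OR" && dn$biotype != "OR"
        if (!both_or && !neither_or) next
        k <- k + 1L
        out[[k]] <- tibble::tibble(
          pair_id = sprintf("%s:%s>%s", ch, up$gene_id, dn$gene_id),
          chrom = ch, strand = st,
          upstream = up$gene_id, downstream = dn$gene_id,
          intergenic_start = gap_start, intergenic_end = gap_end,
          intergenic_len = len,
          pair_class = if (both_or) "OR" else "nonOR")
      }
    }
  }
  if (k == 0) return(tibble::tibble(
    pair_id = character(0), chrom = character(0), strand = character(0),
    upstream = character(0), downstream = character(0),
    intergenic_start = numeric(0), intergenic_end = numeric(0),
    intergenic_len = numeric(0), pair_class = character(0)))
  dplyr::bind_rows(out)
}

#' Sample filtered gene pairs
#'
#' Applies the gene-pair filters: coding-sequence length of both members
#' within `cds_len_bounds`, same strand, intergenic distance within
#' `intergenic_bounds`, and neither gene nor the intergenic interval
#' overlapping any other annotated gene on either strand. OR pairs (both
#' members OR) are returned exhaustively; non-OR pairs (neither member OR)
#' are a seeded uniform sample of size `n_nonor`.
#'
#' @param ann a [genome_annotation()]
#' @param cds_len_bounds numeric(2), bp (default c(100, 10000))
#' @param intergenic_bounds numeric(2), bp (default c(50, 10000))
#' @param n_nonor number of non-OR pairs to sample; NULL = same as number of
#'   OR pairs
#' @param seed integer seed for the non-OR sample
#' @return list with tibbles `or_pairs` and `nonor_pairs`
#' @export
sample_gene_pairs <- function(ann, cds_len_bounds = c(100, 10000),
                              intergenic_bounds = c(50, 10000),
                              n_nonor = NULL, seed = 1L) {
  cand <- gene_pair_candidates(ann, cds_len_bounds, intergenic_bounds)
  or_pairs <- cand[cand$pair_class == "OR", ]
  nonor <- cand[cand$pair_class == "nonOR", ]
  if (is.null(n_nonor)) n_nonor <- nrow(or_pairs)
  if (n_nonor > nrow(nonor)) {
    warnf("requested %d non-OR pairs but only %d available; returning all",
          n_nonor, nrow(nonor))
    n_nonor <- nrow(nonor)
  }
  nonor <- nonor[order(nonor$pair_id), ]
  idx <- withr::with_seed(seed, sample(nrow(nonor), n_nonor))
  list(or_pairs = or_pairs, nonor_pairs = nonor[sort(idx), ])
}

#' Antisense lncRNA overlap per gene
#'
#' A gene overlaps an antisense lncRNA iff some lncRNA on the opposite strand
#' of the same chromosome shares at least 1 bp with its span. Fractions are
#' reported over non-pseudogene OR genes and non-pseudogene "other" genes.
#'
#' @param ann a [genome_annotation()]
#' @return list with `per_gene` (tibble gene_id, biotype, overlaps) and
#'   `frac_OR`, `frac_nonOR`
#' @export
antisense_lncrna_overlap <- function(ann) {
  lnc <- ann[ann$biotype == "lncRNA", ]
  target <- ann[ann$biotype != "lncRNA" & !ann$pseudogene, ]
  hits <- vapply(seq_len(nrow(target)), function(i) {
    g <- target[i, ]
    l <- lnc[lnc$chrom == g$chrom & lnc$strand == other_strand(g$strand), ]
    nrow(l) > 0 && any(intervals_overlap(g$start, g$end, l$start, l$end))
  }, FALSE)
  per_gene <- tibble::tibble(gene_id = target$gene_id,
                             biotype = target$biotype, overlaps = hits)
  frac <- function(bt) {
    n <- sum(per_gene$biotype == bt)
    if (n == 0) NA_real_ else sum(per_gene$overlaps[per_gene$biotype == bt]) / n
  }
  list(per_gene = per_gene, frac_OR = frac("OR"), frac_nonOR = frac("other"))
}

#' lncRNAs nested in a tandem array
#'
#' Returns lncRNAs whose span overlaps the array span, with the nearest OR
#' neighbor on each side of the lncRNA TSS in the array's transcription
#' direction, and TSS-to-TSS distances.
#'
#' @param array one row of the `arrays` tibble from [detect_tandem_arrays()]
#' @param ann a [genome_annotation()]
#' @return tibble: lncrna_id, upstream_or, downstream_or, dist_upstream,
#'   dist_downstream (NA where a neighbor is absent)
#' @export
nested_lncrnas <- function(array, ann) {
  lnc <- ann[ann$biotype == "lncRNA" & ann$chrom == array$chrom, ]
  lnc <- lnc[intervals_overlap(lnc$start, lnc$end, array$start, array$end), ]
  ors <- ann[ann$gene_id %in% array$or_ids[[1]], ]
  or_tss <- gene_anchors(ors)
  rows <- lapply(seq_len(nrow(lnc)), function(i) {
    l <- lnc[i, ]
    ltss <- anchor_tss(l, "annotated")
    # side relative to the lncRNA TSS, in array transcription direction
    rel <- if (array$majority_strand == "+") or_tss - ltss else ltss - or_tss
    up <- which(rel < 0); dn <- which(rel >= 0)
    pick <- function(idx) if (length(idx) == 0) c(NA_character_, NA_real_) else {
      j <- idx[which.min(abs(rel[idx]))]
      c(ors$gene_id[j], abs(rel[j]))
    }
    u <- pick(up); d <- pick(dn)
    tibble::tibble(lncrna_id = l$gene_id,
                   upstream_or = u[1], downstream_or = d[1],
                   dist_upstream = as.numeric(u[2]),
                   dist_downstream = as.numeric(d[2]))
  })
  if (length(rows) == 0)
    return(tibble::tibble(lncrna_id = character(0), upstream_or = character(0),
                          downstream_or = character(0),
                          dist_upstream = numeric(0), dist_downstream = numeric(0)))
  dplyr::bind_rows(rows)
}
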