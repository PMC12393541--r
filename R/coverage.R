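#' Stranded per-base coverage track
#'
#' Dense per-chromosome, per-strand read-depth vectors (reads per
#' nucleotide). Internally a list `chrom -> list("+" = depth, "-" = depth)`
#' with a `chrom_lengths` attribute; positions are 0-based, so depth at base
#' `p` is element `p + 1` of the vector.
#'
#' @param chrom_lengths named numeric vector
#' @return an all-zero `coverage_track`
#' @export
coverage_track <- function(chrom_lengths) {
  tr <- lapply(chrom_lengths, function(L)
    list("+" = numeric(L), "-" = numeric(L)))
  attr(tr, "chrom_lengths") <- chrom_lengths
  class(tr) <- "coverage_track"
  tr
}

#' Read a stranded bedGraph pair into a coverage track
#'
#' One bedGraph per strand, half-open intervals as on disk. Records on
#' unknown chromosomes are skipped with a warning; when records overlap, the
#' later record wins (with a warning).
#'
#' @param plus_path,minus_path bedGraph files for the + and - strand
#' @param chrom_lengths named numeric vector
#' @return a `coverage_track`
#' @export
read_bedgraph_pair <- function(plus_path, minus_path, chrom_lengths) {
  tr <- coverage_track(chrom_lengths)
  fill <- function(path, strand) {
    if (file.size(path) == 0) return()
    gr <- rtracklayer::import(path, format = "bedGraph")
    if (length(gr) == 0) return()
    ch <- as.character(GenomicRanges::seqnames(gr))
    unknown <- !ch %in% names(chrom_lengths)
    if (any(unknown)) {
      warnf("%d bedGraph records on unknown chromosomes skipped", sum(unknown))
      gr <- gr[!unknown]; ch <- ch[!unknown]
    }
    s <- GenomicRanges::start(gr) - 1; e <- GenomicRanges::end(gr)
    v <- S4Vectors::mcols(gr)$score
    seen_overlap <- FALSE
    for (i in seq_along(gr)) {
      idx <- (s[i] + 1):e[i]
      if (!seen_overlap && any(tr[[ch[i]]][[strand]][idx] != 0)) {
        seen_overlap <- TRUE
        warnf("overlapping bedGraph records on %s strand; last record wins", strand)
      }
      tr[[ch[i]]][[strand]][idx] <<- v[i]
    }
  }
  fill(plus_path, "+")
  fill(minus_path, "-")
  tr
}

#' Write a coverage track as a stranded bedGraph pair
#' @param track a `coverage_track`
#' @param plus_path,minus_path output files
#' @export
write_bedgraph_pair <- function(track, plus_path, minus_path) {
  wr <- function(path, strand) {
    con <- file(path, "w")
    on.exit(close(con))
    for (ch in names(track)) {
      v <- track[[ch]][[strand]]
      r <- rle(v)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths
      keep <- r$values != 0
      if (any(keep))
        writeLines(sprintf("%s\t%d\t%d\t%.6g", ch,
                           as.integer(starts[keep]), as.integer(ends[keep]),
                           r$values[keep]), con)
    }
  }
  wr(plus_path, "+")
  wr(minus_path, "-")
  invisible(c(plus_path, minus_path))
}

#' Mean coverage over a union of intervals
#'
#' Base-weighted mean: total depth over the union of interval bases divided
#' by the union width, so multi-exon means weight exons by length.
#'
#' @param track a `coverage_track`
#' @param chrom chromosome name
#' @param intervals 2-column matrix of 0-based half-open intervals
#' @param strand "+" or "-"
#' @return reads per nucleotide
#' @export
mean_region_coverage <- function(track, chrom, intervals, strand) {
  iv <- interval_union(intervals)
  if (is.null(iv) || nrow(iv) == 0 || interval_width(iv) == 0)
    stopf("zero-length interval union on %s", chrom)
  bases <- interval_bases(iv)
  mean(track[[chrom]][[strand]][bases])
}

pair_features <- function(pair, ann) {
  up <- ann[ann$gene_id == pair$upstream, ]
  dn <- ann[ann$gene_id == pair$downstream, ]
  introns <- function(g) {
    ex <- interval_union(g$exons[[1]])
    span <- IRanges::IRanges(g$start + 1, g$end)
    gaps <- IRanges::setdiff(span, IRanges::IRanges(ex[, 1] + 1, ex[, 2]))
    if (length(gaps) == 0) return(matrix(numeric(0), 0, 2))
    cbind(IRanges::start(gaps) - 1, IRanges::end(gaps))
  }
  list(upstream_exons = interval_union(up$exons[[1]]),
       upstream_introns = introns(up),
       downstream_exons = interval_union(dn$exons[[1]]),
       downstream_introns = introns(dn),
       intergenic = matrix(c(pair$intergenic_start, pair$intergenic_end), 1, 2))
}

#' Relative coverage of a gene pair
#'
#' Mean coverage over upstream/downstream exons and introns and the
#' intergenic span, on the sense and/or antisense strand, normalized to the
#' mean sense-strand coverage of the upstream gene's exons. When that
#' normalizer is zero all records of the pair are flagged undefined.
#'
#' @param pair one row of a pair tibble from [sample_gene_pairs()]
#' @param track a `coverage_track`
#' @param ann a [genome_annotation()]
#' @param orientation subset of c("sense", "antisense")
#' @return tibble: pair_id, pair_class, feature, orientation, mean_cov,
#'   rel_cov, defined
#' @export
pair_relative_coverage <- function(pair, track, ann,
                                   orientation = c("sense", "antisense")) {
  orientation <- match.arg(orientation, several.ok = TRUE)
  feats <- pair_features(pair, ann)
  sense_strand <- pair$strand
  norm <- mean_region_coverage(track, pair$chrom, feats$upstream_exons, sense_strand)
  rows <- list()
  for (ori in orientation) {
    st <- if (ori == "sense") sense_strand else other_strand(sense_strand)
    for (f in names(feats)) {
      iv <- feats[[f]]
      mc <- if (nrow(iv) == 0 || interval_width(iv) == 0) NA_real_ else
        mean_region_coverage(track, pair$chrom, iv, st)
      rows[[length(rows) + 1]] <- tibble::tibble(
        pair_id = pair$pair_id, pair_class = pair$pair_class,
        feature = f, orientation = ori, mean_cov = mc,
        rel_cov = if (norm > 0 && !is.na(mc)) mc / norm else NA_real_,
        defined = norm > 0 && !is.na(mc),
        norm_defined = norm > 0)
    }
  }
  dplyr::bind_rows(rows)
}

#' Relative coverage for many pairs
#' @param pairs tibble of pairs
#' @inheritParams pair_relative_coverage
#' @export
pairs_relative_coverage <- function(pairs, track, ann,
                                    orientation = c("sense", "antisense")) {
  res <- lapply(seq_len(nrow(pairs)), function(i)
    pair_relative_coverage(pairs[i, ], track, ann, orientation))
  out <- dplyr::bind_rows(res)
  n_undef <- length(unique(out$pair_id[!out$norm_defined]))
  if (n_undef > 0)
    inform(sprintf("%d pairs with undefined normalizer excluded from statistics", n_undef))
  out
}

#' Compare relative coverage between OR and non-OR pairs
#'
#' Two-sided Wilcoxon rank-sum test of `rel_cov` per feature, with
#' Benjamini-Hochberg adjustment across the tested features when more than
#' one is tested. Undefined records are excluded; features with fewer than
#' two defined values in either group are skipped with a warning.
#'
#' @param or_records,nonor_records outputs of [pairs_relative_coverage()]
#' @param features features to test (default: all shared)
#' @param orientation which orientation's records to compare
#' @return tibble: feature, n_or, n_nonor, statistic, p_raw, p_adj
#' @export
compare_groups <- function(or_records, nonor_records,
                           features = NULL, orientation = "sense") {
  a <- or_records[or_records$orientation == orientation & or_records$defined, ]
  b <- nonor_records[nonor_records$orientation == orientation & nonor_records$defined, ]
  if (is.null(features)) features <- intersect(unique(a$feature), unique(b$feature))
  rows <- lapply(features, function(f) {
    x <- a$rel_cov[a$feature == f]; y <- b$rel_cov[b$feature == f]
    if (length(x) < 2 || length(y) < 2) {
      warnf("feature %s skipped: insufficient data", f)
      return(NULL)
    }
    wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
    tibble::tibble(feature = f, n_or = length(x), n_nonor = length(y),
                   statistic = unname(wt$statistic), p_raw = wt$p.value)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 0) out$p_adj <- p.adjust(out$p_raw, method = "BH")
  out
}
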