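#' Read a cells-by-genes count matrix
#'
#' MTX triplet (matrix + barcodes + genes TSVs, genes in MTX rows as written
#' by CellRanger-style exporters are transposed to cells x genes) or a dense
#' TSV with cells in rows and genes in columns.
#'
#' @param path .mtx file or dense TSV
#' @param genes_path,barcodes_path companion TSVs for the MTX triplet
#' @return sparse dgCMatrix, cells x genes, with dimnames
#' @export
read_counts <- function(path, genes_path = NULL, barcodes_path = NULL) {
  if (grepl("\\.mtx$", path)) {
    m <- Matrix::readMM(path)
    genes <- readLines(genes_path)
    cells <- readLines(barcodes_path)
    if (nrow(m) == length(genes) && ncol(m) == length(cells)) {
      m <- Matrix::t(m)
    } else if (!(nrow(m) == length(cells) && ncol(m) == length(genes))) {
      stopf("MTX dimensions do not match genes/barcodes files")
    }
    dimnames(m) <- list(cells, genes)
    methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
  } else {
    df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                            check.names = FALSE)
    methods::as(Matrix::Matrix(as.matrix(df), sparse = TRUE), "CsparseMatrix")
  }
}

#' Write a count matrix as an MTX triplet
#' @param m cells x genes matrix
#' @param dir output directory (creates matrix.mtx, genes.tsv, barcodes.tsv)
#' @export
write_counts_mtx <- function(m, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(Matrix::t(m), "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(colnames(m), file.path(dir, "genes.tsv"))
  writeLines(rownames(m), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Filter to neurons by marker expression
#'
#' Keeps cells with at least `min_markers` of the marker genes detected at a
#' UMI count of at least `min_umi`.
#'
#' @param m cells x genes count matrix
#' @param markers marker gene ids (absent markers are warned about)
#' @param min_markers minimum number of markers passing (default 2)
#' @param min_umi minimum UMI per passing marker (default 2)
#' @return filtered matrix
#' @export
filter_neurons <- function(m, markers, min_markers = 2, min_umi = 2) {
  present <- intersect(markers, colnames(m))
  if (length(present) == 0) stopf("none of the marker genes are in the matrix")
  if (length(present) < length(markers))
    warnf("markers absent from matrix: %s",
          paste(setdiff(markers, present), collapse = ", "))
  n_pass <- Matrix::rowSums(m[, present, drop = FALSE] >= min_umi)
  m[n_pass >= min_markers, , drop = FALSE]
}

#' Normalize counts to a target sum, then log-transform
#'
#' Per cell, counts are scaled to sum to `target_sum` and natural-log
#' transformed with log1p, so for every non-empty cell
#' sum(expm1(values)) == target_sum. Empty cells stay all-zero.
#'
#' @param m cells x genes count matrix
#' @param target_sum target per-cell total (default 10000)
#' @return normalized sparse matrix with attributes `target_sum` and
#'   `log_base` ("e")
#' @export
normalize_counts <- function(m, target_sum = 10000) {
  totals <- Matrix::rowSums(m)
  scale <- ifelse(totals > 0, target_sum / totals, 0)
  nm <- Matrix::Diagonal(x = scale) %*% m
  nm@x <- log1p(nm@x)
  dimnames(nm) <- dimnames(m)
  nm <- methods::as(nm, "CsparseMatrix")
  attr(nm, "target_sum") <- target_sum
  attr(nm, "log_base") <- "e"
  nm
}

#' Assign the chosen OR per cell
#'
#' The chosen OR is the highest-expressing OR gene in each cell. Ties are
#' broken toward the lowest genomic coordinate and flagged; cells with no OR
#' expression get NA.
#'
#' @param nm normalized cells x genes matrix
#' @param ann a [genome_annotation()] (provides OR genes and coordinates)
#' @param arrays tibble from [detect_tandem_arrays()] (for array membership;
#'   optional)
#' @return tibble: cell_id, chosen_or, chosen_value, array_id, tie_flag
#' @export
assign_chosen_or <- function(nm, ann, arrays = NULL) {
  ors <- ann[ann$biotype == "OR", ]
  or_genes <- intersect(ors$gene_id, colnames(nm))
  if (length(or_genes) == 0) stopf("no OR genes present in the matrix")
  ord <- order(ors$chrom[match(or_genes, ors$gene_id)],
               ors$start[match(or_genes, ors$gene_id)])
  or_genes <- or_genes[ord]                     # genomic order for tie-break
  sub <- as.matrix(nm[, or_genes, drop = FALSE])
  rowmax <- unname(apply(sub, 1, max))
  pick <- max.col(sub, ties.method = "first")   # first = lowest coordinate
  n_at_max <- rowSums(sub == rowmax & sub > 0)
  chosen <- or_genes[pick]
  chosen[rowmax == 0] <- NA_character_
  aid <- rep(NA_character_, length(chosen))
  if (!is.null(arrays) && nrow(arrays) > 0) {
    member <- stats::setNames(rep(arrays$array_id, lengths(arrays$or_ids)),
                              unlist(arrays$or_ids))
    aid <- unname(member[chosen])
    aid[!is.na(chosen) & is.na(aid)] <- "singleton"
  }
  tibble::tibble(cell_id = rownames(nm),
                 chosen_or = chosen,
                 chosen_value = ifelse(rowmax > 0, rowmax, NA_real_),
                 array_id = aid,
                 tie_flag = unname(n_at_max > 1))
}

#' Staircase matrix for one tandem array
#'
#' Cells whose chosen OR belongs to the array, sorted by the genomic
#' position of their chosen OR, against the array's ORs in genomic order.
#' Optionally restrict to cells with detectable (>0) or absent (=0)
#' expression of a named lncRNA.
#'
#' @param array one row of the arrays tibble
#' @param nm normalized matrix
#' @param chosen output of [assign_chosen_or()]
#' @param ann a [genome_annotation()]
#' @param lnc_filter optional list(gene_id =, detectable = TRUE/FALSE)
#' @return dense matrix (cells x array ORs); 0-row matrix with a warning if
#'   no cell qualifies
#' @export
staircase_matrix <- function(array, nm, chosen, ann, lnc_filter = NULL) {
  ors <- ann[ann$gene_id %in% array$or_ids[[1]], ]
  ors <- ors[order(ors$start), ]
  cols <- intersect(ors$gene_id, colnames(nm))
  sel <- chosen[!is.na(chosen$chosen_or) & chosen$chosen_or %in% cols, ]
  if (!is.null(lnc_filter)) {
    v <- as.numeric(nm[sel$cell_id, lnc_filter$gene_id])
    sel <- sel[if (isTRUE(lnc_filter$detectable)) v > 0 else v == 0, ]
  }
  if (nrow(sel) == 0) {
    warnf("no cells with a chosen OR in array %s", array$array_id)
    return(matrix(numeric(0), 0, length(cols), dimnames = list(NULL, cols)))
  }
  pos <- ors$start[match(sel$chosen_or, ors$gene_id)]
  sel <- sel[order(pos, sel$cell_id), ]
  as.matrix(nm[sel$cell_id, cols, drop = FALSE])
}

#' Flanking-gene enrichment dot matrix
#'
#' For each cell group (cells sharing a chosen-OR tandem array) and each
#' flanking gene: the percentage of cells detecting the gene (>0) and the
#' mean log-normalized expression over the group.
#'
#' @param groups named list array_id -> cell ids
#' @param flank_genes character vector of flanking gene ids
#' @param nm normalized matrix
#' @return tibble: array_id, gene_id, pct_detected, mean_lognorm
#' @export
flanking_enrichment <- function(groups, flank_genes, nm) {
  rows <- list()
  for (aid in names(groups)) {
    cells <- intersect(groups[[aid]], rownames(nm))
    for (g in flank_genes) {
      if (!g %in% colnames(nm)) {
        warnf("flanking gene %s absent from matrix", g)
        pct <- 0; mu <- 0
      } else if (length(cells) == 0) {
        pct <- 0; mu <- 0
      } else {
        v <- as.numeric(nm[cells, g])
        pct <- 100 * mean(v > 0); mu <- mean(v)
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        array_id = aid, gene_id = g, pct_detected = pct, mean_lognorm = mu)
    }
  }
  dplyr::bind_rows(rows)
}

# context table pairing each nested lncRNA with its role ORs:
#   upstream_or  = nearest OR upstream of the lncRNA (array direction)
#   chosen_or    = nearest OR downstream of the lncRNA (the promoter that
#                  drives both the lncRNA and, in cells choosing it, the OR)
#   downstream_or = next OR after the chosen one
# distance = chosen OR TSS to lncRNA 3' end (bp)
lnc_context <- function(ann, arrays) {
  rows <- list()
  for (i in seq_len(nrow(arrays))) {
    arr <- arrays[i, ]
    nl <- nested_lncrnas(arr, ann)
    if (nrow(nl) == 0) next
    ors <- ann[ann$gene_id %in% arr$or_ids[[1]], ]
    ors <- ors[order(ors$start), ]
    if (arr$majority_strand == "-") ors <- ors[rev(seq_len(nrow(ors))), ]
    for (j in seq_len(nrow(nl))) {
      ch <- nl$downstream_or[j]
      if (is.na(ch)) next
      k <- match(ch, ors$gene_id)
      dn <- if (k < nrow(ors)) ors$gene_id[k + 1] else NA_character_
      l <- ann[ann$gene_id == nl$lncrna_id[j], ]
      three_prime <- if (l$strand == "+") l$end else l$start
      chosen_tss <- gene_anchors(ann[ann$gene_id == ch, ])
      rows[[length(rows) + 1]] <- tibble::tibble(
        lncrna_id = nl$lncrna_id[j], array_id = arr$array_id,
        upstream_or = nl$upstream_or[j], chosen_or = ch, downstream_or = dn,
        distance = abs(chosen_tss - three_prime))
    }
  }
  if (length(rows) == 0)
    return(tibble::tibble(lncrna_id = character(0), array_id = character(0),
                          upstream_or = character(0), chosen_or = character(0),
                          downstream_or = character(0), distance = numeric(0)))
  dplyr::bind_rows(rows)
}

#' Coexpression of array ORs with a nested lncRNA
#'
#' Mean log-normalized expression of each OR in the lncRNA's array,
#' restricted to cells expressing the lncRNA (>0), with signed TSS-to-TSS
#' distances (negative = OR upstream of the lncRNA in array direction).
#'
#' @param lnc_id lncRNA gene id
#' @param ann a [genome_annotation()]
#' @param arrays tibble from [detect_tandem_arrays()]
#' @param nm normalized matrix
#' @return tibble: or_id, side, tss_tss_distance, mean_lognorm, n_cells
#' @export
lnc_neighbor_coexpression <- function(lnc_id, ann, arrays, nm) {
  l <- ann[ann$gene_id == lnc_id, ]
  hit <- which(vapply(seq_len(nrow(arrays)), function(i)
    arrays$chrom[i] == l$chrom &&
      intervals_overlap(l$start, l$end, arrays$start[i], arrays$end[i]), FALSE))
  if (length(hit) == 0) stopf("lncRNA %s is not nested in any array", lnc_id)
  arr <- arrays[hit[1], ]
  cells <- rownames(nm)[as.numeric(nm[, lnc_id]) > 0]
  if (length(cells) == 0)
    return(tibble::tibble(or_id = character(0), side = character(0),
                          tss_tss_distance = numeric(0),
                          mean_lognorm = numeric(0), n_cells = integer(0)))
  ors <- ann[ann$gene_id %in% arr$or_ids[[1]], ]
  or_tss <- gene_anchors(ors)
  ltss <- anchor_tss(l, "annotated")
  rel <- if (arr$majority_strand == "+") or_tss - ltss else ltss - or_tss
  present <- ors$gene_id %in% colnames(nm)
  tibble::tibble(
    or_id = ors$gene_id,
    side = ifelse(rel < 0, "upstream", "downstream"),
    tss_tss_distance = rel,
    mean_lognorm = ifelse(present,
                          vapply(ors$gene_id, function(g)
                            if (g %in% colnames(nm)) mean(as.numeric(nm[cells, g])) else NA_real_, 0),
                          NA_real_),
    n_cells = length(cells))
}

#' lncRNA-OR expression correlations by promoter distance
#'
#' For each nested lncRNA, restricts to cells whose chosen OR is the
#' lncRNA's paired (promoter-sharing) OR, and computes the Pearson
#' correlation of lncRNA expression with the upstream OR, the chosen OR and
#' the downstream OR. Records are binned by the chosen-OR-TSS to lncRNA-3'
#' distance. With `pooled = TRUE`, cells are pooled across all qualifying
#' lncRNAs within each distance bin before computing r.
#'
#' @param nm normalized matrix
#' @param chosen output of [assign_chosen_or()]
#' @param ann a [genome_annotation()]
#' @param arrays tibble from [detect_tandem_arrays()]
#' @param bins upper bounds of the distance bins in bp
#'   (default c(2500, 5000, 10000))
#' @param min_cells minimum cells for a correlation (default 3)
#' @param pooled pool cells across lncRNAs per bin
#' @return tibble: lncrna_id, partner_role, partner_gene, n_cells,
#'   pearson_r, p_value, distance, distance_bin
#' @export
lnc_or_correlation <- function(nm, chosen, ann, arrays,
                               bins = c(2500, 5000, 10000),
                               min_cells = 3, pooled = FALSE) {
  ctx <- lnc_context(ann, arrays)
  ctx <- ctx[ctx$distance <= max(bins), ]
  bin_label <- function(d) {
    lo <- c(0, bins[-length(bins)])
    i <- findInterval(d, c(0, bins), rightmost.closed = TRUE,
                      left.open = TRUE)
    i[d == 0] <- 1
    sprintf("(%g,%g]", lo[i], bins[i])
  }
  roles <- c(upstream_OR = "upstream_or", chosen_OR = "chosen_or",
             downstream_OR = "downstream_or")
  collect <- function(ctx_rows) {
    # per-role vectors of (lnc value, partner value) across qualifying cells
    out <- list()
    for (j in seq_len(nrow(ctx_rows))) {
      cx <- ctx_rows[j, ]
      cells <- chosen$cell_id[!is.na(chosen$chosen_or) &
                                chosen$chosen_or == cx$chosen_or]
      if (length(cells) == 0 || !cx$lncrna_id %in% colnames(nm)) next
      lv <- as.numeric(nm[cells, cx$lncrna_id])
      for (role in names(roles)) {
        partner <- cx[[roles[[role]]]]
        if (is.na(partner) || !partner %in% colnames(nm)) next
        out[[length(out) + 1]] <- tibble::tibble(
          lncrna_id = cx$lncrna_id, partner_role = role, partner_gene = partner,
          distance = cx$distance, lnc_value = lv,
          partner_value = as.numeric(nm[cells, partner]))
      }
    }
    dplyr::bind_rows(out)
  }
  long <- collect(ctx)
  if (nrow(long) == 0) return(tibble::tibble(
    lncrna_id = character(0), partner_role = character(0),
    partner_gene = character(0), n_cells = integer(0), pearson_r = numeric(0),
    p_value = numeric(0), distance = numeric(0), distance_bin = character(0)))
  long$distance_bin <- bin_label(long$distance)
  key <- if (pooled) c("distance_bin", "partner_role") else
    c("lncrna_id", "partner_role", "partner_gene", "distance", "distance_bin")
  grp <- dplyr::group_by(long, dplyr::across(dplyr::all_of(key)))
  res <- dplyr::summarise(
    grp,
    n_cells = dplyr::n(),
    pearson_r = if (dplyr::n() >= min_cells &&
                    sd(.data$lnc_value) > 0 && sd(.data$partner_value) > 0)
      cor(.data$lnc_value, .data$partner_value) else NA_real_,
    p_value = if (dplyr::n() >= min_cells &&
                  sd(.data$lnc_value) > 0 && sd(.data$partner_value) > 0)
      cor.test(.data$lnc_value, .data$partner_value)$p.value else NA_real_,
    .groups = "drop")
  res <- res[!is.na(res$pearson_r), ]
  if (pooled) {
    res$lncrna_id <- "pooled"
    res$partner_gene <- NA_character_
    res$distance <- NA_real_
  }
  res[, c("lncrna_id", "partner_role", "partner_gene", "n_cells",
          "pearson_r", "p_value", "distance", "distance_bin")]
}

#' Mean per-lncRNA correlation per role, with one-sample t-test against 0
#'
#' @param records output of [lnc_or_correlation()] (unpooled)
#' @return tibble: partner_role, n_lnc, mean_r, t_statistic, p_value
#'   (p is NA with fewer than 2 lncRNAs)
#' @export
per_lnc_mean_correlation <- function(records) {
  rows <- lapply(split(records, records$partner_role), function(df) {
    r <- tapply(df$pearson_r, df$lncrna_id, mean)   # one r per lncRNA
    r <- as.numeric(r)
    if (length(r) >= 2 && sd(r) > 0) {
      tt <- t.test(r, mu = 0)
      tibble::tibble(partner_role = df$partner_role[1], n_lnc = length(r),
                     mean_r = mean(r), t_statistic = unname(tt$statistic),
                     p_value = tt$p.value)
    } else {
      tibble::tibble(partner_role = df$partner_role[1], n_lnc = length(r),
                     mean_r = mean(r), t_statistic = NA_real_,
                     p_value = NA_real_)
    }
  })
  dplyr::bind_rows(rows)
}

#' Switch-like (XOR) expression fraction
#'
#' Fraction of cells detecting exactly one of the lncRNA and the upstream OR
#' above `detect_thresh`.
#'
#' @param cells cell ids
#' @param lnc_id,upstream_or gene ids
#' @param nm normalized matrix
#' @param detect_thresh detection threshold (default 0, i.e. value > 0)
#' @return fraction in [0, 1]
#' @export
switch_fraction <- function(cells, lnc_id, upstream_or, nm, detect_thresh = 0) {
  cells <- intersect(cells, rownames(nm))
  if (length(cells) == 0) stopf("no cells supplied")
  a <- as.numeric(nm[cells, lnc_id]) > detect_thresh
  b <- as.numeric(nm[cells, upstream_or]) > detect_thresh
  mean(xor(a, b))
}
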