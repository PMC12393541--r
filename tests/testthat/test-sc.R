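sparse_counts <- function(m) {
  methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
}

test_that("neuron filtering requires enough markers at the UMI floor", {
  m <- matrix(0, 3, 7, dimnames = list(
    paste0("c", 1:3), c(paste0("mk", 1:5), "g1", "g2")))
  m[1, 1:5] <- c(2, 3, 0, 0, 0)   # two markers at >= 2: kept
  m[2, 1:5] <- c(5, 0, 0, 0, 0)   # one marker only: removed
  m[3, 1:5] <- c(1, 1, 1, 1, 1)   # no marker reaches 2: removed
  f <- filter_neurons(sparse_counts(m), paste0("mk", 1:5))
  expect_equal(rownames(f), "c1")
  expect_warning(filter_neurons(sparse_counts(m), c("mk1", "mk2", "absent")),
                 "absent")
  expect_error(filter_neurons(sparse_counts(m), c("nope1", "nope2")),
               "marker genes")
})

test_that("normalization hits the target sum then logs, leaving empty cells", {
  m <- matrix(c(1, 3, 6, 0, 0, 0), 2, 3, byrow = TRUE,
              dimnames = list(c("c1", "c2"), c("g1", "g2", "g3")))
  nm <- normalize_counts(sparse_counts(m))
  expect_equal(nm["c1", "g1"], log1p(1000), tolerance = 1e-12)
  expect_equal(as.numeric(nm["c2", ]), c(0, 0, 0))
  expect_equal(sum(expm1(as.numeric(nm["c1", ]))), 10000, tolerance = 1e-9)
  expect_equal(attr(nm, "target_sum"), 10000)
  expect_equal(attr(nm, "log_base"), "e")
  # identity holds for every non-empty cell of a generated matrix
  ga <- gen_annotation(seed = 21, n_arrays = 2)
  cnt <- gen_counts(ga$annotation, ga$truth, n_cells = 50, seed = 21)
  nm2 <- normalize_counts(cnt$counts)
  sums <- Matrix::rowSums(expm1(nm2))
  nonzero <- Matrix::rowSums(cnt$counts) > 0
  expect_true(all(abs(sums[nonzero] - 10000) / 10000 < 1e-6))
})

chosen_fixture <- function() {
  ann <- toy_ann(
    toy_coding_gene("orA", 1000, 2000, biotype = "OR"),
    toy_coding_gene("orB", 5000, 6000, biotype = "OR"),
    toy_coding_gene("gX", 20000, 21000))
  arrays <- tibble::tibble(array_id = "A001", chrom = "chr1",
                           majority_strand = "+", start = 1000, end = 6000,
                           n_or = 2L, or_ids = list(c("orA", "orB")))
  list(ann = ann, arrays = arrays)
}

test_that("chosen OR is the per-cell argmax with coordinate tie-break", {
  fx <- chosen_fixture()
  nm <- sparse_counts(matrix(
    c(5, 3, 0,
      4, 4, 1,
      0, 0, 2), 3, 3, byrow = TRUE,
    dimnames = list(paste0("c", 1:3), c("orA", "orB", "gX"))))
  ch <- assign_chosen_or(nm, fx$ann, fx$arrays)
  expect_equal(ch$chosen_or, c("orA", "orA", NA))
  expect_equal(ch$tie_flag, c(FALSE, TRUE, FALSE))
  expect_equal(ch$array_id, c("A001", "A001", NA))
  expect_equal(unname(ch$chosen_value), c(5, 4, NA))
  # permutation invariance of gene column order
  nm2 <- nm[, c("gX", "orB", "orA")]
  ch2 <- assign_chosen_or(nm2, fx$ann, fx$arrays)
  expect_equal(ch2$chosen_or, ch$chosen_or)
})

test_that("staircase matrices sort cells by chosen position and subset by lncRNA", {
  ga <- gen_annotation(seed = 22)
  ann <- ga$annotation
  arrays <- detect_tandem_arrays(ann)$arrays
  cnt <- gen_counts(ann, ga$truth, n_cells = 300, seed = 22)
  nm <- normalize_counts(filter_neurons(cnt$counts, ga$truth$markers))
  ch <- assign_chosen_or(nm, ann, arrays)
  arr <- arrays[1, ]
  sm <- staircase_matrix(arr, nm, ch, ann)
  expect_true(nrow(sm) > 0)
  ors <- ann[ann$gene_id %in% arr$or_ids[[1]], ]
  expect_equal(colnames(sm), ors$gene_id[order(ors$start)])
  # rows sorted by genomic position of the chosen OR
  row_chosen <- ch$chosen_or[match(rownames(sm), ch$cell_id)]
  pos <- ors$start[match(row_chosen, ors$gene_id)]
  expect_true(all(diff(pos) >= 0))
  # lncRNA-filtered subgroup is a subset of the rows
  lnc <- ga$truth$lnc$lncrna_id[1]
  smf <- staircase_matrix(arr, nm, ch, ann,
                          lnc_filter = list(gene_id = lnc, detectable = TRUE))
  expect_true(all(rownames(smf) %in% rownames(sm)))
  # empty selection warns and returns a 0-row matrix
  ch_none <- ch; ch_none$chosen_or <- NA_character_
  expect_warning(sm0 <- staircase_matrix(arr, nm, ch_none, ann), "no cells")
  expect_equal(nrow(sm0), 0)
})

test_that("flanking enrichment reports detection percentage and mean level", {
  nm <- sparse_counts(matrix(
    c(rep(1, 4), rep(0, 6),
      rep(2, 10)), 10, 2,
    dimnames = list(paste0("c", 1:10), c("fl1", "fl2"))))
  fe <- flanking_enrichment(list(A001 = paste0("c", 1:10)), c("fl1", "fl2"), nm)
  expect_equal(fe$pct_detected[fe$gene_id == "fl1"], 40)
  expect_equal(fe$mean_lognorm[fe$gene_id == "fl2"], 2)
  expect_warning(fe2 <- flanking_enrichment(list(A001 = "c1"), "absent", nm),
                 "absent")
  expect_equal(fe2$pct_detected, 0)
  fe3 <- flanking_enrichment(list(A001 = "c1"), c("fl1", "fl2"), nm)
  expect_true(all(fe3$pct_detected %in% c(0, 100)))
  # generator truth: enriched flanks detected more in their own array's cells
  ga <- gen_annotation(seed = 23)
  arrays <- detect_tandem_arrays(ga$annotation)$arrays
  cnt <- gen_counts(ga$annotation, ga$truth, n_cells = 400, seed = 23)
  nm2 <- normalize_counts(filter_neurons(cnt$counts, ga$truth$markers))
  ch <- assign_chosen_or(nm2, ga$annotation, arrays)
  groups <- split(ch$cell_id, ch$array_id)
  fl <- ga$truth$flanks
  fe4 <- flanking_enrichment(groups, fl$downstream_same, nm2)
  own <- fe4$pct_detected[mapply(function(a, g)
    fl$array_id[fl$downstream_same == g] == a, fe4$array_id, fe4$gene_id)]
  other <- fe4$pct_detected[mapply(function(a, g)
    fl$array_id[fl$downstream_same == g] != a, fe4$array_id, fe4$gene_id)]
  expect_gt(min(own), max(other))
})

test_that("lncRNA neighbor coexpression is restricted to expressing cells", {
  ga <- gen_annotation(seed = 24)
  ann <- ga$annotation
  arrays <- detect_tandem_arrays(ann)$arrays
  cnt <- gen_counts(ann, ga$truth, n_cells = 500, seed = 24)
  nm <- normalize_counts(filter_neurons(cnt$counts, ga$truth$markers))
  lnc <- ga$truth$lnc[1, ]
  cx <- lnc_neighbor_coexpression(lnc$lncrna_id, ann, arrays, nm)
  # distances match brute-force TSS subtraction
  l <- ann[ann$gene_id == lnc$lncrna_id, ]
  for (i in seq_len(nrow(cx))) {
    o <- ann[ann$gene_id == cx$or_id[i], ]
    expect_equal(unname(cx$tss_tss_distance[i]),
                 unname((o$start + 150) - l$end))
  }
  # asymmetric coupling: the upstream-adjacent OR of the promoter is
  # expressed above the downstream-of-chosen neighbors' own mean
  up_mean <- cx$mean_lognorm[cx$or_id == lnc$chosen_or]
  expect_gt(up_mean, 0)
  # a lncRNA with no expressing cells yields an empty result
  nm0 <- nm; nm0[, lnc$lncrna_id] <- 0
  cx0 <- lnc_neighbor_coexpression(lnc$lncrna_id, ann, arrays, nm0)
  expect_equal(nrow(cx0), 0)
})

test_that("lncRNA-OR correlations: exact toys and degenerate guards", {
  ann <- toy_ann(
    toy_coding_gene("orUp", 1000, 3000, biotype = "OR"),
    toy_gene("lncX", strand = "-", start = 3500, end = 4700,
             biotype = "lncRNA"),
    toy_coding_gene("orCh", 6950, 8950, biotype = "OR"),
    toy_coding_gene("orDn", 10000, 12000, biotype = "OR"))
  arrays <- tibble::tibble(array_id = "A001", chrom = "chr1",
                           majority_strand = "+", start = 1000, end = 12000,
                           n_or = 3L, or_ids = list(c("orUp", "orCh", "orDn")))
  vals <- matrix(0, 6, 4, dimnames = list(
    paste0("c", 1:6), c("orUp", "lncX", "orCh", "orDn")))
  vals[, "orCh"] <- 10                       # all cells choose orCh
  vals[, "lncX"] <- c(1, 2, 3, 4, 5, 6)
  vals[, "orUp"] <- c(6, 5, 4, 3, 2, 1)      # exactly anti-correlated
  vals[, "orDn"] <- c(2, 4, 6, 8, 10, 12)    # exactly correlated
  nm <- sparse_counts(vals)
  chosen <- tibble::tibble(cell_id = rownames(vals), chosen_or = "orCh",
                           chosen_value = 10, array_id = "A001",
                           tie_flag = FALSE)
  rec <- lnc_or_correlation(nm, chosen, ann, arrays)
  expect_equal(rec$pearson_r[rec$partner_role == "upstream_OR"], -1)
  expect_equal(rec$pearson_r[rec$partner_role == "downstream_OR"], 1)
  expect_equal(unique(rec$distance), 3500)   # chosen CDS TSS 7000 - 3500
  expect_equal(unique(rec$distance_bin), "(2500,5000]")
  # constant lncRNA vector: records skipped
  vals2 <- vals; vals2[, "lncX"] <- 3
  rec2 <- lnc_or_correlation(sparse_counts(vals2), chosen, ann, arrays)
  expect_equal(nrow(rec2), 0)
  # fewer than min_cells: skipped
  rec3 <- lnc_or_correlation(nm[1:2, ], chosen[1:2, ], ann, arrays)
  expect_equal(nrow(rec3), 0)
  # pooling collapses lncRNAs within a bin
  recp <- lnc_or_correlation(nm, chosen, ann, arrays, pooled = TRUE)
  expect_true(all(recp$lncrna_id == "pooled"))
})

test_that("per-lncRNA means and the t-test against zero match closed forms", {
  rec <- tibble::tibble(
    lncrna_id = c("l1", "l2"), partner_role = "upstream_OR",
    partner_gene = "x", n_cells = 10, pearson_r = c(-0.5, -0.3),
    p_value = 0.1, distance = 1000, distance_bin = "(0,2500]")
  pm <- per_lnc_mean_correlation(rec)
  expect_equal(pm$mean_r, -0.4)
  r5 <- c(-0.42, -0.13, -0.55, -0.08, -0.31)
  rec5 <- tibble::tibble(
    lncrna_id = paste0("l", 1:5), partner_role = "upstream_OR",
    partner_gene = "x", n_cells = 10, pearson_r = r5, p_value = 0.1,
    distance = 1000, distance_bin = "(0,2500]")
  pm5 <- per_lnc_mean_correlation(rec5)
  tt <- mean(r5) / (sd(r5) / sqrt(5))
  expect_equal(pm5$t_statistic, tt)
  expect_equal(pm5$p_value, 2 * stats::pt(-abs(tt), 4))
})

test_that("switch fraction is the XOR detection rate", {
  vals <- matrix(c(1, 0, 1, 0,
                   0, 1, 1, 0), 4, 2,
                 dimnames = list(paste0("c", 1:4), c("lnc", "orUp")))
  nm <- sparse_counts(vals)
  expect_equal(switch_fraction(paste0("c", 1:4), "lnc", "orUp", nm), 0.5)
  vals1 <- vals; vals1[, "lnc"] <- 1; vals1[, "orUp"] <- 0
  expect_equal(switch_fraction(paste0("c", 1:4), "lnc", "orUp",
                               sparse_counts(vals1)), 1)
  vals2 <- vals; vals2[, "lnc"] <- 1; vals2[, "orUp"] <- 1
  expect_equal(switch_fraction(paste0("c", 1:4), "lnc", "orUp",
                               sparse_counts(vals2)), 0)
  expect_error(switch_fraction(character(0), "lnc", "orUp", nm), "no cells")
})

test_that("MTX round-trip preserves the matrix", {
  ga <- gen_annotation(seed = 25, n_arrays = 2)
  cnt <- gen_counts(ga$annotation, ga$truth, n_cells = 20, seed = 25)
  d <- withr::local_tempdir()
  write_counts_mtx(cnt$counts, d)
  back <- read_counts(file.path(d, "matrix.mtx"), file.path(d, "genes.tsv"),
                      file.path(d, "barcodes.tsv"))
  expect_equal(as.matrix(back), as.matrix(cnt$counts))
})
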