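test_that("GFF3 round-trip preserves records and converts coordinates", {
  ann <- toy_ann(
    toy_coding_gene("geneA", 100, 1100, biotype = "OR"),
    toy_coding_gene("geneB", 5000, 6200),
    toy_gene("lncA", strand = "-", start = 800, end = 950, biotype = "lncRNA"))
  path <- withr::local_tempfile(fileext = ".gff3")
  write_annotation_gff3(ann, path)
  back <- read_annotation(path, biotype_rules = list(or_ids = "geneA"))
  expect_setequal(back$gene_id, ann$gene_id)
  i <- match("geneA", back$gene_id)
  expect_equal(back$start[i], 100)      # 1-based on disk, 0-based inside
  expect_equal(back$end[i], 1100)
  expect_equal(back$biotype[match(c("geneA", "geneB", "lncA"), back$gene_id)],
               c("OR", "other", "lncRNA"))
  expect_equal(back$cds[[i]], ann$cds[[match("geneA", ann$gene_id)]],
               ignore_attr = TRUE)
  # GFF start=101, end=200 becomes the half-open interval [100, 200)
  raw <- c("##gff-version 3",
           "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=g1")
  p2 <- withr::local_tempfile(fileext = ".gff3")
  writeLines(raw, p2)
  a2 <- read_annotation(p2)
  expect_equal(unname(c(a2$start, a2$end)), c(100, 200))
})

test_that("empty annotation file yields an empty annotation without error", {
  p <- withr::local_tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", p)
  ann <- read_annotation(p)
  expect_s3_class(ann, "genome_annotation")
  expect_equal(nrow(ann), 0)
})

test_that("anchor_tss is strand-aware and demands a CDS in first_cds mode", {
  gp <- toy_gene("g+", strand = "+", start = 900, end = 1600,
                 cds = matrix(c(1000, 1500), 1, 2))
  gm <- toy_gene("g-", strand = "-", start = 900, end = 1600,
                 cds = matrix(c(1000, 1500), 1, 2))
  ann <- toy_ann(gp, gm)
  expect_equal(anchor_tss(ann[1, ], "first_cds"), 1000)
  expect_equal(anchor_tss(ann[2, ], "first_cds"), 1500)
  expect_equal(anchor_tss(ann[1, ], "annotated"), 900)
  expect_equal(anchor_tss(ann[2, ], "annotated"), 1600)
  lnc <- toy_ann(toy_gene("lnc", strand = "+", start = 0, end = 500,
                          biotype = "lncRNA"))
  expect_error(anchor_tss(lnc[1, ], "first_cds"), "no CDS")
})

test_that("tandem arrays chain ORs by gap, strand-agnostically", {
  mk <- function(starts, strands = NULL) {
    if (is.null(strands)) strands <- rep("+", length(starts))
    toy_ann(dplyr::bind_rows(lapply(seq_along(starts), function(i)
      toy_coding_gene(sprintf("or%d", i), starts[i], starts[i] + 1000,
                      strand = strands[i], biotype = "OR"))))
  }
  # gaps 5 kb and 8 kb: one array of three
  r <- detect_tandem_arrays(mk(c(0, 6000, 15000)))
  expect_equal(nrow(r$arrays), 1)
  expect_equal(r$arrays$n_or, 3)
  expect_length(r$singletons, 0)
  # gaps 5 kb and 12 kb: an array of two plus a singleton
  r <- detect_tandem_arrays(mk(c(0, 6000, 19000)))
  expect_equal(r$arrays$n_or, 2)
  expect_equal(r$singletons, "or3")
  # inverted middle member stays in the array; majority strand of the four
  r <- detect_tandem_arrays(mk(seq(0, 4 * 5000, 5000),
                               c("+", "+", "-", "+", "+")))
  expect_equal(nrow(r$arrays), 1)
  expect_equal(r$arrays$n_or, 5)
  expect_equal(r$arrays$majority_strand, "+")
  # exact strand tie falls back to the first member's strand with a warning
  expect_warning(r <- detect_tandem_arrays(mk(c(0, 5000), c("-", "+"))),
                 "strand tie")
  expect_equal(r$arrays$majority_strand, "-")
})

test_that("array chaining matches the transitive-closure oracle", {
  for (seed in 1:20) {
    ann <- random_toy_ann(seed, n_genes = 20)
    got <- suppressWarnings(detect_tandem_arrays(ann))
    groups <- c(lapply(seq_len(nrow(got$arrays)),
                       function(i) sort(got$arrays$or_ids[[i]])),
                as.list(got$singletons))
    groups <- groups[order(vapply(groups, `[`, "", 1))]
    expect_identical(groups, oracle_chain_arrays(ann), label = paste("seed", seed))
  }
})

test_that("flanking genes are the nearest non-OR per side and strand class", {
  arr <- list(chrom = "chr1", majority_strand = "+", start = 10000, end = 20000)
  ann <- toy_ann(
    toy_coding_gene("or1", 10000, 20000, biotype = "OR"),
    toy_coding_gene("downSame", 22000, 23000, strand = "+"),
    toy_coding_gene("downOpp", 25000, 26000, strand = "-"),
    toy_coding_gene("upSame", 5000, 6000, strand = "+"),
    toy_coding_gene("farUpSame", 1000, 2000, strand = "+"))
  fl <- flanking_genes(arr, ann)
  expect_equal(fl$downstream_same, "downSame")
  expect_equal(fl$downstream_opposite, "downOpp")
  expect_equal(fl$upstream_same, "upSame")       # nearest of the two
  expect_true(is.na(fl$upstream_opposite))       # chromosome edge: absent
  # minus-strand array: the gene at lower coordinates is downstream
  arr$majority_strand <- "-"
  fl <- flanking_genes(arr, ann)
  expect_equal(fl$downstream_opposite, "upSame")
  expect_equal(fl$upstream_same, "downOpp")
  expect_equal(fl$upstream_opposite, "downSame")
})

test_that("flanking slots hold the nearest qualifying gene (exhaustive scan)", {
  for (seed in 21:30) {
    ann <- random_toy_ann(seed, n_genes = 15)
    arr <- list(chrom = "chr1", majority_strand = "+",
                start = 20000, end = 40000)
    fl <- flanking_genes(arr, ann)
    cand <- ann[ann$biotype != "OR", ]
    ora <- list(upstream_same = NA_character_, upstream_opposite = NA_character_,
                downstream_same = NA_character_, downstream_opposite = NA_character_)
    best <- list(Inf, Inf, Inf, Inf); names(best) <- names(ora)
    for (i in seq_len(nrow(cand))) {
      g <- cand[i, ]
      slot <- if (g$end <= arr$start) "upstream" else
        if (g$start >= arr$end) "downstream" else next
      slot <- paste0(slot, if (g$strand == "+") "_same" else "_opposite")
      d <- max(arr$start - g$end, g$start - arr$end)
      if (d < best[[slot]]) { best[[slot]] <- d; ora[[slot]] <- g$gene_id }
    }
    expect_equal(fl[names(ora)], ora, label = paste("seed", seed))
  }
})

test_that("gene-pair filters apply and sampling is seeded and order-invariant", {
  iso <- function(id, start, len, strand = "+", bt = "other")
    toy_coding_gene(id, start, start + len, strand = strand, biotype = bt)
  ann <- toy_ann(
    iso("a1", 0, 800), iso("a2", 2800, 900),            # retained pair
    iso("b1", 50000, 800), iso("b2", 63000, 900),       # 12 kb gap: excluded
    iso("c1", 100000, 800), iso("c2", 102800, 900),     # antisense overlap
    toy_gene("antic", strand = "-", start = 101000, end = 101200,
             biotype = "lncRNA"))
  pr <- suppressWarnings(sample_gene_pairs(ann, n_nonor = 5, seed = 1))
  expect_equal(pr$nonor_pairs$upstream, "a1")
  expect_equal(pr$nonor_pairs$downstream, "a2")
  # order invariance and seed reproducibility
  ann2 <- random_toy_ann(99, n_genes = 15)
  shuffled <- reorder_ann <- ann2[rev(seq_len(nrow(ann2))), ]
  shuffled <- genome_annotation(as.data.frame(shuffled), chrom_lengths(ann2))
  p1 <- suppressWarnings(sample_gene_pairs(ann2, n_nonor = 2, seed = 7))
  p2 <- suppressWarnings(sample_gene_pairs(shuffled, n_nonor = 2, seed = 7))
  expect_equal(p1$or_pairs$pair_id, p2$or_pairs$pair_id)
  expect_equal(p1$nonor_pairs$pair_id, p2$nonor_pairs$pair_id)
  p3 <- suppressWarnings(sample_gene_pairs(ann2, n_nonor = 2, seed = 7))
  expect_identical(p1$nonor_pairs$pair_id, p3$nonor_pairs$pair_id)
  # asking for more non-OR pairs than exist warns and returns all
  expect_warning(p4 <- sample_gene_pairs(ann2, n_nonor = 1000, seed = 1),
                 "returning all")
})

test_that("every returned pair satisfies all four filters", {
  for (seed in 31:40) {
    ann <- random_toy_ann(seed, n_genes = 15)
    pr <- suppressWarnings(sample_gene_pairs(ann, seed = seed))
    all_pairs <- dplyr::bind_rows(pr$or_pairs, pr$nonor_pairs)
    for (i in seq_len(nrow(all_pairs))) {
      p <- all_pairs[i, ]
      up <- ann[ann$gene_id == p$upstream, ]
      dn <- ann[ann$gene_id == p$downstream, ]
      expect_equal(up$strand, dn$strand)
      expect_gte(p$intergenic_len, 50)
      expect_lte(p$intergenic_len, 10000)
      for (g in list(up, dn)) {
        cl <- sum(g$cds[[1]][, 2] - g$cds[[1]][, 1])
        expect_gte(cl, 100); expect_lte(cl, 10000)
      }
      others <- ann[!(ann$gene_id %in% c(p$upstream, p$downstream)) &
                      ann$chrom == p$chrom, ]
      if (nrow(others) > 0) {
        expect_false(any(others$start < p$intergenic_end &
                           p$intergenic_start < others$end))
        for (g in list(up, dn))
          expect_false(any(others$start < g$end & g$start < others$end))
      }
    }
  }
})

test_that("antisense lncRNA overlap counts opposite-strand span sharing", {
  genes <- list(
    toy_coding_gene("or1", 0, 2000, biotype = "OR"),
    toy_gene("lnc1", strand = "-", start = 500, end = 700, biotype = "lncRNA"),
    toy_coding_gene("or2", 10000, 12000, biotype = "OR"),
    toy_gene("lncSame", strand = "+", start = 10500, end = 10700,
             biotype = "lncRNA"),
    toy_coding_gene("or3", 20000, 22000, biotype = "OR"),
    toy_coding_gene("or4", 30000, 32000, biotype = "OR"))
  others <- lapply(0:9, function(i)
    toy_coding_gene(sprintf("n%d", i), 50000 + i * 5000, 51000 + i * 5000))
  ann <- toy_ann(dplyr::bind_rows(c(genes, others)))
  ov <- antisense_lncrna_overlap(ann)
  expect_true(ov$per_gene$overlaps[ov$per_gene$gene_id == "or1"])
  expect_false(ov$per_gene$overlaps[ov$per_gene$gene_id == "or2"])  # same strand
  expect_equal(ov$frac_OR, 0.25)
  expect_equal(ov$frac_nonOR, 0)
})

test_that("nested lncRNAs get nearest-TSS OR neighbors within the array", {
  ga <- gen_annotation(seed = 17)
  ann <- ga$annotation
  arrays <- detect_tandem_arrays(ann)$arrays
  found <- dplyr::bind_rows(lapply(seq_len(nrow(arrays)), function(i)
    nested_lncrnas(arrays[i, ], ann)))
  expect_setequal(found$lncrna_id, ga$truth$lnc$lncrna_id)
  # brute-force nearest-TSS oracle
  for (i in seq_len(nrow(found))) {
    l <- ann[ann$gene_id == found$lncrna_id[i], ]
    ltss <- l$end                                 # "-" strand annotated TSS
    arr <- arrays[vapply(seq_len(nrow(arrays)), function(k)
      found$lncrna_id[i] %in% nested_lncrnas(arrays[k, ], ann)$lncrna_id,
      FALSE), ][1, ]
    ors <- ann[ann$gene_id %in% arr$or_ids[[1]], ]
    tss <- vapply(seq_len(nrow(ors)), function(k)
      anchor_tss(ors[k, ], if (nrow(ors$cds[[k]]) > 0) "first_cds" else "annotated"), 0)
    rel <- tss - ltss
    up <- ors$gene_id[rel < 0][which.min(abs(rel[rel < 0]))]
    dn <- ors$gene_id[rel >= 0][which.min(rel[rel >= 0])]
    expect_equal(found$upstream_or[i], up)
    expect_equal(found$downstream_or[i], dn)
    expect_equal(found$dist_upstream[i], min(abs(rel[rel < 0])))
    expect_equal(found$dist_downstream[i], min(rel[rel >= 0]))
  }
  # a lncRNA outside the array span is never returned
  far <- toy_gene("lncFar", chrom = "chrS", strand = "-",
                  start = chrom_lengths(ann)[["chrS"]] - 5000,
                  end = chrom_lengths(ann)[["chrS"]] - 4000,
                  biotype = "lncRNA")
  ann2 <- genome_annotation(rbind(as.data.frame(ann), as.data.frame(far)),
                            chrom_lengths(ann))
  expect_false("lncFar" %in% nested_lncrnas(arrays[1, ], ann2)$lncrna_id)
})
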