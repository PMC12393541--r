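# Toy-annotation builders and independent brute-force oracles used across
# the suite. Oracles are deliberately naive (double loops, per-base sums) so
# they stay independent of the vectorized implementation paths.

toy_gene <- function(id, chrom = "chr1", strand = "+", start, end,
                     biotype = "other", cds = NULL, exons = NULL,
                     pseudogene = FALSE) {
  ex <- if (is.null(exons)) matrix(c(start, end), 1, 2) else exons
  cd <- if (is.null(cds)) matrix(numeric(0), 0, 2) else cds
  tibble::tibble(gene_id = id, chrom = chrom, strand = strand,
                 start = start, end = end, exons = list(ex), cds = list(cd),
                 biotype = biotype, pseudogene = pseudogene)
}

toy_ann <- function(..., chrom_lengths = NULL) {
  genes <- dplyr::bind_rows(...)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(genes$end, genes$chrom, max) + 10000
    chrom_lengths <- stats::setNames(as.numeric(chrom_lengths), names(chrom_lengths))
  }
  genome_annotation(genes, chrom_lengths)
}

# genes with full-span exons and a CDS inset by `inset` (OR-style)
toy_coding_gene <- function(id, start, end, strand = "+", biotype = "other",
                            chrom = "chr1", inset = 50) {
  toy_gene(id, chrom, strand, start, end, biotype,
           cds = matrix(c(start + inset, end - inset), 1, 2))
}

# random toy annotation for property tests: a shuffled mix of coding genes,
# ORs and lncRNAs on two strands of one chromosome
random_toy_ann <- function(seed, n_genes = 15) {
  withr::with_seed(seed, {
    pos <- 1000
    rows <- list()
    for (i in seq_len(n_genes)) {
      len <- sample(c(80, 150, 400, 2000, 6000, 12000), 1)
      # occasional overlap with the previous gene
      if (i > 1 && runif(1) < 0.2) pos <- pos - sample(200:800, 1)
      bt <- sample(c("OR", "other", "lncRNA"), 1, prob = c(0.4, 0.45, 0.15))
      g <- if (bt == "lncRNA")
        toy_gene(sprintf("g%02d", i), strand = sample(c("+", "-"), 1),
                 start = pos, end = pos + len, biotype = bt)
      else
        toy_coding_gene(sprintf("g%02d", i), pos, pos + len,
                        strand = sample(c("+", "-"), 1), biotype = bt,
                        inset = min(25, len %/% 4))
      rows[[i]] <- g
      pos <- pos + len + sample(c(30, 100, 2000, 8000, 15000), 1)
    }
    toy_ann(dplyr::bind_rows(rows))
  })
}

# brute-force transitive-closure chaining of ORs into arrays
oracle_chain_arrays <- function(ann, max_gap = 10000) {
  ors <- ann[ann$biotype == "OR", ]
  out <- list()
  for (ch in sort(unique(ors$chrom))) {
    g <- ors[ors$chrom == ch, ]
    g <- g[order(g$start, g$gene_id), ]
    n <- nrow(g)
    if (n == 0) next
    linked <- matrix(FALSE, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      gap <- max(g$start[j] - g$end[i], g$start[i] - g$end[j])
      linked[i, j] <- gap <= max_gap
    }
    # transitive closure
    repeat {
      nxt <- linked | (linked %*% linked > 0)
      if (identical(nxt, linked)) break
      linked <- nxt
    }
    seen <- rep(FALSE, n)
    for (i in seq_len(n)) {
      if (seen[i]) next
      members <- which(linked[i, ])
      seen[members] <- TRUE
      out[[length(out) + 1]] <- sort(g$gene_id[members])
    }
  }
  out[order(vapply(out, `[`, "", 1))]
}

# exhaustive O(n^2) gene-pair enumeration with all four filters
oracle_gene_pairs <- function(ann, cds_len_bounds = c(100, 10000),
                              intergenic_bounds = c(50, 10000)) {
  res <- list()
  for (i in seq_len(nrow(ann))) for (j in seq_len(nrow(ann))) {
    if (i == j) next
    a <- ann[i, ]; b <- ann[j, ]
    if (a$chrom != b$chrom || a$strand != b$strand) next
    if (a$start >= b$start) next             # consider each ordered pair once
    gap_start <- a$end; gap_end <- b$start
    len <- gap_end - gap_start
    if (len < intergenic_bounds[1] || len > intergenic_bounds[2]) next
    cl <- function(g) sum(g$cds[[1]][, 2] - g$cds[[1]][, 1])
    if (cl(a) < cds_len_bounds[1] || cl(a) > cds_len_bounds[2]) next
    if (cl(b) < cds_len_bounds[1] || cl(b) > cds_len_bounds[2]) next
    clash <- FALSE
    for (k in seq_len(nrow(ann))) {
      if (k %in% c(i, j)) next
      o <- ann[k, ]
      if (o$chrom != a$chrom) next
      if (o$start < a$end && a$start < o$end) clash <- TRUE
      if (o$start < b$end && b$start < o$end) clash <- TRUE
      if (o$start < gap_end && gap_start < o$end) clash <- TRUE
    }
    if (clash) next
    both_or <- a$biotype == "OR" && b$biotype == "OR"
    neither <- a$biotype != "OR" && b$biotype != "OR"
    if (!both_or && !neither) next
    up <- if (a$strand == "+") a$gene_id else b$gene_id
    dn <- if (a$strand == "+") b$gene_id else a$gene_id
    res[[length(res) + 1]] <- data.frame(
      upstream = up, downstream = dn,
      pair_class = if (both_or) "OR" else "nonOR")
  }
  if (length(res) == 0)
    return(data.frame(upstream = character(0), downstream = character(0),
                      pair_class = character(0)))
  df <- do.call(rbind, res)
  df[order(df$upstream, df$downstream), , drop = FALSE]
}

# per-pixel Euclidean-disk dilation oracle
oracle_dilate <- function(mask, r) {
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  fg <- which(mask, arr.ind = TRUE)
  for (y in seq_len(nrow(mask))) for (x in seq_len(ncol(mask))) {
    d2 <- (fg[, 1] - y)^2 + (fg[, 2] - x)^2
    if (any(d2 <= r^2)) out[y, x] <- TRUE
  }
  out
}

# small helper: build a uniform image_stack with the given per-channel value
uniform_stack <- function(ny = 32, nx = 32, nz = 2, vals = c(10, 5)) {
  data <- array(0, c(ny, nx, nz, length(vals)))
  for (ch in seq_along(vals)) data[, , , ch] <- vals[ch]
  image_stack(data, dapi_channel = 1)
}
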