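#' Default run configuration
#'
#' All tunable parameters of every stage with their default values
#' (analysis thresholds use the quantification defaults; generator
#' parameters define the emulated study conditions). The list is plain data
#' and serializes to YAML/JSON.
#'
#' @param seed integer seed used for every stochastic stage
#' @param out_dir output directory for [run_workflow()]
#' @return nested named list
#' @export
default_config <- function(seed = 1L, out_dir = "results") {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    annotation = list(n_arrays = 4, array_size_range = c(5, 8),
                      gene_len = 2000, gap_range = c(1000, 3000),
                      inversion_rate = 0, lnc_per_array = 2,
                      n_nonor_pairs = 60),
    pairs = list(cds_len_bounds = c(100, 10000),
                 intergenic_bounds = c(50, 10000), max_gap = 10000),
    coverage = list(promoter_rate_range = c(10, 30), readthrough_decay = 0.3,
                    antisense_fraction = 0.5, downstream_rate_frac = 0.5),
    tss = list(window_bp = 1000, min_reads = 1, sense_offset = 200,
               antisense_offset = 500, offset_sd = 30, reads_per_gene = 20,
               bidir_fraction = 0.34),
    sc = list(target_sum = 10000, min_markers = 2, min_umi = 2,
              n_cells = 1000, chosen_mean = 100, downstream_decay = 1.5,
              lnc_mean = 30, lnc_coupling = 1.5, leak_mean = 20,
              nb_dispersion = 4, bins = c(2500, 5000, 10000), min_cells = 3),
    fish = list(sigma = 100, min_area = 12, dilate_px = 3, mask_mode = "zeroed",
                q_low = 0.001, q_high = 0.999,
                chosen = list(nuc = 0.75, cyto = 0.2, nuc_area = c(400, 900),
                              cyto_area = 100, ecc = 0.8),
                localization = list(nuc = 0.1, cyto = 0.2),
                stack = list(shape = c(256, 256), n_slices = 4,
                             class_mix = c(chosen = 3, nuclear = 3,
                                           negative = 3),
                             dapi_attenuation = 0.85))
  )
}

validate_config <- function(cfg) {
  num_keys <- list(c("seed"), c("pairs", "max_gap"),
                   c("coverage", "readthrough_decay"),
                   c("coverage", "antisense_fraction"),
                   c("tss", "window_bp"), c("tss", "bidir_fraction"),
                   c("sc", "target_sum"), c("sc", "n_cells"),
                   c("fish", "sigma"), c("fish", "min_area"))
  for (k in num_keys) {
    v <- cfg[[k]]
    if (is.null(v) || !is.numeric(v) || any(is.na(v)))
      stopf("config key '%s' must be numeric", paste(k, collapse = "$"))
  }
  if (!is.character(cfg$out_dir)) stopf("config key 'out_dir' must be a path")
  invisible(cfg)
}

write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  df <- df[, !vapply(df, is.list, TRUE), drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# common synthetic substrate shared by the sequencing workflows
build_genome <- function(cfg) {
  ga <- do.call(gen_annotation, c(list(seed = cfg$seed), cfg$annotation))
  pairs <- sample_gene_pairs(ga$annotation,
                             cds_len_bounds = cfg$pairs$cds_len_bounds,
                             intergenic_bounds = cfg$pairs$intergenic_bounds,
                             seed = cfg$seed)
  arrays <- detect_tandem_arrays(ga$annotation, max_gap = cfg$pairs$max_gap)
  list(ann = ga$annotation, truth = ga$truth, pairs = pairs,
       arrays = arrays$arrays, singletons = arrays$singletons)
}

#' Run a named end-to-end workflow on synthetic data
#'
#' Workflows: `readthrough` (intergenic relative coverage, OR vs non-OR),
#' `antisense` (antisense relative coverage and fraction recovery), `tss`
#' (promoter bidirectionality and sense/antisense peak offsets), `staircase`
#' (chosen-OR assignment recovery and staircase matrices),
#' `lnc_correlation` (lncRNA-OR correlation by promoter distance, per-lncRNA
#' means, switch fraction), `fish` (full imaging pipeline with class
#' recovery), or `demo` (all of the above). Result tables are written to
#' `cfg$out_dir` as TSV plus a JSON summary; the resolved configuration and
#' its hash are written next to them, and every run with the same config is
#' identical.
#'
#' @param name workflow name
#' @param cfg configuration from [default_config()]
#' @return (invisibly) list of summary values
#' @export
run_workflow <- function(name = c("readthrough", "antisense", "tss",
                                  "staircase", "lnc_correlation", "fish",
                                  "demo"),
                         cfg = default_config()) {
  name <- match.arg(name)
  validate_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- rlang::hash(cfg)
  yaml::write_yaml(c(cfg, list(config_hash = cfg_hash)),
                   file.path(cfg$out_dir, "config.yaml"))
  t0 <- Sys.time()
  out <- switch(name,
    readthrough = wf_readthrough(cfg),
    antisense = wf_antisense(cfg),
    tss = wf_tss(cfg),
    staircase = wf_staircase(cfg),
    lnc_correlation = wf_lnc_correlation(cfg),
    fish = wf_fish(cfg),
    demo = {
      res <- list()
      for (wf in c("readthrough", "antisense", "tss", "staircase",
                   "lnc_correlation", "fish"))
        res[[wf]] <- run_workflow(wf, cfg)
      res
    })
  out$config_hash <- cfg_hash
  out$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(out, file.path(cfg$out_dir,
                                      sprintf("summary_%s.json", name)),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}

wf_readthrough <- function(cfg) {
  g <- build_genome(cfg)
  cov <- do.call(gen_coverage,
                 c(list(ann = g$ann, or_pairs = g$pairs$or_pairs,
                        nonor_pairs = g$pairs$nonor_pairs, seed = cfg$seed),
                   cfg$coverage))
  or_rc <- pairs_relative_coverage(g$pairs$or_pairs, cov$track, g$ann, "sense")
  no_rc <- pairs_relative_coverage(g$pairs$nonor_pairs, cov$track, g$ann, "sense")
  stats <- compare_groups(or_rc, no_rc, features = "intergenic")
  write_tsv(dplyr::bind_rows(or_rc, no_rc),
            file.path(cfg$out_dir, "readthrough_relative_coverage.tsv"))
  write_tsv(stats, file.path(cfg$out_dir, "readthrough_tests.tsv"))
  ig <- function(df) df$rel_cov[df$feature == "intergenic" & df$defined]
  list(n_or_pairs = nrow(g$pairs$or_pairs),
       n_nonor_pairs = nrow(g$pairs$nonor_pairs),
       median_intergenic_relcov_or = median(ig(or_rc)),
       median_intergenic_relcov_nonor = median(ig(no_rc)),
       p_intergenic = stats$p_raw[stats$feature == "intergenic"])
}

wf_antisense <- function(cfg) {
  g <- build_genome(cfg)
  cov <- do.call(gen_coverage,
                 c(list(ann = g$ann, or_pairs = g$pairs$or_pairs,
                        nonor_pairs = g$pairs$nonor_pairs, seed = cfg$seed),
                   cfg$coverage))
  or_rc <- pairs_relative_coverage(g$pairs$or_pairs, cov$track, g$ann)
  no_rc <- pairs_relative_coverage(g$pairs$nonor_pairs, cov$track, g$ann)
  stats <- compare_groups(or_rc, no_rc, orientation = "antisense")
  write_tsv(dplyr::bind_rows(or_rc, no_rc),
            file.path(cfg$out_dir, "antisense_relative_coverage.tsv"))
  write_tsv(stats, file.path(cfg$out_dir, "antisense_tests.tsv"))
  ov <- antisense_lncrna_overlap(g$ann)
  sel <- function(df, f) df$rel_cov[df$feature == f &
                                      df$orientation == "antisense" & df$defined]
  list(median_antisense_exon_relcov_or = median(sel(or_rc, "upstream_exons")),
       median_antisense_exon_relcov_nonor = median(sel(no_rc, "upstream_exons")),
       antisense_fraction_truth = cfg$coverage$antisense_fraction,
       frac_or_with_antisense_lncrna = ov$frac_OR,
       frac_nonor_with_antisense_lncrna = ov$frac_nonOR)
}

wf_tss <- function(cfg) {
  g <- build_genome(cfg)
  gene_ids <- unique(c(g$pairs$nonor_pairs$upstream,
                       g$pairs$nonor_pairs$downstream))
  ts <- do.call(gen_tss, c(list(ann = g$ann, gene_ids = gene_ids,
                                seed = cfg$seed),
                           cfg$tss[c("sense_offset", "antisense_offset",
                                     "offset_sd", "reads_per_gene",
                                     "bidir_fraction")]))
  res <- window_assign(ts$track, g$ann, gene_ids,
                       window_bp = cfg$tss$window_bp,
                       min_reads = cfg$tss$min_reads)
  med <- peak_offset_medians(res)
  write_tsv(res[, c("gene_id", "strand", "anchor", "sense_count",
                    "antisense_count", "bidirectional", "truncated")],
            file.path(cfg$out_dir, "tss_windows.tsv"))
  list(n_genes = nrow(res),
       bidirectional_fraction = bidirectional_fraction(res),
       bidirectional_fraction_truth = mean(ts$truth$bidirectional),
       sense_median_offset = unname(med["sense"]),
       antisense_median_offset = unname(med["antisense"]),
       offset_difference = unname(med["antisense"] - med["sense"]))
}

sc_pipeline <- function(cfg, g, counts) {
  filt <- filter_neurons(counts$counts, g$truth$markers,
                         min_markers = cfg$sc$min_markers,
                         min_umi = cfg$sc$min_umi)
  nm <- normalize_counts(filt, target_sum = cfg$sc$target_sum)
  chosen <- assign_chosen_or(nm, g$ann, g$arrays)
  list(filt = filt, nm = nm, chosen = chosen)
}

wf_staircase <- function(cfg) {
  g <- build_genome(cfg)
  counts <- do.call(gen_counts,
                    c(list(ann = g$ann, truth = g$truth, seed = cfg$seed),
                      cfg$sc[c("n_cells", "chosen_mean", "downstream_decay",
                               "lnc_mean", "lnc_coupling", "leak_mean",
                               "nb_dispersion")]))
  sc <- sc_pipeline(cfg, g, counts)
  truth <- counts$truth[match(sc$chosen$cell_id, counts$truth$cell_id), ]
  recovery <- mean(sc$chosen$chosen_or == truth$chosen_or, na.rm = TRUE)
  arr1 <- g$arrays[1, ]
  sm <- staircase_matrix(arr1, sc$nm, sc$chosen, g$ann)
  write_tsv(sc$chosen, file.path(cfg$out_dir, "chosen_or.tsv"))
  utils::write.table(round(sm, 4),
                     file.path(cfg$out_dir, "staircase_matrix.tsv"),
                     sep = "\t", quote = FALSE)
  list(n_cells = nrow(sc$nm),
       chosen_recovery = recovery,
       staircase_cells = nrow(sm), staircase_ors = ncol(sm))
}

wf_lnc_correlation <- function(cfg) {
  g <- build_genome(cfg)
  counts <- do.call(gen_counts,
                    c(list(ann = g$ann, truth = g$truth, seed = cfg$seed),
                      cfg$sc[c("n_cells", "chosen_mean", "downstream_decay",
                               "lnc_mean", "lnc_coupling", "leak_mean",
                               "nb_dispersion")]))
  sc <- sc_pipeline(cfg, g, counts)
  rec <- lnc_or_correlation(sc$nm, sc$chosen, g$ann, g$arrays,
                            bins = cfg$sc$bins, min_cells = cfg$sc$min_cells)
  means <- per_lnc_mean_correlation(rec)
  write_tsv(rec, file.path(cfg$out_dir, "lnc_or_correlation.tsv"))
  write_tsv(means, file.path(cfg$out_dir, "lnc_mean_correlation.tsv"))
  # switch fraction in the closest-distance bin, pooled over its lncRNAs
  ctx <- lnc_context(g$ann, g$arrays)
  near <- ctx[ctx$distance <= cfg$sc$bins[1], ]
  sw <- NA_real_
  if (nrow(near) > 0) {
    fr <- vapply(seq_len(nrow(near)), function(i) {
      cells <- sc$chosen$cell_id[!is.na(sc$chosen$chosen_or) &
                                   sc$chosen$chosen_or == near$chosen_or[i]]
      if (length(cells) == 0) return(NA_real_)
      switch_fraction(cells, near$lncrna_id[i], near$upstream_or[i], sc$nm)
    }, 0)
    sw <- mean(fr, na.rm = TRUE)
  }
  getr <- function(role) {
    v <- means$mean_r[means$partner_role == role]
    if (length(v) == 0) NA_real_ else v
  }
  list(n_lncrnas = length(unique(rec$lncrna_id)),
       mean_r_upstream = getr("upstream_OR"),
       mean_r_chosen = getr("chosen_OR"),
       mean_r_downstream = getr("downstream_OR"),
       switch_fraction = sw)
}

wf_fish <- function(cfg) {
  st <- gen_stack(seed = cfg$seed, shape = cfg$fish$stack$shape,
                  n_slices = cfg$fish$stack$n_slices,
                  class_mix = cfg$fish$stack$class_mix,
                  dapi_attenuation = cfg$fish$stack$dapi_attenuation)
  rec <- fish_pipeline(st$stack, st$labels, sigma = cfg$fish$sigma,
                       min_area = cfg$fish$min_area,
                       mask_mode = cfg$fish$mask_mode,
                       dilate_px = cfg$fish$dilate_px,
                       q_low = cfg$fish$q_low, q_high = cfg$fish$q_high,
                       chosen_thresholds = cfg$fish$chosen)
  truth <- st$truth
  key <- paste(rec$slice, rec$label)
  tclass <- truth$class[match(key, paste(truth$slice, truth$label))]
  pred <- ifelse(rec$chosen_2, "chosen",
                 ifelse(rec$localization_2 == "none", "negative", "nuclear"))
  acc <- mean(pred == tclass)
  rec$true_class <- tclass
  rec$predicted_class <- pred
  write_tsv(rec, file.path(cfg$out_dir, "fish_roi_records.tsv"))
  list(n_rois = nrow(rec), class_accuracy = acc)
}
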