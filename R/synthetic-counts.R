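#' Generate a synthetic cells-by-genes UMI count matrix
#'
#' Each cell draws one chosen promoter: a tandem array (uniform) and then an
#' OR position within it (uniform). A per-cell activity factor
#' s ~ Gamma(shape = `nb_dispersion`, mean 1) scales the whole transcription
#' cascade of that promoter, giving negative-binomial marginals:
#'
#' * chosen OR ~ Poisson(`chosen_mean` * s)
#' * OR at rank r downstream of the chosen (transcription direction)
#'   ~ Poisson(`chosen_mean` * exp(-`downstream_decay` * r) * s), the
#'   staircase signature of transcriptional readthrough
#' * the lncRNA paired with the chosen promoter
#'   ~ Poisson(`lnc_mean` * s) (co-produced by the bidirectional promoter)
#' * leakage of the OR immediately upstream of that lncRNA
#'   ~ Poisson(`leak_mean` * exp(-`lnc_coupling` * l / `lnc_mean`)) where l
#'   is the cell's lncRNA count: antisense transcription suppresses the
#'   upstream OR (rate suppression, exponential in the lncRNA value),
#'   approaching a switch-like XOR detection regime as the coupling grows;
#'   the leak is deliberately independent of s so that at coupling 0 the
#'   lncRNA and the upstream OR are uncorrelated
#'
#' Housekeeping genes are drawn at `hk_mean` each so the OR cascade is a
#' small fraction of the library (avoiding compositional artifacts of
#' target-sum normalization); marker genes are drawn at `marker_mean` so
#' neuron filtering keeps every cell; array flank genes marked in the truth
#' as enriched
#' (downstream-same, upstream-opposite) are expressed in their array's
#' cells; all other genes get Poisson(`background_rate`) background. OR
#' genes outside the cell's staircase get no background so chosen-OR
#' recovery is identifiable.
#'
#' @param ann a [genome_annotation()]
#' @param truth truth list from [gen_annotation()]
#' @param n_cells number of cells (default 1000)
#' @param chosen_mean mean UMI of the chosen OR (default 100)
#' @param downstream_decay per-rank decay of the staircase (default 1.5);
#'   `Inf` silences all downstream ORs
#' @param lnc_mean mean UMI of the active promoter's lncRNA (default 30)
#' @param lnc_coupling suppression strength of the upstream OR by lncRNA
#'   expression (default 1.5; 0 = no coupling)
#' @param leak_mean baseline leaky expression of the OR upstream of an
#'   active lncRNA promoter (default 20)
#' @param nb_dispersion Gamma shape of the per-cell activity factor
#'   (default 4; larger = less overdispersion)
#' @param marker_mean mean UMI of neuron markers (default 10)
#' @param hk_mean mean UMI per housekeeping gene (default 200)
#' @param background_rate Poisson mean for untargeted non-OR genes
#'   (default 0.2)
#' @param flank_mean mean UMI of enriched flank genes in their array's cells
#'   (default 3)
#' @param seed integer seed
#' @return list(counts = sparse cells x genes matrix, truth = tibble
#'   cell_id, array_id, chosen_or)
#' @export
gen_counts <- function(ann, truth, n_cells = 1000, chosen_mean = 100,
                       downstream_decay = 1.5, lnc_mean = 30,
                       lnc_coupling = 1.5, leak_mean = 20,
                       nb_dispersion = 4, marker_mean = 10, hk_mean = 200,
                       background_rate = 0.2, flank_mean = 3, seed = 1L) {
  withr::local_seed(seed)
  genes <- ann$gene_id
  arrays <- truth$arrays
  m <- matrix(0, n_cells, length(genes), dimnames =
                list(sprintf("cell%04d", seq_len(n_cells)), genes))
  arr_pick <- sample(nrow(arrays), n_cells, replace = TRUE)
  chosen_or <- character(n_cells)
  s <- rgamma(n_cells, shape = nb_dispersion, rate = nb_dispersion)
  lnc_by_chosen <- if (!is.null(truth$lnc))
    split(truth$lnc, truth$lnc$chosen_or) else list()
  flank_by_array <- if (!is.null(truth$flanks))
    split(truth$flanks, truth$flanks$array_id) else list()
  for (i in seq_len(n_cells)) {
    arr <- arrays[arr_pick[i], ]
    ids <- arr$or_ids[[1]]                      # transcription order
    k <- sample(length(ids), 1)
    chosen_or[i] <- ids[k]
    m[i, ids[k]] <- rpois(1, chosen_mean * s[i])
    if (is.finite(downstream_decay)) {
      dn <- ids[seq_len(length(ids)) > k]
      if (length(dn) > 0) {
        r <- seq_along(dn)
        m[i, dn] <- rpois(length(dn), chosen_mean * exp(-downstream_decay * r) * s[i])
      }
    }
    lnc <- lnc_by_chosen[[chosen_or[i]]]
    if (!is.null(lnc) && nrow(lnc) > 0) {
      l <- rpois(1, lnc_mean * s[i])
      m[i, lnc$lncrna_id[1]] <- l
      m[i, lnc$upstream_or[1]] <-
        rpois(1, leak_mean * exp(-lnc_coupling * l / lnc_mean))
    }
    fl <- flank_by_array[[arr$array_id]]
    if (!is.null(fl) && nrow(fl) > 0) {
      m[i, fl$downstream_same[1]] <- rpois(1, flank_mean * s[i])
      m[i, fl$upstream_opposite[1]] <- rpois(1, flank_mean * s[i])
    }
  }
  for (mk in truth$markers) m[, mk] <- rpois(n_cells, marker_mean)
  hk <- truth$housekeeping
  if (!is.null(hk) && length(hk) > 0)
    m[, hk] <- matrix(rpois(n_cells * length(hk), hk_mean),
                      n_cells, length(hk))
  background <- setdiff(genes[ann$biotype == "other"],
                        c(truth$markers, truth$housekeeping))
  if (length(background) > 0 && background_rate > 0)
    m[, background] <- m[, background] +
      matrix(rpois(n_cells * length(background), background_rate),
             n_cells, length(background))
  list(counts = methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix"),
       truth = tibble::tibble(cell_id = rownames(m),
                              array_id = arrays$array_id[arr_pick],
                              chosen_or = chosen_or),
       params = list(n_cells = n_cells, chosen_mean = chosen_mean,
                     downstream_decay = downstream_decay,
                     lnc_mean = lnc_mean, lnc_coupling = lnc_coupling,
                     leak_mean = leak_mean, nb_dispersion = nb_dispersion,
                     seed = seed))
}
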