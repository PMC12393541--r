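#' Generate synthetic stranded coverage with readthrough and antisense signal
#'
#' Emulates the coverage signatures around gene pairs: each pair's upstream
#' gene is transcribed at a promoter rate (uniform depth over its span); for
#' readthrough pairs (by default the OR pairs) the sense-strand depth
#' continues past the upstream gene's 3' end, decaying exponentially at
#' `readthrough_decay` per kb through the intergenic span and the downstream
#' gene; the downstream gene additionally has its own promoter rate.
#' Antisense depth over readthrough pairs is `antisense_fraction` times the
#' upstream promoter rate, uniform across the pair locus; non-readthrough
#' pairs get no antisense signal. Depth is drawn per base as
#' Poisson(expected) unless `noise = "none"`.
#'
#' @param ann a [genome_annotation()]
#' @param or_pairs,nonor_pairs pair tibbles from [sample_gene_pairs()]
#' @param promoter_rate_range uniform range of promoter rates, reads/nt
#'   (default c(10, 30))
#' @param readthrough_decay decay rate per kb (default 0.3)
#' @param antisense_fraction antisense depth as a fraction of the upstream
#'   promoter rate over readthrough pairs (default 0.5)
#' @param downstream_rate_frac downstream gene's own promoter rate as a
#'   fraction of the upstream rate (default 0.5)
#' @param noise "poisson" or "none"
#' @param seed integer seed
#' @return list(track = `coverage_track`, truth = tibble of per-pair rates
#'   and expected intergenic relative coverage)
#' @export
gen_coverage <- function(ann, or_pairs, nonor_pairs,
                         promoter_rate_range = c(10, 30),
                         readthrough_decay = 0.3, antisense_fraction = 0.5,
                         downstream_rate_frac = 0.5,
                         noise = c("poisson", "none"), seed = 1L) {
  noise <- match.arg(noise)
  withr::local_seed(seed)
  expected <- coverage_track(chrom_lengths(ann))
  pairs <- dplyr::bind_rows(or_pairs, nonor_pairs)
  rates <- runif(nrow(pairs), promoter_rate_range[1], promoter_rate_range[2])
  truth_rows <- list()
  for (ch in unique(pairs$chrom)) {
    # accumulate into local strand vectors (in-place) and write back once
    plus <- expected[[ch]][["+"]]; minus <- expected[[ch]][["-"]]
    idx_ch <- which(pairs$chrom == ch)
    for (i in idx_ch) {
      p <- pairs[i, ]
      up <- ann[ann$gene_id == p$upstream, ]
      dn <- ann[ann$gene_id == p$downstream, ]
      rate <- rates[i]
      readthrough <- p$pair_class == "OR"
      sense <- p$strand; anti <- other_strand(p$strand)
      add <- function(strand, from, to, depth) {
        # depth: scalar or vector over the half-open interval [from, to)
        if (to <= from) return()
        idx <- (from + 1):to
        if (strand == "+") plus[idx] <<- plus[idx] + depth
        else minus[idx] <<- minus[idx] + depth
      }
      add(sense, up$start, up$end, rate)
      add(sense, dn$start, dn$end, rate * downstream_rate_frac)
      # readthrough: exponential decay of the upstream promoter's signal
      # past the upstream 3' end, through the intergenic span and the
      # downstream gene
      if (readthrough) {
        lam <- readthrough_decay / 1000
        if (p$strand == "+") {
          d <- seq(0, dn$end - up$end - 1)       # bp past the upstream 3' end
          add(sense, up$end, dn$end, rate * exp(-lam * d))
        } else {
          b <- (dn$start + 1):up$start           # 1-based bases, ascending
          d <- up$start - b
          add(sense, dn$start, up$start, rate * exp(-lam * d))
        }
        add(anti, min(up$start, dn$start), max(up$end, dn$end),
            antisense_fraction * rate)
        ig_len <- p$intergenic_len
        exp_relcov <- (1 - exp(-lam * ig_len)) / (lam * ig_len)
      } else {
        exp_relcov <- 0
      }
      truth_rows[[i]] <- tibble::tibble(
        pair_id = p$pair_id, pair_class = p$pair_class, rate = rate,
        readthrough = readthrough, expected_intergenic_relcov = exp_relcov)
    }
    expected[[ch]][["+"]] <- plus; expected[[ch]][["-"]] <- minus
  }
  track <- expected
  if (noise == "poisson") {
    for (ch in names(track)) for (st in c("+", "-")) {
      v <- expected[[ch]][[st]]
      nz <- which(v > 0)
      track[[ch]][[st]][nz] <- rpois(length(nz), v[nz])
    }
  }
  list(track = track,
       truth = dplyr::bind_rows(truth_rows),
       params = list(readthrough_decay = readthrough_decay,
                     antisense_fraction = antisense_fraction, seed = seed))
}
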