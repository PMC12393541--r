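#' Multi-channel confocal z-stack container
#'
#' @param data numeric array indexed (y, x, z, channel), non-negative
#' @param dapi_channel index of the DAPI channel
#' @param pixel_size_um pixel size in micrometers (default 0.09)
#' @param z_step_um z step in micrometers (default 1)
#' @param channel_names optional channel names
#' @return an `image_stack`
#' @export
image_stack <- function(data, dapi_channel = 1, pixel_size_um = 0.09,
                        z_step_um = 1, channel_names = NULL) {
  stopifnot(length(dim(data)) == 4)
  if (dim(data)[4] < 2) stopf("an image stack needs at least 2 channels")
  if (any(data < 0)) stopf("intensities must be non-negative")
  structure(list(data = data, dapi_channel = dapi_channel,
                 pixel_size_um = pixel_size_um, z_step_um = z_step_um,
                 channel_names = channel_names %||%
                   paste0("ch", seq_len(dim(data)[4]))),
            class = "image_stack")
}

n_slices <- function(stack) dim(stack$data)[3]
n_channels <- function(stack) dim(stack$data)[4]

#' Depth-correct a stack using DAPI as reference
#'
#' Each non-DAPI channel slice is multiplied by the ratio of the maximum
#' per-slice mean DAPI intensity across the stack to the mean DAPI intensity
#' of that slice; the DAPI channel is left unchanged.
#'
#' @param stack an [image_stack()]
#' @return corrected `image_stack` with attribute `depth_scalars`
#' @export
depth_correct <- function(stack) {
  dapi_means <- vapply(seq_len(n_slices(stack)), function(z)
    mean(stack$data[, , z, stack$dapi_channel]), 0)
  if (any(dapi_means <= 0))
    stopf("zero-mean DAPI on slice %s; cannot depth-correct",
          paste(which(dapi_means <= 0), collapse = ", "))
  scalars <- max(dapi_means) / dapi_means
  out <- stack
  for (z in seq_len(n_slices(stack)))
    for (ch in setdiff(seq_len(n_channels(stack)), stack$dapi_channel))
      out$data[, , z, ch] <- stack$data[, , z, ch] * scalars[z]
  attr(out, "depth_scalars") <- scalars
  out
}

#' Triangle threshold of an image
#'
#' Geometric triangle algorithm on a 256-bin histogram: a line is drawn from
#' the histogram peak to the far end of the longer tail, and the threshold
#' is the bin maximizing the distance between the line and the histogram.
#'
#' @param x numeric matrix or vector
#' @param nbins number of histogram bins (default 256)
#' @return threshold on the intensity scale of `x`
#' @export
triangle_threshold <- function(x, nbins = 256) {
  v <- as.numeric(x)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(hi)
  h <- tabulate(pmin(nbins, floor((v - lo) / (hi - lo) * nbins) + 1L), nbins)
  centers <- lo + (seq_len(nbins) - 0.5) * (hi - lo) / nbins
  nz <- which(h > 0)
  arg_low <- nz[1]; arg_high <- nz[length(nz)]
  arg_peak <- which.max(h)
  peak_height <- h[arg_peak]
  # orient the histogram so the long tail is on the left of the peak
  flip <- (arg_peak - arg_low) < (arg_high - arg_peak)
  if (flip) {
    h <- rev(h)
    arg_low <- nbins - arg_high + 1L
    arg_peak <- nbins - arg_peak + 1L
  }
  width <- arg_peak - arg_low
  if (width <= 0) {
    idx <- if (flip) nbins - arg_peak + 1L else arg_peak
    return(centers[idx])
  }
  x1 <- 0:(width - 1)
  y1 <- h[arg_low + x1]
  distances <- peak_height * x1 - width * y1
  idx <- arg_low + (which.max(distances) - 1L)
  if (flip) idx <- nbins - idx + 1L
  centers[idx]
}

# 8-connected labeling of a logical matrix via graph components
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  fg <- which(mask)
  if (length(fg) == 0) return(lab)
  id <- integer(length(mask)); id[fg] <- seq_along(fg)
  nr <- nrow(mask); nc <- ncol(mask)
  row <- (fg - 1L) %% nr + 1L
  col <- (fg - 1L) %/% nr + 1L
  edges <- list()
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- row + off[1]; c2 <- col + off[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- mask[nb]
    edges[[length(edges) + 1]] <- cbind(id[fg[ok][hit]], id[nb[hit]])
  }
  em <- do.call(rbind, edges)
  if (is.null(em) || nrow(em) == 0) {
    lab[fg] <- seq_along(fg)
    return(lab)
  }
  g <- igraph::graph_from_edgelist(em, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(fg) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  lab[fg] <- comp
  lab
}

#' Segment FISH signal in one slice
#'
#' Background (a Gaussian blur of the slice at `sigma`) is subtracted with
#' negatives clipped to zero; the residual is Triangle-thresholded and
#' 8-connected objects smaller than `min_area` pixels are dropped.
#'
#' @param img 2-D numeric matrix
#' @param sigma Gaussian background sigma in px (default 100)
#' @param min_area minimum object area in px (default 12)
#' @return list(mask = logical matrix, residual = matrix, threshold = value)
#' @export
segment_signal <- function(img, sigma = 100, min_area = 12) {
  if (max(img) == min(img))
    return(list(mask = matrix(FALSE, nrow(img), ncol(img)),
                residual = matrix(0, nrow(img), ncol(img)), threshold = 0))
  radius <- 2 * ceiling(2 * sigma) + 1
  max_odd <- min(dim(img)) - (min(dim(img)) + 1) %% 2
  bg <- as.matrix(EBImage::gblur(img, sigma = sigma,
                                 radius = min(radius, max_odd)))
  residual <- pmax(img - bg, 0)
  thr <- triangle_threshold(residual)
  mask <- residual > thr
  if (any(mask)) {
    lab <- label_components(mask)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_area)
    mask <- matrix(lab %in% keep & lab > 0, nrow(img), ncol(img))
  }
  list(mask = mask, residual = residual, threshold = thr)
}

#' Segment nuclei (built-in DAPI fallback backend)
#'
#' Interface for per-slice nuclear segmentation. The default backend smooths
#' the DAPI channel, Otsu-thresholds it and splits touching nuclei by
#' watershed on the distance transform. An external backend (e.g. a trained
#' model adapter) can be injected as a function(slice_matrix) -> integer
#' label matrix.
#'
#' @param stack an [image_stack()]
#' @param backend NULL for the built-in fallback, or a function
#' @param sigma DAPI smoothing sigma for the fallback (default 2)
#' @return integer array (y, x, z) of per-slice labels, 0 = background
#' @export
segment_nuclei <- function(stack, backend = NULL, sigma = 2) {
  d <- dim(stack$data)
  labels <- array(0L, d[1:3])
  for (z in seq_len(n_slices(stack))) {
    dapi <- stack$data[, , z, stack$dapi_channel]
    if (is.null(backend)) {
      if (max(dapi) == 0) next
      sm <- as.matrix(EBImage::gblur(dapi, sigma = sigma))
      smn <- sm / max(sm)
      thr <- EBImage::otsu(EBImage::Image(smn))
      binary <- smn > thr
      if (!any(binary)) next
      dm <- EBImage::distmap(EBImage::Image(binary * 1))
      ws <- EBImage::watershed(dm, tolerance = 1)
      labels[, , z] <- as.matrix(EBImage::imageData(ws))
    } else {
      lab <- tryCatch(backend(dapi), error = function(e)
        stopf("nucleus segmentation backend failed on slice %d: %s",
              z, conditionMessage(e)))
      labels[, , z] <- lab
    }
  }
  labels
}

disk_offsets <- function(r) {
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g[g$dy^2 + g$dx^2 <= r^2, ]
}

# binary dilation by a Euclidean disk of radius r (exact offsets)
dilate_disk <- function(mask, r) {
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  off <- disk_offsets(r)
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  row <- (idx - 1L) %% nr + 1L
  col <- (idx - 1L) %/% nr + 1L
  for (i in seq_len(nrow(off))) {
    r2 <- row + off$dy[i]; c2 <- col + off$dx[i]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    out[cbind(r2[ok], c2[ok])] <- TRUE
  }
  out
}

#' Cytoplasmic rings around nuclear ROIs
#'
#' Each nucleus is dilated by a disk of radius `dilate_px` and the nucleus
#' subtracted, leaving a ring approximating the thin OSN cytoplasm. Pixels
#' claimed by more than one ring, or lying inside any nuclear mask, are
#' removed from all claimants.
#'
#' @param labels integer label matrix for one slice
#' @param dilate_px dilation radius in px (default 3, ~270 nm at 90 nm/px)
#' @return integer matrix of ring labels (same ids as `labels`)
#' @export
cytoplasm_rings <- function(labels, dilate_px = 3) {
  ids <- setdiff(sort(unique(as.integer(labels))), 0L)
  rings <- matrix(0L, nrow(labels), ncol(labels))
  claims <- matrix(0L, nrow(labels), ncol(labels))
  per_id <- list()
  for (id in ids) {
    ring <- dilate_disk(labels == id, dilate_px) & labels != id
    per_id[[as.character(id)]] <- ring
    claims <- claims + ring
  }
  any_nucleus <- labels > 0
  for (id in ids) {
    ring <- per_id[[as.character(id)]] & claims == 1L & !any_nucleus
    rings[ring] <- id
  }
  rings
}

region_moments <- function(mask) {
  idx <- which(mask)
  y <- (idx - 1L) %% nrow(mask) + 1L
  x <- (idx - 1L) %/% nrow(mask) + 1L
  cy <- mean(y); cx <- mean(x)
  mu20 <- mean((x - cx)^2); mu02 <- mean((y - cy)^2)
  mu11 <- mean((x - cx) * (y - cy))
  common <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  l1 <- (mu20 + mu02 + common) / 2
  l2 <- (mu20 + mu02 - common) / 2
  ecc <- if (l1 <= 0) 0 else sqrt(pmax(0, 1 - l2 / l1))
  list(centroid_y = cy, centroid_x = cx, area = length(idx), eccentricity = ecc)
}

#' Quantify nuclear and cytoplasmic ROI signal
#'
#' For every nuclear ROI in every slice, records geometry (area, centroid,
#' ellipse-moment eccentricity) and the per-channel mean of the
#' background-subtracted, signal-masked intensity over nuclear and ring
#' pixels. `mask_mode` controls how the signal mask enters the mean:
#' "zeroed" (default) lets non-signal pixels contribute 0 while the
#' denominator stays the full ROI area; "masked_only" averages over signal
#' pixels only; "unmasked" ignores the signal mask.
#'
#' @param stack a depth-corrected [image_stack()]
#' @param labels integer array (y, x, z) of nuclear labels
#' @param rings optional list of ring matrices per slice (computed if NULL)
#' @param signal optional precomputed per-slice, per-channel
#'   [segment_signal()] results (computed if NULL)
#' @param sigma,min_area passed to [segment_signal()]
#' @param mask_mode "zeroed", "masked_only" or "unmasked"
#' @param dilate_px ring dilation radius
#' @return tibble of ROI records; per-channel columns `nuc_mean_<ch>`,
#'   `cyto_mean_<ch>` plus `cyto_defined`
#' @export
quantify_rois <- function(stack, labels, rings = NULL, signal = NULL,
                          sigma = 100, min_area = 12,
                          mask_mode = c("zeroed", "masked_only", "unmasked"),
                          dilate_px = 3) {
  mask_mode <- match.arg(mask_mode)
  chs <- seq_len(n_channels(stack))
  fish_chs <- setdiff(chs, stack$dapi_channel)
  rows <- list()
  for (z in seq_len(n_slices(stack))) {
    lab <- labels[, , z]
    ids <- setdiff(sort(unique(as.integer(lab))), 0L)
    if (length(ids) == 0) next
    ring <- if (is.null(rings)) cytoplasm_rings(lab, dilate_px) else rings[[z]]
    seg <- lapply(chs, function(ch) {
      if (!ch %in% fish_chs) return(NULL)
      if (!is.null(signal)) signal[[z]][[ch]] else
        segment_signal(stack$data[, , z, ch], sigma = sigma, min_area = min_area)
    })
    for (id in ids) {
      nuc_px <- which(lab == id)
      ring_px <- which(ring == id)
      geo <- region_moments(lab == id)
      rec <- tibble::tibble(roi_id = sprintf("z%02d_l%03d", z, id),
                            slice = z, label = id,
                            centroid_y = geo$centroid_y,
                            centroid_x = geo$centroid_x,
                            nuclear_area = geo$area,
                            eccentricity = geo$eccentricity,
                            cytoplasmic_area = length(ring_px),
                            cyto_defined = length(ring_px) > 0)
      for (ch in fish_chs) {
        res <- seg[[ch]]$residual
        smask <- seg[[ch]]$mask
        roi_mean <- function(px) {
          if (length(px) == 0) return(NA_real_)
          switch(mask_mode,
                 zeroed = sum(res[px] * smask[px]) / length(px),
                 masked_only = if (any(smask[px])) mean(res[px][smask[px]]) else 0,
                 unmasked = mean(res[px]))
        }
        rec[[paste0("nuc_mean_", ch)]] <- roi_mean(nuc_px)
        rec[[paste0("cyto_mean_", ch)]] <- roi_mean(ring_px)
      }
      rows[[length(rows) + 1]] <- rec
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 0 && any(!out$cyto_defined))
    warnf("%d ROIs with empty cytoplasmic rings flagged", sum(!out$cyto_defined))
  out
}

#' Robust quantile normalization of ROI signals
#'
#' Per channel (scope: one image/stack), the `q_low` and `q_high` quantiles
#' of the nuclear means define the normalization range; both nuclear and
#' cytoplasmic means are mapped through (x - Qlow) / (Qhigh - Qlow). Values
#' outside [0, 1] are permitted (no clipping).
#'
#' @param records output of [quantify_rois()]
#' @param channels channel indices to normalize (default: all with columns)
#' @param q_low,q_high nuclear quantiles (defaults 0.001, 0.999)
#' @return records with added `nuc_norm_<ch>`, `cyto_norm_<ch>` columns and
#'   a `norm_range` attribute
#' @export
normalize_signals <- function(records, channels = NULL,
                              q_low = 0.001, q_high = 0.999) {
  if (nrow(records) < 2) stopf("need at least 2 ROIs to normalize an image")
  if (is.null(channels))
    channels <- as.integer(sub("nuc_mean_", "",
                               grep("^nuc_mean_", names(records), value = TRUE)))
  ranges <- list()
  for (ch in channels) {
    nuc <- records[[paste0("nuc_mean_", ch)]]
    qs <- quantile(nuc, c(q_low, q_high), na.rm = TRUE, names = FALSE)
    if (qs[2] <= qs[1])
      stopf("degenerate nuclear signal range in channel %d", ch)
    records[[paste0("nuc_norm_", ch)]] <- (nuc - qs[1]) / (qs[2] - qs[1])
    cyto <- records[[paste0("cyto_mean_", ch)]]
    records[[paste0("cyto_norm_", ch)]] <- (cyto - qs[1]) / (qs[2] - qs[1])
    ranges[[as.character(ch)]] <- qs
  }
  attr(records, "norm_range") <- ranges
  records
}

#' Classify chosen-OR-expressing cells
#'
#' Conjunction of five gates on one channel: normalized nuclear signal,
#' normalized cytoplasmic signal, nuclear area window, cytoplasmic area and
#' eccentricity.
#'
#' @param records normalized ROI records
#' @param channel channel index
#' @param thresholds list(nuc, cyto, nuc_area (len 2), cyto_area, ecc) with
#'   defaults 0.75, 0.2, c(400, 900), 100, 0.8
#' @return logical vector per ROI
#' @export
classify_chosen <- function(records, channel,
                            thresholds = list(nuc = 0.75, cyto = 0.2,
                                              nuc_area = c(400, 900),
                                              cyto_area = 100, ecc = 0.8)) {
  nuc <- records[[paste0("nuc_norm_", channel)]]
  cyto <- records[[paste0("cyto_norm_", channel)]]
  !is.na(nuc) & nuc > thresholds$nuc &
    !is.na(cyto) & cyto > thresholds$cyto &
    records$nuclear_area >= thresholds$nuc_area[1] &
    records$nuclear_area <= thresholds$nuc_area[2] &
    records$cytoplasmic_area > thresholds$cyto_area &
    records$eccentricity < thresholds$ecc
}

#' Classify transcript localization
#'
#' "nuclear" if the normalized nuclear signal exceeds `nuc_thresh`;
#' "nuclear+cytoplasmic" if, in addition, the normalized cytoplasmic signal
#' exceeds `cyto_thresh`; otherwise "none". Cytoplasmic status requires
#' nuclear status.
#'
#' @param records normalized ROI records
#' @param channel channel index
#' @param nuc_thresh,cyto_thresh thresholds (defaults 0.1, 0.2)
#' @return character vector per ROI
#' @export
classify_localization <- function(records, channel,
                                  nuc_thresh = 0.1, cyto_thresh = 0.2) {
  nuc <- records[[paste0("nuc_norm_", channel)]]
  cyto <- records[[paste0("cyto_norm_", channel)]]
  out <- rep("none", nrow(records))
  nuclear <- !is.na(nuc) & nuc > nuc_thresh
  out[nuclear] <- "nuclear"
  out[nuclear & !is.na(cyto) & cyto > cyto_thresh] <- "nuclear+cytoplasmic"
  out
}

#' Subnuclear signal-domain overlap between two channels
#'
#' Areas of each channel's signal mask within a nuclear ROI, their
#' intersection, the overlap as a fraction of the channel-1 domain, and the
#' proportion of the nucleus occupied by each.
#'
#' @param mask1,mask2 logical signal masks (full slice)
#' @param roi_mask logical nuclear ROI mask
#' @return list(area_ch1, area_ch2, overlap_area, overlap_fraction,
#'   frac_nucleus_ch1, frac_nucleus_ch2)
#' @export
subnuclear_overlap <- function(mask1, mask2, roi_mask) {
  n <- sum(roi_mask)
  if (n == 0)
    return(list(area_ch1 = 0, area_ch2 = 0, overlap_area = 0,
                overlap_fraction = 0, frac_nucleus_ch1 = 0,
                frac_nucleus_ch2 = 0))
  a1 <- sum(mask1 & roi_mask); a2 <- sum(mask2 & roi_mask)
  ov <- sum(mask1 & mask2 & roi_mask)
  list(area_ch1 = a1, area_ch2 = a2, overlap_area = ov,
       overlap_fraction = if (a1 > 0) ov / a1 else 0,
       frac_nucleus_ch1 = a1 / n, frac_nucleus_ch2 = a2 / n)
}

#' Mean and 95% confidence interval of per-replicate proportions
#'
#' t-distribution CI centered on the mean; undefined (NA bounds) for a
#' single replicate or zero variance with n = 1.
#'
#' @param x numeric vector of per-replicate proportions
#' @return list(mean, ci_low, ci_high, n)
#' @export
proportion_summary <- function(x) {
  stopifnot(length(x) >= 1)
  m <- mean(x); n <- length(x)
  if (n < 2) return(list(mean = m, ci_low = NA_real_, ci_high = NA_real_, n = n))
  half <- qt(0.975, n - 1) * sd(x) / sqrt(n)
  list(mean = m, ci_low = m - half, ci_high = m + half, n = n)
}

#' Run the full FISH quantification pipeline on one stack
#'
#' depth-correct -> per-slice signal segmentation -> cytoplasm rings ->
#' ROI quantification -> quantile normalization -> chosen/localization
#' classification for every non-DAPI channel.
#'
#' @param stack an [image_stack()]
#' @param labels nuclear label array (y, x, z); if NULL, [segment_nuclei()]
#'   with the fallback backend is used
#' @param sigma,min_area signal segmentation parameters
#' @param mask_mode see [quantify_rois()]
#' @param dilate_px ring radius
#' @param q_low,q_high normalization quantiles
#' @param chosen_thresholds see [classify_chosen()]
#' @return tibble of normalized ROI records with `chosen_<ch>` and
#'   `localization_<ch>` columns
#' @export
fish_pipeline <- function(stack, labels = NULL, sigma = 100, min_area = 12,
                          mask_mode = "zeroed", dilate_px = 3,
                          q_low = 0.001, q_high = 0.999,
                          chosen_thresholds = list(nuc = 0.75, cyto = 0.2,
                                                   nuc_area = c(400, 900),
                                                   cyto_area = 100, ecc = 0.8)) {
  corrected <- depth_correct(stack)
  if (is.null(labels)) labels <- segment_nuclei(corrected)
  records <- quantify_rois(corrected, labels, sigma = sigma,
                           min_area = min_area, mask_mode = mask_mode,
                           dilate_px = dilate_px)
  if (nrow(records) == 0) return(records)
  records <- normalize_signals(records, q_low = q_low, q_high = q_high)
  for (ch in setdiff(seq_len(n_channels(stack)), stack$dapi_channel)) {
    records[[paste0("chosen_", ch)]] <-
      classify_chosen(records, ch, chosen_thresholds)
    records[[paste0("localization_", ch)]] <- classify_localization(records, ch)
  }
  records
}
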