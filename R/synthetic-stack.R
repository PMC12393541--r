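#' Generate a synthetic confocal stack with ground-truth cell classes
#'
#' Builds a 2-channel (DAPI + FISH) z-stack of disk-shaped OSN nuclei with
#' per-class FISH signal, emulating the assumptions of the quantification
#' pipeline: depth-dependent multiplicative attenuation of all channels,
#' Gaussian blur as a point-spread proxy, constant background and Poisson
#' shot noise. Classes:
#'
#' * `chosen`: bright nuclear puncta plus puncta in the 3-px cytoplasmic
#'   ring (normalized nuclear signal near the top of the image's range,
#'   cytoplasmic signal well above the 0.2 gate)
#' * `nuclear`: moderate nuclear puncta only (nuclear-retained transcripts)
#' * `negative`: no FISH signal
#'
#' Nucleus radii are drawn so nuclear areas fall inside the 400-900 px
#' chosen-cell gate. Ground-truth label masks are returned so segmentation
#' can be bypassed.
#'
#' @param seed integer seed
#' @param shape c(height, width) in px (default c(256, 256))
#' @param n_slices z slices (default 4)
#' @param class_mix named counts per slice
#'   (default c(chosen = 3, nuclear = 3, negative = 3))
#' @param nucleus_radius_px range of nucleus radii (default c(12, 16);
#'   areas ~452-804 px)
#' @param dapi_attenuation per-slice multiplicative attenuation factor
#'   (default 0.85; 1 = no attenuation)
#' @param dapi_level DAPI intensity inside nuclei before attenuation
#' @param puncta_intensity FISH punctum peak intensity before attenuation
#' @param nuclear_fill_frac fraction of nuclear area covered by puncta for
#'   chosen cells (default 0.35); `nuclear` cells get half of that at 0.8x
#'   intensity
#' @param psf_sigma Gaussian blur sigma in px (default 1)
#' @param background additive background level (default 2)
#' @param noise "poisson" or "none"
#' @return list(stack = [image_stack()], labels = integer array (y,x,z),
#'   truth = tibble slice, label, class, center_y, center_x, radius)
#' @export
gen_stack <- function(seed = 1L, shape = c(256, 256), n_slices = 4,
                      class_mix = c(chosen = 3, nuclear = 3, negative = 3),
                      nucleus_radius_px = c(12, 16), dapi_attenuation = 0.85,
                      dapi_level = 120, puncta_intensity = 80,
                      nuclear_fill_frac = 0.35, psf_sigma = 1,
                      background = 2, noise = c("poisson", "none")) {
  noise <- match.arg(noise)
  withr::local_seed(seed)
  ny <- shape[1]; nx <- shape[2]
  data <- array(0, c(ny, nx, n_slices, 2))
  labels <- array(0L, c(ny, nx, n_slices))
  truth <- list()
  yg <- matrix(seq_len(ny), ny, nx)
  xg <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  for (z in seq_len(n_slices)) {
    classes <- sample(rep(names(class_mix), class_mix))
    n_cells <- length(classes)
    centers <- matrix(NA_real_, 0, 2)
    radii <- numeric(0)
    margin <- max(nucleus_radius_px) + 8
    for (i in seq_len(n_cells)) {
      # rejection-sample non-touching placements (rings must stay disjoint)
      for (try in 1:200) {
        cy <- runif(1, margin, ny - margin)
        cx <- runif(1, margin, nx - margin)
        r <- runif(1, nucleus_radius_px[1], nucleus_radius_px[2])
        if (nrow(centers) == 0 ||
            all(sqrt((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2) >
                radii + r + 10)) break
      }
      centers <- rbind(centers, c(cy, cx)); radii <- c(radii, r)
    }
    dapi <- matrix(0, ny, nx)
    fish <- matrix(0, ny, nx)
    for (i in seq_len(n_cells)) {
      cy <- centers[i, 1]; cx <- centers[i, 2]; r <- radii[i]
      d2 <- (yg - cy)^2 + (xg - cx)^2
      nucleus <- d2 <= r^2
      labels[, , z][nucleus] <- i
      dapi[nucleus] <- dapi_level
      cls <- classes[i]
      if (cls != "negative") {
        # nuclear signal as a bright subnuclear expression domain: a disk
        # covering `frac` of the nuclear area, slightly off-center
        frac <- if (cls == "chosen") nuclear_fill_frac else nuclear_fill_frac / 2
        amp <- if (cls == "chosen") puncta_intensity else 0.8 * puncta_intensity
        rd <- sqrt(frac) * r
        a <- runif(1, 0, 2 * pi); off <- runif(1, 0, 0.15 * r)
        dy <- cy + off * sin(a); dx <- cx + off * cos(a)
        domain <- (yg - dy)^2 + (xg - dx)^2 <= rd^2 & nucleus
        fish[domain] <- amp
      }
      if (cls == "chosen") {
        # ring puncta at radius r + 1.5 (inside the 3-px dilation ring)
        n_ring <- round(2 * pi * (r + 1.5) / 5)
        for (pnc in seq_len(n_ring)) {
          a <- runif(1, 0, 2 * pi)
          py <- cy + (r + 1.5) * sin(a); px <- cx + (r + 1.5) * cos(a)
          punc <- (yg - py)^2 + (xg - px)^2 <= 1.5^2 & !nucleus
          fish[punc] <- pmax(fish[punc], amp)
        }
      }
      truth[[length(truth) + 1]] <- tibble::tibble(
        slice = z, label = i, class = cls, center_y = cy, center_x = cx,
        radius = r)
    }
    att <- dapi_attenuation^(z - 1)
    dapi <- dapi * att
    fish <- fish * att
    if (psf_sigma > 0) {
      dapi <- as.matrix(EBImage::gblur(dapi, sigma = psf_sigma))
      fish <- as.matrix(EBImage::gblur(fish, sigma = psf_sigma))
    }
    dapi <- pmax(dapi + background, 0)
    fish <- pmax(fish + background, 0)
    if (noise == "poisson") {
      dapi <- matrix(rpois(length(dapi), dapi), ny, nx)
      fish <- matrix(rpois(length(fish), fish), ny, nx)
    }
    data[, , z, 1] <- dapi
    data[, , z, 2] <- fish
  }
  list(stack = image_stack(data, dapi_channel = 1),
       labels = labels,
       truth = dplyr::bind_rows(truth),
       params = list(seed = seed, shape = shape, n_slices = n_slices,
                     class_mix = class_mix,
                     dapi_attenuation = dapi_attenuation,
                     puncta_intensity = puncta_intensity,
                     psf_sigma = psf_sigma, background = background))
}

#' Write an image stack as a multi-page TIFF (z-major, channel-minor)
#' @param stack an [image_stack()]
#' @param path output .tif path
#' @export
write_stack_tiff <- function(stack, path) {
  mx <- max(stack$data, 1)
  pages <- list()
  for (z in seq_len(n_slices(stack)))
    for (ch in seq_len(n_channels(stack)))
      pages[[length(pages) + 1]] <- stack$data[, , z, ch] / mx
  EBImage::writeImage(EBImage::Image(simplify2array(pages)), path,
                      type = "tiff")
  invisible(path)
}
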