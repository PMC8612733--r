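#' Droplet mask parameters
#'
#' Parameters of the threshold-based droplet segmentation. The intensity
#' threshold is `mean(image) + k_user * sd(image)`; a median filter of the
#' given radius removes spurious detections; connected components smaller
#' than `min_area_px` are dropped.
#'
#' @param k_user Dimensionless threshold multiplier (default 3).
#' @param median_radius_px Despeckle median-filter window radius in pixels
#'   (default 2; 0 disables despeckling).
#' @param min_area_px Minimum droplet area in pixels (default 4).
#' @param median_on Where the median filter acts: `"mask"` (default) treats it
#'   as a post-threshold cleanup that identifies and removes spurious
#'   detections; `"image"` median-filters the grayscale image before
#'   thresholding.
#' @return A `mask_params` object.
#' @export
mask_params <- function(k_user = 3, median_radius_px = 2, min_area_px = 4,
                        median_on = c("mask", "image")) {
  median_on <- match.arg(median_on)
  stopifnot(is.numeric(k_user), length(k_user) == 1L, k_user > 0,
            is.numeric(median_radius_px), length(median_radius_px) == 1L,
            median_radius_px >= 0,
            is.numeric(min_area_px), length(min_area_px) == 1L,
            min_area_px >= 1)
  structure(list(k_user = k_user,
                 median_radius_px = as.integer(median_radius_px),
                 min_area_px = as.integer(min_area_px),
                 median_on = median_on),
            class = "mask_params")
}

#' Subtract a dark-frame offset from an image
#'
#' Removes the camera offset estimated as the scalar mean intensity of a
#' shutter-closed calibration frame. Resulting negative counts are clamped
#' to 0 (detector counts are non-negative).
#'
#' @param image An [image2d()].
#' @param dark An [image2d()]/matrix of the same shape, or a scalar offset.
#' @return Dark-corrected `image2d`.
#' @export
subtract_dark_frame <- function(image, dark) {
  stopifnot(is_image2d(image) || is.matrix(image))
  if (is.numeric(dark) && length(dark) == 1L) {
    offset <- dark
  } else {
    if (!all(dim(dark) == dim(image))) {
      stop(sprintf("dark frame shape (%s) does not match image shape (%s)",
                   paste(dim(dark), collapse = "x"),
                   paste(dim(image), collapse = "x")), call. = FALSE)
    }
    offset <- mean(unclass(dark))
  }
  px <- pmax(unclass(image) - offset, 0)
  image2d(px, pixel_size_um = attr(image, "pixel_size_um"),
          channel_name = attr(image, "channel_name"))
}

# Binary median filter with a circular window (offsets with dx^2+dy^2 <= r^2,
# as rank filters in Fiji use), truncated at the image border. Output pixel is
# foreground iff foreground pixels form a strict majority of the in-image
# window.
binary_median_circular <- function(bin, radius) {
  nr <- nrow(bin); nc <- ncol(bin)
  offs <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  offs <- offs[offs$dr^2 + offs$dc^2 <= radius^2, ]
  fg <- matrix(0, nr, nc)
  valid <- matrix(0, nr, nc)
  binn <- bin * 1
  for (i in seq_len(nrow(offs))) {
    dr <- offs$dr[i]; dc <- offs$dc[i]
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    fg[rs, cs] <- fg[rs, cs] + binn[rs - dr, cs - dc]
    valid[rs, cs] <- valid[rs, cs] + 1
  }
  2 * fg > valid
}

# 8-connected component labeling by iterative min-label propagation.
# EBImage::bwlabel is 4-connected, whereas blob detection here uses
# 8-connectivity, so labeling is done in-package (vectorized; converges in
# O(component diameter) sweeps). Returns integer matrix, 0 = background,
# labels are arbitrary positive integers (not yet 1..n).
label_components_8 <- function(bin) {
  nr <- nrow(bin); nc <- ncol(bin)
  lab <- matrix(Inf, nr, nc)
  idx <- which(bin)
  if (length(idx) == 0L) return(matrix(0L, nr, nc))
  lab[idx] <- idx
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                 c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  repeat {
    new <- lab
    for (s in shifts) {
      dr <- s[1]; dc <- s[2]
      sh <- matrix(Inf, nr, nc)
      rs <- max(1, 1 + dr):min(nr, nr + dr)
      cs <- max(1, 1 + dc):min(nc, nc + dc)
      sh[rs, cs] <- lab[rs - dr, cs - dc]
      new <- pmin(new, sh)
    }
    new[!bin] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  out <- matrix(0L, nr, nc)
  out[idx] <- as.integer(lab[idx])
  out
}

# Relabel arbitrary positive labels to 1..n in raster-scan (row-major) order
# of each component's first pixel.
relabel_raster_order <- function(lab) {
  idx <- which(lab > 0)
  if (length(idx) == 0L) return(list(labels = lab, n = 0L))
  nr <- nrow(lab); nc <- ncol(lab)
  rows <- (idx - 1L) %% nr
  cols <- (idx - 1L) %/% nr
  rm_order <- rows * nc + cols          # row-major linear index (0-based)
  vals <- lab[idx]
  first <- tapply(rm_order, vals, min)
  ord <- names(first)[order(first)]
  map <- integer(max(vals))
  map[as.integer(ord)] <- seq_along(ord)
  out <- lab
  out[idx] <- map[vals]
  list(labels = out, n = length(ord))
}

#' Segment droplets by threshold and despeckle
#'
#' Builds a labeled droplet mask from a dark-corrected image. The threshold
#' is `T = mean + k_user * sd` over all pixels; pixels above `T` form the raw
#' binary mask. A median filter of radius `median_radius_px` (circular
#' window, as in Fiji's rank filters) then removes spurious noise
#' detections: with the default `median_on = "mask"`, raw connected
#' components that vanish entirely under the binary median filter (isolated
#' speckles) are removed, while components that survive keep their full
#' thresholded extent, so measured droplet areas and intensities are not
#' biased by filter erosion at droplet edges. Components smaller than
#' `min_area_px` are dropped. Remaining components are labeled `1..n` in
#' raster-scan order of their first pixel, using 8-connectivity.
#'
#' Droplets touching the image border are retained.
#'
#' @param image Dark-corrected [image2d()].
#' @param params A [mask_params()].
#' @return A `droplet_mask`: list with `labels` (integer matrix, 0 = light
#'   phase) and `n_droplets`.
#' @examples
#' f <- gen_droplet_field(droplet_field_spec(n_droplets = 3, seed = 1))
#' m <- make_droplet_mask(f$image, mask_params())
#' m$n_droplets
#' @export
make_droplet_mask <- function(image, params = mask_params()) {
  stopifnot(inherits(params, "mask_params"))
  px <- unclass(image)
  if (identical(params$median_on, "image") && params$median_radius_px > 0) {
    # grayscale median before thresholding (alternative reading)
    mx <- max(px)
    if (mx > 0) {
      px <- EBImage::medianFilter(px / mx, params$median_radius_px) * mx
    }
  }
  thr <- mean(px) + params$k_user * stats::sd(px)
  bin <- px > thr
  if (all(bin)) {
    warning("mask-degenerate: all pixels above threshold", call. = FALSE)
  }
  lab <- label_components_8(bin)
  if (identical(params$median_on, "mask") && params$median_radius_px > 0 &&
      any(bin)) {
    med <- binary_median_circular(bin, params$median_radius_px)
    surviving <- unique(lab[med & bin])
    surviving <- surviving[surviving > 0]
    lab[!(lab %in% surviving)] <- 0L
  }
  if (any(lab > 0)) {
    areas <- tabulate(lab[lab > 0])
    small <- which(areas > 0 & areas < params$min_area_px)
    if (length(small)) lab[lab %in% small] <- 0L
  }
  rl <- relabel_raster_order(lab)
  structure(list(labels = rl$labels, n_droplets = rl$n), class = "droplet_mask")
}

#' @export
print.droplet_mask <- function(x, ...) {
  cat(sprintf("<droplet_mask> %d x %d px, %d droplets\n",
              nrow(x$labels), ncol(x$labels), x$n_droplets))
  invisible(x)
}

#' Per-droplet statistics
#'
#' One record per labeled droplet: area, mean and integrated intensity, and
#' centroid in 0-based `(row, col)` coordinates.
#'
#' @param image Dark-corrected [image2d()].
#' @param mask A [make_droplet_mask()] result with matching shape.
#' @return Data frame with columns `droplet_id`, `area_px`, `area_um2`
#'   (NA when pixel size unknown), `mean_intensity`, `integrated_intensity`,
#'   `centroid_row`, `centroid_col`.
#' @export
droplet_stats <- function(image, mask) {
  stopifnot(inherits(mask, "droplet_mask"))
  if (!all(dim(mask$labels) == dim(image))) {
    stop("mask shape does not match image shape", call. = FALSE)
  }
  n <- mask$n_droplets
  empty <- data.frame(droplet_id = integer(0), area_px = integer(0),
                      area_um2 = numeric(0), mean_intensity = numeric(0),
                      integrated_intensity = numeric(0),
                      centroid_row = numeric(0), centroid_col = numeric(0))
  if (n == 0L) return(empty)
  px <- unclass(image)
  lab <- mask$labels
  idx <- which(lab > 0)
  ids <- lab[idx]
  vals <- px[idx]
  nr <- nrow(lab)
  rows0 <- (idx - 1L) %% nr          # 0-based row
  cols0 <- (idx - 1L) %/% nr         # 0-based col
  area <- tabulate(ids, nbins = n)
  tot <- as.numeric(rowsum(vals, ids, reorder = TRUE))
  crow <- as.numeric(rowsum(as.numeric(rows0), ids, reorder = TRUE)) / area
  ccol <- as.numeric(rowsum(as.numeric(cols0), ids, reorder = TRUE)) / area
  psz <- attr(image, "pixel_size_um")
  data.frame(droplet_id = seq_len(n),
             area_px = area,
             area_um2 = if (is.null(psz)) NA_real_ else area * psz^2,
             mean_intensity = tot / area,
             integrated_intensity = tot,
             centroid_row = crow,
             centroid_col = ccol)
}

#' Per-field partition coefficient and condensed fraction
#'
#' Computes, for one field and one channel:
#' * `I_DP`: unweighted average of the per-droplet mean intensities
#'   (dense phase);
#' * `I_LP`: mean intensity over every pixel outside the mask (light phase,
#'   no exclusion buffer);
#' * `PC = I_DP / I_LP`: the partition coefficient;
#' * `I_in`, `I_out`: integrated intensity inside / outside the mask;
#' * `RC = I_in / (I_in + I_out)`: the relative condensed fraction.
#'
#' When the mask is empty, `RC = 0` and `PC` is reported as `NA`. When the
#' light phase has zero mean intensity, `PC` is `NA` and `flag` records why.
#' The mask may come from a paired channel (see
#' [field_quant_two_channel()]).
#'
#' @param image Dark-corrected [image2d()].
#' @param mask A `droplet_mask` of the same shape.
#' @param channel_name Optional channel label recorded in the result.
#' @return A `field_quant` object (list) with fields `n_droplets`, `I_DP`,
#'   `I_LP`, `PC`, `I_in`, `I_out`, `RC`, `mean_area_px`, `channel_name`,
#'   `flag`.
#' @export
field_quant <- function(image, mask, channel_name = NULL) {
  stopifnot(inherits(mask, "droplet_mask"))
  if (!all(dim(mask$labels) == dim(image))) {
    stop("mask shape does not match image shape", call. = FALSE)
  }
  if (is.null(channel_name)) channel_name <- attr(image, "channel_name")
  px <- unclass(image)
  inside <- mask$labels > 0
  n <- mask$n_droplets
  flag <- NA_character_
  if (n == 0L) {
    res <- list(n_droplets = 0L, I_DP = NA_real_,
                I_LP = if (any(!inside)) mean(px[!inside]) else NA_real_,
                PC = NA_real_, I_in = 0, I_out = sum(px), RC = 0,
                mean_area_px = NA_real_,
                channel_name = channel_name, flag = "no-droplets")
    return(structure(res, class = "field_quant"))
  }
  st <- droplet_stats(image, mask)
  I_DP <- mean(st$mean_intensity)
  I_in <- sum(px[inside])
  I_out <- sum(px[!inside])
  if (any(!inside)) {
    I_LP <- mean(px[!inside])
  } else {
    I_LP <- NA_real_
    flag <- "no-light-phase"
  }
  if (!is.na(I_LP) && I_LP == 0) {
    PC <- NA_real_
    flag <- "zero-light-phase"
  } else {
    PC <- I_DP / I_LP
  }
  RC <- I_in / (I_in + I_out)
  structure(list(n_droplets = n, I_DP = I_DP, I_LP = I_LP, PC = PC,
                 I_in = I_in, I_out = I_out, RC = RC,
                 mean_area_px = mean(st$area_px),
                 channel_name = channel_name, flag = flag),
            class = "field_quant")
}

#' @export
print.field_quant <- function(x, ...) {
  cat(sprintf(
    "<field_quant>%s %d droplets; I_DP = %.4g, I_LP = %.4g, PC = %.4g, RC = %.4g\n",
    if (is.null(x$channel_name)) "" else paste0(" [", x$channel_name, "]"),
    x$n_droplets, x$I_DP, x$I_LP, x$PC, x$RC))
  invisible(x)
}

#' @export
as.data.frame.field_quant <- function(x, ...) {
  data.frame(channel = if (is.null(x$channel_name)) NA_character_ else x$channel_name,
             n_droplets = x$n_droplets, I_DP = x$I_DP, I_LP = x$I_LP,
             PC = x$PC, I_in = x$I_in, I_out = x$I_out, RC = x$RC,
             mean_area_px = x$mean_area_px, flag = x$flag)
}

#' Two-channel quantification against a protein-channel mask
#'
#' For co-registered protein and RNA channels (e.g. GFP-tagged protein with a
#' Cy5-labeled miRNA), the droplet mask is built from the protein channel
#' only and applied unchanged to both channels, so the RNA partition
#' coefficient measures enrichment of RNA in protein-defined droplets.
#'
#' @param protein Dark-corrected protein-channel [image2d()].
#' @param rna Dark-corrected second-channel [image2d()], same shape.
#' @param params A [mask_params()].
#' @return List with elements `protein` and `rna` (each a `field_quant`) and
#'   `mask` (the shared `droplet_mask`).
#' @export
field_quant_two_channel <- function(protein, rna, params = mask_params()) {
  if (!all(dim(protein) == dim(rna))) {
    stop("protein and RNA channels must have the same shape", call. = FALSE)
  }
  mask <- make_droplet_mask(protein, params)
  list(protein = field_quant(protein, mask, channel_name = "protein"),
       rna = field_quant(rna, mask, channel_name = "rna"),
       mask = mask)
}

#' Concentration sweep summary and phase-separation onset
#'
#' Aggregates per-field quantification across a protein concentration series
#' and flags the lowest concentration at which any droplets were detected as
#' the apparent phase-separation onset.
#'
#' @param fields A list whose elements are lists with components
#'   `concentration_uM` (numeric) and `quant` (a `field_quant`).
#' @return List with `table` (one row per concentration: `concentration_uM`,
#'   `n_fields`, `mean_n_droplets`, `mean_area_px`, `mean_RC`) and
#'   `onset_uM` (numeric, `NA` when no concentration produced droplets).
#' @export
concentration_sweep <- function(fields) {
  if (length(fields) == 0L) stop("empty concentration sweep", call. = FALSE)
  conc <- vapply(fields, function(f) as.numeric(f$concentration_uM), 0)
  nd <- vapply(fields, function(f) as.numeric(f$quant$n_droplets), 0)
  rc <- vapply(fields, function(f) as.numeric(f$quant$RC), 0)
  ar <- vapply(fields, function(f) as.numeric(f$quant$mean_area_px), 0)
  lev <- sort(unique(conc))
  tab <- do.call(rbind, lapply(lev, function(cc) {
    i <- conc == cc
    data.frame(concentration_uM = cc,
               n_fields = sum(i),
               mean_n_droplets = mean(nd[i]),
               mean_area_px = if (all(is.na(ar[i]))) NA_real_ else mean(ar[i], na.rm = TRUE),
               mean_RC = mean(rc[i]))
  }))
  with_droplets <- tab$concentration_uM[tab$mean_n_droplets > 0]
  onset <- if (length(with_droplets)) min(with_droplets) else NA_real_
  list(table = tab, onset_uM = onset)
}
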