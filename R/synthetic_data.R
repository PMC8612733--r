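# Disk rasterization shared by the generators: 1-based integer center,
# pixels with (r - cr)^2 + (c - cc)^2 <= radius^2.
rasterize_disk <- function(shape, center, radius) {
  rr <- outer((seq_len(shape[1]) - center[1])^2,
              (seq_len(shape[2]) - center[2])^2, `+`)
  rr <= radius^2
}

# Place n non-overlapping disks; returns data.frame(row, col, radius).
# Centers are kept far enough apart that the rendered disks are disjoint and
# not even 8-adjacent, so each disk is one connected component.
place_disks <- function(shape, n, radius_range, max_attempts = 1000L) {
  placed <- data.frame(row = numeric(0), col = numeric(0), radius = numeric(0))
  for (i in seq_len(n)) {
    ok <- FALSE
    for (a in seq_len(max_attempts)) {
      r <- if (radius_range[1] == radius_range[2]) radius_range[1] else
        sample(seq(radius_range[1], radius_range[2]), 1L)
      row <- sample(seq(1L + r, shape[1] - r), 1L)
      col <- sample(seq(1L + r, shape[2] - r), 1L)
      if (nrow(placed) == 0L ||
          all(sqrt((placed$row - row)^2 + (placed$col - col)^2) >
              placed$radius + r + 2)) {
        placed <- rbind(placed, data.frame(row = row, col = col, radius = r))
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop(sprintf(paste("could not place droplet %d of %d without overlap;",
                         "use fewer or smaller droplets"), i, n),
           call. = FALSE)
    }
  }
  placed
}

#' Synthetic droplet-field specification
#'
#' Parameters of a two-phase synthetic fluorescence field: hard-edged
#' (non-anti-aliased) disks of dense-phase intensity on a dilute-phase
#' background, plus a camera offset everywhere and optional additive
#' Gaussian read noise. Hard edges keep the analytic partition coefficient
#' and condensed fraction exact; an optional Gaussian blur is available for
#' realism tests via [gen_droplet_field()].
#'
#' @param shape `(rows, cols)` in pixels (default `c(256, 256)`).
#' @param n_droplets Number of droplets (default 8).
#' @param radius_px `(min, max)` droplet radius in pixels (default
#'   `c(4, 10)`).
#' @param I_dense,I_dilute Dense- and dilute-phase intensities in detector
#'   counts (`I_dense > I_dilute >= 0`; defaults 100 and 10).
#' @param camera_offset Additive camera offset in counts (default 0).
#' @param noise_sd Gaussian read-noise standard deviation in counts
#'   (default 0).
#' @param seed Integer seed; the same spec + seed reproduces the field
#'   bit-identically.
#' @return A `droplet_field_spec` object.
#' @export
droplet_field_spec <- function(shape = c(256L, 256L), n_droplets = 8L,
                               radius_px = c(4L, 10L), I_dense = 100,
                               I_dilute = 10, camera_offset = 0,
                               noise_sd = 0, seed = 1L) {
  stopifnot(length(shape) == 2L, all(shape >= 8),
            n_droplets >= 0,
            length(radius_px) == 2L, radius_px[1] >= 1,
            radius_px[1] <= radius_px[2],
            I_dense > I_dilute, I_dilute >= 0,
            camera_offset >= 0, noise_sd >= 0)
  structure(list(shape = as.integer(shape), n_droplets = as.integer(n_droplets),
                 radius_px = as.integer(radius_px), I_dense = I_dense,
                 I_dilute = I_dilute, camera_offset = camera_offset,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "droplet_field_spec")
}

#' Generate a synthetic two-phase droplet field with analytic ground truth
#'
#' Renders the field described by a [droplet_field_spec()], an optional
#' second channel sharing the same disks (e.g. a labeled miRNA channel with
#' its own dense/dilute intensities), and a matching dark frame
#' (`camera_offset` plus noise). The ground truth is computed analytically
#' from the disk geometry and spec intensities, never from the rendered
#' pixels: `PC = I_dense / I_dilute` and
#' `RC = A_in I_dense / (A_in I_dense + A_out I_dilute)`.
#'
#' @param spec A [droplet_field_spec()].
#' @param channel2 Optional list with `I_dense` and `I_dilute` for a second
#'   channel rendered on the same disks.
#' @param blur_sigma_px Optional Gaussian blur (pixels); when used, the
#'   field is no longer hard-edged and the analytic ground truth for PC/RC
#'   no longer applies exactly (truth then reports the unblurred values).
#' @return List with `image` (dark-uncorrected [image2d()]), `channel2`
#'   (or `NULL`), `dark` ([image2d()]), and `truth` (list: `pc`, `rc`,
#'   `a_in`, `a_out`, per-droplet `disks` and `areas_px`, `labels` truth
#'   raster, and `pc2`/`rc2` when a second channel is present).
#' @examples
#' f <- gen_droplet_field(droplet_field_spec(n_droplets = 5, seed = 7))
#' f$truth$pc
#' @export
gen_droplet_field <- function(spec, channel2 = NULL, blur_sigma_px = 0) {
  stopifnot(inherits(spec, "droplet_field_spec"))
  withr::with_seed(spec$seed, {
    disks <- if (spec$n_droplets > 0) {
      place_disks(spec$shape, spec$n_droplets, spec$radius_px)
    } else {
      data.frame(row = numeric(0), col = numeric(0), radius = numeric(0))
    }
    labels <- matrix(0L, spec$shape[1], spec$shape[2])
    for (i in seq_len(nrow(disks))) {
      d <- rasterize_disk(spec$shape, c(disks$row[i], disks$col[i]),
                          disks$radius[i])
      labels[d] <- i
    }
    inside <- labels > 0
    a_in <- sum(inside)
    a_out <- length(labels) - a_in
    render <- function(I_dense, I_dilute) {
      px <- matrix(I_dilute, spec$shape[1], spec$shape[2])
      px[inside] <- I_dense
      px <- px + spec$camera_offset
      if (spec$noise_sd > 0) {
        px <- px + matrix(stats::rnorm(length(px), 0, spec$noise_sd),
                          nrow(px), ncol(px))
      }
      if (blur_sigma_px > 0) {
        px <- EBImage::gblur(px, sigma = blur_sigma_px)
      }
      image2d(pmax(px, 0))
    }
    img <- render(spec$I_dense, spec$I_dilute)
    img2 <- if (!is.null(channel2)) {
      stopifnot(channel2$I_dense >= 0, channel2$I_dilute >= 0)
      render(channel2$I_dense, channel2$I_dilute)
    } else NULL
    dark <- {
      d <- matrix(spec$camera_offset, spec$shape[1], spec$shape[2])
      if (spec$noise_sd > 0) {
        d <- d + matrix(stats::rnorm(length(d), 0, spec$noise_sd),
                        nrow(d), ncol(d))
      }
      image2d(pmax(d, 0))
    }
    rc_of <- function(I_dense, I_dilute) {
      if (a_in == 0) 0 else
        a_in * I_dense / (a_in * I_dense + a_out * I_dilute)
    }
    truth <- list(
      pc = if (spec$I_dilute > 0) spec$I_dense / spec$I_dilute else NA_real_,
      rc = rc_of(spec$I_dense, spec$I_dilute),
      a_in = a_in, a_out = a_out,
      disks = disks,
      areas_px = if (nrow(disks)) tabulate(labels[inside], nrow(disks)) else integer(0),
      labels = labels)
    if (!is.null(channel2)) {
      truth$pc2 <- if (channel2$I_dilute > 0) {
        channel2$I_dense / channel2$I_dilute
      } else NA_real_
      truth$rc2 <- rc_of(channel2$I_dense, channel2$I_dilute)
    }
    list(image = img, channel2 = img2, dark = dark, truth = truth)
  })
}

#' Synthetic FRAP-trace specification
#'
#' Parameters of a simulated bleach-and-recover acquisition. The underlying
#' normalized recovery is 1 before the bleach and
#' `plateau - (plateau - f0) exp(-t'/tau_s)` after it; the observed bleach
#' signal is this curve times a per-frame multiplicative acquisition-bleach
#' factor and an arbitrary intensity scale, plus background and Gaussian
#' noise. The reference region sees the same acquisition bleaching, which is
#' what the double normalization removes.
#'
#' Defaults emulate a live-cell acquisition of 2 s/frame for 120 frames;
#' in vitro droplet acquisitions (30 ms/frame, 40 frames) or faster cell
#' protocols (1 s/frame, 60 frames) are obtained by changing
#' `frame_interval_s` and `n_frames`.
#'
#' @param f0 Normalized signal immediately after the bleach (`[0, 1]`).
#' @param plateau Recovery asymptote on the normalized scale
#'   (`f0 <= plateau <= 1`).
#' @param tau_s Recovery time constant (seconds, > 0).
#' @param frame_interval_s Seconds per frame (default 2).
#' @param n_frames Total frames including pre-bleach (default 120).
#' @param n_prebleach Pre-bleach frames (>= 1, default 5).
#' @param acquisition_bleach_rate Per-frame multiplicative decay of the
#'   illumination (default 0).
#' @param BG_level Background counts added to all regions (default 50).
#' @param scale,scale_ref Intensity scales of the bleach and reference
#'   regions in counts (defaults 1000 and 800).
#' @param noise_sd Gaussian noise sd in counts (default 0).
#' @param seed Integer seed.
#' @return A `frap_trace_spec` object.
#' @export
frap_trace_spec <- function(f0 = 0.3, plateau = 0.7, tau_s = 10,
                            frame_interval_s = 2, n_frames = 120L,
                            n_prebleach = 5L, acquisition_bleach_rate = 0,
                            BG_level = 50, scale = 1000, scale_ref = 800,
                            noise_sd = 0, seed = 1L) {
  stopifnot(f0 >= 0, f0 <= plateau, plateau <= 1, tau_s > 0,
            frame_interval_s > 0, n_frames >= n_prebleach + 5,
            n_prebleach >= 1,
            acquisition_bleach_rate >= 0, acquisition_bleach_rate < 1,
            BG_level >= 0, scale > 0, scale_ref > 0, noise_sd >= 0)
  structure(list(f0 = f0, plateau = plateau, tau_s = tau_s,
                 frame_interval_s = frame_interval_s,
                 n_frames = as.integer(n_frames),
                 n_prebleach = as.integer(n_prebleach),
                 acquisition_bleach_rate = acquisition_bleach_rate,
                 BG_level = BG_level, scale = scale, scale_ref = scale_ref,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "frap_trace_spec")
}

#' Generate a synthetic FRAP trace with ground truth
#'
#' @param spec A [frap_trace_spec()].
#' @param trace_id Optional trace label.
#' @return List with `trace` (a [frap_trace()]) and `truth` (list: `f0`,
#'   `plateau`, `tau_s`, `mobile_fraction`, and the noise-free normalized
#'   recovery `u`).
#' @export
gen_frap_trace <- function(spec, trace_id = NULL) {
  stopifnot(inherits(spec, "frap_trace_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n_frames
    t <- (seq_len(n) - 1) * spec$frame_interval_s
    bleach_index <- spec$n_prebleach + 1L
    u <- rep(1, n)
    post <- bleach_index:n
    tp <- t[post] - t[post[1]]
    u[post] <- spec$plateau - (spec$plateau - spec$f0) * exp(-tp / spec$tau_s)
    s <- (1 - spec$acquisition_bleach_rate)^(seq_len(n) - 1)
    noise <- function() if (spec$noise_sd > 0) {
      stats::rnorm(n, 0, spec$noise_sd)
    } else rep(0, n)
    BL <- u * s * spec$scale + spec$BG_level + noise()
    REF <- s * spec$scale_ref + spec$BG_level + noise()
    BG <- rep(spec$BG_level, n)
    trace <- frap_trace(t, BL, REF, BG, bleach_index = bleach_index,
                        trace_id = trace_id)
    truth <- list(f0 = spec$f0, plateau = spec$plateau, tau_s = spec$tau_s,
                  mobile_fraction = (spec$plateau - spec$f0) / (1 - spec$f0),
                  u = u)
    list(trace = trace, truth = truth)
  })
}

#' Generate a synthetic puncta-dissolution stack with ground truth
#'
#' Places `n0` non-overlapping puncta in the first frame; each punctum then
#' independently survives each frame interval with probability
#' `exp(-lambda_per_s * interval_s)` (first-order dissolution). Survivors
#' are rendered as hard-edged disks. The ground truth is the analytic
#' expected survival `exp(-lambda * t)` together with the realized
#' per-frame survivor counts.
#'
#' @param n0 Initial number of puncta (>= 1).
#' @param lambda_per_s Dissolution rate (per second, >= 0).
#' @param n_frames Number of frames (default 8).
#' @param interval_s Seconds per frame (default 10).
#' @param shape Frame shape in pixels (default `c(128, 128)`).
#' @param radius_px Punctum radius (default 3).
#' @param I_dense,I_dilute Punctum and background intensities (defaults 100
#'   and 10).
#' @param noise_sd Gaussian noise sd (default 0).
#' @param seed Integer seed.
#' @return List with `stack` (an [image_stack()], frame 1 at the treatment
#'   time) and `truth` (list: `lambda_per_s`, `t`, `expected_survival`,
#'   `counts`).
#' @export
gen_dissolution_stack <- function(n0, lambda_per_s, n_frames = 8L,
                                  interval_s = 10, shape = c(128L, 128L),
                                  radius_px = 3L, I_dense = 100,
                                  I_dilute = 10, noise_sd = 0, seed = 1L) {
  stopifnot(n0 >= 1, lambda_per_s >= 0, n_frames >= 2, interval_s > 0)
  withr::with_seed(as.integer(seed), {
    disks <- place_disks(shape, n0, c(radius_px, radius_px))
    p_survive <- exp(-lambda_per_s * interval_s)
    alive <- matrix(FALSE, n0, n_frames)
    alive[, 1] <- TRUE
    for (f in 2:n_frames) {
      alive[, f] <- alive[, f - 1] & (stats::runif(n0) < p_survive)
    }
    frames <- lapply(seq_len(n_frames), function(f) {
      px <- matrix(I_dilute, shape[1], shape[2])
      for (i in which(alive[, f])) {
        px[rasterize_disk(shape, c(disks$row[i], disks$col[i]),
                          disks$radius[i])] <- I_dense
      }
      if (noise_sd > 0) {
        px <- px + matrix(stats::rnorm(length(px), 0, noise_sd),
                          nrow(px), ncol(px))
      }
      image2d(pmax(px, 0))
    })
    t <- (seq_len(n_frames) - 1) * interval_s
    list(stack = image_stack(frames, frame_interval_s = interval_s),
         truth = list(lambda_per_s = lambda_per_s, t = t,
                      expected_survival = exp(-lambda_per_s * t),
                      counts = colSums(alive)))
  })
}

#' Generate a pair of synthetic gene sets with a known intersection
#'
#' Builds identifier sets with exactly `n_overlap` shared ids, for testing
#' overlap statistics without real proteome lists. Identifiers are labelled
#' as synthetic (`SYN-` prefix).
#'
#' @param n_query,n_reference Set sizes.
#' @param n_overlap Shared ids (`<= min(n_query, n_reference)`).
#' @param seed Integer seed (sets are shuffled for realism).
#' @param query_name,reference_name Set names.
#' @return List with `query` and `reference` ([normalize_ids()]-style
#'   `gene_set` objects).
#' @export
gen_gene_sets <- function(n_query, n_reference, n_overlap, seed = 1L,
                          query_name = "synthetic-query",
                          reference_name = "synthetic-reference") {
  stopifnot(n_query >= 1, n_reference >= 1, n_overlap >= 0)
  if (n_overlap > min(n_query, n_reference)) {
    stop("n_overlap exceeds a set size", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    shared <- sprintf("SYN-S%05d", seq_len(n_overlap))
    q_only <- sprintf("SYN-Q%05d", seq_len(n_query - n_overlap))
    r_only <- sprintf("SYN-R%05d", seq_len(n_reference - n_overlap))
    q <- sample(c(shared, q_only))
    r <- sample(c(shared, r_only))
    list(query = normalize_ids(q, name = query_name),
         reference = normalize_ids(r, name = reference_name))
  })
}
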