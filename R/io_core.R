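#' Calibrated 2-D fluorescence image
#'
#' Container for a single-channel intensity raster in detector counts.
#' Pixel coordinates are 0-based, row-major `(row, col)` throughout the
#' package. Intensities are unitless detector counts; the only photometric
#' calibration applied anywhere is dark-frame subtraction
#' (see [subtract_dark_frame()]).
#'
#' @param pixels Numeric matrix of non-negative, finite intensities.
#' @param pixel_size_um Optional physical pixel size (micrometres per pixel).
#' @param channel_name Optional channel label (e.g. `"GFP"`, `"Cy5"`).
#' @return An `image2d` object (a matrix with metadata attributes).
#' @examples
#' img <- image2d(matrix(10, 32, 32), pixel_size_um = 0.1, channel_name = "GFP")
#' dim(img)
#' @export
image2d <- function(pixels, pixel_size_um = NULL, channel_name = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(pixels))) {
    stop("image contains non-finite pixel values", call. = FALSE)
  }
  if (any(pixels < 0)) {
    stop("image contains negative intensities; calibrated counts must be >= 0",
         call. = FALSE)
  }
  if (!is.null(pixel_size_um)) {
    stopifnot(is.numeric(pixel_size_um), length(pixel_size_um) == 1L,
              pixel_size_um > 0)
  }
  structure(pixels,
            pixel_size_um = pixel_size_um,
            channel_name = channel_name,
            class = c("image2d", "matrix", "array"))
}

#' @export
print.image2d <- function(x, ...) {
  cat(sprintf("<image2d> %d x %d px", nrow(x), ncol(x)))
  if (!is.null(attr(x, "channel_name"))) {
    cat(sprintf(", channel %s", attr(x, "channel_name")))
  }
  if (!is.null(attr(x, "pixel_size_um"))) {
    cat(sprintf(", %.4g um/px", attr(x, "pixel_size_um")))
  }
  cat(sprintf(", range [%.4g, %.4g]\n", min(x), max(x)))
  invisible(x)
}

#' Is an object an image2d?
#' @param x Object to test.
#' @return Logical scalar.
#' @export
is_image2d <- function(x) inherits(x, "image2d")

#' Time-lapse image stack
#'
#' An ordered sequence of same-shape [image2d()] frames with a fixed frame
#' interval.
#'
#' @param frames List of `image2d` objects, all the same shape.
#' @param frame_interval_s Time between consecutive frames (seconds, > 0).
#' @return An `image_stack` object.
#' @export
image_stack <- function(frames, frame_interval_s) {
  if (!is.list(frames) || length(frames) == 0L) {
    stop("`frames` must be a non-empty list of image2d objects", call. = FALSE)
  }
  frames <- lapply(frames, function(f) if (is_image2d(f)) f else image2d(f))
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all frames in a stack must have the same shape", call. = FALSE)
  }
  stopifnot(is.numeric(frame_interval_s), length(frame_interval_s) == 1L,
            frame_interval_s > 0)
  structure(list(frames = frames, frame_interval_s = frame_interval_s),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<image_stack> %d frames of %d x %d px, %.4g s/frame\n",
              length(x$frames), d[1], d[2], x$frame_interval_s))
  invisible(x)
}

#' @export
length.image_stack <- function(x) length(x$frames)

#' Read a TIFF image or stack
#'
#' Reads an 8- or 16-bit TIFF. Single-page files become an [image2d()];
#' multi-page files become an [image_stack()] (page order taken as frame or
#' channel order). Pixel values are returned as raw integer detector counts,
#' not rescaled to `[0, 1]`.
#'
#' @param path Path to a TIFF file.
#' @param frame_interval_s Frame interval to attach when the file is
#'   multi-page (seconds). Default 1.
#' @param pixel_size_um Optional pixel size to attach.
#' @param channel_name Optional channel label.
#' @return An `image2d` or `image_stack`.
#' @export
read_image <- function(path, frame_interval_s = 1, pixel_size_um = NULL,
                       channel_name = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("image file not found: %s", path), call. = FALSE)
  }
  pages <- tryCatch(
    suppressWarnings(tiff::readTIFF(path, all = TRUE, as.is = TRUE)),
    error = function(e) {
      stop(sprintf("cannot read TIFF '%s': %s", path, conditionMessage(e)),
           call. = FALSE)
    })
  if (length(pages) == 0L) {
    stop(sprintf("cannot read TIFF '%s': no image pages", path), call. = FALSE)
  }
  to_img <- function(m) {
    if (length(dim(m)) == 3L) m <- m[, , 1]  # drop extra samples per pixel
    image2d(m * 1.0, pixel_size_um = pixel_size_um, channel_name = channel_name)
  }
  if (length(pages) == 1L) {
    to_img(pages[[1]])
  } else {
    image_stack(lapply(pages, to_img), frame_interval_s = frame_interval_s)
  }
}

#' Write an image or label raster to TIFF
#'
#' Writes integer detector counts (or droplet labels) as 8- or 16-bit TIFF.
#' Values are clamped to the representable range of the chosen bit depth.
#'
#' @param image An `image2d`, numeric/integer matrix, or `image_stack`.
#' @param path Output path.
#' @param bits Bits per sample, 8 or 16 (default 16).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, bits = 16) {
  stopifnot(bits %in% c(8, 16))
  maxv <- 2^bits - 1
  norm <- function(m) {
    m <- pmin(pmax(round(unclass(m)), 0), maxv)
    m / maxv
  }
  pages <- if (inherits(image, "image_stack")) {
    lapply(image$frames, norm)
  } else {
    norm(image)
  }
  ok <- tryCatch({tiff::writeTIFF(pages, path, bits.per.sample = bits); TRUE},
                 error = function(e) {
                   stop(sprintf("cannot write TIFF '%s': %s", path,
                                conditionMessage(e)), call. = FALSE)
                 })
  invisible(path)
}

#' Run configuration
#'
#' Bundles the segmentation/fit parameters and RNG seed of an analysis run so
#' that outputs can record them. The configuration hash and the seed are
#' attached as columns by [write_table()].
#'
#' @param seed Integer RNG seed.
#' @param mask_params A [mask_params()] object.
#' @param fit_params Named list of fit options (free-form).
#' @param out_dir Output directory.
#' @return A `run_config` object.
#' @export
run_config <- function(seed = 1L, mask_params = condquant::mask_params(),
                       fit_params = list(), out_dir = ".") {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  cfg <- structure(list(seed = as.integer(seed), mask_params = mask_params,
                        fit_params = fit_params, out_dir = out_dir),
                   class = "run_config")
  cfg
}

#' Short stable hash of a run configuration
#'
#' Polynomial rolling hash over the deparsed configuration; stable across
#' sessions for the same parameter values.
#'
#' @param config A [run_config()] (or any R object).
#' @return An 8-hex-digit character scalar.
#' @export
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write a results table to CSV with full precision
#'
#' Writes a data frame as UTF-8 comma-separated text with a header row.
#' Doubles are rendered with 17 significant digits so that re-reading
#' reproduces them bit-identically. When a [run_config()] is supplied, `seed`
#' and `config_hash` columns are appended so every results table records its
#' provenance.
#'
#' @param records Data frame of results.
#' @param path Output path.
#' @param config Optional [run_config()] whose seed/hash are recorded.
#' @param allow_empty Allow writing a zero-row table (default FALSE).
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path, config = NULL, allow_empty = FALSE) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L && !allow_empty) {
    stop("refusing to write an empty results table (set allow_empty = TRUE)",
         call. = FALSE)
  }
  if (!is.null(config)) {
    records$seed <- if (inherits(config, "run_config")) config$seed else NA_integer_
    records$config_hash <- config_hash(config)
  }
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- out[[j]]
      s <- sprintf("%.17g", v)
      s[is.na(v)] <- NA_character_
      out[[j]] <- s
    }
  }
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8", na = "NA")
    TRUE
  }, error = function(e) {
    stop(sprintf("cannot write table '%s': %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  invisible(path)
}

#' Read a results table written by [write_table()]
#'
#' @param path CSV path.
#' @return Data frame with numeric columns restored.
#' @export
read_table <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("table not found: %s", path), call. = FALSE)
  }
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
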