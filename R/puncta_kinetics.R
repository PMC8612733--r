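#' Count fluorescent puncta in a frame
#'
#' Number of connected objects found by [make_droplet_mask()] on a
#' dark-corrected frame. Touching puncta merged by 8-connectivity count as
#' one object.
#'
#' @param frame Dark-corrected [image2d()].
#' @param params A [mask_params()].
#' @return Integer count.
#' @export
count_puncta <- function(frame, params = mask_params()) {
  make_droplet_mask(frame, params)$n_droplets
}

#' Puncta survival curve after a treatment
#'
#' Counts puncta in every frame of a time-lapse stack and normalizes to the
#' count at the treatment frame, which defines time 0 (e.g. the moment of
#' hexanediol addition). Frames before `t0_index` are reported with negative
#' time and a survival value of `NA`; they do not enter the normalization.
#' There is no frame-to-frame identity tracking: "surviving puncta" is the
#' per-frame object count relative to time 0.
#'
#' @param stack An [image_stack()].
#' @param t0_index 1-based index of the treatment frame (time 0).
#' @param params A [mask_params()].
#' @return A `dissolution_series`: data frame with columns `frame`, `t`
#'   (seconds from treatment), `counts`, `survival`.
#' @export
survival_curve <- function(stack, t0_index, params = mask_params()) {
  stopifnot(inherits(stack, "image_stack"))
  n <- length(stack$frames)
  t0_index <- as.integer(t0_index)
  if (t0_index < 1L || t0_index > n) {
    stop("t0_index outside the stack", call. = FALSE)
  }
  counts <- vapply(stack$frames, count_puncta, integer(1), params = params)
  if (counts[t0_index] == 0L) {
    stop("zero puncta at the treatment frame; survival undefined",
         call. = FALSE)
  }
  t <- (seq_len(n) - t0_index) * stack$frame_interval_s
  survival <- ifelse(t >= 0, counts / counts[t0_index], NA_real_)
  out <- data.frame(frame = seq_len(n), t = t, counts = counts,
                    survival = survival)
  class(out) <- c("dissolution_series", "data.frame")
  out
}

#' Dissolution rate and half-life from a survival curve
#'
#' Estimates a first-order dissolution rate by a log-linear least-squares fit
#' of `log(counts)` against time over the post-treatment frames with nonzero
#' counts, and reports the half-life `ln(2) / lambda`.
#'
#' @param series A [survival_curve()] result (or data frame with `t`,
#'   `counts`).
#' @return List with `lambda_per_s` and `half_life_s` (both `NA` when fewer
#'   than two usable frames or when counts do not decay).
#' @export
dissolution_half_life <- function(series) {
  d <- series[series$t >= 0 & series$counts > 0, , drop = FALSE]
  if (nrow(d) < 2L) {
    return(list(lambda_per_s = NA_real_, half_life_s = NA_real_))
  }
  fit <- stats::lm(log(counts) ~ t, data = d)
  lambda <- -unname(stats::coef(fit)[2])
  if (!is.finite(lambda) || lambda <= 0) {
    return(list(lambda_per_s = NA_real_, half_life_s = NA_real_))
  }
  list(lambda_per_s = lambda, half_life_s = log(2) / lambda)
}
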