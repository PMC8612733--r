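#' FRAP region-mean intensity trace
#'
#' Raw mean intensities of the bleach (`BL`), reference (`REF`) and
#' background (`BG`) regions of a photobleaching acquisition, with the frame
#' bookkeeping needed for correction: `bleach_index` is the (1-based) index
#' of the first post-bleach frame and `prebleach_indices` are the frames
#' averaged to define 100 % fluorescence.
#'
#' @param t Time points (seconds), strictly increasing.
#' @param BL,REF,BG Numeric vectors, same length as `t`.
#' @param bleach_index Index of the first post-bleach frame (>= 2).
#' @param prebleach_indices Frames used for the pre-bleach mean; defaults to
#'   every frame before `bleach_index`.
#' @param trace_id Optional label.
#' @return A `frap_trace` object.
#' @export
frap_trace <- function(t, BL, REF, BG, bleach_index,
                       prebleach_indices = seq_len(bleach_index - 1L),
                       trace_id = NULL) {
  n <- length(t)
  if (length(BL) != n || length(REF) != n || length(BG) != n) {
    stop("t, BL, REF, BG must have equal lengths", call. = FALSE)
  }
  if (n < 2L || any(diff(t) <= 0)) {
    stop("t must be strictly increasing with at least 2 frames", call. = FALSE)
  }
  bleach_index <- as.integer(bleach_index)
  if (bleach_index < 2L || bleach_index > n) {
    stop("bleach_index must lie in [2, length(t)]", call. = FALSE)
  }
  prebleach_indices <- as.integer(prebleach_indices)
  if (length(prebleach_indices) == 0L || any(prebleach_indices < 1L) ||
      any(prebleach_indices >= bleach_index)) {
    stop("prebleach_indices must be non-empty and all before bleach_index",
         call. = FALSE)
  }
  structure(list(t = as.numeric(t), BL = as.numeric(BL),
                 REF = as.numeric(REF), BG = as.numeric(BG),
                 bleach_index = bleach_index,
                 prebleach_indices = prebleach_indices,
                 trace_id = trace_id),
            class = "frap_trace")
}

#' @export
print.frap_trace <- function(x, ...) {
  cat(sprintf("<frap_trace>%s %d frames, bleach at frame %d (t = %.4g s)\n",
              if (is.null(x$trace_id)) "" else paste0(" ", x$trace_id),
              length(x$t), x$bleach_index, x$t[x$bleach_index]))
  invisible(x)
}

#' Double-normalize a FRAP trace
#'
#' Corrects the bleach-region signal for background and for acquisition
#' photobleaching using the reference region, then normalizes to the
#' pre-bleach level:
#' \deqn{BL_{corr2}(t) = \frac{BL(t) - BG(t)}{REF(t) - BG(t)}}
#' \deqn{BL_{corr3}(t) = \frac{BL_{corr2}(t)}{\langle BL_{corr2}\rangle_{pre}}}
#' so the pre-bleach mean of `BL_corr3` is exactly 1 and any multiplicative
#' acquisition bleaching shared by BL and REF cancels.
#'
#' @param trace A [frap_trace()].
#' @return A `corrected_trace`: list with `t`, `BL_corr2`, `BL_corr3`,
#'   `bleach_index`, `prebleach_indices`, `trace_id`.
#' @export
correct_trace <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  denom <- trace$REF - trace$BG
  bad <- which(denom <= 0)
  if (length(bad)) {
    stop(sprintf("REF <= BG at frame %d: reference correction undefined",
                 bad[1]), call. = FALSE)
  }
  bl2 <- (trace$BL - trace$BG) / denom
  pre <- mean(bl2[trace$prebleach_indices])
  if (!is.finite(pre) || pre == 0) {
    stop("pre-bleach mean of corrected signal is zero; cannot normalize",
         call. = FALSE)
  }
  structure(list(t = trace$t, BL_corr2 = bl2, BL_corr3 = bl2 / pre,
                 bleach_index = trace$bleach_index,
                 prebleach_indices = trace$prebleach_indices,
                 trace_id = trace$trace_id),
            class = "corrected_trace")
}

#' Fit a single-exponential recovery to a corrected FRAP trace
#'
#' Least-squares fit of
#' \deqn{f(t') = plateau - (plateau - f_0)\, e^{-t'/\tau}}
#' on the post-bleach frames, with `t'` measured from the first post-bleach
#' frame (the bleach frame itself is the first fitted point, at `t' = 0`).
#' By default `f0` is pinned to the first post-bleach observation; set
#' `fix_f0 = FALSE` to fit it freely. The mobile fraction is
#' `(plateau - f0) / (1 - f0)` on the pre-bleach-normalized scale.
#'
#' A post-bleach trace that is flat (no recovery signal) returns
#' `mobile_fraction = 0` with `flag = "flat"` and `tau_s = NA`; a fitted
#' plateau below `f0` is reported with `mobile_fraction = 0` and
#' `flag = "plateau-below-f0"`.
#'
#' @param corrected A [correct_trace()] result.
#' @param fix_f0 Pin `f0` to the first post-bleach point (default TRUE).
#' @return A `frap_fit`: list with `f0`, `plateau`, `tau_s`, `half_time_s`,
#'   `mobile_fraction`, `residual_rms`, `flag`, `trace_id`.
#' @export
fit_recovery <- function(corrected, fix_f0 = TRUE) {
  stopifnot(inherits(corrected, "corrected_trace"))
  post <- corrected$bleach_index:length(corrected$t)
  if (length(post) < 5L) {
    stop("need at least 5 post-bleach frames to fit a recovery", call. = FALSE)
  }
  tp <- corrected$t[post] - corrected$t[post[1]]
  y <- corrected$BL_corr3[post]
  f0_obs <- y[1]
  mk_fit <- function(f0, plateau, tau, resid, flag) {
    mobile <- if (is.na(tau) || plateau <= f0) 0 else (plateau - f0) / (1 - f0)
    mobile <- min(max(mobile, 0), 1)
    structure(list(f0 = f0, plateau = plateau, tau_s = tau,
                   half_time_s = if (is.na(tau)) NA_real_ else tau * log(2),
                   mobile_fraction = mobile,
                   residual_rms = resid, flag = flag,
                   trace_id = corrected$trace_id),
              class = "frap_fit")
  }
  if (diff(range(y)) < 1e-12) {
    return(mk_fit(f0_obs, f0_obs, NA_real_, 0, "flat"))
  }
  plateau0 <- mean(utils::tail(y, max(3L, ceiling(length(y) / 5))))
  # time at which the curve crosses 63% of the apparent recovery
  tau0 <- {
    target <- f0_obs + (plateau0 - f0_obs) * (1 - exp(-1))
    k <- which(y >= target)[1]
    if (is.na(k) || k <= 1L || tp[k] <= 0) max(tp) / 3 else tp[k]
  }
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- max(tp) / 3
  fit <- tryCatch({
    if (fix_f0) {
      f0 <- f0_obs
      minpack.lm::nlsLM(y ~ plateau - (plateau - f0) * exp(-tp / tau),
                        start = list(plateau = plateau0, tau = tau0),
                        lower = c(plateau = -Inf, tau = 1e-9),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(y ~ plateau - (plateau - f0) * exp(-tp / tau),
                        start = list(plateau = plateau0, f0 = f0_obs,
                                     tau = tau0),
                        lower = c(plateau = -Inf, f0 = -Inf, tau = 1e-9),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) {
    stop(sprintf("recovery fit did not converge: %s [n_post = %d, f0 = %.4g, plateau start = %.4g]",
                 conditionMessage(e), length(y), f0_obs, plateau0),
         call. = FALSE)
  })
  cf <- stats::coef(fit)
  f0 <- if (fix_f0) f0_obs else unname(cf["f0"])
  plateau <- unname(cf["plateau"])
  tau <- unname(cf["tau"])
  resid <- sqrt(mean(stats::residuals(fit)^2))
  flag <- if (plateau < f0) "plateau-below-f0" else NA_character_
  mk_fit(f0, plateau, tau, resid, flag)
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf(
    "<frap_fit>%s f0 = %.3f, plateau = %.3f, tau = %.3g s (t1/2 = %.3g s), mobile fraction = %.3f\n",
    if (is.null(x$trace_id)) "" else paste0(" ", x$trace_id),
    x$f0, x$plateau, x$tau_s, x$half_time_s, x$mobile_fraction))
  invisible(x)
}

#' @export
as.data.frame.frap_fit <- function(x, ...) {
  data.frame(trace_id = if (is.null(x$trace_id)) NA_character_ else x$trace_id,
             f0 = x$f0, plateau = x$plateau, tau_s = x$tau_s,
             half_time_s = x$half_time_s, mobile_fraction = x$mobile_fraction,
             residual_rms = x$residual_rms, flag = x$flag)
}

#' Evaluate a fitted recovery curve
#'
#' Normalized fluorescence predicted at time `t_s` after the bleach:
#' `f0 + (plateau - f0) * (1 - exp(-t_s / tau))`. A flat fit returns `f0`.
#'
#' @param fit A [fit_recovery()] result.
#' @param t_s Time since bleach (seconds, >= 0); vectorized.
#' @return Numeric vector of normalized intensities.
#' @export
recovery_at <- function(fit, t_s) {
  stopifnot(inherits(fit, "frap_fit"), all(t_s >= 0))
  if (is.na(fit$tau_s)) return(rep(fit$f0, length(t_s)))
  fit$f0 + (fit$plateau - fit$f0) * (1 - exp(-t_s / fit$tau_s))
}

#' Fit a batch of FRAP traces and average the corrected curves
#'
#' Corrects and fits each trace, then averages the normalized curves across
#' traces at each time point with the standard error of the mean. All traces
#' must share a common time base.
#'
#' @param traces List of [frap_trace()] objects.
#' @param fix_f0 Passed to [fit_recovery()].
#' @return List with `fits` (one data-frame row per trace) and `curve`
#'   (data frame: `t`, `mean`, `se`, `n`). With a single trace `se` is `NA`
#'   and the curve carries `flag = "single-trace"`.
#' @export
batch_fit <- function(traces, fix_f0 = TRUE) {
  if (length(traces) < 1L) stop("need at least one trace", call. = FALSE)
  t0 <- traces[[1]]$t
  same <- vapply(traces, function(tr) {
    length(tr$t) == length(t0) && all(tr$t == t0)
  }, TRUE)
  if (!all(same)) {
    stop("traces have incompatible time bases; resample to a common one first",
         call. = FALSE)
  }
  corrected <- lapply(traces, correct_trace)
  fits <- lapply(corrected, fit_recovery, fix_f0 = fix_f0)
  fits_df <- do.call(rbind, lapply(fits, as.data.frame))
  if (all(is.na(fits_df$trace_id))) {
    fits_df$trace_id <- sprintf("trace%02d", seq_along(traces))
  }
  mat <- do.call(cbind, lapply(corrected, function(ct) ct$BL_corr3))
  curve <- data.frame(
    t = t0,
    mean = rowMeans(mat),
    se = if (ncol(mat) >= 2) apply(mat, 1, stats::sd) / sqrt(ncol(mat)) else NA_real_,
    n = ncol(mat))
  attr(curve, "flag") <- if (ncol(mat) == 1L) "single-trace" else NA_character_
  list(fits = fits_df, curve = curve)
}
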