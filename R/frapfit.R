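# FRAP analysis: trace normalization with photofading correction and
# mono-exponential recovery fitting.

#' FRAP trace container
#'
#' Bleach-ROI and whole-image mean intensities over time, with the count
#' of prebleach frames.
#'
#' @param times seconds from the first frame, strictly increasing.
#' @param roi_intensity mean intensity in the bleach ROI per frame.
#' @param whole_image_intensity mean intensity of the full frame per
#'   frame (used for photofading correction).
#' @param n_prebleach number of frames acquired before the bleach (>= 1;
#'   default 3).
#' @return An object of class `frap_trace`.
#' @export
frap_trace <- function(times, roi_intensity, whole_image_intensity,
                       n_prebleach = 3L) {
  n <- length(times)
  if (length(roi_intensity) != n || length(whole_image_intensity) != n) {
    stop("trace arrays must have equal length", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  n_prebleach <- as.integer(n_prebleach)
  if (n_prebleach < 1L || n_prebleach >= n) {
    stop("`n_prebleach` must be >= 1 and leave post-bleach frames",
         call. = FALSE)
  }
  structure(list(times = as.numeric(times),
                 roi_intensity = as.numeric(roi_intensity),
                 whole_image_intensity = as.numeric(whole_image_intensity),
                 n_prebleach = n_prebleach),
            class = "frap_trace")
}

#' @export
print.frap_trace <- function(x, ...) {
  cat(sprintf("<frap_trace> %d frames (%d prebleach), t = %.1f..%.1f s\n",
              length(x$times), x$n_prebleach, min(x$times), max(x$times)))
  invisible(x)
}

#' Normalize a FRAP trace with photofading correction
#'
#' Computes `f_norm(t) = [roi(t) / roi_pre] * [whole_pre / whole(t)]`,
#' where `roi_pre` and `whole_pre` are means over the prebleach frames
#' (the first three by convention): the prebleach signal defines 100%,
#' and dividing by the relative whole-image intensity removes
#' acquisition fading.  Because the correction is a ratio, any fading
#' common to ROI and whole image cancels exactly.  Prebleach frames are
#' excluded from the output; post-bleach times are measured from the
#' bleach event (taken at the last prebleach frame).
#'
#' @param trace a [frap_trace()] object.
#' @return An object of class `normalized_trace`: list with `times_post`
#'   and `f_norm`.
#' @export
normalize_trace <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  if (any(trace$whole_image_intensity <= 0)) {
    stop("whole-image intensities must be positive (division guard)",
         call. = FALSE)
  }
  pre <- seq_len(trace$n_prebleach)
  roi_pre <- mean(trace$roi_intensity[pre])
  whole_pre <- mean(trace$whole_image_intensity[pre])
  if (whole_pre <= 0 || roi_pre <= 0) {
    stop("prebleach means must be positive", call. = FALSE)
  }
  post <- (trace$n_prebleach + 1L):length(trace$times)
  t_bleach <- trace$times[trace$n_prebleach]
  f <- (trace$roi_intensity[post] / roi_pre) *
    (whole_pre / trace$whole_image_intensity[post])
  structure(list(times_post = trace$times[post] - t_bleach, f_norm = f),
            class = "normalized_trace")
}

#' @export
print.normalized_trace <- function(x, ...) {
  cat(sprintf("<normalized_trace> %d post-bleach points, t = %.1f..%.1f s\n",
              length(x$times_post), min(x$times_post), max(x$times_post)))
  invisible(x)
}

#' Fit a mono-exponential FRAP recovery
#'
#' Least-squares fit of `F(t) = plateau - (plateau - floor) * exp(-k t)`
#' to the normalized post-bleach trace.  The floor (intensity at the
#' bleach) is fitted rather than pinned to the first post-bleach sample,
#' reducing sensitivity to single-frame noise.  The initializer is
#' deterministic: floor from the first post-bleach value, plateau from
#' the mean of the last three points, and k from the time at which the
#' trace first crosses the midpoint of that span (linear interpolation),
#' so refitting the same data always gives the same answer.
#'
#' Reported quantities: recovery rate `rate_k` (per second), half-time
#' `t_half = ln 2 / rate_k`, `plateau`, `floor`, percentage mobile
#' fraction `100 * (plateau - floor) / (1 - floor)` (the recovered span
#' over the bleached span), and residual RMS.  A trace whose fitted
#' plateau does not exceed its floor is flagged `non_recovering`; mobile
#' fractions outside [0, 100] are clipped and flagged.
#'
#' @param norm a [normalized_trace()] from [normalize_trace()], with at
#'   least 4 post-bleach points and a first value below 1.
#' @return An object of class `frap_fit` with `print`, `summary`,
#'   `coef`, `predict`, `residuals` and `plot` methods.
#' @examples
#' tr <- make_frap_series(frap_truth(rate_k = 0.0231, mobile_fraction = 0.75,
#'                                   postbleach_floor = 0.2), n_post = 36)
#' fit <- fit_recovery(normalize_trace(tr))
#' coef(fit)
#' @export
fit_recovery <- function(norm) {
  stopifnot(inherits(norm, "normalized_trace"))
  t <- norm$times_post
  y <- norm$f_norm
  if (length(t) < 4L) {
    stop("at least 4 post-bleach points are required", call. = FALSE)
  }
  if (y[1] >= 1) {
    stop("first post-bleach value is not below the prebleach level; not a bleach trace",
         call. = FALSE)
  }
  floor0 <- y[1]
  plateau0 <- mean(utils::tail(y, 3))
  mid <- floor0 + 0.5 * (plateau0 - floor0)
  k0 <- local({
    above <- which(y >= mid)
    if (plateau0 <= floor0 || length(above) == 0L) {
      log(2) / (t[length(t)] / 2)
    } else {
      i <- above[1]
      t_mid <- if (i == 1L) t[1] else {
        t[i - 1] + (mid - y[i - 1]) / (y[i] - y[i - 1]) * (t[i] - t[i - 1])
      }
      log(2) / max(t_mid, t[1] / 2)
    }
  })
  if (stats::sd(y) < 1e-10 || abs(plateau0 - floor0) < 1e-10) {
    # flat trace: no recovery signal; report the degenerate fit directly
    level <- mean(y)
    res <- y - level
    return(structure(list(rate_k = k0, t_half = log(2) / k0,
                          plateau = level, floor = level,
                          mobile_fraction_pct = 0, mobile_fraction_raw = 0,
                          non_recovering = TRUE, clipped = FALSE,
                          residual_rms = sqrt(mean(res^2)),
                          times_post = t, f_norm = y, nls = NULL),
                     class = "frap_fit"))
  }
  dat <- data.frame(t = t, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ plateau - (plateau - fl) * exp(-k * t),
                      data = dat,
                      start = list(plateau = plateau0, fl = floor0, k = k0),
                      lower = c(-Inf, -Inf, 1e-8),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      stop(sprintf("FRAP fit failed to converge: %s (last initializer: plateau=%.4g, floor=%.4g, k=%.4g)",
                   conditionMessage(e), plateau0, floor0, k0), call. = FALSE)
    })
  cf <- stats::coef(fit)
  plateau <- unname(cf["plateau"]); fl <- unname(cf["fl"]); k <- unname(cf["k"])
  mf_raw <- 100 * (plateau - fl) / (1 - fl)
  non_recovering <- plateau <= fl
  clipped <- mf_raw < 0 || mf_raw > 100
  res <- y - (plateau - (plateau - fl) * exp(-k * t))
  structure(list(rate_k = k, t_half = log(2) / k, plateau = plateau,
                 floor = fl,
                 mobile_fraction_pct = min(100, max(0, mf_raw)),
                 mobile_fraction_raw = mf_raw,
                 non_recovering = non_recovering, clipped = clipped,
                 residual_rms = sqrt(mean(res^2)),
                 times_post = t, f_norm = y, nls = fit),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat("Mono-exponential FRAP recovery fit\n")
  cat(sprintf("  rate k          : %.4g /s\n", x$rate_k))
  cat(sprintf("  t1/2            : %.4g s\n", x$t_half))
  cat(sprintf("  plateau / floor : %.4g / %.4g\n", x$plateau, x$floor))
  cat(sprintf("  mobile fraction : %.1f %%%s\n", x$mobile_fraction_pct,
              if (x$clipped) " (clipped)" else ""))
  if (x$non_recovering) cat("  flag: non-recovering trace (plateau <= floor)\n")
  cat(sprintf("  residual RMS    : %.3g (%d points)\n", x$residual_rms,
              length(x$times_post)))
  invisible(x)
}

#' @export
summary.frap_fit <- function(object, ...) {
  print(object)
  cat("\nUnderlying nonlinear least-squares fit:\n")
  print(summary(object$nls))
  invisible(object)
}

#' @export
coef.frap_fit <- function(object, ...) {
  c(rate_k = object$rate_k, t_half = object$t_half,
    plateau = object$plateau, floor = object$floor,
    mobile_fraction_pct = object$mobile_fraction_pct)
}

#' @export
predict.frap_fit <- function(object, times = object$times_post, ...) {
  object$plateau - (object$plateau - object$floor) *
    exp(-object$rate_k * times)
}

#' @export
residuals.frap_fit <- function(object, ...) {
  object$f_norm - predict(object)
}

#' @export
plot.frap_fit <- function(x, ...) {
  graphics::plot(x$times_post, x$f_norm, xlab = "time after bleach (s)",
                 ylab = "normalized intensity",
                 main = "FRAP recovery", ...)
  tt <- seq(0, max(x$times_post), length.out = 200)
  graphics::lines(tt, predict(x, tt))
  graphics::abline(h = x$plateau, lty = 3)
  invisible(x)
}

#' Bootstrap confidence interval for the FRAP recovery rate
#'
#' Resamples fit residuals with replacement, refits, and returns
#' percentile confidence limits for k.
#'
#' @param fit a `frap_fit` object.
#' @param n_boot bootstrap replicates (default 200).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return list with `k_lower`, `k_upper`, `k_boot` (replicate
#'   estimates; failed refits dropped).
#' @export
frap_boot_ci <- function(fit, n_boot = 200L, level = 0.95, seed = 1L) {
  stopifnot(inherits(fit, "frap_fit"))
  res <- residuals(fit)
  yhat <- predict(fit)
  ks <- with_seed(substream_seed(seed, "frapboot"), {
    vapply(seq_len(n_boot), function(i) {
      yb <- yhat + sample(res, length(res), replace = TRUE)
      nb <- structure(list(times_post = fit$times_post, f_norm = yb),
                      class = "normalized_trace")
      tryCatch(fit_recovery(nb)$rate_k, error = function(e) NA_real_)
    }, numeric(1))
  })
  ks <- ks[is.finite(ks)]
  alpha <- (1 - level) / 2
  q <- stats::quantile(ks, c(alpha, 1 - alpha), names = FALSE)
  list(k_lower = q[1], k_upper = q[2], k_boot = ks)
}

#' Extract a FRAP trace from an image stack
#'
#' Convenience helper: measures the mean intensity of a circular bleach
#' ROI (default 25 px diameter) and of the whole frame, per frame.
#'
#' @param frames list of [pixel_image()]s or matrices (time ordered).
#' @param roi_center 0-based (row, col) center of the bleach ROI.
#' @param roi_diameter ROI diameter in pixels (default 25).
#' @param frame_interval seconds between frames.
#' @param n_prebleach prebleach frame count.
#' @return A [frap_trace()] object.
#' @export
extract_frap_trace <- function(frames, roi_center, roi_diameter = 25,
                               frame_interval = 5, n_prebleach = 3L) {
  stopifnot(is.list(frames), length(frames) >= 2L)
  dims <- dim(as_matrix(frames[[1]]))
  pr <- matrix(rep(seq_len(dims[1]) - 1, dims[2]), dims[1], dims[2])
  pc <- matrix(rep(seq_len(dims[2]) - 1, each = dims[1]), dims[1], dims[2])
  roi <- (pr - roi_center[1])^2 + (pc - roi_center[2])^2 <= (roi_diameter / 2)^2
  if (!any(roi)) stop("bleach ROI contains no pixels", call. = FALSE)
  roi_m <- vapply(frames, function(f) mean(as_matrix(f)[roi]), numeric(1))
  whole_m <- vapply(frames, function(f) mean(as_matrix(f)), numeric(1))
  frap_trace(times = (seq_along(frames) - 1) * frame_interval,
             roi_intensity = roi_m, whole_image_intensity = whole_m,
             n_prebleach = n_prebleach)
}
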