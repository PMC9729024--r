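#' Denoising parameters
#'
#' Parameters of the keypoint denoising procedure: keypoints with
#' visibility below 0.5 are treated as outliers; then, per coordinate axis,
#' a point is flagged as an outlier when it deviates from the exponentially
#' weighted moving average (EMA) of the series by more than the
#' exponentially weighted moving standard deviation (EWMSD).  The EWM pass
#' is repeated five times; flagged entries are finally replaced by linear
#' interpolation over frame index.
#'
#' @param visibility_threshold Visibility below which a keypoint is an
#'   outlier (strict `<`); default 0.5.
#' @param window EWM window length in frames.  `NULL` (default) means
#'   "equal to the FPS of the video", resolved when [denoise()] is called.
#' @param n_iterations Number of EWM outlier passes; default 5.
#' @param sigma_multiplier Multiplier of the EWMSD in the outlier rule;
#'   default 1 (deviation greater than one EWMSD flags the point).
#' @return An object of class `denoise_params`.
#' @export
denoise_params <- function(visibility_threshold = 0.5, window = NULL,
                           n_iterations = 5, sigma_multiplier = 1) {
  if (visibility_threshold < 0 || visibility_threshold > 1)
    stop("'visibility_threshold' must lie in [0, 1]")
  if (!is.null(window) && (!is.finite(window) || window < 2))
    stop("'window' must be at least 2 frames")
  if (n_iterations < 1) stop("'n_iterations' must be at least 1")
  if (sigma_multiplier <= 0) stop("'sigma_multiplier' must be positive")
  structure(list(visibility_threshold = visibility_threshold,
                 window = window, n_iterations = n_iterations,
                 sigma_multiplier = sigma_multiplier),
            class = "denoise_params")
}

#' Video geometry policy (resize and rotation)
#'
#' Documents the geometry contract under which upstream pose estimation is
#' run: videos with height 1000 px or more are scaled to one third of their
#' height and width, videos below 1000 px to one half; and frames are
#' rotated so the participant's head points upward (the caller states where
#' the head points in the raw video).  This function does not touch pixel
#' data; it returns the policy for whoever runs the estimator.
#'
#' @param height,width Raw video size in pixels.
#' @param head_direction Where the head points in the raw video: `"up"`,
#'   `"left"`, `"down"` or `"right"`.
#' @return An object of class `geometry_policy` with fields `input_size`,
#'   `scale_factor` (1/3 or 1/2), `output_size` and `rotation` (degrees
#'   clockwise to apply so the head points upward).
#' @export
resize_policy <- function(height, width,
                          head_direction = c("up", "left", "down", "right")) {
  head_direction <- match.arg(head_direction)
  if (!is.finite(height) || !is.finite(width) || height <= 0 || width <= 0)
    stop("'height' and 'width' must be positive")
  scale <- if (height >= 1000) 1 / 3 else 1 / 2
  rotation <- c(up = 0, left = 90, down = 180, right = 270)[[head_direction]]
  structure(list(input_size = c(width = width, height = height),
                 scale_factor = scale,
                 output_size = c(width = width * scale, height = height * scale),
                 rotation = rotation),
            class = "geometry_policy")
}

#' Flag keypoints with low visibility
#'
#' @param traj A [keypoint_trajectory()].
#' @param params A [denoise_params()].
#' @return Logical frame-by-landmark matrix, `TRUE` where the visibility is
#'   strictly below the threshold.
#' @export
flag_low_visibility <- function(traj, params = denoise_params()) {
  stopifnot(inherits(traj, "keypoint_trajectory"))
  m <- traj$visibility < params$visibility_threshold
  m[is.na(m)] <- FALSE
  m
}

#' Exponentially weighted moving mean and standard deviation
#'
#' Causal (past-only) exponentially weighted statistics with the span
#' convention `alpha = 2 / (span + 1)`.  Weights decay per frame; missing
#' entries contribute neither value nor weight (the weights are
#' renormalised over the observations actually present).  The standard
#' deviation is bias-corrected; it is `NA` wherever fewer than two
#' effective observations are available.
#'
#' @param x Numeric vector, `NA` for missing.
#' @param span Window length (frames).
#' @return List with numeric vectors `mean` and `sd` aligned with `x`.
#' @export
ewm_stats <- function(x, span) {
  stopifnot(span >= 1)
  alpha <- 2 / (span + 1)
  beta <- 1 - alpha
  present <- as.numeric(!is.na(x))
  xv <- ifelse(is.na(x), 0, x)
  s0 <- as.numeric(stats::filter(present, beta, method = "recursive"))
  s1 <- as.numeric(stats::filter(xv, beta, method = "recursive"))
  s2 <- as.numeric(stats::filter(xv^2, beta, method = "recursive"))
  w2 <- as.numeric(stats::filter(present, beta^2, method = "recursive"))
  m <- ifelse(s0 > 0, s1 / s0, NA_real_)
  varb <- pmax(s2 / s0 - m^2, 0)
  denom <- 1 - w2 / s0^2
  sdv <- ifelse(s0 > 0 & denom > 0, sqrt(varb / denom), NA_real_)
  list(mean = m, sd = sdv)
}

#' One exponentially weighted outlier-rejection pass
#'
#' Marks entry `i` as an outlier when `|x_i - EMA_i| >
#' sigma_multiplier * EWMSD_i` (strict inequality).  Entries where the
#' EWMSD is undefined (warm-up) or zero are never flagged.  Already-missing
#' entries stay missing and are skipped, not imputed.
#'
#' @param x Numeric vector with `NA` for entries already removed.
#' @param params A [denoise_params()]; `params$window` must be set.
#' @return Logical missingness mask of the same length (`TRUE` = missing or
#'   newly flagged).  If the series is shorter than the window the input
#'   mask is returned unchanged with a warning.
#' @export
ewm_outlier_pass <- function(x, params) {
  mask <- is.na(x)
  if (length(x) < params$window) {
    warning("series shorter than the EWM window; pass skipped")
    return(mask)
  }
  st <- ewm_stats(x, params$window)
  dev <- abs(x - st$mean)
  new <- !mask & !is.na(st$sd) & st$sd > 0 &
    dev > params$sigma_multiplier * st$sd
  mask | new
}

interpolate_na <- function(x) {
  ok <- which(!is.na(x))
  if (length(ok) < 2) return(NULL)
  stats::approx(ok, x[ok], xout = seq_along(x), method = "linear",
                rule = 2)$y
}

#' Denoise a keypoint trajectory
#'
#' Applies, independently per landmark and per coordinate axis: (1) removal
#' of keypoints with visibility below the threshold, (2) `n_iterations`
#' passes of exponentially weighted outlier rejection
#' ([ewm_outlier_pass()]), and (3) linear interpolation of all removed
#' entries over frame index, with leading/trailing gaps filled by the
#' nearest valid value.  A pass that flags nothing ends the iteration early
#' (the result is identical to running all passes).
#'
#' @param traj A [keypoint_trajectory()].
#' @param params A [denoise_params()].  A `NULL` window defaults to
#'   `round(fps)`.
#' @return A [keypoint_trajectory()] with no missing coordinates.
#'   Interpolated entries have visibility 1 (their confidence semantics are
#'   gone).  The attribute `"denoise_log"` holds a per-landmark data frame
#'   with counts of low-visibility, EWM-flagged and interpolated entries.
#' @export
denoise <- function(traj, params = denoise_params()) {
  stopifnot(inherits(traj, "keypoint_trajectory"),
            inherits(params, "denoise_params"))
  if (is.null(params$window)) params$window <- max(2L, round(traj$fps))
  lowvis <- flag_low_visibility(traj, params)
  x <- traj$x; y <- traj$y; vis <- traj$visibility
  x[lowvis] <- NA_real_
  y[lowvis] <- NA_real_
  log <- data.frame(landmark = traj$landmarks,
                    n_low_visibility = colSums(lowvis),
                    n_ewm_flagged = 0L, n_interpolated = 0L,
                    row.names = NULL)
  for (j in seq_along(traj$landmarks)) {
    pre_missing <- sum(is.na(x[, j]) | is.na(y[, j]))
    for (axis in c("x", "y")) {
      s <- if (axis == "x") x[, j] else y[, j]
      for (it in seq_len(params$n_iterations)) {
        mask <- ewm_outlier_pass(s, params)
        if (sum(mask) == sum(is.na(s))) break
        s[mask] <- NA_real_
      }
      filled <- interpolate_na(s)
      if (is.null(filled))
        stop("landmark '", traj$landmarks[j],
             "' has fewer than 2 valid frames; cannot interpolate")
      if (axis == "x") x[, j] <- filled else y[, j] <- filled
    }
    post_missing <- 0L
    interp <- is.na(traj$x[, j]) | is.na(traj$y[, j]) | lowvis[, j] |
      (x[, j] != traj$x[, j]) | (y[, j] != traj$y[, j])
    interp[is.na(interp)] <- TRUE
    log$n_ewm_flagged[j] <- sum(interp) - pre_missing + post_missing
    log$n_interpolated[j] <- sum(interp)
    vis[interp, j] <- 1.0
  }
  out <- keypoint_trajectory(x, y, vis, fps = traj$fps,
                             landmarks = traj$landmarks,
                             image_size = traj$image_size)
  attr(out, "denoise_log") <- log
  out
}
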