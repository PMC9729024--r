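#' Parameters of the bird-dog trial simulator
#'
#' The simulator emulates a lateral-view bird-dog trial in image
#' coordinates (y down): the trunk lies horizontally with the shoulder at
#' smaller x and the hip at larger x, the lifted arm extends in the -x
#' direction from the shoulder and the lifted leg in +x from the hip.
#' Droop rotates both limbs below the horizontal (+y), bend flexes the
#' elbow/knee a further angle in the same direction, so in the noise-free
#' limit AG1 = 2 * droop_deg and AG2 = AG3 = 2 * (droop_deg + bend_deg)
#' exactly.  Limb keypoints sway around their nominal positions; the
#' shoulder and hip carry a small jitter proportional to the sway.  Frames
#' can suffer visibility dropout (visibility drawn in \[0.1, 0.4\] instead
#' of \[0.9, 1.0\], with corrupted coordinates) and sporadic large position
#' spikes.
#'
#' @param fps Frames per second; default 30.
#' @param duration_s Trial duration in seconds, in (0, 60\]; default 30.
#' @param trunk_length_px Nominal shoulder-hip distance in pixels;
#'   default 100.
#' @param sway_amplitude Per-frame RMS displacement of each limb keypoint
#'   as a fraction of the trunk length; default 0.01, which after
#'   denoising yields mean per-frame displacements (SPB1) of a few
#'   thousandths - the magnitude reported for real adult and child trials.
#' @param sway_process `"gaussian_walk_reverting"` (mean-reverting Gaussian
#'   walk, reversion rate 0.1 per frame; default) or
#'   `"sinusoid_plus_noise"` (circular oscillation of radius
#'   `sway_amplitude * t` at 0.25 Hz plus 5% noise, for closed-form
#'   checks).
#' @param droop_deg Mean depression of the limbs below horizontal,
#'   degrees; default 10.
#' @param bend_deg Mean additional elbow/knee flexion, degrees; default 10.
#' @param dropout_prob Per-frame, per-landmark probability of a visibility
#'   dropout; default 0.02.
#' @param outlier_prob Per-frame, per-limb-keypoint probability of a
#'   position spike; default 0.01.
#' @param outlier_magnitude_px Spike magnitude in pixels; default 50.
#' @param side Which arm is lifted; default `"left_arm_right_leg"`.
#' @param seed Integer seed fixing the full sample path, or `NULL` to use
#'   the current RNG state.
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(fps = 30, duration_s = 30,
                              trunk_length_px = 100,
                              sway_amplitude = 0.01,
                              sway_process = c("gaussian_walk_reverting",
                                               "sinusoid_plus_noise"),
                              droop_deg = 10, bend_deg = 10,
                              dropout_prob = 0.02, outlier_prob = 0.01,
                              outlier_magnitude_px = 50,
                              side = "left_arm_right_leg",
                              seed = NULL) {
  sway_process <- match.arg(sway_process)
  stopifnot(fps > 0, duration_s > 0, duration_s <= 60,
            trunk_length_px > 0, sway_amplitude >= 0,
            dropout_prob >= 0, dropout_prob <= 1,
            outlier_prob >= 0, outlier_prob <= 1,
            outlier_magnitude_px >= 0)
  structure(list(fps = fps, duration_s = duration_s,
                 trunk_length_px = trunk_length_px,
                 sway_amplitude = sway_amplitude,
                 sway_process = sway_process,
                 droop_deg = droop_deg, bend_deg = bend_deg,
                 dropout_prob = dropout_prob, outlier_prob = outlier_prob,
                 outlier_magnitude_px = outlier_magnitude_px,
                 side = side, seed = seed),
            class = "simulation_params")
}

mean_reverting_walk <- function(n, step_sd, rate = 0.1) {
  if (step_sd == 0) return(numeric(n))
  as.numeric(stats::filter(stats::rnorm(n, sd = step_sd), 1 - rate,
                           method = "recursive"))
}

#' Simulate one bird-dog trial
#'
#' Generates a noisy trajectory together with its clean ground truth (same
#' sway path, no dropout or spikes, all visibilities 1).  Fully
#' reproducible from `params$seed`.
#'
#' @param params A [simulation_params()].
#' @return Object of class `simulated_trial` with elements `trajectory`
#'   (noisy [keypoint_trajectory()]), `clean_trajectory` and `params`.
#' @export
simulate_trial <- function(params = simulation_params()) {
  stopifnot(inherits(params, "simulation_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  n <- max(2L, round(params$fps * params$duration_s))
  t_len <- params$trunk_length_px
  lm <- side_landmarks(params$side)
  sh0 <- c(300, 200)
  hp0 <- sh0 + c(t_len, 0)
  d <- params$droop_deg * pi / 180
  b <- (params$droop_deg + params$bend_deg) * pi / 180
  seg <- list(upper_arm = 0.6 * t_len, forearm = 0.6 * t_len,
              thigh = 0.8 * t_len, shank = 0.8 * t_len)
  el0 <- sh0 + seg$upper_arm * c(-cos(d), sin(d))
  wr0 <- el0 + seg$forearm * c(-cos(b), sin(b))
  kn0 <- hp0 + seg$thigh * c(cos(d), sin(d))
  an0 <- kn0 + seg$shank * c(cos(b), sin(b))

  jitter_sd <- 0.05 * params$sway_amplitude * t_len
  base <- list(shoulder = sh0, hip = hp0, elbow = el0, wrist = wr0,
               knee = kn0, ankle = an0)
  sway_for <- function(role) {
    if (role %in% c("shoulder", "hip")) {
      cbind(stats::rnorm(n, sd = jitter_sd), stats::rnorm(n, sd = jitter_sd))
    } else if (params$sway_process == "gaussian_walk_reverting") {
      s <- params$sway_amplitude * t_len / sqrt(2)
      cbind(mean_reverting_walk(n, s), mean_reverting_walk(n, s))
    } else {
      a <- params$sway_amplitude * t_len
      ph <- stats::runif(1, 0, 2 * pi)
      tt <- 2 * pi * 0.25 * (seq_len(n) - 1) / params$fps + ph
      cbind(a * sin(tt), a * cos(tt)) +
        matrix(stats::rnorm(2 * n, sd = 0.05 * a), n, 2)
    }
  }
  roles <- c("shoulder", "hip", "elbow", "wrist", "knee", "ankle")
  clean_xy <- lapply(roles, function(r) {
    sweep(sway_for(r), 2, base[[r]], `+`)
  })
  names(clean_xy) <- roles

  xc <- sapply(clean_xy, function(m) m[, 1])
  yc <- sapply(clean_xy, function(m) m[, 2])
  colnames(xc) <- colnames(yc) <- unname(lm[roles])
  clean <- keypoint_trajectory(xc, yc, matrix(1, n, 6), fps = params$fps,
                               image_size = c(1280, 720))

  xn <- xc; yn <- yc
  vis <- matrix(0.9 + stats::runif(n * 6) * 0.1, n, 6)
  drop_mask <- matrix(stats::runif(n * 6) < params$dropout_prob, n, 6)
  if (any(drop_mask)) {
    vis[drop_mask] <- 0.1 + stats::runif(sum(drop_mask)) * 0.3
    xn[drop_mask] <- xn[drop_mask] + stats::rnorm(sum(drop_mask), sd = 0.3 * t_len)
    yn[drop_mask] <- yn[drop_mask] + stats::rnorm(sum(drop_mask), sd = 0.3 * t_len)
  }
  limb_cols <- match(unname(lm[c("elbow", "wrist", "knee", "ankle")]),
                     colnames(xc))
  spike_mask <- matrix(FALSE, n, 6)
  spike_mask[, limb_cols] <- stats::runif(n * 4) < params$outlier_prob
  if (any(spike_mask)) {
    ang <- stats::runif(sum(spike_mask), 0, 2 * pi)
    xn[spike_mask] <- xn[spike_mask] + params$outlier_magnitude_px * cos(ang)
    yn[spike_mask] <- yn[spike_mask] + params$outlier_magnitude_px * sin(ang)
  }
  noisy <- keypoint_trajectory(xn, yn, vis, fps = params$fps,
                               image_size = c(1280, 720))
  structure(list(trajectory = noisy, clean_trajectory = clean,
                 params = params),
            class = "simulated_trial")
}

#' @export
print.simulated_trial <- function(x, ...) {
  p <- x$params
  cat("<simulated_trial> ", x$trajectory$n_frames, " frames @ ", p$fps,
      " fps (", p$sway_process, ")\n", sep = "")
  cat(sprintf("  sway %.4f t/frame, droop %g deg, bend %g deg, dropout %g, outliers %g\n",
              p$sway_amplitude, p$droop_deg, p$bend_deg, p$dropout_prob,
              p$outlier_prob))
  invisible(x)
}

#' Simulate a cohort of scored trials
#'
#' Draws per-trial simulation parameters uniformly from the given ranges,
#' simulates each trial, computes its index report through the real
#' pipeline (denoise + indices), and then generates a clinician score as a
#' linear combination of the z-scored computed indices plus Gaussian
#' noise, clipped to the 7-point rating range \[1, 7\].
#'
#' @param n_trials Number of trials.
#' @param param_ranges Named list of `c(min, max)` ranges drawn uniformly
#'   per trial; defaults cover `sway_amplitude`, `droop_deg`, `bend_deg`
#'   and `duration_s`.
#' @param score_model List with `intercept` (default 4, the scale
#'   midpoint), `coef` (named coefficients on the z-scored indices;
#'   default `c(spb1 = -1, ag2 = -0.5)`: more sway and more droop both
#'   lower the rating) and `noise_sd` (default 0.5 rating points).
#' @param base_params A [simulation_params()] supplying everything not
#'   drawn from `param_ranges`; cohort trials default to clean measurement
#'   (no dropout, no spikes).
#' @param dn_params A [denoise_params()] used by the pipeline.
#' @param cohort Cohort label stored in the records (`"child"` or
#'   `"adult"`).
#' @param seed Optional integer seed.
#' @return Data frame of trial records: `trial_id`, `cohort`,
#'   `clinician_score`, the six indices and `duration_s`, plus the drawn
#'   `sway_amplitude`, `droop_deg`, `bend_deg` for reference.
#' @export
simulate_cohort <- function(n_trials,
                            param_ranges = list(
                              sway_amplitude = c(0.002, 0.02),
                              droop_deg = c(0, 35),
                              bend_deg = c(0, 25),
                              duration_s = c(10, 30)),
                            score_model = list(intercept = 4,
                                               coef = c(spb1 = -1, ag2 = -0.5),
                                               noise_sd = 0.5),
                            base_params = simulation_params(dropout_prob = 0,
                                                            outlier_prob = 0),
                            dn_params = denoise_params(),
                            cohort = "child",
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cols <- c("trial_id", "cohort", "clinician_score", "spb1", "spb2", "spb3",
            "ag1", "ag2", "ag3", "duration_s", "sway_amplitude",
            "droop_deg", "bend_deg")
  if (n_trials == 0) {
    df <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)),
                                        cols))
    df$trial_id <- character(0); df$cohort <- character(0)
    return(df)
  }
  rows <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    p <- unclass(base_params)
    for (nm in names(param_ranges)) {
      r <- param_ranges[[nm]]
      p[[nm]] <- stats::runif(1, r[1], r[2])
    }
    p$seed <- NULL
    trial <- simulate_trial(do.call(simulation_params, p))
    rep_ <- suppressWarnings(
      score_trial(trial$trajectory, p$side, params = dn_params))
    rows[[i]] <- data.frame(
      trial_id = sprintf("trial_%03d", i), cohort = cohort,
      clinician_score = NA_real_,
      spb1 = rep_$spb1, spb2 = rep_$spb2, spb3 = rep_$spb3,
      ag1 = rep_$ag1, ag2 = rep_$ag2, ag3 = rep_$ag3,
      duration_s = rep_$duration_s,
      sway_amplitude = p$sway_amplitude, droop_deg = p$droop_deg,
      bend_deg = p$bend_deg, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  lin <- rep(score_model$intercept %||% 4, n_trials)
  for (nm in names(score_model$coef)) {
    z <- as.numeric(scale(df[[nm]]))
    lin <- lin + score_model$coef[[nm]] * z
  }
  score <- lin + stats::rnorm(n_trials, sd = score_model$noise_sd %||% 0)
  df$clinician_score <- pmin(7, pmax(1, score))
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
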