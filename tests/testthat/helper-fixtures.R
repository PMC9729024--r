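# Fixture builders and coordinate transforms used across test files.

# task_keypoints built directly from per-frame coordinate matrices
make_task <- function(shoulder, hip, elbow, wrist, knee, ankle, fps = 30,
                      side = "left_arm_right_leg") {
  as_m <- function(p) {
    m <- if (is.null(dim(p))) matrix(p, ncol = 2, byrow = TRUE) else as.matrix(p)
    colnames(m) <- c("x", "y")
    m
  }
  sh <- as_m(shoulder); hp <- as_m(hip)
  structure(list(shoulder = sh, hip = hp, elbow = as_m(elbow),
                 wrist = as_m(wrist), knee = as_m(knee), ankle = as_m(ankle),
                 trunk_length = mean(sqrt(rowSums((sh - hp)^2))),
                 side = side, fps = fps, n_frames = nrow(sh),
                 k_index = c("1" = "elbow", "2" = "wrist",
                             "3" = "knee", "4" = "ankle")),
            class = "task_keypoints")
}

# ideal bird-dog posture (trunk horizontal, limbs extended level), repeated
make_ideal_task <- function(n = 10, t_len = 100, fps = 30) {
  rep_m <- function(p) matrix(rep(p, each = n), ncol = 2)
  sh <- c(300, 200); hp <- sh + c(t_len, 0)
  make_task(rep_m(sh), rep_m(hp),
            rep_m(sh + c(-60, 0)), rep_m(sh + c(-120, 0)),
            rep_m(hp + c(80, 0)), rep_m(hp + c(160, 0)), fps = fps)
}

# posture with given droop/bend angles (degrees), constant over frames
make_posture_task <- function(droop = 0, bend = 0, n = 10, t_len = 100,
                              fps = 30) {
  d <- droop * pi / 180; b <- (droop + bend) * pi / 180
  sh <- c(300, 200); hp <- sh + c(t_len, 0)
  el <- sh + 60 * c(-cos(d), sin(d)); wr <- el + 60 * c(-cos(b), sin(b))
  kn <- hp + 80 * c(cos(d), sin(d)); an <- kn + 80 * c(cos(b), sin(b))
  rep_m <- function(p) matrix(rep(p, each = n), ncol = 2)
  make_task(rep_m(sh), rep_m(hp), rep_m(el), rep_m(wr), rep_m(kn),
            rep_m(an), fps = fps)
}

# affine transform p -> A p + b applied to every landmark of a trajectory
transform_traj <- function(traj, A = diag(2), b = c(0, 0)) {
  keypoint_trajectory(A[1, 1] * traj$x + A[1, 2] * traj$y + b[1],
                      A[2, 1] * traj$x + A[2, 2] * traj$y + b[2],
                      traj$visibility, fps = traj$fps,
                      landmarks = traj$landmarks,
                      image_size = traj$image_size)
}

rot_mat <- function(deg) {
  r <- deg * pi / 180
  matrix(c(cos(r), sin(r), -sin(r), cos(r)), 2)
}

rotate_traj <- function(traj, deg, center = c(0, 0)) {
  A <- rot_mat(deg)
  transform_traj(traj, A, center - A %*% center)
}

# a small trajectory with all six task landmarks, constant coordinates
make_constant_traj <- function(n = 90, fps = 30, vis = NULL) {
  tr <- simulate_trial(simulation_params(
    sway_amplitude = 0, droop_deg = 10, bend_deg = 5, dropout_prob = 0,
    outlier_prob = 0, duration_s = n / fps, fps = fps, seed = 1))
  traj <- tr$trajectory
  if (!is.null(vis)) traj$visibility[] <- vis
  traj
}

quiet_score <- function(...) suppressWarnings(score_trial(...))
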