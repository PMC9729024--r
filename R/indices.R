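#' Trunk-normalised inter-frame moving distances
#'
#' For each of the four limb keypoints `k` (1 elbow, 2 wrist, 3 knee,
#' 4 ankle) computes the Euclidean displacement between consecutive frames
#' divided by the trunk length `t`, giving the dimensionless series
#' `d^k` of length `n - 1`, and the combined series `D` with
#' `D_i = sum_k d_i^k`.
#'
#' @param task A [resolve_task_keypoints()] result.
#' @return Object of class `moving_distances`: matrix `d` (`(n-1) x 4`,
#'   columns elbow/wrist/knee/ankle), vector `D`, and `trunk_length`.
#' @export
moving_distances <- function(task) {
  stopifnot(inherits(task, "task_keypoints"))
  t_len <- task$trunk_length
  d <- sapply(c("elbow", "wrist", "knee", "ankle"), function(k) {
    p <- task[[k]]
    sqrt(diff(p[, 1])^2 + diff(p[, 2])^2) / t_len
  })
  d <- matrix(d, ncol = 4,
              dimnames = list(NULL, c("elbow", "wrist", "knee", "ankle")))
  structure(list(d = d, D = rowSums(d), trunk_length = t_len),
            class = "moving_distances")
}

#' SPB1: mean trunk-normalised keypoint displacement
#'
#' The average of the moving-distance series over frames and over the four
#' limb keypoints: `SPB1 = (1/4) sum_k (1/(n-1)) sum_i d_i^k`.  Larger
#' values mean a less stable posture.
#'
#' @param md A [moving_distances()] result.
#' @return Non-negative scalar.
#' @export
spb1 <- function(md) {
  stopifnot(inherits(md, "moving_distances"))
  mean(colMeans(md$d))
}

#' SPB2: maximum combined displacement
#'
#' The maximum over frames of `D_i = sum_k d_i^k`; sensitive to the single
#' largest between-frame movement rather than the average sway.
#'
#' @param md A [moving_distances()] result.
#' @return Non-negative scalar; always at least `4 * spb1(md)`.
#' @export
spb2 <- function(md) {
  stopifnot(inherits(md, "moving_distances"))
  max(md$D)
}

shoelace_area <- function(pts) {
  # pts: m x 2 matrix of hull vertices in order
  m <- nrow(pts)
  if (m < 3) return(0)
  xs <- pts[, 1]; ys <- pts[, 2]
  abs(sum(xs * ys[c(2:m, 1)] - xs[c(2:m, 1)] * ys)) / 2
}

#' SPB3: convex-hull excursion area
#'
#' For each limb keypoint the area of the convex hull of its visited
#' positions is computed, normalised by the squared trunk length (so the
#' index is dimensionless and camera-distance invariant); SPB3 is the sum
#' of the four normalised areas divided by the number of frames `n`.
#' Keypoints whose positions are collinear or fewer than three distinct
#' points contribute zero area.
#'
#' Note the normalisation is a deliberate choice: only division by the
#' squared trunk length makes an area dimensionless, and scale invariance
#' of all indices is a design requirement here.  `normalization = "t"`
#' (area per trunk length, px) and `"none"` (raw px^2) are provided for
#' comparison with conventions that skip this step.
#'
#' @param task A [resolve_task_keypoints()] result.
#' @param normalization `"t2"` (default), `"t"` or `"none"`.
#' @return Non-negative scalar.
#' @export
spb3 <- function(task, normalization = c("t2", "t", "none")) {
  stopifnot(inherits(task, "task_keypoints"))
  normalization <- match.arg(normalization)
  t2 <- switch(normalization, t2 = task$trunk_length^2,
               t = task$trunk_length, none = 1)
  areas <- vapply(c("elbow", "wrist", "knee", "ankle"), function(k) {
    pts <- task[[k]]
    pts <- pts[stats::complete.cases(pts), , drop = FALSE]
    if (nrow(pts) < 3) return(0)
    h <- grDevices::chull(pts)
    shoelace_area(pts[h, , drop = FALSE])
  }, numeric(1))
  sum(areas / t2) / task$n_frames
}

angle_deg <- function(ux, uy, vx, vy) {
  nu <- sqrt(ux^2 + uy^2)
  nv <- sqrt(vx^2 + vy^2)
  cosang <- (ux * vx + uy * vy) / (nu * nv)
  cosang[nu == 0 | nv == 0] <- NA_real_
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Per-frame limb-droop angles against the image horizontal (for AG1)
#'
#' `theta1` is the unsigned angle, in \[0, 180\] degrees, between the vector
#' from the shoulder to the midpoint of elbow and wrist and the horizontal
#' image direction pointing away from the trunk (away from the hip for the
#' arm, away from the shoulder for the leg); `theta2` is the analogue at
#' the hip with the midpoint of knee and ankle.  A perfectly horizontal
#' extended limb gives 0.  Because the angle is unsigned, raising a limb
#' above the horizontal also increases it - the known weakness of AG1.
#'
#' @param task A [resolve_task_keypoints()] result.
#' @return Data frame with per-frame columns `theta1`, `theta2` (degrees;
#'   `NA` where the angle is undefined because the midpoint coincides with
#'   the shoulder/hip).
#' @export
ag1_angles <- function(task) {
  stopifnot(inherits(task, "task_keypoints"))
  sh <- task$shoulder; hp <- task$hip
  arm_dir <- sign(sh[, 1] - hp[, 1])
  overall <- sign(mean(sh[, 1] - hp[, 1]))
  arm_dir[arm_dir == 0] <- overall
  mid_arm <- (task$elbow + task$wrist) / 2
  mid_leg <- (task$knee + task$ankle) / 2
  theta1 <- angle_deg(arm_dir, 0, mid_arm[, 1] - sh[, 1], mid_arm[, 2] - sh[, 2])
  theta2 <- angle_deg(-arm_dir, 0, mid_leg[, 1] - hp[, 1], mid_leg[, 2] - hp[, 2])
  data.frame(theta1 = theta1, theta2 = theta2)
}

#' Per-frame trunk-referenced joint angles (for AG2/AG3)
#'
#' Four angles in \[0, 180\] degrees per frame: `phi1` between the trunk
#' line extended through the shoulder (direction hip to shoulder) and the
#' shoulder-to-elbow vector, clamped to 0 whenever the elbow is above the
#' shoulder (smaller image y); `phi2` the analogue at the hip with the
#' hip-to-knee vector, clamped when the knee is above the hip; `phi3`
#' between the shoulder-to-elbow direction extended through the elbow and
#' the elbow-to-wrist vector (elbow flexion, unclamped); `phi4` the
#' analogue for knee flexion.  Perfect trunk-aligned extension of both
#' limbs gives all zeros.
#'
#' @param task A [resolve_task_keypoints()] result.
#' @return Data frame with columns `phi1`..`phi4` and their per-frame sum
#'   `Phi` (degrees; `NA` where a segment has zero length).
#' @export
ag23_angles <- function(task) {
  stopifnot(inherits(task, "task_keypoints"))
  sh <- task$shoulder; hp <- task$hip
  el <- task$elbow; wr <- task$wrist; kn <- task$knee; an <- task$ankle
  phi1 <- angle_deg(sh[, 1] - hp[, 1], sh[, 2] - hp[, 2],
                    el[, 1] - sh[, 1], el[, 2] - sh[, 2])
  phi1[!is.na(phi1) & el[, 2] < sh[, 2]] <- 0
  phi2 <- angle_deg(hp[, 1] - sh[, 1], hp[, 2] - sh[, 2],
                    kn[, 1] - hp[, 1], kn[, 2] - hp[, 2])
  phi2[!is.na(phi2) & kn[, 2] < hp[, 2]] <- 0
  phi3 <- angle_deg(el[, 1] - sh[, 1], el[, 2] - sh[, 2],
                    wr[, 1] - el[, 1], wr[, 2] - el[, 2])
  phi4 <- angle_deg(kn[, 1] - hp[, 1], kn[, 2] - hp[, 2],
                    an[, 1] - kn[, 1], an[, 2] - kn[, 2])
  data.frame(phi1 = phi1, phi2 = phi2, phi3 = phi3, phi4 = phi4,
             Phi = phi1 + phi2 + phi3 + phi4)
}

mean_excluding_na <- function(v, what) {
  bad <- sum(is.na(v))
  if (bad > 0)
    warning(bad, " frame(s) with undefined ", what, " excluded")
  list(value = mean(v, na.rm = TRUE), frac_excluded = bad / length(v))
}

#' AG1: mean unsigned limb angle against the horizontal
#'
#' `AG1 = (1/n) sum_i (theta1_i + theta2_i)`, in degrees.  Frames with
#' undefined angles are excluded with a warning.
#'
#' @param task A [resolve_task_keypoints()] result.
#' @return Non-negative scalar (degrees).
#' @export
ag1 <- function(task) {
  th <- ag1_angles(task)
  mean_excluding_na(th$theta1 + th$theta2, "AG1 angles")$value
}

#' AG2 and AG3: mean and maximum summed trunk-referenced angles
#'
#' With `Phi_i = phi1_i + phi2_i + phi3_i + phi4_i` (see [ag23_angles()]),
#' `AG2 = (1/n) sum_i Phi_i` and `AG3 = max_i Phi_i`, in degrees.  Frames
#' with undefined angles are excluded from both with a warning.
#'
#' @param task A [resolve_task_keypoints()] result.
#' @return Non-negative scalar (degrees).
#' @export
ag2 <- function(task) {
  ph <- ag23_angles(task)
  mean_excluding_na(ph$Phi, "AG2 angles")$value
}

#' @rdname ag2
#' @export
ag3 <- function(task) {
  ph <- ag23_angles(task)
  v <- ph$Phi
  bad <- sum(is.na(v))
  if (bad > 0) warning(bad, " frame(s) with undefined AG3 angles excluded")
  max(v, na.rm = TRUE)
}

#' Compute the full index report for one trial
#'
#' Runs all six indices plus the trial duration on resolved task keypoints
#' (normally denoised first; see [denoise()]).  If more than 10% of frames
#' had undefined angles the report is marked unreliable.
#'
#' @param task A [resolve_task_keypoints()] result.
#' @param spb3_normalization Normalisation mode for [spb3()].
#' @return Object of class `index_report` with fields `side`, `spb1`,
#'   `spb2`, `spb3`, `ag1`, `ag2`, `ag3`, `duration_s`, `fps`, `n_frames`,
#'   `trunk_length`, `unreliable`.
#' @export
compute_index_report <- function(task, spb3_normalization = "t2") {
  stopifnot(inherits(task, "task_keypoints"))
  md <- moving_distances(task)
  th <- ag1_angles(task)
  ph <- ag23_angles(task)
  a1 <- mean_excluding_na(th$theta1 + th$theta2, "AG1 angles")
  a2 <- mean_excluding_na(ph$Phi, "AG2/AG3 angles")
  structure(list(
    side = task$side,
    spb1 = spb1(md), spb2 = spb2(md),
    spb3 = spb3(task, spb3_normalization),
    ag1 = a1$value, ag2 = a2$value,
    ag3 = max(ph$Phi, na.rm = TRUE),
    duration_s = min(task$n_frames / task$fps, 60),
    fps = task$fps, n_frames = task$n_frames,
    trunk_length = task$trunk_length,
    unreliable = max(a1$frac_excluded, a2$frac_excluded) > 0.1),
    class = "index_report")
}

#' @export
print.index_report <- function(x, ...) {
  cat("<index_report> side =", x$side,
      if (isTRUE(x$unreliable)) " [UNRELIABLE: >10% frames excluded]", "\n")
  cat(sprintf("  SPB1 %.6f  SPB2 %.6f  SPB3 %.6f\n", x$spb1, x$spb2, x$spb3))
  cat(sprintf("  AG1 %7.3f  AG2 %7.3f  AG3 %7.3f  (degrees)\n",
              x$ag1, x$ag2, x$ag3))
  cat(sprintf("  duration %.2f s (%d frames @ %g fps), trunk %.1f px\n",
              x$duration_s, x$n_frames, x$fps, x$trunk_length))
  invisible(x)
}

#' @export
as.data.frame.index_report <- function(x, ...) {
  data.frame(side = x$side, spb1 = x$spb1, spb2 = x$spb2, spb3 = x$spb3,
             ag1 = x$ag1, ag2 = x$ag2, ag3 = x$ag3,
             duration_s = x$duration_s, stringsAsFactors = FALSE)
}

#' Score a trial end to end
#'
#' Convenience wrapper: resolve the task landmarks, denoise (unless
#' `raw = TRUE`) and compute the index report.
#'
#' @param traj A [keypoint_trajectory()].
#' @param side Which arm is lifted (see [resolve_task_keypoints()]).
#' @param params A [denoise_params()].
#' @param raw If `TRUE`, skip denoising (diagnostics only).
#' @param t_mode Trunk-length convention (see [resolve_task_keypoints()]).
#' @param spb3_normalization Normalisation mode for [spb3()].
#' @return An `index_report`.
#' @export
score_trial <- function(traj, side, params = denoise_params(), raw = FALSE,
                        t_mode = "ipsilateral", spb3_normalization = "t2") {
  if (!raw) traj <- denoise(traj, params)
  compute_index_report(resolve_task_keypoints(traj, side, t_mode = t_mode),
                       spb3_normalization = spb3_normalization)
}

#' Write an index report to JSON or one-row CSV
#'
#' @param report An `index_report`.
#' @param path Output path; format chosen by extension (`.json` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_index_report <- function(report, path) {
  stopifnot(inherits(report, "index_report"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                         digits = 10)
  } else {
    utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  }
  invisible(path)
}
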